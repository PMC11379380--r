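# Reverse dosimetry: biomarker concentration -> estimated daily intake
# (EDI) of the parent compound, naphthalene.
#
# Two routes:
#   original route:    EDI = C_u * V_u * (MW_p / MW_m) / (f * BW)
#   creatinine route:  EDI = C_s * C_c * (MW_p / MW_m) / (f * 1000)
# with C_u the uncorrected urinary metabolite concentration (ug/L), C_s the
# creatinine-corrected concentration (ug/g creatinine), C_c the daily
# creatinine excretion per kg body weight (mg/kg-bw/day; the /1000 converts
# its mg of creatinine to g, cancelling C_s's per-gram basis). EDI is kept
# in ug/kg-bw/day throughout; conversion to mg happens only inside the
# cancer-risk formula.

#' Exposure parameters for reverse dosimetry and risk
#'
#' Point constants of the exposure model, with study defaults: daily urine
#' volume V_u = 2 L/day; urinary excretion fraction f = 1 (100%); molecular
#' weights 128.17 (naphthalene, parent) and 144.17 g/mol (2-OHNAP,
#' metabolite), so parent mass = metabolite mass x 128.17/144.17 by mole
#' conservation; daily creatinine excretion C_c = 23 (male) / 18 (female)
#' mg/kg-bw/day; oral reference dose RfD = 20 ug/kg-bw/day for naphthalene;
#' toxic equivalency factor TEF = 0.001 (naphthalene relative to
#' benzo\[a\]pyrene); cancer slope factor CSF = 7.3 (mg/kg-bw/day)^-1, the
#' standard B\[a\]P oral slope factor.
#'
#' @param v_u Urine volume excreted per day, L/day.
#' @param f Urinary excretion fraction of the metabolite, in (0, 1].
#' @param mw_parent Molecular weight of the parent compound, g/mol.
#' @param mw_metabolite Molecular weight of the metabolite, g/mol.
#' @param cc_male,cc_female Daily urinary creatinine excretion per body
#'   weight, mg/kg-bw/day.
#' @param rfd Reference dose, ug/kg-bw/day.
#' @param tef Toxic equivalency factor, dimensionless.
#' @param csf Cancer slope factor, (mg/kg-bw/day)^-1.
#' @return A list of class `exposure_params`.
#' @export
#' @examples
#' p <- exposure_params()
#' edi_original(20.38, p, bw = 67.1)
exposure_params <- function(v_u = 2, f = 1,
                            mw_parent = 128.17, mw_metabolite = 144.17,
                            cc_male = 23, cc_female = 18,
                            rfd = 20, tef = 0.001, csf = 7.3) {
  p <- list(v_u = v_u, f = f, mw_parent = mw_parent,
            mw_metabolite = mw_metabolite, cc_male = cc_male,
            cc_female = cc_female, rfd = rfd, tef = tef, csf = csf)
  for (nm in c("v_u", "f", "mw_parent", "mw_metabolite", "cc_male",
               "cc_female", "rfd")) {
    check_number(p[[nm]], nm, positive = TRUE)
  }
  check_number(p$tef, "tef", nonneg = TRUE)
  check_number(p$csf, "csf", nonneg = TRUE)
  if (p$f > 1) stop_param("`f` must lie in (0, 1]")
  structure(p, class = "exposure_params")
}

mw_ratio <- function(params) params$mw_parent / params$mw_metabolite

#' @export
print.exposure_params <- function(x, ...) {
  cat("Exposure parameters (naphthalene / 2-OHNAP)\n")
  cat(sprintf("  V_u = %g L/day, f = %g, MW ratio = %.4f (%.2f/%.2f)\n",
              x$v_u, x$f, mw_ratio(x), x$mw_parent, x$mw_metabolite))
  cat(sprintf("  C_c = %g (male) / %g (female) mg/kg-bw/day\n",
              x$cc_male, x$cc_female))
  cat(sprintf("  RfD = %g ug/kg-bw/day, TEF = %g, CSF = %g (mg/kg-bw/day)^-1\n",
              x$rfd, x$tef, x$csf))
  invisible(x)
}

#' EDI from uncorrected urinary concentration (original route)
#'
#' `EDI = c_u * v_u * (mw_parent / mw_metabolite) / (f * bw)`, in
#' ug/kg-bw/day.
#'
#' @param c_u Uncorrected urinary metabolite concentration, ug/L.
#'   Vectorised.
#' @param params An [exposure_params()] object.
#' @param bw Body weight, kg. Vectorised, recycled against `c_u`.
#' @return EDI in ug/kg-bw/day.
#' @export
edi_original <- function(c_u, params = exposure_params(), bw) {
  if (any(!is.finite(bw) | bw <= 0)) stop_param("`bw` must be > 0")
  if (any(is.finite(c_u) & c_u < 0)) stop_param("`c_u` must be >= 0")
  c_u * params$v_u * mw_ratio(params) / (params$f * bw)
}

#' EDI from creatinine-corrected concentration (creatinine route)
#'
#' `EDI = c_s * C_c(gender) * (mw_parent / mw_metabolite) / (f * 1000)`, in
#' ug/kg-bw/day. The division by 1000 converts C_c's milligrams of
#' creatinine per kg-bw to grams, cancelling `c_s`'s per-gram basis.
#'
#' @param c_s Creatinine-corrected urinary concentration, ug/g creatinine.
#'   Vectorised.
#' @param params An [exposure_params()] object.
#' @param gender `"male"` or `"female"`; vectorised, recycled against `c_s`.
#' @return EDI in ug/kg-bw/day.
#' @export
edi_creatinine <- function(c_s, params = exposure_params(), gender) {
  if (any(!gender %in% c("male", "female"))) {
    stop_param("`gender` must be 'male' or 'female'")
  }
  if (any(is.finite(c_s) & c_s < 0)) stop_param("`c_s` must be >= 0")
  cc <- ifelse(gender == "male", params$cc_male, params$cc_female)
  c_s * cc * mw_ratio(params) / (params$f * 1000)
}

#' Convert per-kg EDI to mass per day
#'
#' @param per_kg EDI in ug/kg-bw/day. Vectorised.
#' @param bw Body weight, kg.
#' @return Intake in ug/day.
#' @export
edi_mass_per_day <- function(per_kg, bw) {
  if (any(!is.finite(bw) | bw <= 0)) stop_param("`bw` must be > 0")
  per_kg * bw
}
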