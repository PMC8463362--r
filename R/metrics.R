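#' CTA-index (relative thrombus attenuation)
#'
#' The asymmetry index `(hu_t - hu_c) / (hu_t + hu_c)` of the occlusion-site
#' mean attenuation against the contralateral reference, both measured on
#' the arterial-phase CTA. For positive inputs it lies in the open interval
#' (-1, 1); an occluded vessel (hu_t well below hu_c) gives values towards
#' -1.
#'
#' @param hu_t mean HU at the occlusion site (T) on CTA.
#' @param hu_c mean HU at the contralateral position (C) on CTA.
#' @return the index, a dimensionless real.
#' @examples
#' cta_index(60, 180)   # -0.5
#' @export
cta_index <- function(hu_t, hu_c) {
  if (!is.finite(hu_t) || !is.finite(hu_c)) {
    perv_error("attenuation values must be finite", "perv_metric_error")
  }
  if (hu_t + hu_c <= 0) {
    perv_error(
      "non-physical attenuation pair: hu_t + hu_c must be positive on contrast-bearing vessels",
      "perv_metric_error")
  }
  (hu_t - hu_c) / (hu_t + hu_c)
}

#' Attenuation increase between CTA and NCCT
#'
#' `hu_cta - hu_ncct` at one site; at the thrombus this is the perviousness
#' signal (contrast that penetrated the clot), at the contralateral artery
#' it is the full arterial enhancement. Negative values (possible under
#' noise) are returned unchanged; flagging is handled by
#' [compute_result()].
#'
#' @param hu_cta,hu_ncct mean HU of the same site on CTA and NCCT.
#' @return HU difference.
#' @export
delta_attenuation <- function(hu_cta, hu_ncct) {
  if (!is.finite(hu_cta) || !is.finite(hu_ncct)) {
    perv_error("attenuation values must be finite", "perv_metric_error")
  }
  hu_cta - hu_ncct
}

#' Void fraction
#'
#' The thrombus attenuation increase normalized by the contralateral
#' arterial enhancement, `delta_t / delta_c`: the fraction of full contrast
#' opacification reaching the clot (0 = impermeable, 1 = fully pervious).
#'
#' @param delta_t thrombus attenuation increase, HU.
#' @param delta_c contralateral enhancement, HU (must be > 0).
#' @return dimensionless fraction.
#' @export
void_fraction <- function(delta_t, delta_c) {
  if (!is.finite(delta_t) || !is.finite(delta_c)) {
    perv_error("delta values must be finite", "perv_metric_error")
  }
  if (delta_c <= 0) {
    perv_error(
      "no contralateral enhancement: delta_c must be positive (the reference artery must enhance)",
      "perv_metric_error")
  }
  delta_t / delta_c
}

#' Assemble a perviousness result from four attenuation samples
#'
#' @param samples either a `perv_measurement` or a named list with elements
#'   `cta_t`, `cta_c`, `ncct_t`, `ncct_c`, each an `attenuation_sample` or a
#'   bare number (mean HU).
#' @return list of class `perviousness_result` with fields `hu_t_cta`,
#'   `hu_c_cta`, `hu_t_ncct`, `hu_c_ncct`, `delta_t`, `delta_c`,
#'   `void_fraction`, `cta_index` and a character vector `flags`
#'   (`"negative_uptake"` when `delta_t < 0`).
#' @export
compute_result <- function(samples) {
  if (inherits(samples, "perv_measurement")) samples <- samples$samples
  need <- c("cta_t", "cta_c", "ncct_t", "ncct_c")
  missing <- setdiff(need, names(samples))
  if (length(missing)) {
    lab <- vapply(strsplit(missing, "_"), function(p) {
      sprintf("(%s, %s)", toupper(p[1]), toupper(p[2]))
    }, character(1))
    perv_error(sprintf("missing attenuation sample(s): %s",
                       paste(lab, collapse = ", ")),
               "perv_metric_error")
  }
  hu <- function(x) if (is.list(x)) x$mean_hu else as.numeric(x)
  hu_t_cta <- hu(samples$cta_t); hu_c_cta <- hu(samples$cta_c)
  hu_t_ncct <- hu(samples$ncct_t); hu_c_ncct <- hu(samples$ncct_c)
  delta_t <- delta_attenuation(hu_t_cta, hu_t_ncct)
  delta_c <- delta_attenuation(hu_c_cta, hu_c_ncct)
  flags <- character(0)
  if (delta_t < 0) flags <- c(flags, "negative_uptake")
  structure(list(
    hu_t_cta = hu_t_cta, hu_c_cta = hu_c_cta,
    hu_t_ncct = hu_t_ncct, hu_c_ncct = hu_c_ncct,
    delta_t = delta_t, delta_c = delta_c,
    void_fraction = void_fraction(delta_t, delta_c),
    cta_index = cta_index(hu_t_cta, hu_c_cta),
    flags = flags), class = "perviousness_result")
}

#' @export
print.perviousness_result <- function(x, ...) {
  cat(sprintf(
    paste0("perviousness_result:\n",
           "  HU_T: CTA %.1f / NCCT %.1f   HU_C: CTA %.1f / NCCT %.1f\n",
           "  delta_t %.1f HU  delta_c %.1f HU\n",
           "  void fraction %.4f   CTA-index %.4f\n"),
    x$hu_t_cta, x$hu_t_ncct, x$hu_c_cta, x$hu_c_ncct,
    x$delta_t, x$delta_c, x$void_fraction, x$cta_index))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
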