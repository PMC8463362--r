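#' Cohort simulation specification
#'
#' Parameters of the simulated stroke cohorts. Two presets mirror the two
#' study cohorts whose CTA-index group statistics are printed:
#' `"validation"` (default; favorable n = 30 ~ Normal(-0.52, 0.13),
#' non-favorable n = 51 ~ Normal(-0.70, 0.09), 6 records without a 90-day
#' mRS for a total of 87) and `"perviousness"` (favorable n = 23 ~
#' Normal(-0.55, 0.16), non-favorable n = 28 ~ Normal(-0.64, 0.14), 50
#' records without mRS, total 101). Covariates are drawn from marginal
#' models matched to the published medians/IQRs and category frequencies;
#' couplings between covariates and outcome are not simulated.
#'
#' @param preset `"validation"` or `"perviousness"`.
#' @param n_favorable,n_nonfavorable group sizes (mRS <= 2 / mRS > 2).
#' @param n_missing_mrs records drawn from the group mixture with missing
#'   90-day mRS.
#' @param mean_fav,sd_fav,mean_nonfav,sd_nonfav CTA-index normal parameters
#'   per outcome group (draws are rejected outside the open interval
#'   (-1, 1), the mathematical range of the index).
#' @param age_median,age_iqr,sex_p_female,mtici_probs,proctime_median,
#'   proctime_iqr,slice_values,slice_probs,nihss_pre_median,nihss_pre_iqr,
#'   nihss_post_median,nihss_post_iqr covariate marginals; IQRs as 2-vectors.
#' @param rater_noise_sd default per-rater measurement noise SD in index
#'   units for [generate_rater_pairs()].
#' @param seed integer seed stored with the spec.
#' @return object of class `cohort_sim_spec`.
#' @export
cohort_sim_spec <- function(preset = c("validation", "perviousness"),
                            n_favorable = NULL, n_nonfavorable = NULL,
                            n_missing_mrs = NULL,
                            mean_fav = NULL, sd_fav = NULL,
                            mean_nonfav = NULL, sd_nonfav = NULL,
                            age_median = NULL, age_iqr = NULL,
                            sex_p_female = NULL,
                            mtici_probs = NULL,
                            proctime_median = NULL, proctime_iqr = NULL,
                            slice_values = c(0.6, 1.0, 2.0, 3.0),
                            slice_probs = c(0.6, 0.2, 0.1, 0.1),
                            nihss_pre_median = NULL, nihss_pre_iqr = NULL,
                            nihss_post_median = NULL, nihss_post_iqr = NULL,
                            rater_noise_sd = 0.058,
                            seed = 1L) {
  preset <- match.arg(preset)
  def <- if (preset == "validation") {
    list(n_favorable = 30L, n_nonfavorable = 51L, n_missing_mrs = 6L,
         mean_fav = -0.52, sd_fav = 0.13, mean_nonfav = -0.70, sd_nonfav = 0.09,
         age_median = 77, age_iqr = c(69, 84), sex_p_female = 53 / 87,
         mtici_probs = c(`0` = 6, `1` = 1, `2a` = 2, `2b` = 25, `3` = 52) / 86,
         proctime_median = 31, proctime_iqr = c(21, 62),
         nihss_pre_median = 13, nihss_pre_iqr = c(7, 18),
         nihss_post_median = 5, nihss_post_iqr = c(1, 13))
  } else {
    list(n_favorable = 23L, n_nonfavorable = 28L, n_missing_mrs = 50L,
         mean_fav = -0.55, sd_fav = 0.16, mean_nonfav = -0.64, sd_nonfav = 0.14,
         age_median = 78, age_iqr = c(71, 86), sex_p_female = 49 / 101,
         mtici_probs = c(`0` = 12, `1` = 1, `2a` = 5, `2b` = 33, `3` = 50) / 101,
         proctime_median = 35, proctime_iqr = c(22, 49.5),
         nihss_pre_median = 14, nihss_pre_iqr = c(10, 18),
         nihss_post_median = 6, nihss_post_iqr = c(1, 12))
  }
  spec <- list(
    preset = preset,
    n_favorable = n_favorable %||% def$n_favorable,
    n_nonfavorable = n_nonfavorable %||% def$n_nonfavorable,
    n_missing_mrs = n_missing_mrs %||% def$n_missing_mrs,
    mean_fav = mean_fav %||% def$mean_fav,
    sd_fav = sd_fav %||% def$sd_fav,
    mean_nonfav = mean_nonfav %||% def$mean_nonfav,
    sd_nonfav = sd_nonfav %||% def$sd_nonfav,
    age_median = age_median %||% def$age_median,
    age_iqr = age_iqr %||% def$age_iqr,
    sex_p_female = sex_p_female %||% def$sex_p_female,
    mtici_probs = mtici_probs %||% def$mtici_probs,
    proctime_median = proctime_median %||% def$proctime_median,
    proctime_iqr = proctime_iqr %||% def$proctime_iqr,
    slice_values = slice_values, slice_probs = slice_probs,
    nihss_pre_median = nihss_pre_median %||% def$nihss_pre_median,
    nihss_pre_iqr = nihss_pre_iqr %||% def$nihss_pre_iqr,
    nihss_post_median = nihss_post_median %||% def$nihss_post_median,
    nihss_post_iqr = nihss_post_iqr %||% def$nihss_post_iqr,
    rater_noise_sd = rater_noise_sd,
    seed = seed)
  if (spec$n_favorable <= 0 || spec$n_nonfavorable <= 0 ||
      spec$n_missing_mrs < 0) {
    perv_error("group counts must be positive (missing-mRS count >= 0)",
               "perv_input_error")
  }
  if (spec$sd_fav < 0 || spec$sd_nonfav < 0) {
    perv_error("group SDs must be >= 0", "perv_input_error")
  }
  if (spec$rater_noise_sd < 0) {
    perv_error("rater_noise_sd must be >= 0", "perv_input_error")
  }
  class(spec) <- "cohort_sim_spec"
  spec
}

# IQR width of a normal = 2 * qnorm(0.75) * sd = 1.349 sd
iqr_to_sd <- function(iqr) diff(iqr) / (2 * stats::qnorm(0.75))

# CTA-index draws truncated to the open interval (-1, 1) by rejection
rtrunc_index <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= -1 | out >= 1)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= -1 | out[bad] >= 1]
  }
  out
}

#' Simulate a patient cohort
#'
#' Draws one record per patient: a CTA-index from the outcome-group normal
#' distribution (truncated to (-1, 1)), covariates from the preset marginal
#' models, and a 90-day mRS consistent with the group (0-2 favorable, 3-6
#' non-favorable, NA for the missing-mRS fraction). Deterministic under the
#' spec's seed.
#'
#' @param spec a `cohort_sim_spec`.
#' @return data.frame with columns `id`, `cta_index`, `age`, `sex`,
#'   `slice_thickness_mm`, `mtici`, `procedure_time_min`, `nihss_pre`,
#'   `nihss_post`, `mrs90`, `occlusion_site`, `residual_flow`.
#' @export
generate_cohort <- function(spec = cohort_sim_spec()) {
  if (!inherits(spec, "cohort_sim_spec")) {
    perv_error("spec must be a cohort_sim_spec", "perv_input_error")
  }
  with_seed(spec$seed, {
    n_f <- spec$n_favorable; n_n <- spec$n_nonfavorable; n_m <- spec$n_missing_mrs
    n <- n_f + n_n + n_m
    p_fav <- n_f / (n_f + n_n)
    grp <- c(rep("favorable", n_f), rep("nonfavorable", n_n),
             sample(c("favorable", "nonfavorable"), n_m, replace = TRUE,
                    prob = c(p_fav, 1 - p_fav)))
    idx <- grp == "favorable"
    cta <- numeric(n)
    cta[idx] <- rtrunc_index(sum(idx), spec$mean_fav, spec$sd_fav)
    cta[!idx] <- rtrunc_index(sum(!idx), spec$mean_nonfav, spec$sd_nonfav)
    mrs <- integer(n)
    mrs[idx] <- sample(0:2, sum(idx), replace = TRUE)
    mrs[!idx] <- sample(3:6, sum(!idx), replace = TRUE)
    mrs[seq_len(n) > n_f + n_n] <- NA_integer_
    age <- round(pmin(pmax(stats::rnorm(
      n, spec$age_median, iqr_to_sd(spec$age_iqr)), 18), 100))
    sex <- sample(c("F", "M"), n, replace = TRUE,
                  prob = c(spec$sex_p_female, 1 - spec$sex_p_female))
    mtici <- sample(names(spec$mtici_probs), n, replace = TRUE,
                    prob = spec$mtici_probs)
    proct <- round(stats::rlnorm(
      n, meanlog = log(spec$proctime_median),
      sdlog = iqr_to_sd(log(spec$proctime_iqr))))
    slice <- sample(spec$slice_values, n, replace = TRUE,
                    prob = spec$slice_probs)
    nihss_pre <- round(pmin(pmax(stats::rnorm(
      n, spec$nihss_pre_median, iqr_to_sd(spec$nihss_pre_iqr)), 0), 42))
    nihss_post <- round(pmin(pmax(stats::rnorm(
      n, spec$nihss_post_median, iqr_to_sd(spec$nihss_post_iqr)), 0), 42))
    site <- sample(c("M1", "proximal_M2"), n, replace = TRUE,
                   prob = c(0.8, 0.2))
    data.frame(
      id = sprintf("P%03d", seq_len(n)),
      cta_index = cta, age = age, sex = sex,
      slice_thickness_mm = slice, mtici = mtici,
      procedure_time_min = proct,
      nihss_pre = nihss_pre, nihss_post = nihss_post,
      mrs90 = mrs, occlusion_site = site, residual_flow = FALSE,
      stringsAsFactors = FALSE)
  })
}

#' Simulate paired two-rater measurements
#'
#' Each rater's value is the record's true CTA-index plus independent
#' Gaussian measurement noise, emulating two readers independently placing
#' ROIs on the same scans.
#'
#' @param records data.frame with columns `id` and `cta_index`.
#' @param rater_noise_sd per-rater noise SD (index units, >= 0).
#' @param seed integer seed.
#' @return data.frame with columns `id`, `rater1`, `rater2`.
#' @export
generate_rater_pairs <- function(records, rater_noise_sd = 0.058, seed = 1L) {
  if (rater_noise_sd < 0) {
    perv_error("rater_noise_sd must be >= 0", "perv_input_error")
  }
  if (is.null(records$cta_index)) {
    perv_error("records must carry a cta_index column", "perv_schema_error")
  }
  n <- nrow(records)
  with_seed(seed, {
    data.frame(
      id = records$id %||% sprintf("P%03d", seq_len(n)),
      rater1 = records$cta_index + stats::rnorm(n, sd = rater_noise_sd),
      rater2 = records$cta_index + stats::rnorm(n, sd = rater_noise_sd),
      stringsAsFactors = FALSE)
  })
}
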