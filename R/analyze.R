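# Cohort-level orchestration of the statistical battery.

cohort_required_cols <- c("cta_index", "age", "sex", "slice_thickness_mm",
                          "mtici", "procedure_time_min", "nihss_post")

# mTICI grade -> numeric coding
mtici_numeric <- function(mtici, coding = c("ordinal", "binary")) {
  coding <- match.arg(coding)
  lv <- c("0" = 0, "1" = 1, "2a" = 2, "2b" = 3, "3" = 4)
  g <- as.character(mtici)
  if (any(!g %in% names(lv))) {
    perv_error(sprintf("unknown mTICI grade(s): %s",
                       paste(unique(g[!g %in% names(lv)]), collapse = ", ")),
               "perv_schema_error")
  }
  v <- unname(lv[g])
  if (coding == "binary") as.numeric(v >= 3) else v
}

#' Run the full cohort statistical battery
#'
#' Executes every applicable analysis: per-outcome-group summaries and the
#' Wilcoxon rank-sum comparison of the CTA-index; covariate-adjusted
#' logistic regression of favorable 90-day outcome (mRS <= 2) on the
#' CTA-index; Spearman correlation between the covariate-residualized
#' CTA-index and discharge NIHSS; partial correlation of CTA-index with
#' mTICI controlling age and slice thickness; and, when rater pairs are
#' supplied, the two-rater ICC(2,1). Analyses whose preconditions fail are
#' skipped with a recorded reason rather than aborting the report. Records
#' with missing 90-day mRS are excluded listwise from the outcome analyses
#' only.
#'
#' @param records cohort data.frame (schema of [generate_cohort()]).
#' @param rater_pairs optional data.frame with columns `rater1`, `rater2`.
#' @param config list of options: `alpha` (default 0.05), `mtici_coding`
#'   (`"ordinal"` maps 0,1,2a,2b,3 to 0..4; `"binary"` codes success as
#'   mTICI >= 2b), `min_group` (minimum records per outcome group for the
#'   outcome analyses, default 5).
#' @return list of class `stats_report`: `group_summaries`, `wilcoxon`,
#'   `logistic`, `spearman_residual`, `partial_corr`, `icc`, `skipped`
#'   (named character vector of reasons), `config`.
#' @export
analyze_cohort <- function(records, rater_pairs = NULL, config = list()) {
  cfg <- utils::modifyList(
    list(alpha = 0.05, mtici_coding = "ordinal", min_group = 5L), config)
  missing_cols <- setdiff(cohort_required_cols, names(records))
  if (length(missing_cols)) {
    perv_error(sprintf("cohort table lacks required column(s): %s",
                       paste(missing_cols, collapse = ", ")),
               "perv_schema_error")
  }
  skipped <- character(0)
  report <- list()

  covars <- data.frame(
    age = records$age,
    sex = as.numeric(records$sex == "M"),
    slice_thickness_mm = records$slice_thickness_mm,
    mtici = mtici_numeric(records$mtici, cfg$mtici_coding),
    procedure_time_min = records$procedure_time_min)

  has_mrs <- "mrs90" %in% names(records) && any(!is.na(records$mrs90))
  if (has_mrs) {
    keep <- !is.na(records$mrs90)
    fav <- records$mrs90[keep] <= 2
    idx_f <- records$cta_index[keep][fav]
    idx_n <- records$cta_index[keep][!fav]
    report$group_summaries <- data.frame(
      group = c("favorable", "nonfavorable"),
      n = c(length(idx_f), length(idx_n)),
      mean = c(mean(idx_f), mean(idx_n)),
      sd = c(stats::sd(idx_f), stats::sd(idx_n)))
    if (length(idx_f) >= cfg$min_group && length(idx_n) >= cfg$min_group) {
      report$wilcoxon <- mann_whitney(idx_f, idx_n)
      report$logistic <- tryCatch(
        logistic_fit(fav, cbind(cta_index = records$cta_index[keep],
                                covars[keep, ])),
        perv_error = function(e) {
          skipped <<- c(skipped, logistic = conditionMessage(e)); NULL
        })
    } else {
      skipped <- c(skipped,
                   wilcoxon = "fewer than min_group records per outcome group",
                   logistic = "fewer than min_group records per outcome group")
    }
  } else {
    skipped <- c(skipped,
                 wilcoxon = "no mrs90 outcomes available",
                 logistic = "no mrs90 outcomes available")
  }

  report$spearman_residual <- tryCatch({
    resid <- ols_residuals(records$cta_index, covars)
    spearman_corr(resid, records$nihss_post)
  }, perv_error = function(e) {
    skipped <<- c(skipped, spearman_residual = conditionMessage(e)); NULL
  })

  report$partial_corr <- tryCatch(
    partial_corr(records$cta_index, covars$mtici,
                 data.frame(age = covars$age,
                            slice_thickness_mm = covars$slice_thickness_mm)),
    perv_error = function(e) {
      skipped <<- c(skipped, partial_corr = conditionMessage(e)); NULL
    })

  if (!is.null(rater_pairs)) {
    report$icc <- tryCatch(
      icc_two_way(rater_pairs[, c("rater1", "rater2")], alpha = cfg$alpha),
      perv_error = function(e) {
        skipped <<- c(skipped, icc = conditionMessage(e)); NULL
      })
  } else {
    skipped <- c(skipped, icc = "no rater pairs supplied")
  }

  report$skipped <- skipped
  report$config <- cfg
  class(report) <- "stats_report"
  report
}

#' Human-readable summary of a stats report
#' @param report a `stats_report`.
#' @return character vector of lines.
#' @export
format_stats_report <- function(report) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("Cohort statistical report")
  if (!is.null(report$group_summaries)) {
    g <- report$group_summaries
    for (i in seq_len(nrow(g))) {
      add("  %-13s n = %2d  CTA-index %.3f +/- %.3f",
          g$group[i], g$n[i], g$mean[i], g$sd[i])
    }
  }
  if (!is.null(report$wilcoxon)) {
    add("  Wilcoxon rank-sum: U = %.1f, p = %.4g (%s)",
        report$wilcoxon$U, report$wilcoxon$p, report$wilcoxon$method)
  }
  if (!is.null(report$logistic)) {
    co <- report$logistic$coefficients
    i <- which(co$term == "cta_index")
    add("  Logistic (favorable ~ CTA-index + covariates): beta = %.3f, Wald p = %.4g, Nagelkerke R2 = %.3f",
        co$estimate[i], co$p[i], report$logistic$r2_nagelkerke)
  }
  if (!is.null(report$spearman_residual)) {
    add("  Spearman (residual CTA-index vs NIHSS discharge): r = %.3f, p = %.4g",
        report$spearman_residual$r, report$spearman_residual$p)
  }
  if (!is.null(report$partial_corr)) {
    add("  Partial corr (CTA-index vs mTICI | age, slice): r = %.3f, p = %.4g",
        report$partial_corr$r, report$partial_corr$p)
  }
  if (!is.null(report$icc)) {
    add("  %s: %.3f [%.3f, %.3f]", report$icc$model, report$icc$icc,
        report$icc$ci_low, report$icc$ci_high)
  }
  if (length(report$skipped)) {
    add("  Skipped: %s",
        paste(sprintf("%s (%s)", names(report$skipped), report$skipped),
              collapse = "; "))
  }
  ln
}

#' @export
print.stats_report <- function(x, ...) {
  cat(format_stats_report(x), sep = "\n")
  invisible(x)
}
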