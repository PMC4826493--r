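#' Bland-Altman agreement analysis
#'
#' Differences are automated minus manual.  Reports the mean difference,
#' the sample standard deviation (n - 1 denominator) and the 95% limits of
#' agreement, mean +/- 1.96 SD.  Outliers are excluded only when the
#' caller names them by case id (no automatic rule).
#'
#' @param manual,automated paired numeric vectors.
#' @param case_ids optional ids; default seq_along.
#' @param exclude case ids excluded before computing the statistics.
#' @return `bland_altman` list: `mean_difference`, `sd_difference`,
#'   `limits` (lower, upper), `n`, `excluded`.
#' @export
bland_altman <- function(manual, automated, case_ids = seq_along(manual),
                         exclude = NULL) {
  if (length(manual) != length(automated))
    stop("manual and automated must have equal length")
  keep <- !(case_ids %in% exclude)
  m <- manual[keep]; a <- automated[keep]
  if (length(m) < 2) stop("need at least 2 pairs for agreement statistics")
  d <- a - m
  dbar <- mean(d)
  sdd <- sd(d)
  structure(list(mean_difference = dbar, sd_difference = sdd,
                 limits = c(lower = dbar - 1.96 * sdd,
                            upper = dbar + 1.96 * sdd),
                 n = length(d), excluded = case_ids[!keep]),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d, mean difference %.4g, 95%% limits [%.4g, %.4g]\n",
    x$n, x$mean_difference, x$limits[1], x$limits[2]))
  if (length(x$excluded)) cat("  excluded:", toString(x$excluded), "\n")
  invisible(x)
}

#' 2x2 detection contingency table
#'
#' Cross-classifies cases by manual {0, >=1} x automated {0, >=1} counts
#' with cell percentages of the total and the marginals.
#'
#' @param manual,automated non-negative integer count vectors.
#' @return `detection_table` list: `counts` (2x2, rows = manual),
#'   `percent` (rounded as conventionally printed), `row_margins`,
#'   `col_margins`, `n`.
#' @export
detection_table <- function(manual, automated) {
  if (length(manual) != length(automated))
    stop("manual and automated must have equal length")
  if (any(manual < 0) || any(automated < 0))
    stop("counts must be non-negative")
  mpos <- manual >= 1
  apos <- automated >= 1
  counts <- matrix(c(sum(!mpos & !apos), sum(!mpos & apos),
                     sum(mpos & !apos), sum(mpos & apos)),
                   2, 2, byrow = TRUE,
                   dimnames = list(manual = c("count0", "count1plus"),
                                   automated = c("count0", "count1plus")))
  n <- length(manual)
  structure(list(counts = counts,
                 percent = round(100 * counts / n),
                 row_margins = rowSums(counts),
                 col_margins = colSums(counts), n = n),
            class = "detection_table")
}

#' @export
print.detection_table <- function(x, ...) {
  cat("<detection_table> n =", x$n, "\n")
  print(x$counts)
  invisible(x)
}

#' Tally hot-spot overlap categories
#'
#' @param results list of `overlap_result` objects (or a character vector
#'   of categories).
#' @return data.frame with `category`, `count`, `percent`.
#' @export
overlap_tally <- function(results) {
  cats <- c("PERFECT", "MAYOR", "MINOR", "NONE")
  lab <- if (is.character(results)) results
         else vapply(results, function(r) r$category, character(1))
  counts <- vapply(cats, function(cc) sum(lab == cc), integer(1))
  n <- length(lab)
  data.frame(category = cats, count = unname(counts),
             percent = if (n > 0) unname(100 * counts / n) else rep(0, 4))
}

#' Diagnostic performance of a dichotomized index
#'
#' A case tests positive when its value is at or above the cut-off.
#' Sensitivity, specificity, PPV and NPV come from the resulting 2x2 with
#' exact (Clopper-Pearson) binomial 95% confidence intervals; the ROC area
#' is the rank-based probability that a random positive-outcome case has a
#' higher value than a random negative one, ties counting one half
#' (equivalent to the Mann-Whitney statistic).
#'
#' @param values numeric test values (e.g. hot-spot counts).
#' @param outcome binary outcome (logical or 0/1), e.g. disease
#'   recurrence.
#' @param cutoff test-positivity cut-off.
#' @return `diagnostic_performance` list with percentages, 95% CIs, and
#'   `roc_area` (flagged `NA` when only one outcome class is present;
#'   PPV/NPV are `NA` when their denominator is 0).
#' @export
diagnostic_performance <- function(values, outcome, cutoff) {
  outcome <- as.logical(outcome)
  if (length(values) != length(outcome)) stop("length mismatch")
  test_pos <- values >= cutoff
  tp <- sum(test_pos & outcome); fn <- sum(!test_pos & outcome)
  fp <- sum(test_pos & !outcome); tn <- sum(!test_pos & !outcome)
  prop <- function(x, n) {
    if (n == 0) return(list(est = NA_real_, ci = c(NA_real_, NA_real_)))
    bt <- binom.test(x, n)
    list(est = 100 * x / n, ci = 100 * as.numeric(bt$conf.int))
  }
  sens <- prop(tp, tp + fn); spec <- prop(tn, tn + fp)
  ppv <- prop(tp, tp + fp); npv <- prop(tn, tn + fn)
  n1 <- sum(outcome); n0 <- sum(!outcome)
  roc <- if (n1 == 0 || n0 == 0) NA_real_ else {
    r <- rank(values)   # midranks handle ties as 1/2
    (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  structure(list(
    table = matrix(c(tp, fp, fn, tn), 2, 2,
                   dimnames = list(test = c("positive", "negative"),
                                   outcome = c("event", "no_event"))),
    sensitivity = sens$est, sensitivity_ci = sens$ci,
    specificity = spec$est, specificity_ci = spec$ci,
    ppv = ppv$est, ppv_ci = ppv$ci,
    npv = npv$est, npv_ci = npv$ci,
    roc_area = roc, cutoff = cutoff,
    roc_defined = !(n1 == 0 || n0 == 0)),
    class = "diagnostic_performance")
}

#' @export
print.diagnostic_performance <- function(x, ...) {
  cat(sprintf("<diagnostic_performance> cutoff >= %g\n", x$cutoff))
  cat(sprintf("  sensitivity %.3g%%  specificity %.3g%%  ROC area %.3g\n",
              x$sensitivity, x$specificity, x$roc_area))
  cat(sprintf("  PPV %.3g%%  NPV %.3g%%\n", x$ppv, x$npv))
  invisible(x)
}
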