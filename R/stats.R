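#' Kolmogorov-Smirnov normality screen
#'
#' Computes `D = max_x |ECDF(x) - F(x)|` against a normal reference
#' parameterized by the sample mean and standard deviation. The default
#' `"ks"` mode takes the p-value from the Kolmogorov distribution as if the
#' reference were fully specified (the screening convention this pipeline
#' reproduces); because the parameters are estimated from the same sample
#' this p-value is conservative (the Lilliefors problem), so a corrected
#' `"lilliefors"` mode is also provided.
#'
#' @param sample Numeric vector, length >= 5.
#' @param mode `"ks"` (plain KS against the fitted normal) or
#'   `"lilliefors"`.
#' @return A `test_result` list: `statistic` (D), `p_value`, `n1`, `n2`
#'   (NA), `method`, `degenerate` flag.
#' @export
ks_normality <- function(sample, mode = c("ks", "lilliefors")) {
  mode <- match.arg(mode)
  sample <- as.numeric(sample)
  if (length(sample) < 5) stop("need at least 5 observations")
  if (stats::sd(sample) < 1e-12) {
    warning("zero-variance sample: normality test is degenerate")
    return(.test_result(1, 0, length(sample), NA_integer_,
                        "degenerate", degenerate = TRUE))
  }
  if (mode == "ks") {
    res <- suppressWarnings(
      stats::ks.test(sample, "pnorm", mean(sample), stats::sd(sample)))
    .test_result(unname(res$statistic), res$p.value, length(sample),
                 NA_integer_, "ks-fitted-normal")
  } else {
    res <- nortest::lillie.test(sample)
    .test_result(unname(res$statistic), res$p.value, length(sample),
                 NA_integer_, "lilliefors")
  }
}

.test_result <- function(statistic, p_value, n1, n2, method,
                         degenerate = FALSE) {
  structure(list(statistic = statistic, p_value = p_value,
                 n1 = n1, n2 = n2, method = method, degenerate = degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> statistic = %.4g, p = %.4g (%s; n1 = %s, n2 = %s)\n",
              x$statistic, x$p_value, x$method, x$n1, x$n2))
  invisible(x)
}

# U statistic for the first sample, midranks for ties.
.u_statistic <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Two-sample Mann-Whitney U test
#'
#' Two-sided rank test on independent samples. In `"exact"` mode the null
#' distribution of U is enumerated over all group assignments of the pooled
#' values (so arbitrary ties are handled exactly); two-sided p is the
#' probability of a deviation of U from its mean `n1 n2 / 2` at least as
#' large as observed. In `"approx"` mode the normal approximation with tie
#' correction and continuity correction is used. `"auto"` picks exact
#' enumeration when `n1 + n2 <= 16`.
#'
#' @param x,y Numeric samples.
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return A `test_result`; `statistic` is U for `x`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  if (mode == "auto") mode <- if (n1 + n2 <= 16) "exact" else "approx"
  U <- .u_statistic(x, y)
  if (mode == "exact") {
    pooled <- c(x, y)
    r <- rank(pooled)
    offset <- n1 * (n1 + 1) / 2
    combos <- utils::combn(n1 + n2, n1)
    U_all <- colSums(matrix(r[combos], nrow = n1)) - offset
    dev_obs <- abs(U - n1 * n2 / 2)
    p <- mean(abs(U_all - n1 * n2 / 2) >= dev_obs - 1e-9)
    .test_result(U, p, n1, n2, "exact")
  } else {
    n <- n1 + n2
    ties <- table(c(x, y))
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) return(.test_result(U, 1, n1, n2, "normal-approximation"))
    z <- (abs(U - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(0, z)))
    .test_result(U, p, n1, n2, "normal-approximation")
  }
}

#' The nine-comparison MA/VA plan
#'
#' One pooled comparison (both MA events against all four VA events) plus
#' the eight single-event pairings, in the column order of the published
#' per-subject table.
#'
#' @return Data frame with columns `label`, `ma` and `va` (list columns of
#'   event-name vectors), 9 rows.
#' @export
comparison_plan <- function() {
  labels <- c("MA_T vs VA_T",
              "MA1 vs VA1", "MA1 vs VA2", "MA1 vs VA3", "MA1 vs VA4",
              "MA2 vs VA1", "MA2 vs VA2", "MA2 vs VA3", "MA2 vs VA4")
  ma <- c(list(c("MA1", "MA2")), rep(list("MA1"), 4), rep(list("MA2"), 4))
  va <- c(list(c("VA1", "VA2", "VA3", "VA4")),
          as.list(rep(c("VA1", "VA2", "VA3", "VA4"), 2)))
  out <- data.frame(label = labels, stringsAsFactors = FALSE)
  out$ma <- ma
  out$va <- va
  out
}

#' Run the comparison plan on one subject's segment scores
#'
#' The pooled comparison concatenates the segment scores of the MA events
#' against those of the VA events; the eight pairwise comparisons use the
#' single-event score vectors. Decisions are `"ns"` (no significant
#' difference) when `p >= alpha`, `"sig"` otherwise.
#'
#' @param scores Named list mapping each of MA1, MA2, VA1..VA4 to its
#'   numeric segment-score vector (each of length >= 2).
#' @param plan A [comparison_plan()].
#' @param alpha Significance level (default 0.05).
#' @param mode Mann-Whitney mode passed to [mann_whitney_u()].
#' @return Data frame with one row per comparison: `comparison`, `U`,
#'   `p_value`, `n1`, `n2`, `method`, `decision`.
#' @export
run_comparison_plan <- function(scores, plan = comparison_plan(),
                                alpha = 0.05, mode = "auto") {
  missing_ev <- setdiff(TREATMENT_EVENTS, names(scores))
  if (length(missing_ev))
    stop("missing event score(s): ", paste(missing_ev, collapse = ", "))
  short <- TREATMENT_EVENTS[vapply(scores[TREATMENT_EVENTS], length, 0L) < 2]
  if (length(short))
    stop("need >= 2 segments per event; too few in: ",
         paste(short, collapse = ", "))
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    xs <- unlist(scores[plan$ma[[i]]], use.names = FALSE)
    ys <- unlist(scores[plan$va[[i]]], use.names = FALSE)
    res <- mann_whitney_u(xs, ys, mode = mode)
    data.frame(comparison = plan$label[i], U = res$statistic,
               p_value = res$p_value, n1 = res$n1, n2 = res$n2,
               method = res$method,
               decision = decide(res$p_value, alpha),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
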