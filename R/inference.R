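# Cohort statistics: paired sign-flip permutation tests, boxplot summaries
# and multiple-comparison annotation.

#' Paired sign-flip permutation test on per-case differences
#'
#' Statistic: the mean paired difference. The null is generated by
#' independent random sign flips of each case's difference (exchangeability
#' of the pair labels within a case). Two-sided p-value with the add-one
#' rule, `p = (1 + #{|T*| >= |T|}) / (n_perm + 1)`. When `2^n <= 4096` the
#' sign-flip distribution is enumerated exhaustively and the p-value is
#' exact (`#{|T*| >= |T|} / 2^n`).
#'
#' @param differences Numeric vector of per-case paired differences, length
#'   >= 2.
#' @param n_perm Number of random permutations when not exhaustive
#'   (default 1000).
#' @param seed RNG seed for the sampled case.
#' @return Object of class `permutation_result` with fields `statistic`,
#'   `p_value`, `n_perm`, `exhaustive`, `n`, `seed`.
#' @export
#' @examples
#' paired_permutation_test(rep(1, 10))$p_value  # 2/1024
paired_permutation_test <- function(differences, n_perm = 1000, seed = 1L) {
  differences <- as.numeric(differences)
  n <- length(differences)
  if (n < 2) stop("need at least 2 cases", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  t_obs <- mean(differences)
  tol <- 1e-12 * (1 + abs(t_obs))
  if (2^n <= 4096) {
    m <- 2^n
    signs <- matrix(1, m, n)
    for (j in seq_len(n)) {
      signs[, j] <- ifelse(bitwAnd(seq_len(m) - 1L, bitwShiftL(1L, j - 1L)) > 0,
                           -1, 1)
    }
    t_star <- as.numeric(signs %*% differences) / n
    p <- sum(abs(t_star) >= abs(t_obs) - tol) / m
    res <- list(statistic = t_obs, p_value = p, n_perm = m, exhaustive = TRUE,
                n = n, seed = NA_integer_)
  } else {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    t_star <- as.numeric(signs %*% differences) / n
    p <- (1 + sum(abs(t_star) >= abs(t_obs) - tol)) / (n_perm + 1)
    res <- list(statistic = t_obs, p_value = p, n_perm = n_perm,
                exhaustive = FALSE, n = n, seed = seed)
  }
  structure(res, class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> mean difference %.4g, p = %.4g (%s, %d cases)\n",
    x$statistic, x$p_value,
    if (x$exhaustive) sprintf("exhaustive, 2^%d", x$n)
    else sprintf("%d permutations", x$n_perm), x$n))
  invisible(x)
}

#' @rdname paired_permutation_test
#' @param x A `permutation_result`.
#' @param ... Unused.
#' @export
tidy.permutation_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n = x$n, n_perm = x$n_perm, exhaustive = x$exhaustive)
}

#' Boxplot summary statistics
#'
#' Quartiles by linear interpolation; whiskers at the most extreme data
#' points within 1.5 IQR of the quartiles; points beyond the whiskers are
#' flagged as outliers.
#'
#' @param values Numeric vector, length >= 1.
#' @return Object of class `box_stats` (also a one-row tibble via [tidy()]),
#'   with `median`, `q25`, `q75`, `whisker_low`, `whisker_high` and
#'   `outliers`.
#' @export
#' @examples
#' box_summary(c(1, 2, 3, 4, 5))
box_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  structure(list(
    median = q[2], q25 = q[1], q75 = q[3],
    whisker_low = min(values[inside]), whisker_high = max(values[inside]),
    outliers = sort(values[!inside]), n = length(values)
  ), class = "box_stats")
}

#' @export
print.box_stats <- function(x, ...) {
  cat(sprintf(
    "<box_stats> median %.4g [q25 %.4g, q75 %.4g], whiskers [%.4g, %.4g], %d outlier(s)\n",
    x$median, x$q25, x$q75, x$whisker_low, x$whisker_high, length(x$outliers)))
  invisible(x)
}

#' @rdname box_summary
#' @param x A `box_stats` object.
#' @param ... Unused.
#' @export
tidy.box_stats <- function(x, ...) {
  tibble::tibble(median = x$median, q25 = x$q25, q75 = x$q75,
                 whisker_low = x$whisker_low, whisker_high = x$whisker_high,
                 n_outliers = length(x$outliers), n = x$n)
}

#' Annotate a table of p-values
#'
#' Reports raw p-values with ranks and a significance flag at `alpha`.
#' An optional Benjamini-Hochberg adjusted column can be added, but is off
#' by default: the study design reports raw per-comparison p-values.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha Significance level for the raw flag (default 0.01).
#' @param bh Add a Benjamini-Hochberg `p_bh` column (default FALSE).
#' @return Tibble with `p_value`, `rank`, `significant` and optionally
#'   `p_bh`, `significant_bh`.
#' @export
multiple_comparison_annotation <- function(p_values, alpha = 0.01, bh = FALSE) {
  p_values <- as.numeric(p_values)
  if (length(p_values) == 0L) stop("need at least one p-value", call. = FALSE)
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- tibble::tibble(p_value = p_values,
                        rank = rank(p_values, ties.method = "first"),
                        significant = p_values < alpha)
  if (bh) {
    out$p_bh <- p.adjust(p_values, method = "BH")
    out$significant_bh <- out$p_bh < alpha
  }
  out
}
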