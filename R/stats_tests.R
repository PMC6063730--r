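#' Exact Wilcoxon signed-rank test
#'
#' Zero differences are dropped (standard Wilcoxon convention), absolute
#' differences are ranked with mid-ranks for ties, and the statistic
#' `W+` is the sum of ranks of the positive differences. For `n <= 25` the
#' null distribution of `W+` is obtained exactly by full enumeration of all
#' `2^n` sign assignments (computed as the generating-polynomial
#' convolution over doubled ranks, which enumerates the same distribution);
#' one-tailed `p = P(W+ >= w_obs)` for direction `"greater"`,
#' `P(W+ <= w_obs)` for `"less"`; two-tailed `p = min(1, 2 * min(p_less,
#' p_greater))`. Beyond `n = 25` a normal approximation with continuity and
#' tie correction is used and flagged `exact = FALSE`.
#'
#' @param differences Numeric vector of paired differences.
#' @param sided `"two"` or `"one"`.
#' @param direction For one-tailed tests: `"greater"` (positive median
#'   hypothesized) or `"less"`.
#' @param exact_max Largest `n` for which full enumeration is used.
#' @return List of class `test_result`: `test`, `statistic` (`W+`),
#'   `p_value`, `sided`, `direction`, `n`, `n_zero_dropped`, `exact`,
#'   `degenerate` (`TRUE` when all differences were zero; `p_value = 1`).
#' @export
signed_rank_exact <- function(differences, sided = c("two", "one"),
                              direction = c("greater", "less"),
                              exact_max = 25L) {
  sided <- match.arg(sided)
  direction <- match.arg(direction)
  d <- differences[is.finite(differences)]
  if (!length(d)) stop("no finite differences supplied")
  nz <- d != 0
  n_zero <- sum(!nz)
  d <- d[nz]
  n <- length(d)
  if (n == 0) {
    return(structure(list(test = "signed_rank", statistic = NA_real_,
                          p_value = 1, sided = sided, direction = direction,
                          n = 0L, n_zero_dropped = n_zero, exact = TRUE,
                          degenerate = TRUE),
                     class = "test_result"))
  }
  r <- rank(abs(d))            # mid-ranks for tied magnitudes
  r2 <- as.integer(round(2 * r))  # doubled ranks are integers even with ties
  w2_obs <- sum(r2[d > 0])
  if (n <= exact_max) {
    # exact null distribution of 2*W+: product of (1 + x^r2_i) / 2^n
    total <- sum(r2)
    cnt <- numeric(total + 1)
    cnt[1] <- 1
    for (rr in r2) {
      shifted <- c(numeric(rr), cnt[1:(total + 1 - rr)])
      cnt <- cnt + shifted
    }
    probs <- cnt / 2^n
    p_ge <- sum(probs[(w2_obs + 1):(total + 1)])
    p_le <- sum(probs[1:(w2_obs + 1)])
    exact <- TRUE
  } else {
    mu <- sum(r2) / 2
    sig <- sqrt(sum(r2^2)) / 2
    z_ge <- (w2_obs - mu - 1) / sig   # continuity correction of 1 on 2W+
    z_le <- (w2_obs - mu + 1) / sig
    p_ge <- stats::pnorm(z_ge, lower.tail = FALSE)
    p_le <- stats::pnorm(z_le)
    exact <- FALSE
  }
  p <- switch(sided,
              two = min(1, 2 * min(p_ge, p_le)),
              one = if (direction == "greater") p_ge else p_le)
  structure(list(test = "signed_rank", statistic = w2_obs / 2, p_value = p,
                 sided = sided, direction = direction, n = n,
                 n_zero_dropped = n_zero, exact = exact, degenerate = FALSE),
            class = "test_result")
}

#' Exact Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Pooled observations are ranked with mid-ranks for ties; the statistic is
#' the rank sum of `x`. For `n1 + n2 <= 25` the null distribution is exact,
#' enumerating all `choose(n1 + n2, n1)` group assignments (via the
#' subset-sum generating polynomial over doubled ranks); beyond that a
#' normal approximation with continuity and tie correction is used and
#' flagged `exact = FALSE`. Two-tailed `p = min(1, 2 * min(p_less,
#' p_greater))`.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param sided `"two"` or `"one"`.
#' @param direction For one-tailed tests: `"greater"` means `x` tends
#'   larger than `y`.
#' @param exact_max Largest `n1 + n2` for which full enumeration is used.
#' @return List of class `test_result` with `statistic` (rank sum of `x`),
#'   `p_value`, `n1`, `n2`, `exact`.
#' @export
rank_sum_exact <- function(x, y, sided = c("two", "one"),
                           direction = c("greater", "less"),
                           exact_max = 25L) {
  sided <- match.arg(sided)
  direction <- match.arg(direction)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  r2 <- as.integer(round(2 * r))
  w2_obs <- sum(r2[seq_len(n1)])
  if (N <= exact_max) {
    total <- sum(r2)
    # cnt[k+1, s+1] = number of k-subsets of the ranks with doubled-rank sum s
    cnt <- matrix(0, nrow = n1 + 1, ncol = total + 1)
    cnt[1, 1] <- 1
    for (rr in r2) {
      for (k in n1:1) {
        # iterate k downward so each rank is used at most once
        cnt[k + 1, (rr + 1):(total + 1)] <-
          cnt[k + 1, (rr + 1):(total + 1)] + cnt[k, 1:(total + 1 - rr)]
      }
    }
    counts <- cnt[n1 + 1, ]
    tot_assign <- choose(N, n1)
    p_ge <- sum(counts[(w2_obs + 1):(total + 1)]) / tot_assign
    p_le <- sum(counts[1:(w2_obs + 1)]) / tot_assign
    exact <- TRUE
  } else {
    mu <- n1 * (N + 1)
    ties <- table(r2)
    tie_term <- sum(ties^3 - ties)
    sig <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))) * 2
    p_ge <- stats::pnorm((w2_obs - mu - 1) / sig, lower.tail = FALSE)
    p_le <- stats::pnorm((w2_obs - mu + 1) / sig)
    exact <- FALSE
  }
  p <- switch(sided,
              two = min(1, 2 * min(p_ge, p_le)),
              one = if (direction == "greater") p_ge else p_le)
  structure(list(test = "rank_sum", statistic = w2_obs / 2, p_value = p,
                 sided = sided, direction = direction, n1 = n1, n2 = n2,
                 exact = exact, degenerate = FALSE),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  # p reported to two significant figures in text output
  cat(sprintf("Wilcoxon %s test (%s-tailed%s): W = %g, n = %s, p = %.2g%s\n",
              x$test, x$sided,
              if (x$sided == "one") paste0(", ", x$direction) else "",
              x$statistic,
              if (!is.null(x$n)) x$n else paste0(x$n1, "+", x$n2),
              x$p_value, if (x$exact) " (exact)" else " (normal approx.)"))
  invisible(x)
}

#' Box-plot summary statistics
#'
#' Quartiles by linear interpolation; whiskers extend to the smallest data
#' point within 1.5 IQR below the first quartile and the largest data point
#' within 1.5 IQR above the third quartile (actual data points, not the
#' fence values).
#'
#' @param values Numeric vector, `n >= 1`.
#' @return List of class `box_stats`: `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `mean`, `n`.
#' @export
box_stats <- function(values) {
  v <- values[is.finite(values)]
  if (!length(v)) stop("box_stats needs at least one finite value")
  q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  structure(list(median = q[2], q1 = q[1], q3 = q[3],
                 whisker_low = min(v[v >= lo_fence]),
                 whisker_high = max(v[v <= hi_fence]),
                 mean = mean(v), n = length(v)),
            class = "box_stats")
}

#' @export
print.box_stats <- function(x, ...) {
  cat(sprintf("median %.3g [Q1 %.3g, Q3 %.3g], whiskers [%.3g, %.3g], mean %.3g (n = %d)\n",
              x$median, x$q1, x$q3, x$whisker_low, x$whisker_high, x$mean,
              x$n))
  invisible(x)
}
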