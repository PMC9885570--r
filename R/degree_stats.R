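#' Hurwitz zeta function
#'
#' Computes sum_{k>=0} (q + k)^(-a) for a > 1, q > 0 by direct summation of
#' the first `nterms` terms plus an Euler-Maclaurin tail correction. Accurate
#' to ~1e-12 for the exponent range used in degree fitting (1 < a <= 8).
#'
#' @param a Exponent, > 1.
#' @param q Offset, > 0 (vectorised).
#' @return Numeric vector of zeta(a, q) values.
#' @export
hurwitz_zeta <- function(a, q, nterms = 64L) {
  stopifnot(a > 1, all(q > 0))
  vapply(q, function(qi) {
    k <- 0:(nterms - 1L)
    head_sum <- sum((qi + k)^(-a))
    m <- qi + nterms
    tail <- m^(1 - a) / (a - 1) + 0.5 * m^(-a) +
      a / 12 * m^(-a - 1) -
      a * (a + 1) * (a + 2) / 720 * m^(-a - 3) +
      a * (a + 1) * (a + 2) * (a + 3) * (a + 4) / 30240 * m^(-a - 5)
    head_sum + tail
  }, numeric(1))
}

#' Reverse-cumulative degree distribution (CCDF)
#'
#' For a sample of positive integer degrees, returns P(K >= k) at each
#' distinct observed k. On log-log axes this curve is linear under a power
#' law, which is how scale-free degree structure is conventionally displayed.
#'
#' @param degrees Non-empty vector of positive integers.
#' @return A `reverse_cumulative` data.frame with columns `k` (ascending) and
#'   `ccdf`.
#' @export
reverse_cumulative <- function(degrees) {
  if (length(degrees) == 0) stop("degrees must be non-empty")
  stopifnot(all(degrees >= 1), all(degrees == round(degrees)))
  k <- sort(unique(degrees))
  n <- length(degrees)
  ccdf <- vapply(k, function(ki) sum(degrees >= ki) / n, numeric(1))
  structure(data.frame(k = k, ccdf = ccdf),
            class = c("reverse_cumulative", "data.frame"))
}

# Model CCDF of the discrete power law: P(X >= x) = zeta(a, x)/zeta(a, xmin).
plaw_ccdf <- function(x, alpha, xmin) {
  hurwitz_zeta(alpha, x) / hurwitz_zeta(alpha, xmin)
}

#' Draw from a discrete power law (zeta distribution)
#'
#' Inverse-CDF sampling on P(X >= x) = zeta(alpha, x)/zeta(alpha, xmin) with
#' doubling plus binary search, so arbitrarily heavy tails are sampled
#' exactly without truncation.
#'
#' @param n Number of draws.
#' @param alpha Exponent, > 1.
#' @param xmin Minimum value (default 1).
#' @return Integer vector of length `n`.
#' @export
rpowerlaw <- function(n, alpha, xmin = 1) {
  stopifnot(alpha > 1, xmin >= 1)
  z0 <- hurwitz_zeta(alpha, xmin)
  u <- stats::runif(n)
  vapply(u, function(ui) {
    # find smallest x with P(X >= x + 1) <= ui, i.e. CDF(x) >= 1 - ui
    lo <- xmin; hi <- 2 * xmin
    while (hurwitz_zeta(alpha, hi + 1) / z0 > ui) {
      lo <- hi; hi <- 2 * hi
    }
    while (hi - lo > 0) {
      mid <- (lo + hi) %/% 2
      if (hurwitz_zeta(alpha, mid + 1) / z0 > ui) lo <- mid + 1 else hi <- mid
    }
    as.integer(lo)
  }, integer(1))
}

# Discrete MLE of the power-law exponent for the tail >= xmin.
plaw_mle_alpha <- function(tail_x, xmin, interval = c(1.01, 8)) {
  slog <- sum(log(tail_x))
  n <- length(tail_x)
  nll <- function(a) n * log(hurwitz_zeta(a, xmin)) + a * slog
  stats::optimize(nll, interval = interval)$minimum
}

# One-sample KS distance between the empirical tail and the fitted model.
plaw_ks <- function(tail_x, alpha, xmin) {
  ks <- sort(unique(tail_x))
  n <- length(tail_x)
  emp_cdf <- cumsum(tabulate(match(tail_x, ks))) / n
  mod_cdf <- 1 - plaw_ccdf(ks + 1, alpha, xmin)
  max(abs(emp_cdf - mod_cdf))
}

#' Fit a discrete power law to a degree sample
#'
#' Maximum-likelihood fit of the zeta (discrete power-law) exponent to the
#' tail `degrees >= xmin`. With `xmin = "auto"` the cutoff is chosen by
#' minimising the Kolmogorov-Smirnov distance between the empirical tail and
#' the fitted model over candidate cutoffs (the field-standard procedure).
#'
#' @param degrees Vector of positive integers.
#' @param xmin Positive integer cutoff, or `"auto"`.
#' @param max_candidates With `xmin = "auto"`, cap on the number of distinct
#'   candidate cutoffs scanned (quantile-spread when exceeded).
#' @return A `power_law_fit`: list with `alpha`, `xmin`, `n_tail`,
#'   `ks_distance`.
#' @export
fit_power_law <- function(degrees, xmin = "auto", max_candidates = 50L) {
  stopifnot(length(degrees) > 0, all(degrees >= 1), all(degrees == round(degrees)))
  fit_at <- function(xm) {
    tail_x <- degrees[degrees >= xm]
    if (length(unique(tail_x)) < 2) return(NULL)
    alpha <- plaw_mle_alpha(tail_x, xm)
    list(alpha = alpha, xmin = as.integer(xm), n_tail = length(tail_x),
         ks_distance = plaw_ks(tail_x, alpha, xm))
  }
  if (identical(xmin, "auto")) {
    cands <- sort(unique(degrees))
    cands <- cands[cands <= sort(degrees, decreasing = TRUE)[2]]  # need >= 2 tail points
    if (length(cands) > max_candidates) {
      cands <- unique(round(stats::quantile(cands, probs = seq(0, 1, length.out = max_candidates),
                                            type = 1)))
    }
    fits <- Filter(Negate(is.null), lapply(cands, fit_at))
    if (length(fits) == 0) stop("degenerate tail: cannot fit a power law (need >= 2 distinct values)")
    best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "ks_distance"))]]
  } else {
    stopifnot(is.numeric(xmin), xmin >= 1)
    best <- fit_at(xmin)
    if (is.null(best)) stop("degenerate tail: all degrees >= xmin are equal; not a fit")
  }
  structure(best, class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("power_law_fit: alpha = %.3f, xmin = %d, n_tail = %d, KS = %.4f\n",
              x$alpha, x$xmin, x$n_tail, x$ks_distance))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison of degree samples
#'
#' Used to assess whether one gene set's degree distribution is
#' representative of another's (small KS distance); reported, not
#' pass/fail-ed, since representativeness has no canonical cutoff.
#'
#' @param a,b Non-empty vectors of positive integers.
#' @return List with `statistic` (max ECDF gap) and `p_value` (asymptotic;
#'   conservative under heavy ties).
#' @export
compare_distributions <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("both samples must be non-empty")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Plot a reverse-cumulative degree distribution on log-log axes
#'
#' @param rc A `reverse_cumulative`, or a named list of them (overlaid).
#' @param fit Optional `power_law_fit` to overlay as a reference line.
#' @return A ggplot object (requires ggplot2).
#' @export
plot_ccdf <- function(rc, fit = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_ccdf() requires ggplot2")
  }
  if (inherits(rc, "reverse_cumulative")) rc <- list(degrees = rc)
  df <- do.call(rbind, lapply(names(rc), function(nm) {
    cbind(as.data.frame(rc[[nm]]), sample = nm)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = k, y = ccdf, colour = sample)) +
    ggplot2::geom_point() + ggplot2::geom_line(alpha = 0.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "P(K ≥ k)") +
    ggplot2::theme_bw()
  if (!is.null(fit)) {
    ks <- unique(df$k[df$k >= fit$xmin])
    ref <- data.frame(k = ks, ccdf = plaw_ccdf(ks, fit$alpha, fit$xmin) *
                        max(df$ccdf[df$k >= fit$xmin]))
    p <- p + ggplot2::geom_line(data = ref, ggplot2::aes(x = k, y = ccdf),
                                inherit.aes = FALSE, linetype = 2)
  }
  p
}
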