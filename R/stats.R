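# Nonparametric group comparison (Mann-Whitney, exact by enumeration of the
# null rank-sum distribution for small untied samples) and univariate ROUT
# outlier removal at a stated false discovery rate.

# Null distribution of the Mann-Whitney U statistic for group sizes (m, n)
# without ties, as a probability vector over U = 0..m*n. Counts subsets of
# size m of the pooled ranks 1..m+n by rank sum via the classical dynamic
# program, then shifts to U = W - m(m+1)/2.
exact_u_distribution <- function(m, n) {
  N <- m + n
  w_max <- sum((n + 1):N)             # largest rank sum of an m-subset
  f <- matrix(0, nrow = m + 1, ncol = w_max + 1)
  f[1, 1] <- 1                        # zero elements chosen, sum 0
  for (j in seq_len(N)) {
    for (k in min(j, m):1) {
      cols <- (j + 1):(w_max + 1)
      f[k + 1, cols] <- f[k + 1, cols] + f[k, cols - j]
    }
  }
  w_min <- m * (m + 1) / 2
  counts <- f[m + 1, (w_min + 1):(w_max + 1)]
  counts / sum(counts)
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided test that two independent samples come from the same
#' distribution, comparing ranks. For small untied samples
#' (`n_a * n_b <= 400` by default) the p-value is exact, from full
#' enumeration of the null U distribution; otherwise a normal
#' approximation with tie, continuity and Edgeworth kurtosis corrections
#' is used.
#'
#' @param a,b Numeric vectors (non-empty).
#' @param exact Force (`TRUE`)/suppress (`FALSE`) the exact path;
#'   default `NULL` chooses automatically.
#' @param exact_cutoff Largest `n_a * n_b` for the automatic exact path.
#'
#' @return A `mw_test` object with elements `u` (U of sample `a`),
#'   `p_value` (two-tailed), `n_a`, `n_b`, `exact`, `degenerate`.
#'   [tidy()] returns it as a one-row tibble.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))$p_value  # exact 0.1
#' @export
mann_whitney <- function(a, b, exact = NULL, exact_cutoff = 400) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) {
    abort("Both samples must be non-empty.", class = "myowave_validation_error")
  }
  if (any(!is.finite(c(a, b)))) {
    abort("Samples must be finite.", class = "myowave_validation_error")
  }
  na <- length(a); nb <- length(b); N <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  degenerate <- length(unique(pooled)) == 1
  if (degenerate) {
    res <- list(u = u, p_value = 1, n_a = na, n_b = nb, exact = FALSE,
                degenerate = TRUE)
    class(res) <- "myowave_mw_test"
    return(res)
  }
  use_exact <- if (is.null(exact)) (na * nb <= exact_cutoff && !has_ties) else exact
  if (use_exact && has_ties) {
    abort("Exact p-values require untied data.", class = "myowave_validation_error")
  }
  if (use_exact) {
    dist <- exact_u_distribution(na, nb)
    u_low <- min(u, na * nb - u)
    p <- min(1, 2 * sum(dist[seq_len(u_low + 1)]))
  } else {
    mu <- na * nb / 2
    tie_tab <- table(pooled)
    sigma2 <- na * nb / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      # continuity-corrected lower-tail CDF at the smaller tail, sharpened
      # by the Edgeworth kurtosis term of the untied U distribution
      u_low <- min(u, na * nb - u)
      z <- (u_low + 0.5 - mu) / sqrt(sigma2)
      g2 <- -1.2 * (na^2 + nb^2 + na * nb + na + nb) / (na * nb * (N + 1))
      cdf <- pnorm(z) - g2 / 24 * (z^3 - 3 * z) * stats::dnorm(z)
      p <- min(1, max(2 * cdf, .Machine$double.xmin))
    }
  }
  res <- list(u = u, p_value = p, n_a = na, n_b = nb, exact = use_exact,
              degenerate = FALSE)
  class(res) <- "myowave_mw_test"
  res
}

#' @export
print.myowave_mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney: U = %g, two-tailed p = %.4g (%s, n = %d/%d)%s\n",
              x$u, x$p_value, if (x$exact) "exact" else "normal approximation",
              x$n_a, x$n_b,
              if (x$degenerate) " [degenerate: all values identical]" else ""))
  invisible(x)
}

#' @method tidy myowave_mw_test
#' @export
tidy.myowave_mw_test <- function(x, ...) {
  tibble(u = x$u, p_value = x$p_value, n_a = x$n_a, n_b = x$n_b,
         exact = x$exact, degenerate = x$degenerate)
}

#' @method glance myowave_mw_test
#' @export
glance.myowave_mw_test <- function(x, ...) tidy(x)

#' ROUT outlier removal for one sample
#'
#' Univariate reduction of the ROUT (robust regression and outlier
#' removal) procedure: the robust "model" for a single sample is its
#' median; the robust scale is the RSDR, the 68.27th percentile of the
#' absolute residuals with the small-sample correction `n / (n - 1)`.
#' Residual t-scores are converted to two-tailed p-values and tested with
#' a Benjamini-Hochberg-style step at false discovery rate `q`; flagged
#' points are removed and the fit repeated until stable. Samples smaller
#' than 5 are returned untouched, as are samples with zero robust scale.
#'
#' Flags are invariant to rescaling the sample, since both residuals and
#' the RSDR scale together.
#'
#' @param x Numeric vector.
#' @param params A [rout_params()] (`q` defaults to 0.01).
#'
#' @return A tibble `value`, `outlier` (logical), in input order.
#' @examples
#' rout_outliers(c(0.1, -0.2, 0.05, 0.3, -0.1, 0.2, 0, 50))
#' @export
rout_outliers <- function(x, params = rout_params()) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) abort("Values must be finite.", class = "myowave_validation_error")
  out <- rep(FALSE, length(x))
  if (length(x) < 5) return(tibble(value = x, outlier = out))
  kept <- seq_along(x)
  for (iter in seq_len(params$max_iterations)) {
    nk <- length(kept)
    if (nk < 5) break
    center <- median(x[kept])
    resid <- abs(x[kept] - center)
    rsdr <- quantile(resid, 0.6827, names = FALSE, type = 7) * nk / (nk - 1)
    if (rsdr <= 0) break
    p <- 2 * pt(-resid / rsdr, df = nk - 1)
    ord <- order(p)
    passes <- p[ord] <= params$q * seq_len(nk) / nk
    if (!any(passes)) break
    cut <- max(which(passes))
    flagged <- kept[ord[seq_len(cut)]]
    out[flagged] <- TRUE
    kept <- setdiff(kept, flagged)
  }
  tibble(value = x, outlier = out)
}

#' Compare waveform metrics between two groups
#'
#' For each metric shared by the two tables: ROUT outlier removal within
#' each group, then a two-tailed Mann-Whitney test on the cleaned values.
#'
#' @param metrics_a,metrics_b Metrics tibbles (as from [compute_metrics()],
#'   or any tibbles sharing numeric metric columns).
#' @param metrics Metric column names to compare; defaults to the standard
#'   waveform metrics present in both tables.
#' @param rout A [rout_params()].
#' @param alpha Significance level for the `significant` flag. Default 0.05.
#' @param labels Length-2 character vector naming the groups.
#'
#' @return A tibble with one row per metric: group sizes before/after
#'   outlier removal, group medians, `u`, `p_value`, `significant`.
#' @export
compare_conditions <- function(metrics_a, metrics_b, metrics = NULL,
                               rout = rout_params(), alpha = 0.05,
                               labels = c("a", "b")) {
  if (is.null(metrics)) {
    metrics <- intersect(metric_names, intersect(names(metrics_a), names(metrics_b)))
    # auto-selection keeps only metrics observed in both groups (waves
    # without a successor carry no period-derived metrics)
    metrics <- metrics[vapply(metrics, function(m) {
      any(!is.na(metrics_a[[m]])) && any(!is.na(metrics_b[[m]]))
    }, logical(1))]
  }
  unknown <- setdiff(metrics, intersect(names(metrics_a), names(metrics_b)))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown metric(s): %s.", paste(unknown, collapse = ", ")),
          class = "myowave_validation_error")
  }
  if (length(metrics) == 0) {
    abort("No shared metric columns to compare.", class = "myowave_validation_error")
  }
  purrr::map_dfr(metrics, function(m) {
    xa <- metrics_a[[m]]; xa <- xa[!is.na(xa)]
    xb <- metrics_b[[m]]; xb <- xb[!is.na(xb)]
    fa <- rout_outliers(xa, rout)
    fb <- rout_outliers(xb, rout)
    ca <- fa$value[!fa$outlier]
    cb <- fb$value[!fb$outlier]
    if (length(ca) == 0 || length(cb) == 0) {
      abort(sprintf("Metric '%s': a group is empty after outlier removal.", m),
            class = "myowave_validation_error")
    }
    mw <- mann_whitney(ca, cb)
    tibble(
      metric = m,
      group_a = labels[1], group_b = labels[2],
      n_a = length(ca), n_b = length(cb),
      removed_a = sum(fa$outlier), removed_b = sum(fb$outlier),
      median_a = median(ca), median_b = median(cb),
      u = mw$u, p_value = mw$p_value,
      significant = mw$p_value < alpha
    )
  })
}
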