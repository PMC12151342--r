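#' Fish-level bootstrapped Kolmogorov-Smirnov test
#'
#' Two-sample KS test whose null distribution respects the clustered
#' structure of behavioral data: most variability arises between fish, not
#' between individual swim bouts, so a standard KS test (which counts bouts)
#' badly overstates the effective sample size. The observed statistic is the
#' KS distance between the pooled values of the two groups. For the null,
#' all fish from both groups are pooled and bootstrap variates are formed by
#' drawing whole fish with replacement, as many fish per sample as in the
#' original comparison; the p-value is the fraction of bootstrap statistics
#' at least as large as the observed one (floored at `1/n_boot`, never 0).
#'
#' @param a,b Data frames with columns `value` and `fish` (fish id is the
#'   resampling unit).
#' @param n_boot Number of bootstrap variates.
#' @param seed Seed.
#' @param resample_within If `TRUE`, values are additionally resampled with
#'   replacement within each drawn fish (default keeps each fish's values
#'   intact).
#' @return List of class `thermoplaid_ks` with `statistic`, `p_value`,
#'   `p_floored`, `n_boot`, `n_fish`.
#' @export
bootstrap_ks <- function(a, b, n_boot = 10000, seed = 1,
                         resample_within = FALSE) {
  ga <- split(a$value, a$fish)
  gb <- split(b$value, b$fish)
  if (length(ga) < 2 || length(gb) < 2) stop("need at least 2 fish per group")
  if (any(lengths(ga) == 0) || any(lengths(gb) == 0)) stop("empty groups")
  obs <- ks_stat_cpp(unlist(ga, use.names = FALSE), unlist(gb, use.names = FALSE))
  pool <- c(ga, gb)
  np <- length(pool)
  na <- length(ga)
  nb <- length(gb)
  set.seed(seed)
  if (resample_within) {
    null <- numeric(n_boot)
    for (i in seq_len(n_boot)) {
      va <- unlist(pool[sample.int(np, na, replace = TRUE)], use.names = FALSE)
      vb <- unlist(pool[sample.int(np, nb, replace = TRUE)], use.names = FALSE)
      va <- va[sample.int(length(va), replace = TRUE)]
      vb <- vb[sample.int(length(vb), replace = TRUE)]
      null[i] <- ks_stat_cpp(va, vb)
    }
  } else {
    lens <- lengths(pool)
    null <- as.numeric(ks_boot_null(
      unlist(pool, use.names = FALSE),
      rep(seq_along(pool) - 1L, lens), np, na, nb, n_boot
    ))
  }
  p <- mean(null >= obs)
  structure(
    list(
      statistic = obs, p_value = max(p, 1 / n_boot), p_floored = p < 1 / n_boot,
      n_boot = n_boot, n_fish = c(a = na, b = nb)
    ),
    class = "thermoplaid_ks"
  )
}

#' @export
print.thermoplaid_ks <- function(x, ...) {
  cat(sprintf(
    "Fish-level bootstrap KS: D = %.4f, p %s %.4g (%d variates, %d vs %d fish)\n",
    x$statistic, if (x$p_floored) "<" else "=", x$p_value,
    x$n_boot, x$n_fish["a"], x$n_fish["b"]
  ))
  invisible(x)
}

#' Binned density with fish-level bootstrap standard errors
#'
#' Histogram density (normalized so that `sum(density * bin width) = 1`)
#' with per-bin standard errors from resampling whole fish with replacement.
#'
#' @param values Data frame with columns `value` and `fish`.
#' @param bin_edges Numeric vector of bin edges; values outside are dropped.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed.
#' @return Tibble with `bin_lo`, `bin_hi`, `density`, `se`.
#' @export
binned_density_with_se <- function(values, bin_edges, n_boot = 1000, seed = 1) {
  g <- split(values$value, values$fish)
  if (length(g) < 2) stop("need at least 2 fish")
  width <- diff(bin_edges)
  dens <- function(v) {
    v <- v[v >= bin_edges[1] & v <= bin_edges[length(bin_edges)]]
    h <- graphics::hist(v, breaks = bin_edges, plot = FALSE)
    h$counts / (length(v) * width)
  }
  set.seed(seed)
  boots <- replicate(n_boot, dens(unlist(
    g[sample.int(length(g), replace = TRUE)],
    use.names = FALSE
  )))
  tibble::tibble(
    bin_lo = bin_edges[-length(bin_edges)],
    bin_hi = bin_edges[-1],
    density = dens(unlist(g, use.names = FALSE)),
    se = apply(boots, 1, stats::sd)
  )
}

#' Two-sided rank-sum (Mann-Whitney) test
#'
#' Thin wrapper over [stats::wilcox.test()] that also reports the normal
#' z-approximation of the statistic.
#'
#' @param a,b Numeric samples.
#' @return List with `statistic` (W), `z`, `p_value`.
#' @export
ranksum <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  if (stats::var(c(a, b)) == 0) {
    # fully tied samples carry no evidence of a difference
    return(list(statistic = n1 * n2 / 2, z = 0, p_value = 1))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
  w <- unname(wt$statistic)
  z <- (w - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  list(statistic = w, z = z, p_value = wt$p.value)
}

#' Two-sided Wilcoxon signed-rank test on paired differences
#'
#' Reports the smaller of the two signed rank sums as the statistic (so
#' fully one-sided paired differences give statistic 0).
#'
#' @param diffs Paired differences.
#' @return List with `statistic` (smaller rank sum), `v` (positive rank
#'   sum), `p_value`.
#' @export
signed_rank <- function(diffs) {
  nz <- diffs[diffs != 0]
  if (length(nz) == 0) stop("all paired differences are zero")
  wt <- suppressWarnings(stats::wilcox.test(nz, exact = FALSE, correct = FALSE))
  v <- unname(wt$statistic)
  total <- length(nz) * (length(nz) + 1) / 2
  list(statistic = min(v, total - v), v = v, p_value = wt$p.value)
}
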