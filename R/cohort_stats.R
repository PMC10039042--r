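#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation between two metric vectors (e.g. HRD index
#' vs SBS3 exposure) with the usual t-based two-sided p-value,
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3, finite, each with
#'   positive variance.
#' @return One-row tibble with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) abort("inputs must be finite")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Fit a three-component Gaussian mixture and locate the upper cutoff
#'
#' Models a cohort's HRD-index distribution as a trimodal (3-component)
#' univariate Gaussian mixture fitted by EM (unequal variances,
#' deterministic model-based initialization), and returns the boundary
#' between the two upper components: the point between their means where
#' the posterior membership switches, plus the smallest integer score
#' classified with the top component. This is the construction that turns
#' a trimodal score distribution into an integer high-HRD threshold.
#'
#' @param hrd_indices Numeric vector, n >= 30.
#' @param n_components Number of mixture components. Default 3.
#' @param seed Integer seed for the k-means initialization; the EM run is
#'   deterministic given the seed.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return A list of class `trimodal_fit` with elements `cutoff`
#'   (continuous boundary), `integer_cutoff`, `means`, `sds`, `weights`,
#'   `loglik`, `n`. `tidy()` returns the component table; `glance()` the
#'   cutoffs and log-likelihood.
#' @export
fit_trimodal_cutoff <- function(hrd_indices, n_components = 3, seed = 1,
                                max_iter = 500, tol = 1e-8) {
  if (length(hrd_indices) < 30) abort("need n >= 30 to fit the mixture")
  x <- as.numeric(hrd_indices)
  n <- length(x)
  k <- n_components
  km <- withr::with_seed(seed, stats::kmeans(x, centers = k, nstart = 10))
  means <- as.numeric(km$centers)
  sds <- vapply(seq_len(k), function(j) {
    s <- sd(x[km$cluster == j])
    if (!is.finite(s) || s < 1e-3) s <- sd(x) / k
    s
  }, numeric(1))
  weights <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n
  loglik <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j) {
      weights[j] * stats::dnorm(x, means[j], sds[j])
    }, numeric(n))
    tot <- rowSums(dens)
    ll <- sum(log(pmax(tot, 1e-300)))
    resp <- dens / pmax(tot, 1e-300)
    nk <- colSums(resp)
    if (any(nk < 1e-8)) {
      abort(paste0("degenerate mixture: component collapsed (means = ",
                   paste(round(means, 3), collapse = ", "), ")"))
    }
    means <- colSums(resp * x) / nk
    sds <- sqrt(colSums(resp * (outer(x, means, "-")^2)) / nk)
    if (any(sds < 1e-6)) {
      abort(paste0("degenerate mixture component (sd < 1e-6): means = ",
                   paste(round(means, 3), collapse = ", ")))
    }
    weights <- nk / n
    if (abs(ll - loglik) < tol) {
      loglik <- ll
      break
    }
    loglik <- ll
  }
  ord <- order(means)
  means <- means[ord]; sds <- sds[ord]; weights <- weights[ord]
  post_diff <- function(x) {
    # weighted density of top component minus runner-up
    weights[k] * stats::dnorm(x, means[k], sds[k]) -
      weights[k - 1] * stats::dnorm(x, means[k - 1], sds[k - 1])
  }
  lo <- means[k - 1]; hi <- means[k]
  cutoff <- tryCatch(uniroot(post_diff, c(lo, hi))$root,
                     error = function(e) (lo + hi) / 2)
  structure(list(cutoff = cutoff,
                 integer_cutoff = as.integer(ceiling(cutoff)),
                 means = means, sds = sds, weights = weights,
                 loglik = loglik, n = n),
            class = "trimodal_fit")
}

#' @exportS3Method generics::tidy
tidy.trimodal_fit <- function(x, ...) {
  tibble::tibble(component = seq_along(x$means), mean = x$means,
                 sd = x$sds, weight = x$weights)
}

#' @exportS3Method generics::glance
glance.trimodal_fit <- function(x, ...) {
  tibble::tibble(cutoff = x$cutoff, integer_cutoff = x$integer_cutoff,
                 loglik = x$loglik, n = x$n)
}

#' @export
print.trimodal_fit <- function(x, ...) {
  cat("<trimodal_fit> cutoff", format(x$cutoff), "-> integer cutoff",
      x$integer_cutoff, "\n")
  invisible(x)
}

#' Percentile of a value against a reference cohort
#'
#' Percentile rank by strictly-below counting:
#' `100 * #(reference < value) / #reference`. A value below the entire
#' reference scores 0, matching the convention in which the
#' lowest-expressed gene sits at the 0th percentile; a value above the
#' entire reference scores 100.
#'
#' @param value Single expression value.
#' @param reference Non-empty numeric reference distribution (e.g. a
#'   TCGA disease cohort).
#' @return One-row tibble with `percentile` (exact) and
#'   `percentile_rounded` (nearest integer).
#' @export
expression_percentile <- function(value, reference) {
  if (length(reference) == 0) abort("reference distribution is empty")
  p <- 100 * sum(reference < value) / length(reference)
  tibble::tibble(percentile = p, percentile_rounded = as.integer(round(p)))
}

#' Wilcoxon rank-sum tests with Holm step-down correction
#'
#' Runs a two-sided Wilcoxon (Mann-Whitney) rank-sum test for each
#' comparison and adjusts the p-values by the Holm-Bonferroni step-down
#' procedure (monotone, never below the raw p). Exact enumeration is used
#' when both groups have at most 10 observations and there are no ties;
#' otherwise the normal approximation with tie-corrected variance.
#' Comparisons where every value is identical across both groups get
#' p = 1.
#'
#' @param comparisons A list of comparisons, each a list with elements
#'   `a` and `b` (numeric vectors), optionally named.
#' @return Tibble with columns `comparison`, `statistic` (Mann-Whitney
#'   U for group `a`), `p`, `p_adj`.
#' @examples
#' wilcoxon_holm(list(low_vs_high = list(a = c(1, 2, 3), b = c(10, 11, 12))))
#' @export
wilcoxon_holm <- function(comparisons) {
  nm <- names(comparisons) %||% as.character(seq_along(comparisons))
  nm[!nzchar(nm)] <- as.character(which(!nzchar(nm)))
  res <- purrr::map2_dfr(comparisons, nm, function(cmp, name) {
    a <- cmp$a
    b <- cmp$b
    if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
    if (length(unique(c(a, b))) == 1) {
      # no information: all values identical across both groups
      return(tibble::tibble(comparison = name,
                            statistic = length(a) * length(b) / 2, p = 1))
    }
    exact <- length(a) <= 10 && length(b) <= 10 && !anyDuplicated(c(a, b))
    wt <- suppressWarnings(
      wilcox.test(a, b, alternative = "two.sided", exact = exact,
                  correct = !exact)
    )
    tibble::tibble(comparison = name, statistic = unname(wt$statistic),
                   p = min(wt$p.value, 1))
  })
  res$p_adj <- p.adjust(res$p, method = "holm")
  res
}
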