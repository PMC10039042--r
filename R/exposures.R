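sig_to_matrix <- function(signatures, catalog) {
  if (is.matrix(signatures)) {
    S <- signatures
  } else {
    S <- as.matrix(signatures[, -1, drop = FALSE])
    rownames(S) <- signatures[[1]]
  }
  if (nrow(S) != nrow(catalog)) {
    abort(paste0("catalog has ", nrow(catalog), " channels but signatures have ",
                 nrow(S)))
  }
  if (!is.null(rownames(S)) && !identical(rownames(S), catalog$channel)) {
    if (!setequal(rownames(S), catalog$channel)) {
      abort("catalog and signature channel labels do not match")
    }
    S <- S[catalog$channel, , drop = FALSE]
  }
  S
}

new_exposure_vector <- function(signature, raw) {
  total <- sum(raw)
  tibble::tibble(
    signature = signature,
    raw = raw,
    proportion = if (total > 0) raw / total else rep(0, length(raw))
  )
}

#' Refit signature exposures by non-negative least squares
#'
#' Estimates the number of mutations attributable to each signature as
#' `argmin || counts - S e ||_2` subject to `e >= 0`, solved with the
#' Lawson-Hanson active-set algorithm. This is the deterministic, primary
#' exposure estimator; proportions are the raw exposures normalized to sum
#' one (all zero for an empty catalog).
#'
#' @param catalog A `mutational_catalog` tibble (see
#'   [build_sbs_catalog()]).
#' @param signatures Signature matrix as returned by
#'   [read_signature_matrix()] (tibble, first column `channel`) or a plain
#'   numeric matrix with channels as rows.
#' @return Tibble with columns `signature`, `raw`, `proportion`.
#' @export
fit_exposures_nnls <- function(catalog, signatures) {
  S <- sig_to_matrix(signatures, catalog)
  y <- as.numeric(catalog$count)
  if (sum(y) == 0) {
    return(new_exposure_vector(colnames(S), rep(0, ncol(S))))
  }
  fit <- pracma::lsqnonneg(S, y)
  new_exposure_vector(colnames(S), fit$x)
}

#' Refit signature exposures by MCMC
#'
#' Samples the posterior of the exposure proportions under a Poisson count
#' likelihood, `count_j ~ Poisson(N * (S p)_j)` with `N` the total
#' mutation count, and a uniform prior on the proportion simplex. The
#' sampler is random-walk Metropolis on softmax-parameterized proportions
#' (the simplex Jacobian is included in the target). On well-conditioned
#' catalogs of a few thousand mutations the posterior means agree with the
#' NNLS proportions to a few hundredths.
#'
#' @inheritParams fit_exposures_nnls
#' @param n_iterations Total iterations; the first half is burn-in, during
#'   which the proposal scale is adapted toward a ~30% acceptance rate and
#'   then frozen for the sampling phase.
#' @param seed Integer seed; the run is reproducible given the seed.
#' @param step_size Initial Gaussian proposal standard deviation.
#' @return Tibble with columns `signature`, `raw`, `proportion`,
#'   `ci_lower`, `ci_upper` (95% credible interval on the proportion);
#'   attribute `acceptance_rate` (sampling phase). A warning is raised
#'   when the sampling-phase acceptance rate leaves [0.1, 0.6].
#' @export
fit_exposures_mcmc <- function(catalog, signatures, n_iterations = 20000,
                               seed = 1, step_size = 0.1) {
  S <- sig_to_matrix(signatures, catalog)
  k <- ncol(S)
  y <- as.numeric(catalog$count)
  N <- sum(y)
  if (N == 0) {
    out <- new_exposure_vector(colnames(S), rep(0, k))
    out$ci_lower <- 0
    out$ci_upper <- 0
    attr(out, "acceptance_rate") <- NA_real_
    return(out)
  }
  softmax <- function(x) {
    e <- exp(x - max(x))
    e / sum(e)
  }
  log_target <- function(x) {
    p <- softmax(x)
    lambda <- N * as.numeric(S %*% p)
    sum(dpois(y, pmax(lambda, 1e-300), log = TRUE)) + sum(log(pmax(p, 1e-300)))
  }
  burn <- floor(n_iterations / 2)
  draws <- matrix(NA_real_, n_iterations - burn, k)
  rate <- NA_real_
  withr::with_seed(seed, {
    x <- rep(0, k)
    lt <- log_target(x)
    step <- step_size
    accepted <- 0L
    acc_window <- 0L
    for (it in seq_len(n_iterations)) {
      prop <- x + stats::rnorm(k, 0, step)
      lt_prop <- log_target(prop)
      if (log(runif(1)) < lt_prop - lt) {
        x <- prop
        lt <- lt_prop
        if (it > burn) accepted <- accepted + 1L
        acc_window <- acc_window + 1L
      }
      # Robbins-Monro style step adaptation toward ~30% acceptance,
      # during burn-in only; the sampling phase uses a frozen step.
      if (it <= burn && it %% 200 == 0) {
        step <- step * exp(acc_window / 200 - 0.3)
        acc_window <- 0L
      }
      if (it > burn) draws[it - burn, ] <- softmax(x)
    }
    rate <- accepted / (n_iterations - burn)
  })
  if (rate < 0.1 || rate > 0.6) {
    warn(sprintf("MCMC acceptance rate %.3f outside [0.1, 0.6]; consider tuning step_size", rate))
  }
  p_mean <- colMeans(draws)
  out <- tibble::tibble(
    signature = colnames(S),
    raw = p_mean * N,
    proportion = p_mean,
    ci_lower = apply(draws, 2, quantile, probs = 0.025),
    ci_upper = apply(draws, 2, quantile, probs = 0.975)
  )
  attr(out, "acceptance_rate") <- rate
  out
}

#' Extract the named HRD signature exposures and the SBS3 flag
#'
#' Pulls SBS3 and SBS8 from an SBS exposure fit and SV3 and SV5 from an SV
#' exposure fit, and applies the SBS3 positivity rule: high SBS3 is a
#' proportion strictly greater than `config$sbs3_cutoff` (default 0.05).
#'
#' @param sbs_exposures Exposure tibble containing signatures named
#'   `SBS3` and `SBS8`.
#' @param sv_exposures Exposure tibble containing signatures named `SV3`
#'   and `SV5`.
#' @param config An [hrd_config()].
#' @return One-row tibble `sbs3`, `sbs8`, `sv3`, `sv5`, `sbs3_high`.
#' @export
exposure_flags <- function(sbs_exposures, sv_exposures, config = hrd_config()) {
  pull_sig <- function(exposures, name) {
    i <- match(name, exposures$signature)
    if (is.na(i)) {
      abort(paste0("signature '", name, "' absent from the exposure fit"))
    }
    exposures$proportion[i]
  }
  sbs3 <- pull_sig(sbs_exposures, "SBS3")
  tibble::tibble(
    sbs3 = sbs3,
    sbs8 = pull_sig(sbs_exposures, "SBS8"),
    sv3 = pull_sig(sv_exposures, "SV3"),
    sv5 = pull_sig(sv_exposures, "SV5"),
    sbs3_high = sbs3 > config$sbs3_cutoff
  )
}
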