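# Independent brute-force oracles. Deliberately written as plain loops over
# per-chromosome segment vectors, with no reuse of the package's merging or
# smoothing helpers.

oracle_chrom_runs <- function(df, member) {
  # maximal runs of abutting segments sharing membership status
  runs <- list()
  cur <- NULL
  for (i in seq_len(nrow(df))) {
    if (!member[i]) {
      if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
      cur <- NULL
      next
    }
    if (!is.null(cur) && df$start[i] == cur$end) {
      cur$end <- df$end[i]
    } else {
      if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
      cur <- list(start = df$start[i], end = df$end[i])
    }
  }
  if (!is.null(cur)) runs[[length(runs) + 1]] <- cur
  runs
}

oracle_loh <- function(segments, genome, config = hrd_config()) {
  n <- 0L
  for (ci in seq_len(nrow(genome))) {
    df <- segments[segments$chrom == genome$chrom[ci], , drop = FALSE]
    df <- df[order(df$start), , drop = FALSE]
    if (nrow(df) == 0) next
    is_loh <- if (config$loh_include_homdel) df$minor_cn == 0 else
      df$minor_cn == 0 & df$total_cn >= 1
    for (r in oracle_chrom_runs(df, is_loh)) {
      long_enough <- (r$end - r$start) > config$loh_min_mb * 1e6
      whole <- r$start == 0 && r$end == genome$length[ci]
      if (long_enough && !whole) n <- n + 1L
    }
  }
  n
}

oracle_tai <- function(segments, genome, config = hrd_config()) {
  n <- 0L
  for (ci in seq_len(nrow(genome))) {
    df <- segments[segments$chrom == genome$chrom[ci], , drop = FALSE]
    df <- df[order(df$start), , drop = FALSE]
    if (nrow(df) == 0) next
    ai <- df$minor_cn != df$total_cn - df$minor_cn
    for (r in oracle_chrom_runs(df, ai)) {
      telomeric <- r$start == 0 || r$end == genome$length[ci]
      crosses <- r$start < genome$cen_start[ci] && r$end > genome$cen_end[ci]
      long_enough <- (r$end - r$start) >= config$tai_min_mb * 1e6
      if (telomeric && !crosses && long_enough) n <- n + 1L
    }
  }
  n
}

oracle_lst <- function(segments, genome, config = hrd_config()) {
  smooth <- config$lst_smooth_mb * 1e6
  min_seg <- config$lst_min_seg_mb * 1e6
  n <- 0L
  for (ci in seq_len(nrow(genome))) {
    mid <- (genome$cen_start[ci] + genome$cen_end[ci]) / 2
    df <- segments[segments$chrom == genome$chrom[ci], , drop = FALSE]
    df <- df[order(df$start), , drop = FALSE]
    for (arm in c("p", "q")) {
      if (arm == "p") {
        a <- df[df$start < mid, , drop = FALSE]
        a$end <- pmin(a$end, mid)
      } else {
        a <- df[df$end > mid, , drop = FALSE]
        a$start <- pmax(a$start, mid)
      }
      a <- a[, c("start", "end", "total_cn", "minor_cn")]
      # smoothing to fixed point
      repeat {
        before <- nrow(a)
        a <- a[a$end - a$start >= smooth, , drop = FALSE]
        if (nrow(a) > 1) {
          i <- 1
          while (i < nrow(a)) {
            same <- a$total_cn[i] == a$total_cn[i + 1] &&
              a$minor_cn[i] == a$minor_cn[i + 1] &&
              (a$start[i + 1] - a$end[i]) < smooth
            if (same) {
              a$end[i] <- a$end[i + 1]
              a <- a[-(i + 1), , drop = FALSE]
            } else {
              i <- i + 1
            }
          }
        }
        if (nrow(a) == before) break
      }
      if (nrow(a) >= 2) {
        for (i in seq_len(nrow(a) - 1)) {
          differ <- a$total_cn[i] != a$total_cn[i + 1] ||
            a$minor_cn[i] != a$minor_cn[i + 1]
          big <- (a$end[i] - a$start[i]) >= min_seg &&
            (a$end[i + 1] - a$start[i + 1]) >= min_seg
          close_gap <- (a$start[i + 1] - a$end[i]) < smooth
          if (differ && big && close_gap) n <- n + 1L
        }
      }
    }
  }
  n
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(nA + nB, nA) group assignments (no ties assumed).
oracle_wilcoxon_exact_p <- function(a, b) {
  pooled <- c(a, b)
  nA <- length(a)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(nA)])
  combos <- utils::combn(length(pooled), nA)
  w_all <- colSums(matrix(ranks[combos], nrow = nA))
  mu <- nA * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

# Product-limit estimator by direct loop.
oracle_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (i in seq_along(ut)) {
    d <- sum(time == ut[i] & event == 1)
    r <- sum(time >= ut[i])
    s <- s * (1 - d / r)
    out[i] <- s
  }
  list(time = ut, surv = out)
}

# Two-group log-rank chi-square by the standard O-E / V table.
oracle_logrank_chisq <- function(time_a, event_a, time_b, event_b) {
  time <- c(time_a, time_b)
  event <- c(event_a, event_b)
  grp <- rep(c(1, 0), c(length(time_a), length(time_b)))
  ut <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in ut) {
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & grp == 1)
    r <- sum(time >= t)
    r1 <- sum(time >= t & grp == 1)
    e1 <- d * r1 / r
    o_minus_e <- o_minus_e + (d1 - e1)
    if (r > 1) v <- v + d * (r1 / r) * (1 - r1 / r) * (r - d) / (r - 1)
  }
  (o_minus_e)^2 / v
}
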