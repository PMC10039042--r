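#' Genomic scar scores: LOH, TAI, LST and the HRD index
#'
#' The HRD index is the plain arithmetic sum of three genomic scar counts
#' computed from an allele-specific copy-number profile:
#'
#' * **LOH** — number of merged loss-of-heterozygosity regions
#'   (`minor_cn == 0`) longer than `loh_min_mb` (strict, default 15 Mb)
#'   that do not span an entire chromosome.
#' * **TAI** — number of merged allelic-imbalance regions that reach a
#'   telomere (position 0 or the chromosome end), do not span the
#'   centromere, and are at least `tai_min_mb` long (default 11 Mb).
#' * **LST** — number of junctions, per chromosome arm, between adjacent
#'   differing copy-number states where both flanking segments are at
#'   least `lst_min_seg_mb` (default 10 Mb) after segments shorter than
#'   `lst_smooth_mb` (default 3 Mb) have been smoothed away, and the gap
#'   between the flanks is smaller than `lst_smooth_mb`.
#'
#' No ploidy correction is applied to LST; the index is the raw sum.
#'
#' @param segments Segment tibble for one sample (see
#'   [validate_segments()]).
#' @param genome A [genome_model()] supplying lengths and centromeres.
#' @param config An [hrd_config()].
#' @return `compute_scar_scores()` returns a one-row tibble with integer
#'   columns `loh`, `tai`, `lst`, `hrd_index`; the component functions
#'   return single integers.
#' @examples
#' g <- make_toy_genome(1, 100)
#' segs <- tibble::tibble(chrom = "chr1",
#'                        start = c(0, 20e6, 40e6),
#'                        end = c(20e6, 40e6, 100e6),
#'                        total_cn = c(2, 2, 2), minor_cn = c(1, 0, 1))
#' compute_scar_scores(segs, g)
#' @export
compute_scar_scores <- function(segments, genome, config = hrd_config()) {
  segments <- validate_segments(segments, genome)
  tibble::tibble(
    loh = compute_loh_score(segments, genome, config),
    tai = compute_tai_score(segments, genome, config),
    lst = compute_lst_score(segments, genome, config),
    hrd_index = .data$loh + .data$tai + .data$lst
  )
}

#' @rdname compute_scar_scores
#' @export
compute_loh_score <- function(segments, genome, config = hrd_config()) {
  merged <- merge_segments(segments, by = "loh",
                           include_homdel = config$loh_include_homdel)
  if (nrow(merged) == 0) return(0L)
  gl <- setNames(genome$length, genome$chrom)
  keep <- merged$class_member &
    (merged$end - merged$start) > config$loh_min_mb * 1e6 &
    !(merged$start == 0 & merged$end == gl[merged$chrom])
  sum(keep)
}

#' @rdname compute_scar_scores
#' @export
compute_tai_score <- function(segments, genome, config = hrd_config()) {
  merged <- merge_segments(segments, by = "imbalance")
  if (nrow(merged) == 0) return(0L)
  gl <- setNames(genome$length, genome$chrom)
  cs <- setNames(genome$cen_start, genome$chrom)
  ce <- setNames(genome$cen_end, genome$chrom)
  telomeric <- merged$start == 0 | merged$end == gl[merged$chrom]
  crosses_cen <- merged$start < cs[merged$chrom] & merged$end > ce[merged$chrom]
  keep <- merged$class_member & telomeric & !crosses_cen &
    (merged$end - merged$start) >= config$tai_min_mb * 1e6
  sum(keep)
}

# Split segments at the centromere midpoint into p/q arm pieces;
# centromere-spanning segments are truncated at the split.
split_arms <- function(segments, genome) {
  mid <- setNames((genome$cen_start + genome$cen_end) / 2, genome$chrom)
  m <- mid[segments$chrom]
  p <- segments |>
    dplyr::filter(.data$start < m) |>
    dplyr::mutate(end = pmin(.data$end, mid[.data$chrom]), arm = "p")
  q <- segments |>
    dplyr::filter(.data$end > m) |>
    dplyr::mutate(start = pmax(.data$start, mid[.data$chrom]), arm = "q")
  dplyr::bind_rows(p, q) |>
    dplyr::arrange(.data$chrom, .data$arm, .data$start)
}

# Iterative smoothing of one arm's segments: drop segments shorter than
# smooth_bp, re-join equal-state neighbours whose gap is below smooth_bp,
# repeat to a fixed point.
smooth_arm <- function(arm, smooth_bp) {
  repeat {
    n0 <- nrow(arm)
    arm <- arm[arm$end - arm$start >= smooth_bp, , drop = FALSE]
    if (nrow(arm) > 1) {
      n <- nrow(arm)
      same <- arm$total_cn[-1] == arm$total_cn[-n] &
        arm$minor_cn[-1] == arm$minor_cn[-n] &
        (arm$start[-1] - arm$end[-n]) < smooth_bp
      run <- cumsum(c(TRUE, !same))
      arm <- arm |>
        dplyr::mutate(.run = run) |>
        dplyr::group_by(.data$.run) |>
        dplyr::summarise(
          start = min(.data$start), end = max(.data$end),
          total_cn = dplyr::first(.data$total_cn),
          minor_cn = dplyr::first(.data$minor_cn),
          .groups = "drop"
        ) |>
        dplyr::select(-".run")
    }
    if (nrow(arm) == n0) break
  }
  arm
}

#' @rdname compute_scar_scores
#' @export
compute_lst_score <- function(segments, genome, config = hrd_config()) {
  smooth_bp <- config$lst_smooth_mb * 1e6
  min_seg_bp <- config$lst_min_seg_mb * 1e6
  arms <- split_arms(segments, genome)
  if (nrow(arms) == 0) return(0L)
  total <- 0L
  for (key in unique(paste(arms$chrom, arms$arm))) {
    a <- arms[paste(arms$chrom, arms$arm) == key,
              c("start", "end", "total_cn", "minor_cn"), drop = FALSE]
    a <- smooth_arm(dplyr::arrange(a, .data$start), smooth_bp)
    if (nrow(a) < 2) next
    n <- nrow(a)
    len <- a$end - a$start
    differ <- a$total_cn[-1] != a$total_cn[-n] | a$minor_cn[-1] != a$minor_cn[-n]
    big <- len[-1] >= min_seg_bp & len[-n] >= min_seg_bp
    close_gap <- (a$start[-1] - a$end[-n]) < smooth_bp
    total <- total + sum(differ & big & close_gap)
  }
  as.integer(total)
}
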