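#' Validate an allele-specific segment profile
#'
#' A segment profile is a tibble with columns `chrom`, `start`, `end`
#' (0-based half-open bp), `total_cn` and `minor_cn` (integer copy numbers,
#' minor being the lesser allele), optionally a `sample` column. Segments
#' must be non-overlapping within each chromosome. LOH holds where
#' `minor_cn == 0` and `total_cn >= 1`; allelic imbalance where the two
#' allele copy numbers differ (`2 * minor_cn != total_cn`).
#'
#' @param segments Segment tibble.
#' @param genome Optional `genome_model`; when given, chromosome names and
#'   bounds are checked against it.
#' @return The profile, sorted by chromosome and start, invisibly usable
#'   downstream.
#' @export
validate_segments <- function(segments, genome = NULL) {
  need <- c("chrom", "start", "end", "total_cn", "minor_cn")
  miss <- setdiff(need, names(segments))
  if (length(miss) > 0) {
    abort(paste0("segment profile is missing columns: ", paste(miss, collapse = ", ")))
  }
  if (any(segments$start >= segments$end)) abort("segments must satisfy start < end")
  if (any(segments$total_cn < 0 | segments$minor_cn < 0)) {
    abort("copy numbers must be non-negative")
  }
  if (any(segments$minor_cn > segments$total_cn - segments$minor_cn)) {
    abort("minor_cn must be the lesser allele (minor_cn <= total_cn - minor_cn)")
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(segments$chrom), genome$chrom)
    if (length(unknown) > 0) {
      abort(paste0("unknown chromosome(s): ", paste(unknown, collapse = ", ")))
    }
    gl <- setNames(genome$length, genome$chrom)
    if (any(segments$end > gl[segments$chrom])) {
      abort("segment end beyond chromosome length")
    }
  }
  segments <- dplyr::arrange(segments, .data$chrom, .data$start)
  ov <- segments |>
    dplyr::group_by(dplyr::across(dplyr::any_of("sample")), .data$chrom) |>
    dplyr::filter(dplyr::lag(.data$end, default = -Inf) > .data$start) |>
    dplyr::ungroup()
  if (nrow(ov) > 0) {
    abort(paste0("overlapping segments on ", paste(unique(ov$chrom), collapse = ", ")))
  }
  segments
}

seg_is_loh <- function(segments, include_homdel = TRUE) {
  if (include_homdel) segments$minor_cn == 0
  else segments$minor_cn == 0 & segments$total_cn >= 1
}

seg_is_imbalanced <- function(segments) {
  2 * segments$minor_cn != segments$total_cn
}

#' Merge adjacent equivalent segments
#'
#' Collapses maximal runs of abutting segments (zero gap) that fall in the
#' same equivalence class into single segments. With `by = "state"` the
#' class is the exact `(total_cn, minor_cn)` pair; with `by = "loh"` or
#' `by = "imbalance"` it is the LOH / allelic-imbalance status, so e.g. an
#' abutting (2,0) and (3,0) pair merges into one LOH region. Merging is
#' idempotent. For non-state merges the merged segment keeps the copy
#' numbers of its first member (the class, not the copy numbers, is what
#' downstream counting uses).
#'
#' @param segments Segment tibble for a single sample.
#' @param by One of `"state"`, `"loh"`, `"imbalance"`.
#' @param include_homdel Passed to the LOH predicate.
#' @return Merged segment tibble with a logical `class_member` column when
#'   `by != "state"` indicating the predicate class of each merged run.
#' @examples
#' segs <- tibble::tibble(chrom = "chr1", start = c(0, 8e6), end = c(8e6, 16e6),
#'                        total_cn = 2, minor_cn = 0)
#' merge_segments(segs)
#' @export
merge_segments <- function(segments, by = c("state", "loh", "imbalance"),
                           include_homdel = TRUE) {
  by <- match.arg(by)
  segments <- dplyr::arrange(segments, .data$chrom, .data$start)
  key <- switch(by,
    state = paste(segments$total_cn, segments$minor_cn),
    loh = as.character(seg_is_loh(segments, include_homdel)),
    imbalance = as.character(seg_is_imbalanced(segments))
  )
  n <- nrow(segments)
  if (n == 0) {
    out <- segments
    if (by != "state") out$class_member <- logical(0)
    return(out)
  }
  new_run <- c(TRUE, segments$chrom[-1] != segments$chrom[-n] |
                 segments$start[-1] != segments$end[-n] |
                 key[-1] != key[-n])
  run <- cumsum(new_run)
  out <- segments |>
    dplyr::mutate(.run = run) |>
    dplyr::group_by(.data$.run) |>
    dplyr::summarise(
      dplyr::across(dplyr::any_of("sample"), dplyr::first),
      chrom = dplyr::first(.data$chrom),
      start = min(.data$start),
      end = max(.data$end),
      total_cn = dplyr::first(.data$total_cn),
      minor_cn = dplyr::first(.data$minor_cn),
      .groups = "drop"
    ) |>
    dplyr::select(-".run")
  if (by != "state") {
    out$class_member <- key[!duplicated(run)] == "TRUE"
  }
  out
}
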