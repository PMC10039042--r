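#' Breakpoint microhomology length of a deletion
#'
#' Measures the sequence identity shared between a deletion and its
#' flanks: the longest prefix of the deleted sequence matching the
#' reference immediately 3' of the deletion, and the longest suffix
#' matching the reference immediately 5' of it. The reported length is
#' the maximum of the two, capped at `min(nchar(deleted_seq), max_scan)`;
#' taking both sides makes the measure invariant to whether the caller
#' left- or right-aligned the deletion. Flank bases beyond the contig are
#' treated as non-matching.
#'
#' @param chrom Contig name.
#' @param pos 1-based position of the first deleted base.
#' @param deleted_seq The deleted bases (length >= 1).
#' @param reference Named character vector of contig sequences.
#' @param max_scan Maximum homology length examined. Default 10.
#' @return Integer homology length (>= 0).
#' @examples
#' ref <- c(chr1 = "AAATAGGTAGCCAAA")
#' # deletion of TAGG at pos 4; 3' flank begins TAGC -> prefix match TAG
#' microhomology_length("chr1", 4, "TAGG", ref)
#' @export
microhomology_length <- function(chrom, pos, deleted_seq, reference,
                                 max_scan = 10L) {
  reference <- as_reference(reference)
  d <- strsplit(toupper(deleted_seq), "")[[1]]
  L <- length(d)
  if (L < 1) abort("deleted_seq must have length >= 1")
  cap <- min(L, max_scan)
  # prefix of deleted vs 3' flank (bases just after the deleted interval)
  right <- ref_slice(reference, chrom, pos + L, pos + L + cap - 1)
  pre <- 0L
  for (i in seq_len(cap)) {
    if (is.na(right[i]) || right[i] != d[i]) break
    pre <- i
  }
  # suffix of deleted vs 5' flank (bases just before the deletion)
  left <- if (pos - 1 >= 1) {
    rev(ref_slice(reference, chrom, max(1, pos - cap), pos - 1))
  } else {
    character(0)
  }
  suf <- 0L
  for (i in seq_len(cap)) {
    if (i > length(left) || is.na(left[i]) || left[i] != d[L - i + 1]) break
    suf <- i
  }
  as.integer(max(pre, suf))
}

#' Microhomology-deletion fraction
#'
#' The HRDetect deletion feature: among deletions longer than three base
#' pairs, the proportion whose breakpoints share at least
#' `config$mh_min_len` bases of microhomology (default 1, i.e. any
#' overlap counts). Deletions of three or fewer bases are never eligible;
#' with no eligible deletion the fraction is 0.
#'
#' @param deletions Tibble with columns `chrom`, `pos` (1-based first
#'   deleted base) and `deleted_seq`.
#' @param reference Named character vector of contig sequences.
#' @param config An [hrd_config()].
#' @param max_scan Passed to [microhomology_length()].
#' @return One-row tibble with `fraction`, `n_eligible`, `n_mh`.
#' @export
microhomology_fraction <- function(deletions, reference,
                                   config = hrd_config(), max_scan = 10L) {
  reference <- as_reference(reference)
  eligible <- deletions[nchar(deletions$deleted_seq) > 3, , drop = FALSE]
  n_eligible <- nrow(eligible)
  if (n_eligible == 0) {
    return(tibble::tibble(fraction = 0, n_eligible = 0L, n_mh = 0L))
  }
  mh <- purrr::pmap_int(
    list(eligible$chrom, eligible$pos, eligible$deleted_seq),
    function(chrom, pos, seq) microhomology_length(chrom, pos, seq, reference, max_scan)
  )
  n_mh <- sum(mh >= config$mh_min_len)
  tibble::tibble(fraction = n_mh / n_eligible,
                 n_eligible = as.integer(n_eligible),
                 n_mh = as.integer(n_mh))
}
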