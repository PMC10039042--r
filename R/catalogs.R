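#' Mutation catalog channel layouts
#'
#' `sbs96_channels()` returns the 96 single-base-substitution classes in
#' the conventional order (pyrimidine-strand substitutions C>A, C>G, C>T,
#' T>A, T>C, T>G, each with the 16 flanking-base contexts ordered A, C, G,
#' T on both sides), labelled like `"A[C>A]A"`. `sv32_channels()` returns
#' the 32 rearrangement classes: clustered / non-clustered crossed with
#' deletion, duplication and inversion in five size bins plus
#' translocation.
#'
#' @return Character vector of channel labels.
#' @export
sbs96_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    unlist(lapply(bases, function(p) paste0(p, "[", s, "]", bases)))
  }))
}

sv_size_bins <- c("<10kb", "10-100kb", "100kb-1Mb", "1-10Mb", ">10Mb")

#' @rdname sbs96_channels
#' @export
sv32_channels <- function() {
  one_block <- function(prefix) {
    c(unlist(lapply(c("DEL", "DUP", "INV"), function(t) {
      paste(prefix, t, sv_size_bins, sep = "_")
    })), paste(prefix, "TRA", sep = "_"))
  }
  c(one_block("clustered"), one_block("non-clustered"))
}

revcomp_chr <- function(x) chartr("ACGT", "TGCA", x)

#' Build an SBS-96 trinucleotide catalog
#'
#' Maps each single-nucleotide variant to one of the 96 classes under the
#' pyrimidine-strand convention: variants with a purine reference base are
#' reverse-complemented together with their flanking bases. Variants whose
#' immediate flanks contain a non-ACGT base (including contig ends) are
#' rejected and counted; a position outside the contig is an error.
#'
#' @param snvs Tibble with columns `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param reference Named character vector of contig sequences (see
#'   [as_reference()]).
#' @return A tibble of class `mutational_catalog` with columns `channel`
#'   (the 96 labels, in order) and `count`; attribute `n_rejected` holds
#'   the number of rejected variants.
#' @examples
#' ref <- c(chr1 = "GGACTGG")
#' snvs <- tibble::tibble(chrom = "chr1", pos = 4, ref = "C", alt = "T")
#' build_sbs_catalog(snvs, ref)
#' @export
build_sbs_catalog <- function(snvs, reference) {
  reference <- as_reference(reference)
  channels <- sbs96_channels()
  counts <- integer(96)
  n_rejected <- 0L
  if (nrow(snvs) > 0) {
    contig_len <- nchar(reference)
    if (any(!(snvs$chrom %in% names(reference)))) {
      abort("SNV on a contig absent from the reference")
    }
    if (any(snvs$pos < 1 | snvs$pos > contig_len[snvs$chrom])) {
      abort("SNV position outside its contig")
    }
    ctx5 <- substr(reference[snvs$chrom], snvs$pos - 1, snvs$pos - 1)
    ctx3 <- substr(reference[snvs$chrom], snvs$pos + 1, snvs$pos + 1)
    ref <- toupper(snvs$ref)
    alt <- toupper(snvs$alt)
    purine <- ref %in% c("A", "G")
    p5 <- ifelse(purine, revcomp_chr(ctx3), ctx5)
    p3 <- ifelse(purine, revcomp_chr(ctx5), ctx3)
    pref <- ifelse(purine, revcomp_chr(ref), ref)
    palt <- ifelse(purine, revcomp_chr(alt), alt)
    ok <- p5 %in% c("A", "C", "G", "T") & p3 %in% c("A", "C", "G", "T") &
      pref %in% c("C", "T") & palt %in% c("A", "C", "G", "T") & pref != palt
    n_rejected <- sum(!ok)
    lab <- paste0(p5[ok], "[", pref[ok], ">", palt[ok], "]", p3[ok])
    tab <- table(factor(lab, levels = channels))
    counts <- as.integer(tab)
  }
  out <- tibble::tibble(channel = channels, count = counts)
  attr(out, "n_rejected") <- as.integer(n_rejected)
  class(out) <- c("mutational_catalog", class(out))
  out
}

sv_size_bin <- function(size) {
  cut(size, breaks = c(-Inf, 1e4, 1e5, 1e6, 1e7, Inf),
      labels = sv_size_bins, right = FALSE)
}

#' Build an SV-32 rearrangement catalog
#'
#' Classifies structural variants into 32 channels: clustered or
#' non-clustered, crossed with DEL/DUP/INV in five size bins (<10 kb,
#' 10-100 kb, 100 kb-1 Mb, 1-10 Mb, >10 Mb) and TRA. A breakpoint is
#' clustered when the nearest breakpoint of *another* variant on the same
#' chromosome lies within `config$sv_cluster_dist_bp` (default 1 Mb); a
#' variant is clustered when either of its breakpoints is.
#'
#' @param svs Tibble with columns `sv_type`, `chrom1`, `pos1`, `chrom2`,
#'   `pos2` and `size` (bp; NA for TRA) for one sample.
#' @param config An [hrd_config()].
#' @return A `mutational_catalog` tibble over the 32 channels.
#' @export
build_sv_catalog <- function(svs, config = hrd_config()) {
  channels <- sv32_channels()
  counts <- integer(32)
  if (nrow(svs) > 0) {
    bp <- dplyr::bind_rows(
      tibble::tibble(id = seq_len(nrow(svs)), chrom = svs$chrom1, pos = svs$pos1),
      tibble::tibble(id = seq_len(nrow(svs)), chrom = svs$chrom2, pos = svs$pos2)
    )
    clustered_bp <- vapply(seq_len(nrow(bp)), function(i) {
      others <- bp$chrom == bp$chrom[i] & bp$id != bp$id[i]
      any(abs(bp$pos[others] - bp$pos[i]) <= config$sv_cluster_dist_bp)
    }, logical(1))
    sv_clustered <- vapply(seq_len(nrow(svs)), function(i) {
      any(clustered_bp[bp$id == i])
    }, logical(1))
    prefix <- ifelse(sv_clustered, "clustered", "non-clustered")
    lab <- ifelse(svs$sv_type == "TRA",
                  paste(prefix, "TRA", sep = "_"),
                  paste(prefix, svs$sv_type, as.character(sv_size_bin(svs$size)),
                        sep = "_"))
    tab <- table(factor(lab, levels = channels))
    counts <- as.integer(tab)
  }
  out <- tibble::tibble(channel = channels, count = counts)
  attr(out, "n_rejected") <- 0L
  class(out) <- c("mutational_catalog", class(out))
  out
}
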