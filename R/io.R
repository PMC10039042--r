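#' Read allele-specific copy-number segments
#'
#' Reads a tab-separated segment table with columns `sample`, `chrom`,
#' `start`, `end`, `total_cn`, `minor_cn`. File coordinates are 1-based
#' inclusive; they are converted to the package's internal 0-based
#' half-open convention. Rows where the stated minor allele exceeds half
#' the total copy number have their allele roles swapped with a warning
#' (upstream callers disagree on column order); overlapping segments and
#' unknown chromosomes are errors.
#'
#' @param path Path to the TSV file.
#' @param genome A [genome_model()] used to validate chromosome names and
#'   bounds.
#' @return A tibble with one row per segment and columns `sample`,
#'   `chrom`, `start`, `end`, `total_cn`, `minor_cn`, sorted within each
#'   sample.
#' @seealso [write_segments()]
#' @export
read_segments <- function(path, genome) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           sample = readr::col_character(),
                           chrom = readr::col_character(),
                           start = readr::col_double(),
                           end = readr::col_double(),
                           total_cn = readr::col_integer(),
                           minor_cn = readr::col_integer()
                         ))
  unknown <- which(!(raw$chrom %in% genome$chrom))
  if (length(unknown) > 0) {
    abort(paste0("read_segments: unknown chromosome '", raw$chrom[unknown[1]],
                 "' in row ", unknown[1]))
  }
  segs <- raw |>
    dplyr::mutate(start = .data$start - 1)  # 1-based inclusive -> 0-based half-open
  swap <- segs$minor_cn > segs$total_cn - segs$minor_cn
  if (any(swap)) {
    warn(paste0("read_segments: swapped minor/major allele roles in ",
                sum(swap), " row(s)"))
    segs$minor_cn[swap] <- segs$total_cn[swap] - segs$minor_cn[swap]
  }
  segs <- dplyr::arrange(segs, .data$sample, .data$chrom, .data$start)
  ov <- segs |>
    dplyr::group_by(.data$sample, .data$chrom) |>
    dplyr::filter(dplyr::lag(.data$end, default = -Inf) > .data$start |
                    dplyr::lead(.data$start, default = Inf) < .data$end) |>
    dplyr::ungroup()
  if (nrow(ov) > 0) {
    abort(paste0(
      "read_segments: overlapping segments:\n",
      paste(utils::capture.output(print(as.data.frame(ov))), collapse = "\n")
    ))
  }
  validate_segments(segs, genome)
}

#' Write segments in the 1-based inclusive file convention
#'
#' @param segments Internal segment tibble (0-based half-open).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  segments |>
    dplyr::mutate(start = .data$start + 1) |>
    readr::write_tsv(path)
  invisible(path)
}

#' Normalize a reference sequence set
#'
#' Accepts a named character vector of contig sequences or a
#' `Biostrings::DNAStringSet` and returns a named character vector in
#' upper case.
#' @param reference Named character vector or DNAStringSet.
#' @return Named character vector.
#' @export
as_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) reference <- as.character(reference)
  if (is.null(names(reference)) || any(!nzchar(names(reference)))) {
    abort("reference sequences must be named by contig")
  }
  toupper(reference)
}

#' Read a reference FASTA
#'
#' @param path FASTA file path.
#' @return Named character vector of contig sequences.
#' @export
read_reference_fasta <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("read_reference_fasta requires the Biostrings package")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  as_reference(seqs)
}

# Substring of a contig, 1-based inclusive; returns NA-padded characters
# for positions beyond the contig so callers can treat them as non-matching.
ref_slice <- function(reference, chrom, from, to) {
  if (!chrom %in% names(reference)) {
    abort(paste0("contig '", chrom, "' not present in the reference"))
  }
  seq <- reference[[chrom]]
  n <- nchar(seq)
  pos <- seq.int(from, to)
  out <- rep(NA_character_, length(pos))
  inb <- pos >= 1 & pos <= n
  if (any(inb)) {
    out[inb] <- strsplit(substr(seq, max(from, 1), min(to, n)), "")[[1]]
  }
  out
}

#' Read somatic small variants from a VCF
#'
#' Splits multi-allelic records, verifies each REF against the reference
#' sequence, and partitions records into single-nucleotide variants
#' (`len(REF) == len(ALT) == 1`) and simple deletions (`len(REF) > 1`,
#' `len(ALT) == 1`, ALT equal to the first REF base). For a deletion the
#' reported position is the first deleted base (VCF POS + 1) and
#' `deleted_seq` the deleted bases. Insertions, complex substitutions,
#' symbolic alleles and records whose REF disagrees with the reference are
#' rejected and counted.
#'
#' @param path VCF 4.x file path (plain text).
#' @param reference Named character vector of contig sequences (or
#'   DNAStringSet); see [as_reference()].
#' @return A list with elements `snvs` (tibble `chrom`, `pos`, `ref`,
#'   `alt`), `deletions` (tibble `chrom`, `pos`, `deleted_seq`) and
#'   `n_rejected`.
#' @export
read_vcf_small_variants <- function(path, reference) {
  reference <- as_reference(reference)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(vcfR::getFIX(v)[, c("CHROM", "POS", "REF", "ALT"), drop = FALSE])
  if (nrow(fix) == 0) {
    return(list(snvs = tibble::tibble(chrom = character(), pos = integer(),
                                      ref = character(), alt = character()),
                deletions = tibble::tibble(chrom = character(), pos = integer(),
                                           deleted_seq = character()),
                n_rejected = 0L))
  }
  recs <- fix |>
    dplyr::mutate(POS = as.integer(.data$POS)) |>
    tidyr::separate_rows("ALT", sep = ",") |>
    dplyr::mutate(REF = toupper(.data$REF), ALT = toupper(.data$ALT))
  for (chrom in unique(recs$CHROM)) {
    if (!chrom %in% names(reference)) {
      abort(paste0("VCF contig '", chrom, "' not present in the reference"))
    }
  }
  ref_ok <- vapply(seq_len(nrow(recs)), function(i) {
    obs <- ref_slice(reference, recs$CHROM[i], recs$POS[i],
                     recs$POS[i] + nchar(recs$REF[i]) - 1)
    !anyNA(obs) && paste(obs, collapse = "") == recs$REF[i]
  }, logical(1))
  simple <- grepl("^[ACGT]+$", recs$REF) & grepl("^[ACGT]+$", recs$ALT)
  is_snv <- simple & ref_ok & nchar(recs$REF) == 1 & nchar(recs$ALT) == 1
  is_del <- simple & ref_ok & nchar(recs$REF) > 1 & nchar(recs$ALT) == 1 &
    substr(recs$REF, 1, 1) == recs$ALT
  snvs <- recs[is_snv, ] |>
    dplyr::transmute(chrom = .data$CHROM, pos = .data$POS,
                     ref = .data$REF, alt = .data$ALT)
  dels <- recs[is_del, ] |>
    dplyr::transmute(chrom = .data$CHROM, pos = .data$POS + 1L,
                     deleted_seq = substr(.data$REF, 2, nchar(.data$REF)))
  list(snvs = snvs, deletions = dels,
       n_rejected = as.integer(sum(!(is_snv | is_del))))
}

#' Read a COSMIC-layout signature matrix
#'
#' First column holds the channel labels (96 SBS trinucleotide classes or
#' 32 SV classes); every other column is one signature's probability
#' vector. Columns whose sum lies within 1e-3 of 1 are renormalized to sum
#' exactly 1; anything further off is an error, as are negative entries or
#' an unexpected channel count.
#'
#' @param path TSV path.
#' @return A tibble whose first column is `channel` followed by one column
#'   per signature, each summing to 1.
#' @export
read_signature_matrix <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  names(m)[1] <- "channel"
  if (!nrow(m) %in% c(96L, 32L)) {
    abort(paste0("signature matrix must have 96 (SBS) or 32 (SV) channels, got ", nrow(m)))
  }
  sig_cols <- names(m)[-1]
  for (sc in sig_cols) {
    col <- m[[sc]]
    if (any(col < 0)) abort(paste0("signature '", sc, "' has negative entries"))
    s <- sum(col)
    if (abs(s - 1) > 1e-3) {
      abort(paste0("signature '", sc, "' sums to ", format(s),
                   ", outside 1e-3 of 1"))
    }
    m[[sc]] <- col / s
  }
  m
}

#' Read a structural-variant breakpoint table
#'
#' Tab-separated with columns `sample`, `sv_type` (DEL/DUP/INV/TRA),
#' `chrom1`, `pos1`, `chrom2`, `pos2`. Sizes for intrachromosomal events
#' are `abs(pos2 - pos1)`; translocations must join different chromosomes.
#'
#' @param path TSV path.
#' @return Tibble with the columns above plus `size` (NA for TRA).
#' @export
read_sv_table <- function(path) {
  sv <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          sample = readr::col_character(),
                          sv_type = readr::col_character(),
                          chrom1 = readr::col_character(),
                          pos1 = readr::col_double(),
                          chrom2 = readr::col_character(),
                          pos2 = readr::col_double()
                        ))
  bad_type <- setdiff(unique(sv$sv_type), c("DEL", "DUP", "INV", "TRA"))
  if (length(bad_type) > 0) {
    abort(paste0("unknown sv_type: ", paste(bad_type, collapse = ", ")))
  }
  tra <- sv$sv_type == "TRA"
  if (any(tra & sv$chrom1 == sv$chrom2)) {
    abort("TRA records must join two different chromosomes")
  }
  if (any(!tra & sv$chrom1 != sv$chrom2)) {
    abort("intrachromosomal SV records must stay on one chromosome")
  }
  sv$size <- ifelse(tra, NA_real_, abs(sv$pos2 - sv$pos1))
  if (any(!tra & sv$size <= 0)) abort("intrachromosomal SV size must be > 0")
  sv
}

#' Read a clinical treatment-line table
#'
#' One row per treatment line with patient-level fields repeated:
#' `patient_id`, `tumor_group` (GI/thoracic), `brca_status`, `line`,
#' `agent_class`, `is_platinum`, `start`, `end` (optional), `death_date`
#' (optional), `last_followup`. Dates are ISO-8601.
#'
#' @param path TSV path.
#' @return Tibble of treatment lines (class `clinical_table`), grouped
#'   implicitly by `patient_id`.
#' @export
read_clinical_table <- function(path) {
  cl <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          patient_id = readr::col_character(),
                          tumor_group = readr::col_character(),
                          brca_status = readr::col_character(),
                          line = readr::col_integer(),
                          agent_class = readr::col_character(),
                          is_platinum = readr::col_logical(),
                          start = readr::col_date(),
                          end = readr::col_date(),
                          death_date = readr::col_date(),
                          last_followup = readr::col_date()
                        ))
  if (anyNA(cl$last_followup)) {
    abort(paste0("missing last_followup for patient(s): ",
                 paste(unique(cl$patient_id[is.na(cl$last_followup)]), collapse = ", ")))
  }
  bad <- !is.na(cl$end) & cl$end < cl$start
  if (any(bad)) {
    abort(paste0("treatment end before start for patient ",
                 cl$patient_id[which(bad)[1]], " line ", cl$line[which(bad)[1]]))
  }
  dup <- cl |>
    dplyr::count(.data$patient_id, .data$line) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicated line numbers for patient(s): ",
                 paste(unique(dup$patient_id), collapse = ", ")))
  }
  class(cl) <- c("clinical_table", class(cl))
  cl
}

#' Write and re-read the per-sample metrics table
#'
#' Writes one row per sample (scar components, HRD index, signature
#' exposures, microhomology fraction, HRDetect score and classification
#' flags) both as TSV and as a JSON mirror; `read_results()` returns a
#' tibble identical to the one written.
#'
#' @param metrics Per-sample metric tibble; must contain a `sample`
#'   column.
#' @param path Output path stem; `.tsv` and `.json` are appended.
#' @return Invisible named character vector of the two file paths.
#' @export
write_results <- function(metrics, path) {
  if (!"sample" %in% names(metrics)) abort("write_results: metrics need a 'sample' column")
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  readr::write_tsv(metrics, tsv)
  jsonlite::write_json(metrics, json, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  readr::read_tsv(paste0(path, ".tsv"), show_col_types = FALSE)
}
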