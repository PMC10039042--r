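#' Classification and scoring configuration
#'
#' Bundles every threshold and size parameter used across the pipeline so
#' that each cutoff appearing in an output is traceable to a single config
#' object. Defaults follow the published conventions: HRD index high at a
#' score of 34 or more (inclusive), SBS3 exposure high strictly above 0.05,
#' HRDetect positive strictly above 0.7. The CHORD probability cutoff of 0.5
#' is carried for annotation of externally computed scores only; CHORD itself
#' is not implemented here.
#'
#' Scar-region size parameters are in megabases: LOH regions must exceed
#' `loh_min_mb` (sub-chromosomal, per the Abkevich-style definition),
#' telomeric allelic-imbalance regions must reach `tai_min_mb`, and
#' large-scale state transitions require flanking segments of at least
#' `lst_min_seg_mb` after smoothing away segments shorter than
#' `lst_smooth_mb`.
#'
#' @param hrd_index_cutoff HRD-index threshold; classified high when the
#'   score is `>=` this value. Default 34.
#' @param sbs3_cutoff SBS3 exposure proportion threshold, strict `>`.
#'   Default 0.05.
#' @param hrdetect_cutoff HRDetect probability threshold, strict `>`.
#'   Default 0.7.
#' @param chord_cutoff CHORD probability threshold (annotation only).
#'   Default 0.5.
#' @param loh_min_mb Minimum LOH region length in Mb (strict `>`). Default 15.
#' @param tai_min_mb Minimum telomeric allelic-imbalance length in Mb
#'   (`>=`). Default 11.
#' @param lst_min_seg_mb Minimum flanking-segment length for a large-scale
#'   state transition, Mb. Default 10.
#' @param lst_smooth_mb Smoothing scale for LST: segments shorter than this
#'   are removed and equal-state flanks re-joined; junction gaps must stay
#'   below it. Default 3.
#' @param mh_min_len Minimum breakpoint microhomology length (bp) for a
#'   deletion to count as microhomology-mediated. Default 1.
#' @param log_epsilon Offset added before the natural-log transform of
#'   HRDetect features (exposures can be exactly zero). Default 1.
#' @param loh_include_homdel Should homozygous deletions (total copy number
#'   0) count as LOH regions? Default TRUE.
#' @param sv_cluster_dist_bp Breakpoints closer than this to another
#'   structural variant's breakpoint are called clustered. Default 1e6.
#'
#' @return A list of class `hrd_config`.
#' @examples
#' cfg <- hrd_config()
#' cfg$hrd_index_cutoff
#' @export
hrd_config <- function(hrd_index_cutoff = 34,
                       sbs3_cutoff = 0.05,
                       hrdetect_cutoff = 0.7,
                       chord_cutoff = 0.5,
                       loh_min_mb = 15,
                       tai_min_mb = 11,
                       lst_min_seg_mb = 10,
                       lst_smooth_mb = 3,
                       mh_min_len = 1,
                       log_epsilon = 1.0,
                       loh_include_homdel = TRUE,
                       sv_cluster_dist_bp = 1e6) {
  cfg <- list(
    hrd_index_cutoff = hrd_index_cutoff,
    sbs3_cutoff = sbs3_cutoff,
    hrdetect_cutoff = hrdetect_cutoff,
    chord_cutoff = chord_cutoff,
    loh_min_mb = loh_min_mb,
    tai_min_mb = tai_min_mb,
    lst_min_seg_mb = lst_min_seg_mb,
    lst_smooth_mb = lst_smooth_mb,
    mh_min_len = mh_min_len,
    log_epsilon = log_epsilon,
    loh_include_homdel = loh_include_homdel,
    sv_cluster_dist_bp = sv_cluster_dist_bp
  )
  num <- setdiff(names(cfg), "loh_include_homdel")
  bad <- num[!vapply(cfg[num], function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("hrd_config: these parameters must be single positive numbers: ",
                 paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "hrd_config")
}

#' @export
print.hrd_config <- function(x, ...) {
  cat("<hrd_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Homologous recombination gene panel
#'
#' The 51 genes with established roles in homologous recombination repair
#' surveyed when looking for non-BRCA1/2 drivers of an HRD phenotype
#' (RAD51 paralogs, Fanconi/BLM helicase machinery, resection and
#' strand-invasion factors, RECQL5, and others).
#'
#' @return Character vector of 51 gene symbols.
#' @examples
#' length(hr_gene_panel())
#' @export
hr_gene_panel <- function() {
  c("BARD1", "BLM", "BRCA1", "BRCA2", "BRIP1", "DNA2", "EXO1", "MRE11A",
    "NBN", "PALB2", "RAD50", "RAD51", "RAD51B", "RAD51C", "RAD51D",
    "RAD52", "RAD54L", "RBBP8", "WRN", "XRCC2", "XRCC3", "ATM", "BAP1",
    "CUL3", "EME1", "ERCC1", "ERCC4", "FBXO18", "GEN1", "HELQ", "MUS81",
    "PARPBP", "PCNA", "POLD1", "POLK", "POLN", "PSIP1", "RAD51AP1",
    "RECQL5", "RIF1", "RMI1", "RMI2", "RPA1", "RPA2", "RPA3", "RTEL1",
    "SLX1A", "SLX4", "TOP3A", "TP53BP1", "USP11")
}
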