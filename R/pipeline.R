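#' Score one sample end to end
#'
#' Runs every per-sample stage on one sample's inputs: scar scores from
#' the segment profile, SBS-96 and SV-32 catalogs and NNLS exposures,
#' microhomology-deletion fraction, and the assembled raw HRDetect
#' feature set. The HRDetect probability itself is cohort-level (its
#' normalization is fitted across samples) and is added by
#' [run_cohort()], or directly via [hrdetect()] with fixed normalization
#' parameters.
#'
#' @param sample_id Sample name.
#' @param segments Allele-specific segment tibble for the sample.
#' @param snvs SNV tibble (`chrom`, `pos`, `ref`, `alt`).
#' @param deletions Deletion tibble (`chrom`, `pos`, `deleted_seq`).
#' @param svs SV tibble (`sv_type`, `chrom1`, `pos1`, `chrom2`, `pos2`,
#'   `size`).
#' @param reference Named character vector of contig sequences.
#' @param sbs_signatures,sv_signatures Signature matrices (96 and 32
#'   channels).
#' @param genome A [genome_model()].
#' @param config An [hrd_config()].
#' @return One-row tibble: `sample`, `loh`, `tai`, `lst`, `hrd_index`,
#'   `sbs3`, `sbs8`, `sv3`, `sv5`, `mh_fraction`, `n_snvs`,
#'   `n_deletions`, `n_svs`, `sbs3_high`.
#' @export
run_sample <- function(sample_id, segments, snvs, deletions, svs, reference,
                       sbs_signatures, sv_signatures, genome,
                       config = hrd_config()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("sample '", sample_id, "', stage ", name, ": ",
                   conditionMessage(e)))
    })
  }
  scars <- stage("scar_scores", compute_scar_scores(segments, genome, config))
  sbs_cat <- stage("sbs_catalog", build_sbs_catalog(snvs, reference))
  sv_cat <- stage("sv_catalog", build_sv_catalog(svs, config))
  sbs_exp <- stage("sbs_exposures", fit_exposures_nnls(sbs_cat, sbs_signatures))
  sv_exp <- stage("sv_exposures", fit_exposures_nnls(sv_cat, sv_signatures))
  flags <- stage("exposure_flags", exposure_flags(sbs_exp, sv_exp, config))
  mh <- stage("microhomology", microhomology_fraction(deletions, reference, config))
  tibble::tibble(
    sample = sample_id,
    loh = scars$loh, tai = scars$tai, lst = scars$lst,
    hrd_index = scars$hrd_index,
    sbs3 = flags$sbs3, sbs8 = flags$sbs8,
    sv3 = flags$sv3, sv5 = flags$sv5,
    mh_fraction = mh$fraction,
    n_snvs = nrow(snvs), n_deletions = nrow(deletions), n_svs = nrow(svs),
    sbs3_high = flags$sbs3_high
  )
}

#' Cohort-level analysis report
#'
#' Takes the per-sample metric table (rows from [run_sample()] or
#' equivalent), computes HRDetect with cohort-fitted normalization,
#' applies the classification thresholds, and assembles the cohort
#' statistics: Pearson correlation of HRD index vs SBS3, classification
#' counts, the trimodal HRD-score cutoff diagnostic (cohorts of at least
#' 30), and — when a clinical table is supplied — TTPp Kaplan-Meier
#' curves, log-rank tests and Cox models stratified by the HRD flags.
#' Samples without a clinical match are excluded from the survival layer
#' with a warning.
#'
#' @param metrics Per-sample tibble with at least `sample` and the six
#'   feature columns `sbs3`, `sbs8`, `sv3`, `sv5`, `hrd_index`,
#'   `mh_fraction`.
#' @param clinical Optional clinical tibble ([read_clinical_table()]);
#'   `patient_id` values are matched to `sample`.
#' @param config An [hrd_config()].
#' @param seed Integer seed for the mixture-fit initialization.
#' @return A list of class `hrd_cohort`: `metrics` (with `hrdetect` and
#'   flags), `correlation`, `counts`, `trimodal`, `survival` (or NULL),
#'   `config`. `tidy()` returns the metric table and `glance()` the
#'   headline cohort numbers.
#' @export
run_cohort <- function(metrics, clinical = NULL, config = hrd_config(),
                       seed = 1) {
  if (nrow(metrics) < 2) abort("run_cohort needs at least 2 samples")
  model <- hrdetect_model(log_epsilon = config$log_epsilon)
  metrics <- hrdetect(metrics, model)
  metrics <- classify_sample(metrics, config)
  correlation <- pearson_correlation(metrics$hrd_index, metrics$sbs3)
  counts <- tibble::tibble(
    n = nrow(metrics),
    n_hrd_high = sum(metrics$hrd_high),
    n_sbs3_high = sum(metrics$sbs3_high),
    n_hrdetect_positive = sum(metrics$hrdetect_positive)
  )
  trimodal <- if (nrow(metrics) >= 30) {
    tryCatch(fit_trimodal_cutoff(metrics$hrd_index, seed = seed),
             error = function(e) {
               warn(paste0("trimodal cutoff fit skipped: ", conditionMessage(e)))
               NULL
             })
  } else {
    NULL
  }
  surv <- NULL
  if (!is.null(clinical)) {
    ttpp <- compute_ttpp(clinical)
    unlinked <- setdiff(metrics$sample, ttpp$patient_id)
    if (length(unlinked) > 0) {
      warn(paste0("samples without platinum clinical linkage excluded from ",
                  "survival: ", paste(unlinked, collapse = ", ")))
    }
    obs <- dplyr::inner_join(ttpp, metrics, by = c(patient_id = "sample")) |>
      dplyr::mutate(brca_positive = .data$brca_status %in%
                      c("pathogenic-germline", "somatic"))
    surv <- list(observations = obs, strata = list())
    for (flag in c("hrd_high", "sbs3_high", "hrdetect_positive", "brca_positive")) {
      g1 <- obs[obs[[flag]], , drop = FALSE]
      g0 <- obs[!obs[[flag]], , drop = FALSE]
      if (nrow(g1) == 0 || nrow(g0) == 0) {
        warn(paste0("stratified analysis by ", flag,
                    " skipped: one group is empty"))
        next
      }
      cox <- tryCatch({
        dat <- dplyr::mutate(obs, flag = as.numeric(.data[[flag]]))
        cox_fit(dat, c("flag", "tumor_group", "n_platinum_lines"))
      }, error = function(e) {
        warn(paste0("Cox fit for ", flag, " failed: ", conditionMessage(e)))
        NULL
      })
      surv$strata[[flag]] <- list(
        km_positive = km_estimate(g1),
        km_negative = km_estimate(g0),
        logrank = logrank_test(g1, g0),
        cox = cox
      )
    }
  }
  structure(list(metrics = metrics, correlation = correlation, counts = counts,
                 trimodal = trimodal, survival = surv, config = config,
                 model = attr(metrics, "model")),
            class = "hrd_cohort")
}

#' @exportS3Method generics::tidy
tidy.hrd_cohort <- function(x, ...) x$metrics

#' @exportS3Method generics::glance
glance.hrd_cohort <- function(x, ...) {
  dplyr::bind_cols(
    x$counts,
    tibble::tibble(hrd_sbs3_r = x$correlation$r, hrd_sbs3_p = x$correlation$p,
                   trimodal_cutoff = if (is.null(x$trimodal)) NA_real_
                                     else x$trimodal$cutoff)
  )
}

#' @export
print.hrd_cohort <- function(x, ...) {
  cat("<hrd_cohort> ", x$counts$n, "samples;",
      x$counts$n_hrd_high, "HRD-high,", x$counts$n_sbs3_high, "SBS3-high,",
      x$counts$n_hrdetect_positive, "HRDetect-positive\n")
  cat("  HRD index vs SBS3: r =", format(round(x$correlation$r, 3)),
      " p =", format(signif(x$correlation$p, 3)), "\n")
  invisible(x)
}

#' Write a cohort report to disk
#'
#' Emits the per-sample metric table (TSV + JSON, via [write_results()])
#' and a machine-readable `report.json` containing the correlation,
#' classification counts, trimodal diagnostic, per-stratification
#' log-rank and Cox tables, and the full configuration echo, so every
#' threshold in the report is traceable. Identical inputs produce
#' byte-identical files.
#'
#' @param cohort An `hrd_cohort` from [run_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisible character vector of written paths.
#' @export
write_cohort_report <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- write_results(cohort$metrics, file.path(dir, "per_sample_metrics"))
  report <- list(
    config = unclass(cohort$config),
    counts = as.list(cohort$counts),
    correlation = as.list(cohort$correlation),
    trimodal = if (!is.null(cohort$trimodal)) {
      list(cutoff = cohort$trimodal$cutoff,
           integer_cutoff = cohort$trimodal$integer_cutoff,
           means = cohort$trimodal$means, sds = cohort$trimodal$sds,
           weights = cohort$trimodal$weights)
    },
    survival = if (!is.null(cohort$survival)) {
      lapply(cohort$survival$strata, function(s) {
        list(logrank = as.list(s$logrank),
             median_positive = s$km_positive$median,
             median_negative = s$km_negative$median,
             cox = if (!is.null(s$cox)) as.list(tidy(s$cox)))
      })
    }
  )
  rj <- file.path(dir, "report.json")
  jsonlite::write_json(report, rj, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(paths, report = rj))
}
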