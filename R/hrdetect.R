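hrdetect_features <- c("sbs3", "sbs8", "sv3", "sv5", "hrd_index", "mh_fraction")

#' The HRDetect logistic model
#'
#' HRDetect aggregates six HRD-associated features — SBS3 and SBS8
#' exposure proportions, SV signature 3 and 5 exposure proportions, the
#' HRD index, and the microhomology-deletion fraction — through a
#' logistic model whose published intercept (-3.364) and coefficients
#' (1.611, 0.091, 1.153, 0.847, 0.667, 2.398, in that feature order) are
#' used as-is, without refitting. Before entering the model each raw
#' feature x is transformed to `z = (ln(x + eps) - mean) / sd`; the
#' (mean, sd) pairs can be fitted on the analyzed cohort with
#' [fit_normalization()] or supplied fixed for single-sample scoring.
#'
#' @param normalization Optional tibble with columns `feature`, `mean`,
#'   `sd` covering the six features.
#' @param log_epsilon Offset inside the log transform (> 0; exposures can
#'   be exactly zero). Default 1.
#' @param intercept,coefficients Model constants; override only to
#'   explore, the defaults are the published values.
#' @return A list of class `hrdetect_model`.
#' @examples
#' m <- hrdetect_model()
#' m$coefficients
#' @export
hrdetect_model <- function(normalization = NULL, log_epsilon = 1.0,
                           intercept = -3.364,
                           coefficients = c(sbs3 = 1.611, sbs8 = 0.091,
                                            sv3 = 1.153, sv5 = 0.847,
                                            hrd_index = 0.667,
                                            mh_fraction = 2.398)) {
  if (length(coefficients) != 6) abort("hrdetect_model: exactly 6 coefficients required")
  names(coefficients) <- hrdetect_features
  if (log_epsilon <= 0) abort("hrdetect_model: log_epsilon must be > 0")
  if (!is.null(normalization)) {
    miss <- setdiff(hrdetect_features, normalization$feature)
    if (length(miss) > 0) {
      abort(paste0("normalization missing feature(s): ", paste(miss, collapse = ", ")))
    }
    if (any(normalization$sd <= 0)) abort("normalization sd must be > 0")
  }
  structure(list(intercept = intercept, coefficients = coefficients,
                 normalization = normalization, log_epsilon = log_epsilon),
            class = "hrdetect_model")
}

#' Fit per-feature normalization parameters on a cohort
#'
#' Computes the mean and standard deviation (denominator n-1) of
#' `ln(x + log_epsilon)` for each of the six HRDetect features across a
#' cohort, so that the cohort's transformed features have mean 0 and
#' standard deviation 1.
#'
#' @param features Tibble with one row per sample and the six feature
#'   columns `sbs3`, `sbs8`, `sv3`, `sv5`, `hrd_index`, `mh_fraction`.
#' @param log_epsilon Offset inside the log transform. Default 1.
#' @return Tibble with columns `feature`, `mean`, `sd`.
#' @export
fit_normalization <- function(features, log_epsilon = 1.0) {
  miss <- setdiff(hrdetect_features, names(features))
  if (length(miss) > 0) {
    abort(paste0("features missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (nrow(features) < 2) abort("fit_normalization needs a cohort of >= 2 samples")
  norm <- purrr::map_dfr(hrdetect_features, function(f) {
    lx <- log(features[[f]] + log_epsilon)
    tibble::tibble(feature = f, mean = mean(lx), sd = sd(lx))
  })
  flat <- norm$feature[norm$sd == 0 | !is.finite(norm$sd)]
  if (length(flat) > 0) {
    abort(paste0("constant feature(s), cannot normalize: ", paste(flat, collapse = ", ")))
  }
  norm
}

#' Transform raw HRDetect features to z-scores
#'
#' Applies `z = (ln(x + log_epsilon) - mean) / sd` per feature using the
#' model's normalization parameters.
#'
#' @param features Tibble with the six raw feature columns.
#' @param model An [hrdetect_model()] with normalization set.
#' @return Tibble of the six z-scored feature columns.
#' @export
transform_features <- function(features, model) {
  if (is.null(model$normalization)) {
    abort("model has no normalization parameters; fit or supply them first")
  }
  norm <- model$normalization
  out <- purrr::map(hrdetect_features, function(f) {
    i <- match(f, norm$feature)
    (log(features[[f]] + model$log_epsilon) - norm$mean[i]) / norm$sd[i]
  })
  names(out) <- hrdetect_features
  tibble::as_tibble(out)
}

#' HRDetect probability from normalized features
#'
#' `score = 1 / (1 + exp(-(intercept + sum(coef_i * z_i))))`. All six
#' coefficients are positive, so the score is strictly increasing in
#' every normalized feature, and lies strictly inside (0, 1) for finite
#' input.
#'
#' @param normalized Tibble (or named numeric vector) of the six
#'   z-scored features in model order.
#' @param model An [hrdetect_model()].
#' @return Numeric vector of probabilities, one per row.
#' @examples
#' z <- tibble::tibble(sbs3 = 0, sbs8 = 0, sv3 = 0, sv5 = 0,
#'                     hrd_index = 0, mh_fraction = 0)
#' hrdetect_score(z)  # 1 / (1 + exp(3.364))
#' @export
hrdetect_score <- function(normalized, model = hrdetect_model()) {
  if (is.numeric(normalized) && is.null(dim(normalized))) {
    normalized <- tibble::as_tibble(as.list(setNames(normalized, hrdetect_features)))
  }
  z <- as.matrix(normalized[, hrdetect_features, drop = FALSE])
  if (any(!is.finite(z))) abort("hrdetect_score: non-finite normalized feature")
  as.numeric(plogis(model$intercept + z %*% model$coefficients))
}

#' Score raw features through the full HRDetect pipeline
#'
#' Convenience wrapper: fits (or reuses) normalization, transforms the
#' features and evaluates the logistic model.
#'
#' @param features Tibble of raw features (>= 2 rows when normalization
#'   is fitted on the cohort itself).
#' @param model An [hrdetect_model()]; when its normalization is NULL the
#'   parameters are fitted on `features`.
#' @return Input tibble with an added `hrdetect` column; the model used
#'   (with its normalization) is attached as attribute `model`.
#' @export
hrdetect <- function(features, model = hrdetect_model()) {
  if (is.null(model$normalization)) {
    model <- hrdetect_model(normalization = fit_normalization(features, model$log_epsilon),
                            log_epsilon = model$log_epsilon,
                            intercept = model$intercept,
                            coefficients = model$coefficients)
  }
  out <- dplyr::mutate(features,
                       hrdetect = hrdetect_score(transform_features(features, model), model))
  attr(out, "model") <- model
  out
}

#' @exportS3Method generics::tidy
tidy.hrdetect_model <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", hrdetect_features),
                 estimate = c(x$intercept, unname(x$coefficients)))
}

#' @exportS3Method generics::glance
glance.hrdetect_model <- function(x, ...) {
  tibble::tibble(n_features = 6L, log_epsilon = x$log_epsilon,
                 normalization = if (is.null(x$normalization)) "unset" else "set")
}

#' Apply the HRD classification thresholds
#'
#' Adds the three published classification flags to a per-sample metric
#' table: `hrd_high` when the HRD index is at least 34 (inclusive),
#' `sbs3_high` when the SBS3 proportion strictly exceeds 0.05, and
#' `hrdetect_positive` when the HRDetect probability strictly exceeds
#' 0.7. When a `chord` column is present (externally computed), a
#' `chord_positive` flag (> 0.5) is carried through as annotation.
#'
#' @param metrics Tibble with columns `hrd_index`, `sbs3`, `hrdetect`
#'   (and optionally `chord`).
#' @param config An [hrd_config()].
#' @return `metrics` with the flag columns appended.
#' @examples
#' classify_sample(tibble::tibble(hrd_index = 34, sbs3 = 0.05, hrdetect = 0.7))
#' @export
classify_sample <- function(metrics, config = hrd_config()) {
  out <- dplyr::mutate(
    metrics,
    hrd_high = .data$hrd_index >= config$hrd_index_cutoff,
    sbs3_high = .data$sbs3 > config$sbs3_cutoff,
    hrdetect_positive = .data$hrdetect > config$hrdetect_cutoff
  )
  if ("chord" %in% names(metrics)) {
    out <- dplyr::mutate(out, chord_positive = .data$chord > config$chord_cutoff)
  }
  out
}
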