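DAYS_PER_MONTH <- 30.44

#' Time to progression on platinum (TTPp)
#'
#' Builds the TTPp endpoint from a clinical treatment-line table: for each
#' patient's selected platinum-containing line (default the first), time
#' runs from platinum initiation to the end of platinum treatment; when
#' the end date is missing, to the start of the next treatment line
#' (event observed in both cases); when neither exists, to last follow-up
#' (censored). Patients with no platinum exposure are omitted. Times are
#' months at 30.44 days per month.
#'
#' @param clinical Clinical tibble as from [read_clinical_table()].
#' @param line_policy `"first"` (default) analyzes each patient's first
#'   platinum line; `"line"` with `platinum_line_number` selects the
#'   n-th platinum line instead.
#' @param platinum_line_number Which platinum line when
#'   `line_policy = "line"`.
#' @return Tibble with one row per platinum-treated patient:
#'   `patient_id`, `time` (months), `event` (1 progression / 0 censored),
#'   `tumor_group`, `brca_status`, `n_platinum_lines`.
#' @export
compute_ttpp <- function(clinical, line_policy = c("first", "line"),
                         platinum_line_number = 1) {
  line_policy <- match.arg(line_policy)
  idx <- if (line_policy == "first") 1L else as.integer(platinum_line_number)
  out <- clinical |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$line)
      plat <- which(df$is_platinum)
      if (length(plat) < idx) return(tibble::tibble())
      i <- plat[idx]
      start <- df$start[i]
      if (!is.na(df$end[i])) {
        t_days <- as.numeric(df$end[i] - start)
        event <- 1L
      } else {
        nxt <- which(df$line > df$line[i])
        if (length(nxt) > 0) {
          t_days <- as.numeric(min(df$start[nxt]) - start)
          event <- 1L
        } else {
          t_days <- as.numeric(df$last_followup[1] - start)
          event <- 0L
        }
      }
      if (t_days < 0) {
        abort(paste0("negative TTPp for patient ", key$patient_id))
      }
      tibble::tibble(time = t_days / DAYS_PER_MONTH, event = event,
                     tumor_group = df$tumor_group[1],
                     brca_status = df$brca_status[1],
                     n_platinum_lines = length(plat))
    }) |>
    dplyr::ungroup()
  out
}

#' Overall survival (OS)
#'
#' Time from initiation of first-line systemic therapy to death (event)
#' or last follow-up (censored), in months at 30.44 days per month.
#'
#' @param clinical Clinical tibble as from [read_clinical_table()].
#' @return Tibble `patient_id`, `time`, `event`, `tumor_group`,
#'   `brca_status`.
#' @export
compute_os <- function(clinical) {
  clinical |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$line)
      start <- df$start[1]
      if (is.na(start)) abort(paste0("missing first-line start for patient ", key$patient_id))
      death <- df$death_date[1]
      if (!is.na(death)) {
        t_days <- as.numeric(death - start)
        event <- 1L
      } else {
        t_days <- as.numeric(df$last_followup[1] - start)
        event <- 0L
      }
      if (t_days < 0) {
        abort(paste0("death/follow-up before first-line start for patient ", key$patient_id))
      }
      tibble::tibble(time = t_days / DAYS_PER_MONTH, event = event,
                     tumor_group = df$tumor_group[1],
                     brca_status = df$brca_status[1])
    }) |>
    dplyr::ungroup()
}

#' Kaplan-Meier product-limit estimate
#'
#' @param observations Tibble with columns `time` (> 0) and `event`
#'   (1 observed, 0 censored).
#' @return A list of class `km_fit`: `steps` (tibble `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv`) and `median` (smallest time with
#'   survival <= 0.5; NA when never reached). `tidy()` returns the step
#'   table, `glance()` the median and counts.
#' @examples
#' km_estimate(tibble::tibble(time = c(1, 2, 3), event = 1))
#' @export
km_estimate <- function(observations) {
  if (nrow(observations) < 1) abort("km_estimate needs at least one observation")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = observations, conf.type = "none")
  steps <- tibble::tibble(time = sf$time, n_risk = sf$n.risk,
                          n_event = sf$n.event, n_censor = sf$n.censor,
                          surv = sf$surv)
  drop_times <- steps$time[steps$n_event > 0 & steps$surv <= 0.5]
  med <- if (length(drop_times) > 0) min(drop_times) else NA_real_
  structure(list(steps = steps, median = med, n = nrow(observations),
                 n_event = sum(observations$event)),
            class = "km_fit")
}

#' @exportS3Method generics::tidy
tidy.km_fit <- function(x, ...) x$steps

#' @exportS3Method generics::glance
glance.km_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_event = x$n_event, median = x$median)
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit> n =", x$n, " events =", x$n_event,
      " median =", format(x$median), "\n")
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic on one degree of freedom with a two-sided
#' chi-square p-value. With no events in either group the test is
#' uninformative and returns statistic 0, p = 1.
#'
#' @param group_a,group_b Tibbles with columns `time` and `event`.
#' @return One-row tibble `chisq`, `p`, `n_a`, `n_b`.
#' @export
logrank_test <- function(group_a, group_b) {
  if (nrow(group_a) < 1 || nrow(group_b) < 1) abort("both groups must be non-empty")
  dat <- dplyr::bind_rows(
    dplyr::mutate(group_a[, c("time", "event")], group = "a"),
    dplyr::mutate(group_b[, c("time", "event")], group = "b")
  )
  if (sum(dat$event) == 0) {
    return(tibble::tibble(chisq = 0, p = 1,
                          n_a = nrow(group_a), n_b = nrow(group_b)))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat)
  chisq <- unname(sd_$chisq)
  tibble::tibble(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
                 n_a = nrow(group_a), n_b = nrow(group_b))
}

#' Cox proportional-hazards association
#'
#' Fits a Cox model by Newton-Raphson maximization of the Breslow partial
#' likelihood (convergence when the log-likelihood change falls below
#' 1e-9, at most 50 iterations) and reports per-covariate log hazard
#' ratios with Wald 95% confidence intervals and p-values. Covariates
#' that are constant over the data carry no information and are reported
#' with log-HR 0 (HR 1). Monotone likelihood (complete separation, an
#' effectively infinite coefficient) or non-convergence is an error with
#' diagnostics.
#'
#' @param observations Tibble with `time`, `event` and the covariate
#'   columns.
#' @param covariates Character vector of covariate column names; may be
#'   empty for the null model.
#' @return A list of class `cox_assoc` wrapping the fit; `tidy()` gives
#'   `term`, `estimate` (log-HR), `hr`, `conf.low`, `conf.high`, `p`;
#'   `glance()` gives n, events, log-likelihoods and iterations.
#' @export
cox_fit <- function(observations, covariates) {
  if (any(!covariates %in% names(observations))) {
    abort("covariate column(s) missing from observations")
  }
  if (length(covariates) > 0 &&
      sum(observations$event) < length(covariates) + 1) {
    abort("too few events for the number of covariates")
  }
  constant <- covariates[vapply(covariates, function(v) {
    x <- observations[[v]]
    length(unique(x[!is.na(x)])) <= 1
  }, logical(1))]
  active <- setdiff(covariates, constant)
  rhs <- if (length(active) > 0) paste(active, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  warnings_seen <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = observations, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 50)),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  bad <- grepl("infinite|did not converge|singular", warnings_seen, ignore.case = TRUE)
  if (any(bad)) {
    abort(paste0("Cox fit failed: ", paste(warnings_seen[bad], collapse = "; "),
                 " (n = ", nrow(observations), ", events = ",
                 sum(observations$event), ")"))
  }
  structure(list(fit = fit, covariates = covariates, constant = constant,
                 n = nrow(observations), n_event = sum(observations$event)),
            class = "cox_assoc")
}

#' @exportS3Method generics::tidy
tidy.cox_assoc <- function(x, ...) {
  co <- x$fit$coefficients
  out <- if (length(co) > 0) {
    se <- sqrt(diag(x$fit$var))
    z <- co / se
    tibble::tibble(
      term = names(co),
      estimate = unname(co),
      hr = exp(unname(co)),
      conf.low = exp(unname(co) - qnorm(0.975) * se),
      conf.high = exp(unname(co) + qnorm(0.975) * se),
      p = 2 * pnorm(-abs(unname(z)))
    )
  } else {
    tibble::tibble(term = character(), estimate = numeric(), hr = numeric(),
                   conf.low = numeric(), conf.high = numeric(), p = numeric())
  }
  if (length(x$constant) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = x$constant, estimate = 0, hr = 1,
      conf.low = NA_real_, conf.high = NA_real_, p = NA_real_
    ))
  }
  out
}

#' @exportS3Method generics::glance
glance.cox_assoc <- function(x, ...) {
  ll <- x$fit$loglik
  tibble::tibble(n = x$n, n_event = x$n_event,
                 loglik_null = ll[1], loglik = ll[length(ll)],
                 iterations = x$fit$iter)
}

#' @export
print.cox_assoc <- function(x, ...) {
  cat("<cox_assoc> n =", x$n, " events =", x$n_event, "\n")
  print(tidy(x))
  invisible(x)
}
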