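test_that("TTPp follows the end-date / next-line / follow-up precedence", {
  cl <- clinical_fixture()
  ttpp <- compute_ttpp(cl)
  # P1: platinum line 1 with an end date, 2015-01-01 to 2015-07-01
  p1 <- ttpp[ttpp$patient_id == "P1", ]
  expect_equal(p1$time, 181 / 30.44, tolerance = 1e-12)
  expect_equal(p1$event, 1L)
  # P4: single platinum line, no end date, no next line: censored at follow-up
  p4 <- ttpp[ttpp$patient_id == "P4", ]
  expect_equal(p4$event, 0L)
  expect_equal(p4$time, as.numeric(as.Date("2016-04-01") - as.Date("2015-04-01")) / 30.44)
  # P3: platinum only in line 2; first-platinum policy picks line 2,
  # end date missing and no later line -> censored at follow-up
  p3 <- ttpp[ttpp$patient_id == "P3", ]
  expect_equal(p3$event, 0L)
  expect_equal(p3$n_platinum_lines, 1L)

  # end missing but a next line exists: event at next-line start
  cl2 <- cl
  cl2$end[cl2$patient_id == "P1"] <- as.Date(NA)
  t_next <- compute_ttpp(cl2)
  p1b <- t_next[t_next$patient_id == "P1", ]
  expect_equal(p1b$event, 1L)
  expect_equal(p1b$time, as.numeric(as.Date("2015-09-01") - as.Date("2015-01-01")) / 30.44)

  # a patient with no platinum at all is dropped
  cl3 <- cl
  cl3$is_platinum[cl3$patient_id == "P4"] <- FALSE
  expect_false("P4" %in% compute_ttpp(cl3)$patient_id)
})

test_that("OS runs from first-line start to death or censoring", {
  cl <- clinical_fixture()
  os <- compute_os(cl)
  p2 <- os[os$patient_id == "P2", ]
  expect_equal(p2$event, 1L)
  expect_equal(p2$time, as.numeric(as.Date("2017-01-01") - as.Date("2015-02-01")) / 30.44)
  p1 <- os[os$patient_id == "P1", ]
  expect_equal(p1$event, 0L)

  bad <- cl
  bad$death_date[bad$patient_id == "P1"] <- as.Date("2014-06-01")
  expect_error(compute_os(bad), "before")
})

test_that("Kaplan-Meier matches the hand product-limit table", {
  km <- km_estimate(tibble::tibble(time = c(1, 2, 3), event = 1))
  expect_equal(tidy(km)$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(glance(km)$median, 2)

  all_cens <- km_estimate(tibble::tibble(time = c(5, 8, 9), event = 0))
  expect_true(all(tidy(all_cens)$surv == 1))
  expect_true(is.na(glance(all_cens)$median))

  withr::with_seed(3, {
    obs <- tibble::tibble(time = rexp(40, 0.2), event = rbinom(40, 1, 0.7))
  })
  km2 <- km_estimate(obs)
  o <- oracle_km(obs$time, obs$event)
  got <- tidy(km2)
  expect_equal(got$surv[got$n_event > 0], o$surv, tolerance = 1e-12)

  # duplicating every observation leaves the curve unchanged
  km_dup <- km_estimate(dplyr::bind_rows(obs, obs))
  expect_equal(tidy(km_dup)$surv, tidy(km2)$surv, tolerance = 1e-12)

  # with no censoring KM equals the empirical survival function
  ev <- tibble::tibble(time = c(2, 4, 4, 7, 9), event = 1)
  km3 <- km_estimate(ev)
  emp <- vapply(tidy(km3)$time, function(t) mean(ev$time > t), numeric(1))
  expect_equal(tidy(km3)$surv, emp, tolerance = 1e-12)
})

test_that("log-rank statistic matches the hand O-E/V computation", {
  a <- tibble::tibble(time = c(1, 3, 5, 8), event = c(1, 1, 0, 1))
  b <- tibble::tibble(time = c(2, 4, 6, 9), event = c(1, 0, 1, 1))
  out <- logrank_test(a, b)
  hand <- oracle_logrank_chisq(a$time, a$event, b$time, b$event)
  expect_equal(out$chisq, hand, tolerance = 1e-10)

  # symmetry and the identical-group null
  expect_equal(logrank_test(b, a)$chisq, out$chisq, tolerance = 1e-12)
  same <- logrank_test(a, a)
  expect_equal(same$chisq, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  none <- logrank_test(tibble::tibble(time = 1:3, event = 0),
                       tibble::tibble(time = 2:4, event = 0))
  expect_equal(none$p, 1)
})

test_that("Cox fit recovers a two-group hazard ratio and handles degenerate input", {
  withr::with_seed(7, {
    n <- 500
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.1 * ifelse(x == 1, 0.5, 1))
    obs <- tibble::tibble(time = t, event = 1L, x = x)
  })
  fit <- cox_fit(obs, "x")
  td <- tidy(fit)
  expect_gt(td$hr, 0.4)
  expect_lt(td$hr, 0.62)
  expect_true(td$conf.low < 0.5 && 0.5 < td$conf.high)

  # constant covariate carries no information: log-HR 0
  obs$flat <- 0
  td2 <- tidy(cox_fit(obs, c("x", "flat")))
  expect_equal(td2$estimate[td2$term == "flat"], 0)
  expect_equal(td2$hr[td2$term == "flat"], 1)

  # time rescaling leaves the estimate unchanged
  obs2 <- dplyr::mutate(obs, time = time * 12)
  expect_equal(tidy(cox_fit(obs2, "x"))$estimate[1], td$estimate[1],
               tolerance = 1e-8)
})

test_that("null Cox partial likelihood equals -sum(log risk-set size) at event times", {
  withr::with_seed(8, {
    obs <- tibble::tibble(time = rexp(30, 0.2), event = 1L)
  })
  fit <- cox_fit(obs, character(0))
  expected <- -sum(vapply(obs$time, function(t) log(sum(obs$time >= t)),
                          numeric(1)))
  expect_equal(glance(fit)$loglik, expected, tolerance = 1e-10)
})

test_that("Cox errors on complete separation with diagnostics", {
  obs <- tibble::tibble(time = c(1, 2, 3, 10, 11, 12),
                        event = 1L, x = c(1, 1, 1, 0, 0, 0))
  expect_error(cox_fit(obs, "x"), "infinite|converge")
  expect_error(cox_fit(tibble::tibble(time = 1:3, event = c(1L, 0L, 0L),
                                      x = c(0, 1, 0), y = c(1, 0, 0)),
                       c("x", "y")), "few events")
})
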