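test_that("SBS catalog maps contexts under the pyrimidine-strand convention", {
  # forward strand: A C G with C>T at the centre
  ref <- c(chr1 = "TTACGTT")
  cat1 <- build_sbs_catalog(tibble::tibble(chrom = "chr1", pos = 4, ref = "C",
                                           alt = "T"), ref)
  expect_equal(cat1$count[cat1$channel == "A[C>T]G"], 1L)
  expect_equal(sum(cat1$count), 1L)

  # purine reference: G>A with 5' T and 3' C reverse-complements to G[C>T]A
  ref2 <- c(chr1 = "AATGCAA")
  cat2 <- build_sbs_catalog(tibble::tibble(chrom = "chr1", pos = 4, ref = "G",
                                           alt = "A"), ref2)
  expect_equal(cat2$count[cat2$channel == "G[C>T]A"], 1L)
})

test_that("catalog building conserves counts and reports rejections", {
  sim <- simulate_snvs(toy_sbs_sigs, c(0.5, 0.3, 0.2, rep(0, 7)), 1000, seed = 3)
  ct <- build_sbs_catalog(sim$snvs, sim$reference)
  expect_equal(sum(ct$count), 1000L)
  expect_equal(setNames(ct$count, ct$channel), sim$truth$channel_counts)
  expect_equal(attr(ct, "n_rejected"), 0L)

  # an SNV at the very first base has no 5' flank: rejected, not an error
  edge <- tibble::tibble(chrom = "chrS", pos = 1L,
                         ref = substr(sim$reference[["chrS"]], 1, 1), alt = "T")
  edge$alt <- setdiff(c("A", "C", "G", "T"), edge$ref)[1]
  ct_edge <- build_sbs_catalog(edge, sim$reference)
  expect_equal(sum(ct_edge$count), 0L)
  expect_equal(attr(ct_edge, "n_rejected"), 1L)

  expect_error(build_sbs_catalog(tibble::tibble(chrom = "chrS", pos = 1e9,
                                                ref = "A", alt = "T"),
                                 sim$reference), "outside")
})

test_that("reverse-complementing the genome leaves the catalog unchanged", {
  sim <- simulate_snvs(toy_sbs_sigs, c(rep(0.1, 10)), 400, seed = 8)
  ct <- build_sbs_catalog(sim$snvs, sim$reference)
  seq <- sim$reference[["chrS"]]
  n <- nchar(seq)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
  comp <- function(x) chartr("ACGT", "TGCA", x)
  snvs_rc <- dplyr::mutate(sim$snvs, pos = n - pos + 1L,
                           ref = comp(ref), alt = comp(alt))
  ct_rc <- build_sbs_catalog(snvs_rc, c(chrS = rc))
  expect_equal(ct_rc$count, ct$count)
})

test_that("SV catalog applies size bins and the breakpoint clustering rule", {
  lone <- tibble::tibble(sv_type = "DEL", chrom1 = "chr1", pos1 = 1e6,
                         chrom2 = "chr1", pos2 = 1e6 + 5e4, size = 5e4)
  ct <- build_sv_catalog(lone)
  expect_equal(ct$count[ct$channel == "non-clustered_DEL_10-100kb"], 1L)
  expect_equal(sum(ct$count), 1L)

  two_tra <- tibble::tibble(
    sv_type = "TRA", chrom1 = "chr1", pos1 = c(5e6, 5e6 + 1e4),
    chrom2 = c("chr2", "chr3"), pos2 = c(1e6, 9e7), size = NA_real_)
  ct2 <- build_sv_catalog(two_tra)
  expect_equal(ct2$count[ct2$channel == "clustered_TRA"], 2L)

  empty <- build_sv_catalog(lone[0, ])
  expect_equal(sum(empty$count), 0L)
  expect_equal(nrow(empty), 32L)
})

test_that("NNLS recovers noiseless integral mixtures exactly", {
  S <- as.matrix(integral_sigs[, -1])
  counts <- as.integer(round(1000 * (S %*% c(0.6, 0.3, 0.1))))
  expect_equal(sum(abs(1000 * (S %*% c(0.6, 0.3, 0.1)) - counts)), 0)  # integral
  fit <- fit_exposures_nnls(make_catalog(counts), integral_sigs)
  expect_equal(fit$proportion, c(0.6, 0.3, 0.1), tolerance = 1e-9)
  expect_equal(sum(fit$raw), 1000, tolerance = 1e-9)
})

test_that("NNLS degenerate inputs: empty catalog and single signature", {
  fit0 <- fit_exposures_nnls(make_catalog(integer(96)), integral_sigs)
  expect_equal(fit0$raw, rep(0, 3))
  expect_equal(fit0$proportion, rep(0, 3))

  S <- as.matrix(integral_sigs[, -1])
  counts <- as.integer(round(500 * S[, 1]))
  fit1 <- fit_exposures_nnls(make_catalog(counts), integral_sigs)
  expect_equal(fit1$proportion, c(1, 0, 0), tolerance = 1e-12)

  expect_error(fit_exposures_nnls(make_catalog(integer(96))[1:40, ], integral_sigs),
               "channels")
})

test_that("NNLS recovers multinomial mixtures with small error", {
  p_true <- c(0.5, 0.3, 0.2)
  S <- as.matrix(toy_sbs_sigs[, 2:4])
  errs <- vapply(1:5, function(s) {
    counts <- withr::with_seed(s, as.integer(rmultinom(1, 10000, S %*% p_true)))
    fit <- fit_exposures_nnls(make_catalog(counts), toy_sbs_sigs[, 1:4])
    mean(abs(fit$proportion - p_true))
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})

test_that("MCMC exposures are reproducible and agree with NNLS", {
  S <- as.matrix(toy_sbs_sigs[, 2:4])
  counts <- withr::with_seed(77,
    as.integer(rmultinom(1, 10000, S %*% c(0.5, 0.3, 0.2))))
  catalog <- make_catalog(counts)
  sigs3 <- toy_sbs_sigs[, 1:4]
  m1 <- fit_exposures_mcmc(catalog, sigs3, n_iterations = 8000, seed = 5)
  m2 <- fit_exposures_mcmc(catalog, sigs3, n_iterations = 8000, seed = 5)
  expect_equal(m1, m2)
  nn <- fit_exposures_nnls(catalog, sigs3)
  expect_true(all(abs(m1$proportion - nn$proportion) < 0.03))
  expect_true(all(m1$ci_lower <= m1$proportion & m1$proportion <= m1$ci_upper))

  # single-signature catalog concentrates on that signature
  counts1 <- as.integer(round(6000 * S[, 2]))
  mono <- fit_exposures_mcmc(make_catalog(counts1), sigs3,
                             n_iterations = 8000, seed = 6)
  expect_gt(mono$proportion[mono$signature == "SBS2"], 0.97)
})

test_that("exposure flags apply the strict SBS3 cutoff and need the named signatures", {
  mk <- function(sigs, props) tibble::tibble(signature = sigs, raw = props * 100,
                                             proportion = props)
  sbs <- mk(c("SBS1", "SBS3", "SBS8"), c(0.75, 0.05, 0.20))
  sv <- mk(c("SV1", "SV3", "SV5"), c(0.5, 0.3, 0.2))
  f <- exposure_flags(sbs, sv)
  expect_false(f$sbs3_high)   # 0.05 exactly is not high (strict >)
  expect_equal(f$sv3, 0.3)

  sbs$proportion[2] <- 0.223
  expect_true(exposure_flags(sbs, sv)$sbs3_high)

  sbs$proportion[2] <- 0
  expect_false(exposure_flags(sbs, sv)$sbs3_high)

  expect_error(exposure_flags(mk("SBS1", 1), sv), "SBS3")
  expect_error(exposure_flags(sbs, mk("SV1", 1)), "SV3")
})
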