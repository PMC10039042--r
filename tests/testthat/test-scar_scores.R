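g1 <- make_toy_genome(1, 100)  # centromere 48.5-51.5 Mb

test_that("merge_segments joins abutting equal-state runs and is idempotent", {
  segs <- seg("chr1", c(0, 8, 16), c(8, 16, 30), c(2, 2, 3), c(0, 0, 0))
  m_state <- merge_segments(segs)
  expect_equal(nrow(m_state), 2)
  expect_equal(m_state$end[1], 16e6)

  m_loh <- merge_segments(segs, by = "loh")
  expect_equal(nrow(m_loh), 1)
  expect_true(m_loh$class_member)
  expect_equal(c(m_loh$start, m_loh$end), c(0, 30e6))

  expect_equal(merge_segments(m_state), m_state)

  gap <- seg("chr1", c(0, 10), c(8, 20), c(2, 2), c(0, 0))
  expect_equal(nrow(merge_segments(gap, by = "loh")), 2)
})

test_that("LOH score counts long sub-chromosomal LOH regions only", {
  diploid <- seg("chr1", 0, 100, 2, 1)
  expect_equal(compute_loh_score(diploid, g1), 0)

  one <- seg("chr1", c(0, 30, 50), c(30, 50, 100), c(2, 2, 2), c(1, 0, 1))
  expect_equal(compute_loh_score(one, g1), 1)
  expect_equal(oracle_loh(one, g1), 1)

  short <- seg("chr1", c(0, 30, 44), c(30, 44, 100), c(2, 2, 2), c(1, 0, 1))
  expect_equal(compute_loh_score(short, g1), 0)  # 14 Mb, below 15

  whole <- seg("chr1", 0, 100, 1, 0)
  expect_equal(compute_loh_score(whole, g1), 0)
  expect_equal(oracle_loh(whole, g1), 0)
})

test_that("TAI score requires telomere anchoring and centromere exclusion", {
  balanced <- seg("chr1", 0, 100, 2, 1)
  expect_equal(compute_tai_score(balanced, g1), 0)

  p_term <- seg("chr1", c(0, 20), c(20, 100), c(3, 2), c(1, 1))
  expect_equal(compute_tai_score(p_term, g1), 1)
  expect_equal(oracle_tai(p_term, g1), 1)

  spanning <- seg("chr1", c(0, 60), c(60, 100), c(3, 2), c(1, 1))
  expect_equal(compute_tai_score(spanning, g1), 0)  # crosses the centromere

  interior <- seg("chr1", c(0, 20, 40), c(20, 40, 100), c(2, 3, 2), c(1, 1, 1))
  expect_equal(compute_tai_score(interior, g1), 0)  # AI region not telomeric

  short_tai <- seg("chr1", c(0, 10), c(10, 100), c(3, 2), c(1, 1))
  expect_equal(compute_tai_score(short_tai, g1), 0)  # 10 Mb < 11
})

test_that("LST counts junctions between large segments after smoothing", {
  uniform <- seg("chr1", 0, 100, 2, 1)
  expect_equal(compute_lst_score(uniform, g1), 0)

  # one junction on the q arm: 20 Mb (2,1) | 20 Mb (3,1) abutting
  one <- seg("chr1", c(0, 52, 72), c(52, 72, 92), c(2, 2, 3), c(1, 1, 1))
  expect_equal(compute_lst_score(one, g1), 1)
  expect_equal(oracle_lst(one, g1), 1)

  # a 2 Mb interloper is smoothed away and the junction still counts
  smoothed <- seg("chr1", c(52, 70, 72), c(70, 72, 92), c(2, 4, 3), c(1, 2, 1))
  expect_equal(compute_lst_score(smoothed, g1), 1)
  expect_equal(oracle_lst(smoothed, g1), 1)

  # equal-state flanks re-merge across the removed segment: no junction
  healed <- seg("chr1", c(52, 70, 72), c(70, 72, 92), c(2, 4, 2), c(1, 2, 1))
  expect_equal(compute_lst_score(healed, g1), 0)

  # junction across a gap wider than the smoothing scale does not count
  gapped <- seg("chr1", c(52, 76), c(72, 96), c(2, 3), c(1, 1))
  expect_equal(compute_lst_score(gapped, g1), 0)

  # arm split: segments on opposite sides of the centromere midpoint
  # never form a junction
  split <- seg("chr1", c(20, 50), c(50, 80), c(2, 3), c(1, 1))
  expect_equal(compute_lst_score(split, g1), oracle_lst(split, g1))
})

test_that("HRD index is exactly the sum of the three components", {
  sim <- simulate_profile(toy_genome8, 3, 2, 4, seed = 21)
  s <- compute_scar_scores(sim$segments, toy_genome8)
  expect_equal(s$hrd_index, s$loh + s$tai + s$lst)
  expect_equal(unlist(s), c(loh = 3, tai = 2, lst = 4, hrd_index = 9))
  expect_true(s$hrd_index >= max(s$loh, s$tai, s$lst))
})

test_that("scar scores equal the brute-force oracle on random profiles", {
  for (i in 1:25) {
    n_loh <- i %% 5
    n_tai <- i %% 4
    n_lst <- i %% 6
    sim <- simulate_profile(toy_genome8, n_loh, n_tai, n_lst, seed = 1000 + i)
    s <- compute_scar_scores(sim$segments, toy_genome8)
    expect_equal(s$loh, oracle_loh(sim$segments, toy_genome8), info = paste("seed", i))
    expect_equal(s$tai, oracle_tai(sim$segments, toy_genome8), info = paste("seed", i))
    expect_equal(s$lst, oracle_lst(sim$segments, toy_genome8), info = paste("seed", i))
    expect_equal(s$loh, n_loh)
    expect_equal(s$tai, n_tai)
    expect_equal(s$lst, n_lst)
  }
})

test_that("planting one extra LOH region increments only the LOH score", {
  base <- simulate_profile(toy_genome8, 2, 2, 2, seed = 31)
  more <- simulate_profile(toy_genome8, 3, 2, 2, seed = 31)
  s0 <- compute_scar_scores(base$segments, toy_genome8)
  s1 <- compute_scar_scores(more$segments, toy_genome8)
  expect_equal(s1$loh, s0$loh + 1)
  expect_equal(s1$tai, s0$tai)
  expect_equal(s1$lst, s0$lst)
})

test_that("scores are invariant under joint rescaling of coordinates and thresholds", {
  sim <- simulate_profile(toy_genome8, 2, 1, 3, seed = 41)
  f <- 2.5
  segs2 <- dplyr::mutate(sim$segments, start = start * f, end = end * f)
  g2 <- genome_model(toy_genome8$chrom, toy_genome8$length * f,
                     toy_genome8$cen_start * f, toy_genome8$cen_end * f)
  cfg2 <- hrd_config(loh_min_mb = 15 * f, tai_min_mb = 11 * f,
                     lst_min_seg_mb = 10 * f, lst_smooth_mb = 3 * f)
  expect_equal(compute_scar_scores(segs2, g2, cfg2),
               compute_scar_scores(sim$segments, toy_genome8))
})
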