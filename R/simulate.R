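# Synthetic-data generators. Every generator is constructive: features are
# planted with enforced spacing so the ground truth is exact, and every
# generator is deterministic given its seed.

MARGIN_BP <- 4e6      # isolation margin around planted events (> LST smoothing)
SLOT_BP <- 30e6       # interior slot width for one planted LOH or LST event
TEL_RESERVE_BP <- 24e6  # telomere reservation: up to 20 Mb event + margin

profile_slots <- function(genome) {
  tel <- list()
  interior <- list()
  for (i in seq_len(nrow(genome))) {
    chrom <- genome$chrom[i]
    L <- genome$length[i]
    cs <- genome$cen_start[i]
    ce <- genome$cen_end[i]
    if (cs >= TEL_RESERVE_BP) {
      tel[[length(tel) + 1]] <- list(chrom = chrom, side = "p")
    }
    if (L - ce >= TEL_RESERVE_BP) {
      tel[[length(tel) + 1]] <- list(chrom = chrom, side = "q")
    }
    p_lo <- TEL_RESERVE_BP
    p_hi <- cs - MARGIN_BP
    if (p_hi - p_lo >= SLOT_BP) {
      for (s in seq(p_lo, p_hi - SLOT_BP, by = SLOT_BP)) {
        interior[[length(interior) + 1]] <- list(chrom = chrom, start = s)
      }
    }
    q_lo <- ce + MARGIN_BP
    q_hi <- L - TEL_RESERVE_BP
    if (q_hi - q_lo >= SLOT_BP) {
      for (s in seq(q_lo, q_hi - SLOT_BP, by = SLOT_BP)) {
        interior[[length(interior) + 1]] <- list(chrom = chrom, start = s)
      }
    }
  }
  list(telomeric = tel, interior = interior)
}

#' Simulate an allele-specific segment profile with planted scars
#'
#' Plants exactly `n_loh` qualifying LOH regions, `n_tai` telomeric
#' allelic-imbalance regions and `n_lst` large-scale state transitions on
#' a diploid heterozygous (2,1) background. Events are placed in
#' pre-computed slots separated by isolation margins larger than the LST
#' smoothing scale, so no accidental scars arise and
#' [compute_scar_scores()] on the output returns exactly the requested
#' counts (under the default [hrd_config()] thresholds).
#'
#' @param genome A [genome_model()]; each chromosome contributes up to two
#'   telomeric slots (TAI) and several interior slots (LOH or LST).
#' @param n_loh,n_tai,n_lst Requested scar counts.
#' @param seed Integer seed.
#' @param sample_id Sample name stored in the profile.
#' @return List with `segments` (profile tibble) and `truth`
#'   (`loh`, `tai`, `lst`, `hrd_index`).
#' @examples
#' g <- make_toy_genome(4, 200)
#' sim <- simulate_profile(g, 2, 1, 2, seed = 7)
#' sim$truth
#' @export
simulate_profile <- function(genome, n_loh, n_tai, n_lst, seed,
                             sample_id = "synthetic") {
  slots <- profile_slots(genome)
  if (n_tai > length(slots$telomeric)) {
    abort(paste0("requested ", n_tai, " TAI events but the genome offers only ",
                 length(slots$telomeric), " telomeric slots"))
  }
  if (n_loh + n_lst > length(slots$interior)) {
    abort(paste0("requested ", n_loh + n_lst, " interior events but the genome ",
                 "offers only ", length(slots$interior), " interior slots"))
  }
  events <- withr::with_seed(seed, {
    ev <- list()
    tel_use <- sample(slots$telomeric, n_tai)
    int_use <- sample(slots$interior, n_loh + n_lst)
    for (t in tel_use) {
      len <- runif(1, 12e6, 19e6)
      L <- genome$length[genome$chrom == t$chrom]
      if (t$side == "p") {
        ev[[length(ev) + 1]] <- tibble::tibble(chrom = t$chrom, start = 0,
                                               end = len, total_cn = 3L, minor_cn = 1L)
      } else {
        ev[[length(ev) + 1]] <- tibble::tibble(chrom = t$chrom, start = L - len,
                                               end = L, total_cn = 3L, minor_cn = 1L)
      }
    }
    kinds <- sample(c(rep("loh", n_loh), rep("lst", n_lst)))
    for (j in seq_along(kinds)) {
      s <- int_use[[j]]$start + MARGIN_BP
      if (kinds[j] == "loh") {
        len <- runif(1, 16e6, 21e6)
        ev[[length(ev) + 1]] <- tibble::tibble(chrom = int_use[[j]]$chrom,
                                               start = s, end = s + len,
                                               total_cn = 2L, minor_cn = 0L)
      } else {
        w <- runif(1, 10.5e6, 11e6)
        ev[[length(ev) + 1]] <- dplyr::bind_rows(
          tibble::tibble(chrom = int_use[[j]]$chrom, start = s, end = s + w,
                         total_cn = 2L, minor_cn = 1L),
          tibble::tibble(chrom = int_use[[j]]$chrom, start = s + w, end = s + 2 * w,
                         total_cn = 3L, minor_cn = 1L)
        )
      }
    }
    dplyr::bind_rows(
      tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                     total_cn = integer(), minor_cn = integer()),
      ev
    )
  })
  # Fill the complement (with isolation margins around events) with the
  # diploid heterozygous baseline.
  baseline <- list()
  for (i in seq_len(nrow(genome))) {
    chrom <- genome$chrom[i]
    L <- genome$length[i]
    ev <- events[events$chrom == chrom, , drop = FALSE]
    ev <- dplyr::arrange(ev, .data$start)
    cursor <- 0
    bounds <- rbind(cbind(pmax(ev$start - MARGIN_BP, 0), pmin(ev$end + MARGIN_BP, L)))
    if (nrow(ev) > 0) {
      for (r in seq_len(nrow(bounds))) {
        if (bounds[r, 1] > cursor) {
          baseline[[length(baseline) + 1]] <- tibble::tibble(
            chrom = chrom, start = cursor, end = bounds[r, 1],
            total_cn = 2L, minor_cn = 1L)
        }
        cursor <- max(cursor, bounds[r, 2])
      }
    }
    if (cursor < L) {
      baseline[[length(baseline) + 1]] <- tibble::tibble(
        chrom = chrom, start = cursor, end = L, total_cn = 2L, minor_cn = 1L)
    }
  }
  segments <- dplyr::bind_rows(dplyr::bind_rows(baseline), events) |>
    dplyr::mutate(sample = sample_id, .before = 1) |>
    dplyr::arrange(.data$chrom, .data$start)
  list(segments = validate_segments(segments, genome),
       truth = list(loh = n_loh, tai = n_tai, lst = n_lst,
                    hrd_index = n_loh + n_tai + n_lst))
}

#' Deterministic toy signature matrix
#'
#' Builds a synthetic signature reference in the COSMIC layout: sparse
#' random probability columns over the 96 SBS or 32 SV channels, named
#' `SBS1 ... SBSk` / `SV1 ... SVk` so the HRD-relevant names (SBS3, SBS8,
#' SV3, SV5) exist for the default sizes. Purely synthetic — the columns
#' are not the COSMIC signatures, only a stand-in with the same shape.
#'
#' @param kind `"sbs"` (96 channels) or `"sv"` (32 channels).
#' @param n_signatures Number of columns (default 10 for SBS, 6 for SV).
#' @param seed Integer seed.
#' @return Signature tibble as from [read_signature_matrix()].
#' @export
simulate_signature_matrix <- function(kind = c("sbs", "sv"),
                                      n_signatures = NULL, seed = 1) {
  kind <- match.arg(kind)
  channels <- if (kind == "sbs") sbs96_channels() else sv32_channels()
  prefix <- if (kind == "sbs") "SBS" else "SV"
  if (is.null(n_signatures)) n_signatures <- if (kind == "sbs") 10L else 6L
  cols <- withr::with_seed(seed, {
    lapply(seq_len(n_signatures), function(j) {
      w <- stats::rgamma(length(channels), shape = 0.3)
      w / sum(w)
    })
  })
  out <- tibble::tibble(channel = channels)
  for (j in seq_len(n_signatures)) {
    out[[paste0(prefix, j)]] <- cols[[j]]
  }
  out
}

snv_channel_parts <- function(channel) {
  tibble::tibble(
    p5 = substr(channel, 1, 1),
    ref = substr(channel, 3, 3),
    alt = substr(channel, 5, 5),
    p3 = substr(channel, 7, 7)
  )
}

#' Simulate SNVs from a signature mixture
#'
#' Draws `n` channel assignments from the multinomial mixture
#' `signatures %*% proportions` and plants each variant at a reference
#' locus whose trinucleotide context matches its channel. The synthetic
#' reference is a tiling of all 64 trinucleotides, so every channel is
#' placeable and [build_sbs_catalog()] on the output reproduces the drawn
#' channel counts exactly.
#'
#' @param signatures SBS-96 signature tibble (see
#'   [read_signature_matrix()] / [simulate_signature_matrix()]).
#' @param proportions Named or positional mixture weights over the
#'   signature columns, summing to 1.
#' @param n Number of variants.
#' @param seed Integer seed.
#' @return List with `snvs` (tibble `chrom`, `pos`, `ref`, `alt`),
#'   `reference` (named character vector) and `truth` (list with the
#'   generating `proportions` and realized `channel_counts`).
#' @export
simulate_snvs <- function(signatures, proportions, n, seed) {
  channels <- sbs96_channels()
  S <- as.matrix(signatures[, -1, drop = FALSE])
  if (abs(sum(proportions) - 1) > 1e-8) abort("proportions must sum to 1")
  if (length(proportions) != ncol(S)) abort("one proportion per signature required")
  mix <- as.numeric(S %*% proportions)
  counts <- if (n > 0) {
    withr::with_seed(seed, as.integer(rmultinom(1, n, mix)))
  } else {
    integer(96)
  }
  # Reference: all 64 trinucleotides concatenated, tiled so every draw of
  # the same channel gets its own locus.
  bases <- c("A", "C", "G", "T")
  triples <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  unit <- paste(triples, collapse = "")
  tiles <- max(1L, max(counts))
  reference <- c(chrS = paste(rep(unit, tiles), collapse = ""))
  parts <- snv_channel_parts(channels)
  ctx <- paste0(parts$p5, parts$ref, parts$p3)
  triple_idx <- match(ctx, triples)
  snvs <- purrr::map_dfr(which(counts > 0), function(ci) {
    k <- counts[ci]
    centers <- (seq_len(k) - 1) * nchar(unit) + (triple_idx[ci] - 1) * 3 + 2
    tibble::tibble(chrom = "chrS", pos = centers,
                   ref = parts$ref[ci], alt = parts$alt[ci])
  })
  if (nrow(snvs) == 0) {
    snvs <- tibble::tibble(chrom = character(), pos = integer(),
                           ref = character(), alt = character())
  }
  snvs <- dplyr::arrange(snvs, .data$pos)
  list(snvs = snvs, reference = reference,
       truth = list(proportions = proportions,
                    channel_counts = setNames(counts, channels)))
}

#' Simulate deletions with engineered breakpoint microhomology
#'
#' Constructs `n_eligible` deletions longer than 3 bp, of which exactly
#' `round(target_fraction * n_eligible)` carry at least one engineered
#' base of breakpoint microhomology (the 3' flank repeats the start of
#' the deleted sequence) while the remainder are guaranteed to have none
#' on either side; `n_small` deletions of 1-3 bp are added as
#' ineligible distractors. [microhomology_fraction()] on the output
#' returns the target count ratio exactly.
#'
#' @param n_eligible Number of deletions longer than 3 bp.
#' @param target_fraction Desired microhomology fraction in [0, 1].
#' @param n_small Number of distractor deletions of 3 bp or shorter.
#' @param seed Integer seed.
#' @return List with `deletions` (tibble `chrom`, `pos`, `deleted_seq`),
#'   `reference`, and `truth` (`fraction`, `n_mh`, `n_eligible`).
#' @export
simulate_deletions <- function(n_eligible, target_fraction, n_small, seed) {
  if (target_fraction < 0 || target_fraction > 1) {
    abort("target_fraction must lie in [0, 1]")
  }
  n_mh <- round(target_fraction * n_eligible)
  withr::with_seed(seed, {
    blocks <- character(0)
    dels <- list()
    cursor <- 1L
    add_block <- function(left, del, right) {
      blocks <<- c(blocks, left, del, right)
      pos <- cursor + nchar(left)
      dels[[length(dels) + 1]] <<- tibble::tibble(
        chrom = "chrD", pos = pos, deleted_seq = del)
      cursor <<- cursor + nchar(left) + nchar(del) + nchar(right)
    }
    total <- n_eligible + n_small
    kind <- c(rep("mh", n_mh), rep("plain", n_eligible - n_mh),
              rep("small", n_small))
    for (k in sample(kind)) {
      if (k == "mh") {
        len <- sample(4:8, 1)
        # deleted run of T; 3' flank repeats its first two bases
        add_block(strrep("C", 8), strrep("T", len), paste0("TT", strrep("G", 8)))
      } else if (k == "plain") {
        len <- sample(4:8, 1)
        # flanks share no base with the deleted A-run on either side
        add_block(strrep("C", 8), strrep("A", len), strrep("G", 10))
      } else {
        len <- sample(1:3, 1)
        add_block(strrep("C", 8), strrep("G", len), strrep("A", 10))
      }
    }
    reference <- c(chrD = paste(blocks, collapse = ""))
    deletions <- if (length(dels) > 0) dplyr::bind_rows(dels) else
      tibble::tibble(chrom = character(), pos = integer(), deleted_seq = character())
    list(deletions = deletions, reference = reference,
         truth = list(fraction = if (n_eligible > 0) n_mh / n_eligible else 0,
                      n_mh = n_mh, n_eligible = n_eligible))
  })
}

#' Simulate structural variants from an SV-32 mixture
#'
#' Draws `n` channel assignments from `sv_signatures %*% proportions` and
#' lays the variants out so that the clustered/non-clustered status of
#' every breakpoint is by construction: non-clustered variants are spaced
#' more than the clustering distance apart across chromosomes, clustered
#' variants form a chain with inter-variant breakpoint gaps well inside
#' it. A lone clustered draw cannot exist (clustering needs a neighbour)
#' and is demoted to its non-clustered channel; the returned truth
#' reflects the emitted set.
#'
#' @param sv_signatures SV-32 signature tibble.
#' @param proportions Mixture weights, summing to 1.
#' @param n Number of variants.
#' @param seed Integer seed.
#' @return List with `svs` (tibble `sample`, `sv_type`, `chrom1`, `pos1`,
#'   `chrom2`, `pos2`, `size`) and `truth` (realized channel counts).
#' @export
simulate_svs <- function(sv_signatures, proportions, n, seed) {
  channels <- sv32_channels()
  S <- as.matrix(sv_signatures[, -1, drop = FALSE])
  if (abs(sum(proportions) - 1) > 1e-8) abort("proportions must sum to 1")
  counts <- if (n > 0) {
    withr::with_seed(seed, as.integer(rmultinom(1, n, as.numeric(S %*% proportions))))
  } else {
    integer(32)
  }
  names(counts) <- channels
  n_clustered <- sum(counts[startsWith(channels, "clustered")])
  if (n_clustered == 1) {
    ci <- which(startsWith(channels, "clustered") & counts > 0)
    counts[sub("^clustered", "non-clustered", channels[ci])] <-
      counts[sub("^clustered", "non-clustered", channels[ci])] + 1L
    counts[ci] <- 0L
  }
  size_for_bin <- function(bin) {
    switch(bin,
           "<10kb" = 5e3, "10-100kb" = 5e4, "100kb-1Mb" = 5e5,
           "1-10Mb" = 5e6, ">10Mb" = 2e7)
  }
  recs <- list()
  # non-clustered: sequential layout, > 2x cluster distance between events
  nc_cursor <- 1e6
  nc_chrom_gap <- 3e6
  for (ch in channels[startsWith(channels, "non-clustered")]) {
    k <- counts[ch]
    if (k == 0) next
    parts <- strsplit(ch, "_")[[1]]
    type <- parts[2]
    for (j in seq_len(k)) {
      if (type == "TRA") {
        recs[[length(recs) + 1]] <- tibble::tibble(
          sv_type = "TRA", chrom1 = "chrA", pos1 = nc_cursor,
          chrom2 = "chrB", pos2 = nc_cursor, size = NA_real_)
        nc_cursor <- nc_cursor + nc_chrom_gap
      } else {
        size <- size_for_bin(parts[3])
        recs[[length(recs) + 1]] <- tibble::tibble(
          sv_type = type, chrom1 = "chrA", pos1 = nc_cursor,
          chrom2 = "chrA", pos2 = nc_cursor + size, size = size)
        nc_cursor <- nc_cursor + size + nc_chrom_gap
      }
    }
  }
  # clustered: chained on a dedicated chromosome, adjacent breakpoints 100 kb apart
  cl_cursor <- 1e6
  for (ch in channels[startsWith(channels, "clustered")]) {
    k <- counts[ch]
    if (k == 0) next
    parts <- strsplit(ch, "_")[[1]]
    type <- parts[2]
    for (j in seq_len(k)) {
      if (type == "TRA") {
        recs[[length(recs) + 1]] <- tibble::tibble(
          sv_type = "TRA", chrom1 = "chrC", pos1 = cl_cursor,
          chrom2 = "chrB", pos2 = 5e8 + cl_cursor, size = NA_real_)
        cl_cursor <- cl_cursor + 1e5
      } else {
        size <- size_for_bin(parts[3])
        recs[[length(recs) + 1]] <- tibble::tibble(
          sv_type = type, chrom1 = "chrC", pos1 = cl_cursor,
          chrom2 = "chrC", pos2 = cl_cursor + size, size = size)
        cl_cursor <- cl_cursor + size + 1e5
      }
    }
  }
  svs <- if (length(recs) > 0) dplyr::bind_rows(recs) else
    tibble::tibble(sv_type = character(), chrom1 = character(), pos1 = numeric(),
                   chrom2 = character(), pos2 = numeric(), size = numeric())
  svs <- dplyr::mutate(svs, sample = "synthetic", .before = 1)
  list(svs = svs, truth = list(channel_counts = counts))
}

#' Simulate a platinum-treated cohort with a known hazard ratio
#'
#' Generates a clinical treatment-line table in which every patient
#' receives one first-line platinum regimen. HRD-positive patients
#' (prevalence `hrd_prevalence`) have their time to progression drawn
#' from an exponential whose hazard is the baseline hazard (median
#' `baseline_median_months`) multiplied by `true_hr`. Censoring is
#' uniform on (0, b), independent of the event time, with b solved per
#' risk group so the marginal censoring probability equals
#' `censor_fraction`; censored patients carry no treatment end date and
#' no later line, so [compute_ttpp()] recovers the censored time from
#' last follow-up.
#'
#' @param n_patients Cohort size.
#' @param hrd_prevalence P(HRD positive), strictly in (0, 1).
#' @param true_hr Hazard ratio of HRD-positive vs negative (> 0; values
#'   below 1 mean longer time on platinum).
#' @param baseline_median_months Median TTPp of HRD-negative patients.
#' @param censor_fraction Marginal probability of censoring in [0, 1).
#' @param seed Integer seed; same seed, byte-identical tables.
#' @return List with `clinical` (treatment-line tibble the survival
#'   module parses), `flags` (tibble `patient_id`, `hrd_high`), and
#'   `truth` (per-patient event times and the generating parameters).
#' @export
simulate_cohort <- function(n_patients, hrd_prevalence, true_hr,
                            baseline_median_months = 6,
                            censor_fraction = 0.2, seed = 1) {
  if (hrd_prevalence <= 0 || hrd_prevalence >= 1) {
    abort("hrd_prevalence must lie strictly in (0, 1)")
  }
  if (true_hr <= 0) abort("true_hr must be > 0")
  if (censor_fraction < 0 || censor_fraction >= 1) {
    abort("censor_fraction must lie in [0, 1)")
  }
  rate0 <- log(2) / baseline_median_months
  censor_bound <- function(rate) {
    if (censor_fraction == 0) return(Inf)
    # solve (1 - exp(-x)) / x = censor_fraction, b = x / rate
    f <- function(x) (1 - exp(-x)) / x - censor_fraction
    uniroot(f, c(1e-9, 1e6))$root / rate
  }
  withr::with_seed(seed, {
    hrd <- runif(n_patients) < hrd_prevalence
    rate <- rate0 * ifelse(hrd, true_hr, 1)
    t_event <- rexp(n_patients, rate)
    if (censor_fraction > 0) {
      b <- vapply(rate, censor_bound, numeric(1))
      c_time <- runif(n_patients, 0, b)
    } else {
      c_time <- rep(Inf, n_patients)
    }
    observed <- pmin(t_event, c_time)
    event <- t_event <= c_time
    tumor_group <- sample(c("GI", "thoracic"), n_patients, replace = TRUE,
                          prob = c(0.7, 0.3))
    start <- as.Date("2015-01-01")
    obs_days <- pmax(1, round(observed * DAYS_PER_MONTH))
    clinical <- tibble::tibble(
      patient_id = sprintf("P%04d", seq_len(n_patients)),
      tumor_group = tumor_group,
      brca_status = "wild-type",
      line = 1L,
      agent_class = "platinum",
      is_platinum = TRUE,
      start = start,
      end = dplyr::if_else(event, start + obs_days, as.Date(NA)),
      death_date = as.Date(NA),
      last_followup = start + obs_days + dplyr::if_else(event, 30L, 0L)
    )
    class(clinical) <- c("clinical_table", class(clinical))
    list(clinical = clinical,
         flags = tibble::tibble(patient_id = clinical$patient_id,
                                hrd_high = hrd),
         truth = list(hrd = hrd, t_event = t_event, observed = observed,
                      event = event,
                      params = list(n_patients = n_patients,
                                    hrd_prevalence = hrd_prevalence,
                                    true_hr = true_hr,
                                    baseline_median_months = baseline_median_months,
                                    censor_fraction = censor_fraction,
                                    seed = seed)))
  })
}

#' Write SNVs as a minimal VCF
#'
#' Emits a VCF 4.2 file (CHROM, POS, REF, ALT and dot placeholders) that
#' [read_vcf_small_variants()] parses back. Deletions are encoded in the
#' standard anchor-base convention.
#'
#' @param snvs Tibble `chrom`, `pos`, `ref`, `alt`.
#' @param deletions Optional tibble `chrom`, `pos`, `deleted_seq`; needs
#'   `reference` to recover the anchor base.
#' @param reference Named character vector (required with deletions).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(snvs, path, deletions = NULL, reference = NULL) {
  rows <- tibble::tibble(chrom = snvs$chrom, pos = snvs$pos,
                         ref = snvs$ref, alt = snvs$alt)
  if (!is.null(deletions) && nrow(deletions) > 0) {
    if (is.null(reference)) abort("writing deletions requires the reference")
    reference <- as_reference(reference)
    anchor <- vapply(seq_len(nrow(deletions)), function(i) {
      paste(ref_slice(reference, deletions$chrom[i], deletions$pos[i] - 1,
                      deletions$pos[i] - 1), collapse = "")
    }, character(1))
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      chrom = deletions$chrom, pos = deletions$pos - 1L,
      ref = paste0(anchor, deletions$deleted_seq), alt = anchor))
  }
  rows <- dplyr::arrange(rows, .data$chrom, .data$pos)
  lines <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
            rows$chrom, as.integer(rows$pos), rows$ref, rows$alt)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a reference as FASTA
#'
#' @param reference Named character vector of contig sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  lines <- unlist(lapply(names(reference), function(nm) {
    c(paste0(">", nm), reference[[nm]])
  }))
  writeLines(lines, path)
  invisible(path)
}
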