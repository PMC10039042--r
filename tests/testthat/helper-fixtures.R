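# Shared fixtures, all built in code.

toy_genome8 <- make_toy_genome(8, 200)

toy_sbs_sigs <- simulate_signature_matrix("sbs", seed = 42)
toy_sv_sigs <- simulate_signature_matrix("sv", seed = 43)

# Three overlapping-support signatures with rational entries so that
# integral mixtures produce integral channel counts.
integral_sigs <- local({
  channels <- sbs96_channels()
  sigA <- rep(0, 96); sigA[1:4] <- 1 / 4
  sigB <- rep(0, 96); sigB[3:7] <- 1 / 5
  sigC <- rep(0, 96); sigC[c(1, 6, 11:18)] <- 1 / 10
  tibble::tibble(channel = channels, sigA = sigA, sigB = sigB, sigC = sigC)
})

make_catalog <- function(counts, channels = sbs96_channels()) {
  out <- tibble::tibble(channel = channels, count = as.integer(counts))
  class(out) <- c("mutational_catalog", class(out))
  out
}

# Segment tibble shorthand
seg <- function(chrom, start_mb, end_mb, total, minor) {
  tibble::tibble(chrom = chrom, start = start_mb * 1e6, end = end_mb * 1e6,
                 total_cn = as.integer(total), minor_cn = as.integer(minor))
}

# A small clinical fixture: 4 patients, 7 treatment lines.
clinical_fixture <- function() {
  d <- function(x) as.Date(x)
  tibble::tibble(
    patient_id = c("P1", "P1", "P2", "P2", "P3", "P3", "P4"),
    tumor_group = c("GI", "GI", "GI", "GI", "thoracic", "thoracic", "GI"),
    brca_status = c("wild-type", "wild-type", "pathogenic-germline",
                    "pathogenic-germline", "wild-type", "wild-type", "somatic"),
    line = c(1L, 2L, 1L, 2L, 1L, 2L, 1L),
    agent_class = c("platinum", "taxane", "platinum", "platinum",
                    "targeted", "platinum", "platinum"),
    is_platinum = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
    start = d(c("2015-01-01", "2015-09-01", "2015-02-01", "2016-02-01",
                "2015-03-01", "2015-12-01", "2015-04-01")),
    end = d(c("2015-07-01", NA, "2015-12-01", "2016-08-01",
              "2015-11-01", NA, NA)),
    death_date = d(c(NA, NA, "2017-01-01", "2017-01-01", NA, NA, NA)),
    last_followup = d(c("2016-06-01", "2016-06-01", "2017-01-01", "2017-01-01",
                        "2017-03-01", "2017-03-01", "2016-04-01"))
  )
}
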