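test_that("excision re-ligates MDS segments and maps coordinates", {
  ex <- excise("AAACCCGGG", data.frame(start = 3L, end = 6L))
  expect_equal(ex$mac_seq, "AAAGGG")
  expect_equal(ex$mic_to_mac, c(0L, 1L, 2L, NA, NA, NA, 3L, 4L, 5L))
  ex <- excise("ACGT", data.frame(start = integer(0), end = integer(0)))
  expect_equal(ex$mac_seq, "ACGT")
  expect_equal(ex$mic_to_mac, 0:3)
  expect_error(excise("ACGTACGT", data.frame(start = c(1L, 3L),
                                             end = c(4L, 6L))),
               "non-overlapping")
  expect_error(excise("ACGT", data.frame(start = 2L, end = 9L)),
               "sequence length")
})

test_that("excision equals a brute-force slice-and-join on random inputs", {
  set.seed(3)
  for (i in 1:10) {
    mic <- random_dna_chr(sample(200:400, 1))
    n <- nchar(mic)
    cut <- sort(sample(0:n, 6, replace = FALSE))
    iv <- data.frame(start = cut[c(1, 3, 5)], end = cut[c(2, 4, 6)])
    iv <- iv[iv$start < iv$end, , drop = FALSE]
    ex <- excise(mic, iv)
    keep <- rep(TRUE, n)
    for (j in seq_len(nrow(iv))) keep[(iv$start[j] + 1):iv$end[j]] <- FALSE
    oracle <- paste(strsplit(mic, "")[[1]][keep], collapse = "")
    expect_equal(ex$mac_seq, oracle)
    # coordinate map round-trips every MDS position
    mds_pos <- which(keep) - 1L
    expect_equal(ex$mic_to_mac[mds_pos + 1L], seq_along(mds_pos) - 1L)
    expect_equal(unname(substring(mic, mds_pos + 1L, mds_pos + 1L)),
                 strsplit(ex$mac_seq, "")[[1]])
  }
})

test_that("genome generation conserves length and is deterministic", {
  for (s in 1:3) {
    p <- small_params(seed = s)
    g <- generate_genome(p)
    expect_equal(nrow(g$ies_intervals), p$n_ies)
    expect_equal(nchar(g$mic_seq) - nchar(g$mac_seq),
                 sum(g$ies_intervals$end - g$ies_intervals$start))
  }
  g1 <- generate_genome(small_params(seed = 5))
  g2 <- generate_genome(small_params(seed = 5))
  expect_identical(g1, g2)
})

test_that("the repeat unit is planted in both compartments", {
  p <- small_params(seed = 2)
  g <- generate_genome(p)
  hits <- gregexpr(p$repeat_unit, g$mic_seq, fixed = TRUE)[[1]] - 1L
  expect_gte(length(hits), 2L)
  in_ies <- vapply(hits, function(h)
    any(h >= g$ies_intervals$start &
          h + nchar(p$repeat_unit) <= g$ies_intervals$end), logical(1))
  expect_true(any(in_ies))
  expect_true(any(!in_ies))
  # and it makes the corresponding reads non-unique: the repeat occurs in
  # the somatic genome too
  expect_true(grepl(p$repeat_unit, g$mac_seq, fixed = TRUE))
})

test_that("degenerate and infeasible genome parameters are handled", {
  p0 <- sim_params(genome_length = 5000L, n_ies = 0L, seed = 1)
  g0 <- generate_genome(p0)
  expect_equal(g0$mac_seq, g0$mic_seq)
  expect_equal(nrow(g0$ies_intervals), 0L)
  expect_error(generate_genome(
    sim_params(genome_length = 4000L, n_ies = 10L,
               ies_length_range = c(400L, 500L), seed = 1)),
    "infeasible sizing")
  expect_error(sim_params(read_length_range = c(10L, 32L)), "\\[20, 40\\]")
  expect_error(sim_params(decay_rate_mds_per_h = c(WT = 0.6)), "EMA2_KO")
})

test_that("simulated reads are exact substrings of the germline genome", {
  p <- small_params(seed = 4, reads = 2000L)
  g <- generate_genome(p)
  sets <- simulate_scnrna(g, p, "WT")
  expect_length(sets, length(p$timepoints_h))
  for (rs in sets) {
    expect_true(all(nchar(rs$reads$sequence) >= p$read_length_range[1]))
    expect_true(all(nchar(rs$reads$sequence) <= p$read_length_range[2]))
    expect_true(all(rs$reads$multiplicity >= 1L))
    mic_rc <- rc_chr(g$mic_seq)
    found <- vapply(rs$reads$sequence, function(s)
      grepl(s, g$mic_seq, fixed = TRUE) || grepl(s, mic_rc, fixed = TRUE),
      logical(1))
    expect_true(all(found))
  }
  expect_error(simulate_scnrna(g, p, "TWI1_KO"), "unknown genotype")
  # determinism
  expect_identical(simulate_scnrna(g, p, "EMA1_KO"),
                   simulate_scnrna(g, p, "EMA1_KO"))
})

test_that("read mass follows the per-compartment decay law", {
  # closed form: MDS mass ratio between 8 and 3 hpm is exp(-0.6 * 5),
  # IES mass is constant; check within 3 binomial standard errors
  p <- sim_params(genome_length = 30000L, n_ies = 5L,
                  ies_length_range = c(500L, 1500L),
                  production_weight_ies = 1,
                  reads_per_timepoint = 50000L, seed = 6)
  g <- generate_genome(p)
  ref <- combined_reference(g)
  mask <- compute_mappability(ref, k = 26)
  tiles <- rbind(build_mds_tiles(ref["MAC"], mask),
                 build_ies_tiles(g, mask))
  qr <- c(MAC = g$mac_seq, MIC = g$mic_seq)
  mass <- function(rs, kind) {
    counts <- attr(quantify_reads(rs, tiles, qr), "counts")
    sum(counts$counts[tiles$tile_id[tiles$kind == kind]])
  }
  for (geno in c("WT", "EMA1_KO")) {
    sets <- simulate_scnrna(g, p, geno)
    m3 <- mass(sets[[1]], "MDS"); m8 <- mass(sets[[2]], "MDS")
    true_ratio <- exp(-p$decay_rate_mds_per_h[[geno]] * 5)
    se <- true_ratio * sqrt(1 / max(m8, 1) + 1 / m3)
    expect_lt(abs(m8 / m3 - true_ratio), 3 * se + 1e-9)
    i3 <- mass(sets[[1]], "IES"); i8 <- mass(sets[[2]], "IES")
    se_i <- sqrt(1 / i8 + 1 / i3)
    expect_lt(abs(i8 / i3 - 1), 3 * se_i)
  }
})

test_that("genome and IES annotations round-trip through FASTA and BED", {
  p <- small_params(seed = 7)
  g <- generate_genome(p)
  fa <- tempfile(fileext = ".fa"); bed <- tempfile(fileext = ".bed")
  write_genome(g, fa, bed)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(seqs[["MIC"]]), g$mic_seq)
  expect_equal(as.character(seqs[["MAC"]]), g$mac_seq)
  ann <- read_ies_bed(bed)
  expect_equal(ann$start, g$ies_intervals$start)
  expect_equal(ann$end, g$ies_intervals$end)
  expect_equal(ann$type_label, g$ies_intervals$type_label)
})
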