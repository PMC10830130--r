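lfq_rec <- function(id, wt = NA, ko = NA, ctrl = NA, aa = "MKLV") {
  data.frame(protein_id = id, aa_sequence = aa,
             lfq_NOHIS = 2^ctrl, lfq_WT = 2^wt, lfq_KO = 2^ko,
             stringsAsFactors = FALSE)
}

test_that("the poly-His filter is strict at more than six residues", {
  expect_true(has_poly_his("MHHHHHHHK"))    # run of 7
  expect_false(has_poly_his("MHHHHHHK"))    # run of 6
  expect_true(has_poly_his("mkhhhhhhhl"))   # case-insensitive
  expect_false(has_poly_his(""))
  expect_false(has_poly_his(NA_character_))
  # fuzzed sequences against a run-length oracle
  set.seed(51)
  for (i in 1:50) {
    aa <- paste(sample(c("H", "A", "K"), 60, replace = TRUE,
                       prob = c(0.4, 0.3, 0.3)), collapse = "")
    runs <- rle(strsplit(aa, "")[[1]])
    oracle <- any(runs$values == "H" & runs$lengths >= 7)
    expect_identical(has_poly_his(aa), oracle)
  }
})

test_that("the bead-binder filter is strict at log2 LFQ 25", {
  recs <- rbind(lfq_rec("over", ctrl = 25.1), lfq_rec("at", ctrl = 25.0),
                lfq_rec("missing"))
  expect_equal(flag_bead_binders(recs), c(TRUE, FALSE, FALSE))
  expect_error(flag_bead_binders(recs, control_condition = "XYZ"),
               "unknown condition")
})

test_that("condition comparison ranks by log2 difference", {
  recs <- rbind(lfq_rec("target", wt = 30, ko = 24),
                lfq_rec("flat", wt = 26, ko = 26),
                lfq_rec("bead", wt = 31, ko = 22, ctrl = 27),
                lfq_rec("his", wt = 31, ko = 20, aa = strrep("H", 8)))
  res <- compare_conditions(recs)
  expect_equal(res$delta[res$protein_id == "target"], 6)
  expect_equal(res$delta[res$protein_id == "flat"], 0)
  expect_equal(res$rank[res$protein_id == "target"], 1L)
  # flagged proteins carry no rank, whatever their delta
  expect_true(is.na(res$rank[res$protein_id == "bead"]))
  expect_true(is.na(res$rank[res$protein_id == "his"]))
  # the two filters commute: excluded set is the same in either order
  bead_then_his <- res$bead_binder | res$poly_his
  his_then_bead <- res$poly_his | res$bead_binder
  expect_identical(bead_then_his, his_then_bead)
})

test_that("missing intensities are floor-imputed or excluded", {
  recs <- rbind(lfq_rec("a", wt = 20, ko = 18),
                lfq_rec("ko_missing", wt = 21),
                lfq_rec("gone"))
  expect_warning(res <- compare_conditions(recs), "excluded")
  expect_false("gone" %in% res$protein_id)
  # floor = min observed log2 - 1 = 17
  expect_equal(res$log2_ko[res$protein_id == "ko_missing"], 17)
  expect_true(res$imputed_ko[res$protein_id == "ko_missing"])
  expect_false(res$imputed_wt[res$protein_id == "ko_missing"])
})

test_that("ties in delta break by WT abundance", {
  recs <- rbind(lfq_rec("lo", wt = 20, ko = 18),
                lfq_rec("hi", wt = 28, ko = 26))
  res <- compare_conditions(recs)
  expect_equal(res$rank[res$protein_id == "hi"], 1L)
  expect_equal(res$rank[res$protein_id == "lo"], 2L)
})

test_that("synthetic LFQ tables embed the designed ground truth", {
  tab <- simulate_lfq_table(n_proteins = 200, n_targets = 1,
                            n_bead_binders = 10, n_polyhis = 5,
                            effect_log2 = 3, seed = 4)
  expect_equal(sum(tab$is_target), 1L)
  expect_true(all(has_poly_his(tab$aa_sequence[tab$is_polyhis])))
  expect_false(any(has_poly_his(tab$aa_sequence[!tab$is_polyhis])))
  expect_true(all(log2(tab$lfq_NOHIS[tab$is_bead_binder]) > 25))
  # exactly n_targets proteins reach the planted effect size
  d <- log2(tab$lfq_WT) - log2(tab$lfq_KO)
  expect_equal(sum(d >= 3, na.rm = TRUE), 1L)
  # the screen recovers the planted target
  res <- suppressWarnings(compare_conditions(tab))
  expect_equal(res$protein_id[which(res$rank == 1L)],
               tab$protein_id[tab$is_target])
  # no contaminants planted: the filters remove nothing
  clean <- simulate_lfq_table(n_proteins = 50, n_targets = 1,
                              n_bead_binders = 0, n_polyhis = 0,
                              missing_rate = 0, seed = 5)
  res <- compare_conditions(clean)
  expect_false(any(res$bead_binder | res$poly_his))
  expect_equal(sum(!is.na(res$rank)), 50L)
  expect_error(simulate_lfq_table(n_proteins = 5, n_polyhis = 10),
               "sizing")
})

test_that("tabular synthetic inputs round-trip through TSV", {
  tab <- simulate_lfq_table(n_proteins = 30, n_targets = 1,
                            n_bead_binders = 2, n_polyhis = 2, seed = 6)
  path <- tempfile(fileext = ".tsv")
  write_table_tsv(tab, path)
  back <- read_table_tsv(path)
  expect_equal(back$protein_id, tab$protein_id)
  expect_equal(back$lfq_WT, tab$lfq_WT)
  expect_equal(back$is_target, tab$is_target)
  itab <- simulate_intensity_table(5, c(G = 0.5), seed = 6)
  write_table_tsv(itab, path)
  expect_equal(read_table_tsv(path), itab)
})
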