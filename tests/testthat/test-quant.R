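# a tiny hand-built reference: two "chromosomes", three tiles
toy_ref <- c(
  MAC = "ACGATCGATTTAGCCGGATCACTGACGGCCATAGCGATACGGATTACAGCATGGCAGCTA",
  MIC = "TTGACCATGAGGCCTAGCATCCGATTGCCAATGCCGGATCACTGACGGCCAATTGGCCAT")
toy_tiles <- data.frame(
  tile_id = c("T1", "T2", "T3"), kind = c("MDS", "MDS", "IES"),
  chrom = c("MAC", "MAC", "MIC"),
  start = c(0L, 30L, 10L), end = c(30L, 60L, 50L),
  mappable_length = c(30L, 30L, 40L), stringsAsFactors = FALSE)

reads_df <- function(seqs, mult = 1L) {
  data.frame(sequence = seqs,
             multiplicity = rep_len(mult, length(seqs)),
             stringsAsFactors = FALSE)
}

test_that("length filtering is inclusive at both bounds", {
  rd <- reads_df(strrep("A", c(25, 26, 30, 32, 33)))
  kept <- filter_by_length(rd)
  expect_equal(nchar(kept$sequence), c(26, 30, 32))
  expect_equal(nrow(filter_by_length(reads_df(character(0)))), 0L)
  expect_error(filter_by_length(rd, 30, 20), "min_nt")
  set.seed(41)
  rd <- reads_df(vapply(sample(20:40, 50, TRUE), random_dna_chr,
                        character(1)))
  expect_equal(sum(filter_by_length(rd)$multiplicity),
               sum(nchar(rd$sequence) >= 26 & nchar(rd$sequence) <= 32))
})

test_that("unique assignment follows the single-tile rule", {
  one_tile <- reads_df(substr(toy_ref["MAC"], 3, 28))       # inside T1
  res <- assign_unique(one_tile, toy_tiles, toy_ref)
  expect_equal(unname(res$counts), c(1L, 0L, 0L))
  # reverse-complemented read maps identically
  res_rc <- assign_unique(reads_df(rc_chr(one_tile$sequence)), toy_tiles,
                          toy_ref)
  expect_equal(res_rc$counts, res$counts)
  # the shared 18-mer "GCCGGATCACTGACGGCC" occurs in T1 and T3: unassigned
  shared <- reads_df(substr(toy_ref["MAC"], 13, 30))
  expect_true(grepl(shared$sequence, substr(toy_ref["MIC"], 11, 50),
                    fixed = TRUE))
  res <- assign_unique(shared, toy_tiles, toy_ref)
  expect_equal(res$total_assigned, 0L)
  expect_equal(res$unassigned, 1L)
  # a read absent from every tile is unassigned
  res <- assign_unique(reads_df(strrep("A", 26)), toy_tiles, toy_ref)
  expect_equal(res$total_assigned, 0L)
  # multiplicity is added in full
  res <- assign_unique(reads_df(substr(toy_ref["MIC"], 15, 44), 7L),
                       toy_tiles, toy_ref)
  expect_equal(unname(res$counts["T3"]), 7L)
  expect_error(
    assign_unique(one_tile,
                  transform(toy_tiles, end = c(30L, 99L, 50L)), toy_ref),
    "outside its reference")
})

test_that("assignment conserves reads and matches the brute-force oracle", {
  set.seed(42)
  for (i in 1:8) {
    ref <- c(A = random_dna_chr(sample(200:400, 1)),
             B = random_dna_chr(sample(200:400, 1)))
    nt <- sample(1:5, 1)
    tiles <- do.call(rbind, lapply(seq_len(nt), function(j) {
      chrom <- sample(names(ref), 1)
      len <- nchar(ref[[chrom]])
      start <- sample(0:(len - 60), 1)
      data.frame(tile_id = paste0("t", j), kind = "MDS", chrom = chrom,
                 start = start, end = start + sample(40:60, 1),
                 mappable_length = 40L, stringsAsFactors = FALSE)
    }))
    # reads: genuine substrings (some reverse complemented) + random junk
    n_reads <- sample(50:150, 1)
    seqs <- vapply(seq_len(n_reads), function(r) {
      if (runif(1) < 0.7) {
        chrom <- sample(names(ref), 1)
        l <- sample(26:32, 1)
        s0 <- sample(1:(nchar(ref[[chrom]]) - l), 1)
        s <- substr(ref[[chrom]], s0, s0 + l - 1)
        if (runif(1) < 0.5) rc_chr(s) else s
      } else random_dna_chr(sample(26:32, 1))
    }, character(1))
    rd <- reads_df(seqs, mult = sample(1:3, n_reads, replace = TRUE))
    res <- assign_unique(rd, tiles, ref)
    oracle <- brute_assign(rd, tiles, ref)
    expect_equal(res$counts, oracle$counts)
    expect_equal(res$total_assigned, oracle$total_assigned)
    expect_equal(res$total_assigned + res$unassigned,
                 res$length_filtered_total)
    expect_equal(sum(res$counts), res$total_assigned)
  }
})

test_that("RPKM follows the unique-sequence normalization", {
  counts <- structure(list(
    counts = c(T1 = 10L, T2 = 0L, T3 = 5L),
    total_assigned = 1000000L, length_filtered_total = 2000000L,
    unassigned = 1000000L), class = "tile_counts")
  tiles <- transform(toy_tiles, mappable_length = c(1000L, 500L, 0L))
  tab <- rpkm(counts, tiles)
  expect_equal(tab$rpkm[tab$tile_id == "T1"], 10)
  # zero-mappable tiles are excluded
  expect_false("T3" %in% tab$tile_id)
  # doubling every multiplicity leaves RPKM unchanged
  counts2 <- counts
  counts2$counts <- counts$counts * 2L
  counts2$total_assigned <- counts$total_assigned * 2L
  expect_equal(rpkm(counts2, tiles)$rpkm, tab$rpkm)
  # the alternative denominator uses the length-filtered total
  tab_lf <- rpkm(counts, tiles, denominator = "length_filtered")
  expect_equal(tab_lf$rpkm, tab$rpkm / 2)
  counts$total_assigned <- 0L
  expect_error(rpkm(counts, tiles), "undefined normalization")
})

test_that("counts are invariant under reverse-complementing every read", {
  p <- small_params(seed = 43, reads = 1500L)
  g <- generate_genome(p)
  ref <- combined_reference(g)
  mask <- compute_mappability(ref, k = 26)
  tiles <- rbind(build_mds_tiles(ref["MAC"], mask),
                 build_ies_tiles(g, mask))
  qr <- c(MAC = g$mac_seq, MIC = g$mic_seq)
  rs <- simulate_scnrna(g, p, "WT")[[1]]
  fwd <- assign_unique(rs$reads, tiles, qr)
  flipped <- rs$reads
  flipped$sequence <- rc_chr(flipped$sequence)
  rev <- assign_unique(flipped, tiles, qr)
  expect_equal(rev$counts, fwd$counts)
})

test_that("read sets round-trip through TSV and FASTA readers", {
  rd <- reads_df(c("ACGTACGTACGTACGTACGTACGTAC", "TTTTGGGGCCCCAAAATTTTGGGGCC"),
                 c(3L, 1L))
  rs <- list(genotype = "WT", timepoint_h = 3, reads = rd)
  tsv <- tempfile(fileext = ".tsv")
  write_reads_tsv(rs, tsv)
  back <- read_reads_tsv(tsv, genotype = "WT", timepoint_h = 3)
  expect_equal(back$reads, rd)
  fa <- tempfile(fileext = ".fa.gz")
  recs <- Biostrings::DNAStringSet(rep(rd$sequence, rd$multiplicity))
  names(recs) <- paste0("r", seq_along(recs))
  Biostrings::writeXStringSet(recs, fa, compress = TRUE)
  back_fa <- read_reads_fasta(fa)
  expect_equal(back_fa$reads[order(back_fa$reads$sequence), ],
               rd[order(rd$sequence), ], ignore_attr = TRUE)
})
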