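# Independent oracles and fixture builders.  Everything here is written
# against base R only (no reuse of package internals), so the oracle path
# stays independent of the implementation it checks.

# reverse complement, base R only
rc_chr <- function(x) {
  vapply(x, function(s)
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")),
    character(1), USE.NAMES = FALSE)
}

random_dna_chr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force mappability: every k-mer of the reference is counted on
# both strands by table lookup; a position is mappable iff its word (or
# its reverse complement) occurs at exactly one locus.
brute_mask <- function(ref_seqs, k) {
  all_kmers <- unlist(lapply(ref_seqs, function(q) {
    n <- nchar(q)
    if (n < k) character(0) else substring(q, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  tab <- table(all_kmers)
  lapply(ref_seqs, function(q) {
    n <- nchar(q)
    v <- logical(n)
    if (n < k) return(v)
    for (i in 1:(n - k + 1L)) {
      w <- substr(q, i, i + k - 1L)
      if (grepl("[^ACGT]", w)) next
      r <- rc_chr(w)
      cnt <- sum(tab[w], na.rm = TRUE) +
        if (r != w) sum(tab[r], na.rm = TRUE) else 0
      v[i] <- cnt == 1
    }
    v
  })
}

# Quadratic brute-force unique assignment: for every (read, tile) pair,
# substring search of the read and its reverse complement in the tile
# sequence.
brute_assign <- function(reads, tiles, reference_sequences) {
  tseq <- vapply(seq_len(nrow(tiles)), function(j)
    substr(reference_sequences[[tiles$chrom[j]]],
           tiles$start[j] + 1L, tiles$end[j]), character(1))
  counts <- structure(integer(nrow(tiles)), names = tiles$tile_id)
  assigned <- 0L
  for (r in seq_len(nrow(reads))) {
    s <- reads$sequence[r]
    rcs <- rc_chr(s)
    hit <- which(vapply(tseq, function(q)
      grepl(s, q, fixed = TRUE) || grepl(rcs, q, fixed = TRUE),
      logical(1)))
    if (length(hit) == 1L) {
      counts[hit] <- counts[hit] + reads$multiplicity[r]
      assigned <- assigned + reads$multiplicity[r]
    }
  }
  list(counts = counts, total_assigned = assigned)
}

# Exact two-sided rank-sum p by enumerating every split of the pooled
# ranks (no ties assumed); two-sided by doubling the smaller tail,
# capped at 1.
enum_ranksum_p <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  stopifnot(!any(duplicated(pooled)))
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  splits <- utils::combn(n + m, n)
  us <- apply(splits, 2, function(idx) sum(rk[idx]) - n * (n + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# A small genome/read configuration for fast unit tests.
small_params <- function(seed = 1L, reads = 5000L, ...) {
  sim_params(genome_length = 30000L, n_ies = 5L,
             ies_length_range = c(500L, 1500L),
             reads_per_timepoint = as.integer(reads), seed = seed, ...)
}
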