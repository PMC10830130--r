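# k-mer mappability over the combined somatic + IES reference.
#
# A position is mappable iff the k-mer starting there occurs at exactly
# one locus across the whole reference, where a k-mer and its reverse
# complement count as the same word.  Uniqueness across the *combined*
# reference (somatic chromosome plus every IES sequence) is what makes the
# MDS/IES dichotomy meaningful: a read matching both compartments can
# never be assigned uniquely, so positions carrying such words must be
# non-mappable.

#' Combined reference of a genome pair
#'
#' The somatic chromosome (`MAC`) plus one entry per IES interval
#' (`IES_1`, `IES_2`, ...), the reference over which mappability and
#' unique matching are defined.
#'
#' @param genome A `genome_pair`.
#' @return Named character vector of sequences.
#' @export
combined_reference <- function(genome) {
  stopifnot(inherits(genome, "genome_pair"))
  ies <- genome$ies_intervals
  if (nrow(ies) == 0L) return(c(MAC = genome$mac_seq))
  ies_seqs <- substring(genome$mic_seq, ies$start + 1L, ies$end)
  names(ies_seqs) <- paste0("IES_", seq_len(nrow(ies)))
  c(MAC = genome$mac_seq, ies_seqs)
}

#' Compute a k-mer mappability mask
#'
#' @param ref_seqs Named character vector of reference sequences (e.g.
#'   from [combined_reference()]).
#' @param k Word length; defaults to 26, the shortest read length counted,
#'   since a read can be placed uniquely iff its footprint contains a word
#'   unique at read scale.
#' @return A list of class `mappability_mask` with one logical vector per
#'   sequence (`TRUE` = k-mer starting at this position is unique across
#'   the whole reference, both strands collapsed).  Positions within
#'   `k - 1` of a sequence end, and positions whose k-mer contains a
#'   non-ACGT symbol, are `FALSE`.  The word length is kept in attribute
#'   `k`.
#' @export
compute_mappability <- function(ref_seqs, k = 26L) {
  if (length(ref_seqs) == 0L || all(nchar(ref_seqs) == 0L))
    stop("empty reference", call. = FALSE)
  stopifnot(k >= 1, !is.null(names(ref_seqs)),
            !anyDuplicated(names(ref_seqs)))
  lens <- nchar(ref_seqs)
  canon <- unlist(lapply(seq_along(ref_seqs), function(i)
    canonical_kmer_codes(ref_seqs[[i]], k)), use.names = FALSE)
  # occurrence count per canonical word by sorting (no string hashing)
  ord <- order(canon, na.last = TRUE)
  sorted <- canon[ord]
  n_def <- sum(!is.na(sorted))
  count <- rep(NA_real_, length(canon))
  if (n_def > 0) {
    s <- sorted[seq_len(n_def)]
    grp <- cumsum(c(TRUE, s[-1] != s[-n_def]))
    run <- tabulate(grp)
    count[ord[seq_len(n_def)]] <- run[grp]
  }
  unique_start <- !is.na(count) & count == 1
  # split back per sequence, pad the k-1 tail positions with FALSE
  out <- vector("list", length(ref_seqs))
  names(out) <- names(ref_seqs)
  offset <- 0L
  for (i in seq_along(ref_seqs)) {
    n_start <- max(0L, lens[i] - k + 1L)
    mask <- rep(FALSE, lens[i])
    if (n_start > 0)
      mask[seq_len(n_start)] <- unique_start[offset + seq_len(n_start)]
    out[[i]] <- mask
    offset <- offset + n_start
  }
  structure(out, k = as.integer(k), class = "mappability_mask")
}

# Canonical numeric codes of all k-mer start positions of one sequence.
#
# Each k-mer is encoded base-4 (A=0, C=1, G=2, T=3) into a double; for
# k <= 26 the code is below 2^53 and therefore exact.  The canonical code
# is the smaller of the k-mer's code and its reverse complement's, so a
# word and its reverse complement collapse to one key.  Positions whose
# k-mer contains a non-ACGT symbol get NA.  Longer k fall back to string
# keys (prefixed to stay distinct from numeric codes after sorting).
canonical_kmer_codes <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(numeric(0))
  if (k > 26L) {
    kmers <- substring(seq, 1:(n - k + 1L), k:n)
    valid <- !grepl("[^ACGT]", kmers)
    out <- rep(NA_character_, length(kmers))
    if (any(valid))
      out[valid] <- pmin(kmers[valid], revcomp(kmers[valid]))
    return(out)
  }
  d <- match(strsplit(seq, "", fixed = TRUE)[[1]],
             c("A", "C", "G", "T")) - 1
  m <- n - k + 1L
  code <- numeric(m)
  rc <- numeric(m)
  p4 <- 1
  for (j in seq_len(k)) {
    code <- code * 4 + d[j:(m + j - 1L)]
    rc <- rc + (3 - d[j:(m + j - 1L)]) * p4
    p4 <- p4 * 4
  }
  pmin(code, rc)
}

#' Run-length encode a mappability mask as a TSV
#'
#' Columns: sequence name, 0-based run start, run length, value (0/1).
#'
#' @param mask A `mappability_mask`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_mask_rle <- function(mask, path) {
  rows <- lapply(names(mask), function(nm) {
    r <- rle(mask[[nm]])
    if (length(r$lengths) == 0L) return(NULL)
    data.frame(seq = nm,
               start = cumsum(c(0L, r$lengths[-length(r$lengths)])),
               length = r$lengths, value = as.integer(r$values),
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
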