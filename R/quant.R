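# Unique-match counting of small RNA reads over genomic tiles and RPKM
# normalization.
#
# A read is assigned to a tile iff its exact occurrences (both strands)
# across all tile sequences are non-empty and confined to that single
# tile; reads occurring in two or more tiles, or nowhere, stay
# unassigned.  Matching is exact string matching over the tile sequences
# — the synthetic reads are error-free, so no aligner is involved.

#' Filter reads by length
#'
#' Keeps reads whose length is within the inclusive `[min_nt, max_nt]`
#' window (default 26-32 nt, the scnRNA size class); multiplicities are
#' preserved.
#'
#' @param reads Data frame with `sequence` and `multiplicity` columns, or
#'   a read-set list carrying such a data frame in `$reads`.
#' @param min_nt,max_nt Inclusive length bounds.
#' @return Object of the same shape as `reads`, filtered.
#' @export
filter_by_length <- function(reads, min_nt = 26L, max_nt = 32L) {
  if (min_nt > max_nt)
    stop("min_nt must be <= max_nt", call. = FALSE)
  if (is.list(reads) && !is.data.frame(reads) && !is.null(reads$reads)) {
    reads$reads <- filter_by_length(reads$reads, min_nt, max_nt)
    return(reads)
  }
  len <- nchar(reads$sequence)
  reads[len >= min_nt & len <= max_nt, , drop = FALSE]
}

# Extract tile sequences from the reference, with locus consistency checks.
tile_sequences <- function(tiles, reference_sequences) {
  missing_chrom <- setdiff(unique(tiles$chrom), names(reference_sequences))
  if (length(missing_chrom))
    stop("tiles reference unknown sequence(s): ",
         paste(missing_chrom, collapse = ", "), call. = FALSE)
  ref_len <- nchar(reference_sequences)[tiles$chrom]
  if (any(tiles$start < 0) || any(tiles$end > ref_len) ||
      any(tiles$start >= tiles$end))
    stop("tile locus outside its reference sequence", call. = FALSE)
  substring(reference_sequences[tiles$chrom], tiles$start + 1L, tiles$end)
}

#' Assign reads uniquely to tiles
#'
#' @param reads Data frame (`sequence`, `multiplicity`) or a read-set
#'   list; typically length-filtered first.
#' @param tiles Tile data frame from the tiling step.
#' @param reference_sequences Named character vector holding every
#'   sequence the tiles live on (e.g. `c(MAC = ..., MIC = ...)`).
#' @return A list of class `tile_counts`: `counts` (named integer vector
#'   over all `tile_id`s, full multiplicity of every uniquely assigned
#'   read), `total_assigned`, `length_filtered_total` (total input
#'   multiplicity) and `unassigned`.
#' @export
assign_unique <- function(reads, tiles, reference_sequences) {
  if (is.list(reads) && !is.data.frame(reads) && !is.null(reads$reads))
    reads <- reads$reads
  stopifnot(is.data.frame(reads), nrow(tiles) >= 0)
  tseq <- tile_sequences(tiles, reference_sequences)
  counts <- structure(integer(nrow(tiles)), names = tiles$tile_id)
  total_in <- sum(reads$multiplicity)
  if (nrow(reads) == 0L || nrow(tiles) == 0L) {
    return(structure(list(counts = counts, total_assigned = 0L,
                          length_filtered_total = as.integer(total_in),
                          unassigned = as.integer(total_in)),
                     class = "tile_counts"))
  }
  uniq <- unique(reads$sequence)
  clean <- !grepl("[^ACGT]", uniq)
  subjects <- Biostrings::DNAStringSet(tseq)
  subjects_rc <- Biostrings::reverseComplement(subjects)
  # per unique read, the set of tiles containing it on either strand;
  # PDict needs constant width, so process reads per length class
  n_tiles_hit <- integer(length(uniq))
  tile_hit <- integer(length(uniq))       # last (or only) hit
  for (w in sort(unique(nchar(uniq[clean])))) {
    sel <- which(clean & nchar(uniq) == w)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(uniq[sel]))
    hits_f <- Biostrings::vwhichPDict(pd, subjects)
    hits_r <- Biostrings::vwhichPDict(pd, subjects_rc)
    for (j in seq_along(tseq)) {
      h <- unique(c(hits_f[[j]], hits_r[[j]]))
      if (length(h)) {
        idx <- sel[h]
        n_tiles_hit[idx] <- n_tiles_hit[idx] + 1L
        tile_hit[idx] <- j
      }
    }
  }
  assigned_unique <- n_tiles_hit == 1L
  read_tile <- tile_hit[match(reads$sequence, uniq)]
  read_ok <- assigned_unique[match(reads$sequence, uniq)]
  if (any(read_ok)) {
    agg <- rowsum(reads$multiplicity[read_ok],
                  group = read_tile[read_ok], reorder = TRUE)
    counts[as.integer(rownames(agg))] <- as.integer(agg[, 1])
  }
  total_assigned <- sum(counts)
  structure(list(counts = counts,
                 total_assigned = as.integer(total_assigned),
                 length_filtered_total = as.integer(total_in),
                 unassigned = as.integer(total_in - total_assigned)),
            class = "tile_counts")
}

#' RPKM-normalize tile counts
#'
#' RPKM = count / (mappable kb of the tile) / (millions of reads in the
#' normalization denominator).  "Per kilobase" uses the tile's *mappable*
#' length, per the unique-sequence normalization; tiles with zero
#' mappable length are excluded.
#'
#' @param counts A `tile_counts` object from [assign_unique()].
#' @param tiles The tile data frame the counts were computed over.
#' @param denominator Either `"assigned"` (reads assigned to any tile;
#'   default) or `"length_filtered"` (all reads passing the length
#'   filter).
#' @return Data frame: `tile_id`, `kind`, `count`, `mappable_length`,
#'   `rpkm`.
#' @export
rpkm <- function(counts, tiles, denominator = c("assigned",
                                                "length_filtered")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(counts, "tile_counts"))
  total <- if (denominator == "assigned") counts$total_assigned
           else counts$length_filtered_total
  if (total == 0)
    stop("undefined normalization: the '", denominator,
         "' denominator is zero", call. = FALSE)
  keep <- tiles$mappable_length > 0
  ct <- counts$counts[match(tiles$tile_id[keep], names(counts$counts))]
  data.frame(tile_id = tiles$tile_id[keep], kind = tiles$kind[keep],
             count = as.integer(ct),
             mappable_length = tiles$mappable_length[keep],
             rpkm = ct / (tiles$mappable_length[keep] / 1000) /
               (total / 1e6),
             stringsAsFactors = FALSE)
}

#' Quantify one read set over a tile table
#'
#' Convenience wrapper: length filter, unique assignment, RPKM.
#'
#' @inheritParams assign_unique
#' @inheritParams filter_by_length
#' @inheritParams rpkm
#' @return The RPKM data frame, with the `tile_counts` attached as
#'   attribute `counts`.
#' @export
quantify_reads <- function(reads, tiles, reference_sequences,
                           min_nt = 26L, max_nt = 32L,
                           denominator = "assigned") {
  flt <- filter_by_length(reads, min_nt, max_nt)
  counts <- assign_unique(flt, tiles, reference_sequences)
  out <- rpkm(counts, tiles, denominator)
  attr(out, "counts") <- counts
  out
}
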