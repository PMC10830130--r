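# Genomic quantification tiles: fixed-size MDS windows over the somatic
# chromosome(s) filtered by mappable length, plus one tile per annotated
# type-A IES.

#' Build MDS tiles
#'
#' Cuts each somatic sequence into consecutive non-overlapping windows of
#' `tile_size` bp (the final partial window is retained) and keeps a
#' window iff it contains strictly more than `min_mappable` mappable
#' positions.
#'
#' @param mac_genome Named character vector of somatic sequences.
#' @param mask A `mappability_mask` computed over (at least) these
#'   sequences.
#' @param tile_size Window size in bp (default 10 kb).
#' @param min_mappable Strict lower bound on mappable bp per kept window
#'   (default 3 kb).
#' @return Data frame of tiles: `tile_id`, `kind` ("MDS"), `chrom`,
#'   `start`, `end` (0-based half-open), `mappable_length`.
#' @export
build_mds_tiles <- function(mac_genome, mask, tile_size = 10000L,
                            min_mappable = 3000L) {
  if (tile_size <= 0) stop("tile_size must be positive", call. = FALSE)
  stopifnot(inherits(mask, "mappability_mask"),
            all(names(mac_genome) %in% names(mask)))
  rows <- lapply(names(mac_genome), function(chrom) {
    n <- nchar(mac_genome[[chrom]])
    if (length(mask[[chrom]]) != n)
      stop("mask length does not match sequence ", chrom, call. = FALSE)
    if (n == 0L) return(NULL)
    starts <- seq(0L, n - 1L, by = tile_size)
    ends <- pmin(starts + tile_size, n)
    mapp <- vapply(seq_along(starts), function(i)
      sum(mask[[chrom]][(starts[i] + 1L):ends[i]]), integer(1))
    data.frame(tile_id = paste0(chrom, "_", starts),
               kind = "MDS", chrom = chrom,
               start = starts, end = ends, mappable_length = mapp,
               stringsAsFactors = FALSE)
  })
  tiles <- do.call(rbind, rows)
  tiles[tiles$mappable_length > min_mappable, , drop = FALSE]
}

#' Build IES tiles
#'
#' One tile per annotated interval with type label "A", located on the
#' germline chromosome at the annotated coordinates.  No size or
#' mappability filter is applied; the mappable length is taken from the
#' IES entries of the combined-reference mask.
#'
#' @param genome A `genome_pair` carrying IES annotations.
#' @param mask A `mappability_mask` over [combined_reference()] of the
#'   genome.
#' @return Data frame of tiles as in [build_mds_tiles()], with `kind`
#'   "IES" and `chrom` "MIC".
#' @export
build_ies_tiles <- function(genome, mask) {
  stopifnot(inherits(genome, "genome_pair"),
            inherits(mask, "mappability_mask"))
  ies <- genome$ies_intervals
  validate_intervals(ies, nchar(genome$mic_seq))
  idx <- which(ies$type_label == "A")
  if (length(idx) == 0L)
    return(data.frame(tile_id = character(0), kind = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), mappable_length = integer(0),
                      stringsAsFactors = FALSE))
  mapp <- vapply(idx, function(i) {
    nm <- paste0("IES_", i)
    if (!nm %in% names(mask))
      stop("mask is missing entry ", nm,
           "; compute it over combined_reference(genome)", call. = FALSE)
    sum(mask[[nm]])
  }, integer(1))
  data.frame(tile_id = paste0("IES_", idx), kind = "IES", chrom = "MIC",
             start = ies$start[idx], end = ies$end[idx],
             mappable_length = mapp, stringsAsFactors = FALSE)
}

#' Write/read tiles as a 6-column BED dialect
#'
#' Columns: chrom, start, end, tile_id, kind, mappable_length (0-based
#' half-open, tab-separated, no header).
#'
#' @param tiles Tile data frame.
#' @param path File path.
#' @return Invisibly `path`; the reader returns the tile data frame.
#' @export
write_tiles_bed <- function(tiles, path) {
  write.table(tiles[, c("chrom", "start", "end", "tile_id", "kind",
                        "mappable_length")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_tiles_bed
#' @export
read_tiles_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "tile_id",
                                 "kind", "mappable_length"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "character", "integer"))
  df[, c("tile_id", "kind", "chrom", "start", "end", "mappable_length")]
}
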