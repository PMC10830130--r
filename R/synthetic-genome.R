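# Synthetic germline/somatic genome pairs.
#
# The germline (MIC-like) chromosome carries non-overlapping internal
# eliminated sequences (IESs); excising them and re-ligating the remaining
# macronuclear-destined sequences (MDSs) yields the somatic (MAC-like)
# chromosome.  A short repeat family is planted in both compartments so
# that some sequence is shared between IES and MDS and therefore
# non-mappable, mimicking the repetitive elements that make parts of real
# genomes unassignable.

# Fixed 60-nt repeat unit planted in both compartments (a literal constant,
# not drawn from the RNG, so two genomes with different seeds still share
# the same repeat family).
DEFAULT_REPEAT_UNIT <-
  "ACGTTAGCCTAGGATCCATGCGTACGTTAACGGCTAAGCTTACGGATCCTAGGCATGCAA"

#' Simulation parameters for the synthetic study
#'
#' Bundles every knob of the synthetic-data generator: genome geometry,
#' scnRNA production and degradation rates per genotype, sequencing depth
#' and the seed.  Defaults are the package's scaled-down emulation of the
#' study conditions: a 200 kb germline chromosome with 20 IESs of 1-3 kb,
#' scnRNA production biased 15:1 (per bp) towards IESs, first-order
#' degradation of MDS-matching scnRNAs at 0.6/h (wild type), 0.15/h
#' (EMA2 knockout) and 0/h (EMA1 knockout), sampling at 3 and 8 hours
#' post-mixing with 50,000 candidate reads per timepoint.
#'
#' @param genome_length Germline chromosome length in bp.
#' @param n_ies Number of IES intervals to place.
#' @param ies_length_range Length-2 integer vector, inclusive bp range of
#'   IES lengths.
#' @param repeat_unit Nucleotide string planted once inside an IES and once
#'   inside an MDS region.
#' @param read_length_range Inclusive nt range of simulated read lengths;
#'   must lie within 20-40 nt.
#' @param production_weight_ies,production_weight_mds Relative per-bp
#'   scnRNA production weights of the two compartments.
#' @param decay_rate_mds_per_h Named numeric vector mapping genotype to the
#'   per-hour degradation rate of MDS-matching scnRNAs; must cover at least
#'   WT, EMA2_KO and EMA1_KO.
#' @param decay_rate_ies_per_h Per-hour degradation rate of IES-matching
#'   scnRNAs (single number, shared by all genotypes).
#' @param timepoints_h Sampling times in hours post-mixing.
#' @param reads_per_timepoint Candidate reads drawn per timepoint before
#'   degradation thinning.
#' @param seed Integer seed; all generators are pure functions of
#'   (params, seed).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(genome_length = 200000L,
                       n_ies = 20L,
                       ies_length_range = c(1000L, 3000L),
                       repeat_unit = DEFAULT_REPEAT_UNIT,
                       read_length_range = c(26L, 32L),
                       production_weight_ies = 15,
                       production_weight_mds = 1,
                       decay_rate_mds_per_h = c(WT = 0.6, EMA2_KO = 0.15,
                                                EMA1_KO = 0),
                       decay_rate_ies_per_h = 0,
                       timepoints_h = c(3, 8),
                       reads_per_timepoint = 50000L,
                       seed = 1L) {
  stopifnot(length(genome_length) == 1L, genome_length >= 1,
            length(n_ies) == 1L, n_ies >= 0,
            length(ies_length_range) == 2L,
            ies_length_range[1] >= 1,
            ies_length_range[1] <= ies_length_range[2],
            length(read_length_range) == 2L,
            read_length_range[1] <= read_length_range[2])
  if (read_length_range[1] < 20 || read_length_range[2] > 40)
    stop("read_length_range must lie within [20, 40] nt", call. = FALSE)
  if (any(decay_rate_mds_per_h < 0) || any(decay_rate_ies_per_h < 0) ||
      production_weight_ies < 0 || production_weight_mds < 0)
    stop("production weights and decay rates must be >= 0", call. = FALSE)
  required <- c("WT", "EMA2_KO", "EMA1_KO")
  if (!all(required %in% names(decay_rate_mds_per_h)))
    stop("decay_rate_mds_per_h must name at least genotypes ",
         paste(required, collapse = ", "), call. = FALSE)
  if (!grepl("^[ACGT]+$", repeat_unit))
    stop("repeat_unit must be an ACGT string", call. = FALSE)
  if (length(timepoints_h) < 1L || any(timepoints_h < 0))
    stop("timepoints_h must be non-negative times", call. = FALSE)
  structure(list(
    genome_length = as.integer(genome_length),
    n_ies = as.integer(n_ies),
    ies_length_range = as.integer(ies_length_range),
    repeat_unit = repeat_unit,
    read_length_range = as.integer(read_length_range),
    production_weight_ies = production_weight_ies,
    production_weight_mds = production_weight_mds,
    decay_rate_mds_per_h = decay_rate_mds_per_h,
    decay_rate_ies_per_h = decay_rate_ies_per_h,
    timepoints_h = as.numeric(timepoints_h),
    reads_per_timepoint = as.integer(reads_per_timepoint),
    seed = as.integer(seed)
  ), class = "sim_params")
}

validate_intervals <- function(intervals, seq_len_bp) {
  if (nrow(intervals) == 0L) return(invisible(intervals))
  if (any(intervals$start < 0) || any(intervals$end > seq_len_bp) ||
      any(intervals$start >= intervals$end))
    stop("IES intervals must satisfy 0 <= start < end <= sequence length",
         call. = FALSE)
  if (is.unsorted(intervals$start, strictly = TRUE) ||
      any(intervals$start[-1] < intervals$end[-nrow(intervals)]))
    stop("IES intervals must be sorted and non-overlapping", call. = FALSE)
  invisible(intervals)
}

#' Excise IES intervals from a germline sequence
#'
#' Removes the given 0-based half-open intervals and re-ligates the
#' remaining MDS segments in order, returning the somatic sequence and a
#' germline-to-somatic coordinate map.
#'
#' @param mic_seq Germline nucleotide string.
#' @param ies_intervals Data frame with 0-based half-open `start`, `end`
#'   columns; must be sorted, non-overlapping and in range.
#' @return List with `mac_seq` (somatic sequence) and `mic_to_mac`, an
#'   integer vector of length `nchar(mic_seq)` giving, for position `p`
#'   (0-based, stored at index `p + 1`), the 0-based somatic coordinate,
#'   or `NA` for IES positions.  The defined part of the map is strictly
#'   increasing.
#' @export
excise <- function(mic_seq, ies_intervals) {
  stopifnot(is.character(mic_seq), length(mic_seq) == 1L)
  n <- nchar(mic_seq)
  if (is.null(ies_intervals) || NROW(ies_intervals) == 0L) {
    return(list(mac_seq = mic_seq,
                mic_to_mac = if (n > 0) 0:(n - 1L) else integer(0)))
  }
  ies_intervals <- as.data.frame(ies_intervals)
  validate_intervals(ies_intervals, n)
  keep <- rep(TRUE, n)
  for (i in seq_len(nrow(ies_intervals)))
    keep[(ies_intervals$start[i] + 1L):ies_intervals$end[i]] <- FALSE
  mds_segments <- substring(mic_seq,
                            ifelse(c(0, ies_intervals$end) + 1L <=
                                     c(ies_intervals$start, n),
                                   c(0, ies_intervals$end) + 1L, 1L),
                            c(ies_intervals$start, n))
  mds_segments <- mds_segments[c(0, ies_intervals$end) < c(ies_intervals$start, n)]
  mac_seq <- paste(mds_segments, collapse = "")
  mic_to_mac <- rep(NA_integer_, n)
  mic_to_mac[keep] <- seq_len(sum(keep)) - 1L
  list(mac_seq = mac_seq, mic_to_mac = mic_to_mac)
}

#' Generate a synthetic germline/somatic genome pair
#'
#' Draws a random germline chromosome, places `n_ies` non-overlapping IES
#' intervals (all labelled type "A"), plants one copy of the repeat unit
#' inside the first IES and one inside an MDS region, and derives the
#' somatic chromosome by excision.
#'
#' @param params A [sim_params()] object.
#' @return A list of class `genome_pair` with elements `mic_seq`,
#'   `ies_intervals` (data frame: start, end, type_label; 0-based
#'   half-open), `mac_seq` and `mic_to_mac`.
#' @export
generate_genome <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  L <- params$genome_length
  n_ies <- params$n_ies
  rep_len <- nchar(params$repeat_unit)
  min_gap <- max(100L, rep_len + 20L)
  max_total_ies <- n_ies * params$ies_length_range[2]
  if (L <= max_total_ies + 2 * rep_len)
    stop("infeasible sizing: genome_length must exceed n_ies * max IES ",
         "length plus repeat insertions", call. = FALSE)
  if (n_ies > 0 &&
      params$ies_length_range[1] < rep_len + 20L)
    stop("infeasible sizing: IESs must be at least repeat length + 20 bp ",
         "to host a planted repeat copy", call. = FALSE)

  with_seed(params$seed, {
    mic <- random_dna(L)
    if (n_ies > 0) {
      lens <- sample(seq(params$ies_length_range[1],
                         params$ies_length_range[2]), n_ies, replace = TRUE)
      slack <- L - sum(lens) - (n_ies + 1L) * min_gap
      if (slack < 0)
        stop("infeasible sizing: IES intervals cannot be placed without ",
             "overlap at the requested gaps", call. = FALSE)
      # gap i = min_gap + share of the slack; multinomial split keeps it
      # deterministic under the seed
      extra <- if (slack > 0)
        as.vector(stats::rmultinom(1, slack, rep(1, n_ies + 1L)))
      else rep(0L, n_ies + 1L)
      gaps <- min_gap + extra
      starts <- cumsum(c(gaps[1],
                         lens[-n_ies] + gaps[-c(1, n_ies + 1L)]))
      ies <- data.frame(start = as.integer(starts),
                        end = as.integer(starts + lens),
                        type_label = "A",
                        stringsAsFactors = FALSE)
      # plant the repeat family: one copy inside the first IES, one in the
      # MDS gap upstream of it
      mic <- plant(mic, params$repeat_unit, ies$start[1] + 10L)
      mic <- plant(mic, params$repeat_unit, ies$start[1] - rep_len - 10L)
    } else {
      ies <- data.frame(start = integer(0), end = integer(0),
                        type_label = character(0), stringsAsFactors = FALSE)
    }
    ex <- excise(mic, ies)
    # per-locus scnRNA production multipliers (lognormal): small RNA
    # output varies strongly between loci, which is what gives the
    # simulated per-tile RPKM distributions their heavy dispersion
    mult <- list(ies = stats::rlnorm(n_ies, 0, 0.5),
                 mds = stats::rlnorm(n_ies + 1L, 0, 0.5))
    structure(list(mic_seq = mic, ies_intervals = ies,
                   mac_seq = ex$mac_seq, mic_to_mac = ex$mic_to_mac,
                   production_mult = mult),
              class = "genome_pair")
  })
}

# Overwrite `unit` into `seq` at 0-based position `at`.
plant <- function(seq, unit, at) {
  stopifnot(at >= 0, at + nchar(unit) <= nchar(seq))
  paste0(substr(seq, 1L, at), unit,
         substr(seq, at + nchar(unit) + 1L, nchar(seq)))
}

# Alternating MDS-gap / IES segmentation of the germline chromosome,
# with per-segment production weights (compartment weight x locus
# multiplier x segment length).  0-based half-open coordinates.
production_segments <- function(genome, params) {
  n <- nchar(genome$mic_seq)
  ies <- genome$ies_intervals
  mult <- genome$production_mult %||%
    list(ies = rep(1, nrow(ies)), mds = rep(1, nrow(ies) + 1L))
  bounds_lo <- c(0L, ies$end)
  bounds_hi <- c(ies$start, n)
  mds <- data.frame(start = bounds_lo, end = bounds_hi,
                    compartment = "MDS", mult = mult$mds)
  seg <- rbind(mds[mds$start < mds$end, , drop = FALSE],
               if (nrow(ies))
                 data.frame(start = ies$start, end = ies$end,
                            compartment = "IES", mult = mult$ies))
  base_w <- ifelse(seg$compartment == "IES",
                   params$production_weight_ies,
                   params$production_weight_mds)
  seg$weight <- base_w * seg$mult * (seg$end - seg$start)
  seg
}

#' Write/read a genome pair as FASTA and BED
#'
#' The two chromosomes are written as FASTA records named `MIC` and `MAC`;
#' IES annotations as 5-column BED (chrom, start, end, name, type_label),
#' 0-based half-open.
#'
#' @param genome A `genome_pair`.
#' @param fasta_path,bed_path Output paths.
#' @return Invisibly, the paths.
#' @export
write_genome <- function(genome, fasta_path, bed_path) {
  seqs <- Biostrings::DNAStringSet(c(MIC = genome$mic_seq,
                                     MAC = genome$mac_seq))
  Biostrings::writeXStringSet(seqs, fasta_path)
  write_ies_bed(genome$ies_intervals, bed_path)
  invisible(c(fasta = fasta_path, bed = bed_path))
}

#' @rdname write_genome
#' @param ies_intervals IES annotation data frame (start, end, type_label).
#' @param path BED file path.
#' @export
write_ies_bed <- function(ies_intervals, path) {
  df <- data.frame(chrom = "MIC",
                   start = ies_intervals$start,
                   end = ies_intervals$end,
                   name = if (nrow(ies_intervals)) paste0("IES_", seq_len(nrow(ies_intervals))) else character(0),
                   type_label = ies_intervals$type_label,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_ies_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "name",
                                 "type_label"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "character"))
  df
}
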