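# Synthetic scnRNA pools with target-directed degradation structure.
#
# Production is collapsed into a timepoint-0 pool: at each sampling time a
# fixed number of candidate reads is drawn (compartment by production
# weight, position uniform within the compartment, strand by fair coin,
# length uniform over the read-length window), and each candidate survives
# to time t with probability exp(-rate * t), where the rate depends on the
# source compartment (MDS vs IES) and, for MDS, on the genotype.  Expected
# read mass per compartment therefore decays as exp(-rate * t) exactly,
# with binomial sampling error.

#' Simulate scnRNA read sets for one genotype
#'
#' @param genome A `genome_pair` from [generate_genome()].
#' @param params A [sim_params()] object.
#' @param genotype Genotype label; must name an entry of
#'   `params$decay_rate_mds_per_h`.
#' @return A list of read sets, one per timepoint.  Each read set is a list
#'   with `genotype`, `timepoint_h` and `reads`, a data frame with columns
#'   `sequence` and `multiplicity` (identical sequences aggregated).
#' @export
simulate_scnrna <- function(genome, params, genotype) {
  stopifnot(inherits(genome, "genome_pair"), inherits(params, "sim_params"))
  rates <- params$decay_rate_mds_per_h
  if (!genotype %in% names(rates))
    stop("unknown genotype label: ", genotype, "; configured genotypes: ",
         paste(names(rates), collapse = ", "), call. = FALSE)
  rate_mds <- unname(rates[[genotype]])
  rate_ies <- params$decay_rate_ies_per_h
  seg <- production_segments(genome, params)
  L <- nchar(genome$mic_seq)
  if (sum(seg$weight) <= 0)
    stop("at least one compartment must have positive production weight",
         call. = FALSE)
  seed <- derive_seed(params$seed, match(genotype, names(rates)))
  with_seed(seed, {
    lapply(params$timepoints_h, function(t) {
      n <- params$reads_per_timepoint
      len <- sample(seq(params$read_length_range[1],
                        params$read_length_range[2]), n, replace = TRUE)
      # segment by production weight, then position uniform within it
      si <- sample.int(nrow(seg), n, replace = TRUE, prob = seg$weight)
      start <- seg$start[si] +
        floor(runif(n) * (seg$end[si] - seg$start[si]))
      from_ies <- seg$compartment[si] == "IES"
      # keep reads inside the chromosome (clamp the rare end overhangs)
      start <- pmin(start, L - len)
      surv_rate <- ifelse(from_ies, rate_ies, rate_mds)
      keep <- runif(n) < exp(-surv_rate * t)
      minus <- runif(n) < 0.5
      start <- start[keep]; len <- len[keep]; minus <- minus[keep]
      seqs <- substring(genome$mic_seq, start + 1L, start + len)
      if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
      reads <- aggregate_reads(seqs)
      list(genotype = genotype, timepoint_h = t, reads = reads)
    })
  })
}

# Collapse a character vector of read sequences into a (sequence,
# multiplicity) data frame, sorted by sequence for determinism.
aggregate_reads <- function(seqs) {
  if (length(seqs) == 0L)
    return(data.frame(sequence = character(0), multiplicity = integer(0),
                      stringsAsFactors = FALSE))
  tab <- table(seqs)
  data.frame(sequence = names(tab),
             multiplicity = as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Write/read a read set as a two-column TSV (sequence, count)
#'
#' @param read_set A read set as returned by [simulate_scnrna()].
#' @param path Output path.
#' @return Invisibly, `path` (writer) or a read-set list (reader; genotype
#'   and timepoint are taken from the arguments, not the file).
#' @export
write_reads_tsv <- function(read_set, path) {
  write.table(read_set$reads, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_reads_tsv
#' @param genotype,timepoint_h Labels to attach to the read set.
#' @export
read_reads_tsv <- function(path, genotype = NA_character_,
                           timepoint_h = NA_real_) {
  reads <- read.table(path, sep = "\t", header = TRUE,
                      colClasses = c("character", "integer"))
  names(reads) <- c("sequence", "multiplicity")
  list(genotype = genotype, timepoint_h = timepoint_h, reads = reads)
}

#' Read small-RNA reads from FASTA/FASTQ
#'
#' Record duplication encodes multiplicity; identical sequences are
#' aggregated.  Gzipped files are accepted.
#'
#' @param path FASTA or FASTQ file.
#' @param format `"fasta"` or `"fastq"`.
#' @inheritParams read_reads_tsv
#' @return A read-set list as in [simulate_scnrna()].
#' @export
read_reads_fasta <- function(path, format = c("fasta", "fastq"),
                             genotype = NA_character_,
                             timepoint_h = NA_real_) {
  format <- match.arg(format)
  seqs <- as.character(Biostrings::readDNAStringSet(path, format = format))
  list(genotype = genotype, timepoint_h = timepoint_h,
       reads = aggregate_reads(unname(seqs)))
}
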