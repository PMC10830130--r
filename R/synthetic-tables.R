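# Synthetic per-cell FISH intensity tables and label-free proteomics
# (LFQ) tables with known ground truth.

# Noise-free region means used by the intensity generator.  FISH signal in
# the new MAC is background + retention * kappa * (DAPI excess), so the
# noise-free per-cell ratio-of-ratios equals the group's true retention
# level exactly.
INTENSITY_BASELINE <- list(dapi_A = 200, dapi_I = 50, dapi_C = 10,
                           fish_C = 10, kappa = 2)

#' Simulate a per-cell two-channel intensity table
#'
#' Emulates manual region quantification of a DNA elimination FISH assay:
#' per cell, mean intensities of the new MAC (A), the MIC (I) and a patch
#' of cytoplasm (C) in the FISH and DAPI channels.  The FISH A-signal
#' scales with the group's true retention level; additive Gaussian noise
#' (truncated at 0) is applied to every region mean, then per-channel
#' multiplicative gains.  Because the noise is drawn before the gains are
#' applied, runs at the same seed but different gains yield identical
#' downstream retention indices.
#'
#' @param n_cells Cells per group (the conventional design uses 20).
#' @param group_effects Named numeric vector mapping group label to its
#'   true retention level (>= 0; 0 = complete elimination, 1 = complete
#'   block).
#' @param noise_sd Standard deviation of the additive intensity noise, in
#'   the same arbitrary units as the baselines.
#' @param channel_gains Length-2 numeric vector `c(fish, dapi)` of
#'   multiplicative channel gains.
#' @param seed Integer seed.
#' @return Data frame with columns `cell_id`, `group`, `fish_A`, `fish_I`,
#'   `fish_C`, `dapi_A`, `dapi_I`, `dapi_C`.
#' @export
simulate_intensity_table <- function(n_cells = 20L, group_effects,
                                     noise_sd = 2, channel_gains = c(1, 1),
                                     seed = 1L) {
  if (length(noise_sd) != 1L || is.na(noise_sd) || noise_sd < 0)
    stop("noise_sd must be a single value >= 0", call. = FALSE)
  stopifnot(is.numeric(group_effects), length(group_effects) >= 1L,
            !is.null(names(group_effects)), all(group_effects >= 0),
            length(channel_gains) == 2L, all(channel_gains > 0))
  b <- INTENSITY_BASELINE
  with_seed(seed, {
    rows <- lapply(names(group_effects), function(g) {
      ret <- group_effects[[g]]
      means <- cbind(
        fish_A = b$fish_C + ret * b$kappa * (b$dapi_A - b$dapi_C),
        fish_I = b$fish_C + b$kappa * (b$dapi_I - b$dapi_C),
        fish_C = b$fish_C,
        dapi_A = b$dapi_A, dapi_I = b$dapi_I, dapi_C = b$dapi_C)
      m <- matrix(rep(means, each = n_cells), nrow = n_cells,
                  dimnames = list(NULL, colnames(means)))
      m <- m + matrix(rnorm(n_cells * 6, sd = noise_sd), nrow = n_cells)
      m[m < 0] <- 0
      gain <- rep(channel_gains, c(3, 3))
      m <- sweep(m, 2, gain, `*`)
      data.frame(cell_id = paste0(g, "_", seq_len(n_cells)), group = g,
                 m, stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

#' Simulate a label-free quantification (LFQ) protein table
#'
#' Emulates a His-tag pulldown proteomics screen for SUMOylation targets:
#' background proteins detected similarly in the WT and KO crosses,
#' `n_targets` planted targets whose WT-minus-KO log2 LFQ difference is at
#' least `effect_log2` (the first planted target is made the most abundant
#' WT protein, mimicking the screen's top hit), `n_bead_binders` proteins
#' with control-condition log2 LFQ above 25 (nickel-bead binders), and
#' `n_polyhis` decoys whose sequences carry a run of at least 7
#' histidines.  Exactly `n_targets` proteins have an observed WT-minus-KO
#' difference >= `effect_log2`; all other differences are clipped below it.
#'
#' @param n_proteins Total number of proteins.
#' @param n_targets Number of planted condition-dependent targets (>= 1).
#' @param n_bead_binders,n_polyhis Numbers of planted contaminants.
#' @param effect_log2 Minimum WT-minus-KO log2 LFQ difference of targets.
#' @param missing_rate Fraction of WT/KO intensities left-censored below
#'   the detection limit (reported as NA).
#' @param seed Integer seed.
#' @return Data frame with columns `protein_id`, `aa_sequence`,
#'   `lfq_NOHIS`, `lfq_WT`, `lfq_KO` (linear-scale intensities, NA =
#'   not detected) and ground-truth flags `is_target`, `is_bead_binder`,
#'   `is_polyhis`.
#' @export
simulate_lfq_table <- function(n_proteins = 300L, n_targets = 1L,
                               n_bead_binders = 15L, n_polyhis = 10L,
                               effect_log2 = 6, missing_rate = 0.05,
                               seed = 1L) {
  if (n_targets < 1)
    stop("n_targets must be >= 1 (at least one planted target)",
         call. = FALSE)
  if (n_polyhis > n_proteins || n_targets + n_bead_binders + n_polyhis > n_proteins)
    stop("sizing error: planted classes exceed n_proteins", call. = FALSE)
  stopifnot(effect_log2 > 0, missing_rate >= 0, missing_rate <= 1)
  with_seed(seed, {
    id <- sprintf("P%04d", seq_len(n_proteins))
    role <- rep("background", n_proteins)
    role[seq_len(n_targets)] <- "target"
    if (n_bead_binders > 0)
      role[n_targets + seq_len(n_bead_binders)] <- "bead"
    if (n_polyhis > 0)
      role[n_targets + n_bead_binders + seq_len(n_polyhis)] <- "polyhis"

    aa <- vapply(sample(80:300, n_proteins, replace = TRUE),
                 random_protein, character(1))
    # random 20-letter sequences essentially never carry a 7-His run, but
    # guarantee it for the ground truth to be exact
    redraw <- role != "polyhis" & has_poly_his(aa)
    while (any(redraw)) {
      aa[redraw] <- vapply(sample(80:300, sum(redraw), replace = TRUE),
                           random_protein, character(1))
      redraw <- role != "polyhis" & has_poly_his(aa)
    }
    his_run <- strrep("H", sample(7:10, n_proteins, replace = TRUE))
    idx_ph <- which(role == "polyhis")
    aa[idx_ph] <- paste0(substr(aa[idx_ph], 1, 40), his_run[idx_ph],
                         substring(aa[idx_ph], 41))

    # log2 intensities; WT/KO differences of non-targets clipped strictly
    # below the planted effect
    base <- rnorm(n_proteins, mean = 20, sd = 2)
    clip <- min(1.5, 0.8 * effect_log2)
    diff <- pmax(-clip, pmin(clip, rnorm(n_proteins, sd = 0.5)))
    log2_wt <- base + diff / 2
    log2_ko <- base - diff / 2
    idx_t <- which(role == "target")
    log2_wt[idx_t] <- 28 + abs(rnorm(n_targets))
    log2_wt[idx_t[1]] <- max(log2_wt) + 1   # most abundant WT protein
    log2_ko[idx_t] <- log2_wt[idx_t] - effect_log2 - abs(rnorm(n_targets, sd = 0.5))
    # control condition: bead binders bind the beads without the tag
    log2_ctrl <- rep(NA_real_, n_proteins)
    idx_b <- which(role == "bead")
    log2_ctrl[idx_b] <- runif(n_bead_binders, 25.5, 30)
    low_ctrl <- role != "bead" & runif(n_proteins) < 0.2
    log2_ctrl[low_ctrl] <- rnorm(sum(low_ctrl), 15, 2)

    # missingness is left-censoring at a detection limit: the lowest
    # missing_rate fraction of WT/KO intensities is not detected
    if (missing_rate > 0) {
      limit <- quantile(c(log2_wt, log2_ko), missing_rate, names = FALSE)
      log2_wt[log2_wt < limit] <- NA_real_
      log2_ko[log2_ko < limit] <- NA_real_
    }

    data.frame(protein_id = id, aa_sequence = aa,
               lfq_NOHIS = 2^log2_ctrl, lfq_WT = 2^log2_wt,
               lfq_KO = 2^log2_ko,
               is_target = role == "target",
               is_bead_binder = role == "bead",
               is_polyhis = role == "polyhis",
               stringsAsFactors = FALSE)
  })
}

#' Write/read the tabular synthetic inputs as TSV with header
#'
#' @param table A data frame (intensity or LFQ table).
#' @param path Output path.
#' @return Invisibly `path`; the reader returns the data frame.
#' @export
write_table_tsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
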