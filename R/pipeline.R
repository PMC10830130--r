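# End-to-end orchestration: simulate -> tiles -> quantify -> kinetics ->
# retention -> screen, as one reproducible run driven by a single config
# and seed.  One global seed fans out to per-stage child seeds by a fixed
# derivation so each stage is independently reproducible.

#' Default run configuration
#'
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return A list of class `run_config` with components `sim`
#'   ([sim_params()]), `tiling`, `quant`, `retention` and `screen`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    sim = sim_params(seed = derive_seed(seed, 1)),
    tiling = list(tile_size = 10000L, min_mappable = 3000L, k = 26L),
    quant = list(min_nt = 26L, max_nt = 32L, denominator = "assigned"),
    kinetics = list(pseudocount = 0.1),
    retention = list(n_cells = 20L,
                     group_effects = c(WT = 0, EMA2_KO = 0.4,
                                       TWI1_KO = 1),
                     noise_sd = 2, channel_gains = c(1, 1),
                     calibrate_on = "TWI1_KO",
                     seed = derive_seed(seed, 2)),
    screen = list(n_proteins = 300L, n_targets = 1L,
                  n_bead_binders = 15L, n_polyhis = 10L,
                  effect_log2 = 6, missing_rate = 0.05,
                  cond_wt = "WT", cond_ko = "KO",
                  control_condition = "NOHIS", log2_threshold = 25,
                  his_run = 7L, seed = derive_seed(seed, 3))
  ), class = "run_config")
}

#' Run the whole pipeline
#'
#' Generates the synthetic inputs, builds tiles, quantifies every
#' genotype x timepoint read set, compares tile distributions between
#' timepoints (rank-sum), fits decay rates and ranks genotypes, scores
#' the retention-index assay and runs the proteomics screen.  The run is
#' a pure function of the configuration (including its seeds).
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param out_json Optional path; if given, the report is written there
#'   as JSON.
#' @return A list of class `run_report`; see the vignette for the layout.
#' @export
run_pipeline <- function(config = default_run_config(), out_json = NULL) {
  stopifnot(inherits(config, "run_config"))
  params <- config$sim

  genome <- generate_genome(params)
  ref <- combined_reference(genome)
  mask <- compute_mappability(ref, k = config$tiling$k)
  mds_tiles <- build_mds_tiles(ref["MAC"], mask,
                               tile_size = config$tiling$tile_size,
                               min_mappable = config$tiling$min_mappable)
  ies_tiles <- build_ies_tiles(genome, mask)
  if (nrow(ies_tiles) == 0L)
    warning("no IES tiles: the IES section of the report is empty",
            call. = FALSE)
  tiles <- rbind(mds_tiles, ies_tiles)
  quant_ref <- c(MAC = genome$mac_seq, MIC = genome$mic_seq)

  genotypes <- names(params$decay_rate_mds_per_h)
  rpkm_long <- do.call(rbind, lapply(genotypes, function(g) {
    sets <- simulate_scnrna(genome, params, g)
    do.call(rbind, lapply(sets, function(rs) {
      tab <- quantify_reads(rs, tiles, quant_ref,
                            min_nt = config$quant$min_nt,
                            max_nt = config$quant$max_nt,
                            denominator = config$quant$denominator)
      tab$genotype <- g
      tab$timepoint_h <- rs$timepoint_h
      attr(tab, "counts") <- NULL
      tab
    }))
  }))

  # rank-sum comparison of per-tile RPKM between the first and last
  # timepoint, per genotype and compartment
  t0 <- min(params$timepoints_h); t1 <- max(params$timepoints_h)
  comparisons <- do.call(rbind, unlist(lapply(genotypes, function(g)
    lapply(intersect(c("MDS", "IES"), unique(tiles$kind)), function(kind) {
      a <- rpkm_long$rpkm[rpkm_long$genotype == g &
                            rpkm_long$kind == kind &
                            rpkm_long$timepoint_h == t0]
      b <- rpkm_long$rpkm[rpkm_long$genotype == g &
                            rpkm_long$kind == kind &
                            rpkm_long$timepoint_h == t1]
      if (!length(a) || !length(b)) return(NULL)
      ht <- rank_sum_test(a, b)
      data.frame(genotype = g, kind = kind, t_a = t0, t_b = t1,
                 n_tiles = length(a), U = ht$U, p = ht$p,
                 median_a = median(a), median_b = median(b),
                 stringsAsFactors = FALSE)
    })), recursive = FALSE))

  fits <- unlist(lapply(intersect(c("MDS", "IES"), unique(tiles$kind)),
                        function(kind) {
    lapply(genotypes, function(g) {
      sub <- rpkm_long[rpkm_long$genotype == g & rpkm_long$kind == kind,
                       c("timepoint_h", "rpkm")]
      if (!nrow(sub)) return(NULL)
      fit_decay(sub, pseudocount = config$kinetics$pseudocount,
                genotype = g, compartment = kind)
    })
  }), recursive = FALSE)
  fits <- Filter(Negate(is.null), fits)
  mds_fits <- Filter(function(f) f$compartment == "MDS", fits)
  ordering <- if (length(mds_fits)) rank_genotypes(mds_fits) else character(0)

  ret_tab <- simulate_intensity_table(
    n_cells = config$retention$n_cells,
    group_effects = config$retention$group_effects,
    noise_sd = config$retention$noise_sd,
    channel_gains = config$retention$channel_gains,
    seed = config$retention$seed)
  ret <- score_retention(ret_tab, calibrate_on = config$retention$calibrate_on)
  ret_summary <- summarize_retention(ret$per_cell)

  scr_cfg <- config$screen
  lfq <- simulate_lfq_table(n_proteins = scr_cfg$n_proteins,
                            n_targets = scr_cfg$n_targets,
                            n_bead_binders = scr_cfg$n_bead_binders,
                            n_polyhis = scr_cfg$n_polyhis,
                            effect_log2 = scr_cfg$effect_log2,
                            missing_rate = scr_cfg$missing_rate,
                            seed = scr_cfg$seed)
  screen <- suppressWarnings(compare_conditions(
    lfq, cond_wt = scr_cfg$cond_wt, cond_ko = scr_cfg$cond_ko,
    control_condition = scr_cfg$control_condition,
    log2_threshold = scr_cfg$log2_threshold, his_run = scr_cfg$his_run))
  top <- screen[!is.na(screen$rank), ]
  top <- top[order(top$rank), ][seq_len(min(10, nrow(top))), ]

  report <- structure(list(
    config = config,
    genome = list(mic_length = nchar(genome$mic_seq),
                  mac_length = nchar(genome$mac_seq),
                  n_ies = nrow(genome$ies_intervals)),
    tiles = list(n_mds = nrow(mds_tiles), n_ies = nrow(ies_tiles)),
    rpkm = rpkm_long,
    comparisons = comparisons,
    decay_fits = decay_fits_table(fits),
    genotype_order_mds = as.character(ordering),
    retention = list(factor = ret$factor, summary = ret_summary$summary,
                     pairwise = ret_summary$pairwise),
    screen = list(top_candidates = top,
                  n_flagged_bead = sum(screen$bead_binder),
                  n_flagged_polyhis = sum(screen$poly_his),
                  truth = lfq[, c("protein_id", "is_target",
                                  "is_bead_binder", "is_polyhis")])
  ), class = "run_report")

  if (!is.null(out_json)) {
    jsonlite::write_json(report_to_json(report), out_json,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# JSON-friendly view of a report (drops the bulky per-tile table).
report_to_json <- function(report) {
  list(
    seed = report$config$seed,
    genome = report$genome,
    tiles = report$tiles,
    comparisons = report$comparisons,
    decay_fits = report$decay_fits,
    genotype_order_mds = report$genotype_order_mds,
    retention = list(factor = report$retention$factor,
                     summary = report$retention$summary,
                     pairwise = report$retention$pairwise),
    screen_top = report$screen$top_candidates
  )
}
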