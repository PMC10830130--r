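# Calibrated IES retention index from per-cell two-channel intensity
# measurements.
#
# Per cell, both channels are background-corrected against the cytoplasm
# and referenced to the MIC; the index is the FISH ratio divided by the
# DAPI ratio, times a calibration factor.  The factor is either the
# conventional default 0.35 or re-derived so that a complete-elimination-
# block control group has mean index exactly 1.

#' Background-corrected region ratio
#'
#' `(a - c) / (i - c)`: the new-MAC signal over the MIC signal, both
#' corrected by the cytoplasmic background.  May be negative when the
#' new-MAC mean is below background; such values are reported as-is.
#'
#' @param a,i,c Mean intensities of the new MAC, the MIC and the
#'   cytoplasm (vectorized).
#' @return Dimensionless ratio(s).
#' @export
corrected_ratio <- function(a, i, c) {
  if (any(i <= c))
    stop("degenerate background: MIC intensity must exceed the ",
         "cytoplasmic background (i > c)", call. = FALSE)
  (a - c) / (i - c)
}

# Raw per-cell ratio-of-ratios (FISH over DAPI), NA for cells failing the
# i > c precondition in either channel.
raw_ratio_of_ratios <- function(records) {
  ok <- records$fish_I > records$fish_C & records$dapi_I > records$dapi_C
  out <- rep(NA_real_, nrow(records))
  if (any(ok)) {
    fr <- corrected_ratio(records$fish_A[ok], records$fish_I[ok],
                          records$fish_C[ok])
    dr <- corrected_ratio(records$dapi_A[ok], records$dapi_I[ok],
                          records$dapi_C[ok])
    bad_dapi <- dr == 0
    if (any(bad_dapi))
      stop("undefined index: DAPI corrected ratio is 0 for cell(s) ",
           paste(records$cell_id[ok][bad_dapi], collapse = ", "),
           call. = FALSE)
    out[ok] <- fr / dr
  }
  out
}

#' Compute per-cell IES retention indices
#'
#' @param records Intensity data frame with columns `cell_id`, `group`,
#'   `fish_A`, `fish_I`, `fish_C`, `dapi_A`, `dapi_I`, `dapi_C`.
#' @param factor Calibration factor; the conventional rounded constant 0.35 by
#'   default.
#' @return Data frame `cell_id`, `group`, `raw_ratio` (ratio-of-ratios),
#'   `index` (`factor * raw_ratio`), `factor_used`.  Cells with a
#'   degenerate background (`I <= C` in either channel) are dropped with
#'   a warning.
#' @export
retention_index <- function(records, factor = 0.35) {
  stopifnot(is.data.frame(records), length(factor) == 1L, factor > 0)
  raw <- raw_ratio_of_ratios(records)
  dropped <- is.na(raw)
  if (any(dropped))
    warning(sum(dropped), " cell(s) dropped for degenerate background: ",
            paste(records$cell_id[dropped], collapse = ", "),
            call. = FALSE)
  data.frame(cell_id = records$cell_id[!dropped],
             group = records$group[!dropped],
             raw_ratio = raw[!dropped],
             index = factor * raw[!dropped],
             factor_used = factor,
             stringsAsFactors = FALSE)
}

#' Derive the calibration factor from a control group
#'
#' The factor is the reciprocal of the mean raw ratio-of-ratios over the
#' control cells, so that the control group's mean calibrated index is
#' exactly 1 (the complete-elimination-block convention).
#'
#' @param control_records Intensity rows of the control group (at least
#'   2 cells with defined raw ratios).
#' @return The calibration factor.
#' @export
calibrate_factor <- function(control_records) {
  raw <- raw_ratio_of_rat_defined(control_records)
  if (length(raw) < 2L)
    stop("calibration needs at least 2 control cells with defined raw ",
         "ratios", call. = FALSE)
  m <- mean(raw)
  if (m <= 0)
    stop("calibration error: mean raw ratio of the control group is <= 0",
         call. = FALSE)
  1 / m
}

raw_ratio_of_rat_defined <- function(records) {
  raw <- raw_ratio_of_ratios(records)
  raw[!is.na(raw)]
}

#' Score a whole intensity table
#'
#' Applies [retention_index()] to every cell, optionally re-deriving the
#' calibration factor from one group.
#'
#' @inheritParams retention_index
#' @param calibrate_on If non-NULL, the group label to calibrate the
#'   factor on (overrides `factor`).
#' @return List with `per_cell` (the [retention_index()] data frame) and
#'   `factor`.
#' @export
score_retention <- function(records, factor = 0.35, calibrate_on = NULL) {
  if (!is.null(calibrate_on)) {
    if (!calibrate_on %in% records$group)
      stop("calibration group not present: ", calibrate_on, call. = FALSE)
    factor <- calibrate_factor(records[records$group == calibrate_on, ,
                                       drop = FALSE])
  }
  list(per_cell = retention_index(records, factor), factor = factor)
}

#' Group summary and pairwise Welch tests of retention indices
#'
#' @param per_cell A per-cell result data frame from [retention_index()].
#' @return List with `summary` (per group: n, mean, median, 10th and
#'   90th percentiles) and `pairwise` (per group pair: Welch `t`, `df`,
#'   two-sided `p`).
#' @export
summarize_retention <- function(per_cell) {
  groups <- unique(per_cell$group)
  summary <- do.call(rbind, lapply(groups, function(g) {
    v <- per_cell$index[per_cell$group == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               median = median(v),
               p10 = unname(quantile(v, 0.1, type = 7)),
               p90 = unname(quantile(v, 0.9, type = 7)),
               stringsAsFactors = FALSE)
  }))
  pairs <- if (length(groups) >= 2) utils::combn(groups, 2) else
    matrix(character(0), nrow = 2)
  pairwise <- if (ncol(pairs)) do.call(rbind, lapply(seq_len(ncol(pairs)),
    function(j) {
      a <- per_cell$index[per_cell$group == pairs[1, j]]
      b <- per_cell$index[per_cell$group == pairs[2, j]]
      ht <- welch_t_test(a, b)
      data.frame(group_a = pairs[1, j], group_b = pairs[2, j],
                 t = ht$t, df = ht$df, p = ht$p, stringsAsFactors = FALSE)
    })) else data.frame(group_a = character(0), group_b = character(0),
                        t = numeric(0), df = numeric(0), p = numeric(0))
  list(summary = summary, pairwise = pairwise)
}
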