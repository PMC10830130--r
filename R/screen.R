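# SUMO-proteomics candidate filter and WT-vs-KO LFQ comparison.
#
# The screen first removes likely bead contaminants — proteins abundant
# in the no-tag control pulldown (log2 LFQ strictly above 25) and
# proteins with a poly-histidine tract (a run of 7 or more H, i.e. "more
# than six") that would bind the nickel beads without a His-tagged SUMO
# conjugate — then ranks the remaining proteins by their WT-minus-KO
# log2 LFQ difference.  The screen ranks; it does not test (the design
# is single-replicate).

#' Detect poly-histidine tracts
#'
#' @param aa_sequence Character vector of amino-acid sequences
#'   (case-insensitive); `NA` or empty sequences give `FALSE`.
#' @param min_run Minimum run length of consecutive histidines (default
#'   7, i.e. strictly more than six).
#' @return Logical vector.
#' @export
has_poly_his <- function(aa_sequence, min_run = 7L) {
  stopifnot(min_run >= 1)
  out <- grepl(strrep("H", min_run), toupper(aa_sequence), fixed = TRUE)
  out[is.na(aa_sequence)] <- FALSE
  out
}

lfq_column <- function(records, condition) {
  col <- paste0("lfq_", condition)
  if (!col %in% names(records))
    stop("unknown condition label: ", condition, " (no column ", col, ")",
         call. = FALSE)
  records[[col]]
}

#' Flag nickel-bead binders by the control pulldown
#'
#' A protein is flagged iff its log2 LFQ intensity in the no-tag control
#' condition is strictly above the threshold; proteins not detected in
#' the control are never flagged.
#'
#' @param records Protein data frame with `lfq_<condition>` columns
#'   (linear-scale intensities).
#' @param control_condition Label of the no-tag control condition.
#' @param log2_threshold Strict log2 LFQ cutoff (default 25).
#' @return Logical vector.
#' @export
flag_bead_binders <- function(records, control_condition = "NOHIS",
                              log2_threshold = 25) {
  v <- lfq_column(records, control_condition)
  !is.na(v) & log2(v) > log2_threshold
}

#' Compare WT and KO LFQ intensities and rank candidates
#'
#' Applies the bead-binder and poly-His filters, computes per-protein
#' `delta = log2(WT) - log2(KO)` with missing intensities imputed at a
#' detection floor (the table's minimum observed log2 value minus 1,
#' flagged in the output), and ranks unflagged proteins by `delta`
#' descending, then WT abundance descending.
#'
#' @param records Protein data frame (`protein_id`, optional
#'   `aa_sequence`, `lfq_<condition>` columns).
#' @param cond_wt,cond_ko Condition labels of the WT and KO crosses.
#' @param control_condition No-tag control label for the bead filter.
#' @param log2_threshold Bead-binder cutoff.
#' @param his_run Poly-His run-length threshold.
#' @return Data frame of class `screen_result`: per protein, `log2_wt`,
#'   `log2_ko`, `delta`, `imputed_wt`, `imputed_ko`, `bead_binder`,
#'   `poly_his` and `rank` (NA for flagged proteins); proteins missing
#'   in both conditions are excluded with a warning.
#' @export
compare_conditions <- function(records, cond_wt = "WT", cond_ko = "KO",
                               control_condition = "NOHIS",
                               log2_threshold = 25, his_run = 7L) {
  wt <- lfq_column(records, cond_wt)
  ko <- lfq_column(records, cond_ko)
  bead <- flag_bead_binders(records, control_condition, log2_threshold)
  phis <- if ("aa_sequence" %in% names(records))
    has_poly_his(records$aa_sequence, his_run)
  else rep(FALSE, nrow(records))
  both_missing <- is.na(wt) & is.na(ko)
  if (any(both_missing))
    warning(sum(both_missing), " protein(s) excluded: not detected in ",
            "either compared condition", call. = FALSE)
  keep <- !both_missing
  l2wt <- log2(wt[keep]); l2ko <- log2(ko[keep])
  floor_log2 <- min(c(l2wt, l2ko), na.rm = TRUE) - 1
  imputed_wt <- is.na(l2wt)
  imputed_ko <- is.na(l2ko)
  l2wt[imputed_wt] <- floor_log2
  l2ko[imputed_ko] <- floor_log2
  out <- data.frame(protein_id = records$protein_id[keep],
                    log2_wt = l2wt, log2_ko = l2ko,
                    delta = l2wt - l2ko,
                    imputed_wt = imputed_wt, imputed_ko = imputed_ko,
                    bead_binder = bead[keep], poly_his = phis[keep],
                    rank = NA_integer_, stringsAsFactors = FALSE)
  cand <- which(!out$bead_binder & !out$poly_his)
  ord <- cand[order(-out$delta[cand], -out$log2_wt[cand])]
  out$rank[ord] <- seq_along(ord)
  class(out) <- c("screen_result", class(out))
  out
}
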