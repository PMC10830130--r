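# First-order decay fits of per-tile RPKM time courses.
#
# The degradation model is log-linear: log(median RPKM + pseudocount)
# regressed on time; the negative slope is the per-hour decay rate,
# clipped at 0.  The median across tiles (not per-tile fits) is used
# because tile-to-tile dispersion is heavy; the pseudocount keeps the
# log defined when a compartment is fully degraded.

#' Fit a first-order decay rate to an RPKM time course
#'
#' @param rpkm_by_timepoint Data frame with columns `timepoint_h` and
#'   `rpkm` (one row per tile per timepoint).
#' @param pseudocount Added to the median RPKM before the log (default
#'   0.1 RPKM).
#' @param genotype,compartment Optional labels stored in the fit.
#' @return A list of class `decay_fit`: `genotype`, `compartment`,
#'   `rate_per_h` (>= 0), `intercept_log`, `stderr_rate` (NA for the
#'   exact two-timepoint fit), `n_tiles`, `n_timepoints`.
#' @export
fit_decay <- function(rpkm_by_timepoint, pseudocount = 0.1,
                      genotype = NA_character_,
                      compartment = NA_character_) {
  stopifnot(is.data.frame(rpkm_by_timepoint),
            all(c("timepoint_h", "rpkm") %in% names(rpkm_by_timepoint)),
            pseudocount > 0)
  if (any(rpkm_by_timepoint$rpkm < 0))
    stop("RPKM values must be >= 0", call. = FALSE)
  tp <- sort(unique(rpkm_by_timepoint$timepoint_h))
  if (length(tp) < 2L)
    stop("at least 2 timepoints are required", call. = FALSE)
  med <- vapply(tp, function(t) {
    v <- rpkm_by_timepoint$rpkm[rpkm_by_timepoint$timepoint_h == t]
    if (length(v) == 0L)
      stop("timepoint ", t, " has no tiles", call. = FALSE)
    median(v)
  }, numeric(1))
  y <- log(med + pseudocount)
  if (length(tp) == 2L) {
    slope <- (y[2] - y[1]) / (tp[2] - tp[1])
    intercept <- y[1] - slope * tp[1]
    se <- NA_real_
  } else {
    fit <- lm(y ~ tp)
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    se <- summary(fit)$coefficients[2, 2]
  }
  structure(list(genotype = genotype, compartment = compartment,
                 rate_per_h = max(0, -slope), intercept_log = intercept,
                 stderr_rate = se,
                 n_tiles = nrow(rpkm_by_timepoint),
                 n_timepoints = length(tp)),
            class = "decay_fit")
}

#' Order genotypes by fitted decay rate
#'
#' @param fits List of `decay_fit` objects for the same compartment.
#' @return Character vector of genotype labels in descending order of
#'   `rate_per_h`; ties are broken lexicographically and flagged in the
#'   logical attribute `tied`.
#' @export
rank_genotypes <- function(fits) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "decay_fit")))
  comp <- unique(vapply(fits, `[[`, character(1), "compartment"))
  if (length(comp) > 1L)
    stop("fits mix compartments: ", paste(comp, collapse = ", "),
         call. = FALSE)
  g <- vapply(fits, `[[`, character(1), "genotype")
  r <- vapply(fits, `[[`, numeric(1), "rate_per_h")
  ord <- order(-r, g)
  out <- g[ord]
  attr(out, "rates") <- r[ord]
  attr(out, "tied") <- anyDuplicated(r) > 0L
  out
}

#' Serialize decay fits
#'
#' @param fits List of `decay_fit` objects.
#' @return One-row-per-fit data frame.
#' @export
decay_fits_table <- function(fits) {
  do.call(rbind, lapply(fits, function(f)
    data.frame(genotype = f$genotype, compartment = f$compartment,
               rate_per_h = f$rate_per_h, intercept_log = f$intercept_log,
               stderr_rate = f$stderr_rate, n_tiles = f$n_tiles,
               n_timepoints = f$n_timepoints, stringsAsFactors = FALSE)))
}
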