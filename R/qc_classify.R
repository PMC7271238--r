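# cell-inclusion filters and the hypoexcitability classification

#' Apply the standard motoneuron inclusion filters
#'
#' A cell passes QC iff all of: soma max diameter > 20 um, RMP < -50 mV,
#' action-potential peak > 0 mV, input resistance < 110 MOhm (derived as
#' 1000 / G_in with G_in in nS), series resistance < 25 MOhm, RMP drift
#' <= 10 mV, and series-resistance drift <= 10 MOhm (exclusion when a drift
#' strictly exceeds 10). Inequalities are strict or not exactly as the
#' criteria are worded. A missing metric makes that filter indeterminate
#' (`NA`) and the cell fails overall.
#'
#' @param records Data frame with one row per cell and columns
#'   `soma_diam_um`, `RMP_mV`, `AP_peak_mV`, `G_in_nS`, `Rs_MOhm`,
#'   `RMP_drift_mV`, `Rs_drift_MOhm` (extra columns are carried through).
#' @return `records` with logical verdict columns `filter_diameter`,
#'   `filter_rmp`, `filter_ap_peak`, `filter_rin`, `filter_rs`,
#'   `filter_rmp_drift`, `filter_rs_drift`, a derived `R_in_MOhm`, and the
#'   overall `qc_pass`.
#' @export
apply_inclusion_filters <- function(records) {
  records <- as.data.frame(records)
  need <- c("soma_diam_um", "RMP_mV", "AP_peak_mV", "G_in_nS", "Rs_MOhm",
            "RMP_drift_mV", "Rs_drift_MOhm")
  for (nm in setdiff(need, names(records))) records[[nm]] <- NA_real_
  records$R_in_MOhm <- 1000 / records$G_in_nS
  records$filter_diameter  <- records$soma_diam_um > 20
  records$filter_rmp       <- records$RMP_mV < -50
  records$filter_ap_peak   <- records$AP_peak_mV > 0
  records$filter_rin       <- records$R_in_MOhm < 110
  records$filter_rs        <- records$Rs_MOhm < 25
  records$filter_rmp_drift <- !(records$RMP_drift_mV > 10)
  records$filter_rs_drift  <- !(records$Rs_drift_MOhm > 10)
  verdicts <- records[, paste0("filter_", c("diameter", "rmp", "ap_peak",
                                            "rin", "rs", "rmp_drift", "rs_drift"))]
  pass <- apply(verdicts, 1L, function(r) all(r %in% TRUE))
  records$qc_pass <- as.logical(pass)
  records
}

#' Classify hypoexcitability from the three protocol outcomes
#'
#' A cell is hypoexcitable iff it fires at most `few_spike_max` spikes on
#' the standard current bi-ramp AND at most `few_spike_max` on the
#' double-amplitude bi-ramp, yet remains capable of at least one spike in
#' response to the 1 nA step. A cell that cannot spike under any of the
#' three protocols is not hypoexcitable but unexcitable. Missing counts
#' give `NA` (indeterminate).
#'
#' @param ramp_spikes_standard,ramp_spikes_doubled,step_spikes_1nA Integer
#'   spike counts (vectorized).
#' @param few_spike_max "A few spikes" cutoff; default 4.
#' @return Logical vector: `TRUE` = hypoexcitable. The parallel category
#'   vector (`"normal"`, `"hypoexcitable"`, `"unexcitable"`) is attached as
#'   attribute `category`.
#' @export
classify_hypoexcitable <- function(ramp_spikes_standard, ramp_spikes_doubled,
                                   step_spikes_1nA, few_spike_max = 4) {
  n <- max(length(ramp_spikes_standard), length(ramp_spikes_doubled),
           length(step_spikes_1nA))
  s1 <- rep_len(ramp_spikes_standard, n)
  s2 <- rep_len(ramp_spikes_doubled, n)
  s3 <- rep_len(step_spikes_1nA, n)
  hypo <- s1 <= few_spike_max & s2 <= few_spike_max & s3 >= 1
  unex <- s1 == 0 & s2 == 0 & s3 == 0
  cat_ <- rep(NA_character_, n)
  cat_[hypo %in% TRUE] <- "hypoexcitable"
  cat_[hypo %in% FALSE] <- "normal"
  cat_[unex %in% TRUE] <- "unexcitable"
  structure(hypo, category = cat_)
}

#' QC + classification report for a metrics table
#'
#' Convenience wrapper: applies [apply_inclusion_filters()] and, when the
#' spike-count columns `ramp_spikes_std`, `ramp_spikes_dbl`,
#' `step_spikes_1nA` are present, appends `hypoexcitable` and
#' `excitability_class`.
#'
#' @param metrics Per-cell metrics data frame.
#' @param few_spike_max Passed to [classify_hypoexcitable()].
#' @return Augmented data frame.
#' @export
qc_cohort <- function(metrics, few_spike_max = 4) {
  out <- apply_inclusion_filters(metrics)
  cnt <- c("ramp_spikes_std", "ramp_spikes_dbl", "step_spikes_1nA")
  if (all(cnt %in% names(out))) {
    h <- classify_hypoexcitable(out$ramp_spikes_std, out$ramp_spikes_dbl,
                                out$step_spikes_1nA, few_spike_max)
    out$hypoexcitable <- as.logical(h)
    out$excitability_class <- attr(h, "category")
  }
  out
}
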