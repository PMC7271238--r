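# pipeline orchestration: simulate -> analyze -> qc -> stats -> report

#' Default run configuration
#'
#' All protocol parameters, analysis thresholds and cohort sizes of a
#' simulated study in one serializable list. A run is reproducible from its
#' config plus one integer seed. Defaults are the study conditions of the
#' electrophysiology data set: 25/22/21/24 cells per group with 4 of the 24
#' treated mSOD1 cells hypoexcitable, and 120/60/75/76 soma volumes.
#'
#' @param n_per_group Named cell counts for groups WT, mSOD1, WT+PF,
#'   mSOD1+PF.
#' @param n_hypo How many of the mSOD1+PF cells are drawn from the
#'   hypoexcitable preset.
#' @param soma_n Named soma-volume sample sizes per group.
#' @param noise_sd Recording noise SD (pA).
#' @param dt_vc,dt_cc Sample intervals for voltage-/current-clamp
#'   simulation (ms).
#' @param vc_ramp,cc_ramp,cc_step,vc_steps Protocol parameter lists; see
#'   the waveform constructors.
#' @param leak_window Leak-fit voltage window (mV).
#' @param onset_current,onset_sustain_ms,smooth_n PIC onset criterion.
#' @param few_spike_max Hypoexcitability spike-count cutoff.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(n_per_group = c("WT" = 25, "mSOD1" = 22,
                                               "WT+PF" = 21, "mSOD1+PF" = 24),
                               n_hypo = 4,
                               soma_n = c("WT" = 120, "mSOD1" = 60,
                                          "WT+PF" = 75, "mSOD1+PF" = 76),
                               noise_sd = 5, dt_vc = 0.1, dt_cc = 0.01,
                               vc_ramp = list(v_start = -80, v_peak = 10, rate = 20),
                               cc_ramp = list(rate = 600, peak = 1500),
                               cc_step = list(amplitude = 1000, duration = 800),
                               vc_steps = list(v_hold = -80,
                                               step_amplitudes = c(-10, -5, 5, 10),
                                               step_duration = 500),
                               leak_window = c(-80, -60),
                               onset_current = -10, onset_sustain_ms = 50,
                               smooth_n = 201, few_spike_max = 4) {
  structure(list(n_per_group = n_per_group, n_hypo = n_hypo, soma_n = soma_n,
                 noise_sd = noise_sd, dt_vc = dt_vc, dt_cc = dt_cc,
                 vc_ramp = vc_ramp, cc_ramp = cc_ramp, cc_step = cc_step,
                 vc_steps = vc_steps, leak_window = leak_window,
                 onset_current = onset_current,
                 onset_sustain_ms = onset_sustain_ms, smooth_n = smooth_n,
                 few_spike_max = few_spike_max),
            class = "run_config")
}

#' Read / write a run configuration (JSON or YAML)
#'
#' @param config A `run_config`.
#' @param path File path; `.json` always supported, `.yaml`/`.yml` when the
#'   yaml package is installed.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: a
#'   `run_config`.
#' @export
write_run_config <- function(config, path) {
  config <- unclass(config)
  # named count vectors as objects so JSON/YAML keep the group names
  config$n_per_group <- as.list(config$n_per_group)
  config$soma_n <- as.list(config$soma_n)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_data("the 'yaml' package is required for YAML configs")
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_data(sprintf("missing config: %s", path))
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_data("the 'yaml' package is required for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg <- default_run_config()
  for (nm in names(raw)) {
    if (nm %in% c("n_per_group", "soma_n")) cfg[[nm]] <- unlist(raw[[nm]])
    else cfg[[nm]] <- raw[[nm]]
  }
  cfg
}

#' Simulate the full protocol battery for one cell
#'
#' Gap-free resting recording, voltage-step family, slow voltage bi-ramp,
#' standard and double-amplitude current bi-ramps, and the prolonged
#' current step.
#'
#' @param params A `cell_params`.
#' @param config A `run_config`.
#' @param seed Integer seed (one stream per cell; sub-protocol seeds are
#'   derived deterministically).
#' @return Named list of `trace`s: `gapfree`, `vc_steps` (list), `vc_ramp`,
#'   `cc_ramp`, `cc_ramp2x`, `cc_step`.
#' @export
simulate_cell_protocols <- function(params, config = default_run_config(),
                                    seed = params$rng_seed) {
  seed <- as.integer(seed)
  vr <- config$vc_ramp
  cr <- config$cc_ramp
  cs <- config$cc_step
  vs <- config$vc_steps
  ramp_v <- make_voltage_biramp(vr$v_start, vr$v_peak, vr$rate, dt = config$dt_vc)
  steps_v <- make_voltage_steps(vs$v_hold, vs$step_amplitudes, vs$step_duration,
                                dt = config$dt_vc)
  ramp_i <- make_current_biramp(cr$rate, cr$peak, dt = config$dt_cc)
  ramp_i2 <- make_current_biramp(cr$rate, 2 * cr$peak, dt = config$dt_cc)
  step_i <- make_current_step(cs$amplitude, cs$duration, dt = config$dt_cc)
  gap <- make_current_step(0, 2000, dt = config$dt_vc, baseline_ms = 0,
                           post_ms = 0)
  list(gapfree = simulate_current_clamp(params, gap, seed = seed + 1L),
       vc_steps = lapply(seq_along(steps_v), function(i)
         simulate_voltage_clamp(params, steps_v[[i]], seed = seed + 1L + i)),
       vc_ramp = simulate_voltage_clamp(params, ramp_v, seed = seed + 10L),
       cc_ramp = simulate_current_clamp(params, ramp_i, seed = seed + 11L),
       cc_ramp2x = simulate_current_clamp(params, ramp_i2, seed = seed + 12L),
       cc_step = simulate_current_clamp(params, step_i, seed = seed + 13L))
}

#' Extract the per-cell metric row from one cell's protocol traces
#'
#' Runs the voltage-clamp analysis (input conductance, capacitance, leak
#' fit, PIC extraction), the current-clamp analysis (RMP, spike shape, F-I
#' fit) and the three spike counts feeding the hypoexcitability
#' classification. Metrics whose preconditions fail (e.g. fewer than two
#' spikes for an F-I fit) are `NA`.
#'
#' @param traces Output of [simulate_cell_protocols()] (or equivalently
#'   structured recorded data).
#' @param config A `run_config`.
#' @return One-row data frame of metrics.
#' @export
analyze_cell <- function(traces, config = default_run_config()) {
  g_in <- estimate_input_conductance(traces$vc_steps)
  cap <- tryCatch(estimate_capacitance(traces$vc_steps[[1]]),
                  picramp_error = function(e) NA_real_)
  leak <- fit_leak(traces$vc_ramp, window = config$leak_window)
  pic <- extract_pic(traces$vc_ramp, leak,
                     onset_current = config$onset_current,
                     onset_sustain_ms = config$onset_sustain_ms,
                     smooth_n = config$smooth_n)
  rmp <- measure_rmp(traces$gapfree)
  st <- detect_spikes(traces$cc_ramp)
  fi_row <- tryCatch({
    fi <- build_fi(traces$cc_ramp)
    ion <- traces$cc_ramp$command[round(st$times[1] / traces$cc_ramp$dt) + 1L]
    ioff <- traces$cc_ramp$command[round(st$times[st$n] / traces$cc_ramp$dt) + 1L]
    ff <- fit_fi(fi, ion, ioff)
    data.frame(Ion_pA = ff$I_on, Ioff_pA = ff$I_off, dI_pA = ff$delta_I,
               FI_asc_Hz_per_nA = ff$slope_asc,
               FI_desc_Hz_per_nA = ff$slope_desc)
  }, picramp_error = function(e)
    data.frame(Ion_pA = NA_real_, Ioff_pA = NA_real_, dI_pA = NA_real_,
               FI_asc_Hz_per_nA = NA_real_, FI_desc_Hz_per_nA = NA_real_))
  ap_peak <- if (st$n > 0) mean(st$peaks) else NA_real_
  vthr <- if (st$n > 0) mean(st$thresholds, na.rm = TRUE) else NA_real_
  cbind(data.frame(G_in_nS = g_in, C_pF = cap, RMP_mV = rmp,
                   PIC_amp_pA = pic$amplitude,
                   PIC_peak_mV = pic$peak_voltage,
                   PIC_onset_mV = pic$onset_voltage,
                   AP_overshoot_mV = ap_peak, Vthresh_mV = vthr),
        fi_row,
        data.frame(ramp_spikes_std = st$n,
                   ramp_spikes_dbl = detect_spikes(traces$cc_ramp2x)$n,
                   step_spikes_1nA = assess_repetitive_firing(traces$cc_step)))
}

.equiv_diameter <- function(volume) 2 * (3 * volume / (4 * pi))^(1 / 3)

#' Run a complete simulated study
#'
#' Draws the per-group cohorts (including the hypoexcitable subpopulation
#' of the treated mSOD1 group), simulates every cell's protocol battery,
#' extracts all metrics, attaches recording metadata (series resistance and
#' drifts within the inclusion limits, soma diameter from a volume draw),
#' applies QC and the hypoexcitability classification, and samples the
#' per-group soma-volume cohorts.
#'
#' @param seed Integer master seed; everything derives from it.
#' @param config A `run_config`.
#' @param presets Group presets (default [motoneuron_presets()] at the
#'   config's noise level).
#' @return An object of class `mn_study`: list with `metrics` (per-cell
#'   data frame incl. QC/classification), `truth` (generator ground truth
#'   per cell), `soma` (named list of volume vectors), `config`, `seed`.
#' @export
run_study <- function(seed = 1L, config = default_run_config(),
                      presets = motoneuron_presets(config$noise_sd)) {
  seed <- as.integer(seed)
  set.seed(seed)
  group_names <- names(config$n_per_group)
  seeds <- stats::setNames(sample.int(2^31 - 10L, length(group_names) * 2 + 1),
                           NULL)
  metrics <- list(); truth <- list()
  row_i <- 0L
  for (gi in seq_along(group_names)) {
    gname <- group_names[gi]
    n <- config$n_per_group[[gname]]
    n_hypo <- if (gname == "mSOD1+PF") min(config$n_hypo, n) else 0L
    cells <- make_cohort(presets[[gname]], n - n_hypo, seed = seeds[gi])
    if (n_hypo > 0)
      cells <- c(cells, make_cohort(presets[["mSOD1+PF-hypo"]], n_hypo,
                                    seed = seeds[gi] + 1L))
    # recording metadata: series resistance and drifts inside the inclusion
    # limits (the recorded cohort represents cells that survived QC), soma
    # diameter from a volume draw of the group's distribution
    set.seed(seeds[length(group_names) + gi])
    rs <- .draw_trunc(length(cells), 15, 4, lo = 5, hi = 24)
    rmp_drift <- abs(.draw_trunc(length(cells), 0, 2, lo = -9.5, hi = 9.5))
    rs_drift <- abs(.draw_trunc(length(cells), 0, 2, lo = -9.5, hi = 9.5))
    vols <- sample_soma_volumes(presets[[gname]], length(cells),
                                seed = seeds[length(group_names) + gi] + 1L)
    for (ci in seq_along(cells)) {
      p <- cells[[ci]]
      traces <- simulate_cell_protocols(p, config, seed = p$rng_seed)
      m <- analyze_cell(traces, config)
      row_i <- row_i + 1L
      m <- cbind(data.frame(cell_id = sprintf("%s_%02d", gname, ci),
                            group = gname,
                            preset = attr(p, "group"),
                            stringsAsFactors = FALSE),
                 m,
                 data.frame(Rs_MOhm = rs[ci], RMP_drift_mV = rmp_drift[ci],
                            Rs_drift_MOhm = rs_drift[ci],
                            soma_diam_um = .equiv_diameter(vols[ci]),
                            AP_peak_mV = m$AP_overshoot_mV))
      metrics[[row_i]] <- m
      truth[[row_i]] <- data.frame(cell_id = m$cell_id, group = gname,
                                   preset = attr(p, "group"),
                                   C = p$C, G_leak = p$G_leak,
                                   E_leak = p$E_leak, G_pic = p$G_pic,
                                   V_T = p$V_T, ap_peak = p$ap_peak,
                                   pic_target = attr(p, "pic_target"),
                                   hypo = p$avail_use > 0,
                                   rng_seed = p$rng_seed,
                                   stringsAsFactors = FALSE)
    }
  }
  metrics <- do.call(rbind, metrics)
  metrics <- qc_cohort(metrics, config$few_spike_max)
  soma <- lapply(stats::setNames(group_names, group_names), function(gname)
    sample_soma_volumes(presets[[gname]], config$soma_n[[gname]],
                        seed = seeds[length(seeds)] + which(group_names == gname)))
  structure(list(metrics = metrics, truth = do.call(rbind, truth),
                 soma = soma, config = config, seed = seed),
            class = "mn_study")
}

#' @export
print.mn_study <- function(x, ...) {
  cat(sprintf("<mn_study> seed %d: %d cells in %d groups; %d QC-pass, %d hypoexcitable\n",
              x$seed, nrow(x$metrics), length(unique(x$metrics$group)),
              sum(x$metrics$qc_pass, na.rm = TRUE),
              sum(x$metrics$hypoexcitable, na.rm = TRUE)))
  invisible(x)
}

.summary_cols <- c("G_in_nS", "RMP_mV", "Ion_pA", "Ioff_pA", "dI_pA",
                   "FI_asc_Hz_per_nA", "FI_desc_Hz_per_nA", "AP_overshoot_mV",
                   "Vthresh_mV", "C_pF", "PIC_amp_pA", "PIC_peak_mV",
                   "PIC_onset_mV")

#' Group-level statistics of a study
#'
#' Per-group (and hypoexcitable-subgroup) summary table of every
#' electrophysiological metric, one-way ANOVA + Tukey post hoc across the
#' four groups for each metric, soma-volume ANOVA and per-group histograms
#' (5000-um^3 bins) with upper-tail percentages.
#'
#' @param study An `mn_study`, or a metrics data frame (then `soma` may be
#'   given separately).
#' @param soma Optional named list of per-group volume vectors.
#' @return List with `group_table`, `anova`, `tukey`, `soma_anova`,
#'   `histograms`, `tail_pct`.
#' @export
study_stats <- function(study, soma = NULL) {
  if (inherits(study, "mn_study")) {
    metrics <- study$metrics
    soma <- study$soma
  } else metrics <- as.data.frame(study)
  groups <- unique(metrics$group)
  split_rows <- c(
    stats::setNames(lapply(groups, function(g)
      metrics[metrics$group == g, , drop = FALSE]), groups),
    if (!is.null(metrics$hypoexcitable) && any(metrics$hypoexcitable, na.rm = TRUE))
      list("mSOD1+PF (non-hypo)" = metrics[metrics$group == "mSOD1+PF" &
                                             !metrics$hypoexcitable %in% TRUE, ],
           "mSOD1+PF (hypo)" = metrics[metrics$hypoexcitable %in% TRUE, ]))
  group_table <- do.call(rbind, lapply(names(split_rows), function(nm) {
    d <- split_rows[[nm]]
    row <- data.frame(group = nm, n = nrow(d))
    for (cl in intersect(.summary_cols, names(d))) {
      v <- d[[cl]][is.finite(d[[cl]])]
      row[[paste0(cl, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      row[[paste0(cl, "_sd")]] <- if (length(v) > 1) stats::sd(v) else NA_real_
    }
    row
  }))
  by_group <- lapply(stats::setNames(groups, groups), function(g)
    metrics[metrics$group == g, , drop = FALSE])
  anova <- list(); tukey <- list()
  for (cl in intersect(.summary_cols, names(metrics))) {
    vals <- lapply(by_group, function(d) d[[cl]][is.finite(d[[cl]])])
    vals <- vals[lengths(vals) >= 2]
    if (length(vals) >= 2) {
      anova[[cl]] <- anova_oneway(vals)
      tukey[[cl]] <- tukey_hsd(vals)
    }
  }
  soma_anova <- NULL; histograms <- NULL; tail_pct <- NULL
  if (!is.null(soma)) {
    soma_anova <- anova_oneway(soma)
    nb <- floor(max(unlist(soma)) / 5000) + 1L
    histograms <- lapply(soma, histogram_volumes, bin_width = 5000, n_bins = nb)
    tail_pct <- vapply(soma, tail_fraction, numeric(1))
  }
  list(group_table = group_table, anova = anova, tukey = tukey,
       soma_anova = soma_anova, histograms = histograms, tail_pct = tail_pct)
}

#' Assemble and optionally write the study report
#'
#' A single JSON-serializable report: the per-group metric table (four
#' groups plus the hypoexcitable sub-rows), soma-volume histogram table,
#' test results, QC verdicts and the hypoexcitable fraction. With `path`
#' set, writes `<path>.json` and a human-readable `<path>.md`.
#'
#' @param study An `mn_study`.
#' @param path Output path stem (optional).
#' @return The report list, invisibly when writing.
#' @export
study_report <- function(study, path = NULL) {
  stopifnot(inherits(study, "mn_study"))
  st <- study_stats(study)
  mpf <- study$metrics[study$metrics$group == "mSOD1+PF", ]
  n_hypo <- sum(mpf$hypoexcitable %in% TRUE)
  report <- list(
    seed = study$seed,
    n_cells = nrow(study$metrics),
    qc_pass = sum(study$metrics$qc_pass %in% TRUE),
    group_table = st$group_table,
    hypoexcitable = list(n = n_hypo, of = nrow(mpf),
                         pct = round(100 * n_hypo / max(nrow(mpf), 1), 1)),
    anova_p = lapply(st$anova, `[[`, "p"),
    soma_anova = if (!is.null(st$soma_anova))
      list(F = st$soma_anova$statistic, p = st$soma_anova$p),
    soma_tail_pct = as.list(st$tail_pct),
    histograms = st$histograms)
  if (!is.null(path)) {
    jsonlite::write_json(report, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = 10, dataframe = "columns")
    md <- c(sprintf("# Simulated motoneuron study (seed %d)", study$seed),
            "",
            sprintf("Cells: %d (%d QC-pass). Hypoexcitable: %d of %d mSOD1+PF (%.1f%%).",
                    report$n_cells, report$qc_pass, n_hypo, nrow(mpf),
                    report$hypoexcitable$pct),
            "", "## Group means (mean / sd)", "")
    gt <- st$group_table
    md <- c(md, paste(names(gt), collapse = " | "),
            paste(rep("---", ncol(gt)), collapse = " | "),
            vapply(seq_len(nrow(gt)), function(i)
              paste(vapply(gt[i, ], function(v)
                if (is.numeric(v)) sprintf("%.3g", v) else as.character(v),
                character(1)), collapse = " | "), character(1)))
    writeLines(md, paste0(path, ".md"))
    return(invisible(report))
  }
  report
}

# disk-based pipeline verbs ---------------------------------------------------

#' Disk-based pipeline: simulate, analyze, qc, stats, report
#'
#' Thin file-based wrappers over the in-memory pipeline, for running the
#' stages separately on a directory tree: `cmd_simulate` writes one CSV (+
#' JSON sidecar) per trace and a ground-truth TSV; `cmd_analyze` reads a
#' trace directory back into per-cell metrics; `cmd_qc` appends QC and
#' classification columns; `cmd_stats` writes the test results;
#' `cmd_report` assembles the final JSON/markdown report. Missing inputs
#' raise an error naming the missing artifact.
#'
#' @param config A `run_config`.
#' @param seed Integer seed.
#' @param outdir,trace_dir,run_dir Directories.
#' @param metrics_tsv Path to a metrics TSV.
#' @return Each verb returns its primary output path, invisibly.
#' @export
cmd_simulate <- function(config = default_run_config(), seed = 1L,
                         outdir = "run") {
  dir.create(file.path(outdir, "traces"), recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))
  presets <- motoneuron_presets(config$noise_sd)
  truth <- list()
  for (gname in names(config$n_per_group)) {
    n <- config$n_per_group[[gname]]
    n_hypo <- if (gname == "mSOD1+PF") min(config$n_hypo, n) else 0L
    gseed <- sample.int(2^31 - 10L, 1)
    cells <- make_cohort(presets[[gname]], n - n_hypo, seed = gseed)
    if (n_hypo > 0)
      cells <- c(cells, make_cohort(presets[["mSOD1+PF-hypo"]], n_hypo,
                                    seed = gseed + 1L))
    for (ci in seq_along(cells)) {
      p <- cells[[ci]]
      id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", gname), ci)
      traces <- simulate_cell_protocols(p, config, seed = p$rng_seed)
      cell_dir <- file.path(outdir, "traces", id)
      dir.create(cell_dir, showWarnings = FALSE)
      write_trace_csv(traces$gapfree, file.path(cell_dir, "gapfree.csv"))
      for (si in seq_along(traces$vc_steps))
        write_trace_csv(traces$vc_steps[[si]],
                        file.path(cell_dir, sprintf("vc_step_%d.csv", si)))
      write_trace_csv(traces$vc_ramp, file.path(cell_dir, "vc_ramp.csv"))
      write_trace_csv(traces$cc_ramp, file.path(cell_dir, "cc_ramp.csv"))
      write_trace_csv(traces$cc_ramp2x, file.path(cell_dir, "cc_ramp2x.csv"))
      write_trace_csv(traces$cc_step, file.path(cell_dir, "cc_step.csv"))
      truth[[id]] <- data.frame(cell_id = id, group = gname,
                                preset = attr(p, "group"),
                                C = p$C, G_leak = p$G_leak, E_leak = p$E_leak,
                                G_pic = p$G_pic, V_T = p$V_T,
                                ap_peak = p$ap_peak,
                                pic_target = attr(p, "pic_target"))
    }
  }
  data.table::fwrite(do.call(rbind, truth),
                     file.path(outdir, "ground_truth.tsv"), sep = "\t")
  write_run_config(config, file.path(outdir, "config.json"))
  invisible(file.path(outdir, "traces"))
}

#' @rdname cmd_simulate
#' @export
cmd_analyze <- function(trace_dir, config = NULL) {
  if (!dir.exists(trace_dir)) stop_data(sprintf("missing artifact: %s", trace_dir))
  if (is.null(config)) {
    cfg_path <- file.path(dirname(trace_dir), "config.json")
    config <- if (file.exists(cfg_path)) read_run_config(cfg_path)
              else default_run_config()
  }
  cells <- list.dirs(trace_dir, recursive = FALSE)
  if (!length(cells)) stop_data(sprintf("missing artifact: no cell directories in %s", trace_dir))
  rows <- lapply(cells, function(cd) {
    need <- c("gapfree.csv", "vc_ramp.csv", "cc_ramp.csv", "cc_ramp2x.csv",
              "cc_step.csv")
    for (f in need)
      if (!file.exists(file.path(cd, f)))
        stop_data(sprintf("missing artifact: %s", file.path(cd, f)))
    steps <- sort(list.files(cd, pattern = "^vc_step_\\d+\\.csv$",
                             full.names = TRUE))
    traces <- list(gapfree = read_trace_csv(file.path(cd, "gapfree.csv")),
                   vc_steps = lapply(steps, read_trace_csv),
                   vc_ramp = read_trace_csv(file.path(cd, "vc_ramp.csv")),
                   cc_ramp = read_trace_csv(file.path(cd, "cc_ramp.csv")),
                   cc_ramp2x = read_trace_csv(file.path(cd, "cc_ramp2x.csv")),
                   cc_step = read_trace_csv(file.path(cd, "cc_step.csv")))
    cbind(data.frame(cell_id = basename(cd)), analyze_cell(traces, config))
  })
  metrics <- do.call(rbind, rows)
  truth_path <- file.path(dirname(trace_dir), "ground_truth.tsv")
  if (file.exists(truth_path)) {
    truth <- as.data.frame(data.table::fread(truth_path, sep = "\t"))
    metrics <- merge(truth[, c("cell_id", "group", "preset")], metrics,
                     by = "cell_id", sort = TRUE)
  }
  out <- file.path(dirname(trace_dir), "metrics.tsv")
  data.table::fwrite(metrics, out, sep = "\t")
  invisible(out)
}

#' @rdname cmd_simulate
#' @export
cmd_qc <- function(metrics_tsv, few_spike_max = 4) {
  if (!file.exists(metrics_tsv))
    stop_data(sprintf("missing artifact: %s", metrics_tsv))
  metrics <- as.data.frame(data.table::fread(metrics_tsv, sep = "\t"))
  out <- qc_cohort(metrics, few_spike_max)
  path <- file.path(dirname(metrics_tsv), "qc_report.tsv")
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname cmd_simulate
#' @export
cmd_stats <- function(metrics_tsv) {
  if (!file.exists(metrics_tsv))
    stop_data(sprintf("missing artifact: %s", metrics_tsv))
  metrics <- as.data.frame(data.table::fread(metrics_tsv, sep = "\t"))
  st <- study_stats(metrics)
  path <- file.path(dirname(metrics_tsv), "stats.json")
  jsonlite::write_json(
    list(group_table = st$group_table,
         anova = lapply(st$anova, function(t)
           list(F = t$statistic, df = t$df, p = t$p)),
         tukey = st$tukey),
    path, auto_unbox = TRUE, digits = 10, dataframe = "columns")
  invisible(path)
}

#' @rdname cmd_simulate
#' @export
cmd_report <- function(run_dir) {
  for (f in c("metrics.tsv", "config.json"))
    if (!file.exists(file.path(run_dir, f)))
      stop_data(sprintf("missing artifact: %s", file.path(run_dir, f)))
  qc_path <- file.path(run_dir, "qc_report.tsv")
  metrics <- if (file.exists(qc_path))
    as.data.frame(data.table::fread(qc_path, sep = "\t"))
  else qc_cohort(as.data.frame(data.table::fread(file.path(run_dir, "metrics.tsv"),
                                                 sep = "\t")))
  st <- study_stats(metrics)
  path <- file.path(run_dir, "report.json")
  jsonlite::write_json(list(group_table = st$group_table,
                            anova_p = lapply(st$anova, `[[`, "p")),
                       path, auto_unbox = TRUE, digits = 10,
                       dataframe = "columns")
  invisible(path)
}
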