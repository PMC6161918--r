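# End-to-end pipeline: simulate -> preprocess -> detect -> extract ->
# filter -> stats, writing every intermediate artifact.  Re-running with an
# identical configuration and seed reproduces identical outputs.

#' Run the full analysis pipeline on synthetic sessions
#'
#' Simulates `n_participants` sessions, preprocesses the samples, detects
#' saccades and microsaccades, extracts the six binned eye parameters,
#' filters trials, assembles condition cells, and runs the statistical
#' layer: a two-factor repeated-measures ANOVA (condition x time) per eye
#' parameter, planned paired comparisons of the two multiplication
#' conditions per parameter and bin (Bonferroni-corrected over the four
#' bins, with JZS Bayes factors), and the performance summary with paired
#' tests per performance measure.  All artifacts are written as CSV under
#' `config$out_dir`, together with a run log recording the seed and
#' configuration.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results (`trials`,
#'   `discards`, `events`, `binned`, `cells`, `performance`, `anova`,
#'   `comparisons`, `files`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  sim <- config$sim
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (config$verbose) message(...)

  say("simulating ", sim$n_participants, " session(s)")
  sessions <- lapply(seq_len(sim$n_participants),
                     function(p) simulate_session(sim, participant = p))
  samples <- do.call(rbind, lapply(sessions, `[[`, "samples"))
  trials <- do.call(rbind, lapply(sessions, `[[`, "trials"))
  truth <- do.call(rbind, lapply(sessions, `[[`, "truth"))

  say("preprocessing")
  prep <- preprocess_samples(samples, config$exclusion, sim)

  say("detecting events")
  events <- detect_saccades(samples, prep$mask, config$detection, sim)

  say("extracting binned parameters")
  binned <- bin_parameters(samples, prep$mask, events, prep$blinks, trials,
                           config$binning, config$baseline, sim)

  say("filtering trials")
  filtered <- filter_trials(trials)
  cells <- assemble_conditions(filtered, binned)
  perf <- performance_summary(trials)

  say("statistics")
  anova_rows <- list(); comp_rows <- list()
  analysis <- cells$cells
  analysis <- analysis[!analysis$participant %in% cells$flagged, , drop = FALSE]
  for (param in param_names) {
    d <- analysis[analysis$parameter == param, , drop = FALSE]
    if (length(unique(d$participant)) >= 2 &&
        length(unique(d$condition)) == 3) {
      an <- tryCatch(suppressMessages(rm_anova_2way(d)), error = function(e) NULL)
      if (!is.null(an)) {
        an$parameter <- param
        anova_rows[[length(anova_rows) + 1L]] <- as.data.frame(an)
      }
    }
    for (bin in unique(d$bin)) {
      wide <- merge(
        d[d$condition == "mult_no_distractor" & d$bin == bin,
          c("participant", "value")],
        d[d$condition == "mult_distractor" & d$bin == bin,
          c("participant", "value")],
        by = "participant", suffixes = c("_no", "_with"))
      wide <- wide[complete.cases(wide), , drop = FALSE]
      if (nrow(wide) < 3) next
      tt <- tryCatch(paired_t(wide$value_with, wide$value_no,
                              k_corrections = 4, bayes = config$bayes),
                     error = function(e) NULL)
      if (is.null(tt)) next
      comp_rows[[length(comp_rows) + 1L]] <- data.frame(
        parameter = param, bin = bin, n = tt$n, t = tt$t, df = tt$df,
        p_raw = tt$p_raw, p_corrected = tt$p_corrected, d_z = tt$d_z,
        bf10 = tt$bf10, bf01 = tt$bf01, stringsAsFactors = FALSE)
    }
  }
  anova_tab <- if (length(anova_rows)) do.call(rbind, anova_rows) else NULL
  comp_tab <- if (length(comp_rows)) do.call(rbind, comp_rows) else NULL

  files <- list(
    samples = file.path(config$out_dir, "samples.csv"),
    trials = file.path(config$out_dir, "trials.csv"),
    truth = file.path(config$out_dir, "truth_events.csv"),
    discards = file.path(config$out_dir, "discard_summary.csv"),
    events = file.path(config$out_dir, "events.csv"),
    binned = file.path(config$out_dir, "binned_parameters.csv"),
    cells = file.path(config$out_dir, "condition_cells.csv"),
    exclusions = file.path(config$out_dir, "trial_exclusions.csv"),
    performance = file.path(config$out_dir, "performance_summary.csv"),
    anova = file.path(config$out_dir, "anova.csv"),
    comparisons = file.path(config$out_dir, "planned_comparisons.csv"),
    log = file.path(config$out_dir, "run_log.txt"))

  write_samples(samples, files$samples)
  write_trials(trials, files$trials)
  write_events(truth, files$truth)
  write.csv(prep$summary, files$discards, row.names = FALSE)
  write_events(events, files$events)
  write.csv(binned, files$binned, row.names = FALSE, na = "")
  write.csv(cells$cells, files$cells, row.names = FALSE, na = "")
  write.csv(filtered$report, files$exclusions, row.names = FALSE)
  write.csv(perf, files$performance, row.names = FALSE)
  if (!is.null(anova_tab)) write.csv(anova_tab, files$anova, row.names = FALSE)
  if (!is.null(comp_tab)) write.csv(comp_tab, files$comparisons, row.names = FALSE)
  writeLines(c(
    paste("idcgaze", as.character(utils::packageVersion("idcgaze"))),
    paste("R", paste(R.version$major, R.version$minor, sep = ".")),
    paste("seed", config$seed),
    paste("participants", sim$n_participants),
    paste("lambda", config$detection$lambda),
    paste("prior_scale", config$bayes$prior_scale)),
    files$log)

  invisible(list(trials = trials, discards = prep$summary, events = events,
                 binned = binned, cells = cells$cells, performance = perf,
                 anova = anova_tab, comparisons = comp_tab, files = files))
}
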