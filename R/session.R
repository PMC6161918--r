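# Trial-level filtering and condition assembly: correct trials only, catch
# trials out, per-participant 3-SD response-time rule, passive-viewing
# validity, and pooling of passive trials across blocks.

#' Filter trials for analysis
#'
#' Retains correct, non-catch multiplication trials with response time
#' within `rt_sd_multiplier` standard deviations of the participant's mean
#' (computed over correct non-catch multiplication trials pooled across
#' blocks), and passive-viewing trials with a valid response.  Participants
#' with any invalid passive-viewing response (they answered with a number)
#' are excluded wholesale.
#'
#' @param trials a trial metadata table (see [simulate_session()]).
#' @param rt_sd_multiplier SD cut for the response-time rule.
#' @return list with `trials` (input plus `included` and `reason` columns)
#'   and `report` (one row per excluded trial: participant, trial, reason).
#' @export
filter_trials <- function(trials, rt_sd_multiplier = 3) {
  stopifnot(all(trials$rt_s > 0 | trials$condition == "passive_viewing"))
  n <- nrow(trials)
  included <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  flag <- function(i, why) {
    sel <- i & included
    included[sel] <<- FALSE
    reason[sel] <<- why
  }
  is_mult <- trials$condition != "passive_viewing"

  bad_pv <- unique(trials$participant[!is_mult & !trials$passive_response_valid])
  flag(trials$participant %in% bad_pv, "passive_violation")
  flag(is_mult & trials$correctness == "forgot", "forgot")
  flag(is_mult & trials$correctness == "incorrect", "incorrect")
  flag(is_mult & trials$catch_flag, "catch")

  for (p in unique(trials$participant)) {
    pool <- which(trials$participant == p & is_mult & included)
    if (length(pool) < 2) {
      if (length(pool) > 0)
        warning("participant ", p, ": fewer than 2 eligible trials, ",
                "RT-SD rule skipped", call. = FALSE)
      next
    }
    m <- mean(trials$rt_s[pool]); s <- sd(trials$rt_s[pool])
    if (!is.finite(s) || s == 0) next
    out <- pool[abs(trials$rt_s[pool] - m) > rt_sd_multiplier * s]
    if (length(out)) {
      sel <- rep(FALSE, n); sel[out] <- TRUE
      flag(sel, "rt_outlier")
    }
  }

  trials$included <- included
  trials$reason <- reason
  report <- trials[!included, c("participant", "trial", "reason")]
  rownames(report) <- NULL
  list(trials = trials, report = report)
}

#' Assemble per-participant condition cells
#'
#' Pools passive-viewing trials across the two blocks into a single cell
#' and keeps multiplication trials per block, yielding the three analysis
#' conditions (multiplication without distractor, multiplication with
#' distractor, passive viewing).  Per-cell values of the binned parameters
#' are trial means of the baseline-corrected values.
#'
#' @param filtered output of [filter_trials()].
#' @param binned long-format table from [bin_parameters()].
#' @return list with `cells` (participant, condition, bin, parameter,
#'   value, n_trials) and `flagged` (participants with at least one empty
#'   condition cell, for listwise handling in the stats layer).
#' @export
assemble_conditions <- function(filtered, binned) {
  trials <- filtered$trials
  keep <- trials[trials$included, c("participant", "trial")]
  binned <- merge(binned, keep, by = c("participant", "trial"))
  if (!nrow(binned))
    return(list(cells = data.frame(participant = integer(0),
                                   condition = character(0), bin = character(0),
                                   bin_start_ms = numeric(0),
                                   parameter = character(0), value = numeric(0),
                                   n_trials = integer(0)),
                flagged = unique(trials$participant)))
  # passive trials from both blocks form one condition level already
  cells <- aggregate(corrected ~ participant + condition + bin + bin_start_ms + parameter,
                     data = binned, FUN = mean, na.rm = TRUE, na.action = NULL)
  names(cells)[names(cells) == "corrected"] <- "value"
  counts <- aggregate(trial ~ participant + condition,
                      data = unique(binned[, c("participant", "condition", "trial")]),
                      FUN = length)
  names(counts)[names(counts) == "trial"] <- "n_trials"
  cells <- merge(cells, counts, by = c("participant", "condition"))
  conds <- c("mult_no_distractor", "mult_distractor", "passive_viewing")
  flagged <- unlist(lapply(unique(trials$participant), function(p) {
    have <- unique(cells$condition[cells$participant == p])
    if (!all(conds %in% have)) p else NULL
  }))
  cells$value[is.nan(cells$value)] <- NA_real_
  list(cells = cells[order(cells$participant, cells$condition,
                           cells$bin_start_ms, cells$parameter), ],
       flagged = flagged)
}

#' Performance summary per participant and block
#'
#' For multiplication trials of each block: percentage of correct,
#' incorrect and forgotten trials (summing to 100), median response time
#' and the standard deviation of response times.
#'
#' @param trials a trial metadata table.
#' @return data frame: participant, block, pct_correct, pct_incorrect,
#'   pct_forgot, median_rt_s, sd_rt_s, n_trials.
#' @export
performance_summary <- function(trials) {
  mult <- trials[trials$condition != "passive_viewing", , drop = FALSE]
  if (!nrow(mult))
    return(data.frame(participant = integer(0), block = character(0),
                      pct_correct = numeric(0), pct_incorrect = numeric(0),
                      pct_forgot = numeric(0), median_rt_s = numeric(0),
                      sd_rt_s = numeric(0), n_trials = integer(0)))
  out <- list()
  for (p in unique(mult$participant)) for (b in unique(mult$block)) {
    g <- mult[mult$participant == p & mult$block == b, , drop = FALSE]
    if (!nrow(g)) next
    n <- nrow(g)
    out[[length(out) + 1L]] <- data.frame(
      participant = p, block = b,
      pct_correct = 100 * sum(g$correctness == "correct") / n,
      pct_incorrect = 100 * sum(g$correctness == "incorrect") / n,
      pct_forgot = 100 * sum(g$correctness == "forgot") / n,
      median_rt_s = median(g$rt_s), sd_rt_s = sd(g$rt_s),
      n_trials = n, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
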