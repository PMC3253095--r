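# TrialTable: one row per trial with 0-based inclusive volume bounds, a
# status flag driving selection, and per-trial condition events. On disk the
# table is long tab-separated text, one row per event (BIDS-events-like
# columns onset/duration/condition plus the trial bookkeeping columns).

TRIAL_STATUSES <- c("accepted", "auto_flagged", "manually_rejected")

#' Construct a trial table
#'
#' @param trial_id integer trial identifiers (unique)
#' @param run_id 0-based run label per trial
#' @param start_vol,end_vol 0-based inclusive volume bounds within the run
#' @param status one of `"accepted"`, `"auto_flagged"`, `"manually_rejected"`
#' @param events optional list (one element per trial) of data frames with
#'   columns `condition`, `onset` (s from run start), `duration` (s)
#' @return a data frame of class `trial_table` with an `events` list-column
#' @export
trial_table <- function(trial_id, run_id, start_vol, end_vol,
                        status = "accepted", events = NULL) {
  n <- length(trial_id)
  status <- rep_len(status, n)
  if (!all(status %in% TRIAL_STATUSES))
    stop("status must be one of: ", paste(TRIAL_STATUSES, collapse = ", "))
  if (anyDuplicated(trial_id)) stop("trial_id values must be unique")
  if (any(end_vol < start_vol)) stop("end_vol must be >= start_vol")
  if (any(start_vol < 0)) stop("volume indices are 0-based and non-negative")
  tab <- data.frame(trial_id = as.integer(trial_id),
                    run_id = as.integer(run_id),
                    start_vol = as.integer(start_vol),
                    end_vol = as.integer(end_vol),
                    status = as.character(status))
  if (is.null(events))
    events <- rep(list(empty_events()), n)
  tab$events <- events
  # overlap check within runs
  for (r in unique(tab$run_id)) {
    sub <- tab[tab$run_id == r, ]
    sub <- sub[order(sub$start_vol), ]
    if (nrow(sub) > 1 &&
        any(sub$start_vol[-1] <= sub$end_vol[-nrow(sub)]))
      stop("trials overlap within run ", r)
  }
  class(tab) <- c("trial_table", "data.frame")
  tab
}

empty_events <- function() {
  data.frame(condition = character(0), onset = numeric(0),
             duration = numeric(0))
}

#' Validate a trial table against a series
#'
#' Checks that every trial's volume range lies inside its run and that event
#' windows lie within the trial's time span.
#' @param trials a [trial_table]
#' @param series a [volume_series]
#' @return `trials`, invisibly; errors on violation
#' @export
validate_trials <- function(trials, series) {
  rl <- run_lengths(series)
  runs <- as.integer(names(rl))
  tr <- series$intervolume_time
  for (i in seq_len(nrow(trials))) {
    r <- trials$run_id[i]
    if (!(r %in% runs)) stop("trial ", trials$trial_id[i],
                             " references unknown run ", r)
    n <- rl[match(r, runs)]
    if (trials$end_vol[i] >= n)
      stop("trial ", trials$trial_id[i], " extends beyond run ", r,
           " (", n, " volumes)")
    ev <- trials$events[[i]]
    if (nrow(ev)) {
      t0 <- trials$start_vol[i] * tr
      t1 <- (trials$end_vol[i] + 1) * tr
      if (any(ev$onset < t0 - 1e-9) ||
          any(ev$onset + ev$duration > t1 + 1e-9))
        stop("events of trial ", trials$trial_id[i],
             " lie outside the trial's time span")
    }
  }
  invisible(trials)
}

#' Read a trial/events table from tab-separated text
#'
#' Expects columns `trial_id`, `run_id`, `start_vol`, `end_vol`, `status` and
#' optionally `condition`, `onset`, `duration` (one row per event; trials
#' without events carry empty event fields).
#'
#' @param path file path
#' @param run_lengths optional per-run volume counts for range validation
#' @return a [trial_table]
#' @export
read_trial_table <- function(path, run_lengths = NULL) {
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("trial_id", "run_id", "start_vol", "end_vol", "status")
  if (!all(need %in% names(raw)))
    stop("trial table must have columns: ", paste(need, collapse = ", "))
  ids <- unique(raw$trial_id)
  rows <- lapply(ids, function(id) raw[raw$trial_id == id, , drop = FALSE])
  events <- lapply(rows, function(rr) {
    if (!all(c("condition", "onset", "duration") %in% names(rr)))
      return(empty_events())
    ev <- rr[!is.na(rr$onset) & !is.na(rr$duration) &
               !is.na(rr$condition) & rr$condition != "",
             c("condition", "onset", "duration")]
    rownames(ev) <- NULL
    ev
  })
  first <- do.call(rbind, lapply(rows, function(rr) rr[1, need]))
  tab <- trial_table(first$trial_id, first$run_id, first$start_vol,
                     first$end_vol, first$status, events)
  if (!is.null(run_lengths)) {
    rl <- as.integer(run_lengths)
    for (i in seq_len(nrow(tab))) {
      r <- tab$run_id[i] + 1L
      if (r > length(rl) || tab$end_vol[i] >= rl[r])
        stop("trial ", tab$trial_id[i], " extends beyond its run")
    }
  }
  tab
}

#' Write a trial table as tab-separated text
#' @param trials a [trial_table]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trial_table <- function(trials, path) {
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    base <- data.frame(trial_id = trials$trial_id[i],
                       run_id = trials$run_id[i],
                       start_vol = trials$start_vol[i],
                       end_vol = trials$end_vol[i],
                       status = trials$status[i])
    ev <- trials$events[[i]]
    if (nrow(ev) == 0)
      return(cbind(base, condition = NA_character_, onset = NA_real_,
                   duration = NA_real_))
    cbind(base[rep(1, nrow(ev)), , drop = FALSE], ev)
  })
  out <- do.call(rbind, rows)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# row indices (1-based, session-global) covered by one trial
trial_rows <- function(trials, i, series) {
  rl <- run_lengths(series)
  runs <- as.integer(names(rl))
  offset <- c(0L, cumsum(rl))[match(trials$run_id[i], runs)]
  offset + (trials$start_vol[i]:trials$end_vol[i]) + 1L
}
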