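# Trial-aligned spike data. Spike times are in seconds relative to stimulus
# onset (stim_on = 0 by convention). Trials with zero spikes are first-class:
# the trial table is kept separately from the spike table so empty trials
# survive I/O round trips.

#' Construct a trial set
#'
#' @param trials data.frame with columns `trial_id`, `condition_id`.
#' @param spikes data.frame with columns `trial_id`, `condition_id`,
#'   `spike_time_s`; may have zero rows. Times are relative to stimulus
#'   onset and must lie in `[0, epoch_end]`.
#' @param conditions condition table as produced by [stimulus_schedule()]
#'   (must contain at least one blank condition).
#' @param stim_on,stim_off stimulus onset/offset, seconds (onset 0 by
#'   convention).
#' @param epoch_end end of the recorded epoch, seconds (defaults to
#'   `stim_off + 0.3` to retain latency-shifted spikes).
#' @return object of class `trial_set`.
#' @export
trial_set <- function(trials, spikes, conditions, stim_on = 0,
                      stim_off = NULL, epoch_end = NULL) {
  stopifnot(all(c("trial_id", "condition_id") %in% names(trials)),
            all(c("trial_id", "condition_id", "spike_time_s") %in%
                  names(spikes)))
  if (is.null(stim_off)) stim_off <- conditions$duration_s[1]
  if (is.null(epoch_end)) epoch_end <- stim_off + 0.3
  if (!any(conditions$direction == "blank"))
    stop_lgnsnr("condition table contains no blank condition",
                "lgnsnr_missing_baseline")
  if (nrow(spikes) > 0) {
    if (any(spikes$spike_time_s < 0 | spikes$spike_time_s > epoch_end,
            na.rm = TRUE))
      stop_lgnsnr("spike times outside recorded epoch",
                  "lgnsnr_invalid_input")
    if (!all(spikes$condition_id %in% conditions$condition_id))
      stop_lgnsnr("spike rows reference unknown condition_id",
                  "lgnsnr_invalid_input")
    o <- order(spikes$trial_id, spikes$spike_time_s)
    spikes <- spikes[o, , drop = FALSE]
    rownames(spikes) <- NULL
  }
  structure(list(trials = trials, spikes = spikes, conditions = conditions,
                 stim_on = stim_on, stim_off = stim_off,
                 epoch_end = epoch_end),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials, %d spikes, %d conditions, stimulus [%g, %g] s\n",
              nrow(x$trials), nrow(x$spikes), nrow(x$conditions),
              x$stim_on, x$stim_off))
  invisible(x)
}

#' Spike times of one trial
#' @param ts a [trial_set()].
#' @param trial_id trial identifier.
#' @return numeric vector of spike times (possibly empty), seconds.
#' @export
trial_spikes <- function(ts, trial_id) {
  st <- ts$spikes$spike_time_s[ts$spikes$trial_id == trial_id]
  sort(st[!is.na(st)])
}

#' Write / read a spike raster as tab-delimited text
#'
#' One row per spike with columns `trial_id`, `condition_id`,
#' `spike_time_s`. Trials with no spikes are written as a single row with
#' `spike_time_s = NA` so the trial roster round-trips losslessly. The
#' condition table is written alongside (same columns as a
#' [stimulus_schedule()]).
#'
#' @param ts a [trial_set()].
#' @param raster_path path of the raster file.
#' @param conditions_path path of the condition table file.
#' @export
write_raster <- function(ts, raster_path, conditions_path) {
  spk <- ts$spikes
  empty <- setdiff(ts$trials$trial_id, spk$trial_id)
  if (length(empty) > 0) {
    idx <- match(empty, ts$trials$trial_id)
    spk <- rbind(spk, data.frame(
      trial_id = empty, condition_id = ts$trials$condition_id[idx],
      spike_time_s = NA_real_))
  }
  spk <- spk[order(spk$trial_id, spk$spike_time_s), ]
  # full precision so times survive the round trip bit-for-bit
  spk$spike_time_s <- sprintf("%.17g", spk$spike_time_s)
  spk$spike_time_s[spk$spike_time_s == "nan"] <- "NA"
  write.table(spk, raster_path, sep = "\t", quote = FALSE, row.names = FALSE)
  cond <- as.data.frame(ts$conditions)
  cond$stim_off <- ts$stim_off
  cond$epoch_end <- ts$epoch_end
  write.table(cond, conditions_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(raster_path)
}

#' @rdname write_raster
#' @return `read_raster`: the reconstructed [trial_set()].
#' @export
read_raster <- function(raster_path, conditions_path) {
  spk <- read.delim(raster_path, stringsAsFactors = FALSE)
  cond <- read.delim(conditions_path, stringsAsFactors = FALSE)
  stim_off <- cond$stim_off[1]
  epoch_end <- cond$epoch_end[1]
  cond$stim_off <- NULL
  cond$epoch_end <- NULL
  class(cond) <- c("stimulus_schedule", "data.frame")
  trials <- unique(spk[, c("trial_id", "condition_id")])
  rownames(trials) <- NULL
  spikes <- spk[!is.na(spk$spike_time_s), , drop = FALSE]
  rownames(spikes) <- NULL
  trial_set(trials, spikes, cond, stim_on = 0, stim_off = stim_off,
            epoch_end = epoch_end)
}
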