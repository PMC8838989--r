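# Phase-wise blink features: blink number (BN), mean blink interval
# (Mean_BI), mean blink duration (Mean_BD), group blink number (GBN),
# mean group blink interval (Mean_GBI), incomplete blink number (IBN)
# and mean incomplete blink interval (Mean_IBI). All intervals are
# start-to-start and computed within a phase.

#' Assign blink events to session phases
#'
#' Phase `k` (1-based) covers the half-open frame window
#' `[(k-1) * L, k * L)` with `L = phase_duration * frame_rate`. An event
#' belongs to the phase containing its start frame, so an event whose
#' frames spill over a boundary stays in its start phase. Events
#' starting at or beyond the end of the last phase are dropped with a
#' warning.
#'
#' @param events A [blink_events()] table, sorted.
#' @param config A [session_config()].
#' @return Named list of `n_phases` event tables (`phase1`, `phase2`,
#'   ...); an attribute `dropped` counts discarded events.
#' @export
partition_phases <- function(events, config = session_config()) {
  L <- config$phase_duration * config$frame_rate
  phase <- floor(events$start_frame / L) + 1L
  over <- phase > config$n_phases
  if (any(over)) {
    warning(sum(over), " event(s) start beyond the last phase; dropped",
            call. = FALSE)
    events <- events[!over, , drop = FALSE]
    phase <- phase[!over]
  }
  out <- lapply(seq_len(config$n_phases), function(k) {
    ev <- events[phase == k, , drop = FALSE]
    class(ev) <- c("blink_events", "data.frame")
    ev
  })
  names(out) <- paste0("phase", seq_len(config$n_phases))
  attr(out, "dropped") <- sum(over)
  out
}

#' Find blink groups (bursts)
#'
#' A group is a maximal run of two or more consecutive blinks whose
#' successive start-to-start intervals are all strictly below
#' `group_window` seconds.
#'
#' @param events A sorted [blink_events()] table.
#' @param group_window Interval bound in seconds (default 1).
#' @param frame_rate Frames per second.
#' @return Data frame with one row per group: `group_id`, `first_event`
#'   (row index of the first member), `n_members`, `start_frame` (first
#'   member's start frame).
#' @export
find_groups <- function(events, group_window = 1.0, frame_rate = 60) {
  n <- nrow(events)
  empty <- data.frame(group_id = integer(0), first_event = integer(0),
                      n_members = integer(0), start_frame = integer(0))
  if (n < 2L) return(empty)
  close_gap <- diff(events$start_frame) / frame_rate < group_window
  r <- rle(close_gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(empty)
  first <- starts[keep]
  members <- r$lengths[keep] + 1L   # k close gaps join k + 1 blinks
  data.frame(group_id = seq_along(first),
             first_event = first,
             n_members = members,
             start_frame = events$start_frame[first])
}

.mean_or_na <- function(x) if (length(x) >= 1L) mean(x) else NA_real_

#' Blink features of one phase
#'
#' Computes the seven features from one phase's classified events:
#' * `BN` — blink count (complete + incomplete);
#' * `Mean_BI` — mean start-to-start interval between adjacent blinks (s);
#' * `Mean_BD` — mean blink duration, `sum(n_i) / (fr * BN)` (s);
#' * `GBN` — number of blink groups (bursts with successive intervals
#'   under `group_window`); set `group_count = "members"` to count the
#'   blinks inside groups instead;
#' * `Mean_GBI` — mean start-to-start interval between adjacent groups (s);
#' * `IBN` — incomplete blink count;
#' * `Mean_IBI` — mean start-to-start interval between adjacent
#'   incomplete blinks (s).
#'
#' Any mean over fewer than one interval is `NA`. Open-ended events
#' (truncated by the trace boundary) are kept by default; set
#' `include_open_ended = FALSE` to drop them first.
#'
#' @param events One phase's [blink_events()] table.
#' @param frame_rate Frames per second.
#' @param group_window Group interval bound in seconds (default 1).
#' @param group_count `"bursts"` (default: GBN counts groups) or
#'   `"members"` (GBN counts blinks belonging to groups).
#' @param include_open_ended Keep boundary-truncated events
#'   (default TRUE).
#' @return One-row data frame with columns `BN`, `Mean_BI`, `Mean_BD`,
#'   `GBN`, `Mean_GBI`, `IBN`, `Mean_IBI`.
#' @export
#' @examples
#' ev <- blink_events(c(0L, 120L), c(6L, 9L))
#' blink_features(ev, frame_rate = 60)$Mean_BD  # (6+9)/(60*2) = 0.125
blink_features <- function(events, frame_rate = 60, group_window = 1.0,
                           group_count = c("bursts", "members"),
                           include_open_ended = TRUE) {
  group_count <- match.arg(group_count)
  if (!include_open_ended)
    events <- events[!events$open_ended, , drop = FALSE]
  bn <- nrow(events)
  if (bn == 0L)
    return(data.frame(BN = 0L, Mean_BI = NA_real_, Mean_BD = NA_real_,
                      GBN = 0L, Mean_GBI = NA_real_, IBN = 0L,
                      Mean_IBI = NA_real_))
  mean_bi <- .mean_or_na(diff(events$start_frame) / frame_rate)
  mean_bd <- sum(events$n_frames) / (frame_rate * bn)
  groups <- find_groups(events, group_window, frame_rate)
  gbn <- if (group_count == "bursts") nrow(groups) else sum(groups$n_members)
  mean_gbi <- .mean_or_na(diff(groups$start_frame) / frame_rate)
  inc <- events$start_frame[events$completeness == "incomplete"]
  data.frame(BN = bn, Mean_BI = mean_bi, Mean_BD = mean_bd,
             GBN = as.integer(gbn), Mean_GBI = mean_gbi,
             IBN = length(inc),
             Mean_IBI = .mean_or_na(diff(inc) / frame_rate))
}

#' Per-phase feature table of a session
#'
#' Partitions a session's events into phases and computes the seven
#' blink features for each phase.
#'
#' @param events The session's [blink_events()] table.
#' @param config A [session_config()].
#' @inheritParams blink_features
#' @return Data frame with one row per phase, a `phase` column and the
#'   seven feature columns.
#' @export
session_features <- function(events, config = session_config(),
                             group_window = 1.0,
                             group_count = "bursts",
                             include_open_ended = TRUE) {
  phases <- partition_phases(events, config)
  rows <- lapply(seq_along(phases), function(k) {
    cbind(phase = k,
          blink_features(phases[[k]], config$frame_rate, group_window,
                         group_count, include_open_ended))
  })
  do.call(rbind, rows)
}
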