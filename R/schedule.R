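TREATMENT_EVENTS <- c("MA1", "MA2", "VA1", "VA2", "VA3", "VA4")

#' Construct an event schedule
#'
#' An ordered table of named events within a session day. Treatment events
#' (MA1, MA2, VA1..VA4) may each appear at most once across the schedule;
#' `fixation` and `rest` blocks may repeat. Events within a day must be
#' non-overlapping and ordered by onset.
#'
#' @param events Data frame with columns `name`, `day` (1 or 2), `onset`
#'   (seconds), `duration` (seconds).
#' @return An object of class `event_schedule` (a validated data frame).
#' @export
event_schedule <- function(events) {
  events <- as.data.frame(events, stringsAsFactors = FALSE)
  req <- c("name", "day", "onset", "duration")
  if (!all(req %in% names(events)))
    stop("`events` must have columns name, day, onset, duration")
  events <- events[req]
  events$name <- as.character(events$name)
  ok_names <- c(TREATMENT_EVENTS, "fixation", "rest")
  bad <- setdiff(unique(events$name), ok_names)
  if (length(bad))
    stop("unknown event name(s): ", paste(bad, collapse = ", "))
  if (!all(events$day %in% c(1, 2)))
    stop("`day` must be 1 or 2")
  if (any(events$duration <= 0) || any(events$onset < 0))
    stop("onsets must be >= 0 and durations > 0")
  trt <- events$name[events$name %in% TREATMENT_EVENTS]
  if (anyDuplicated(trt))
    stop("treatment events may appear at most once: ",
         paste(unique(trt[duplicated(trt)]), collapse = ", "))
  for (d in unique(events$day)) {
    e <- events[events$day == d, ]
    e <- e[order(e$onset), ]
    if (nrow(e) > 1 && any(e$onset[-1] < (e$onset + e$duration)[-nrow(e)] - 1e-9))
      stop("events overlap on day ", d)
  }
  events <- events[order(events$day, events$onset), ]
  rownames(events) <- NULL
  class(events) <- c("event_schedule", "data.frame")
  events
}

#' Default session schedule for one study day
#'
#' Day 1 opens with a 6-minute fixation block (1 min closed-eye plus 5 min
#' open-eye rest), followed by two 5-minute manual acupuncture events (MA1,
#' MA2) alternating with 5-minute open-eye rests, then two 5-minute virtual
#' acupuncture events (VA1, VA2) alternating with rests. Day 2 repeats the
#' fixation block and runs VA3 and VA4 with rests. Onsets are contiguous
#' recording time: the between-phase intermission on day 1 is not recorded,
#' so day 1 spans 2760 s and day 2 spans 1560 s (together 4320 s = 72 min of
#' EEG per participant).
#'
#' @param day Which study day, 1 or 2.
#' @param treatment_seconds Duration of each treatment event (default 300).
#' @param rest_seconds Duration of each rest block (default 300).
#' @param fixation_seconds Duration of the opening fixation block
#'   (default 360).
#' @return An `event_schedule`.
#' @export
default_schedule <- function(day, treatment_seconds = 300,
                             rest_seconds = 300, fixation_seconds = 360) {
  if (!length(day) == 1L || !day %in% c(1, 2))
    stop("`day` must be 1 or 2")
  seq_names <- if (day == 1) {
    c("fixation", "MA1", "rest", "MA2", "rest", "VA1", "rest", "VA2", "rest")
  } else {
    c("fixation", "VA3", "rest", "VA4", "rest")
  }
  durs <- ifelse(seq_names == "fixation", fixation_seconds,
                 ifelse(seq_names == "rest", rest_seconds, treatment_seconds))
  onsets <- cumsum(c(0, durs[-length(durs)]))
  event_schedule(data.frame(name = seq_names, day = day,
                            onset = onsets, duration = durs,
                            stringsAsFactors = FALSE))
}

#' Total scheduled duration in seconds
#' @param schedule An `event_schedule`.
#' @return Span in seconds from 0 to the end of the last event.
#' @export
schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "event_schedule"))
  max(schedule$onset + schedule$duration)
}
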