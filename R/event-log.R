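#' Behavioral event log for one session
#'
#' Validated container for one session's behavioral timestamps and metadata:
#' lever-press, lick and reward times plus snout-in-ROI occupancy intervals,
#' all in seconds from session start.
#'
#' @param session_id,mouse_id identifiers.
#' @param day_index integer day of imaging/testing.
#' @param lever_side `"left"` or `"right"`.
#' @param hemisphere imaged or lesioned hemisphere: `"left"`, `"right"` or
#'   `"none"`.
#' @param epoch `"before"`, `"after"` or `"none"` (lesion designs).
#' @param treatment `"6OHDA"`, `"saline"` or `"none"`.
#' @param press_times strictly increasing press timestamps (s).
#' @param lick_times,reward_times event timestamps (s).
#' @param occupancy two-column matrix or data frame of disjoint, sorted
#'   (start, end) snout-ROI occupancy intervals (s).
#' @param press_velocity optional per-press velocity (arbitrary units).
#' @param session_duration session length (s).
#' @return An object of class `event_log`.
#' @export
event_log <- function(session_id, mouse_id = "m1", day_index = 1L,
                      lever_side = c("left", "right"),
                      hemisphere = c("none", "left", "right"),
                      epoch = c("none", "before", "after"),
                      treatment = c("none", "6OHDA", "saline"),
                      press_times = numeric(), lick_times = numeric(),
                      reward_times = numeric(),
                      occupancy = matrix(numeric(), ncol = 2),
                      press_velocity = NULL, session_duration) {
  lever_side <- match.arg(lever_side)
  hemisphere <- match.arg(hemisphere)
  epoch <- match.arg(epoch)
  treatment <- match.arg(treatment)
  occ <- as.matrix(occupancy)
  if (ncol(occ) != 2 && length(occ) > 0) stop("occupancy must have 2 columns")
  if (length(press_times) > 1 && any(diff(press_times) <= 0))
    stop("press times must be strictly increasing")
  allt <- c(press_times, lick_times, reward_times, as.vector(occ))
  if (length(allt) && (min(allt) < 0 || max(allt) > session_duration))
    stop("timestamps outside [0, session_duration]")
  if (nrow(occ) > 0) {
    if (any(occ[, 2] <= occ[, 1])) stop("occupancy intervals need start < end")
    if (nrow(occ) > 1) {
      o <- order(occ[, 1])
      occ <- occ[o, , drop = FALSE]
      if (any(occ[-1, 1] < occ[-nrow(occ), 2]))
        stop("occupancy intervals overlap")
    }
  }
  if (!is.null(press_velocity) && length(press_velocity) != length(press_times))
    stop("press_velocity must match press_times")
  structure(list(session_id = session_id, mouse_id = mouse_id,
                 day_index = as.integer(day_index), lever_side = lever_side,
                 hemisphere = hemisphere, epoch = epoch, treatment = treatment,
                 press_times = as.numeric(press_times),
                 lick_times = as.numeric(lick_times),
                 reward_times = as.numeric(reward_times),
                 occupancy = occ, press_velocity = press_velocity,
                 session_duration = as.numeric(session_duration)),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("event_log %s (mouse %s, day %d, lever %s, hemi %s): %d presses, %d rewards, %d occupancy intervals, %.0f s\n",
              x$session_id, x$mouse_id, x$day_index, x$lever_side, x$hemisphere,
              length(x$press_times), length(x$reward_times), nrow(x$occupancy),
              x$session_duration))
  invisible(x)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  l1 <- readLines(path, n = 1L)
  sep <- if (grepl("\t", l1)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
}

#' Read behavioral event logs from delimited text
#'
#' Reads a long-format events file (columns `session_id`, `time`,
#' `event_type` with types `press`, `lick`, `reward`, `roi_enter`,
#' `roi_exit`) and a sessions manifest (columns `session_id`, `mouse_id`,
#' `day_index`, `lever_side`, `hemisphere`, `epoch`, `treatment`,
#' `session_duration`), and assembles one validated [event_log] per session.
#' ROI enter/exit events are paired in order into occupancy intervals; an
#' unmatched final `roi_enter` is closed at session end.
#'
#' @param events_path path to the events file (TSV or CSV).
#' @param manifest_path path to the sessions manifest.
#' @return A named list of [event_log] objects (one per manifest row).
#' @export
read_event_log <- function(events_path, manifest_path) {
  ev <- read_delim_auto(events_path)
  man <- read_delim_auto(manifest_path)
  need_ev <- c("session_id", "time", "event_type")
  need_man <- c("session_id", "mouse_id", "day_index", "lever_side",
                "hemisphere", "epoch", "treatment", "session_duration")
  if (!all(need_ev %in% names(ev)))
    stop("events file missing columns: ", paste(setdiff(need_ev, names(ev)), collapse = ", "))
  if (!all(need_man %in% names(man)))
    stop("manifest missing columns: ", paste(setdiff(need_man, names(man)), collapse = ", "))
  logs <- lapply(seq_len(nrow(man)), function(i) {
    mi <- man[i, ]
    e <- ev[ev$session_id == mi$session_id, , drop = FALSE]
    e <- e[order(e$time), , drop = FALSE]
    ent <- e$time[e$event_type == "roi_enter"]
    ext <- e$time[e$event_type == "roi_exit"]
    if (length(ent) == length(ext) + 1L) ext <- c(ext, mi$session_duration)
    if (length(ent) != length(ext))
      stop("session ", mi$session_id, ": unpaired roi_enter/roi_exit events")
    occ <- cbind(ent, ext)
    event_log(session_id = mi$session_id, mouse_id = mi$mouse_id,
              day_index = mi$day_index, lever_side = mi$lever_side,
              hemisphere = mi$hemisphere, epoch = mi$epoch,
              treatment = mi$treatment,
              press_times = e$time[e$event_type == "press"],
              lick_times = e$time[e$event_type == "lick"],
              reward_times = e$time[e$event_type == "reward"],
              occupancy = occ,
              press_velocity = if ("velocity" %in% names(e)) {
                v <- e$velocity[e$event_type == "press"]
                if (all(is.na(v))) NULL else v
              } else NULL,
              session_duration = mi$session_duration)
  })
  names(logs) <- man$session_id
  logs
}

#' Write an event log back to long-format delimited text
#'
#' Inverse of [read_event_log()] for a list of logs; used by the simulator
#' so synthetic sessions round-trip through the same on-disk format.
#'
#' @param logs list of [event_log] objects.
#' @param events_path,manifest_path output paths (TSV).
#' @return Invisibly, the two paths.
#' @export
write_event_logs <- function(logs, events_path, manifest_path) {
  rows <- lapply(logs, function(l) {
    data.frame(
      session_id = l$session_id,
      time = c(l$press_times, l$lick_times, l$reward_times,
               l$occupancy[, 1], l$occupancy[, 2]),
      event_type = c(rep("press", length(l$press_times)),
                     rep("lick", length(l$lick_times)),
                     rep("reward", length(l$reward_times)),
                     rep("roi_enter", nrow(l$occupancy)),
                     rep("roi_exit", nrow(l$occupancy))),
      stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$session_id, ev$time), ]
  man <- do.call(rbind, lapply(logs, function(l) {
    data.frame(session_id = l$session_id, mouse_id = l$mouse_id,
               day_index = l$day_index, lever_side = l$lever_side,
               hemisphere = l$hemisphere, epoch = l$epoch,
               treatment = l$treatment, session_duration = l$session_duration,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(ev, events_path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(man, manifest_path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(events_path, manifest_path))
}
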