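#' One imaging session: traces, behavior, trial structure, metadata
#'
#' Bundles the per-session arrays the pipeline consumes: the neurons x frames
#' \eqn{\Delta F/F} matrix, frame-wise corridor position and running velocity,
#' lick and reward event frames, trial boundaries, and session metadata.
#' Frames are 1-based inside R; trial bounds are half-open `[start, end)` so a
#' trial covers frames `start:(end - 1)`. Frames outside every trial (screen
#' blackout between corridor resets) are excluded from all analyses.
#'
#' @param dff Numeric matrix, neurons x frames, no missing values.
#' @param position_cm Numeric vector, corridor position per frame.
#' @param velocity_cm_s Numeric vector, running velocity per frame.
#' @param lick_frames Sorted integer vector of frames with a lick.
#' @param reward_frames Sorted integer vector of reward-delivery frames.
#' @param trial_bounds Integer matrix, trials x 2, half-open `[start, end)`.
#' @param day Integer day relative to injection (<= 0 is pre-injection).
#' @param mouse_id Character scalar.
#' @param frame_rate_hz Sampling rate in Hz.
#'
#' @return A validated object of class `session_data`.
#' @export
session_data <- function(dff, position_cm, velocity_cm_s,
                         lick_frames = integer(), reward_frames = integer(),
                         trial_bounds, day = 0L, mouse_id = "m0",
                         frame_rate_hz = 30) {
  s <- structure(list(
    dff = as.matrix(dff),
    position_cm = as.numeric(position_cm),
    velocity_cm_s = as.numeric(velocity_cm_s),
    lick_frames = as.integer(sort(unique(lick_frames))),
    reward_frames = as.integer(sort(unique(reward_frames))),
    trial_bounds = matrix(as.integer(trial_bounds), ncol = 2,
                          dimnames = list(NULL, c("start", "end"))),
    day = as.integer(day), mouse_id = as.character(mouse_id),
    frame_rate_hz = frame_rate_hz
  ), class = "session_data")
  validate_session(s)
}

#' Validate a session container
#'
#' Checks every structural invariant: matching array lengths, in-range event
#' frames, disjoint ordered trials, monotone non-decreasing position within
#' trials, and the absence of missing values in `dff`.
#'
#' @param session A `session_data` object (or a bare list with its fields).
#' @return The validated session, invisibly classed as `session_data`.
#' @export
validate_session <- function(session) {
  s <- session
  n_frames <- ncol(s$dff)
  fail <- function(field, msg) {
    stop(sprintf("invalid session_data [%s]: %s", field, msg), call. = FALSE)
  }
  if (anyNA(s$dff) || any(!is.finite(s$dff))) {
    fail("dff", "contains missing or non-finite values")
  }
  if (length(s$position_cm) != n_frames) {
    fail("position_cm", "length differs from number of frames")
  }
  if (length(s$velocity_cm_s) != n_frames) {
    fail("velocity_cm_s", "length differs from number of frames")
  }
  for (f in c("lick_frames", "reward_frames")) {
    v <- s[[f]]
    if (length(v) && (min(v) < 1L || max(v) > n_frames)) {
      fail(f, "frame index outside the recording")
    }
  }
  tb <- s$trial_bounds
  if (nrow(tb) < 1) fail("trial_bounds", "at least one trial required")
  if (any(tb[, 2] <= tb[, 1])) fail("trial_bounds", "empty or inverted trial")
  if (min(tb) < 1L || max(tb) > n_frames + 1L) {
    fail("trial_bounds", "trial bounds outside the recording")
  }
  if (nrow(tb) > 1 && any(tb[-1, 1] < tb[-nrow(tb), 2])) {
    fail("trial_bounds", "trials overlap or are out of order")
  }
  for (t in seq_len(nrow(tb))) {
    pos <- s$position_cm[tb[t, 1]:(tb[t, 2] - 1L)]
    if (any(diff(pos) < -1e-6)) {
      fail("position_cm", sprintf("position decreases within trial %d", t))
    }
  }
  invisible(structure(s, class = "session_data"))
}

#' @export
print.session_data <- function(x, ...) {
  cat("<session_data> mouse ", x$mouse_id, ", day ", x$day, " (",
      session_phase(x$day), "): ", nrow(x$dff), " neurons x ", ncol(x$dff),
      " frames, ", nrow(x$trial_bounds), " trials, ",
      length(x$lick_frames), " licks\n", sep = "")
  invisible(x)
}

#' Frames belonging to any trial
#' @param session A `session_data`.
#' @return Integer frame indices covered by trials, in order; the companion
#'   trial id per frame is in attribute `"trial"`.
#' @export
trial_frames <- function(session) {
  tb <- session$trial_bounds
  idx <- unlist(lapply(seq_len(nrow(tb)),
                       function(t) tb[t, 1]:(tb[t, 2] - 1L)))
  trial <- rep(seq_len(nrow(tb)), times = tb[, 2] - tb[, 1])
  structure(as.integer(idx), trial = as.integer(trial))
}

# ---- HDF5 persistence --------------------------------------------------
# On-disk layout (language neutral, 0-based frame indices, half-open trials):
#   /dff (neurons x frames), /behavior/{position_cm, velocity_cm_s},
#   /events/{lick_frames, reward_frames}, /trials (n x 2),
#   attrs on /: mouse_id, day, frame_rate_hz

#' Write a session to an HDF5 file
#'
#' Stores the documented layout with 0-based frame indices on disk; the R
#' representation stays 1-based. Overwrites `path` if it exists.
#'
#' @param session A `session_data`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  h5 <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(h5), add = TRUE)
  rhdf5::h5writeDataset(session$dff, h5, "dff")
  rhdf5::h5createGroup(h5, "behavior")
  rhdf5::h5writeDataset(session$position_cm, h5, "behavior/position_cm")
  rhdf5::h5writeDataset(session$velocity_cm_s, h5, "behavior/velocity_cm_s")
  rhdf5::h5createGroup(h5, "events")
  rhdf5::h5writeDataset(session$lick_frames - 1L, h5, "events/lick_frames")
  rhdf5::h5writeDataset(session$reward_frames - 1L, h5, "events/reward_frames")
  rhdf5::h5writeDataset(session$trial_bounds - 1L, h5, "trials")
  rhdf5::h5writeAttribute(session$mouse_id, h5, "mouse_id")
  rhdf5::h5writeAttribute(session$day, h5, "day")
  rhdf5::h5writeAttribute(session$frame_rate_hz, h5, "frame_rate_hz")
  invisible(path)
}

#' Read a session from an HDF5 file
#'
#' Counterpart of [write_session()]. A dataset missing from the documented
#' layout raises a schema error naming it; the loaded session is fully
#' validated before it is returned.
#'
#' @param path File written by [write_session()] (or following its layout).
#' @return A `session_data`.
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ls <- rhdf5::h5ls(path)
  have <- file.path(ls$group, ls$name)
  have <- sub("^//*", "/", have)
  need <- c("/dff", "/behavior/position_cm", "/behavior/velocity_cm_s",
            "/events/lick_frames", "/events/reward_frames", "/trials")
  missing <- setdiff(need, have)
  if (length(missing)) {
    stop("session file schema error: missing dataset(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  att <- rhdf5::h5readAttributes(path, "/")
  s <- structure(list(
    dff = as.matrix(rhdf5::h5read(path, "dff")),
    position_cm = as.numeric(rhdf5::h5read(path, "behavior/position_cm")),
    velocity_cm_s = as.numeric(rhdf5::h5read(path, "behavior/velocity_cm_s")),
    lick_frames = as.integer(rhdf5::h5read(path, "events/lick_frames")) + 1L,
    reward_frames = as.integer(rhdf5::h5read(path, "events/reward_frames")) + 1L,
    trial_bounds = matrix(as.integer(rhdf5::h5read(path, "trials")), ncol = 2,
                          dimnames = list(NULL, c("start", "end"))) + 1L,
    day = as.integer(att$day %||% 0L),
    mouse_id = as.character(att$mouse_id %||% "unknown"),
    frame_rate_hz = as.numeric(att$frame_rate_hz %||% 30)
  ), class = "session_data")
  validate_session(s)
}

#' Write result tables plus a run manifest
#'
#' Writes each table as `<name>.csv` under `dir` and a `manifest.json`
#' recording the configuration, seed, package version and table checksums,
#' so a rerun with the same config and seed is byte-identical.
#'
#' @param tables Named list of data frames (may be empty).
#' @param dir Output directory, created if needed.
#' @param config Optional configuration list stored in the manifest.
#' @param seed Optional seed stored in the manifest.
#' @return Invisibly, the manifest path.
#' @export
save_results <- function(tables, dir, config = NULL, seed = NULL) {
  stopifnot(is.list(tables))
  if (length(tables) && is.null(names(tables))) {
    stop("`tables` must be named", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory ", dir, call. = FALSE)
  for (nm in names(tables)) {
    write.csv(tables[[nm]], file.path(dir, paste0(nm, ".csv")),
              row.names = FALSE)
  }
  manifest <- list(
    package = "placecode",
    version = as.character(utils::packageVersion("placecode")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed, config = config, tables = as.list(names(tables)) %||% list()
  )
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(mp)
}
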