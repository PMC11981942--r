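# Session containers and trace alignment. A session bundle is the unit of
# training and evaluation: stimulus frames and timestamps, behaviour traces,
# a neurons x time response matrix, a trial table carrying the
# train/test/battery structure, and (for simulated sessions) the embedded
# ground truth. On disk a bundle is a versioned directory: a JSON manifest,
# CSV tables and flat little-endian binary arrays.

SESSION_SCHEMA_VERSION <- 1L

#' Construct a session bundle
#'
#' Validates alignment (equal time lengths across stimulus, behaviour and
#' responses) and the trial table, and returns a `session_bundle`.
#'
#' @param stimulus List with `frames` (`T x H x W` integer array, 0-255).
#' @param behavior List with length-T numeric `treadmill`, `pupil`,
#'   `pupil_d` and a `T x 2` `pupil_xy` matrix.
#' @param responses `T x N` nonnegative response matrix.
#' @param trials Data frame with columns `trial`, `kind`, `clip_id`, `split`,
#'   `onset_frame`, `offset_frame`.
#' @param fps Common sampling rate (Hz) of all time axes.
#' @param monitor A [monitor_geometry()].
#' @param ground_truth Optional list with `neurons` (data frame) and `rate`
#'   (`T x N` noiseless rate matrix).
#' @return A `session_bundle`.
#' @export
session_bundle <- function(stimulus, behavior, responses, trials, fps = 30,
                           monitor = monitor_geometry(), ground_truth = NULL) {
  T <- dim(stimulus$frames)[1]
  for (nm in c("treadmill", "pupil", "pupil_d")) {
    if (length(behavior[[nm]]) != T) {
      stop(sprintf("alignment error: behavior$%s has length %d, stimulus has %d frames",
                   nm, length(behavior[[nm]]), T), call. = FALSE)
    }
  }
  if (nrow(behavior$pupil_xy) != T) stop("alignment error: pupil_xy", call. = FALSE)
  if (nrow(responses) != T) {
    stop(sprintf("alignment error: responses have %d rows, stimulus has %d frames",
                 nrow(responses), T), call. = FALSE)
  }
  need <- c("trial", "kind", "clip_id", "split", "onset_frame", "offset_frame")
  if (!all(need %in% names(trials))) {
    stop("trial table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  structure(list(schema_version = SESSION_SCHEMA_VERSION, fps = fps,
                 monitor = monitor, stimulus = stimulus, behavior = behavior,
                 responses = responses, trials = trials,
                 ground_truth = ground_truth),
            class = "session_bundle")
}

#' @export
print.session_bundle <- function(x, ...) {
  d <- dim(x$stimulus$frames)
  cat(sprintf("<session_bundle v%d: %d frames @ %g fps (%.1f min), %d x %d px, %d neurons, %d trials%s>\n",
              x$schema_version, d[1], x$fps, d[1] / x$fps / 60, d[2], d[3],
              ncol(x$responses), nrow(x$trials),
              if (is.null(x$ground_truth)) "" else ", ground truth embedded"))
  invisible(x)
}

write_bin_array <- function(x, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(dim(x)), con, size = 4L, endian = "little")
  writeBin(as.vector(as.numeric(x)), con, size = 8L, endian = "little")
}

read_bin_array <- function(path, ndim) {
  con <- file(path, "rb")
  on.exit(close(con))
  d <- readBin(con, "integer", ndim, size = 4L, endian = "little")
  v <- readBin(con, "numeric", prod(d), size = 8L, endian = "little")
  array(v, d)
}

#' Write a session bundle to a directory container
#'
#' Layout: `manifest.json` (schema version, fps, monitor pose, array dims),
#' `stimulus_frames.u8` (raw bytes), `behavior.f64`, `responses.f64`,
#' `trials.csv`, and optionally `ground_truth_neurons.csv` +
#' `ground_truth_rate.f64`.
#'
#' @param session A `session_bundle`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session_bundle"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(session$stimulus$frames)
  mon <- session$monitor
  manifest <- list(
    schema_version = session$schema_version, fps = session$fps,
    frames_dim = d, n_neurons = ncol(session$responses),
    monitor = list(m0 = mon$m0, angles = mon$angles, width_cm = mon$width_cm,
                   height_cm = mon$height_cm, width_px = mon$width_px,
                   height_px = mon$height_px),
    has_ground_truth = !is.null(session$ground_truth))
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "stimulus_frames.u8"), "wb")
  writeBin(as.raw(as.vector(session$stimulus$frames)), con)
  close(con)
  beh <- cbind(session$behavior$treadmill, session$behavior$pupil,
               session$behavior$pupil_d, session$behavior$pupil_xy)
  write_bin_array(beh, file.path(path, "behavior.f64"))
  write_bin_array(session$responses, file.path(path, "responses.f64"))
  utils::write.csv(session$trials, file.path(path, "trials.csv"), row.names = FALSE)
  if (!is.null(session$ground_truth)) {
    utils::write.csv(session$ground_truth$neurons,
                     file.path(path, "ground_truth_neurons.csv"), row.names = FALSE)
    if (!is.null(session$ground_truth$rate)) {
      write_bin_array(session$ground_truth$rate, file.path(path, "ground_truth_rate.f64"))
    }
  }
  invisible(path)
}

#' Read a session bundle from a directory container
#'
#' Fails with an explicit error if a required dataset is missing or the
#' schema version is not supported; never silently reinterprets.
#'
#' @param path Directory written by [write_session()].
#' @return A `session_bundle`.
#' @export
read_session <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("schema error: missing dataset 'manifest.json'", call. = FALSE)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(as.integer(manifest$schema_version), SESSION_SCHEMA_VERSION)) {
    stop(sprintf("unsupported session schema version %s (reader supports %d)",
                 manifest$schema_version, SESSION_SCHEMA_VERSION), call. = FALSE)
  }
  for (f in c("stimulus_frames.u8", "behavior.f64", "responses.f64", "trials.csv")) {
    if (!file.exists(file.path(path, f))) {
      stop(sprintf("schema error: missing dataset '%s'", f), call. = FALSE)
    }
  }
  d <- as.integer(manifest$frames_dim)
  con <- file(file.path(path, "stimulus_frames.u8"), "rb")
  frames <- array(as.integer(readBin(con, "raw", prod(d))), d)
  close(con)
  beh <- read_bin_array(file.path(path, "behavior.f64"), 2L)
  responses <- read_bin_array(file.path(path, "responses.f64"), 2L)
  trials <- utils::read.csv(file.path(path, "trials.csv"), stringsAsFactors = FALSE)
  mn <- manifest$monitor
  mon <- monitor_geometry(width_cm = mn$width_cm, height_cm = mn$height_cm,
                          width_px = mn$width_px, height_px = mn$height_px,
                          angles = as.numeric(mn$angles), m0 = as.numeric(mn$m0))
  gt <- NULL
  if (isTRUE(manifest$has_ground_truth)) {
    gt <- list(neurons = utils::read.csv(file.path(path, "ground_truth_neurons.csv"),
                                         stringsAsFactors = FALSE))
    rf <- file.path(path, "ground_truth_rate.f64")
    if (file.exists(rf)) gt$rate <- read_bin_array(rf, 2L)
  }
  session_bundle(
    stimulus = list(frames = frames),
    behavior = list(treadmill = beh[, 1], pupil = beh[, 2], pupil_d = beh[, 3],
                    pupil_xy = beh[, 4:5, drop = FALSE]),
    responses = responses, trials = trials, fps = manifest$fps,
    monitor = mon, ground_truth = gt)
}

#' Resample a trace onto a uniform grid by linear interpolation
#'
#' Interpolates linearly between samples; the destination grid starts at the
#' first source time and steps at `1/dst_rate`. No extrapolation: values
#' beyond the source endpoints hold the edge value.
#'
#' @param trace Numeric values at `src_times`.
#' @param src_times Strictly increasing sample times (s).
#' @param dst_rate Destination rate (Hz), e.g. 30 or the hardware 29.967.
#' @return List with `times` and `values`.
#' @export
resample_traces <- function(trace, src_times, dst_rate) {
  if (any(diff(src_times) <= 0)) {
    stop("src_times must be strictly increasing", call. = FALSE)
  }
  stopifnot(length(trace) == length(src_times), dst_rate > 0)
  times <- seq(src_times[1], src_times[length(src_times)], by = 1 / dst_rate)
  values <- stats::approx(src_times, trace, xout = times, rule = 2)$y
  list(times = times, values = values)
}

#' Frame ranges of trials belonging to a split
#' @param session A `session_bundle`.
#' @param split One of the values in `trials$split`.
#' @return Integer vector of frame indices.
#' @export
split_frames <- function(session, split) {
  tr <- session$trials[session$trials$split == split, , drop = FALSE]
  unlist(lapply(seq_len(nrow(tr)), function(i) tr$onset_frame[i]:tr$offset_frame[i]))
}

#' Collect repeat matrices for the repeated test clips
#'
#' @param session A `session_bundle` whose test trials share `clip_id`s.
#' @return List: `clip_ids`, `pred_frames` (frame indices of the first repeat
#'   of each clip, concatenated), and `trials_list` (per neuron, the
#'   `repeats x T_test` observed matrix over concatenated clips).
#' @export
test_repeats <- function(session) {
  tr <- session$trials[session$trials$split == "test", , drop = FALSE]
  clip_ids <- unique(tr$clip_id)
  reps <- min(table(tr$clip_id))
  first_frames <- integer(0)
  frames_by_rep <- vector("list", reps)
  for (r in seq_len(reps)) frames_by_rep[[r]] <- integer(0)
  for (cid in clip_ids) {
    rows <- which(tr$clip_id == cid)[seq_len(reps)]
    for (r in seq_len(reps)) {
      fr <- tr$onset_frame[rows[r]]:tr$offset_frame[rows[r]]
      frames_by_rep[[r]] <- c(frames_by_rep[[r]], fr)
    }
    first_frames <- c(first_frames, tr$onset_frame[rows[1]]:tr$offset_frame[rows[1]])
  }
  N <- ncol(session$responses)
  trials_list <- lapply(seq_len(N), function(n) {
    do.call(rbind, lapply(frames_by_rep, function(fr) session$responses[fr, n]))
  })
  list(clip_ids = clip_ids, pred_frames = first_frames,
       frames_by_rep = frames_by_rep, trials_list = trials_list, repeats = reps)
}
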