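#' Read and write 2D keypoint tracks in the DeepLabCut CSV dialect
#'
#' The dialect is the de-facto export convention of markerless tracking
#' software: a three-row header — `scorer`, `bodyparts`, `coords` — over an
#' index column plus an `(x, y, likelihood)` column triplet per landmark,
#' one data row per frame. The frame rate is not part of the format and is
#' supplied by the caller on read. Unknown extra landmarks are preserved in
#' the track but ignored by the kinematics layer. Numbers are written with
#' six decimals, making write-then-read stable at that precision.
#'
#' @param path File path.
#' @param frame_rate Acquisition rate in Hz to attach on read.
#' @param track A [keypoint_track()] to write.
#' @param scorer Scorer name written into the header row.
#' @return `read_dlc_csv()` returns a [keypoint_track()];
#'   `write_dlc_csv()` returns `path` invisibly.
#' @export
read_dlc_csv <- function(path, frame_rate = 15) {
  if (!file.exists(path)) {
    stop_reach(sprintf("file not found: %s", path), "reachstart_error_format")
  }
  lines <- readLines(path)
  if (length(lines) < 5) {
    stop_reach("DLC file needs a 3-row header plus at least 2 data rows.",
               "reachstart_error_format")
  }
  hdr <- strsplit(lines[1:3], ",", fixed = TRUE)
  labels <- vapply(hdr, `[[`, "", 1)
  if (!identical(tolower(labels), c("scorer", "bodyparts", "coords"))) {
    bad <- which(tolower(labels) != c("scorer", "bodyparts", "coords"))[1]
    stop_reach(sprintf(
      "malformed DLC header at row %d: expected `%s`, found `%s`.",
      bad, c("scorer", "bodyparts", "coords")[bad], labels[bad]),
      "reachstart_error_format")
  }
  bodyparts <- hdr[[2]][-1]
  coords <- hdr[[3]][-1]
  if (length(bodyparts) %% 3 != 0 ||
      !all(coords == rep(c("x", "y", "likelihood"),
                         length(bodyparts) / 3))) {
    stop_reach("DLC header must hold (x, y, likelihood) triplets per landmark.",
               "reachstart_error_format")
  }
  landmarks <- bodyparts[seq(1, length(bodyparts), by = 3)]
  missing_lm <- setdiff(c("wrist", "elbow", "shoulder", "nape"), landmarks)
  if (length(missing_lm)) {
    stop_reach(paste0("DLC header lacks required landmark(s): ",
                      paste(missing_lm, collapse = ", ")),
               "reachstart_error_format")
  }
  dat <- utils::read.csv(text = lines[-(1:3)], header = FALSE)
  if (ncol(dat) != length(bodyparts) + 1) {
    stop_reach("DLC data rows do not match the header width.",
               "reachstart_error_format")
  }
  long <- purrr::map_dfr(seq_along(landmarks), function(i) {
    off <- 1 + (i - 1) * 3
    tibble(frame = dat[[1]], landmark = landmarks[i],
           x = dat[[off + 1]], y = dat[[off + 2]],
           likelihood = dat[[off + 3]])
  })
  keypoint_track(long, frame_rate = frame_rate)
}

#' @rdname read_dlc_csv
#' @export
write_dlc_csv <- function(track, path, scorer = "reachstart") {
  if (!inherits(track, "keypoint_track")) {
    stop_reach("`track` must be a keypoint_track().",
               "reachstart_error_format")
  }
  landmarks <- track_landmarks(track)
  frames <- sort(unique(track$frame))
  wide <- purrr::map(landmarks, function(lm) {
    d <- dplyr::filter(track, .data$landmark == lm) |>
      dplyr::arrange(.data$frame)
    cbind(d$x, d$y, d$likelihood)
  })
  header <- c(
    paste(c("scorer", rep(scorer, 3 * length(landmarks))), collapse = ","),
    paste(c("bodyparts", rep(landmarks, each = 3)), collapse = ","),
    paste(c("coords", rep(c("x", "y", "likelihood"), length(landmarks))),
          collapse = ",")
  )
  body <- vapply(seq_along(frames), function(i) {
    vals <- unlist(lapply(wide, function(m) m[i, ]))
    paste(c(frames[i], sprintf("%.6f", vals)), collapse = ",")
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

# ---- plain-CSV formats with `# key: value` metadata headers ----

write_meta_csv <- function(df, path, meta) {
  meta_lines <- sprintf("# %s: %s", names(meta), vapply(meta, format, ""))
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  body <- c(paste(names(df), collapse = ","),
            do.call(paste, c(unname(df), sep = ",")))
  writeLines(c(meta_lines, body), path)
  invisible(path)
}

read_meta_csv <- function(path, required_meta) {
  if (!file.exists(path)) {
    stop_reach(sprintf("file not found: %s", path), "reachstart_error_format")
  }
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta_raw <- sub("^#\\s*", "", lines[is_meta])
  meta <- as.list(sub("^[^:]+:\\s*", "", meta_raw))
  names(meta) <- sub(":.*$", "", meta_raw)
  missing_meta <- setdiff(required_meta, names(meta))
  if (length(missing_meta)) {
    stop_reach(paste0("missing metadata header(s): ",
                      paste(missing_meta, collapse = ", ")),
               "reachstart_error_format")
  }
  df <- utils::read.csv(text = lines[!is_meta], header = TRUE)
  list(meta = meta, data = as_tibble(df))
}

#' Read and write 3D pose tracks as CSV
#'
#' Long-format CSV (`frame, landmark, x_mm, y_mm, z_mm`) with `# key: value`
#' metadata lines carrying `frame_rate_hz` and `units` (which must be
#' `mm`).
#'
#' @param path File path.
#' @param track A [pose3d_track()] to write.
#' @return `read_pose3d_csv()` returns a [pose3d_track()].
#' @export
read_pose3d_csv <- function(path) {
  parsed <- read_meta_csv(path, c("frame_rate_hz", "units"))
  if (parsed$meta$units != "mm") {
    stop_reach(sprintf("3D track units must be mm, found `%s`.",
                       parsed$meta$units),
               "reachstart_error_format")
  }
  pose3d_track(parsed$data,
               frame_rate = as.numeric(parsed$meta$frame_rate_hz))
}

#' @rdname read_pose3d_csv
#' @export
write_pose3d_csv <- function(track, path) {
  if (!inherits(track, "pose3d_track")) {
    stop_reach("`track` must be a pose3d_track().", "reachstart_error_format")
  }
  df <- as_tibble(track)
  write_meta_csv(df, path,
                 list(frame_rate_hz = frame_rate(track), units = "mm"))
}

#' Read and write cue-locked EMG trials as CSV
#'
#' Two columns (`time_ms, voltage_mV`) under metadata headers
#' `sampling_rate_hz`, `cue_time_ms`, `condition`, `trial_id` and optional
#' `true_onset_ms` (simulated trials). Type invariants are enforced on
#' read; a cue earlier than 200 ms is rejected because the onset rule needs
#' a full baseline window.
#'
#' @param path File path.
#' @param trial An [emg_trial()] to write.
#' @return `read_emg_csv()` returns an [emg_trial()].
#' @export
read_emg_csv <- function(path) {
  parsed <- read_meta_csv(path, c("sampling_rate_hz", "cue_time_ms",
                                  "condition", "trial_id"))
  if (!all(c("time_ms", "voltage_mV") %in% names(parsed$data))) {
    stop_reach("EMG CSV needs columns time_ms, voltage_mV.",
               "reachstart_error_format")
  }
  emg_trial(parsed$data$voltage_mV,
            sampling_rate = as.numeric(parsed$meta$sampling_rate_hz),
            cue_time = as.numeric(parsed$meta$cue_time_ms),
            condition = parsed$meta$condition,
            trial_id = parsed$meta$trial_id,
            true_onset_ms = as.numeric(parsed$meta$true_onset_ms %||%
                                         NA_real_))
}

#' @rdname read_emg_csv
#' @export
write_emg_csv <- function(trial, path) {
  stopifnot_emg(trial)
  meta <- list(sampling_rate_hz = trial_attr(trial, "sampling_rate"),
               cue_time_ms = trial_attr(trial, "cue_time"),
               condition = trial_attr(trial, "condition"),
               trial_id = trial_attr(trial, "trial_id"))
  truth <- trial_attr(trial, "true_onset_ms")
  if (!is.na(truth)) meta$true_onset_ms <- truth
  write_meta_csv(as_tibble(trial), path, meta)
}

#' Read and write cohort tables as CSV
#'
#' Plain CSV, one row per subject, with the documented column schema of
#' [simulate_cohort()]. On read, every row's ARAT scores are validated
#' against the subscale maxima and the total, and the StartReact column is
#' checked against `vart_mean - vsrt_mean`.
#'
#' @param path File path.
#' @param cohort A cohort table to write.
#' @param tol Tolerance (ms) for the StartReact consistency check.
#' @return `read_cohort_csv()` returns a `cohort_table` tibble.
#' @export
read_cohort_csv <- function(path, tol = 1e-3) {
  if (!file.exists(path)) {
    stop_reach(sprintf("file not found: %s", path), "reachstart_error_format")
  }
  df <- as_tibble(utils::read.csv(path))
  need <- c("subject_id", "ioee", "vrt_mean", "vart_mean", "vsrt_mean",
            "startreact", "arat_grasp", "arat_grip", "arat_pinch",
            "arat_gross", "arat_total", "mas", "grip_affected",
            "grip_less_affected", "grip_normalized")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_reach(paste0("cohort CSV lacks column(s): ",
                      paste(missing_cols, collapse = ", ")),
               "reachstart_error_format")
  }
  for (i in seq_len(nrow(df))) {
    tryCatch(
      validate_arat(list(grasp = df$arat_grasp[i], grip = df$arat_grip[i],
                         pinch = df$arat_pinch[i], gross = df$arat_gross[i],
                         total = df$arat_total[i])),
      reachstart_error_validation = function(e) {
        stop_reach(sprintf("row %d (%s): %s", i, df$subject_id[i],
                           conditionMessage(e)),
                   "reachstart_error_validation")
      }
    )
    if (abs(df$startreact[i] - (df$vart_mean[i] - df$vsrt_mean[i])) > tol) {
      stop_reach(sprintf(
        "row %d (%s): startreact %.4f != vart_mean - vsrt_mean = %.4f.",
        i, df$subject_id[i], df$startreact[i],
        df$vart_mean[i] - df$vsrt_mean[i]),
        "reachstart_error_validation")
    }
  }
  structure(df, class = c("cohort_table", class(tibble())))
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Write a ground-truth sidecar JSON
#'
#' Serialises the generating parameters and latent values of any simulated
#' object next to its CSV, so downstream analyses can be scored against the
#' truth that produced the data.
#'
#' @param truth A named list of ground-truth values.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
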