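#' Pair top- and front-camera frames by timestamp
#'
#' Greedy nearest-timestamp matching: the two streams are walked in time
#' order and each top frame is matched to the closest not-yet-used front
#' frame within the tolerance. Each record is used at most once;
#' unmatched records are counted, not assessed. Timestamp pairing (rather
#' than frame-index pairing) keeps the cascade robust to clock drift
#' between cameras.
#'
#' @param top_stream,front_stream Lists of \code{lapskill_record}s sorted
#'   by timestamp.
#' @param tolerance Maximum |timestamp difference| in seconds for a pair
#'   (default 0.020 s, about half a frame at 30 FPS).
#' @return List with \code{pairs} (list of \code{list(top =, front =)}
#'   records), \code{n_unmatched_top}, \code{n_unmatched_front}, and
#'   \code{empty_input} flag.
#' @export
pair_frames <- function(top_stream, front_stream, tolerance = 0.020) {
  stopifnot(tolerance > 0)
  n_t <- length(top_stream); n_f <- length(front_stream)
  if (n_t == 0L || n_f == 0L) {
    if (n_t == 0L) warning("top stream is empty", call. = FALSE)
    if (n_f == 0L) warning("front stream is empty", call. = FALSE)
    return(list(pairs = list(), n_unmatched_top = n_t,
                n_unmatched_front = n_f, empty_input = TRUE))
  }
  ts_t <- vapply(top_stream, function(r) r$timestamp, numeric(1L))
  ts_f <- vapply(front_stream, function(r) r$timestamp, numeric(1L))
  pairs <- list()
  j <- 1L
  for (i in seq_len(n_t)) {
    # advance to the front frame nearest this top frame
    while (j < n_f &&
           abs(ts_f[j + 1L] - ts_t[i]) < abs(ts_f[j] - ts_t[i])) {
      j <- j + 1L
    }
    if (abs(ts_f[j] - ts_t[i]) <= tolerance) {
      pairs[[length(pairs) + 1L]] <-
        list(top = top_stream[[i]], front = front_stream[[j]])
      j <- j + 1L
      if (j > n_f) break
    }
  }
  list(pairs = pairs,
       n_unmatched_top = n_t - length(pairs),
       n_unmatched_front = n_f - length(pairs),
       empty_input = FALSE)
}

is_right_label <- function(label) grepl("right", label, ignore.case = TRUE)
is_left_label <- function(label) grepl("left", label, ignore.case = TRUE)

#' Assign detections to hands
#'
#' Detections below \code{min_score} are dropped. If class labels
#' distinguish the right and left graspers (any label containing
#' "right"/"left", case-insensitively), the highest-scoring detection per
#' class wins; unlabelled grasper detections fall back to x-ordering —
#' the rightmost centroid becomes the right hand. Surplus detections
#' beyond one per hand are dropped with a flag.
#'
#' @param detections List of \code{list(label, score, bbox)} from one
#'   \code{lapskill_record}.
#' @param min_score Minimum confidence to keep a detection.
#' @return List with \code{right} and \code{left} (each a
#'   \code{list(label, score, bbox, centroid_px)} or \code{NULL}) and
#'   \code{flags}.
#' @export
assign_hands <- function(detections, min_score = 0.5) {
  flags <- character(0)
  kept <- Filter(function(d) d$score >= min_score, detections)
  kept <- lapply(kept, function(d) {
    b <- bounding_box(d$bbox[1L], d$bbox[2L], d$bbox[3L], d$bbox[4L])
    d$centroid_px <- bbox_centroid(b)
    d
  })
  right <- NULL; left <- NULL
  labelled_r <- Filter(function(d) is_right_label(d$label), kept)
  labelled_l <- Filter(function(d) is_left_label(d$label), kept)
  unlabelled <- Filter(function(d) !is_right_label(d$label) &&
                                   !is_left_label(d$label), kept)
  pick_best <- function(ds) {
    ds[[which.max(vapply(ds, function(d) d$score, numeric(1L)))]]
  }
  if (length(labelled_r) > 0L) {
    right <- pick_best(labelled_r)
    if (length(labelled_r) > 1L) flags <- c(flags, "duplicate_right")
  }
  if (length(labelled_l) > 0L) {
    left <- pick_best(labelled_l)
    if (length(labelled_l) > 1L) flags <- c(flags, "duplicate_left")
  }
  if (length(unlabelled) > 0L) {
    xs <- vapply(unlabelled, function(d) d$centroid_px[["x"]], numeric(1L))
    if (is.null(right)) {
      i_r <- which.max(xs)
      right <- unlabelled[[i_r]]
      unlabelled <- unlabelled[-i_r]
      xs <- xs[-i_r]
    }
    if (is.null(left) && length(unlabelled) > 0L) {
      left <- unlabelled[[which.min(xs)]]
      unlabelled <- unlabelled[-which.min(xs)]
    }
    if (length(unlabelled) > 0L) flags <- c(flags, "surplus_dropped")
  }
  list(right = right, left = left, flags = flags)
}

#' Run a full assessment session
#'
#' The end-to-end pipeline: pair the two camera streams by timestamp,
#' assign detections to hands, calibrate centroids to cm, assess every
#' paired frame through the two-level cascade, and aggregate a session
#' summary. Deterministic for fixed inputs and configuration; frames are
#' processed one at a time, so memory stays bounded by a frame plus the
#' scalar aggregates.
#'
#' @param top_stream,front_stream Detection streams (lists of
#'   \code{lapskill_record}s) from the top and front cameras.
#' @param config Run configuration (see [default_config()]).
#' @return Object of class \code{lapskill_session}: \code{series}, a
#'   data.frame with one row per paired frame (timestamps, SRHPA, SLHPA,
#'   FPA crisp scores and letters, flags), and \code{summary}, a list of
#'   aggregate statistics (mean/min FPA, per-letter time fractions over
#'   assessed frames, skip and unmatched counts).
#' @export
run_session <- function(top_stream, front_stream,
                        config = default_config()) {
  validate_config(config)
  supervisor <- build_supervisor(config)
  calib_top <- with(config$calibration$top,
                    camera_calibration(frame_width_px, frame_height_px,
                                       real_width_cm, real_height_cm))
  calib_front <- with(config$calibration$front,
                      camera_calibration(frame_width_px, frame_height_px,
                                         real_width_cm, real_height_cm))
  paired <- pair_frames(top_stream, front_stream,
                        config$fusion$pairing_tolerance_s)
  n_pairs <- length(paired$pairs)
  # column buffers (assembled into the series data.frame at the end)
  col_frame_top <- integer(n_pairs); col_frame_front <- integer(n_pairs)
  col_ts <- numeric(n_pairs)
  col_srhpa <- rep(NA_real_, n_pairs)
  col_srhpa_l <- rep(NA_character_, n_pairs)
  col_slhpa <- rep(NA_real_, n_pairs)
  col_slhpa_l <- rep(NA_character_, n_pairs)
  col_fpa <- rep(NA_real_, n_pairs)
  col_fpa_l <- rep(NA_character_, n_pairs)
  col_flags <- rep("", n_pairs)
  state <- NULL
  letters_out <- names(supervisor$level2$output$labels)
  letter_frames <- stats::setNames(integer(length(letters_out)),
                                   letters_out)
  fpa_sum <- 0; fpa_min <- Inf; n_assessed <- 0L; n_skipped <- 0L
  min_score <- config$fusion$min_score

  to_obs <- function(d, camera, hand, calib) {
    if (is.null(d)) return(NULL)
    instrument_observation(camera, hand, to_cm(d$centroid_px, calib),
                           d$score)
  }
  for (k in seq_len(n_pairs)) {
    pr <- paired$pairs[[k]]
    top_assign <- assign_hands(pr$top$detections, min_score)
    front_assign <- assign_hands(pr$front$detections, min_score)
    top_obs <- list(
      right = to_obs(top_assign$right, "top", "right", calib_top),
      left = to_obs(top_assign$left, "top", "left", calib_top))
    front_obs <- list(
      right = to_obs(front_assign$right, "front", "right", calib_front),
      left = to_obs(front_assign$left, "front", "left", calib_front))
    fr <- assess_frame(top_obs, front_obs, config, supervisor, state)
    state <- fr$state
    col_frame_top[k] <- pr$top$frame_index
    col_frame_front[k] <- pr$front$frame_index
    col_ts[k] <- pr$top$timestamp
    if (!is.null(fr$right)) {
      col_srhpa[k] <- fr$right$crisp
      col_srhpa_l[k] <- fr$right$letter
    }
    if (!is.null(fr$left)) {
      col_slhpa[k] <- fr$left$crisp
      col_slhpa_l[k] <- fr$left$letter
    }
    all_flags <- unique(c(top_assign$flags, front_assign$flags, fr$flags))
    col_flags[k] <- paste(all_flags, collapse = ";")
    if (!is.null(fr$final)) {
      col_fpa[k] <- fr$final$crisp
      col_fpa_l[k] <- fr$final$letter
      n_assessed <- n_assessed + 1L
      fpa_sum <- fpa_sum + fr$final$crisp
      fpa_min <- min(fpa_min, fr$final$crisp)
      letter_frames[fr$final$letter] <- letter_frames[fr$final$letter] + 1L
    } else {
      n_skipped <- n_skipped + 1L
    }
  }
  series <- data.frame(
    frame_top = col_frame_top, frame_front = col_frame_front,
    timestamp = col_ts,
    srhpa = col_srhpa, srhpa_letter = col_srhpa_l,
    slhpa = col_slhpa, slhpa_letter = col_slhpa_l,
    fpa = col_fpa, fpa_letter = col_fpa_l,
    flags = col_flags, stringsAsFactors = FALSE)
  frac <- if (n_assessed > 0L) letter_frames / n_assessed
          else letter_frames * NA_real_
  summary <- list(
    n_frames_top = length(top_stream),
    n_frames_front = length(front_stream),
    n_paired = n_pairs,
    n_assessed = n_assessed,
    n_skipped = n_skipped,
    n_unmatched_top = paired$n_unmatched_top,
    n_unmatched_front = paired$n_unmatched_front,
    mean_fpa = if (n_assessed > 0L) fpa_sum / n_assessed else NA_real_,
    min_fpa = if (n_assessed > 0L) fpa_min else NA_real_,
    letter_fractions = as.list(frac),
    warning = if (paired$empty_input) "empty input stream" else NULL)
  structure(list(series = series, summary = summary),
            class = "lapskill_session")
}

#' @export
print.lapskill_session <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<session: %d paired frames, %d assessed, %d ",
                     "skipped; mean FPA %.1f%%, min %.1f%%>\n"),
              s$n_paired, s$n_assessed, s$n_skipped,
              ifelse(is.na(s$mean_fpa), NaN, s$mean_fpa),
              ifelse(is.na(s$min_fpa), NaN, s$min_fpa)))
  invisible(x)
}
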