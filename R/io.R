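#' Detection record for one frame of one camera
#'
#' @param camera \code{"top"} or \code{"front"}.
#' @param frame_index Integer frame number, >= 0, strictly increasing
#'   within a stream.
#' @param timestamp Seconds since stream start, non-decreasing.
#' @param detections List of detections, each a list with \code{label}
#'   (character), \code{score} in \code{[0, 1]}, and \code{bbox}
#'   \code{c(xmin, ymin, xmax, ymax)} in pixels. May be empty.
#' @return An object of class \code{lapskill_record}.
#' @export
detection_record <- function(camera, frame_index, timestamp,
                             detections = list()) {
  camera <- match.arg(camera, c("top", "front"))
  stopifnot(is.finite(frame_index), frame_index >= 0,
            is.finite(timestamp), timestamp >= 0)
  for (d in detections) {
    if (is.null(d$label) || is.null(d$score) || is.null(d$bbox)) {
      stop("each detection needs label, score and bbox", call. = FALSE)
    }
    if (d$score < 0 || d$score > 1) {
      stop("detection score must be in [0, 1]", call. = FALSE)
    }
    bounding_box(d$bbox[1L], d$bbox[2L], d$bbox[3L], d$bbox[4L])
  }
  structure(list(camera = camera, frame_index = as.integer(frame_index),
                 timestamp = as.numeric(timestamp),
                 detections = detections),
            class = "lapskill_record")
}

validate_stream <- function(records, where = "stream") {
  if (length(records) == 0L) {
    warning(where, " is empty", call. = FALSE)
    return(records)
  }
  idx <- vapply(records, function(r) r$frame_index, numeric(1L))
  ts <- vapply(records, function(r) r$timestamp, numeric(1L))
  if (any(diff(idx) <= 0)) {
    stop(where, ": frame_index must be strictly increasing (violated at ",
         "record ", which(diff(idx) <= 0)[1L] + 1L, ")", call. = FALSE)
  }
  if (any(diff(ts) < 0)) {
    stop(where, ": timestamps must be non-decreasing (violated at record ",
         which(diff(ts) < 0)[1L] + 1L, ")", call. = FALSE)
  }
  records
}

#' Read a detection stream
#'
#' Two dialects are supported. \code{"jsonl"}: one JSON object per line
#' with fields \code{camera}, \code{frame_index}, \code{timestamp} and a
#' \code{detections} array of \code{\{label, score, bbox\}} objects.
#' \code{"csv"}: one detection per row with columns \code{camera,
#' frame_index, timestamp, label, score, xmin, ymin, xmax, ymax}; a row
#' with an empty label marks a frame that produced no detections, so
#' empty frames survive a CSV round-trip.
#'
#' Records are validated (ordering, box geometry, score range); a
#' malformed line fails with its line number.
#'
#' @param path File path.
#' @param format \code{"jsonl"} or \code{"csv"}; guessed from the file
#'   extension by default.
#' @return List of \code{lapskill_record}s, ordered by frame.
#' @export
read_detection_stream <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
              else "jsonl"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "jsonl") read_stream_jsonl(path) else read_stream_csv(path)
}

read_stream_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines_keep <- which(nzchar(trimws(lines)))
  records <- vector("list", length(lines_keep))
  for (k in seq_along(lines_keep)) {
    i <- lines_keep[k]
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) {
                      stop(path, " line ", i, ": invalid JSON (",
                           conditionMessage(e), ")", call. = FALSE)
                    })
    records[[k]] <- tryCatch(
      detection_record(rec$camera, rec$frame_index, rec$timestamp,
                       lapply(rec$detections, function(d) {
                         list(label = d$label, score = d$score,
                              bbox = as.numeric(unlist(d$bbox)))
                       })),
      error = function(e) {
        stop(path, " line ", i, ": ", conditionMessage(e), call. = FALSE)
      })
  }
  validate_stream(records, path)
}

read_stream_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("camera", "frame_index", "timestamp", "label", "score",
            "xmin", "ymin", "xmax", "ymax")
  if (!all(need %in% names(df))) {
    stop(path, ": missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  records <- list()
  for (fi in unique(df$frame_index)) {
    rows <- df[df$frame_index == fi, , drop = FALSE]
    dets <- list()
    for (r in seq_len(nrow(rows))) {
      lab <- rows$label[r]
      if (is.na(lab) || !nzchar(lab)) next # empty-frame marker row
      dets[[length(dets) + 1L]] <- tryCatch(
        list(label = lab, score = rows$score[r],
             bbox = c(rows$xmin[r], rows$ymin[r], rows$xmax[r],
                      rows$ymax[r])),
        error = function(e) stop(path, " frame ", fi, ": ",
                                 conditionMessage(e), call. = FALSE))
    }
    records[[length(records) + 1L]] <-
      detection_record(rows$camera[1L], fi, rows$timestamp[1L], dets)
  }
  validate_stream(records, path)
}

#' Write a detection stream
#'
#' @param records List of \code{lapskill_record}s.
#' @param path Output path.
#' @param format \code{"jsonl"} or \code{"csv"} (see
#'   [read_detection_stream()] for the dialects).
#' @return \code{path}, invisibly.
#' @export
write_detection_stream <- function(records, path,
                                   format = c("jsonl", "csv")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- vapply(records, function(r) {
      jsonlite::toJSON(list(camera = r$camera,
                            frame_index = r$frame_index,
                            timestamp = r$timestamp,
                            detections = lapply(r$detections, function(d) {
                              list(label = d$label, score = d$score,
                                   bbox = as.numeric(d$bbox))
                            })),
                      auto_unbox = TRUE, digits = I(6))
    }, character(1L))
    writeLines(lines, path)
  } else {
    rows <- list()
    for (r in records) {
      if (length(r$detections) == 0L) {
        rows[[length(rows) + 1L]] <-
          data.frame(camera = r$camera, frame_index = r$frame_index,
                     timestamp = r$timestamp, label = "",
                     score = NA_real_, xmin = NA_real_, ymin = NA_real_,
                     xmax = NA_real_, ymax = NA_real_)
      }
      for (d in r$detections) {
        rows[[length(rows) + 1L]] <-
          data.frame(camera = r$camera, frame_index = r$frame_index,
                     timestamp = r$timestamp, label = d$label,
                     score = d$score, xmin = d$bbox[1L], ymin = d$bbox[2L],
                     xmax = d$bbox[3L], ymax = d$bbox[4L])
      }
    }
    utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  }
  invisible(path)
}

#' Write session results
#'
#' Writes the per-frame assessment series as CSV and the aggregate summary
#' as JSON.
#'
#' @param result A \code{lapskill_session} from [run_session()].
#' @param series_path,summary_path Output paths (either may be
#'   \code{NULL} to skip).
#' @return Invisible list of the paths written.
#' @export
write_session_result <- function(result, series_path = NULL,
                                 summary_path = NULL) {
  stopifnot(inherits(result, "lapskill_session"))
  if (!is.null(series_path)) {
    utils::write.csv(result$series, series_path, row.names = FALSE)
  }
  if (!is.null(summary_path)) {
    jsonlite::write_json(result$summary, summary_path, auto_unbox = TRUE,
                         digits = I(10), pretty = TRUE)
  }
  invisible(list(series = series_path, summary = summary_path))
}
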