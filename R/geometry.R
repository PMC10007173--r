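#' Bounding box in pixel coordinates
#'
#' Axis-aligned detection box. The origin is the frame's top-left corner,
#' x grows rightward and y grows downward, so larger y means physically
#' lower in the front view.
#'
#' @param xmin,ymin,xmax,ymax Box edges in pixels, \code{xmin < xmax},
#'   \code{ymin < ymax}, all non-negative.
#' @return An object of class \code{lapskill_bbox}.
#' @export
bounding_box <- function(xmin, ymin, xmax, ymax) {
  vals <- c(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("bounding-box coordinates must be finite and non-negative",
         call. = FALSE)
  }
  if (xmin >= xmax || ymin >= ymax) {
    stop("degenerate bounding box: need xmin < xmax and ymin < ymax",
         call. = FALSE)
  }
  structure(as.list(vals), class = "lapskill_bbox")
}

#' Centroid of a bounding box
#'
#' @param b A \code{lapskill_bbox}.
#' @return Numeric \code{c(x, y)} in pixels (continuous; no rounding).
#' @export
bbox_centroid <- function(b) {
  stopifnot(inherits(b, "lapskill_bbox"))
  c(x = (b$xmin + b$xmax) / 2, y = (b$ymin + b$ymax) / 2)
}

#' Camera calibration: pixel to centimetre scaling
#'
#' Maps frame pixels to real-world centimetres with a plain per-axis scale
#' (average pixels per cm = frame extent in px / real extent in cm).
#' Anisotropic pixels are supported: each axis carries its own scale.
#'
#' @param frame_width_px,frame_height_px Frame size in pixels.
#' @param real_width_cm,real_height_cm Real-world extent of the imaged
#'   plane in cm.
#' @return An object of class \code{lapskill_calib}.
#' @export
camera_calibration <- function(frame_width_px, frame_height_px,
                               real_width_cm, real_height_cm) {
  vals <- c(frame_width_px, frame_height_px, real_width_cm, real_height_cm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("calibration extents must be strictly positive", call. = FALSE)
  }
  structure(list(frame_width_px = frame_width_px,
                 frame_height_px = frame_height_px,
                 real_width_cm = real_width_cm,
                 real_height_cm = real_height_cm),
            class = "lapskill_calib")
}

#' Pixels per centimetre
#'
#' @param calib A \code{lapskill_calib}.
#' @return Named numeric \code{c(x = , y = )}: average pixels per cm along
#'   each axis.
#' @export
px_per_cm <- function(calib) {
  stopifnot(inherits(calib, "lapskill_calib"))
  c(x = calib$frame_width_px / calib$real_width_cm,
    y = calib$frame_height_px / calib$real_height_cm)
}

#' Convert a pixel point to centimetres (and back)
#'
#' Per-axis division (multiplication) by the calibration's pixels-per-cm.
#' The origin stays at the frame's top-left corner.
#'
#' @param p Numeric \code{c(x, y)}.
#' @param calib A \code{lapskill_calib}.
#' @return Numeric \code{c(x, y)} in the target units.
#' @export
to_cm <- function(p, calib) {
  s <- px_per_cm(calib)
  c(x = p[[1L]] / s[["x"]], y = p[[2L]] / s[["y"]])
}

#' @rdname to_cm
#' @export
to_px <- function(p, calib) {
  s <- px_per_cm(calib)
  c(x = p[[1L]] * s[["x"]], y = p[[2L]] * s[["y"]])
}

#' Field of interest on the trainer board
#'
#' The central region of the test board the instruments should stay near:
#' its centroid on the top-camera plane (cm), and the acceptable height
#' band on the front-camera vertical axis (cm from the frame top).
#'
#' @param center Numeric \code{c(x, y)} in cm, top-camera plane.
#' @param front_field_band Numeric \code{c(h_low, h_high)} in cm,
#'   \code{h_low < h_high}.
#' @return An object of class \code{lapskill_field}.
#' @export
field_of_interest <- function(center, front_field_band) {
  stopifnot(length(center) == 2L, length(front_field_band) == 2L)
  if (front_field_band[1L] >= front_field_band[2L]) {
    stop("front_field_band must satisfy h_low < h_high", call. = FALSE)
  }
  structure(list(center = as.numeric(center),
                 front_field_band = as.numeric(front_field_band)),
            class = "lapskill_field")
}

#' Distance from a point to the field-of-interest centre
#'
#' Plain Euclidean distance on the top-camera plane, in cm. This is the
#' first input (Dis) of each first-level fuzzy system.
#'
#' @param p_cm Numeric \code{c(x, y)} in cm.
#' @param field A \code{lapskill_field} (or a length-2 centre).
#' @return Non-negative distance in cm.
#' @export
distance_to_field <- function(p_cm, field) {
  ctr <- if (inherits(field, "lapskill_field")) field$center else field
  sqrt(sum((as.numeric(p_cm)[1:2] - as.numeric(ctr)[1:2])^2))
}

#' Instrument observation in one camera
#'
#' One detected grasper in one frame, already calibrated to cm.
#'
#' @param camera \code{"top"} or \code{"front"}.
#' @param hand \code{"right"} or \code{"left"}.
#' @param centroid_cm Numeric \code{c(x, y)} in cm (frame origin top-left).
#' @param score Detection confidence in \code{[0, 1]}.
#' @return An object of class \code{lapskill_obs}.
#' @export
instrument_observation <- function(camera, hand, centroid_cm, score = 1) {
  camera <- match.arg(camera, c("top", "front"))
  hand <- match.arg(hand, c("right", "left"))
  stopifnot(length(centroid_cm) == 2L, is.finite(score),
            score >= 0, score <= 1)
  structure(list(camera = camera, hand = hand,
                 centroid_cm = as.numeric(centroid_cm), score = score),
            class = "lapskill_obs")
}

#' Instrument height from a front-camera observation
#'
#' The vertical (second) coordinate of the front-camera centroid, in cm
#' from the frame top. With the top-left origin, smaller values mean the
#' instrument is physically HIGHER. This is the second input (H) of each
#' first-level fuzzy system.
#'
#' @param obs A front-camera \code{lapskill_obs}.
#' @return Height h in cm.
#' @export
height_from_front <- function(obs) {
  stopifnot(inherits(obs, "lapskill_obs"))
  if (obs$camera != "front") {
    stop("height is defined by the front camera; got a ", obs$camera,
         "-camera observation", call. = FALSE)
  }
  obs$centroid_cm[[2L]]
}

#' Crisp region labels (reporting helper)
#'
#' Label of maximal membership for a calibrated measurement on the
#' corresponding input variable: Close/Middle/Far for the top-view
#' distance, High/Field/Down for the front-view height. The fuzzy
#' assessment path never hard-thresholds; these helpers exist for tests
#' and human-readable reports.
#'
#' @param dis,h Distance / height in cm.
#' @param var The matching input \code{lapskill_lv}.
#' @return A region label.
#' @export
classify_top_region <- function(dis, var) {
  deg <- fuzzify_singleton(var, dis)
  names(deg)[which.max(deg)]
}

#' @rdname classify_top_region
#' @export
classify_front_region <- function(h, var) {
  deg <- fuzzify_singleton(var, h)
  names(deg)[which.max(deg)]
}
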