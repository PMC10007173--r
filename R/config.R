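#' Default run configuration
#'
#' One document governs the whole pipeline: camera calibrations, the
#' field-of-interest geometry, both fuzzy-system definitions (variables and
#' rule tables), and the stream-fusion policy. There are no hidden
#' constants in code — anything tunable is surfaced here.
#'
#' Defaults: 1280 x 720 px frames imaged over 40 x 22.5 cm (16:9
#' preserved, 32 px/cm on both axes); field centre at the top-frame
#' centre; three 50%-overlapping triangular labels per input spanning each
#' universe; five triangular score labels E..A with peaks at
#' 10/30/50/70/90 over 0-100%; rule tables for both cascade levels;
#' min/max Mamdani operators with center-of-average defuzzification.
#'
#' @return Nested list of class \code{lapskill_config}.
#' @export
default_config <- function() {
  calib <- list(frame_width_px = 1280, frame_height_px = 720,
                real_width_cm = 40, real_height_cm = 22.5)
  cfg <- list(
    calibration = list(top = calib, front = calib),
    field = list(center_cm = c(20, 11.25),
                 front_field_band_cm = c(7.5, 15)),
    fuzzy = list(
      defuzz_method = "center_of_average",
      distance = list(
        units = "cm", universe = c(0, 23),
        labels = list(
          Close  = list(shape = "triangular", breakpoints = c(0, 0, 11.5)),
          Middle = list(shape = "triangular", breakpoints = c(0, 11.5, 23)),
          Far    = list(shape = "triangular", breakpoints = c(11.5, 23, 23)))),
      height = list(
        units = "cm", universe = c(0, 22.5),
        labels = list(
          High  = list(shape = "triangular", breakpoints = c(0, 0, 11.25)),
          Field = list(shape = "triangular", breakpoints = c(0, 11.25, 22.5)),
          Down  = list(shape = "triangular", breakpoints = c(11.25, 22.5, 22.5)))),
      hand_score = list(
        units = "percent", universe = c(0, 100),
        labels = list(
          E = list(shape = "triangular", breakpoints = c(0, 10, 30)),
          D = list(shape = "triangular", breakpoints = c(10, 30, 50)),
          C = list(shape = "triangular", breakpoints = c(30, 50, 70)),
          B = list(shape = "triangular", breakpoints = c(50, 70, 90)),
          A = list(shape = "triangular", breakpoints = c(70, 90, 100)))),
      refuzzified = list(
        units = "percent", universe = c(0, 100),
        labels = list(
          Bad       = list(shape = "trapezoidal",
                           breakpoints = c(0, 0, 10, 50)),
          Good      = list(shape = "triangular",
                           breakpoints = c(10, 50, 90)),
          Excellent = list(shape = "trapezoidal",
                           breakpoints = c(50, 90, 100, 100)))),
      final_score = list(
        units = "percent", universe = c(0, 100),
        labels = list(
          E = list(shape = "triangular", breakpoints = c(0, 10, 30)),
          D = list(shape = "triangular", breakpoints = c(10, 30, 50)),
          C = list(shape = "triangular", breakpoints = c(30, 50, 70)),
          B = list(shape = "triangular", breakpoints = c(50, 70, 90)),
          A = list(shape = "triangular", breakpoints = c(70, 90, 100)))),
      # first level: rows = front-view height, columns = top-view distance
      rules_level1 = list(
        list(height = "High",  distance = "Close",  grade = "B"),
        list(height = "High",  distance = "Middle", grade = "E"),
        list(height = "High",  distance = "Far",    grade = "E"),
        list(height = "Field", distance = "Close",  grade = "A"),
        list(height = "Field", distance = "Middle", grade = "B"),
        list(height = "Field", distance = "Far",    grade = "C"),
        list(height = "Down",  distance = "Close",  grade = "B"),
        list(height = "Down",  distance = "Middle", grade = "B"),
        list(height = "Down",  distance = "Far",    grade = "D")),
      # second level: rows = right hand (SRHPAr), columns = left (SLHPAr).
      # The table is asymmetric as published (Good x Bad -> E, but
      # Bad x Good -> D) and is encoded verbatim.
      rules_level2 = list(
        list(right = "Excellent", left = "Excellent", grade = "A"),
        list(right = "Excellent", left = "Good",      grade = "B"),
        list(right = "Excellent", left = "Bad",       grade = "C"),
        list(right = "Good",      left = "Excellent", grade = "B"),
        list(right = "Good",      left = "Good",      grade = "C"),
        list(right = "Good",      left = "Bad",       grade = "E"),
        list(right = "Bad",       left = "Excellent", grade = "C"),
        list(right = "Bad",       left = "Good",      grade = "D"),
        list(right = "Bad",       left = "Bad",       grade = "D")),
      # OFF by default: replace each asymmetric rule pair by the less
      # severe of its two grades (restores monotonicity; see vignette)
      symmetrize_level2 = FALSE),
    fusion = list(pairing_tolerance_s = 0.020, min_score = 0.5,
                  hold_window_frames = 15),
    output = list(series = "series.csv", summary = "summary.json"),
    seed = 1
  )
  structure(cfg, class = c("lapskill_config", "list"))
}

cfg_stop <- function(where, msg) {
  stop("config error at '", where, "': ", msg, call. = FALSE)
}

build_mf <- function(spec, where) {
  if (is.null(spec$shape) || is.null(spec$breakpoints)) {
    cfg_stop(where, "needs 'shape' and 'breakpoints'")
  }
  bp <- as.numeric(spec$breakpoints)
  if (spec$shape == "triangular") {
    mf_triangular(bp[1L], bp[2L], bp[3L])
  } else if (spec$shape == "trapezoidal") {
    mf_trapezoidal(bp[1L], bp[2L], bp[3L], bp[4L])
  } else {
    cfg_stop(where, paste0("unknown shape '", spec$shape, "'"))
  }
}

build_variable <- function(name, spec, where, complete = TRUE) {
  if (is.null(spec$universe) || is.null(spec$labels)) {
    cfg_stop(where, "needs 'universe' and 'labels'")
  }
  labels <- lapply(seq_along(spec$labels), function(i) {
    build_mf(spec$labels[[i]],
             paste0(where, ".labels.", names(spec$labels)[i]))
  })
  names(labels) <- names(spec$labels)
  linguistic_variable(name, as.numeric(spec$universe), labels,
                      units = if (is.null(spec$units)) "" else spec$units,
                      complete = complete)
}

symmetrize_rules2 <- function(rules, order_worst_first) {
  grade_rank <- stats::setNames(seq_along(order_worst_first),
                                order_worst_first)
  lookup <- list()
  for (r in rules) lookup[[paste(r$right, r$left)]] <- r$grade
  lapply(rules, function(r) {
    g1 <- r$grade
    g2 <- lookup[[paste(r$left, r$right)]]
    best <- if (grade_rank[[g1]] >= grade_rank[[g2]]) g1 else g2
    list(right = r$right, left = r$left, grade = best)
  })
}

#' Build the cascade's fuzzy systems from a configuration
#'
#' Constructs the shared first-level MISO system (inputs: top-view distance
#' and front-view height; output: hand performance score), the refuzzified
#' score variables for both hands, and the second-level system (inputs:
#' right and left refuzzified scores; output: final performance
#' assessment).
#'
#' @param config A configuration list (see [default_config()]).
#' @return List with elements \code{level1} (a \code{lapskill_fis}),
#'   \code{level2} (a \code{lapskill_fis}), \code{refuzz_var} (the
#'   Excellent/Good/Bad variable), \code{dis_var}, \code{h_var}, and the
#'   defuzzification method.
#' @export
build_supervisor <- function(config = default_config()) {
  fz <- config$fuzzy
  if (is.null(fz)) cfg_stop("fuzzy", "missing block")
  dis_var <- build_variable("distance", fz$distance, "fuzzy.distance")
  h_var <- build_variable("height", fz$height, "fuzzy.height")
  hand_out <- build_variable("hand_score", fz$hand_score,
                             "fuzzy.hand_score", complete = FALSE)
  final_out <- build_variable("final_score", fz$final_score,
                              "fuzzy.final_score", complete = FALSE)
  refuzz <- build_variable("refuzzified", fz$refuzzified,
                           "fuzzy.refuzzified")
  method <- if (is.null(fz$defuzz_method)) "center_of_average"
            else fz$defuzz_method
  rules1 <- lapply(fz$rules_level1, function(r) {
    fuzzy_rule(c(distance = r$distance, height = r$height), r$grade)
  })
  level1 <- mamdani_system(list(dis_var, h_var), hand_out, rules1,
                           defuzz = method)
  r2 <- fz$rules_level2
  if (isTRUE(fz$symmetrize_level2)) {
    r2 <- symmetrize_rules2(r2, names(final_out$labels))
  }
  right_var <- refuzz; right_var$name <- "right"
  left_var <- refuzz; left_var$name <- "left"
  rules2 <- lapply(r2, function(r) {
    fuzzy_rule(c(right = r$right, left = r$left), r$grade)
  })
  level2 <- mamdani_system(list(right_var, left_var), final_out, rules2,
                           defuzz = method)
  list(level1 = level1, level2 = level2, refuzz_var = refuzz,
       dis_var = dis_var, h_var = h_var, method = method)
}

#' Read / write / validate a configuration
#'
#' Configurations are YAML documents mirroring [default_config()]. Reading
#' validates by actually constructing every calibration, geometry and
#' fuzzy object, so malformed entries fail fast with the offending key.
#'
#' @param path File path.
#' @return \code{read_config()}: a validated \code{lapskill_config};
#'   \code{write_config()}: \code{path}, invisibly;
#'   \code{validate_config()}: the config, invisibly, or an error.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(default_config()), cfg)
  class(cfg) <- c("lapskill_config", "list")
  validate_config(cfg)
}

#' @rdname read_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname read_config
#' @export
validate_config <- function(config) {
  for (cam in c("top", "front")) {
    cc <- config$calibration[[cam]]
    if (is.null(cc)) cfg_stop(paste0("calibration.", cam), "missing")
    tryCatch(camera_calibration(cc$frame_width_px, cc$frame_height_px,
                                cc$real_width_cm, cc$real_height_cm),
             error = function(e) cfg_stop(paste0("calibration.", cam),
                                          conditionMessage(e)))
  }
  fld <- config$field
  if (is.null(fld$center_cm) || length(fld$center_cm) != 2L) {
    cfg_stop("field.center_cm", "need c(x, y) in cm")
  }
  top <- config$calibration$top
  if (fld$center_cm[1L] < 0 || fld$center_cm[1L] > top$real_width_cm ||
      fld$center_cm[2L] < 0 || fld$center_cm[2L] > top$real_height_cm) {
    cfg_stop("field.center_cm", "centre outside the calibrated top frame")
  }
  field_of_interest(fld$center_cm, fld$front_field_band_cm)
  fus <- config$fusion
  if (fus$pairing_tolerance_s <= 0) {
    cfg_stop("fusion.pairing_tolerance_s", "must be > 0")
  }
  if (fus$min_score < 0 || fus$min_score > 1) {
    cfg_stop("fusion.min_score", "must be in [0, 1]")
  }
  if (fus$hold_window_frames < 0) {
    cfg_stop("fusion.hold_window_frames", "must be >= 0")
  }
  build_supervisor(config) # constructs and validates both fuzzy levels
  invisible(config)
}
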