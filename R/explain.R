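#' Explain one paired frame
#'
#' Runs the per-frame pipeline on a single top/front record pair and
#' returns (and optionally prints) every intermediate quantity: assigned
#' hands, calibrated centroids, the crisp Dis/h inputs, fuzzification
#' degrees, rule activations at both cascade levels, and the crisp
#' outputs. Intended for debugging a rule table or calibration.
#'
#' @param top_record,front_record One \code{lapskill_record} each.
#' @param config Run configuration.
#' @param quiet If \code{TRUE}, do not print, just return.
#' @return Invisible list with \code{right}, \code{left} (per-hand input
#'   values, degrees, activations, crisp score), \code{final}, and
#'   \code{flags}.
#' @export
explain_frame <- function(top_record, front_record,
                          config = default_config(), quiet = FALSE) {
  stopifnot(inherits(top_record, "lapskill_record"),
            inherits(front_record, "lapskill_record"))
  supervisor <- build_supervisor(config)
  calib_top <- with(config$calibration$top,
                    camera_calibration(frame_width_px, frame_height_px,
                                       real_width_cm, real_height_cm))
  calib_front <- with(config$calibration$front,
                      camera_calibration(frame_width_px, frame_height_px,
                                         real_width_cm, real_height_cm))
  min_score <- config$fusion$min_score
  top_assign <- assign_hands(top_record$detections, min_score)
  front_assign <- assign_hands(front_record$detections, min_score)
  to_obs <- function(d, camera, hand, calib) {
    if (is.null(d)) return(NULL)
    instrument_observation(camera, hand, to_cm(d$centroid_px, calib),
                           d$score)
  }
  top_obs <- list(
    right = to_obs(top_assign$right, "top", "right", calib_top),
    left = to_obs(top_assign$left, "top", "left", calib_top))
  front_obs <- list(
    right = to_obs(front_assign$right, "front", "right", calib_front),
    left = to_obs(front_assign$left, "front", "left", calib_front))
  fr <- assess_frame(top_obs, front_obs, config, supervisor)

  fired_rules <- function(fis, fuzzified) {
    out <- character(0)
    for (r in fis$rules) {
      fire <- min(vapply(names(fis$inputs), function(v) {
        fuzzified[[v]][[r$antecedent[[v]]]]
      }, numeric(1L)))
      if (fire > 0) {
        out <- c(out, sprintf("%s -> %s (%.3f)",
                              paste(r$antecedent[names(fis$inputs)],
                                    collapse = " & "),
                              r$consequent, fire))
      }
    }
    out
  }
  res <- list(flags = fr$flags)
  for (side in c("right", "left")) {
    hs <- fr[[side]]
    if (is.null(hs)) { res[[side]] <- NULL; next }
    res[[side]] <- list(
      dis_cm = hs$inputs_used[["dis"]], h_cm = hs$inputs_used[["h"]],
      degrees = hs$fuzzified,
      fired = fired_rules(supervisor$level1, hs$fuzzified),
      activations = hs$activations,
      crisp = hs$crisp, letter = hs$letter,
      refuzzified = refuzzify(hs, supervisor))
  }
  if (!is.null(fr$final)) {
    fz2 <- list(right = res$right$refuzzified,
                left = res$left$refuzzified)
    res$final <- list(fired = fired_rules(supervisor$level2, fz2),
                      activations = fr$final$activations,
                      crisp = fr$final$crisp, letter = fr$final$letter)
  }
  if (!quiet) {
    for (side in c("right", "left")) {
      hs <- res[[side]]
      if (is.null(hs)) {
        cat(sprintf("%s hand: not assessable this frame\n", side))
        next
      }
      cat(sprintf("%s hand: Dis = %.2f cm, h = %.2f cm\n", side,
                  hs$dis_cm, hs$h_cm))
      for (v in names(hs$degrees)) {
        deg <- hs$degrees[[v]]
        cat(sprintf("  %s degrees: %s\n", v,
                    paste(sprintf("%s=%.3f", names(deg), deg),
                          collapse = ", ")))
      }
      for (fr_ln in hs$fired) cat("  rule ", fr_ln, "\n", sep = "")
      cat(sprintf("  crisp %.1f%% -> %s\n", hs$crisp, hs$letter))
    }
    if (!is.null(res$final)) {
      for (fr_ln in res$final$fired) {
        cat("final rule ", fr_ln, "\n", sep = "")
      }
      cat(sprintf("final: %.1f%% -> %s\n", res$final$crisp,
                  res$final$letter))
    }
    if (length(res$flags)) {
      cat("flags:", paste(res$flags, collapse = ", "), "\n")
    }
  }
  invisible(res)
}
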