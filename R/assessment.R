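#' First-level hand assessment (SRHPA / SLHPA)
#'
#' Runs the shared first-level MISO system on one hand's measurements:
#' distance from the field-of-interest centre (top camera, cm) and
#' instrument height (front camera, cm from the frame top). Left and right
#' hands are assessed by the identical variables and rule table; the
#' \code{hand} argument only tags the result.
#'
#' @param dis Distance to the field centre in cm (clamped to the universe).
#' @param h Front-view height in cm (clamped).
#' @param hand \code{"right"} or \code{"left"}.
#' @param supervisor A supervisor bundle from [build_supervisor()] (built
#'   from the default configuration if omitted).
#' @return List of class \code{lapskill_hand}: \code{hand}, \code{crisp}
#'   (per cent), \code{letter} (A-E), \code{inputs_used = c(dis, h)},
#'   \code{activations}.
#' @export
assess_hand <- function(dis, h, hand = c("right", "left"),
                        supervisor = build_supervisor()) {
  hand <- match.arg(hand)
  stopifnot(is.finite(dis), dis >= 0, is.finite(h))
  res <- fis_infer(supervisor$level1, list(distance = dis, height = h))
  structure(list(hand = hand, crisp = res$crisp, letter = res$letter,
                 inputs_used = c(dis = dis, h = h),
                 activations = res$activations,
                 fuzzified = res$fuzzified),
            class = "lapskill_hand")
}

#' @export
print.lapskill_hand <- function(x, ...) {
  cat(sprintf("<%s hand: %.1f%% (%s) at Dis = %.2f cm, h = %.2f cm>\n",
              x$hand, x$crisp, x$letter, x$inputs_used[["dis"]],
              x$inputs_used[["h"]]))
  invisible(x)
}

#' Refuzzify a first-level score for the second level
#'
#' The crisp SRHPA/SLHPA score (0-100%) is singleton-fuzzified on the
#' coarser three-label variable \{Bad, Good, Excellent\}, revising the
#' granulation for the final cascade stage.
#'
#' @param score A \code{lapskill_hand} result, or a bare crisp score.
#' @param supervisor Supervisor bundle (see [build_supervisor()]).
#' @return Named degree vector over \{Bad, Good, Excellent\}.
#' @export
refuzzify <- function(score, supervisor = build_supervisor()) {
  crisp <- if (inherits(score, "lapskill_hand")) score$crisp else score
  stopifnot(is.finite(crisp))
  fuzzify_singleton(supervisor$refuzz_var, crisp)
}

#' Second-level final assessment (FPA)
#'
#' Evaluates the second-level rule table on the refuzzified right- and
#' left-hand scores and defuzzifies to the final performance assessment.
#' The published table is asymmetric in the two hands and is applied as
#' encoded in the configuration.
#'
#' @param right,left Refuzzified degree vectors (from [refuzzify()]).
#' @param supervisor Supervisor bundle.
#' @return List of class \code{lapskill_final}: \code{crisp},
#'   \code{letter}, \code{activations}.
#' @export
assess_final <- function(right, left, supervisor = build_supervisor()) {
  fz <- list(right = right, left = left)
  act <- evaluate_rules(supervisor$level2, fz)
  crisp <- defuzzify(supervisor$level2$output, act, supervisor$method)
  structure(list(crisp = crisp,
                 letter = grade_letter(supervisor$level2$output, crisp),
                 activations = act),
            class = "lapskill_final")
}

#' @export
print.lapskill_final <- function(x, ...) {
  cat(sprintf("<final assessment: %.1f%% (%s)>\n", x$crisp, x$letter))
  invisible(x)
}

#' Assess one paired frame
#'
#' The per-frame pipeline: top-camera centroids give each hand's distance
#' to the field centre, front-camera centroids give its height, both
#' first-level systems run, their scores are refuzzified, and the
#' second-level system produces the FPA.
#'
#' Missing detections follow the cascade's occlusion semantics:
#' \itemize{
#'   \item Hand absent from the FRONT view but present in the top view: the
#'     instrument has been lifted toward the top camera, out of the front
#'     camera's view, so its height is taken at the High-label prototype.
#'   \item Hand absent from the TOP view: its last known distance is held
#'     for up to \code{hold_window_frames} consecutive frames
#'     (\code{state} carries this memory between calls); beyond the window
#'     the frame is flagged-skipped for that hand, and with either hand
#'     unassessable the frame yields no FPA.
#' }
#'
#' @param top_obs,front_obs Named lists with optional elements
#'   \code{right} and \code{left}, each a \code{lapskill_obs} (cm
#'   coordinates), or \code{NULL} when the hand was not detected.
#' @param config Run configuration.
#' @param supervisor Prebuilt supervisor bundle (rebuilt from
#'   \code{config} if omitted).
#' @param state Hold-window memory from the previous frame's result
#'   (\code{NULL} at session start).
#' @return List of class \code{lapskill_frame}: per-hand assessments
#'   (\code{right}, \code{left}, possibly \code{NULL}), \code{final}
#'   (possibly \code{NULL}), \code{flags} (character), and \code{state}
#'   to pass to the next frame.
#' @export
assess_frame <- function(top_obs, front_obs, config = default_config(),
                         supervisor = build_supervisor(config),
                         state = NULL) {
  if (is.null(state)) {
    state <- list(right = list(dis = NA_real_, age = Inf),
                  left = list(dis = NA_real_, age = Inf))
  }
  field <- field_of_interest(config$field$center_cm,
                             config$field$front_field_band_cm)
  hold <- config$fusion$hold_window_frames
  high_proto <- label_peaks(supervisor$h_var)[["High"]]
  flags <- character(0)
  hands <- list(right = NULL, left = NULL)

  for (side in c("right", "left")) {
    t_obs <- top_obs[[side]]
    f_obs <- front_obs[[side]]
    dis <- NA_real_
    if (!is.null(t_obs)) {
      dis <- distance_to_field(t_obs$centroid_cm, field)
      state[[side]] <- list(dis = dis, age = 0)
    } else {
      state[[side]]$age <- state[[side]]$age + 1
      if (is.finite(state[[side]]$dis) && state[[side]]$age <= hold) {
        dis <- state[[side]]$dis
        flags <- c(flags, paste0(side, "_top_held"))
      } else {
        flags <- c(flags, paste0(side, "_skipped"))
      }
    }
    if (!is.na(dis)) {
      if (!is.null(f_obs)) {
        h <- height_from_front(f_obs)
      } else {
        # lifted out of the front view: infer the High region
        h <- high_proto
        flags <- c(flags, paste0(side, "_front_high_inferred"))
      }
      hands[[side]] <- assess_hand(dis, h, side, supervisor)
    }
  }

  final <- NULL
  if (!is.null(hands$right) && !is.null(hands$left)) {
    final <- assess_final(refuzzify(hands$right, supervisor),
                          refuzzify(hands$left, supervisor),
                          supervisor)
  } else {
    flags <- c(flags, "frame_skipped")
  }
  structure(list(right = hands$right, left = hands$left, final = final,
                 flags = unique(flags), state = state),
            class = "lapskill_frame")
}
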