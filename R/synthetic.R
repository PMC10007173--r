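#' Skill profile for the synthetic session generator
#'
#' Describes the stochastic hand kinematics and detection noise the
#' generator uses to emulate a box-trainer exercise. Each hand follows a
#' mean-reverting random walk (discrete Ornstein-Uhlenbeck) around its
#' mean position on the top-camera plane and its mean height on the
#' front-camera axis, interrupted by a two-state semi-Markov excursion
#' process: from calm, the hand enters an excursion with a per-frame
#' probability, drifts toward a Far (board edge) or High (lifted) target
#' for a geometrically distributed dwell, then reverts.
#'
#' @param name Profile name.
#' @param right,left Per-hand kinematics, lists as built by [hand_dynamics()].
#' @param centroid_jitter_px Detection-noise sd of the reported bounding-box
#'   centre, in pixels.
#' @param score_mean Mean detection confidence (Beta-distributed scores).
#' @param false_negative_rate Per-camera, per-frame probability of missing
#'   a detection outright.
#' @param occlusion_prob Probability that a front detection is dropped
#'   while the hand's true height is in the High band (lifted close to the
#'   top camera and out of the front camera's view).
#' @param box_w_px,box_h_px Nominal bounding-box size in pixels.
#' @param size_jitter Relative sd of the box size.
#' @return List of class \code{lapskill_profile}.
#' @export
skill_profile <- function(name, right, left,
                          centroid_jitter_px = 3,
                          score_mean = 0.9,
                          false_negative_rate = 0.01,
                          occlusion_prob = 0.8,
                          box_w_px = 120, box_h_px = 60,
                          size_jitter = 0.1) {
  stopifnot(false_negative_rate >= 0, false_negative_rate <= 1,
            occlusion_prob >= 0, occlusion_prob <= 1,
            score_mean > 0, score_mean < 1,
            centroid_jitter_px >= 0, size_jitter >= 0,
            box_w_px > 0, box_h_px > 0)
  structure(list(name = name, right = right, left = left,
                 centroid_jitter_px = centroid_jitter_px,
                 score_mean = score_mean,
                 false_negative_rate = false_negative_rate,
                 occlusion_prob = occlusion_prob,
                 box_w_px = box_w_px, box_h_px = box_h_px,
                 size_jitter = size_jitter),
            class = "lapskill_profile")
}

#' @rdname skill_profile
#' @param mean_xy_cm Mean top-plane position, cm.
#' @param mean_h_cm Mean front-view height, cm (frame-top origin: smaller
#'   is physically higher).
#' @param sigma_cm,h_sigma_cm Per-frame innovation sd of the walk, cm.
#' @param reversion Mean-reversion rate per frame in \code{(0, 1]}.
#' @param excursion_prob Per-frame probability of starting an excursion
#'   while calm.
#' @param excursion_dwell Mean excursion length, frames (geometric).
#' @param far_target_xy_cm,high_target_h_cm Excursion targets.
#' @param far_weight Probability an excursion is a Far drift (otherwise a
#'   High lift).
#' @export
hand_dynamics <- function(mean_xy_cm, mean_h_cm, sigma_cm = 0.6,
                          h_sigma_cm = 0.4, reversion = 0.2,
                          excursion_prob = 0.005, excursion_dwell = 10,
                          far_target_xy_cm = c(38, 4),
                          high_target_h_cm = 1.5,
                          far_weight = 0.5) {
  stopifnot(excursion_prob >= 0, excursion_prob <= 1,
            far_weight >= 0, far_weight <= 1,
            sigma_cm >= 0, h_sigma_cm >= 0,
            reversion > 0, reversion <= 1, excursion_dwell >= 1)
  list(mean_xy_cm = as.numeric(mean_xy_cm), mean_h_cm = mean_h_cm,
       sigma_cm = sigma_cm, h_sigma_cm = h_sigma_cm,
       reversion = reversion, excursion_prob = excursion_prob,
       excursion_dwell = excursion_dwell,
       far_target_xy_cm = as.numeric(far_target_xy_cm),
       high_target_h_cm = high_target_h_cm, far_weight = far_weight)
}

#' Built-in skill profiles
#'
#' Three canned profiles spanning the skill range the supervisor is meant
#' to separate. The expert keeps both instruments near the
#' field-of-interest centre at working height with rare, short excursions;
#' the novice sits about 6 cm off-centre with frequent long drifts to the
#' board edge and lifts into the High band (which usually hide the
#' instrument from the front camera); the intermediate lies between.
#' Positions are relative to the default calibration (40 x 22.5 cm top
#' frame, field centre at its middle).
#'
#' @return A \code{lapskill_profile}.
#' @export
expert_profile <- function() {
  skill_profile(
    "expert",
    right = hand_dynamics(c(22, 11.25), 11.25, sigma_cm = 0.6,
                          excursion_prob = 0.005, excursion_dwell = 10),
    left = hand_dynamics(c(18, 11.25), 11.25, sigma_cm = 0.6,
                         excursion_prob = 0.005, excursion_dwell = 10,
                         far_target_xy_cm = c(2, 4)),
    false_negative_rate = 0.01, score_mean = 0.92)
}

#' @rdname expert_profile
#' @export
intermediate_profile <- function() {
  skill_profile(
    "intermediate",
    right = hand_dynamics(c(24, 12), 12, sigma_cm = 1.0,
                          excursion_prob = 0.02, excursion_dwell = 15),
    left = hand_dynamics(c(16, 12), 12, sigma_cm = 1.0,
                         excursion_prob = 0.02, excursion_dwell = 15,
                         far_target_xy_cm = c(2, 4)),
    false_negative_rate = 0.02, score_mean = 0.85)
}

#' @rdname expert_profile
#' @export
novice_profile <- function() {
  skill_profile(
    "novice",
    right = hand_dynamics(c(26, 13), 13, sigma_cm = 1.5,
                          excursion_prob = 0.05, excursion_dwell = 20),
    left = hand_dynamics(c(14, 13), 13, sigma_cm = 1.5,
                         excursion_prob = 0.05, excursion_dwell = 20,
                         far_target_xy_cm = c(2, 4)),
    false_negative_rate = 0.05, score_mean = 0.75)
}

# h below which the High label dominates its falling edge (membership >
# 0.5): the generator's occlusion band.
high_band_threshold <- function(h_var) {
  mf <- h_var$labels[["High"]]
  bp <- mf$breakpoints
  peak <- mf_peak(mf)
  foot <- bp[length(bp)]
  peak + 0.5 * (foot - peak)
}

#' Simulate a dual-camera detection session
#'
#' Generates synchronized top- and front-camera detection streams for a
#' skill profile, plus a ground-truth sidecar. Hand positions follow the
#' profile's mean-reverting walk with semi-Markov excursions; true
#' positions are projected to each camera through the configuration's
#' calibration and emitted as bounding boxes with detection noise
#' (centroid jitter, Beta-distributed scores, false negatives). Front
#' detections are dropped with the profile's occlusion probability
#' whenever the true height is in the High band, emulating an instrument
#' lifted out of the front camera's view.
#'
#' @param profile A \code{lapskill_profile}.
#' @param n_frames Number of frames (> 0).
#' @param fps Frame rate (default 30).
#' @param seed Integer seed; fixed seed gives byte-identical streams.
#' @param config Run configuration (calibration and fuzzy geometry).
#' @return List with \code{top} and \code{front} (lists of
#'   \code{lapskill_record}s) and \code{truth}, a data.frame with one row
#'   per frame and hand: true \code{dis_cm}, \code{h_cm}, and the
#'   \code{occluded_front}, \code{dropped_top}, \code{dropped_front}
#'   flags.
#' @export
simulate_session <- function(profile, n_frames, fps = 30, seed = 1,
                             config = default_config()) {
  stopifnot(inherits(profile, "lapskill_profile"),
            n_frames > 0, fps > 0)
  set.seed(seed)
  supervisor <- build_supervisor(config)
  calib_top <- with(config$calibration$top,
                    camera_calibration(frame_width_px, frame_height_px,
                                       real_width_cm, real_height_cm))
  calib_front <- with(config$calibration$front,
                      camera_calibration(frame_width_px, frame_height_px,
                                         real_width_cm, real_height_cm))
  field <- field_of_interest(config$field$center_cm,
                             config$field$front_field_band_cm)
  h_high_band <- high_band_threshold(supervisor$h_var)
  top_w <- config$calibration$top$real_width_cm
  top_h <- config$calibration$top$real_height_cm
  front_h <- config$calibration$front$real_height_cm

  sim_hand <- function(dyn) {
    xy <- matrix(NA_real_, n_frames, 2L)
    hh <- numeric(n_frames)
    pos <- dyn$mean_xy_cm
    h <- dyn$mean_h_cm
    exc <- "calm"; exc_left <- 0L; exc_kind <- "far"
    for (t in seq_len(n_frames)) {
      if (exc == "calm") {
        if (stats::runif(1) < dyn$excursion_prob) {
          exc <- "excursion"
          exc_kind <- if (stats::runif(1) < dyn$far_weight) "far"
                      else "high"
          exc_left <- 1L + stats::rgeom(1, 1 / dyn$excursion_dwell)
        }
      } else {
        exc_left <- exc_left - 1L
        if (exc_left <= 0L) exc <- "calm"
      }
      tgt_xy <- dyn$mean_xy_cm
      tgt_h <- dyn$mean_h_cm
      if (exc == "excursion") {
        if (exc_kind == "far") tgt_xy <- dyn$far_target_xy_cm
        else tgt_h <- dyn$high_target_h_cm
      }
      # excursions revert faster toward their target so short dwells
      # actually reach the Far/High regions
      th <- if (exc == "excursion") min(1, 2 * dyn$reversion)
            else dyn$reversion
      pos <- pos + th * (tgt_xy - pos) +
        stats::rnorm(2L, 0, dyn$sigma_cm)
      h <- h + th * (tgt_h - h) + stats::rnorm(1L, 0, dyn$h_sigma_cm)
      pos[1L] <- min(max(pos[1L], 0), top_w)
      pos[2L] <- min(max(pos[2L], 0), top_h)
      h <- min(max(h, 0), front_h)
      xy[t, ] <- pos
      hh[t] <- h
    }
    list(xy = xy, h = hh)
  }

  paths <- list(right = sim_hand(profile$right),
                left = sim_hand(profile$left))

  make_bbox <- function(center_px, w, h_box, frame_w, frame_h) {
    cx <- min(max(center_px[1L], w / 2), frame_w - w / 2)
    cy <- min(max(center_px[2L], h_box / 2), frame_h - h_box / 2)
    round(c(cx - w / 2, cy - h_box / 2, cx + w / 2, cy + h_box / 2), 1)
  }
  score_draw <- function() {
    k <- 40
    round(stats::rbeta(1, profile$score_mean * k,
                       (1 - profile$score_mean) * k), 3)
  }

  top_records <- vector("list", n_frames)
  front_records <- vector("list", n_frames)
  n_truth <- 2L * n_frames
  tr_frame <- integer(n_truth); tr_ts <- numeric(n_truth)
  tr_hand <- character(n_truth); tr_dis <- numeric(n_truth)
  tr_h <- numeric(n_truth); tr_occ <- logical(n_truth)
  tr_dt <- logical(n_truth); tr_df <- logical(n_truth)
  fw_t <- config$calibration$top$frame_width_px
  fh_t <- config$calibration$top$frame_height_px
  fw_f <- config$calibration$front$frame_width_px
  fh_f <- config$calibration$front$frame_height_px

  for (t in seq_len(n_frames)) {
    ts <- round((t - 1L) / fps, 5)
    top_dets <- list(); front_dets <- list()
    for (side in c("right", "left")) {
      xy <- paths[[side]]$xy[t, ]
      h <- paths[[side]]$h[t]
      dis <- distance_to_field(xy, field)
      in_high <- h <= h_high_band
      occluded <- in_high && stats::runif(1) < profile$occlusion_prob
      drop_top <- stats::runif(1) < profile$false_negative_rate
      drop_front <- !occluded &&
        stats::runif(1) < profile$false_negative_rate
      # box grows as the instrument nears the top camera (small h)
      size_gain <- 1 + 0.6 * max(0, (front_h / 2 - h) / (front_h / 2))
      jit <- function() stats::rnorm(1, 0, profile$centroid_jitter_px)
      if (!drop_top) {
        ctr <- to_px(xy, calib_top) + c(jit(), jit())
        w <- profile$box_w_px * size_gain *
          (1 + stats::rnorm(1, 0, profile$size_jitter))
        hb <- profile$box_h_px * size_gain *
          (1 + stats::rnorm(1, 0, profile$size_jitter))
        top_dets[[length(top_dets) + 1L]] <-
          list(label = paste0(side, "_grasper"), score = score_draw(),
               bbox = make_bbox(ctr, max(10, w), max(10, hb), fw_t, fh_t))
      }
      if (!occluded && !drop_front) {
        ctr <- to_px(c(xy[1L], h), calib_front) + c(jit(), jit())
        w <- profile$box_w_px *
          (1 + stats::rnorm(1, 0, profile$size_jitter))
        hb <- profile$box_h_px *
          (1 + stats::rnorm(1, 0, profile$size_jitter))
        front_dets[[length(front_dets) + 1L]] <-
          list(label = paste0(side, "_grasper"), score = score_draw(),
               bbox = make_bbox(ctr, max(10, w), max(10, hb), fw_f, fh_f))
      }
      ti <- 2L * (t - 1L) + (side == "left") + 1L
      tr_frame[ti] <- t - 1L; tr_ts[ti] <- ts; tr_hand[ti] <- side
      tr_dis[ti] <- dis; tr_h[ti] <- h; tr_occ[ti] <- occluded
      tr_dt[ti] <- drop_top; tr_df[ti] <- drop_front
    }
    top_records[[t]] <- detection_record("top", t - 1L, ts, top_dets)
    front_records[[t]] <- detection_record("front", t - 1L, ts, front_dets)
  }
  list(top = top_records, front = front_records,
       truth = data.frame(frame_index = tr_frame, timestamp = tr_ts,
                          hand = tr_hand, dis_cm = tr_dis, h_cm = tr_h,
                          occluded_front = tr_occ, dropped_top = tr_dt,
                          dropped_front = tr_df,
                          stringsAsFactors = FALSE))
}

#' Paths of the packaged demo fixtures
#'
#' Small pre-generated sessions (60 frames at 30 FPS) for the three
#' built-in profiles, shipped as JSON Lines streams with ground-truth
#' sidecars and the session summaries the assessor produced for them.
#' They are regenerated verbatim by [generate_fixture_files()] with the
#' documented seeds (expert 101, intermediate 102, novice 103).
#'
#' @return Named list (one per profile) of lists with elements
#'   \code{top}, \code{front}, \code{truth}, \code{summary} (file paths).
#' @export
packaged_fixtures <- function() {
  base <- system.file("extdata", "fixtures", package = "lapskill")
  out <- list()
  for (p in c("expert", "intermediate", "novice")) {
    out[[p]] <- list(
      top = file.path(base, paste0(p, "_top.jsonl")),
      front = file.path(base, paste0(p, "_front.jsonl")),
      truth = file.path(base, paste0(p, "_truth.csv")),
      summary = file.path(base, paste0(p, "_summary.json")))
  }
  out
}

#' Generate fixture files for the built-in profiles
#'
#' Writes, per profile, the two detection streams (JSON Lines), the
#' ground-truth sidecar (CSV) and the assessor's summary (JSON) to
#' \code{dir}. Used to (re)create the packaged fixtures.
#'
#' @param dir Output directory.
#' @param n_frames Frames per session (default 60).
#' @param seeds Named integer seeds per profile.
#' @param config Run configuration.
#' @return Invisible list of written paths per profile.
#' @export
generate_fixture_files <- function(dir, n_frames = 60,
                                   seeds = c(expert = 101,
                                             intermediate = 102,
                                             novice = 103),
                                   config = default_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- list(expert = expert_profile(),
                   intermediate = intermediate_profile(),
                   novice = novice_profile())
  out <- list()
  for (p in names(profiles)) {
    sim <- simulate_session(profiles[[p]], n_frames = n_frames,
                            seed = seeds[[p]], config = config)
    paths <- list(
      top = file.path(dir, paste0(p, "_top.jsonl")),
      front = file.path(dir, paste0(p, "_front.jsonl")),
      truth = file.path(dir, paste0(p, "_truth.csv")),
      summary = file.path(dir, paste0(p, "_summary.json")))
    write_detection_stream(sim$top, paths$top)
    write_detection_stream(sim$front, paths$front)
    utils::write.csv(sim$truth, paths$truth, row.names = FALSE)
    res <- run_session(sim$top, sim$front, config)
    jsonlite::write_json(res$summary, paths$summary, auto_unbox = TRUE,
                         digits = I(10), pretty = TRUE)
    out[[p]] <- paths
  }
  invisible(out)
}
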