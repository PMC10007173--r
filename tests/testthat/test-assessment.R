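test_that("first-level rule table reproduces the printed letter grades", {
  # label-prototype inputs must yield exactly the published letter for
  # BOTH hands (18 assertions)
  for (i in seq_len(nrow(table3))) {
    dis <- dis_peaks[[table3$distance[i]]]
    h <- h_peaks[[table3$height[i]]]
    for (side in c("right", "left")) {
      got <- assess_hand(dis, h, side, default_sup)
      expect_identical(got$letter, table3$grade[i],
                       label = sprintf("(%s, %s, %s)", table3$distance[i],
                                       table3$height[i], side))
    }
  }
})

test_that("second-level rule table reproduces the printed letter grades", {
  for (i in seq_len(nrow(table4))) {
    got <- assess_final(refuzz_singleton(table4$right[i]),
                        refuzz_singleton(table4$left[i]), default_sup)
    expect_identical(got$letter, table4$grade[i],
                     label = sprintf("(R=%s, L=%s)", table4$right[i],
                                     table4$left[i]))
  }
  # the published table is asymmetric in the hands and must stay so
  gb <- assess_final(refuzz_singleton("Good"), refuzz_singleton("Bad"),
                     default_sup)
  bg <- assess_final(refuzz_singleton("Bad"), refuzz_singleton("Good"),
                     default_sup)
  expect_identical(gb$letter, "E")
  expect_identical(bg$letter, "D")
})

test_that("left and right hands are assessed identically", {
  set.seed(47)
  for (i in 1:200) {
    dis <- stats::runif(1, 0, 25)
    h <- stats::runif(1, 0, 24)
    r <- assess_hand(dis, h, "right", default_sup)
    l <- assess_hand(dis, h, "left", default_sup)
    expect_identical(r$crisp, l$crisp)
    expect_identical(r$letter, l$letter)
  }
})

test_that("refuzzification revises the granulation to three labels", {
  rv <- default_sup$refuzz_var
  peaks <- label_peaks(rv)
  expect_named(fuzzify_singleton(rv, 50),
               c("Bad", "Good", "Excellent"))
  expect_equal(refuzzify(peaks[["Excellent"]], default_sup),
               c(Bad = 0, Good = 0, Excellent = 1))
  # crisp 0 is Bad-dominant
  d0 <- refuzzify(0, default_sup)
  expect_identical(names(which.max(d0)), "Bad")
  # at the Good/Bad crossover the two degrees are equal
  cross <- 30 # Bad falls 10->50 while Good rises 10->50
  dc <- refuzzify(cross, default_sup)
  expect_equal(dc[["Bad"]], dc[["Good"]])
  # a first-level A-prototype score refuzzifies to pure Excellent,
  # E-prototype to pure Bad (the cascade's composition contract)
  a_score <- assess_hand(dis_peaks[["Close"]], h_peaks[["Field"]],
                         "right", default_sup)
  expect_equal(refuzzify(a_score, default_sup),
               c(Bad = 0, Good = 0, Excellent = 1))
})

test_that("hand scores fall monotonically with distance at Field height", {
  set.seed(51)
  dists <- sort(stats::runif(300, 0, 23))
  crisps <- vapply(dists, function(d) {
    assess_hand(d, h_peaks[["Field"]], "right", default_sup)$crisp
  }, numeric(1L))
  expect_true(all(diff(crisps) <= 1e-9))
})

test_that("crisp outputs stay within 0-100 over the input space", {
  set.seed(53)
  for (i in 1:100) {
    hs <- assess_hand(stats::runif(1, 0, 40), stats::runif(1, -5, 30),
                      "right", default_sup)
    expect_gte(hs$crisp, 0); expect_lte(hs$crisp, 100)
    fin <- assess_final(refuzzify(hs, default_sup),
                        refuzzify(stats::runif(1, 0, 100), default_sup),
                        default_sup)
    expect_gte(fin$crisp, 0); expect_lte(fin$crisp, 100)
  }
})

test_that("symmetrized second level restores hand-exchange symmetry and monotonicity", {
  cfg <- default_config()
  cfg$fuzzy$symmetrize_level2 <- TRUE
  sup <- build_supervisor(cfg)
  # exact monotonicity at the label prototypes (the rule-grid ordering)
  protos <- c(Bad = 10, Good = 50, Excellent = 90)
  grid <- outer(protos, protos, Vectorize(function(a, b) {
    assess_final(refuzzify(a, sup), refuzzify(b, sup), sup)$crisp
  }))
  expect_true(all(diff(grid) >= 0))     # right hand improves down rows
  expect_true(all(diff(t(grid)) >= 0))  # left hand improves down cols
  set.seed(59)
  # profiles the cascade actually produces: singleton refuzzifications of
  # a crisp first-level score; "improving" a hand = raising that score.
  # Mamdani max-aggregation is only approximately monotone between
  # prototypes (see the vignette); dips stay under 2 percentage points.
  for (i in 1:50) {
    s_r <- stats::runif(1, 10, 90); s_l <- stats::runif(1, 10, 90)
    r <- refuzzify(s_r, sup); l <- refuzzify(s_l, sup)
    base <- assess_final(r, l, sup)$crisp
    expect_equal(assess_final(l, r, sup)$crisp, base) # hand exchange
    d_r <- stats::runif(1, 0, 90 - s_r)
    d_l <- stats::runif(1, 0, 90 - s_l)
    expect_gte(assess_final(refuzzify(s_r + d_r, sup), l, sup)$crisp,
               base - 2)
    expect_gte(assess_final(r, refuzzify(s_l + d_l, sup), sup)$crisp,
               base - 2)
  }
})

test_that("the published second-level table is non-monotone in a hand's score", {
  # With the rule table encoded verbatim, Good x Bad -> E grades worse
  # than Bad x Bad -> D, so raising the right hand's score from the
  # E prototype to the D prototype while the left hand stays at E
  # LOWERS the final score. This documents the published behaviour; the
  # symmetrize_level2 switch removes it.
  low <- assess_final(refuzzify(10, default_sup),
                      refuzzify(10, default_sup), default_sup)$crisp
  dipped <- assess_final(refuzzify(30, default_sup),
                         refuzzify(10, default_sup), default_sup)$crisp
  expect_lt(dipped, low)
})

test_that("per-frame assessment handles missing detections", {
  cfg <- default_config()
  sup <- build_supervisor(cfg)
  mk_obs <- function(camera, hand, xy) {
    instrument_observation(camera, hand, xy)
  }
  ctr <- cfg$field$center_cm
  field_h <- h_peaks[["Field"]]
  both_top <- list(right = mk_obs("top", "right", ctr),
                   left = mk_obs("top", "left", ctr))
  both_front <- list(right = mk_obs("front", "right", c(22, field_h)),
                     left = mk_obs("front", "left", c(18, field_h)))
  # full frame at the (Close, Field) prototypes -> FPA letter A
  fr <- assess_frame(both_top, both_front, cfg, sup)
  expect_identical(fr$final$letter, "A")
  expect_identical(fr$right$letter, "A")

  # left missing from the front view at Middle distance -> inferred High
  # -> letter E for that hand
  mid_pt <- ctr + c(dis_peaks[["Middle"]], 0)
  top2 <- list(right = mk_obs("top", "right", ctr),
               left = mk_obs("top", "left", mid_pt))
  front2 <- list(right = mk_obs("front", "right", c(22, field_h)),
                 left = NULL)
  fr2 <- assess_frame(top2, front2, cfg, sup)
  expect_identical(fr2$left$letter, "E")
  expect_equal(fr2$left$inputs_used[["h"]], h_peaks[["High"]])
  expect_true("left_front_high_inferred" %in% fr2$flags)

  # hand missing from the top view: last distance is held for the window,
  # then the hand (and frame) is flagged-skipped
  hold <- cfg$fusion$hold_window_frames
  st <- fr$state
  for (k in seq_len(hold)) {
    frk <- assess_frame(list(right = NULL, left = both_top$left),
                        both_front, cfg, sup, st)
    st <- frk$state
    expect_false(is.null(frk$right))
    expect_true("right_top_held" %in% frk$flags)
  }
  fr_beyond <- assess_frame(list(right = NULL, left = both_top$left),
                            both_front, cfg, sup, st)
  expect_null(fr_beyond$right)
  expect_null(fr_beyond$final)
  expect_true(all(c("right_skipped", "frame_skipped") %in%
                    fr_beyond$flags))

  # no detections at all -> flagged-skip record
  fr_none <- assess_frame(list(right = NULL, left = NULL),
                          list(right = NULL, left = NULL), cfg, sup)
  expect_null(fr_none$final)
  expect_true("frame_skipped" %in% fr_none$flags)
})
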