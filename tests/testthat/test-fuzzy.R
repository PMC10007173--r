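test_that("membership functions evaluate piecewise-linearly", {
  tri <- mf_triangular(0, 5, 10)
  expect_equal(membership_degree(tri, 5), 1)
  expect_equal(membership_degree(tri, 12), 0)
  expect_equal(membership_degree(tri, -1), 0)
  expect_equal(membership_degree(tri, 2.5), 0.5)
  expect_equal(membership_degree(tri, 7.5), 0.5)
  trap <- mf_trapezoidal(0, 2, 8, 10)
  expect_equal(membership_degree(trap, c(1, 2, 5, 8, 9)),
               c(0.5, 1, 1, 1, 0.5))
  # degenerate sides give shoulders with full membership at the boundary
  sh <- mf_triangular(0, 0, 10)
  expect_equal(membership_degree(sh, c(0, 5, 10)), c(1, 0.5, 0))
})

test_that("malformed membership functions are rejected", {
  expect_error(mf_triangular(5, 1, 10), "non-decreasing")
  expect_error(mf_trapezoidal(0, 5, 2, 10), "non-decreasing")
  expect_error(mf_triangular(0, NA, 10), "finite")
  expect_error(membership_degree(mf_triangular(0, 5, 10), Inf), "finite")
})

test_that("membership degrees stay in [0, 1] for random MFs", {
  set.seed(11)
  for (i in 1:200) {
    bp <- sort(stats::runif(sample(3:4, 1L), -50, 50))
    mf <- if (length(bp) == 3L) mf_triangular(bp[1], bp[2], bp[3])
          else mf_trapezoidal(bp[1], bp[2], bp[3], bp[4])
    x <- stats::runif(20, -100, 100)
    deg <- membership_degree(mf, x)
    expect_true(all(deg >= 0 & deg <= 1))
    expect_equal(membership_degree(mf, mf_peak(mf)), 1)
  }
})

test_that("linguistic variables enforce support and completeness", {
  lab <- list(Lo = mf_triangular(0, 0, 6), Hi = mf_triangular(4, 10, 10))
  v <- linguistic_variable("v", c(0, 10), lab, complete = TRUE)
  expect_s3_class(v, "lapskill_lv")
  expect_error(
    linguistic_variable("v", c(0, 5), lab),
    "support outside")
  gap <- list(Lo = mf_triangular(0, 0, 3), Hi = mf_triangular(7, 10, 10))
  expect_error(linguistic_variable("v", c(0, 10), gap), "incomplete")
})

test_that("singleton fuzzification reads degrees and clamps", {
  v <- default_sup$dis_var
  expect_equal(fuzzify_singleton(v, dis_peaks[["Close"]]),
               c(Close = 1, Middle = 0, Far = 0))
  # midway in the 50% Close/Middle overlap
  mid <- (dis_peaks[["Close"]] + dis_peaks[["Middle"]]) / 2
  expect_equal(fuzzify_singleton(v, mid),
               c(Close = 0.5, Middle = 0.5, Far = 0))
  # out-of-universe input is clamped to the bound
  expect_equal(fuzzify_singleton(v, 1e6),
               fuzzify_singleton(v, v$universe[2L]))
  expect_equal(fuzzify_singleton(v, -5), fuzzify_singleton(v, 0))
})

test_that("rule evaluation follows min/max Mamdani semantics", {
  sys <- default_sup$level1
  fz_proto <- list(distance = c(Close = 1, Middle = 0, Far = 0),
                   height = c(High = 0, Field = 1, Down = 0))
  act <- evaluate_rules(sys, fz_proto)
  expect_equal(act[["A"]], 1)
  expect_equal(sum(act), 1)
  # all-zero degrees fire nothing
  fz0 <- list(distance = c(Close = 0, Middle = 0, Far = 0),
              height = c(High = 0, Field = 0, Down = 0))
  expect_true(all(evaluate_rules(sys, fz0) == 0))
  # hand-evaluated min/max over the 9 first-level rules:
  # (Close .6, Middle .4) x (Field 1) fires Close&Field->A at .6 and
  # Middle&Field->B at .4; nothing else is active
  fz <- list(distance = c(Close = 0.6, Middle = 0.4, Far = 0),
             height = c(High = 0, Field = 1, Down = 0))
  act <- evaluate_rules(sys, fz)
  expect_equal(act[["A"]], 0.6)
  expect_equal(act[["B"]], 0.4)
  expect_equal(act[["C"]], 0)
  expect_error(evaluate_rules(sys, fz["distance"]), "missing")
})

test_that("rule evaluation is monotone in antecedent degrees", {
  set.seed(13)
  sys <- default_sup$level1
  for (i in 1:100) {
    d1 <- stats::runif(3); d2 <- stats::runif(3)
    fz <- list(distance = stats::setNames(d1, c("Close", "Middle", "Far")),
               height = stats::setNames(d2, c("High", "Field", "Down")))
    act <- evaluate_rules(sys, fz)
    # raise one random degree; no activation may drop
    which_var <- sample(c("distance", "height"), 1L)
    which_lab <- sample(names(fz[[which_var]]), 1L)
    fz2 <- fz
    fz2[[which_var]][which_lab] <-
      min(1, fz2[[which_var]][which_lab] + stats::runif(1))
    act2 <- evaluate_rules(sys, fz2)
    expect_true(all(act2 >= act - 1e-12))
  }
})

test_that("rule bases must cover the label cross-product exactly once", {
  sys <- default_sup$level1
  expect_length(sys$rules, 9L)
  expect_error(
    mamdani_system(sys$inputs, sys$output, sys$rules[-1L]),
    "exactly once")
  expect_error(
    mamdani_system(sys$inputs, sys$output,
                   c(sys$rules[-1L], sys$rules[2L])),
    "duplicate")
})

test_that("defuzzification methods agree with their contracts", {
  out <- default_sup$level1$output
  peaks <- label_peaks(out)
  one <- stats::setNames(numeric(length(peaks)), names(peaks))
  # single fully-active label with symmetric MF -> its peak, both methods
  for (lab in c("C")) { # C is the interior symmetric label peaked at 50
    act <- one; act[lab] <- 1
    expect_equal(defuzzify(out, act, "center_of_average"), 50)
    expect_equal(defuzzify(out, act, "center_of_gravity"), 50,
                 tolerance = 1e-9)
  }
  # two labels with peaks 30 and 70, equal activations -> midpoint 50
  act <- one; act[c("D", "B")] <- 0.5
  expect_equal(defuzzify(out, act, "center_of_average"), 50)
  expect_error(defuzzify(out, one), "no rule fired")
})

test_that("center of gravity matches a fine-grid centroid oracle", {
  set.seed(17)
  worst <- 0
  for (i in 1:100) {
    var <- random_output_variable()
    act <- stats::setNames(stats::runif(length(var$labels), 0.05, 1),
                           names(var$labels))
    got <- defuzzify(var, act, "center_of_gravity")
    oracle <- cog_grid_oracle(var, as.list(act))
    worst <- max(worst, abs(got - oracle) / abs(oracle))
  }
  expect_lt(worst, 1e-6)
})

test_that("defuzzified values stay inside the output universe", {
  set.seed(19)
  for (i in 1:50) {
    var <- random_output_variable()
    act <- stats::setNames(stats::runif(length(var$labels)),
                           names(var$labels))
    if (all(act <= 0)) act[1L] <- 0.5
    for (m in c("center_of_average", "center_of_gravity")) {
      crisp <- defuzzify(var, act, m)
      expect_gte(crisp, var$universe[1L])
      expect_lte(crisp, var$universe[2L])
    }
  }
})

test_that("a single full activation defuzzifies onto its own label", {
  set.seed(23)
  out <- default_sup$level1$output
  for (lab in names(out$labels)) {
    act <- stats::setNames(numeric(length(out$labels)),
                           names(out$labels))
    act[lab] <- 1
    for (m in c("center_of_average", "center_of_gravity")) {
      crisp <- defuzzify(out, act, m)
      expect_identical(grade_letter(out, crisp), lab)
    }
  }
})

test_that("letter grading breaks ties toward the worse grade", {
  out <- default_sup$level1$output
  expect_identical(grade_letter(out, 90), "A")
  expect_identical(grade_letter(out, 10), "E")
  # exactly at the A/B crossover (80): conservative tie-break -> B
  expect_identical(grade_letter(out, 80), "B")
  expect_identical(grade_letter(out, 20), "E")
})
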