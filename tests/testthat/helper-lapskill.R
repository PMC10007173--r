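# Shared fixtures, built in code.

default_sup <- build_supervisor()
dis_peaks <- label_peaks(default_sup$dis_var)
h_peaks <- label_peaks(default_sup$h_var)

# published first-level rule table: rows = height region, cols = distance
table3 <- rbind(
  data.frame(height = "High", distance = c("Close", "Middle", "Far"),
             grade = c("B", "E", "E")),
  data.frame(height = "Field", distance = c("Close", "Middle", "Far"),
             grade = c("A", "B", "C")),
  data.frame(height = "Down", distance = c("Close", "Middle", "Far"),
             grade = c("B", "B", "D")))

# published second-level table: rows = right (SRHPAr), cols = left (SLHPAr)
table4 <- rbind(
  data.frame(right = "Excellent", left = c("Excellent", "Good", "Bad"),
             grade = c("A", "B", "C")),
  data.frame(right = "Good", left = c("Excellent", "Good", "Bad"),
             grade = c("B", "C", "E")),
  data.frame(right = "Bad", left = c("Excellent", "Good", "Bad"),
             grade = c("C", "D", "D")))

refuzz_singleton <- function(label) {
  d <- c(Bad = 0, Good = 0, Excellent = 0)
  d[label] <- 1
  d
}

# independent fine-grid centroid oracle: discrete weighted-sum centroid of
# the min-clipped, max-aggregated output set on a uniform grid
cog_grid_oracle <- function(var, activations, n = 200001L) {
  xs <- seq(var$universe[1L], var$universe[2L], length.out = n)
  mu <- rep(0, n)
  for (lab in names(var$labels)) {
    mu <- pmax(mu, pmin(activations[[lab]],
                        membership_degree(var$labels[[lab]], xs)))
  }
  sum(mu * xs) / sum(mu)
}

# random fully-overlapping triangular output variable over [0, 100]
random_output_variable <- function(n_labels = sample(3:5, 1L)) {
  lo <- 0; hi <- 100
  peaks <- sort(stats::runif(n_labels, lo, hi))
  labels <- list()
  for (k in seq_len(n_labels)) {
    a <- if (k == 1L) lo else peaks[k - 1L]
    d <- if (k == n_labels) hi else peaks[k + 1L]
    labels[[paste0("L", k)]] <- mf_triangular(a, peaks[k], d)
  }
  linguistic_variable("out", c(lo, hi), labels, complete = FALSE)
}

# noise-free profile pinned to given prototypes (both hands identical
# dynamics unless overridden)
pinned_profile <- function(xy = c(20, 11.25), h = 11.25,
                           left_xy = xy, left_h = h,
                           occlusion_prob = 0, sigma = 0) {
  eps <- 1e-9 # reversion > 0 required; sigma may be exactly 0
  mk <- function(p, hh) hand_dynamics(p, hh, sigma_cm = sigma,
                                      h_sigma_cm = sigma,
                                      excursion_prob = 0,
                                      reversion = 1)
  skill_profile("pinned", right = mk(xy, h), left = mk(left_xy, left_h),
                centroid_jitter_px = 0, score_mean = 0.95,
                false_negative_rate = 0, occlusion_prob = occlusion_prob,
                size_jitter = 0)
}
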