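#' Triangular membership function
#'
#' A piecewise-linear membership function rising from \code{a} to a peak at
#' \code{b} and falling back to zero at \code{c}. Degenerate sides are
#' allowed (\code{a == b} or \code{b == c}) and produce a shoulder: the
#' membership is 1 at the peak and the vertical side is treated as part of
#' the support boundary, so e.g. \code{mf_triangular(0, 0, 10)} is 1 at 0.
#'
#' @param a,b,c Non-decreasing breakpoints (left foot, peak, right foot), in
#'   the units of the variable's universe.
#' @return An object of class \code{lapskill_mf}.
#' @examples
#' mf <- mf_triangular(0, 5, 10)
#' membership_degree(mf, 2.5) # 0.5
#' @export
mf_triangular <- function(a, b, c) {
  new_mf("triangular", c(a, b, c))
}

#' Trapezoidal membership function
#'
#' Rises from \code{a} to 1 at \code{b}, stays 1 on the plateau
#' \code{[b, c]}, and falls to zero at \code{d}.
#'
#' @param a,b,c,d Non-decreasing breakpoints (left foot, plateau start,
#'   plateau end, right foot).
#' @return An object of class \code{lapskill_mf}.
#' @export
mf_trapezoidal <- function(a, b, c, d) {
  new_mf("trapezoidal", c(a, b, c, d))
}

new_mf <- function(shape, breakpoints) {
  shape <- match.arg(shape, c("triangular", "trapezoidal"))
  n_expected <- if (shape == "triangular") 3L else 4L
  if (length(breakpoints) != n_expected || !is.numeric(breakpoints) ||
      any(!is.finite(breakpoints))) {
    stop("a ", shape, " membership function needs ", n_expected,
         " finite breakpoints", call. = FALSE)
  }
  breakpoints <- as.numeric(breakpoints)
  if (is.unsorted(breakpoints)) {
    stop("membership-function breakpoints must be non-decreasing: ",
         paste(breakpoints, collapse = ", "), call. = FALSE)
  }
  structure(list(shape = shape, breakpoints = breakpoints),
            class = "lapskill_mf")
}

#' Evaluate a membership function
#'
#' Piecewise-linear evaluation: 0 outside the support, 1 at the peak or
#' plateau, linear in between. Vectorised over \code{x}.
#'
#' @param mf A \code{lapskill_mf}.
#' @param x Numeric vector of finite abscissae.
#' @return Membership degrees in \code{[0, 1]}, same length as \code{x}.
#' @export
membership_degree <- function(mf, x) {
  stopifnot(inherits(mf, "lapskill_mf"))
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  bp <- mf$breakpoints
  if (mf$shape == "triangular") {
    a <- bp[1L]; b <- bp[2L]; d <- bp[3L]
  } else {
    a <- bp[1L]; b <- bp[2L]; cc <- bp[3L]; d <- bp[4L]
  }
  up <- if (b > a) (x - a) / (b - a) else rep(1, length(x))
  if (mf$shape == "triangular") {
    down <- if (d > b) (d - x) / (d - b) else rep(1, length(x))
    lo <- a; hi <- d; peak_lo <- b; peak_hi <- b
  } else {
    down <- if (d > cc) (d - x) / (d - cc) else rep(1, length(x))
    lo <- a; hi <- d; peak_lo <- b; peak_hi <- cc
  }
  deg <- pmin(up, down, 1)
  deg[x < lo | x > hi] <- 0
  deg[x >= peak_lo & x <= peak_hi] <- 1
  pmax(0, pmin(1, deg))
}

#' @export
print.lapskill_mf <- function(x, ...) {
  cat(sprintf("<%s MF: %s>\n", x$shape,
              paste(format(x$breakpoints), collapse = ", ")))
  invisible(x)
}

# Abscissa of full membership: the peak, or the plateau midpoint for
# trapezoids. This is the label "prototype" used by center-of-average
# defuzzification and by the synthetic generator.
mf_peak <- function(mf) {
  bp <- mf$breakpoints
  if (mf$shape == "triangular") bp[2L] else (bp[2L] + bp[3L]) / 2
}

mf_support <- function(mf) {
  bp <- mf$breakpoints
  c(bp[1L], bp[length(bp)])
}

# Breakpoints of the MF clipped at activation `act` (Mamdani min-clipping),
# as a piecewise-linear (x, y) polyline over the support. Used by the exact
# center-of-gravity integrator.
mf_clipped_polyline <- function(mf, act) {
  bp <- mf$breakpoints
  if (mf$shape == "triangular") {
    xs <- c(bp[1L], bp[2L], bp[2L], bp[3L])
    ys <- c(0, 1, 1, 0)
  } else {
    xs <- c(bp[1L], bp[2L], bp[3L], bp[4L])
    ys <- c(0, 1, 1, 0)
  }
  ys <- pmin(ys, act)
  # insert the x's where the rising/falling edges cross the clip level
  add_x <- numeric(0)
  if (act < 1) {
    if (xs[2L] > xs[1L]) add_x <- c(add_x, xs[1L] + act * (xs[2L] - xs[1L]))
    n <- length(xs)
    if (xs[n] > xs[n - 1L]) add_x <- c(add_x, xs[n] - act * (xs[n] - xs[n - 1L]))
  }
  xs_all <- sort(unique(c(xs, add_x)))
  list(x = xs_all, y = pmin(membership_degree(mf, xs_all), act))
}
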