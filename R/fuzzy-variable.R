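#' Linguistic variable
#'
#' A named variable over a closed universe of discourse, carrying an ordered
#' set of labelled membership functions (e.g. distance in cm with labels
#' Close/Middle/Far, or a performance score in per cent with labels A-E).
#'
#' @param name Identifier for the variable.
#' @param universe Length-2 numeric, \code{c(lo, hi)} with \code{lo < hi}.
#' @param labels Named list of \code{lapskill_mf} objects, ordered. Every
#'   MF's support must lie within the universe.
#' @param units Unit string, for printing only (e.g. \code{"cm"},
#'   \code{"percent"}).
#' @param complete If \code{TRUE} (the default for input variables) require
#'   that at every point of the universe at least one label has positive
#'   membership, so a complete rule base always fires.
#' @return An object of class \code{lapskill_lv}.
#' @export
linguistic_variable <- function(name, universe, labels, units = "",
                                complete = TRUE) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(universe) != 2L || !is.numeric(universe) ||
      universe[1L] >= universe[2L]) {
    stop("universe must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  if (is.null(names(labels)) || any(names(labels) == "") ||
      anyDuplicated(names(labels))) {
    stop("labels must be a uniquely named list", call. = FALSE)
  }
  for (lab in names(labels)) {
    mf <- labels[[lab]]
    if (!inherits(mf, "lapskill_mf")) {
      stop("label '", lab, "' is not a membership function", call. = FALSE)
    }
    sup <- mf_support(mf)
    if (sup[1L] < universe[1L] - 1e-9 || sup[2L] > universe[2L] + 1e-9) {
      stop("label '", lab, "' of variable '", name,
           "' has support outside the universe", call. = FALSE)
    }
  }
  var <- structure(list(name = name, universe = as.numeric(universe),
                        labels = labels, units = units),
                   class = "lapskill_lv")
  if (complete) {
    grid <- seq(universe[1L], universe[2L], length.out = 257L)
    cover <- Reduce(pmax, lapply(labels, membership_degree, x = grid))
    if (any(cover <= 0)) {
      stop("variable '", name, "' is incomplete: no label covers x = ",
           format(grid[which(cover <= 0)[1L]]), call. = FALSE)
    }
  }
  var
}

#' @export
print.lapskill_lv <- function(x, ...) {
  cat(sprintf("<linguistic variable '%s' on [%s, %s] %s>\n", x$name,
              format(x$universe[1L]), format(x$universe[2L]), x$units))
  for (lab in names(x$labels)) {
    mf <- x$labels[[lab]]
    cat(sprintf("  %-10s %s(%s)\n", lab, mf$shape,
                paste(format(mf$breakpoints), collapse = ", ")))
  }
  invisible(x)
}

#' Prototype abscissae of a variable's labels
#'
#' The point of full membership for each label (plateau midpoint for
#' trapezoids), named by label.
#'
#' @param var A \code{lapskill_lv}.
#' @return Named numeric vector.
#' @export
label_peaks <- function(var) {
  stopifnot(inherits(var, "lapskill_lv"))
  vapply(var$labels, mf_peak, numeric(1L))
}

#' Singleton fuzzification
#'
#' Reads every label's membership degree at a crisp measurement. Values
#' outside the universe are clamped to its bounds, so a complete variable
#' always yields at least one positive degree.
#'
#' @param var A \code{lapskill_lv}.
#' @param x Crisp scalar measurement.
#' @return Named numeric vector of degrees in \code{[0, 1]}, one per label.
#' @export
fuzzify_singleton <- function(var, x) {
  stopifnot(inherits(var, "lapskill_lv"), is.numeric(x), length(x) == 1L)
  if (!is.finite(x)) stop("x must be finite", call. = FALSE)
  x <- min(max(x, var$universe[1L]), var$universe[2L])
  vapply(var$labels, membership_degree, numeric(1L), x = x)
}

#' Letter grade of a crisp score
#'
#' The label with maximal membership at the crisp value. Ties are broken
#' toward the worse grade (the earlier label in the variable's order, which
#' for the score variables runs worst to best), a conservative choice for
#' trainee assessment.
#'
#' @param var Output \code{lapskill_lv} whose labels are ordered from worst
#'   to best.
#' @param crisp Crisp value within the universe.
#' @return The winning label name.
#' @export
grade_letter <- function(var, crisp) {
  deg <- fuzzify_singleton(var, crisp)
  names(deg)[which.max(deg)] # which.max takes the first (worst) on ties
}
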