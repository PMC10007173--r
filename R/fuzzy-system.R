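#' Fuzzy IF-THEN rule
#'
#' A conjunctive rule: IF every input variable takes its named label THEN
#' the output takes the consequent label.
#'
#' @param antecedent Named character vector, input-variable name -> label.
#' @param consequent Output label name.
#' @return An object of class \code{lapskill_rule}.
#' @export
fuzzy_rule <- function(antecedent, consequent) {
  stopifnot(is.character(antecedent), length(antecedent) >= 1L,
            !is.null(names(antecedent)),
            is.character(consequent), length(consequent) == 1L)
  structure(list(antecedent = antecedent, consequent = consequent),
            class = "lapskill_rule")
}

#' Mamdani fuzzy inference system
#'
#' Bundles input variables, an output variable, and a rule base, with the
#' classical Mamdani operator pair: min for rule conjunction, max for
#' aggregation over rules sharing a consequent label.
#'
#' @param inputs List of input \code{lapskill_lv} objects (named by their
#'   variable names).
#' @param output Output \code{lapskill_lv}.
#' @param rules List of \code{lapskill_rule}s. The rule base must cover the
#'   cross-product of input labels exactly once (9 rules for two 3-label
#'   inputs), so some rule always fires for clamped inputs.
#' @param defuzz Default defuzzification method, \code{"center_of_average"}
#'   (activation-weighted mean of consequent peaks) or
#'   \code{"center_of_gravity"} (centroid of the min-clipped, max-aggregated
#'   output set).
#' @return An object of class \code{lapskill_fis}.
#' @export
mamdani_system <- function(inputs, output, rules,
                           defuzz = c("center_of_average",
                                      "center_of_gravity")) {
  defuzz <- match.arg(defuzz)
  stopifnot(is.list(inputs), length(inputs) >= 1L,
            inherits(output, "lapskill_lv"), is.list(rules))
  in_names <- vapply(inputs, function(v) v$name, character(1L))
  names(inputs) <- in_names
  # validate rules and check exact cross-product coverage
  combos <- expand.grid(lapply(inputs, function(v) names(v$labels)),
                        stringsAsFactors = FALSE)
  seen <- character(0)
  for (r in rules) {
    stopifnot(inherits(r, "lapskill_rule"))
    if (!setequal(names(r$antecedent), in_names)) {
      stop("rule antecedent must name every input variable", call. = FALSE)
    }
    for (v in in_names) {
      if (!r$antecedent[[v]] %in% names(inputs[[v]]$labels)) {
        stop("unknown label '", r$antecedent[[v]], "' for input '", v, "'",
             call. = FALSE)
      }
    }
    if (!r$consequent %in% names(output$labels)) {
      stop("unknown output label '", r$consequent, "'", call. = FALSE)
    }
    key <- paste(r$antecedent[in_names], collapse = "\r")
    if (key %in% seen) stop("duplicate rule for antecedent (",
                            paste(r$antecedent[in_names], collapse = ", "),
                            ")", call. = FALSE)
    seen <- c(seen, key)
  }
  if (length(rules) != nrow(combos)) {
    stop("rule base must cover the ", nrow(combos),
         " input-label combinations exactly once; got ", length(rules),
         " rules", call. = FALSE)
  }
  structure(list(inputs = inputs, output = output, rules = rules,
                 defuzz = defuzz),
            class = "lapskill_fis")
}

#' @export
print.lapskill_fis <- function(x, ...) {
  cat(sprintf("<Mamdani system: %s -> %s; %d rules; defuzz = %s>\n",
              paste(names(x$inputs), collapse = " x "), x$output$name,
              length(x$rules), x$defuzz))
  invisible(x)
}

#' Evaluate the rule base
#'
#' Mamdani inference: each rule fires at the min of its antecedent degrees;
#' activations are aggregated per output label with max. Labels with no
#' firing rule get activation 0.
#'
#' @param system A \code{lapskill_fis}.
#' @param fuzzified Named list, one entry per input variable, each a named
#'   degree vector as returned by [fuzzify_singleton()].
#' @return Named numeric vector of activations, one per output label.
#' @export
evaluate_rules <- function(system, fuzzified) {
  stopifnot(inherits(system, "lapskill_fis"))
  in_names <- names(system$inputs)
  if (!all(in_names %in% names(fuzzified))) {
    stop("fuzzified degrees missing for input(s): ",
         paste(setdiff(in_names, names(fuzzified)), collapse = ", "),
         call. = FALSE)
  }
  act <- stats::setNames(numeric(length(system$output$labels)),
                         names(system$output$labels))
  for (r in system$rules) {
    fire <- min(vapply(in_names, function(v) {
      d <- fuzzified[[v]][[r$antecedent[[v]]]]
      if (is.null(d) || is.na(d)) {
        stop("degree for label '", r$antecedent[[v]], "' of '", v,
             "' missing from fuzzified input", call. = FALSE)
      }
      d
    }, numeric(1L)))
    act[r$consequent] <- max(act[r$consequent], fire)
  }
  act
}

#' Defuzzify label activations to a crisp value
#'
#' Two methods are provided. \code{center_of_average} is the
#' activation-weighted mean of the activated labels' prototype abscissae
#' (their peaks; plateau midpoints for trapezoids) — the discrete
#' weighted-sum centroid. \code{center_of_gravity} min-clips each
#' consequent MF at its activation, max-aggregates them into one output
#' set, and returns the exact area centroid of that piecewise-linear set,
#' integrated analytically segment by segment.
#'
#' @param output Output \code{lapskill_lv}.
#' @param activations Named activation vector (one per label, in
#'   \code{[0, 1]}); at least one must be positive.
#' @param method \code{"center_of_average"} or \code{"center_of_gravity"}.
#' @return Crisp scalar within the output universe.
#' @export
defuzzify <- function(output, activations,
                      method = c("center_of_average", "center_of_gravity")) {
  method <- match.arg(method)
  stopifnot(inherits(output, "lapskill_lv"))
  labs <- names(output$labels)
  if (!all(labs %in% names(activations))) {
    stop("activations must cover every output label", call. = FALSE)
  }
  act <- pmin(1, pmax(0, as.numeric(activations[labs])))
  if (all(act <= 0)) {
    stop("no rule fired: all activations are zero (rule base incomplete?)",
         call. = FALSE)
  }
  if (method == "center_of_average") {
    peaks <- label_peaks(output)
    return(sum(act * peaks) / sum(act))
  }
  cog_exact(output, act)
}

# Exact centroid of the max-aggregated, min-clipped output set.
# The aggregate mu(x) = max_l min(act_l, mf_l(x)) is piecewise linear; we
# split the universe at every clipped-MF vertex and at every pairwise
# intersection of the clipped polylines, so mu is linear on each cell, then
# integrate x*mu and mu in closed form.
cog_exact <- function(output, act) {
  labs <- names(output$labels)
  polys <- lapply(seq_along(labs), function(i) {
    if (act[i] <= 0) return(NULL)
    mf_clipped_polyline(output$labels[[labs[i]]], act[i])
  })
  polys <- Filter(Negate(is.null), polys)
  cuts <- output$universe
  for (p in polys) cuts <- c(cuts, p$x)
  # pairwise intersections of linear segments from different polylines
  segs <- list()
  for (p in polys) {
    for (k in seq_len(length(p$x) - 1L)) {
      if (p$x[k + 1L] > p$x[k]) {
        segs[[length(segs) + 1L]] <-
          c(p$x[k], p$x[k + 1L], p$y[k], p$y[k + 1L])
      }
    }
  }
  n <- length(segs)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        s1 <- segs[[i]]; s2 <- segs[[j]]
        lo <- max(s1[1L], s2[1L]); hi <- min(s1[2L], s2[2L])
        if (hi <= lo) next
        m1 <- (s1[4L] - s1[3L]) / (s1[2L] - s1[1L])
        m2 <- (s2[4L] - s2[3L]) / (s2[2L] - s2[1L])
        if (m1 == m2) next
        b1 <- s1[3L] - m1 * s1[1L]; b2 <- s2[3L] - m2 * s2[1L]
        xi <- (b2 - b1) / (m1 - m2)
        if (xi > lo && xi < hi) cuts <- c(cuts, xi)
      }
    }
  }
  cuts <- sort(unique(pmin(pmax(cuts, output$universe[1L]),
                           output$universe[2L])))
  mu_at <- function(x) {
    m <- 0
    for (p in polys) {
      y <- stats::approx(p$x, p$y, xout = x, yleft = 0, yright = 0,
                         ties = "ordered")$y
      m <- pmax(m, y)
    }
    m
  }
  num <- 0; den <- 0
  for (k in seq_len(length(cuts) - 1L)) {
    a <- cuts[k]; b <- cuts[k + 1L]
    if (b <= a) next
    ya <- mu_at(a); yb <- mu_at(b)
    # mu is linear on [a, b]: mu(x) = ya + (yb - ya) * (x - a) / (b - a)
    den <- den + (ya + yb) / 2 * (b - a)
    slope <- (yb - ya) / (b - a)
    icept <- ya - slope * a
    num <- num + icept * (b^2 - a^2) / 2 + slope * (b^3 - a^3) / 3
  }
  if (den <= 0) {
    stop("aggregated output set has zero area", call. = FALSE)
  }
  num / den
}

#' Run a Mamdani system on crisp inputs
#'
#' Convenience wrapper: singleton-fuzzify each crisp input, evaluate the
#' rule base, and defuzzify.
#'
#' @param system A \code{lapskill_fis}.
#' @param crisp_inputs Named numeric vector or list, one crisp value per
#'   input variable (clamped to each universe).
#' @param method Defuzzification method; defaults to the system's.
#' @return List with \code{crisp}, \code{letter} (label of maximal
#'   membership at the crisp output), \code{activations}, and
#'   \code{fuzzified}.
#' @export
fis_infer <- function(system, crisp_inputs, method = NULL) {
  stopifnot(inherits(system, "lapskill_fis"))
  if (is.null(method)) method <- system$defuzz
  fuzzified <- lapply(system$inputs, function(v) {
    x <- crisp_inputs[[v$name]]
    if (is.null(x)) stop("missing crisp input '", v$name, "'", call. = FALSE)
    fuzzify_singleton(v, x)
  })
  act <- evaluate_rules(system, fuzzified)
  crisp <- defuzzify(system$output, act, method)
  list(crisp = crisp, letter = grade_letter(system$output, crisp),
       activations = act, fuzzified = fuzzified)
}
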