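# Four-group risk stratification of the frailty index.
#
# Two per-time-point indices drive the cut-point search over Kaplan-Meier
# curves ordered fit -> mild -> moderate -> severe:
#   distance index D(t): the minimum adjacent gap between the four curves —
#     large only when all three gaps are wide and balanced;
#   coverage index C(t) = L_error / L_total: total 95% CI length within the
#     four groups over the fit-vs-severe survival gap — small when estimation
#     error is small relative to the total spread.
# The search is exhaustive over ordered cut-point triples, keeps only
# candidates whose curves are strictly dose-ordered with non-overlapping CIs
# at every grid time after the first year, maximizes the worst-time distance
# index (max-min) and breaks ties by minimizing the worst-time coverage
# index (min-max).

FRAILTY_LEVELS <- c("fit", "mild", "moderate", "severe")

#' Cut-point triple for four frailty groups
#'
#' Intervals are lower-inclusive, upper-exclusive: fit = \[0, c1), mild =
#' \[c1, c2), moderate = \[c2, c3), severe = \[c3, 1\].
#'
#' @param c1,c2,c3 Strictly increasing thresholds in (0, 1).
#' @return A list of class `cut_points`.
#' @export
cut_points <- function(c1, c2, c3) {
  v <- c(c1, c2, c3)
  if (anyNA(v) || any(v <= 0) || any(v >= 1) || any(diff(v) <= 0))
    stop("cut points must satisfy 0 < c1 < c2 < c3 < 1", call. = FALSE)
  structure(list(c1 = c1, c2 = c2, c3 = c3, labels = FRAILTY_LEVELS),
            class = "cut_points")
}

#' @export
print.cut_points <- function(x, ...) {
  cat(sprintf("Frailty cut points: fit [0, %.4g) | mild [%.4g, %.4g) | moderate [%.4g, %.4g) | severe [%.4g, 1]\n",
              x$c1, x$c1, x$c2, x$c2, x$c3, x$c3))
  invisible(x)
}

#' Assign frailty groups from scores
#'
#' A score on a boundary belongs to the upper group (e.g. a score equal to
#' c1 is mild, not fit).
#'
#' @param scores Numeric frailty-index scores in \[0, 1\], or a score
#'   tibble with a `value` column.
#' @param cutpoints A [cut_points()].
#' @return A factor with levels fit, mild, moderate, severe.
#' @export
assign_groups <- function(scores, cutpoints) {
  x <- if (is.data.frame(scores)) scores$value else scores
  if (any(is.na(x)) || any(x < 0 | x > 1))
    stop("data error: scores must lie in [0, 1]", call. = FALSE)
  idx <- findInterval(x, c(cutpoints$c1, cutpoints$c2, cutpoints$c3)) + 1L
  factor(FRAILTY_LEVELS[idx], levels = FRAILTY_LEVELS)
}

#' Distance index of a four-curve set
#'
#' The minimum adjacent survival gap at time `t` across curves ordered fit
#' to severe. Negative values flag a dose-ordering violation.
#'
#' @param curveset A `survival_curveset` with the four frailty groups in
#'   order (see [curveset_by_group()]).
#' @param t Time(s) on the curve grid (months); defaults to the whole grid.
#' @return Numeric vector of D(t).
#' @export
distance_index <- function(curveset, t = curveset$times) {
  j <- match(t, curveset$times)
  if (anyNA(j)) stop("t must lie on the curve-set time grid", call. = FALSE)
  s <- curveset$surv
  gaps <- s[-nrow(s), j, drop = FALSE] - s[-1, j, drop = FALSE]
  apply(gaps, 2, min)
}

#' Coverage index of a four-curve set
#'
#' C(t) = L_error / L_total, where L_error is the summed confidence-interval
#' length of the four curves at `t` and L_total the fit-minus-severe
#' survival gap. `NA` where the gap is non-positive (index undefined, the
#' candidate is infeasible there).
#'
#' @inheritParams distance_index
#' @return Numeric vector of C(t).
#' @export
coverage_index <- function(curveset, t = curveset$times) {
  j <- match(t, curveset$times)
  if (anyNA(j)) stop("t must lie on the curve-set time grid", call. = FALSE)
  l_error <- colSums(curveset$upper[, j, drop = FALSE] -
                       curveset$lower[, j, drop = FALSE])
  l_total <- curveset$surv[1, j] - curveset$surv[nrow(curveset$surv), j]
  ifelse(l_total > 0, l_error / l_total, NA_real_)
}

# Feasibility and objectives of one candidate triple on the grid.
evaluate_candidate <- function(time, event, group, grid_times, conf_level) {
  cs <- km_curveset(time, event, group, grid_times, conf_level)
  d <- distance_index(cs)
  cv <- coverage_index(cs)
  ordering_ok <- all(d > 0)
  # Adjacent CIs overlap when the upper group's lower bound does not clear
  # the lower group's upper bound.
  ci_ok <- all(cs$lower[-4, , drop = FALSE] > cs$upper[-1, , drop = FALSE])
  list(curveset = cs, distance = d, coverage = cv,
       min_distance = min(d),
       max_coverage = if (anyNA(cv)) Inf else max(cv),
       ordering_ok = ordering_ok, ci_ok = ci_ok)
}

#' Search cut points for four dose-ordered frailty groups
#'
#' Exhaustively enumerates ordered cut-point triples drawn from midpoints
#' between consecutive distinct observed score values. A candidate is
#' feasible when every group meets the minimum size and, at every grid time
#' (months, after the first year by default), all three adjacent curve gaps
#' are positive and no adjacent 95% confidence intervals overlap. Among
#' feasible candidates the search maximizes the worst-time distance index,
#' breaks ties by minimizing the worst-time coverage index, and finally by
#' the lexicographically smallest triple. If no candidate is feasible the
#' result reports the best-scoring infeasible candidate and the constraint
#' that failed.
#'
#' @param scores Frailty-index scores (numeric or tibble with `value`).
#' @param time,event Follow-up months and event indicators for the outcome
#'   driving stratification (all-cause mortality by convention).
#' @param grid_times Evaluation grid in months, default monthly 12-96.
#' @param min_group_size Minimum subjects per group; default
#'   `max(30, 0.5% of n)`.
#' @param candidates Optional numeric matrix (rows = triples) restricting
#'   the search to a user-supplied candidate grid.
#' @param conf_level Confidence level for the interval-overlap test.
#' @return A `stratification_result`: `cutpoints`, `feasible`, per-time
#'   `distance_profile` and `coverage_profile`, `objective`
#'   (min-distance, max-coverage), ordering/CI flags, `group_sizes`,
#'   `failed_constraint` (infeasible case) and the candidate count.
#' @export
search_cutpoints <- function(scores, time, event, grid_times = 12:96,
                             min_group_size = NULL, candidates = NULL,
                             conf_level = 0.95) {
  x <- if (is.data.frame(scores)) scores$value else scores
  n <- length(x)
  stopifnot(length(time) == n, length(event) == n)
  if (is.null(min_group_size)) min_group_size <- max(30, ceiling(0.005 * n))

  if (is.null(candidates)) {
    v <- sort(unique(x))
    if (length(v) < 4)
      stop("need at least 4 distinct score values to form 4 groups",
           call. = FALSE)
    mids <- (v[-1] + v[-length(v)]) / 2
    mids <- mids[mids > 0 & mids < 1]
    cmb <- utils::combn(mids, 3)
    candidates <- t(cmb)
  } else {
    candidates <- as.matrix(candidates)
    if (ncol(candidates) != 3) stop("candidates must have 3 columns", call. = FALSE)
    ok <- candidates[, 1] < candidates[, 2] & candidates[, 2] < candidates[, 3]
    candidates <- candidates[ok, , drop = FALSE]
  }
  if (nrow(candidates) == 0)
    stop("configuration error: empty candidate set", call. = FALSE)

  # Cheap size prefilter via the empirical cdf of the scores.
  xs <- sort(x)
  counts_below <- function(c) findInterval(c - 1e-12, xs)
  sizes <- t(apply(candidates, 1, function(cc) {
    b <- vapply(cc, counts_below, numeric(1))
    c(b[1], b[2] - b[1], b[3] - b[2], n - b[3])
  }))
  size_ok <- apply(sizes >= min_group_size, 1, all)

  best <- NULL; best_key <- NULL
  best_infeas <- NULL; best_infeas_key <- -Inf; infeas_why <- NULL
  for (i in which(size_ok)) {
    cp <- cut_points(candidates[i, 1], candidates[i, 2], candidates[i, 3])
    grp <- assign_groups(x, cp)
    ev <- evaluate_candidate(time, event, grp, grid_times, conf_level)
    if (ev$ordering_ok && ev$ci_ok) {
      key <- list(ev$min_distance, ev$max_coverage, candidates[i, ])
      if (is.null(best) || better_candidate(key, best_key)) {
        best <- list(cp = cp, ev = ev, sizes = sizes[i, ])
        best_key <- key
      }
    } else if (ev$min_distance > best_infeas_key) {
      best_infeas <- list(cp = cp, ev = ev, sizes = sizes[i, ])
      best_infeas_key <- ev$min_distance
      infeas_why <- if (!ev$ordering_ok) "curve_ordering" else "ci_overlap"
    }
  }

  if (!is.null(best)) {
    res <- make_stratification_result(best, feasible = TRUE,
                                      grid_times = grid_times,
                                      failed_constraint = NULL,
                                      n_candidates = sum(size_ok),
                                      min_group_size = min_group_size)
    return(res)
  }
  if (is.null(best_infeas)) {
    # Nothing even met the size constraint.
    return(structure(list(
      cutpoints = NULL, feasible = FALSE, failed_constraint = "group_size",
      distance_profile = NULL, coverage_profile = NULL, objective = NULL,
      flags = list(curve_ordering = FALSE, ci_non_overlap = FALSE),
      group_sizes = NULL, n_candidates = 0L,
      min_group_size = min_group_size
    ), class = "stratification_result"))
  }
  make_stratification_result(best_infeas, feasible = FALSE,
                             grid_times = grid_times,
                             failed_constraint = infeas_why,
                             n_candidates = sum(size_ok),
                             min_group_size = min_group_size)
}

# Lexicographic comparison: higher min-distance, then lower max-coverage,
# then smaller (c1, c2, c3).
better_candidate <- function(a, b) {
  if (a[[1]] != b[[1]]) return(a[[1]] > b[[1]])
  if (a[[2]] != b[[2]]) return(a[[2]] < b[[2]])
  cmp <- a[[3]] != b[[3]]
  if (any(cmp)) return(a[[3]][which(cmp)[1]] < b[[3]][which(cmp)[1]])
  FALSE
}

make_stratification_result <- function(sel, feasible, grid_times,
                                       failed_constraint, n_candidates,
                                       min_group_size) {
  ev <- sel$ev
  structure(list(
    cutpoints = sel$cp,
    feasible = feasible,
    failed_constraint = failed_constraint,
    distance_profile = tibble::tibble(time = grid_times, distance = ev$distance),
    coverage_profile = tibble::tibble(time = grid_times, coverage = ev$coverage),
    objective = list(min_distance = ev$min_distance,
                     max_coverage = ev$max_coverage),
    flags = list(curve_ordering = ev$ordering_ok, ci_non_overlap = ev$ci_ok),
    group_sizes = stats::setNames(as.integer(sel$sizes), FRAILTY_LEVELS),
    curveset = ev$curveset,
    n_candidates = n_candidates,
    min_group_size = min_group_size
  ), class = "stratification_result")
}

#' @export
print.stratification_result <- function(x, ...) {
  if (is.null(x$cutpoints)) {
    cat("Stratification infeasible: no candidate met the minimum group size (",
        x$min_group_size, ")\n", sep = "")
    return(invisible(x))
  }
  print(x$cutpoints)
  cat(if (x$feasible) "Feasible" else
    paste0("INFEASIBLE (", x$failed_constraint, ")"),
    "| min distance index", signif(x$objective$min_distance, 4),
    "| max coverage index", signif(x$objective$max_coverage, 4), "\n")
  cat("Group sizes:", paste(names(x$group_sizes), x$group_sizes,
                            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a stratification result to JSON
#'
#' @param result A `stratification_result`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_stratification <- function(result, path) {
  out <- list(
    cutpoints = if (is.null(result$cutpoints)) NULL else
      list(c1 = result$cutpoints$c1, c2 = result$cutpoints$c2,
           c3 = result$cutpoints$c3),
    feasible = result$feasible,
    failed_constraint = result$failed_constraint,
    objective = result$objective,
    flags = result$flags,
    group_sizes = as.list(result$group_sizes),
    distance_profile = result$distance_profile,
    coverage_profile = result$coverage_profile
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Plot the four-group Kaplan-Meier curves
#'
#' @param curveset A `survival_curveset`.
#' @return A ggplot object: one survival curve per frailty group with its
#'   confidence ribbon.
#' @export
plot_curveset <- function(curveset) {
  df <- tibble::tibble(
    group = factor(rep(curveset$groups, each = length(curveset$times)),
                   levels = curveset$groups),
    time = rep(curveset$times, length(curveset$groups)),
    surv = as.vector(t(curveset$surv)),
    lower = as.vector(t(curveset$lower)),
    upper = as.vector(t(curveset$upper))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "months of follow-up", y = "survival probability",
                  colour = "frailty group", fill = "frailty group") +
    ggplot2::theme_minimal()
}
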