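# Random-forest condition selection and frailty-index scoring.
#
# Conditions are ranked by permutation importance (mean decrease in
# out-of-bag accuracy); the index size k is the number of top-ranked
# conditions at which out-of-bag accuracy over the k-grid peaks. The
# frailty index itself follows the cumulative-deficit model: the count of
# selected conditions present divided by k, so scores live on
# {0, 1/k, ..., 1}.

#' Random-forest settings
#'
#' @param ntree Number of trees.
#' @param mtry Variables tried per split; default `floor(sqrt(p))`, resolved
#'   at fit time.
#' @param seed Seed applied before each forest fit, so rankings and traces
#'   are reproducible bit-for-bit.
#' @return A list of class `rf_settings`.
#' @export
rf_settings <- function(ntree = 500, mtry = NULL, seed = 1L) {
  stopifnot(is.numeric(ntree), ntree >= 1)
  structure(list(ntree = as.integer(ntree), mtry = mtry, seed = as.integer(seed)),
            class = "rf_settings")
}

fit_forest <- function(values, outcome, settings, importance = FALSE) {
  x <- as.data.frame(values)
  y <- factor(outcome, levels = c(0, 1))
  mtry <- if (is.null(settings$mtry)) max(1L, floor(sqrt(ncol(x)))) else
    min(as.integer(settings$mtry), ncol(x))
  set.seed(settings$seed)
  randomForest::randomForest(x, y, ntree = settings$ntree, mtry = mtry,
                             importance = importance)
}

oob_accuracy <- function(fit) {
  unname(1 - fit$err.rate[fit$ntree, "OOB"])
}

#' Rank conditions by permutation importance
#'
#' Fits a classification forest of the outcome on the deficit matrix and
#' returns conditions ordered by mean decrease in out-of-bag accuracy under
#' per-condition permutation (unscaled, averaged over trees). Ties are
#' broken by condition id in lexical order. A constant column (e.g. a
#' condition nobody has) gets importance exactly 0.
#'
#' @param dm A `deficit_matrix` from [ascertain_deficits()].
#' @param outcome Binary vector (0/1) aligned with the matrix rows; must
#'   contain both classes.
#' @param settings [rf_settings()].
#' @return A tibble with `condition_id` and `importance`, sorted
#'   non-increasing.
#' @export
rank_importance <- function(dm, outcome, settings = rf_settings()) {
  values <- dm$values
  if (length(outcome) != nrow(values))
    stop("outcome length does not match the deficit matrix rows", call. = FALSE)
  if (length(unique(outcome)) < 2)
    stop("degenerate outcome: a single class cannot be ranked", call. = FALSE)
  fit <- fit_forest(values, outcome, settings, importance = TRUE)
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1]
  ranking <- tibble::tibble(condition_id = colnames(values),
                            importance = unname(imp[colnames(values)]))
  dplyr::arrange(ranking, dplyr::desc(.data$importance), .data$condition_id)
}

# Peak of the accuracy trace; smallest k on exact ties.
choose_best_k <- function(trace) {
  best <- max(trace$accuracy)
  min(trace$k[trace$accuracy == best])
}

#' Select the number of index conditions by out-of-bag accuracy
#'
#' Refits the forest on the top-k ranked conditions for every k in the
#' grid, records out-of-bag accuracy, and selects the k with the highest
#' accuracy (smallest k on ties). The full accuracy-versus-k trace is kept
#' for plotting.
#'
#' @param dm A `deficit_matrix`.
#' @param outcome Binary outcome vector aligned with the matrix rows.
#' @param ranking Ranked importance tibble from [rank_importance()].
#' @param k_grid Integer vector of candidate k values within
#'   `1..n_conditions`; default the full grid (use a stride for large
#'   catalogs).
#' @param settings [rf_settings()].
#' @param target_outcome Label describing the outcome the forest predicts.
#' @return A `frailty_index_model`: ranking, `selected_k`, selected
#'   condition ids, accuracy trace, settings and outcome label.
#' @export
select_k <- function(dm, outcome, ranking, k_grid = NULL,
                     settings = rf_settings(),
                     target_outcome = "death_followup") {
  p <- ncol(dm$values)
  if (is.null(k_grid)) k_grid <- seq_len(p)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(k_grid) == 0)
    stop("configuration error: empty k_grid", call. = FALSE)
  if (any(k_grid < 1 | k_grid > p))
    stop("configuration error: k_grid values must lie in 1..", p, call. = FALSE)
  acc <- vapply(k_grid, function(k) {
    cols <- ranking$condition_id[seq_len(k)]
    oob_accuracy(fit_forest(dm$values[, cols, drop = FALSE], outcome, settings))
  }, numeric(1))
  trace <- tibble::tibble(k = k_grid, accuracy = acc)
  sel_k <- choose_best_k(trace)
  structure(list(
    ranking = ranking,
    selected_k = sel_k,
    selected_conditions = ranking$condition_id[seq_len(sel_k)],
    accuracy_trace = trace,
    settings = settings,
    target_outcome = target_outcome
  ), class = "frailty_index_model")
}

#' @export
print.frailty_index_model <- function(x, ...) {
  best <- x$accuracy_trace$accuracy[x$accuracy_trace$k == x$selected_k]
  cat("Frailty-index model: k =", x$selected_k, "conditions selected of",
      nrow(x$ranking), "(OOB accuracy", signif(best, 4), ")\n")
  cat("Forest:", x$settings$ntree, "trees, outcome =", x$target_outcome, "\n")
  invisible(x)
}

#' Compute frailty-index scores
#'
#' The score is the number of selected conditions present divided by the
#' number of selected conditions, exactly; values fall on
#' `{0, 1/k, 2/k, ..., 1}`.
#'
#' @param dm A `deficit_matrix`.
#' @param selected Character vector of selected condition ids (e.g.
#'   `model$selected_conditions`), all present in the matrix.
#' @param index_kind Label stored with the scores, `"ml_mfi"` by default.
#' @return A tibble with `subject_id`, `value`, `index_kind`.
#' @export
compute_fi <- function(dm, selected, index_kind = "ml_mfi") {
  if (length(selected) == 0)
    stop("configuration error: empty selected condition set", call. = FALSE)
  missing_ids <- setdiff(selected, colnames(dm$values))
  if (length(missing_ids) > 0)
    stop("condition id(s) absent from the deficit matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  k <- length(selected)
  counts <- unname(rowSums(dm$values[, selected, drop = FALSE]))
  tibble::tibble(subject_id = rownames(dm$values),
                 value = counts / k,
                 index_kind = index_kind)
}

#' Score a user-supplied reference (expert) condition list
#'
#' Applies the same count-over-k formula with a comparator catalog chosen
#' by expert opinion rather than by the forest, so the data-driven index
#' can be compared against the conventional one on the same matrix.
#'
#' @param dm A `deficit_matrix`.
#' @param reference Character vector of condition ids, or a catalog tibble
#'   with a `condition_id` column.
#' @return A tibble of scores with `index_kind = "reference_mfi"`.
#' @export
compute_reference_fi <- function(dm, reference) {
  ids <- if (is.data.frame(reference)) reference$condition_id else reference
  compute_fi(dm, ids, index_kind = "reference_mfi")
}

#' Plot the accuracy-versus-k trace
#'
#' @param model A `frailty_index_model`.
#' @return A ggplot object showing out-of-bag accuracy against the number
#'   of top-ranked conditions, with the selected k marked.
#' @export
plot_accuracy_trace <- function(model) {
  tr <- model$accuracy_trace
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$k, y = .data$accuracy)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = model$selected_k, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "number of top-ranked conditions (k)",
                  y = "out-of-bag accuracy",
                  title = paste0("Condition count selection (k = ",
                                 model$selected_k, ")")) +
    ggplot2::theme_minimal()
}

#' Serialize a frailty-index model to JSON
#'
#' @param model A `frailty_index_model`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_fi_model <- function(model, path) {
  out <- list(
    selected_k = model$selected_k,
    selected_conditions = model$selected_conditions,
    ranking = model$ranking,
    accuracy_trace = model$accuracy_trace,
    settings = list(ntree = model$settings$ntree,
                    mtry = model$settings$mtry,
                    seed = model$settings$seed),
    target_outcome = model$target_outcome
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
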