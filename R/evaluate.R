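# Evaluation: RMSE, absolute percentage errors, percentile curves, grouped
# reports and the relative-improvement arithmetic used to compare models.

#' Root-mean-square error
#' @param predictions,references numeric vectors of equal length (>= 1).
#' @return `sqrt(mean((predictions - references)^2))`, in the target's
#'   natural units.
#' @export
rmse <- function(predictions, references) {
  if (length(predictions) != length(references) || length(predictions) < 1L)
    stop("predictions and references must have equal length >= 1")
  sqrt(mean((predictions - references)^2))
}

#' Absolute percentage errors
#' @param predictions,references numeric vectors of equal length; references
#'   must be strictly positive.
#' @return per-sample `100 * |pred - ref| / ref` (%).
#' @export
ape <- function(predictions, references) {
  if (length(predictions) != length(references))
    stop("predictions and references must have equal length")
  if (any(references <= 0)) stop("references must be strictly positive")
  100 * abs(predictions - references) / references
}

#' Percentile curve of a value distribution
#'
#' Uses the project-wide percentile estimator (linear interpolation between
#' closest ranks), so evaluation curves and stratification bins are mutually
#' consistent.
#'
#' @param values non-empty numeric vector.
#' @param grid percentile grid, default `c(5, 25, 50, 75, 95)`.
#' @return named numeric vector, non-decreasing along the grid.
#' @export
percentile_curve <- function(values, grid = c(5, 25, 50, 75, 95)) {
  if (length(values) < 1L) stop("values must be non-empty")
  stats::setNames(percentile(values, grid), paste0("p", grid))
}

#' Relative RMSE improvement
#'
#' Percentage drop from a baseline RMSE to a new one:
#' `100 * (rmse_base - rmse_new) / rmse_base`.
#'
#' @param rmse_base baseline RMSE (> 0).
#' @param rmse_new comparison RMSE.
#' @return percent drop (negative if the new model is worse).
#' @export
relative_improvement <- function(rmse_base, rmse_new) {
  if (rmse_base <= 0) stop("rmse_base must be > 0")
  100 * (rmse_base - rmse_new) / rmse_base
}

#' Evaluate a trained model on a dataset
#'
#' Produces the full report: RMSE (labelled RMSEV for the validation role,
#' RMSEP for the test role), the absolute-percentage-error distribution and
#' its percentile table, and optional per-group sub-reports (e.g. by variety
#' or vintage).
#'
#' @param model a trained `cnn_model` (or any object with a `predict` method
#'   returning one value per row of a spectra matrix).
#' @param dataset a `spec_dataset`, already preprocessed to match the model's
#'   stored provenance.
#' @param role `"test"` (RMSEP) or `"validation"` (RMSEV).
#' @param group_by optional metadata column (`"variety"` or `"vintage"`) for
#'   per-group sub-reports.
#' @param ape_grid percentile grid for the APE table.
#' @return an object of class `eval_report`.
#' @export
evaluate <- function(model, dataset, role = c("test", "validation"),
                     group_by = NULL, ape_grid = c(5, 25, 50, 75, 95)) {
  stopifnot(inherits(dataset, "spec_dataset"))
  role <- match.arg(role)
  target <- if (!is.null(model$target)) model$target else "sugar"
  preds <- predict(model, dataset)
  refs <- dataset$references[[target]]
  report <- .eval_core(preds, refs, target, role, ape_grid)
  report$predictions <- stats::setNames(preds, dataset$references$sample_id)
  if (!is.null(group_by)) {
    g <- dataset$metadata[[group_by]]
    report$group_by <- group_by
    report$groups <- lapply(split(seq_along(preds), g), function(idx)
      .eval_core(preds[idx], refs[idx], target, role, ape_grid))
  }
  report
}

.eval_core <- function(preds, refs, target, role, ape_grid) {
  a <- ape(preds, refs)
  structure(list(
    target = target, role = role, n = length(preds),
    rmse = rmse(preds, refs),
    rmse_label = if (role == "test") "RMSEP" else "RMSEV",
    ape = a,
    ape_percentiles = percentile_curve(a, ape_grid),
    summary = c(min = min(a), mean = mean(a), max = max(a))),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits_rmse = 3, digits_ape = 1, ...) {
  unit <- if (x$target == "sugar") " °Brix" else ""
  cat(sprintf("<eval_report> %s, n = %d\n", x$target, x$n))
  cat(sprintf("  %s = %s%s\n", x$rmse_label,
              formatC(x$rmse, digits = digits_rmse, format = "f"), unit))
  cat("  APE percentiles (%):",
      paste(names(x$ape_percentiles),
            formatC(x$ape_percentiles, digits = digits_ape, format = "f"),
            sep = "=", collapse = "  "), "\n")
  if (!is.null(x$groups)) {
    for (g in names(x$groups))
      cat(sprintf("  [%s = %s] %s = %s (n = %d)\n", x$group_by, g,
                  x$groups[[g]]$rmse_label,
                  formatC(x$groups[[g]]$rmse, digits = digits_rmse,
                          format = "f"),
                  x$groups[[g]]$n))
  }
  invisible(x)
}
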