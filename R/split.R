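# Percentile-stratified, per-vintage train/validation/test partitioning and
# the repeated-split experiment harness.

# Shared percentile estimator: linear interpolation between closest ranks
# (R quantile type 7), used identically for binning and for evaluation
# percentile curves.
percentile <- function(values, probs) {
  quantile(values, probs = probs / 100, type = 7, names = FALSE)
}

round_half_up <- function(x) floor(x + 0.5)

#' Percentile bins of a target variable
#'
#' Cuts a set of reference values into five strata at the 20th, 40th, 60th
#' and 80th percentiles (linear interpolation between closest ranks). Values
#' tied with a cut fall in the lower bin, so a degenerate all-identical group
#' collapses into bin 1.
#'
#' @param values numeric reference values of one group.
#' @param cut_percentiles percentile cut points; default `c(20, 40, 60, 80)`.
#' @param ids optional sample ids naming the assignment.
#' @return an object of class `percentile_bins` with `cut_percentiles`,
#'   `cut_values` and `assignment` (bin 1..k+1 per value).
#' @export
compute_percentile_bins <- function(values, cut_percentiles = c(20, 40, 60, 80),
                                    ids = NULL) {
  n_bins <- length(cut_percentiles) + 1L
  if (length(values) < n_bins)
    stop("group-too-small error: need at least ", n_bins, " values")
  cuts <- percentile(values, cut_percentiles)
  assignment <- 1L + vapply(values, function(x) sum(cuts < x), integer(1))
  if (!is.null(ids)) names(assignment) <- ids
  structure(list(cut_percentiles = cut_percentiles, cut_values = cuts,
                 assignment = assignment),
            class = "percentile_bins")
}

#' Percentile-stratified train/validation/test partition
#'
#' Within each vintage (crossed with variety when the dataset mixes
#' varieties), reference values of `stratify_on` are binned at the
#' 20/40/60/80th percentiles; within each (group x bin) cell,
#' `round(0.1 n)` samples go to the test set and another `round(0.1 n)` to
#' the validation set, drawn without replacement under `seed` (round half
#' up, with a minimum of one test and one validation sample when the cell
#' has at least 3; smaller cells contribute to training only). The final
#' sets are the unions over cells.
#'
#' @param dataset a `spec_dataset`.
#' @param stratify_on target used for binning, `"sugar"` or `"ph"`.
#' @param fractions named fractions, default `c(test = 0.1, val = 0.1)`;
#'   must sum to < 1.
#' @param seed integer seed; identical inputs give byte-identical splits.
#' @param cut_percentiles percentile cut points for binning.
#' @return an object of class `dataset_split` with `train_ids`, `val_ids`,
#'   `test_ids` (disjoint; union = all ids), plus the configuration used.
#' @export
stratified_partition <- function(dataset, stratify_on = c("sugar", "ph"),
                                 fractions = c(test = 0.1, val = 0.1),
                                 seed = 1L,
                                 cut_percentiles = c(20, 40, 60, 80)) {
  stopifnot(inherits(dataset, "spec_dataset"))
  stratify_on <- match.arg(stratify_on)
  if (!all(c("test", "val") %in% names(fractions)))
    stop("fractions must be named with 'test' and 'val'")
  if (sum(fractions) >= 1) stop("config error: fractions must sum to < 1")
  md <- dataset$metadata
  y <- dataset$references[[stratify_on]]
  multi_variety <- length(unique(md$variety)) > 1L
  grp <- if (multi_variety) paste(md$variety, md$vintage, sep = "/")
         else as.character(md$vintage)

  local_seed(seed)
  train_ids <- val_ids <- test_ids <- character(0)
  for (g in sort(unique(grp))) {
    in_g <- which(grp == g)
    bins <- compute_percentile_bins(y[in_g], cut_percentiles,
                                    ids = md$sample_id[in_g])
    for (b in sort(unique(bins$assignment))) {
      cell_ids <- sort(names(bins$assignment)[bins$assignment == b])
      n <- length(cell_ids)
      if (n < 3L) { train_ids <- c(train_ids, cell_ids); next }
      n_test <- max(1L, round_half_up(fractions[["test"]] * n))
      n_val <- max(1L, round_half_up(fractions[["val"]] * n))
      picked <- sample(cell_ids, n_test + n_val)
      test_ids <- c(test_ids, picked[seq_len(n_test)])
      val_ids <- c(val_ids, picked[n_test + seq_len(n_val)])
      train_ids <- c(train_ids, setdiff(cell_ids, picked))
    }
  }
  structure(list(train_ids = train_ids, val_ids = val_ids,
                 test_ids = test_ids, fractions = fractions,
                 seed = as.integer(seed), stratify_on = stratify_on,
                 grouping = if (multi_variety) "variety/vintage" else "vintage"),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split> train ", length(x$train_ids), " / val ",
      length(x$val_ids), " / test ", length(x$test_ids),
      " (stratified on ", x$stratify_on, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Repeated stratified splits
#'
#' Generates `n_repeats` independent splits seeded `base_seed + k - 1`,
#' `k = 1..n_repeats`, each satisfying the [stratified_partition()] contract.
#' Used to check that a reported performance is not an artifact of one lucky
#' split.
#'
#' @inheritParams stratified_partition
#' @param n_repeats number of splits (>= 1).
#' @param base_seed seed of the first split.
#' @return list of `dataset_split` objects.
#' @export
repeated_splits <- function(dataset, stratify_on = c("sugar", "ph"),
                            n_repeats = 10L, base_seed = 1L,
                            fractions = c(test = 0.1, val = 0.1)) {
  if (n_repeats < 1L) stop("n_repeats must be >= 1")
  stratify_on <- match.arg(stratify_on)
  lapply(seq_len(n_repeats), function(k)
    stratified_partition(dataset, stratify_on, fractions,
                         seed = base_seed + k - 1L))
}
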