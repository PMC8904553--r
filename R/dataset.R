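#' Class label from a refractive index
#'
#' Applies the tissue-analog labeling rule: liquids with label refractive
#' indices up to 1.38 stand for healthy tissue (class 0), those from 1.39
#' upward for neoplastic tissue (class 1). A tolerance of 1e-6 guards the
#' floating-point representation of the 0.01 index grid.
#'
#' @param refractive_index Numeric vector of label-scale (589.3 nm)
#'   refractive indices in `[1.30, 1.50]`.
#' @return Integer vector of 0 (healthy) / 1 (cancer).
#' @examples
#' assign_label(c(1.30, 1.38, 1.39, 1.50))
#' @export
assign_label <- function(refractive_index) {
  eps <- 1e-6
  if (!all(is.finite(refractive_index))) {
    stop("refractive indices must be finite", call. = FALSE)
  }
  if (any(refractive_index < 1.30 - eps | refractive_index > 1.50 + eps)) {
    stop("refractive index outside the calibrated range [1.30, 1.50]",
         call. = FALSE)
  }
  as.integer(refractive_index > 1.38 + eps)
}

#' Assemble a labeled dataset from feature rows
#'
#' Fills the `F18` target of a feature table from the per-row refractive
#' indices via [assign_label()] and records the class counts.
#'
#' @param features Data frame of feature rows (columns `F1`..`F18`,
#'   optionally with provenance columns as produced by
#'   [extract_feature_table()]).
#' @param refractive_index One label-scale refractive index per row;
#'   defaults to the table's `label_index` column when present.
#' @return An object of class `labeled_dataset` with fields `features`
#'   (the table with `F18` set), `refractive_index`, `n_healthy`, `n_sick`.
#' @export
build_dataset <- function(features,
                          refractive_index = features[["label_index"]]) {
  if (is.null(refractive_index) && nrow(features) > 0L) {
    stop("`refractive_index` is required (no label_index column found)",
         call. = FALSE)
  }
  if (nrow(features) == 0L) {
    features$F18 <- integer(0)
    return(structure(list(features = features,
                          refractive_index = numeric(0),
                          n_healthy = 0L, n_sick = 0L),
                     class = "labeled_dataset"))
  }
  if (length(refractive_index) != nrow(features)) {
    stop("one refractive index per feature row is required", call. = FALSE)
  }
  features$F18 <- assign_label(refractive_index)
  structure(
    list(features = features,
         refractive_index = as.numeric(refractive_index),
         n_healthy = sum(features$F18 == 0L),
         n_sick = sum(features$F18 == 1L)),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  n <- nrow(x$features)
  cat(sprintf("Labeled dataset: %d rows x 18 features\n", n))
  if (n > 0L) {
    cat(sprintf("  healthy (0): %d (%.0f%%), cancer (1): %d (%.0f%%)\n",
                x$n_healthy, 100 * x$n_healthy / n,
                x$n_sick, 100 * x$n_sick / n))
  }
  invisible(x)
}

# Row subset preserving the labeled_dataset structure.
subset_dataset <- function(ds, idx) {
  structure(
    list(features = ds$features[idx, , drop = FALSE],
         refractive_index = ds$refractive_index[idx],
         n_healthy = sum(ds$features$F18[idx] == 0L),
         n_sick = sum(ds$features$F18[idx] == 1L)),
    class = "labeled_dataset"
  )
}

#' Stratified held-out validation split
#'
#' Reserves a stratified fraction of the rows as a validation set never seen
#' during cross-validation or training. Per class, `round(fraction * n)` rows
#' are drawn, so class proportions are preserved to within one row per
#' class. With `group_by_liquid = TRUE` whole liquids (all replicates
#' sharing a `label_index`) are moved together, which avoids leakage between
#' near-identical replicate spectra at the cost of validating on entirely
#' unseen refractive indices.
#'
#' @param ds A [build_dataset()] result.
#' @param fraction Validation fraction in `(0, 1)`; default 0.2.
#' @param seed Integer seed; the split is deterministic given the seed.
#' @param group_by_liquid Keep replicates of one liquid together.
#' @return List with elements `train` and `validation` (both
#'   `labeled_dataset`) and the integer `validation_indices`.
#' @export
split_validation <- function(ds, fraction = 0.2, seed = 1L,
                             group_by_liquid = FALSE) {
  stopifnot_scalar(fraction, "fraction")
  if (fraction <= 0 || fraction >= 1) {
    stop("`fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  y <- ds$features$F18
  if (ds$n_healthy == 0L || ds$n_sick == 0L) {
    stop("both classes must be present to stratify", call. = FALSE)
  }
  val_idx <- integer(0)
  if (group_by_liquid) {
    li <- ds$features$label_index
    if (is.null(li) || anyNA(li)) {
      stop("group-aware splitting needs a complete label_index column",
           call. = FALSE)
    }
    for (cls in c(0L, 1L)) {
      groups <- unique(li[y == cls])
      n_take <- max(1L, round(fraction * length(groups)))
      take <- with_seed(seed + cls, sample(groups, n_take))
      val_idx <- c(val_idx, which(li %in% take))
    }
  } else {
    for (cls in c(0L, 1L)) {
      rows <- which(y == cls)
      n_take <- round(fraction * length(rows))
      if (n_take < 1L || n_take >= length(rows)) {
        stop("`fraction` leaves a class empty on one side of the split",
             call. = FALSE)
      }
      val_idx <- c(val_idx, with_seed(seed + cls, sample(rows, n_take)))
    }
  }
  val_idx <- sort(val_idx)
  list(train = subset_dataset(ds, setdiff(seq_along(y), val_idx)),
       validation = subset_dataset(ds, val_idx),
       validation_indices = val_idx)
}

#' Stratified k-fold plan
#'
#' Partitions the training rows into `k` folds whose per-fold class counts
#' differ from exact proportionality by less than one row (each class is
#' shuffled and dealt round-robin). Rerunning with the same seed reproduces
#' the plan exactly.
#'
#' @param ds Training `labeled_dataset`.
#' @param k Number of folds (>= 2, at most the smaller class size);
#'   default 3.
#' @param seed Integer seed.
#' @return An object of class `fold_plan`: list with `k` and the integer
#'   `fold` assignment (length = rows of `ds`).
#' @export
stratified_kfold <- function(ds, k = 3L, seed = 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("`k` must be an integer >= 2", call. = FALSE)
  y <- ds$features$F18
  smallest <- min(ds$n_healthy, ds$n_sick)
  if (k > smallest) {
    stop(sprintf("k = %d exceeds the smallest class size (%d)", k, smallest),
         call. = FALSE)
  }
  fold <- integer(length(y))
  for (cls in c(0L, 1L)) {
    rows <- which(y == cls)
    shuffled <- with_seed(seed + 10L * cls, sample(rows))
    fold[shuffled] <- rep_len(seq_len(k), length(shuffled))
  }
  structure(list(k = k, fold = fold, seed = seed), class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("Stratified %d-fold plan over %d rows\n", x$k, length(x$fold)))
  print(table(fold = x$fold))
  invisible(x)
}
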