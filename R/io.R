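#' Write one spectrum as a two-column text file
#'
#' OSA-style format: optional `#`-prefixed metadata comment lines followed
#' by one `wavelength<sep>power` line per sample.
#'
#' @param spectrum An [interferogram()].
#' @param path Output file path.
#' @param sep Column separator (default tab).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path, sep = "\t") {
  meta <- spectrum$metadata
  header <- vapply(names(meta), function(nm) {
    sprintf("# %s: %s", nm, format(meta[[nm]], digits = 17))
  }, "")
  body <- paste(format(spectrum$wavelength, digits = 12, trim = TRUE),
                format(spectrum$power, digits = 12, trim = TRUE), sep = sep)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a two-column spectrum file
#'
#' Accepts whitespace- or comma-delimited wavelength/power files as written
#' by optical spectrum analyzers; lines starting with `#` are treated as
#' `key: value` metadata comments. The delimiter is auto-detected.
#'
#' @param path File path.
#' @return An [interferogram()].
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_comment <- startsWith(trimws(lines), "#")
  meta <- list()
  for (cl in lines[is_comment]) {
    m <- regmatches(cl, regexec("^#\\s*([^:]+):\\s*(.*)$", trimws(cl)))[[1L]]
    if (length(m) == 3L) {
      val <- type.convert(m[3L], as.is = TRUE)
      meta[[trimws(m[2L])]] <- val
    }
  }
  data_lines <- lines[!is_comment]
  if (!length(data_lines)) stop("no data lines in ", path, call. = FALSE)
  sep_is_comma <- grepl(",", data_lines[1L], fixed = TRUE)
  parts <- if (sep_is_comma) {
    strsplit(data_lines, ",")
  } else {
    strsplit(trimws(data_lines), "[[:space:]]+")
  }
  mat <- vapply(parts, function(p) as.numeric(p[1:2]), numeric(2))
  interferogram(wavelength = mat[1L, ], power = mat[2L, ], metadata = meta)
}

#' Write a study design to disk
#'
#' One spectrum file per interferogram plus a `manifest.csv` listing file
#' name, label refractive index, operating index, replicate and noise seed.
#'
#' @param spectra List of [interferogram()] objects with study metadata.
#' @param dir Output directory (created if missing).
#' @return Path to the manifest, invisibly.
#' @export
write_study_design <- function(spectra, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(spectra), function(i) {
    fn <- sprintf("spectrum_%03d.txt", i)
    write_spectrum(spectra[[i]], file.path(dir, fn))
    meta <- spectra[[i]]$metadata
    data.frame(
      file = fn,
      label_index = if (is.null(meta$label_index)) NA_real_ else meta$label_index,
      operating_index = if (is.null(meta$operating_index)) NA_real_ else meta$operating_index,
      replicate = if (is.null(meta$replicate)) NA_integer_ else meta$replicate,
      seed = if (is.null(meta$seed)) NA_integer_ else meta$seed)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a study design from a manifest or directory
#'
#' @param path Either a manifest CSV or a directory containing one
#'   (`manifest.csv`).
#' @return List of [interferogram()] objects with manifest metadata merged.
#' @export
read_study_design <- function(path) {
  manifest_path <- if (dir.exists(path)) file.path(path, "manifest.csv") else path
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  manifest <- utils::read.csv(manifest_path)
  if (nrow(manifest) == 0L) stop("empty manifest", call. = FALSE)
  base_dir <- dirname(manifest_path)
  lapply(seq_len(nrow(manifest)), function(i) {
    sp <- read_spectrum(file.path(base_dir, manifest$file[i]))
    sp$metadata$source <- manifest$file[i]
    for (col in c("label_index", "operating_index", "replicate", "seed")) {
      if (!is.null(manifest[[col]]) && !is.na(manifest[[col]][i])) {
        sp$metadata[[col]] <- manifest[[col]][i]
      }
    }
    sp
  })
}

#' Write / read the feature table CSV
#'
#' The table keeps the provenance columns produced by
#' [extract_feature_table()] followed by `F1`..`F18`.
#'
#' @param features Feature data frame.
#' @param path CSV path.
#' @return `path` invisibly (writer) or the data frame (reader).
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path)
}

#' Export a split + fold plan as a CSV
#'
#' One row per dataset row with its role (`train`/`validation`) and, for
#' training rows, the fold number.
#'
#' @param split Result of [split_validation()] on the full dataset.
#' @param plan [stratified_kfold()] plan over the training rows.
#' @param n_total Total number of rows in the full dataset.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_fold_plan <- function(split, plan, n_total, path) {
  role <- rep("train", n_total)
  role[split$validation_indices] <- "validation"
  fold <- rep(NA_integer_, n_total)
  fold[setdiff(seq_len(n_total), split$validation_indices)] <- plan$fold
  utils::write.csv(
    data.frame(row_id = seq_len(n_total), role = role, fold = fold),
    path, row.names = FALSE)
  invisible(path)
}

#' Write the evaluation report
#'
#' Produces `report.json` (nested per-classifier, per-fold and validation
#' blocks with confusion counts, metrics and timings), `results.csv` (the
#' flat Classifier/Fold/Accuracy/Precision/Recall/F1 table) and
#' `confusion_matrices.csv` (2x2 blocks, one per classifier and split).
#'
#' @param experiment An `fp_experiment` from [run_experiment()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  blocks <- lapply(experiment$classifiers, function(res) {
    list(
      family = res$spec$family,
      hyperparameters = res$spec$hyperparameters,
      seed = res$spec$seed,
      folds = lapply(res$folds, function(fr) list(
        fold = fr$fold,
        confusion = fr$confusion[c("TP", "FP", "FN", "TN")],
        metrics = as.list(fr$metrics),
        confusion_train = fr$confusion_train[c("TP", "FP", "FN", "TN")],
        metrics_train = as.list(fr$metrics_train),
        train_time_s = fr$train_time, predict_time_s = fr$predict_time)),
      validation = list(
        confusion = res$validation$confusion[c("TP", "FP", "FN", "TN")],
        metrics = as.list(res$validation$metrics),
        train_time_s = res$validation$train_time))
  })
  jsonlite::write_json(
    list(k = experiment$k, fold_score = experiment$fold_score,
         n_train = experiment$n_train,
         n_validation = experiment$n_validation,
         classifiers = blocks),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  utils::write.csv(as.data.frame(experiment),
                   file.path(dir, "results.csv"), row.names = FALSE)
  con <- file(file.path(dir, "confusion_matrices.csv"), "w")
  on.exit(close(con))
  for (res in experiment$classifiers) {
    for (fr in res$folds) {
      writeLines(sprintf("%s fold %d,predicted cancer,predicted healthy",
                         res$spec$family, fr$fold), con)
      writeLines(sprintf("actual cancer,%d,%d", fr$confusion$TP,
                         fr$confusion$FN), con)
      writeLines(sprintf("actual healthy,%d,%d", fr$confusion$FP,
                         fr$confusion$TN), con)
    }
    cmv <- res$validation$confusion
    writeLines(sprintf("%s validation,predicted cancer,predicted healthy",
                       res$spec$family), con)
    writeLines(sprintf("actual cancer,%d,%d", cmv$TP, cmv$FN), con)
    writeLines(sprintf("actual healthy,%d,%d", cmv$FP, cmv$TN), con)
  }
  invisible(dir)
}
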