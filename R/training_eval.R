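as_binary_label <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    stop_if(!all(x %in% c("MDD", "HC")), "labels must be 'MDD' or 'HC'")
    as.integer(x == "MDD")
  } else if (is.logical(x)) {
    as.integer(x)
  } else {
    stop_if(!all(x %in% c(0, 1)), "numeric labels must be 0/1")
    as.integer(x)
  }
}

#' Classification metrics with the depressed class as positive
#'
#' Accuracy, precision, recall and F1 in percent, computed from the confusion
#' counts with `MDD` (label 1) as the positive class. Zero-denominator cases
#' (no predicted positives, no true positives, or an empty F1 denominator)
#' return 0 for the affected metric and are marked in `flags`.
#'
#' @param predictions predicted labels (`"MDD"`/`"HC"`, logical, or 0/1).
#' @param labels true labels, same encoding and length.
#' @return List of class `fold_metrics` with `acc`, `pre`, `rec`, `f1`
#'   (percentages), confusion counts `tp`, `fp`, `tn`, `fn`, and `flags`.
#' @export
compute_metrics <- function(predictions, labels) {
  stop_if(length(predictions) == 0, "empty input", "mdgraph_parameter_error")
  stop_if(length(predictions) != length(labels), "length mismatch",
          "mdgraph_shape_error")
  p <- as_binary_label(predictions)
  y <- as_binary_label(labels)
  tp <- sum(p == 1 & y == 1); fp <- sum(p == 1 & y == 0)
  tn <- sum(p == 0 & y == 0); fn <- sum(p == 0 & y == 1)
  flags <- character(0)
  acc <- 100 * (tp + tn) / length(y)
  if (tp + fp == 0) { pre <- 0; flags <- c(flags, "no_predicted_positives") }
  else pre <- 100 * tp / (tp + fp)
  if (tp + fn == 0) { rec <- 0; flags <- c(flags, "no_true_positives") }
  else rec <- 100 * tp / (tp + fn)
  if (pre + rec == 0) { f1 <- 0; flags <- c(flags, "f1_undefined") }
  else f1 <- 2 * pre * rec / (pre + rec)
  structure(list(acc = acc, pre = pre, rec = rec, f1 = f1,
                 tp = tp, fp = fp, tn = tn, fn = fn, flags = flags),
            class = "fold_metrics")
}

#' Cross-validation fold assignment
#'
#' Stratified fold labels per sample. With `split_unit = "subject"` (the
#' default) all segments of one subject land in the same fold, preventing
#' segment leakage between training and validation; subjects are shuffled per
#' class and dealt round-robin. With `split_unit = "segment"` individual
#' samples are stratified, preserving the class ratio within one sample.
#'
#' @param dataset an `mdd_fixture`.
#' @param k number of folds.
#' @param seed shuffling seed.
#' @param split_unit `"subject"` or `"segment"`.
#' @return Integer vector of fold ids (1..k), one per sample.
#' @export
make_folds <- function(dataset, k = 10, seed = 1,
                       split_unit = c("subject", "segment")) {
  split_unit <- match.arg(split_unit)
  labels <- vapply(dataset$samples, `[[`, "", "label")
  subjects <- vapply(dataset$samples, `[[`, "", "subject_id")
  set.seed(seed)
  fold <- integer(length(labels))
  if (split_unit == "subject") {
    for (cls in unique(labels)) {
      subj <- unique(subjects[labels == cls])
      stop_if(length(subj) < k,
              sprintf("class %s has %d subjects for %d folds", cls, length(subj), k),
              "mdgraph_stratification_error")
      subj <- sample(subj)
      assign_f <- rep(seq_len(k), length.out = length(subj))
      for (i in seq_along(subj)) fold[subjects == subj[i]] <- assign_f[i]
    }
  } else {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      stop_if(length(idx) < k,
              sprintf("class %s has %d samples for %d folds", cls, length(idx), k),
              "mdgraph_stratification_error")
      idx <- sample(idx)
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  }
  fold
}

#' k-fold cross-validated training and evaluation
#'
#' Trains one model per fold (re-initialized from a fold-specific seed derived
#' from `seed`), scores the held-out fold, and averages the per-fold metrics
#' with a plain arithmetic mean (confusion matrices are not pooled).
#'
#' @param dataset an `mdd_fixture`.
#' @param config a [model_config()].
#' @param k number of folds (default 10).
#' @param seed master seed; fold `i` trains with seed `seed * 100 + i`.
#' @param split_unit fold unit, see [make_folds()].
#' @return List of class `cv_report` with `folds` (per-fold metric data
#'   frame), `means`, `config`, `k`, `seed`, `split_unit`.
#' @export
run_cv <- function(dataset, config = model_config(), k = 10, seed = 1,
                   split_unit = c("subject", "segment")) {
  split_unit <- match.arg(split_unit)
  fold <- make_folds(dataset, k = k, seed = seed, split_unit = split_unit)
  labels <- vapply(dataset$samples, `[[`, "", "label")
  rows <- vector("list", k)
  for (i in seq_len(k)) {
    val_idx <- which(fold == i)
    train_idx <- which(fold != i)
    for (cls in unique(labels)) {
      stop_if(!any(labels[train_idx] == cls),
              sprintf("class %s absent from fold %d training split", cls, i),
              "mdgraph_stratification_error")
    }
    model <- train_model(dataset, config, seed = seed * 100 + i,
                         indices = train_idx, compute_attention = FALSE)
    prob <- predict_model(model, dataset, indices = val_idx)
    pred <- ifelse(prob[, "MDD"] >= 0.5, "MDD", "HC")
    m <- compute_metrics(pred, labels[val_idx])
    rows[[i]] <- data.frame(fold = i, n_val = length(val_idx),
                            acc = m$acc, pre = m$pre, rec = m$rec, f1 = m$f1,
                            tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn)
  }
  folds <- do.call(rbind, rows)
  means <- list(acc = mean(folds$acc), pre = mean(folds$pre),
                rec = mean(folds$rec), f1 = mean(folds$f1))
  structure(list(folds = folds, means = means, config = config, k = k,
                 seed = seed, split_unit = split_unit),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV (%s split): ACC %.2f%%  PRE %.2f%%  REC %.2f%%  F1 %.2f%%\n",
              x$k, x$split_unit, x$means$acc, x$means$pre, x$means$rec,
              x$means$f1))
  invisible(x)
}

#' Ablation grid over graph-unit depth
#'
#' Fixes the unit count of one modality at `fixed_layers` and varies the
#' other's over the requested values, running a full cross-validation per
#' cell. Duplicate cells (e.g. the shared fully-fixed configuration) are
#' computed once and reused.
#'
#' @param dataset an `mdd_fixture`.
#' @param eeg_layers,audio_layers unit counts to sweep per modality.
#' @param fixed_layers unit count of the non-varied modality.
#' @param config base [model_config()] (its `eeg_units`/`audio_units` are
#'   overridden per cell).
#' @param k,seed,split_unit forwarded to [run_cv()].
#' @return List of class `ablation_grid` with `table` (one row per cell:
#'   modality, layers, mean metrics) and `reports` (named list of
#'   [run_cv()] results keyed `"eeg<L>_audio<L>"`).
#' @export
run_ablation_grid <- function(dataset, eeg_layers = 0:4, audio_layers = 0:4,
                              fixed_layers = 3, config = model_config(),
                              k = 10, seed = 1,
                              split_unit = c("subject", "segment")) {
  split_unit <- match.arg(split_unit)
  stop_if(!all(c(eeg_layers, audio_layers) %in% 0:4),
          "layer counts must be in 0..4", "mdgraph_parameter_error")
  cells <- rbind(data.frame(modality = "EEG", layers = eeg_layers,
                            eeg = eeg_layers, audio = fixed_layers),
                 data.frame(modality = "Audio", layers = audio_layers,
                            eeg = fixed_layers, audio = audio_layers))
  reports <- list()
  rows <- vector("list", nrow(cells))
  for (r in seq_len(nrow(cells))) {
    key <- sprintf("eeg%d_audio%d", cells$eeg[r], cells$audio[r])
    if (is.null(reports[[key]])) {
      cfg <- config
      cfg$eeg_units <- cells$eeg[r]
      cfg$audio_units <- cells$audio[r]
      reports[[key]] <- run_cv(dataset, cfg, k = k, seed = seed,
                               split_unit = split_unit)
    }
    m <- reports[[key]]$means
    rows[[r]] <- data.frame(modality = cells$modality[r],
                            layers = cells$layers[r],
                            acc = m$acc, pre = m$pre, rec = m$rec, f1 = m$f1)
  }
  structure(list(table = do.call(rbind, rows), reports = reports,
                 fixed_layers = fixed_layers, k = k, seed = seed),
            class = "ablation_grid")
}

#' @export
print.ablation_grid <- function(x, ...) {
  cat(sprintf("Ablation grid (other modality fixed at %d units):\n", x$fixed_layers))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Write cross-validation reports to disk
#'
#' Emits per-fold metrics as CSV, the full report as JSON and a Markdown
#' summary table.
#'
#' @param report a [run_cv()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cv_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "cv_folds.csv")
  utils::write.csv(report$folds, csv, row.names = FALSE)
  js <- file.path(dir, "cv_report.json")
  jsonlite::write_json(list(folds = report$folds, means = report$means,
                            k = report$k, seed = report$seed,
                            split_unit = report$split_unit,
                            config = unclass(report$config)),
                       js, auto_unbox = TRUE, digits = NA)
  md <- file.path(dir, "cv_summary.md")
  writeLines(c("| Metric | Mean (%) |", "|---|---|",
               sprintf("| ACC | %.2f |", report$means$acc),
               sprintf("| PRE | %.2f |", report$means$pre),
               sprintf("| REC | %.2f |", report$means$rec),
               sprintf("| F1 | %.2f |", report$means$f1)), md)
  invisible(c(csv, js, md))
}

#' Write an ablation grid as a Markdown table
#'
#' @param grid a [run_ablation_grid()] result.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_ablation_table <- function(grid, path) {
  lines <- c("| Modality | Units | ACC (%) | PRE (%) | REC (%) | F1 (%) |",
             "|---|---|---|---|---|---|")
  for (r in seq_len(nrow(grid$table))) {
    t <- grid$table[r, ]
    lines <- c(lines, sprintf("| %s | %d | %.2f | %.2f | %.2f | %.2f |",
                              t$modality, t$layers, t$acc, t$pre, t$rec, t$f1))
  }
  writeLines(lines, path)
  invisible(path)
}
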