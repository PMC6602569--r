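# ROC/AUC machinery and the two-dataset benchmark harness. The AUC is the
# trapezoidal area under the empirical ROC curve with simultaneous steps at
# tied scores, which equals the Mann-Whitney U statistic divided by
# n1 * n0 with half credit for ties.

#' ROC curve and AUC
#'
#' Sweeps thresholds over the unique scores (descending), computing the
#' false- and true-positive rates with predicted-positive defined as
#' `score >= threshold`; tied scores step simultaneously. The curve starts at
#' (0, 0) and ends at (1, 1); the AUC is its trapezoidal area.
#'
#' @param scores Finite numeric scores.
#' @param labels 0/1 labels with both classes present.
#' @return A `roc_result`: list(thresholds, fpr, tpr, auc).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  ths <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(ths, function(t) sum(scores >= t & labels == 1L), numeric(1)) / n1
  fpr <- vapply(ths, function(t) sum(scores >= t & labels == 0L), numeric(1)) / n0
  tpr <- c(0, tpr)
  fpr <- c(0, fpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = c(Inf, ths), fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> %d threshold(s), AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Sensitivity at a threshold
#'
#' Counts positives whose score strictly exceeds the threshold.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold (default 0.5).
#' @return list(detected, total): detected positives and total positives.
#' @export
sensitivity_at <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  list(detected = sum(labels == 1L & scores > threshold),
       total = sum(labels == 1L))
}

#' Run a labeled benchmark through the full pipeline
#'
#' Maps every labeled mutation to a site under the database's mapping mode,
#' featurizes and scores the mappable ones, and summarizes detection counts
#' and AUC. Unmappable entries (no site, unknown protein, reference mismatch,
#' missing annotation) are excluded from the metrics and listed explicitly —
#' silent exclusion would inflate sensitivity.
#'
#' @param label_table data.frame from [read_label_table()].
#' @param db A `site_db`.
#' @param seqs Named sequences, or `NULL`.
#' @param model A `driver_model`.
#' @param name Dataset name for the report.
#' @param out_dir Optional directory to write the per-mutation score TSV and
#'   ROC points TSV into.
#' @return A `benchmark_report`: list(name, n_driver, n_passenger, n_scored,
#'   detected_drivers, auc, scores (data.frame), excluded (data.frame)).
#' @export
run_benchmark <- function(label_table, db, seqs = NULL, model, name,
                          out_dir = NULL) {
  if (nrow(label_table) == 0) stop("empty label table", call. = FALSE)
  muts <- data.frame(sample_id = name, gene_symbol = label_table$gene_symbol,
                     uniprot_id = label_table$uniprot_id,
                     ref_aa = label_table$ref_aa,
                     position = as.integer(label_table$position),
                     alt_aa = label_table$alt_aa, stringsAsFactors = FALSE)
  cohort <- new_cohort(muts, "LIST")
  mc <- suppressWarnings(map_cohort(cohort, db, seqs))
  mapped <- mc$mapped
  y <- as.integer(label_table$label == "driver")
  scoreable <- mapped$scoreable
  # drop rows whose residue annotation is missing as well
  ann_ok <- rep(TRUE, nrow(mapped))
  for (i in which(scoreable)) {
    if (is.null(residue_annotation_for(db, mapped$uniprot_id[i],
                                       mapped$position[i]))) {
      ann_ok[i] <- FALSE
    }
  }
  use <- scoreable & ann_ok
  if (!any(use)) stop("no mappable labeled mutations", call. = FALSE)
  x <- featurize_all(mapped[use, , drop = FALSE], db)
  sc <- predict(model, x)
  scores_df <- data.frame(
    uniprot_id = mapped$uniprot_id[use], gene_symbol = mapped$gene_symbol[use],
    mutation = paste0(mapped$ref_aa[use], mapped$position[use],
                      mapped$alt_aa[use]),
    area = mapped$area[use], label = label_table$label[use], score = sc,
    is_driver = classify_driver(sc, model$config$threshold),
    stringsAsFactors = FALSE)
  excluded <- data.frame(
    gene_symbol = mapped$gene_symbol[!use], uniprot_id = mapped$uniprot_id[!use],
    mutation = paste0(mapped$ref_aa[!use], mapped$position[!use],
                      mapped$alt_aa[!use]),
    reason = ifelse(mapped$ref_check[!use] == "mismatch",
                    "reference mismatch",
                    ifelse(!ann_ok[!use], "missing residue annotation",
                           "not on an active site")),
    stringsAsFactors = FALSE)
  if (nrow(excluded) > 0) {
    warning(sprintf("%d labeled mutation(s) excluded from benchmark metrics",
                    nrow(excluded)), call. = FALSE)
  }
  y_use <- y[use]
  auc <- if (length(unique(y_use)) == 2) roc_auc(sc, y_use)$auc else NA_real_
  sens <- sensitivity_at(sc, y_use, model$config$threshold)
  report <- structure(list(
    name = name, n_driver = sum(y == 1L), n_passenger = sum(y == 0L),
    n_scored = sum(use), detected_drivers = sens$detected, auc = auc,
    scores = scores_df, excluded = excluded), class = "benchmark_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(scores_df, file.path(out_dir, paste0(name, "_scores.tsv")))
    if (!is.na(auc)) {
      roc <- roc_auc(sc, y_use)
      write_tsv(data.frame(threshold = roc$thresholds, fpr = roc$fpr,
                           tpr = roc$tpr),
                file.path(out_dir, paste0(name, "_roc.tsv")))
    }
    write_tsv(data.frame(name = name, n_driver = report$n_driver,
                         n_passenger = report$n_passenger,
                         n_scored = report$n_scored,
                         detected_drivers = report$detected_drivers,
                         auc = report$auc),
              file.path(out_dir, paste0(name, "_summary.tsv")))
  }
  report
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("<benchmark_report> %s: %d/%d drivers detected (of %d scored), AUC = %s\n",
              x$name, x$detected_drivers, x$n_driver, x$n_scored,
              ifelse(is.na(x$auc), "NA", sprintf("%.3f", x$auc))))
  invisible(x)
}
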