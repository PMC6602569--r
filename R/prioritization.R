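# Turn per-mutation scores into the per-sample ranked driver-protein table
# and the annotation summaries: score profile, pan-cancer site-mutation
# frequency matrix and PFAM-style domain overlay.

#' Score all scoreable mutations of a mapped cohort
#'
#' Deduplicates identical mutations within a sample (duplicates still count
#' in frequency profiles, which are built from the full mapped frame), then
#' featurizes and scores them.
#'
#' @param mapped Mapped mutation frame from [map_cohort()].
#' @param db A `site_db`.
#' @param model A `driver_model`.
#' @param schema Feature schema.
#' @return data.frame: sample_id, gene_symbol, uniprot_id, ref_aa, position,
#'   alt_aa, area, score, is_driver.
#' @export
score_cohort <- function(mapped, db, model, schema = default_schema()) {
  sc <- mapped[mapped$scoreable, , drop = FALSE]
  key <- paste(sc$sample_id, sc$uniprot_id, sc$ref_aa, sc$position, sc$alt_aa)
  sc <- sc[!duplicated(key), , drop = FALSE]
  if (nrow(sc) == 0) {
    return(data.frame(sample_id = character(), gene_symbol = character(),
                      uniprot_id = character(), ref_aa = character(),
                      position = integer(), alt_aa = character(),
                      area = character(), score = numeric(),
                      is_driver = logical(), stringsAsFactors = FALSE))
  }
  x <- featurize_all(sc, db, schema)
  score <- predict(model, x)
  out <- sc[, c("sample_id", "gene_symbol", "uniprot_id", "ref_aa",
                "position", "alt_aa", "area")]
  out$score <- score
  out$is_driver <- classify_driver(score, model$config$threshold)
  rownames(out) <- NULL
  out
}

order_predictions <- function(p) {
  order(p$sample_id, -p$score, p$gene_symbol, p$position, method = "radix")
}

#' Rank driver targets per sample
#'
#' Keeps only predictions whose score strictly exceeds the threshold, ordered
#' within each sample by score descending with deterministic tie-breaks
#' (gene symbol ascending, then position ascending). A protein appears once
#' per qualifying driver mutation; its headline rank is driven by its best
#' mutation score.
#'
#' @param predictions data.frame from [score_cohort()].
#' @param threshold Driver threshold (default 0.5, strict).
#' @return A `ranked_targets` data.frame.
#' @export
rank_targets <- function(predictions, threshold = 0.5) {
  keep <- predictions[predictions$score > threshold &
                        predictions$area != "OTHER", , drop = FALSE]
  keep <- keep[order_predictions(keep), , drop = FALSE]
  rownames(keep) <- NULL
  class(keep) <- c("ranked_targets", "data.frame")
  keep
}

#' Score profile for one sample
#'
#' One row per scored site mutation, including sub-threshold ones (flagged by
#' `is_driver`), sorted by score descending with the same tie-breaks as the
#' ranking.
#'
#' @param predictions data.frame from [score_cohort()].
#' @param sample_id Sample to profile.
#' @return data.frame sorted by score.
#' @export
score_profile <- function(predictions, sample_id) {
  if (!sample_id %in% predictions$sample_id) {
    stop("unknown sample: ", sample_id, call. = FALSE)
  }
  p <- predictions[predictions$sample_id == sample_id, , drop = FALSE]
  p <- p[order_predictions(p), , drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Pan-cancer site-mutation frequency matrix
#'
#' Tallies clinical mutations falling on the active site residues of one
#' protein, grouped by cancer type: rows are the cancer types observed,
#' columns the on-site residue positions observed, cells raw mutation counts.
#'
#' @param clinical_table data.frame: cancer_type, uniprot_id, position,
#'   ref_aa, alt_aa.
#' @param db A `site_db`.
#' @param uniprot_id Protein of interest (must carry sites in the database).
#' @return Integer matrix (cancer types x site positions).
#' @export
pan_cancer_matrix <- function(clinical_table, db, uniprot_id) {
  s <- sites_for(db, uniprot_id)
  if (nrow(s) == 0) {
    stop("protein has no active sites in the database: ", uniprot_id,
         call. = FALSE)
  }
  site_res <- sort(unique(unlist(s$residues)))
  cl <- clinical_table[clinical_table$uniprot_id == uniprot_id &
                         clinical_table$position %in% site_res, , drop = FALSE]
  types <- sort(unique(cl$cancer_type))
  cols <- sort(unique(as.integer(cl$position)))
  m <- matrix(0L, nrow = length(types), ncol = length(cols),
              dimnames = list(types, as.character(cols)))
  for (i in seq_len(nrow(cl))) {
    m[cl$cancer_type[i], as.character(cl$position[i])] <-
      m[cl$cancer_type[i], as.character(cl$position[i])] + 1L
  }
  m
}

#' Domain overlay for predicted driver mutations
#'
#' Annotates each predicted driver position on a protein with the covering
#' PFAM-style domain(s) (1-based inclusive intervals, ordered by start;
#' `"none"` when uncovered) and its per-position frequency in the prediction
#' set.
#'
#' @param domain_table data.frame: uniprot_id, domain_name, start, end.
#' @param predictions data.frame from [score_cohort()] (driver rows are used).
#' @param uniprot_id Protein of interest.
#' @return data.frame: position, frequency, domains (comma-joined).
#' @export
domain_overlay <- function(domain_table, predictions, uniprot_id) {
  dom <- domain_table[domain_table$uniprot_id == uniprot_id, , drop = FALSE]
  if (nrow(dom) > 0 && any(dom$start > dom$end)) {
    stop("inverted domain interval (start > end)", call. = FALSE)
  }
  dom <- dom[order(dom$start, dom$domain_name, method = "radix"), , drop = FALSE]
  p <- predictions[predictions$uniprot_id == uniprot_id & predictions$is_driver,
                   , drop = FALSE]
  pos <- sort(unique(p$position))
  freq <- vapply(pos, function(q) sum(p$position == q), integer(1))
  domains <- vapply(pos, function(q) {
    hit <- dom$domain_name[dom$start <= q & q <= dom$end]
    if (length(hit) == 0) "none" else paste(hit, collapse = ",")
  }, character(1))
  data.frame(position = pos, frequency = freq, domains = domains,
             stringsAsFactors = FALSE)
}
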