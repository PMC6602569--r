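# Assign each mutation to one of the four areas (experimental allosteric,
# predicted allosteric, orthosteric, other) and build per-sample
# area-frequency profiles.
#
# Precedence for positions belonging to several overlapping sites is
# ORTHO > ALLO_EXP > ALLO_PRED (configurable via `precedence`): orthosteric
# membership is the more specific functional claim and keeps the four-area
# accounting mutually exclusive.

#' Map one mutation to a site area
#'
#' Resolves the gene symbol through the database's gene map (unless a UniProt
#' accession is already present), checks the stated reference residue against
#' the protein sequence, and assigns the area by membership of the position in
#' the active site residue sets.
#'
#' @param m One-row data.frame (or list) with sample_id, gene_symbol,
#'   uniprot_id, ref_aa, position, alt_aa.
#' @param db A `site_db`.
#' @param seqs Named sequences from [load_fasta()], or `NULL` to skip the
#'   reference check.
#' @param precedence Area precedence for overlapping sites.
#' @return A list: uniprot_id, area, site_id, pdb_id, ref_check
#'   (match/mismatch/unknown).
#' @export
map_mutation <- function(m, db, seqs = NULL,
                         precedence = c("ORTHO", "ALLO_EXP", "ALLO_PRED")) {
  uid <- m$uniprot_id
  if (is.null(uid) || is.na(uid)) uid <- unname(db$gene_map[m$gene_symbol])
  if (is.null(uid) || is.na(uid)) {
    return(list(uniprot_id = NA_character_, area = "OTHER",
                site_id = NA_character_, pdb_id = NA_character_,
                ref_check = "unknown"))
  }
  ref_check <- "unknown"
  if (!is.null(seqs) && uid %in% names(seqs)) {
    sq <- seqs[[uid]]
    if (m$position > nchar(sq)) {
      return(list(uniprot_id = uid, area = "OTHER", site_id = NA_character_,
                  pdb_id = NA_character_, ref_check = "mismatch"))
    }
    ref_check <- if (substr(sq, m$position, m$position) == m$ref_aa)
      "match" else "mismatch"
  }
  s <- sites_for(db, uid)
  area <- "OTHER"
  site_id <- NA_character_
  pdb_id <- NA_character_
  if (nrow(s) > 0) {
    hit <- vapply(s$residues, function(r) m$position %in% r, logical(1))
    if (any(hit)) {
      h <- s[hit, , drop = FALSE]
      h <- h[order(match(h$site_type, precedence), h$site_id,
                   method = "radix"), , drop = FALSE]
      area <- h$site_type[1]
      site_id <- h$site_id[1]
      pdb_id <- h$pdb_id[1]
    }
  }
  list(uniprot_id = uid, area = area, site_id = site_id, pdb_id = pdb_id,
       ref_check = ref_check)
}

#' Map a whole cohort
#'
#' Applies [map_mutation()] to every mutation. Mutations whose stated
#' reference residue disagrees with the sequence are handled per
#' `cfg$on_ref_mismatch`: by default they are excluded from scoring
#' (`scoreable = FALSE`) and counted under OTHER in profiles; `"error"`
#' aborts. Unknown genes are likewise skipped with a warning or abort per
#' `cfg$on_unknown_gene`.
#'
#' @param cohort A validated `cohort`.
#' @param db A `site_db`.
#' @param seqs Optional named sequences.
#' @param cfg A [validation_config()].
#' @param precedence Passed to [map_mutation()].
#' @return list(mapped = data.frame of mapped mutations, report = data.frame
#'   of per-mutation issues). The mapped frame keeps input order and adds
#'   uniprot_id, area, site_id, pdb_id, ref_check, scoreable.
#' @export
map_cohort <- function(cohort, db, seqs = NULL, cfg = validation_config(),
                       precedence = c("ORTHO", "ALLO_EXP", "ALLO_PRED")) {
  stopifnot(inherits(cohort, "cohort"), inherits(db, "site_db"))
  muts <- cohort$mutations
  n <- nrow(muts)
  res <- vector("list", n)
  issues <- list()
  for (i in seq_len(n)) {
    mm <- map_mutation(muts[i, ], db, seqs, precedence)
    if (is.na(mm$uniprot_id)) {
      if (cfg$on_unknown_gene == "error") {
        stop("unknown gene: ", muts$gene_symbol[i], call. = FALSE)
      }
      issues[[length(issues) + 1]] <- data.frame(
        sample_id = muts$sample_id[i], gene_symbol = muts$gene_symbol[i],
        position = muts$position[i], issue = "unknown gene",
        action = "mapped to OTHER", stringsAsFactors = FALSE)
    } else if (mm$ref_check == "mismatch") {
      if (cfg$on_ref_mismatch == "error") {
        stop(sprintf("reference residue mismatch: %s %s%d", mm$uniprot_id,
                     muts$ref_aa[i], muts$position[i]), call. = FALSE)
      }
      mm$area <- "OTHER"
      mm$site_id <- NA_character_
      mm$pdb_id <- NA_character_
      issues[[length(issues) + 1]] <- data.frame(
        sample_id = muts$sample_id[i], gene_symbol = muts$gene_symbol[i],
        position = muts$position[i], issue = "reference residue mismatch",
        action = "excluded from scoring", stringsAsFactors = FALSE)
    }
    res[[i]] <- mm
  }
  mapped <- muts
  mapped$uniprot_id <- vapply(res, `[[`, character(1), "uniprot_id")
  mapped$area <- vapply(res, `[[`, character(1), "area")
  mapped$site_id <- vapply(res, `[[`, character(1), "site_id")
  mapped$pdb_id <- vapply(res, `[[`, character(1), "pdb_id")
  mapped$ref_check <- vapply(res, `[[`, character(1), "ref_check")
  mapped$scoreable <- mapped$area != "OTHER" & mapped$ref_check != "mismatch"
  rownames(mapped) <- NULL
  report <- if (length(issues)) do.call(rbind, issues) else
    data.frame(sample_id = character(), gene_symbol = character(),
               position = integer(), issue = character(), action = character(),
               stringsAsFactors = FALSE)
  if (nrow(report) > 0 && (cfg$on_unknown_gene == "skip_warn" ||
                           cfg$on_ref_mismatch == "skip_warn")) {
    warning(sprintf("%d mutation(s) with mapping issues (see report)",
                    nrow(report)), call. = FALSE)
  }
  list(mapped = mapped, report = report)
}

#' Area-frequency profile for one sample
#'
#' Tallies the mapped mutations of one sample over the four areas and per
#' mapped protein (stacked per-protein counts).
#'
#' @param mapped Mapped mutation data.frame from [map_cohort()].
#' @param sample_id Sample to profile.
#' @return list(sample_id, counts = named integer vector over the four areas,
#'   per_protein = gene x area count matrix), class `area_profile`.
#' @export
area_profile <- function(mapped, sample_id) {
  m <- mapped[mapped$sample_id == sample_id, , drop = FALSE]
  counts <- vapply(AREAS, function(a) sum(m$area == a), integer(1))
  genes <- sort(unique(m$gene_symbol))
  per_protein <- matrix(0L, nrow = length(genes), ncol = length(AREAS),
                        dimnames = list(genes, AREAS))
  for (i in seq_len(nrow(m))) {
    per_protein[m$gene_symbol[i], m$area[i]] <-
      per_protein[m$gene_symbol[i], m$area[i]] + 1L
  }
  structure(list(sample_id = sample_id, counts = counts,
                 per_protein = per_protein),
            class = "area_profile")
}

#' @export
print.area_profile <- function(x, ...) {
  cat(sprintf("<area_profile> sample %s: %s\n", x$sample_id,
              paste(names(x$counts), x$counts, sep = "=", collapse = " ")))
  invisible(x)
}
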