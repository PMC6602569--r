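# Site database: allosteric/orthosteric site annotations, per-residue
# structural attributes and the gene -> UniProt map. Residue numbering is
# 1-based UniProt sequence coordinates throughout; the pdb_id field is
# annotation only.

SITE_TYPES <- c("ORTHO", "ALLO_EXP", "ALLO_PRED")
AREAS <- c("ALLO_EXP", "ALLO_PRED", "ORTHO", "OTHER")

#' Load the site database
#'
#' Reads the three tables consumed by mapping and featurization: site records
#' (residue sets typed as experimentally verified allosteric, predicted
#' allosteric or orthosteric), per-residue structural annotations (wild-type
#' residue, relative solvent accessibility, flexibility proxy) and the
#' gene-symbol to UniProt map. In `"allosteric"` mapping mode, orthosteric
#' records are loaded but inactive for mapping; in `"functional"` mode all
#' records are active.
#'
#' @param sites_path TSV: uniprot_id, gene_symbol, pdb_id, site_id, site_type
#'   (ALLO_EXP/ALLO_PRED/ORTHO), residues (comma-separated 1-based positions).
#' @param residues_path TSV: uniprot_id, position, wt_aa, rsa, flex.
#' @param genemap_path Two-column TSV: gene_symbol, uniprot_id.
#' @param mode `"allosteric"` or `"functional"` mapping area.
#' @return A `site_db` object.
#' @export
load_site_db <- function(sites_path, residues_path, genemap_path,
                         mode = c("allosteric", "functional")) {
  mode <- match.arg(mode)
  sites <- read_tsv_checked(sites_path, required = c("uniprot_id", "gene_symbol",
                                                     "pdb_id", "site_id",
                                                     "site_type", "residues"))
  bad_type <- !sites$site_type %in% SITE_TYPES
  if (any(bad_type)) {
    stop("invalid site_type value(s): ",
         paste(unique(sites$site_type[bad_type]), collapse = ", "), call. = FALSE)
  }
  key <- paste(sites$uniprot_id, sites$site_id)
  if (anyDuplicated(key)) {
    stop("duplicate (uniprot_id, site_id): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  res_sets <- lapply(strsplit(as.character(sites$residues), ","), function(v) {
    v <- trimws(v)
    if (length(v) == 0 || any(!grepl("^[0-9]+$", v))) {
      stop("site residue lists must be comma-separated positive integers",
           call. = FALSE)
    }
    sort(unique(as.integer(v)))
  })
  if (any(lengths(res_sets) == 0)) stop("empty site residue set", call. = FALSE)
  sites$residues <- I(res_sets)

  resid <- read_tsv_checked(residues_path, required = c("uniprot_id", "position",
                                                        "wt_aa", "rsa", "flex"))
  resid$position <- as.integer(resid$position)
  resid$rsa <- as.numeric(resid$rsa)
  resid$flex <- as.numeric(resid$flex)
  if (any(is.na(resid$rsa)) || any(resid$rsa < 0 | resid$rsa > 1)) {
    stop("rsa values must lie in [0, 1]", call. = FALSE)
  }
  rkey <- paste(resid$uniprot_id, resid$position)
  if (anyDuplicated(rkey)) {
    stop("duplicate (uniprot_id, position) in residue annotations", call. = FALSE)
  }

  gm <- read_tsv_checked(genemap_path, required = c("gene_symbol", "uniprot_id"))
  gene_map <- stats::setNames(as.character(gm$uniprot_id),
                              as.character(gm$gene_symbol))
  structure(list(sites = sites,
                 residue_annotations = resid,
                 residue_index = stats::setNames(seq_len(nrow(resid)), rkey),
                 gene_map = gene_map,
                 mode = mode),
            class = "site_db")
}

#' @export
print.site_db <- function(x, ...) {
  cn <- site_counts(x)
  cat(sprintf("<site_db> %d protein(s); sites: %s; mode=%s\n",
              length(unique(x$sites$uniprot_id)),
              paste(names(cn), cn, sep = "=", collapse = " "), x$mode))
  invisible(x)
}

#' Per-type site counts
#'
#' @param db A `site_db`.
#' @return Named integer vector over ALLO_EXP, ALLO_PRED, ORTHO.
#' @export
site_counts <- function(db) {
  stopifnot(inherits(db, "site_db"))
  vapply(c("ALLO_EXP", "ALLO_PRED", "ORTHO"),
         function(t) sum(db$sites$site_type == t), integer(1))
}

site_is_active <- function(db, site_type) {
  db$mode == "functional" | site_type != "ORTHO"
}

#' Active site records for one protein, in canonical order
#'
#' Order is site_type ORTHO, ALLO_EXP, ALLO_PRED, then site_id lexicographic;
#' an unknown accession yields an empty set. In `"allosteric"` mode ORTHO
#' records are hidden.
#'
#' @param db A `site_db`.
#' @param uniprot_id Accession to query.
#' @return data.frame subset of the site table (residues is a list column).
#' @export
sites_for <- function(db, uniprot_id) {
  stopifnot(inherits(db, "site_db"))
  s <- db$sites[db$sites$uniprot_id == uniprot_id &
                  site_is_active(db, db$sites$site_type), , drop = FALSE]
  if (nrow(s) == 0) return(s)
  ord <- order(match(s$site_type, SITE_TYPES), s$site_id, method = "radix")
  s <- s[ord, , drop = FALSE]
  rownames(s) <- NULL
  s
}

residue_annotation_for <- function(db, uniprot_id, position) {
  i <- db$residue_index[paste(uniprot_id, position)]
  if (is.na(i)) return(NULL)
  db$residue_annotations[i, , drop = FALSE]
}

#' Cross-validate site annotations against protein sequences
#'
#' Checks that every annotated wild-type residue matches the FASTA sequence
#' and that all site residues fall within sequence bounds. Violations are
#' reported, not silently dropped.
#'
#' @param db A `site_db`.
#' @param seqs Named sequence vector from [load_fasta()].
#' @return data.frame of violations (uniprot_id, position, issue); zero rows
#'   when consistent.
#' @export
check_site_db <- function(db, seqs) {
  stopifnot(inherits(db, "site_db"))
  viol <- list()
  ra <- db$residue_annotations
  for (i in seq_len(nrow(ra))) {
    uid <- ra$uniprot_id[i]
    if (!uid %in% names(seqs)) next
    sq <- seqs[[uid]]
    pos <- ra$position[i]
    if (pos > nchar(sq)) {
      viol[[length(viol) + 1]] <- data.frame(uniprot_id = uid, position = pos,
                                             issue = "position beyond sequence",
                                             stringsAsFactors = FALSE)
    } else if (substr(sq, pos, pos) != ra$wt_aa[i]) {
      viol[[length(viol) + 1]] <- data.frame(uniprot_id = uid, position = pos,
                                             issue = "wt_aa/FASTA mismatch",
                                             stringsAsFactors = FALSE)
    }
  }
  for (i in seq_len(nrow(db$sites))) {
    uid <- db$sites$uniprot_id[i]
    if (!uid %in% names(seqs)) next
    over <- db$sites$residues[[i]][db$sites$residues[[i]] > nchar(seqs[[uid]])]
    for (pos in over) {
      viol[[length(viol) + 1]] <- data.frame(uniprot_id = uid, position = pos,
                                             issue = "site residue beyond sequence",
                                             stringsAsFactors = FALSE)
    }
  }
  if (length(viol)) do.call(rbind, viol) else
    data.frame(uniprot_id = character(), position = integer(),
               issue = character(), stringsAsFactors = FALSE)
}
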