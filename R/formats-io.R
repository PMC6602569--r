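# Input parsers and output writers for every external table the pipeline
# touches: MAF cohorts, ANNOVAR single-sample output, plain mutation lists,
# protein FASTA, driver/passenger label tables and the ranked target table.

TARGET_TABLE_COLUMNS <- c("Sample", "Gene/Protein", "UniProt ID",
                          "Driver mutation", "Location", "Area", "Score")

read_tsv_checked <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "", fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

split_lines <- function(text) {
  # tolerate \n and \r\n endings
  strsplit(gsub("\r\n", "\n", text, fixed = TRUE), "\n", fixed = TRUE)[[1]]
}

#' Parse an HGVS-style protein change
#'
#' Accepts `V600E`, `p.V600E` and three-letter `p.Val600Glu` forms and
#' decomposes them into reference residue, 1-based position and alternate
#' residue (one-letter codes).
#'
#' @param x Character vector of protein-change strings.
#' @return A data.frame with columns `ref_aa`, `position`, `alt_aa`; rows are
#'   `NA` where the string is not a parseable missense substitution.
#' @export
parse_protein_change <- function(x) {
  x <- sub("^p\\.", "", trimws(x))
  out <- data.frame(ref_aa = NA_character_, position = NA_integer_,
                    alt_aa = NA_character_, stringsAsFactors = FALSE)[rep(1, length(x)), , drop = FALSE]
  rownames(out) <- NULL
  one <- regmatches(x, regexec("^([A-Z])([0-9]+)([A-Z])$", x))
  three <- regmatches(x, regexec("^([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$", x))
  for (i in seq_along(x)) {
    m <- one[[i]]
    if (length(m) == 4 && is_aa(m[2]) && is_aa(m[4])) {
      out$ref_aa[i] <- m[2]
      out$position[i] <- as.integer(m[3])
      out$alt_aa[i] <- m[4]
      next
    }
    m <- three[[i]]
    if (length(m) == 4 && m[2] %in% names(AA_THREE_TO_ONE) &&
        m[4] %in% names(AA_THREE_TO_ONE)) {
      out$ref_aa[i] <- unname(AA_THREE_TO_ONE[m[2]])
      out$position[i] <- as.integer(m[3])
      out$alt_aa[i] <- unname(AA_THREE_TO_ONE[m[4]])
    }
  }
  out
}

empty_mutations <- function() {
  data.frame(sample_id = character(), gene_symbol = character(),
             uniprot_id = character(), ref_aa = character(),
             position = integer(), alt_aa = character(),
             stringsAsFactors = FALSE)
}

new_cohort <- function(mutations, source_format) {
  structure(list(mutations = mutations, source_format = source_format),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d mutation(s) across %d sample(s) [%s]\n",
              nrow(x$mutations), length(unique(x$mutations$sample_id)),
              x$source_format))
  invisible(x)
}

#' Parse a plain mutation list
#'
#' One mutation per line in the grammar `sample;gene;V600E`. Synonymous
#' changes (reference equal to alternate residue) are dropped and reported in
#' the `rejected` attribute rather than raising an error.
#'
#' @param text Multi-line character scalar (or vector of lines).
#' @return A data.frame of valid records with columns `sample_id`,
#'   `gene_symbol`, `ref_aa`, `position`, `alt_aa` and an attribute
#'   `rejected` (data.frame of line number + reason).
#' @export
parse_mutation_list <- function(text) {
  lines <- if (length(text) == 1) split_lines(text) else text
  keep <- which(nzchar(trimws(lines)))
  recs <- list()
  rejected <- data.frame(line = integer(), reason = character(),
                         stringsAsFactors = FALSE)
  for (i in keep) {
    fields <- trimws(strsplit(lines[i], ";", fixed = TRUE)[[1]])
    if (length(fields) != 3 || any(!nzchar(fields))) {
      stop(sprintf("line %d: expected 'sample;gene;RefPosAlt', got '%s'",
                   i, lines[i]), call. = FALSE)
    }
    pc <- parse_protein_change(fields[3])
    if (is.na(pc$ref_aa)) {
      stop(sprintf(
        "line %d: invalid protein change '%s' (expected e.g. V600E with a reference residue, position and alternate residue)",
        i, fields[3]), call. = FALSE)
    }
    if (pc$ref_aa == pc$alt_aa) {
      rejected <- rbind(rejected, data.frame(
        line = i, reason = sprintf("synonymous change '%s'", fields[3]),
        stringsAsFactors = FALSE))
      next
    }
    recs[[length(recs) + 1]] <- data.frame(
      sample_id = fields[1], gene_symbol = fields[2],
      ref_aa = pc$ref_aa, position = pc$position, alt_aa = pc$alt_aa,
      stringsAsFactors = FALSE)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    empty_mutations()[, c("sample_id", "gene_symbol", "ref_aa", "position", "alt_aa")]
  attr(out, "rejected") <- rejected
  out
}

#' Parse a mutation list into a cohort
#'
#' @param text See [parse_mutation_list()].
#' @return A `cohort` object.
#' @export
parse_list_cohort <- function(text) {
  recs <- parse_mutation_list(text)
  muts <- data.frame(sample_id = recs$sample_id, gene_symbol = recs$gene_symbol,
                     uniprot_id = NA_character_, ref_aa = recs$ref_aa,
                     position = recs$position, alt_aa = recs$alt_aa,
                     stringsAsFactors = FALSE)
  new_cohort(muts, "LIST")
}

#' Parse a MAF file into a cohort
#'
#' Reads a tab-separated Mutation Annotation Format file, keeps only rows with
#' `Variant_Classification == "Missense_Mutation"`, and decomposes
#' `HGVSp_Short` (e.g. `p.V600E`) into protein coordinates. Rows with an
#' unparseable protein change are skipped with a warning; genomic columns are
#' ignored (the method operates purely in protein coordinates).
#'
#' @param path Path to the MAF file.
#' @return A `cohort` object (possibly multiple samples).
#' @export
parse_maf <- function(path) {
  df <- read_tsv_checked(path, required = c("Hugo_Symbol", "Tumor_Sample_Barcode",
                                            "Variant_Classification", "HGVSp_Short"))
  df <- df[df$Variant_Classification == "Missense_Mutation", , drop = FALSE]
  pc <- parse_protein_change(df$HGVSp_Short)
  bad <- is.na(pc$ref_aa) | (pc$ref_aa == pc$alt_aa)
  if (any(bad)) {
    warning(sprintf("skipped %d MAF row(s) with unparseable or synonymous HGVSp_Short",
                    sum(bad)), call. = FALSE)
  }
  muts <- data.frame(sample_id = as.character(df$Tumor_Sample_Barcode)[!bad],
                     gene_symbol = as.character(df$Hugo_Symbol)[!bad],
                     uniprot_id = NA_character_,
                     ref_aa = pc$ref_aa[!bad], position = pc$position[!bad],
                     alt_aa = pc$alt_aa[!bad], stringsAsFactors = FALSE)
  new_cohort(muts, "MAF")
}

#' Parse ANNOVAR gene-annotation output into a single-sample cohort
#'
#' All mutations in the file are treated as one sample whose id is the file
#' stem. Both the headered table form (`ExonicFunc.*` / `AAChange.*` columns)
#' and the headerless `exonic_variant_function` form are understood; only
#' `nonsynonymous SNV` rows are retained. The amino-acid-change field uses the
#' colon-delimited grammar `GENE:TRANSCRIPT:exon:c.X:p.V600E`.
#'
#' @param path Path to the ANNOVAR output file.
#' @return A `cohort` object with a single sample.
#' @export
parse_annovar <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sample_id <- tools::file_path_sans_ext(basename(path))
  first <- readLines(path, n = 1)
  headered <- grepl("AAChange", first)
  if (headered) {
    df <- read_tsv_checked(path)
    fn_col <- grep("^ExonicFunc", names(df), value = TRUE)[1]
    aa_col <- grep("^AAChange", names(df), value = TRUE)[1]
    if (is.na(fn_col) || is.na(aa_col)) {
      stop("ANNOVAR file lacks ExonicFunc/AAChange columns", call. = FALSE)
    }
    func <- df[[fn_col]]
    aach <- df[[aa_col]]
  } else {
    raw <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                             stringsAsFactors = FALSE, fileEncoding = "UTF-8")
    known <- c("nonsynonymous SNV", "synonymous SNV", "stopgain", "stoploss",
               "frameshift insertion", "frameshift deletion",
               "nonframeshift insertion", "nonframeshift deletion", "unknown")
    hits <- vapply(seq_len(ncol(raw)),
                   function(j) sum(raw[[j]] %in% known), integer(1))
    fn_idx <- which.max(hits)
    if (hits[fn_idx] == 0 || fn_idx == ncol(raw)) {
      stop("no missense mutations found in ", basename(path), call. = FALSE)
    }
    func <- raw[[fn_idx]]
    aach <- raw[[fn_idx + 1]]
  }
  keep <- which(func == "nonsynonymous SNV")
  recs <- list()
  for (i in keep) {
    # one row may list several transcripts, comma-separated
    for (tok in strsplit(aach[i], ",", fixed = TRUE)[[1]]) {
      parts <- strsplit(trimws(tok), ":", fixed = TRUE)[[1]]
      pchg <- grep("^p\\.", parts, value = TRUE)
      if (length(pchg) == 0) next
      pc <- parse_protein_change(pchg[1])
      if (is.na(pc$ref_aa) || pc$ref_aa == pc$alt_aa) next
      recs[[length(recs) + 1]] <- data.frame(
        sample_id = sample_id, gene_symbol = parts[1],
        uniprot_id = NA_character_, ref_aa = pc$ref_aa,
        position = pc$position, alt_aa = pc$alt_aa, stringsAsFactors = FALSE)
      break
    }
  }
  if (length(recs) == 0) {
    stop("no missense mutations found in ", basename(path), call. = FALSE)
  }
  new_cohort(do.call(rbind, recs), "ANNOVAR")
}

#' Validation configuration for cohorts
#'
#' @param max_mutations_per_sample Samples with more mutations are rejected
#'   (default 2000).
#' @param on_unknown_gene What to do with mutations on genes absent from the
#'   site database's gene map: `"skip_warn"` (default) or `"error"`.
#' @param on_ref_mismatch What to do when the stated reference residue
#'   disagrees with the protein sequence: `"skip_warn"` (default) or `"error"`.
#' @return A `validation_config` list.
#' @export
validation_config <- function(max_mutations_per_sample = 2000,
                              on_unknown_gene = c("skip_warn", "error"),
                              on_ref_mismatch = c("skip_warn", "error")) {
  stopifnot(max_mutations_per_sample >= 1)
  structure(list(max_mutations_per_sample = as.integer(max_mutations_per_sample),
                 on_unknown_gene = match.arg(on_unknown_gene),
                 on_ref_mismatch = match.arg(on_ref_mismatch)),
            class = "validation_config")
}

#' Validate a cohort against per-sample limits
#'
#' Samples whose mutation count exceeds `max_mutations_per_sample` are
#' rejected and listed in the report; accepted samples pass through unchanged.
#'
#' @param cohort A `cohort`.
#' @param cfg A [validation_config()].
#' @return A list with elements `cohort` (accepted samples only) and `report`
#'   (data.frame: sample_id, n_mutations, status, reason).
#' @export
validate_cohort <- function(cohort, cfg = validation_config()) {
  stopifnot(inherits(cohort, "cohort"))
  muts <- cohort$mutations
  ids <- unique(muts$sample_id)
  n <- vapply(ids, function(s) sum(muts$sample_id == s), integer(1))
  over <- n > cfg$max_mutations_per_sample
  report <- data.frame(
    sample_id = ids, n_mutations = unname(n),
    status = ifelse(over, "rejected", "accepted"),
    reason = ifelse(over, sprintf("exceeds %d mutations",
                                  cfg$max_mutations_per_sample), ""),
    stringsAsFactors = FALSE)
  if (all(over) && length(ids) > 0) {
    stop("empty cohort after validation: all samples exceed the mutation cap",
         call. = FALSE)
  }
  kept <- muts[muts$sample_id %in% ids[!over], , drop = FALSE]
  rownames(kept) <- NULL
  list(cohort = new_cohort(kept, cohort$source_format), report = report)
}

#' Load protein sequences from FASTA keyed by UniProt accession
#'
#' Headers in the UniProt convention `>sp|Q06124|PTN11_HUMAN desc` are keyed
#' by the accession (second pipe-delimited field); other headers by their
#' first whitespace-delimited token.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of amino-acid sequences.
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  hdr <- names(set)
  first <- vapply(strsplit(hdr, "[[:space:]]+"), `[`, character(1), 1)
  acc <- vapply(first, function(tok) {
    parts <- strsplit(tok, "|", fixed = TRUE)[[1]]
    if (length(parts) >= 2) parts[2] else parts[1]
  }, character(1), USE.NAMES = FALSE)
  if (anyDuplicated(acc)) {
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "), call. = FALSE)
  }
  seqs <- as.character(set)
  bad <- vapply(seqs, function(s) {
    any(!strsplit(s, "")[[1]] %in% AA_LETTERS)
  }, logical(1))
  if (any(bad)) {
    stop("non-amino-acid characters in FASTA record(s): ",
         paste(acc[bad], collapse = ", "), call. = FALSE)
  }
  stats::setNames(unname(seqs), acc)
}

#' Read a driver/passenger label table
#'
#' @param path TSV with columns uniprot_id, gene_symbol, ref_aa, position,
#'   alt_aa, label (driver/passenger), source.
#' @return Validated data.frame.
#' @export
read_label_table <- function(path) {
  df <- read_tsv_checked(path, required = c("uniprot_id", "gene_symbol",
                                            "ref_aa", "position", "alt_aa",
                                            "label", "source"))
  if (nrow(df) == 0) stop("empty label table: ", basename(path), call. = FALSE)
  bad <- !df$label %in% c("driver", "passenger")
  if (any(bad)) stop("invalid label value(s): ",
                     paste(unique(df$label[bad]), collapse = ", "), call. = FALSE)
  key <- paste(df$uniprot_id, df$position, df$ref_aa, df$alt_aa)
  lab_per_key <- tapply(df$label, key, function(l) length(unique(l)))
  if (any(lab_per_key > 1)) {
    stop("conflicting labels for mutation(s): ",
         paste(names(lab_per_key)[lab_per_key > 1], collapse = "; "),
         call. = FALSE)
  }
  df$position <- as.integer(df$position)
  df
}

format_num <- function(x) {
  vapply(x, function(v) format(v, digits = 15, scientific = FALSE, trim = TRUE),
         character(1))
}

#' Write the ranked target table
#'
#' Emits the per-sample driver summary as TSV with columns Sample,
#' Gene/Protein, UniProt ID, Driver mutation, Location, Area, Score, sorted by
#' score descending within sample.
#'
#' @param ranked A `ranked_targets` data.frame from [rank_targets()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_target_table <- function(ranked, path) {
  out <- data.frame(
    Sample = ranked$sample_id,
    `Gene/Protein` = ranked$gene_symbol,
    `UniProt ID` = ranked$uniprot_id,
    `Driver mutation` = paste0(ranked$ref_aa, ranked$position, ranked$alt_aa),
    Location = ranked$position,
    Area = ranked$area,
    Score = format_num(ranked$score),
    check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(ranked) == 0) out <- out[0, , drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(TARGET_TABLE_COLUMNS, collapse = "\t"), con)
  if (nrow(out) > 0) {
    writeLines(do.call(paste, c(lapply(out, as.character), sep = "\t")), con)
  }
  invisible(path)
}

#' Read back a target table written by [write_target_table()]
#'
#' @param path Path to the TSV.
#' @return data.frame with the canonical columns; Score numeric, Location
#'   integer.
#' @export
read_target_table <- function(path) {
  df <- read_tsv_checked(path, required = TARGET_TABLE_COLUMNS)
  df$Location <- as.integer(df$Location)
  df$Score <- as.numeric(df$Score)
  df
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    cols <- lapply(df, function(x) if (is.numeric(x) && !is.integer(x)) format_num(x) else as.character(x))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}
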