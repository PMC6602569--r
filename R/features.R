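# Featurization of site-mapped mutations. The v1 schema is a fixed-order,
# 11-feature descriptor combining site-type one-hot flags, the local
# structural annotations (relative solvent accessibility, flexibility proxy)
# and physicochemical substitution deltas from standard residue property
# tables. Model code is schema-agnostic: schemas are versioned so a richer
# feature set can be added without breaking stored models.

#' The default (v1) feature schema
#'
#' Eleven features, in fixed order: `is_allo_exp`, `is_allo_pred`, `is_ortho`
#' (one-hot over the three site areas); `rsa` (relative solvent accessibility
#' of the wild-type residue, \[0,1\]); `flex` (z-scored flexibility proxy);
#' `d_hydropathy` (Kyte-Doolittle, alt minus ref); `d_volume` (residue volume
#' in cubic Angstrom, alt minus ref); `d_charge` (formal charge at pH 7, alt
#' minus ref); `blosum62` (substitution score ref to alt); `pro_introduced`
#' and `gly_lost` (0/1 backbone-disruption flags).
#'
#' @return A `feature_schema`: list(names, version).
#' @export
default_schema <- function() {
  structure(list(
    names = c("is_allo_exp", "is_allo_pred", "is_ortho", "rsa", "flex",
              "d_hydropathy", "d_volume", "d_charge", "blosum62",
              "pro_introduced", "gly_lost"),
    version = "v1"), class = "feature_schema")
}

#' Featurize one site-mapped mutation
#'
#' Only mutations mapped to a site (area other than OTHER) are scoreable; a
#' residue annotation must exist for the (protein, position) pair. The
#' function is total on that domain: it either returns a complete finite
#' vector or fails.
#'
#' @param mm One-row data.frame from the mapped frame of [map_cohort()].
#' @param db A `site_db`.
#' @param schema A [default_schema()]-style schema.
#' @return Named numeric vector in schema order.
#' @export
featurize <- function(mm, db, schema = default_schema()) {
  if (mm$area == "OTHER") {
    stop("not scoreable: mutation is not mapped to any site", call. = FALSE)
  }
  ra <- residue_annotation_for(db, mm$uniprot_id, mm$position)
  if (is.null(ra)) {
    stop(sprintf("missing residue annotation for (%s, %d)",
                 mm$uniprot_id, mm$position), call. = FALSE)
  }
  ref <- mm$ref_aa
  alt <- mm$alt_aa
  if (!is_aa(ref) || !is_aa(alt)) {
    stop("residues must be standard one-letter amino acids", call. = FALSE)
  }
  v <- c(
    is_allo_exp   = as.numeric(mm$area == "ALLO_EXP"),
    is_allo_pred  = as.numeric(mm$area == "ALLO_PRED"),
    is_ortho      = as.numeric(mm$area == "ORTHO"),
    rsa           = ra$rsa,
    flex          = ra$flex,
    d_hydropathy  = unname(AA_HYDROPATHY[alt] - AA_HYDROPATHY[ref]),
    d_volume      = unname(AA_VOLUME[alt] - AA_VOLUME[ref]),
    d_charge      = unname(AA_CHARGE[alt] - AA_CHARGE[ref]),
    blosum62      = unname(BLOSUM62[ref, alt]),
    pro_introduced = as.numeric(alt == "P" && ref != "P"),
    gly_lost      = as.numeric(ref == "G" && alt != "G")
  )
  stopifnot(all(is.finite(v)))
  v[schema$names]
}

#' Featurize all scoreable mutations of a mapped cohort
#'
#' @param mapped Mapped mutation frame from [map_cohort()].
#' @param db A `site_db`.
#' @param schema Feature schema.
#' @return Numeric matrix (rows = scoreable mutations, in input order) with
#'   schema-ordered columns; row order matches `mapped[mapped$scoreable, ]`.
#' @export
featurize_all <- function(mapped, db, schema = default_schema()) {
  rows <- which(mapped$scoreable)
  x <- matrix(NA_real_, nrow = length(rows), ncol = length(schema$names),
              dimnames = list(NULL, schema$names))
  for (j in seq_along(rows)) {
    x[j, ] <- featurize(mapped[rows[j], ], db, schema)
  }
  x
}

#' Fit z-scaling parameters on training vectors
#'
#' Uses the population (1/n) standard deviation; constant features get an sd
#' of 1 so scaling is a no-op for them. Parameters are computed on training
#' data only and never re-estimated at apply time.
#'
#' @param x Numeric training matrix (rows = vectors).
#' @return list(means, sds), class `standardization`.
#' @export
standardize_fit <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 training vectors", call. = FALSE)
  means <- colMeans(x)
  sds <- sqrt(colMeans(sweep(x, 2, means)^2))
  # constant features pass through unchanged: no centering, unit scale
  means[sds == 0] <- 0
  sds[sds == 0] <- 1
  structure(list(means = means, sds = sds), class = "standardization")
}

#' Apply fitted z-scaling
#'
#' @param x Numeric matrix or vector.
#' @param fit A `standardization` from [standardize_fit()].
#' @return Scaled matrix with the same shape.
#' @export
standardize_apply <- function(x, fit) {
  stopifnot(inherits(fit, "standardization"))
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  sweep(sweep(x, 2, fit$means), 2, fit$sds, "/")
}

#' Export a feature matrix for audit
#'
#' @param x Feature matrix from [featurize_all()].
#' @param mapped The corresponding scoreable mapped rows.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_feature_matrix <- function(x, mapped, path) {
  sc <- mapped[mapped$scoreable, , drop = FALSE]
  df <- cbind(sc[, c("sample_id", "uniprot_id", "gene_symbol",
                     "ref_aa", "position", "alt_aa")],
              as.data.frame(x))
  write_tsv(df, path)
}
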