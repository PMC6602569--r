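# Seeded synthetic-data generators for every input the pipeline needs: a
# mutually consistent "site world" (site table, residue annotations, gene
# map, FASTA), MAF cohorts drawn over that world, labeled feature datasets
# with a planted class separation, and label tables shaped like the
# published benchmark datasets. All generators are pure functions of their
# spec and seed; generated artifacts always pass the package's own loaders.

#' Fixture specification for a synthetic site world
#'
#' @param n_proteins Number of proteins (default 5).
#' @param sites_per_protein Sites per protein (default 3; site types cycle
#'   ALLO_EXP, ALLO_PRED, ORTHO).
#' @param seq_length Protein length in residues (default 120).
#' @param n_samples Cohort samples (default 3).
#' @param muts_per_sample Missense mutations per sample (default 10).
#' @param frac_on_sites Fraction of mutations placed on site residues
#'   (default 0.5).
#' @param seed RNG seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_proteins = 5, sites_per_protein = 3,
                         seq_length = 120, n_samples = 3,
                         muts_per_sample = 10, frac_on_sites = 0.5,
                         seed = 1) {
  stopifnot(n_proteins >= 1, sites_per_protein >= 1, seq_length >= 1,
            n_samples >= 1, muts_per_sample >= 1,
            frac_on_sites >= 0, frac_on_sites <= 1)
  structure(list(n_proteins = as.integer(n_proteins),
                 sites_per_protein = as.integer(sites_per_protein),
                 seq_length = as.integer(seq_length),
                 n_samples = as.integer(n_samples),
                 muts_per_sample = as.integer(muts_per_sample),
                 frac_on_sites = frac_on_sites, seed = as.integer(seed)),
            class = "fixture_spec")
}

SITE_SIZE <- 5L  # residues per synthetic site

#' Generate a synthetic site world
#'
#' Writes four mutually consistent files into `dir`: `sites.tsv`,
#' `residues.tsv`, `genemap.tsv` and `proteins.fasta`. Every site residue
#' exists in the sequence and the residue table, and annotated wild-type
#' residues agree with the FASTA. Byte-identical for a given spec.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return list of file paths (sites, residues, genemap, fasta, dir).
#' @export
gen_site_world <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$sites_per_protein * SITE_SIZE > spec$seq_length) {
    stop("sites_per_protein x site size exceeds sequence length", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(spec$seed, {
    uids <- sprintf("P%05d", seq_len(spec$n_proteins))
    genes <- sprintf("GENE%d", seq_len(spec$n_proteins))
    seqs <- vapply(uids, function(u) {
      paste(sample(AA_LETTERS, spec$seq_length, replace = TRUE), collapse = "")
    }, character(1))
    site_rows <- list()
    type_cycle <- c("ALLO_EXP", "ALLO_PRED", "ORTHO")
    counter <- 0L
    for (i in seq_len(spec$n_proteins)) {
      pool <- sample.int(spec$seq_length,
                         spec$sites_per_protein * SITE_SIZE)
      for (j in seq_len(spec$sites_per_protein)) {
        counter <- counter + 1L
        res <- sort(pool[((j - 1) * SITE_SIZE + 1):(j * SITE_SIZE)])
        site_rows[[counter]] <- data.frame(
          uniprot_id = uids[i], gene_symbol = genes[i],
          pdb_id = sprintf("%d%s%02d", (i %% 9) + 1, LETTERS[(i %% 26) + 1], j),
          site_id = sprintf("S%02d", j),
          site_type = type_cycle[((counter - 1) %% 3) + 1],
          residues = paste(res, collapse = ","), stringsAsFactors = FALSE)
      }
    }
    sites <- do.call(rbind, site_rows)
    resid <- do.call(rbind, lapply(seq_len(spec$n_proteins), function(i) {
      data.frame(uniprot_id = uids[i], position = seq_len(spec$seq_length),
                 wt_aa = strsplit(seqs[i], "")[[1]],
                 rsa = sprintf("%.4f", stats::runif(spec$seq_length)),
                 flex = sprintf("%.4f", stats::rnorm(spec$seq_length)),
                 stringsAsFactors = FALSE)
    }))
    genemap <- data.frame(gene_symbol = genes, uniprot_id = uids,
                          stringsAsFactors = FALSE)
    paths <- list(sites = file.path(dir, "sites.tsv"),
                  residues = file.path(dir, "residues.tsv"),
                  genemap = file.path(dir, "genemap.tsv"),
                  fasta = file.path(dir, "proteins.fasta"),
                  dir = dir)
    write_tsv(sites, paths$sites)
    write_tsv(resid, paths$residues)
    write_tsv(genemap, paths$genemap)
    con <- file(paths$fasta, open = "wb")
    for (i in seq_len(spec$n_proteins)) {
      writeLines(sprintf(">sp|%s|%s_SYN synthetic protein %d",
                         uids[i], genes[i], i), con)
      writeLines(gsub("(.{60})", "\\1\n", seqs[i]), con)
    }
    close(con)
    paths
  })
}

world_site_positions <- function(db) {
  # named list uid -> sorted vector of all site residues
  uids <- unique(db$sites$uniprot_id)
  stats::setNames(lapply(uids, function(u) {
    sort(unique(unlist(db$sites$residues[db$sites$uniprot_id == u])))
  }), uids)
}

#' Generate a synthetic MAF cohort over a site world
#'
#' Emits `spec$n_samples` samples with `spec$muts_per_sample` missense rows
#' each; a `frac_on_sites` fraction is placed on site residues (with the
#' correct wild-type residue read from the FASTA), the rest on off-site
#' positions. If more on-site mutations are requested than distinct site
#' residues exist, positions are re-used with a warning.
#'
#' @param spec A [fixture_spec()].
#' @param world Path list from [gen_site_world()] (or a directory containing
#'   the four world files).
#' @param path Output MAF path.
#' @return Invisibly, `path`.
#' @export
gen_cohort_maf <- function(spec, world, path) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (is.character(world)) {
    world <- list(sites = file.path(world, "sites.tsv"),
                  residues = file.path(world, "residues.tsv"),
                  genemap = file.path(world, "genemap.tsv"),
                  fasta = file.path(world, "proteins.fasta"))
  }
  db <- load_site_db(world$sites, world$residues, world$genemap, "functional")
  seqs <- load_fasta(world$fasta)
  site_pos <- world_site_positions(db)
  uid2gene <- stats::setNames(names(db$gene_map), unname(db$gene_map))
  with_seed(spec$seed + 1L, {
    rows <- list()
    for (s in seq_len(spec$n_samples)) {
      sample_id <- sprintf("sample_%d", s)
      n_on <- round(spec$frac_on_sites * spec$muts_per_sample)
      n_off <- spec$muts_per_sample - n_on
      avail <- sum(lengths(site_pos))
      if (n_on > avail) {
        warning("requested on-site mutations exceed available site residues; sampling with replacement",
                call. = FALSE)
      }
      pick_mut <- function(on_site) {
        uid <- sample(names(seqs), 1)
        pos_pool <- if (on_site) site_pos[[uid]] else
          setdiff(seq_len(nchar(seqs[[uid]])), site_pos[[uid]])
        pos <- if (length(pos_pool) == 1) pos_pool else sample(pos_pool, 1)
        ref <- substr(seqs[[uid]], pos, pos)
        alt <- sample(setdiff(AA_LETTERS, ref), 1)
        data.frame(Hugo_Symbol = unname(uid2gene[uid]),
                   Tumor_Sample_Barcode = sample_id,
                   Variant_Classification = "Missense_Mutation",
                   HGVSp_Short = sprintf("p.%s%d%s", ref, pos, alt),
                   stringsAsFactors = FALSE)
      }
      for (k in seq_len(n_on)) rows[[length(rows) + 1]] <- pick_mut(TRUE)
      for (k in seq_len(n_off)) rows[[length(rows) + 1]] <- pick_mut(FALSE)
    }
    write_tsv(do.call(rbind, rows), path)
  })
  invisible(path)
}

#' Separation specification for a labeled feature dataset
#'
#' @param n_pos Driver (positive) count, >= 2.
#' @param n_neg Passenger (negative) count, >= 2. The default shape
#'   (73 / 582, imbalance 0.125) mirrors the functional benchmark dataset.
#' @param dprime Class-mean separation in pooled-sd units, >= 0.
#' @param seed RNG seed.
#' @return A `separation_spec` list.
#' @export
separation_spec <- function(n_pos = 73, n_neg = 582, dprime = 2.5, seed = 1) {
  if (dprime < 0) stop("dprime must be >= 0", call. = FALSE)
  stopifnot(n_pos >= 2, n_neg >= 2)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 dprime = dprime, seed = as.integer(seed)),
            class = "separation_spec")
}

#' Generate a labeled feature dataset with planted separation
#'
#' Continuous schema features (rsa, flex, d_hydropathy, d_volume, d_charge,
#' blosum62) are drawn from unit-variance Gaussians; the positive-class mean
#' is shifted by `dprime` pooled-sd units along a random unit direction in
#' that subspace. The three site flags are a valid one-hot draw per row and
#' the two backbone flags are sparse Bernoulli, all class-independent so that
#' the planted direction alone carries the signal.
#'
#' @param sep A [separation_spec()].
#' @param schema Feature schema (default v1).
#' @return A [labeled_dataset()] (negatives first) with attribute
#'   `direction` (the planted unit vector over the continuous features).
#' @export
gen_labeled_dataset <- function(sep, schema = default_schema()) {
  stopifnot(inherits(sep, "separation_spec"))
  cont <- c("rsa", "flex", "d_hydropathy", "d_volume", "d_charge", "blosum62")
  flags <- c("is_allo_exp", "is_allo_pred", "is_ortho")
  bern <- c("pro_introduced", "gly_lost")
  n <- sep$n_pos + sep$n_neg
  with_seed(sep$seed, {
    u <- stats::rnorm(length(cont))
    u <- u / sqrt(sum(u^2))
    x <- matrix(0, nrow = n, ncol = length(schema$names),
                dimnames = list(NULL, schema$names))
    y <- c(rep(0L, sep$n_neg), rep(1L, sep$n_pos))
    x[, cont] <- matrix(stats::rnorm(n * length(cont)), nrow = n)
    x[y == 1L, cont] <- sweep(x[y == 1L, cont, drop = FALSE], 2,
                              sep$dprime * u, "+")
    onehot <- sample.int(3, n, replace = TRUE)
    for (j in 1:3) x[, flags[j]] <- as.numeric(onehot == j)
    for (b in bern) x[, b] <- stats::rbinom(n, 1, 0.1)
    ds <- labeled_dataset(x, y, schema$version)
    attr(ds, "direction") <- stats::setNames(u, cont)
    ds
  })
}

#' Generate a synthetic benchmark label table over a site world
#'
#' Draws site-residue mutations from the world and labels them
#' driver/passenger at the requested counts (source column `"synthetic"`),
#' producing a table in the shape of the published benchmark datasets (for
#' example 24/197 allosteric, 73/582 functional).
#'
#' @param world Path list or world directory (see [gen_cohort_maf()]).
#' @param n_driver,n_passenger Label counts.
#' @param seed RNG seed.
#' @param path Optional TSV output path.
#' @return The label table data.frame (invisibly written to `path` if given).
#' @export
gen_label_table <- function(world, n_driver, n_passenger, seed = 1,
                            path = NULL) {
  if (is.character(world)) {
    world <- list(sites = file.path(world, "sites.tsv"),
                  residues = file.path(world, "residues.tsv"),
                  genemap = file.path(world, "genemap.tsv"),
                  fasta = file.path(world, "proteins.fasta"))
  }
  db <- load_site_db(world$sites, world$residues, world$genemap, "functional")
  seqs <- load_fasta(world$fasta)
  site_pos <- world_site_positions(db)
  uid2gene <- stats::setNames(names(db$gene_map), unname(db$gene_map))
  n <- n_driver + n_passenger
  with_seed(seed, {
    pool <- do.call(rbind, lapply(names(site_pos), function(u) {
      data.frame(uniprot_id = u, position = site_pos[[u]],
                 stringsAsFactors = FALSE)
    }))
    alts <- expand.grid(idx = seq_len(nrow(pool)), alt_aa = AA_LETTERS,
                        stringsAsFactors = FALSE)
    alts$uniprot_id <- pool$uniprot_id[alts$idx]
    alts$position <- pool$position[alts$idx]
    alts$ref_aa <- substr(seqs[alts$uniprot_id],
                          alts$position, alts$position)
    alts <- alts[alts$ref_aa != alts$alt_aa, , drop = FALSE]
    take <- alts[sample.int(nrow(alts), n, replace = nrow(alts) < n), ,
                 drop = FALSE]
    df <- data.frame(uniprot_id = take$uniprot_id,
                     gene_symbol = unname(uid2gene[take$uniprot_id]),
                     ref_aa = take$ref_aa, position = take$position,
                     alt_aa = take$alt_aa,
                     label = c(rep("driver", n_driver),
                               rep("passenger", n_passenger)),
                     source = "synthetic", stringsAsFactors = FALSE)
    rownames(df) <- NULL
    if (!is.null(path)) write_tsv(df, path)
    df
  })
}
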