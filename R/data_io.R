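#' Read a genotype matrix with its genetic map
#'
#' Reads a delimited table of biallelic SNP dosages coded \{0, 1, 2\} together
#' with a genetic map (chromosome label and position in centimorgan), applies
#' marker quality control, and returns a `GenotypeMatrix` object.
#'
#' Two dialects are accepted and auto-detected. If the header contains the
#' map columns (`marker_id`, `chrom`, `pos_cM`) the file is markers-in-rows
#' with one column per genotype ID. Otherwise rows are taken to be genotypes
#' (first column the genotype ID, remaining columns markers) and a companion
#' map file with columns `marker_id`, `chrom`, `pos_cM` must be supplied.
#'
#' QC drops markers whose minor allele frequency is at or below
#' `maf_threshold` (monomorphic markers have MAF 0 and are always dropped).
#' Missing dosages are an error unless `impute_missing = TRUE`, in which case
#' they are replaced by the marker mean rounded to the nearest dosage class.
#' Counts of markers dropped per rule are recorded in the `qc_log` attribute
#' and reported via `message()`.
#'
#' @param path Path to the genotype table (CSV or TSV, auto-detected).
#' @param maf_threshold Minor allele frequency below or at which a marker is
#'   removed. Default 0.05.
#' @param map_path Optional companion map file for the genotypes-in-rows
#'   dialect.
#' @param impute_missing Replace missing dosages by the rounded marker mean
#'   instead of failing. Default `FALSE`.
#' @return A `GenotypeMatrix`: list with `dosages` (I x m integer matrix,
#'   markers in rows), `marker_ids`, `chromosome`, `position_cM`,
#'   `allele_freq` (frequency of the counted allele), and a `qc_log`
#'   attribute.
#' @export
read_genotypes <- function(path, maf_threshold = 0.05, map_path = NULL,
                           impute_missing = FALSE) {
  sep <- detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  map_cols <- c("marker_id", "chrom", "pos_cM")
  if (all(map_cols %in% names(tab))) {
    ids <- as.character(tab$marker_id)
    chrom <- as.character(tab$chrom)
    pos <- as.numeric(tab$pos_cM)
    geno_cols <- setdiff(names(tab), map_cols)
    dos <- matrix(as.numeric(as.matrix(tab[, geno_cols, drop = FALSE])),
                  nrow = nrow(tab))
    colnames(dos) <- geno_cols
    rownames(dos) <- ids
  } else {
    if (is.null(map_path))
      stop("no map columns (marker_id, chrom, pos_cM) in ", path,
           " and no companion map file given")
    map <- utils::read.table(map_path, header = TRUE, sep = detect_sep(map_path),
                             stringsAsFactors = FALSE)
    if (!all(map_cols %in% names(map)))
      stop("map file must have columns marker_id, chrom, pos_cM")
    ids <- as.character(map$marker_id)
    chrom <- as.character(map$chrom)
    pos <- as.numeric(map$pos_cM)
    gid <- as.character(tab[[1]])
    dos <- t(matrix(as.numeric(as.matrix(tab[, -1, drop = FALSE])),
                    nrow = nrow(tab)))
    if (nrow(dos) != length(ids))
      stop("map lists ", length(ids), " markers but genotype table has ",
           nrow(dos))
    rownames(dos) <- ids
    colnames(dos) <- gid
  }
  if (anyDuplicated(ids))
    stop("duplicate marker ID: ", ids[duplicated(ids)][1])
  bad <- which(!(dos %in% c(0, 1, 2) | is.na(dos)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(dos))
    stop("dosage value ", dos[bad[1]], " outside {0,1,2} at marker ",
         ids[rc[1]], ", genotype ", colnames(dos)[rc[2]])
  }
  n_missing_dropped <- 0L
  if (anyNA(dos)) {
    if (!impute_missing) {
      rc <- arrayInd(which(is.na(dos))[1], dim(dos))
      stop("missing dosage at marker ", ids[rc[1]], ", genotype ",
           colnames(dos)[rc[2]], "; set impute_missing = TRUE to mean-impute")
    }
    for (i in which(rowSums(is.na(dos)) > 0)) {
      mu <- mean(dos[i, ], na.rm = TRUE)
      dos[i, is.na(dos[i, ])] <- round(mu)
    }
  }
  new_genotype_matrix(dos, ids, chrom, pos, maf_threshold)
}

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Construct a GenotypeMatrix from an in-memory dosage matrix
#'
#' Applies the MAF filter and computes allele frequencies. Used by
#' [read_genotypes()] and by the synthetic genotype generator.
#'
#' @param dosages I x m matrix of dosages in \{0,1,2\} (markers in rows).
#' @param marker_ids,chromosome,position_cM Per-marker map vectors.
#' @param maf_threshold Markers with MAF <= this value are dropped.
#' @return A `GenotypeMatrix`.
#' @export
new_genotype_matrix <- function(dosages, marker_ids, chromosome, position_cM,
                                maf_threshold = 0.05) {
  stopifnot(nrow(dosages) == length(marker_ids),
            length(marker_ids) == length(chromosome),
            length(chromosome) == length(position_cM))
  p <- rowMeans(dosages) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf > maf_threshold
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(n_drop, " marker(s) dropped: MAF <= ", maf_threshold)
  g <- list(dosages = dosages[keep, , drop = FALSE],
            marker_ids = marker_ids[keep],
            chromosome = chromosome[keep],
            position_cM = position_cM[keep],
            allele_freq = p[keep])
  attr(g, "qc_log") <- c(maf_dropped = n_drop)
  class(g) <- "GenotypeMatrix"
  g
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat("GenotypeMatrix:", nrow(x$dosages), "markers x", ncol(x$dosages),
      "genotypes\n")
  cat("chromosomes:", length(unique(x$chromosome)),
      " MAF range:", sprintf("%.3f-%.3f", min(pmin(x$allele_freq, 1 - x$allele_freq)),
                             max(pmin(x$allele_freq, 1 - x$allele_freq))), "\n")
  invisible(x)
}

#' Genomic relationship matrix
#'
#' Computes the marker-based relationship between genotypes j and k as
#' \deqn{G_{jk} = \sum_i (x_{ij} - 2p_i)(x_{ik} - 2p_i) / \{2 p_i (1-p_i)\},}
#' where \eqn{p_i} is the frequency of the counted allele of marker i,
#' optionally divided by the marker count I (`scale_by_markers`, default on)
#' so the diagonal is of order 1. Kernel scale is absorbed by the variance
#' components downstream, so the flag does not change any test statistic.
#'
#' @param geno A `GenotypeMatrix`.
#' @param scale_by_markers Divide by the number of markers. Default `TRUE`.
#' @return m x m symmetric numeric matrix with genotype IDs as dimnames.
#' @export
compute_grm <- function(geno, scale_by_markers = TRUE) {
  p <- geno$allele_freq
  if (any(p <= 0 | p >= 1))
    stop("allele frequency 0 or 1 present; apply the MAF filter first ",
         "(2p(1-p) denominator would be zero)")
  W <- (geno$dosages - 2 * p) / sqrt(2 * p * (1 - p))
  G <- crossprod(W)
  if (scale_by_markers) G <- G / nrow(geno$dosages)
  dimnames(G) <- list(colnames(geno$dosages), colnames(geno$dosages))
  (G + t(G)) / 2
}

#' Population-structure covariates from genotype PCA
#'
#' Principal-component scores of the centred (optionally standardised)
#' genotype-level dosage matrix, broadcast to the n observations through the
#' genotype incidence of the experimental design. The leading components are
#' used as fixed covariates to absorb population stratification.
#'
#' @param geno A `GenotypeMatrix`.
#' @param n_components Number of components c (default 2).
#' @param design An `ExperimentDesign` from [build_design()]; if `NULL` the
#'   genotype-level score matrix is returned un-broadcast.
#' @param standardize Standardise markers to unit variance before the PCA
#'   (default `FALSE`: centred-only).
#' @return List with `S` (n x c, or m x c when `design` is NULL), `scores`
#'   (m x c genotype-level), `explained_fraction`.
#' @export
compute_structure_covariates <- function(geno, n_components = 2,
                                         design = NULL, standardize = FALSE) {
  m <- ncol(geno$dosages)
  if (n_components < 1) stop("n_components must be >= 1")
  if (n_components >= m) stop("n_components must be < number of genotypes")
  X <- t(geno$dosages)                      # genotypes x markers
  pc <- stats::prcomp(X, center = TRUE, scale. = standardize)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  ev <- pc$sdev^2
  ef <- (ev / sum(ev))[seq_len(n_components)]
  S <- scores
  if (!is.null(design)) S <- design$Z_G %*% scores
  list(S = S, scores = scores, explained_fraction = ef)
}

#' Empirical logit transform for fraction-valued phenotypes
#'
#' Maps a fraction v in \[0, 1\] to `log((v + a) / (1 - v + a))` with a
#' positive adjustment `a` so that the boundaries stay finite. Used for
#' traits such as fruit-set ratio before mixed-model analysis.
#'
#' @param values Numeric vector of fractions in \[0, 1\].
#' @param adjustment Positive adjustment a. The conventional choice is 0.5
#'   divided by the per-observation denominator (e.g. flower count) when
#'   known; default 0.5.
#' @return Transformed numeric vector.
#' @export
empirical_logit <- function(values, adjustment = 0.5) {
  if (any(values < 0 | values > 1, na.rm = TRUE))
    stop("values must lie in [0, 1]")
  if (adjustment <= 0) stop("adjustment must be positive")
  log((values + adjustment) / (1 - values + adjustment))
}

#' Read a long- or wide-format phenotype table
#'
#' Expects columns `genotype_id`, `trial_id`, `environment_id` plus either a
#' single `value` column (long format) or one column per trait (wide format,
#' converted internally; pick one with `trait`).
#'
#' @param path CSV/TSV file path.
#' @param trait Trait column to keep when the file is wide. Default: the
#'   single non-key column.
#' @return A `PhenotypeTable`: data.frame with columns `genotype_id`,
#'   `trial_id`, `environment_id`, `value`.
#' @export
read_phenotypes <- function(path, trait = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                           stringsAsFactors = FALSE)
  key <- c("genotype_id", "trial_id", "environment_id")
  if (!all(key %in% names(tab)))
    stop("phenotype file must have columns genotype_id, trial_id, environment_id")
  rest <- setdiff(names(tab), key)
  if ("value" %in% rest && is.null(trait)) {
    out <- tab[, c(key, "value")]
  } else {
    if (is.null(trait)) {
      if (length(rest) != 1)
        stop("multiple trait columns (", paste(rest, collapse = ", "),
             "); pick one with `trait`")
      trait <- rest
    }
    if (!trait %in% names(tab)) stop("no trait column named ", trait)
    out <- tab[, key]
    out$value <- as.numeric(tab[[trait]])
  }
  as_phenotype_table(out)
}

#' Validate and classify a phenotype data.frame
#'
#' @param df Data frame with columns `genotype_id`, `trial_id`,
#'   `environment_id`, `value`.
#' @return The validated data.frame with class `PhenotypeTable`.
#' @export
as_phenotype_table <- function(df) {
  stopifnot(all(c("genotype_id", "trial_id", "environment_id", "value")
                %in% names(df)))
  te <- unique(df[, c("trial_id", "environment_id")])
  if (anyDuplicated(te$trial_id))
    stop("trial assigned to more than one environment: ",
         te$trial_id[duplicated(te$trial_id)][1])
  df$genotype_id <- as.character(df$genotype_id)
  df$trial_id <- as.character(df$trial_id)
  df$environment_id <- as.character(df$environment_id)
  class(df) <- c("PhenotypeTable", "data.frame")
  df
}

#' Write a genotype matrix with its map to CSV
#'
#' Inverse of [read_genotypes()] (markers-in-rows dialect).
#'
#' @param geno A `GenotypeMatrix`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(marker_id = geno$marker_ids,
                   chrom = geno$chromosome,
                   pos_cM = geno$position_cM,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(geno$dosages))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
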