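#' @keywords internal
"_PACKAGE"

GENO_LEVELS <- c("AA", "AB", "BB")
VALID_ALLELES <- c("A", "C", "G", "T")

#' Genotype matrix for biallelic SNPs
#'
#' Container for unphased biallelic genotypes of a set of subjects. Each SNP
#' carries an ordered allele pair (A, B) where A precedes B in lexicographic
#' order (A < C < G < T) regardless of allele frequency, so the three
#' genotype states AA, AB, BB are defined unambiguously. Genotypes are
#' stored as integer codes 0 = AA, 1 = AB, 2 = BB, `NA` = missing.
#'
#' @param genotypes integer matrix (subjects x SNPs) with values in
#'   \{0, 1, 2, NA\}.
#' @param subject_ids character vector of unique subject identifiers.
#' @param snp_ids character vector of unique SNP identifiers.
#' @param alleles character matrix (SNPs x 2) of single-letter allele
#'   symbols; column 1 must precede column 2 lexicographically.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(genotypes, subject_ids, snp_ids, alleles) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (length(subject_ids) != nrow(genotypes))
    stop("subject_ids length must match genotype rows")
  if (length(snp_ids) != ncol(genotypes))
    stop("snp_ids length must match genotype columns")
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique")
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique")
  alleles <- as.matrix(alleles)
  if (nrow(alleles) != length(snp_ids) || ncol(alleles) != 2L)
    stop("alleles must be a (n SNPs) x 2 matrix")
  if (!all(alleles %in% VALID_ALLELES))
    stop("allele symbols must be single characters among A, C, G, T")
  if (any(alleles[, 1L] >= alleles[, 2L]))
    stop("for every SNP the first allele must precede the second (A < C < G < T)")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0 (AA), 1 (AB), 2 (BB) or NA")
  dimnames(genotypes) <- list(subject_ids, snp_ids)
  structure(
    list(genotypes = genotypes,
         subject_ids = as.character(subject_ids),
         snp_ids = as.character(snp_ids),
         alleles = alleles),
    class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$genotypes)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d SNPs (%d missing calls)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              sum(is.na(x$genotypes))))
  invisible(x)
}

#' Subset a genotype matrix by SNP
#'
#' @param x a `genotype_matrix`.
#' @param snps SNP identifiers or column indices, in the desired order.
#' @return A `genotype_matrix` restricted (and reordered) to `snps`.
#' @export
subset_snps <- function(x, snps) {
  stopifnot(inherits(x, "genotype_matrix"))
  idx <- if (is.character(snps)) match(snps, x$snp_ids) else as.integer(snps)
  if (anyNA(idx)) stop("unknown SNP id(s) in subset")
  genotype_matrix(x$genotypes[, idx, drop = FALSE], x$subject_ids,
                  x$snp_ids[idx], x$alleles[idx, , drop = FALSE])
}

#' Binary phenotype vector
#'
#' The dichotomous trait, labelled 1 (trait present, "T") or 0 (absent).
#' Subjects must align one-to-one with a companion [genotype_matrix()].
#'
#' @param labels integer/numeric vector of 0/1 labels, no missing values.
#' @param subject_ids character vector matching the genotype matrix.
#' @return An object of class `phenotype_vector`.
#' @export
phenotype_vector <- function(labels, subject_ids) {
  labels <- as.integer(labels)
  if (anyNA(labels) || !all(labels %in% c(0L, 1L)))
    stop("phenotype labels must be 0 or 1 with no missing values")
  if (length(labels) != length(subject_ids))
    stop("labels and subject_ids lengths differ")
  if (anyDuplicated(subject_ids)) stop("subject_ids must be unique")
  structure(list(labels = labels, subject_ids = as.character(subject_ids)),
            class = "phenotype_vector")
}

#' @export
print.phenotype_vector <- function(x, ...) {
  cat(sprintf("phenotype_vector: %d subjects (%d cases, %d controls)\n",
              length(x$labels), sum(x$labels), sum(1L - x$labels)))
  invisible(x)
}

check_aligned <- function(G, y) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(y, "phenotype_vector"))
  if (!identical(G$subject_ids, y$subject_ids))
    stop("genotype matrix and phenotype vector subjects are not aligned")
  invisible(TRUE)
}

#' Per-SNP genotype count tables
#'
#' Tabulates, for every SNP, the 2 x 3 (phenotype x genotype) counts that
#' are the sufficient statistic for all per-SNP fits in this package, plus
#' per-group missing-call counts. Stored column-wise: one row per SNP.
#'
#' @param G a [genotype_matrix()].
#' @param y an aligned [phenotype_vector()].
#' @return An object of class `genotype_counts`: a data frame with columns
#'   `snp_id`, `T_AA`, `T_AB`, `T_BB`, `N_AA`, `N_AB`, `N_BB`, `miss_T`,
#'   `miss_N` and attributes `n_cases`, `n_controls`.
#' @export
count_genotypes <- function(G, y) {
  check_aligned(G, y)
  case <- y$labels == 1L
  gc <- G$genotypes[case, , drop = FALSE]
  gn <- G$genotypes[!case, , drop = FALSE]
  tab <- function(m, code) colSums(m == code, na.rm = TRUE)
  out <- data.frame(
    snp_id = G$snp_ids,
    T_AA = tab(gc, 0L), T_AB = tab(gc, 1L), T_BB = tab(gc, 2L),
    N_AA = tab(gn, 0L), N_AB = tab(gn, 1L), N_BB = tab(gn, 2L),
    miss_T = colSums(is.na(gc)), miss_N = colSums(is.na(gn)),
    stringsAsFactors = FALSE, row.names = NULL)
  new_genotype_counts(out, n_cases = sum(case), n_controls = sum(!case))
}

new_genotype_counts <- function(df, n_cases, n_controls) {
  stopifnot(all(c("snp_id", "T_AA", "T_AB", "T_BB",
                  "N_AA", "N_AB", "N_BB") %in% names(df)))
  if (is.null(df$miss_T)) df$miss_T <- 0L
  if (is.null(df$miss_N)) df$miss_N <- 0L
  structure(df, class = c("genotype_counts", "data.frame"),
            n_cases = n_cases, n_controls = n_controls)
}

#' Build a genotype_counts object from raw count rows
#'
#' Convenience constructor when counts are known directly (e.g. simulated
#' in count mode) rather than tabulated from a subject-level matrix.
#'
#' @param snp_id character vector.
#' @param counts_T,counts_N integer matrices (SNPs x 3) of AA/AB/BB counts
#'   in cases and controls.
#' @param n_cases,n_controls group sizes (default: row sums, assuming no
#'   missing calls).
#' @return A `genotype_counts` object.
#' @export
genotype_counts <- function(snp_id, counts_T, counts_N,
                            n_cases = NULL, n_controls = NULL) {
  counts_T <- as.matrix(counts_T); counts_N <- as.matrix(counts_N)
  stopifnot(ncol(counts_T) == 3L, ncol(counts_N) == 3L,
            nrow(counts_T) == length(snp_id),
            nrow(counts_N) == length(snp_id))
  if (any(counts_T < 0) || any(counts_N < 0)) stop("counts must be >= 0")
  if (is.null(n_cases)) n_cases <- max(rowSums(counts_T))
  if (is.null(n_controls)) n_controls <- max(rowSums(counts_N))
  df <- data.frame(
    snp_id = as.character(snp_id),
    T_AA = counts_T[, 1L], T_AB = counts_T[, 2L], T_BB = counts_T[, 3L],
    N_AA = counts_N[, 1L], N_AB = counts_N[, 2L], N_BB = counts_N[, 3L],
    miss_T = n_cases - rowSums(counts_T),
    miss_N = n_controls - rowSums(counts_N),
    stringsAsFactors = FALSE, row.names = NULL)
  new_genotype_counts(df, n_cases = n_cases, n_controls = n_controls)
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("genotype_counts: %d SNPs, %d cases / %d controls\n",
              nrow(x), attr(x, "n_cases"), attr(x, "n_controls")))
  NextMethod()
}

subset_counts <- function(counts, snps) {
  idx <- if (is.character(snps)) match(snps, counts$snp_id)
         else as.integer(snps)
  if (anyNA(idx)) stop("unknown SNP id(s) in counts subset")
  new_genotype_counts(as.data.frame(counts)[idx, , drop = FALSE],
                      n_cases = attr(counts, "n_cases"),
                      n_controls = attr(counts, "n_controls"))
}

count_matrices <- function(counts) {
  list(T = cbind(counts$T_AA, counts$T_AB, counts$T_BB),
       N = cbind(counts$N_AA, counts$N_AB, counts$N_BB))
}

# Haldane-Anscombe-style smoothing shared by the genotypic fit and the NBC
# conditionals: the pseudo-count is added to every cell of a SNP's 2x3 table
# if and only if some cell of that table is zero. Using one rule for both
# estimators is what keeps the GRS/NBC rule equivalence exact after
# smoothing.
smoothed_count_matrices <- function(counts, smoothing) {
  cm <- count_matrices(counts)
  if (smoothing > 0) {
    has_zero <- (rowSums(cm$T == 0) + rowSums(cm$N == 0)) > 0
    add <- ifelse(has_zero, smoothing, 0)
    cm$T <- cm$T + add
    cm$N <- cm$N + add
  }
  cm
}
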