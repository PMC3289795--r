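#' Read the native genotype TSV dialect
#'
#' Format: a header line `subject_id<TAB>phenotype<TAB><snp_id>:<A>/<B> ...`
#' followed by one row per subject. Phenotype is 0/1 (1 = trait present).
#' Genotypes are two-character allele strings (e.g. `AG`, `GA`) or `..` for
#' missing; the two orderings of a heterozygote are canonicalized to the
#' same AB state using the SNP's lexicographically ordered allele pair.
#'
#' @param path path to a TSV file.
#' @return A list with elements `genotypes` ([genotype_matrix()]) and
#'   `phenotype` ([phenotype_vector()]).
#' @export
read_genotype_tsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty genotype file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 3L || header[1L] != "subject_id" ||
      header[2L] != "phenotype")
    stop("malformed header: expected 'subject_id<TAB>phenotype<TAB><snp>:<A>/<B> ...'")
  snp_cols <- header[-(1:2)]
  m <- regmatches(snp_cols, regexec("^([^:]+):([A-Z])/([A-Z])$", snp_cols))
  bad <- which(lengths(m) != 4L)
  if (length(bad))
    stop("malformed SNP column header: '", snp_cols[bad[1L]],
         "' (expected <snp_id>:<A>/<B>)")
  snp_ids <- vapply(m, `[`, "", 2L)
  alleles <- cbind(vapply(m, `[`, "", 3L), vapply(m, `[`, "", 4L))
  if (!all(alleles %in% VALID_ALLELES))
    stop("allele symbols must be among A, C, G, T")
  if (any(alleles[, 1L] >= alleles[, 2L]))
    stop("SNP column alleles must be in lexicographic order A < C < G < T")

  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(body)
  if (any(nf != length(header)))
    stop("row ", which(nf != length(header))[1L] + 1L,
         " has ", nf[nf != length(header)][1L], " fields, expected ",
         length(header))
  subj <- vapply(body, `[`, "", 1L)
  phen <- vapply(body, `[`, "", 2L)
  if (!all(phen %in% c("0", "1")))
    stop("phenotype values must be 0 or 1; offending subject '",
         subj[which(!phen %in% c("0", "1"))[1L]], "'")
  geno <- matrix(NA_integer_, nrow = length(body), ncol = length(snp_ids))
  for (j in seq_along(snp_ids)) {
    gs <- vapply(body, `[`, "", j + 2L)
    geno[, j] <- canonicalize_genotypes(gs, alleles[j, 1L], alleles[j, 2L],
                                        snp_ids[j], subj)
  }
  list(genotypes = genotype_matrix(geno, subj, snp_ids, alleles),
       phenotype = phenotype_vector(as.integer(phen), subj))
}

# Maps two-character genotype strings onto codes 0/1/2 given the ordered
# allele pair (a, b); ".." is missing. Any other composition is a data error.
canonicalize_genotypes <- function(gs, a, b, snp_id, subject_ids) {
  out <- rep(NA_integer_, length(gs))
  out[gs == paste0(a, a)] <- 0L
  out[gs == paste0(a, b) | gs == paste0(b, a)] <- 1L
  out[gs == paste0(b, b)] <- 2L
  bad <- which(is.na(out) & gs != "..")
  if (length(bad))
    stop("genotype '", gs[bad[1L]], "' at subject '", subject_ids[bad[1L]],
         "', SNP '", snp_id, "' is not composed of declared alleles ",
         a, "/", b)
  out
}

#' Write the native genotype TSV dialect
#'
#' Inverse of [read_genotype_tsv()]; round-trips canonicalized data.
#'
#' @param G a [genotype_matrix()].
#' @param y an aligned [phenotype_vector()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(G, y, path) {
  check_aligned(G, y)
  header <- c("subject_id", "phenotype",
              paste0(G$snp_ids, ":", G$alleles[, 1L], "/", G$alleles[, 2L]))
  gs <- matrix("..", nrow = nrow(G$genotypes), ncol = ncol(G$genotypes))
  for (j in seq_len(ncol(G$genotypes))) {
    a <- G$alleles[j, 1L]; b <- G$alleles[j, 2L]
    lab <- c(paste0(a, a), paste0(a, b), paste0(b, b))
    ok <- !is.na(G$genotypes[, j])
    gs[ok, j] <- lab[G$genotypes[ok, j] + 1L]
  }
  rows <- apply(cbind(G$subject_ids, y$labels, gs), 1L, paste,
                collapse = "\t")
  writeLines(c(paste(header, collapse = "\t"), rows), path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Optional ingestion path for standard VCF 4.x. Only biallelic SNP records
#' with a GT field are used; multi-allelic and non-SNP records are skipped
#' (the skip count is reported in a message). REF/ALT are re-ordered
#' lexicographically into the package's (A, B) convention before genotype
#' coding: for REF=G/ALT=A the stored allele pair is (A, G), so a 0/0 call
#' (two G copies) becomes BB and a 1/1 call (two A copies) becomes AA.
#' Phenotypes come from a separate two-column TSV
#' (`subject_id<TAB>phenotype`) keyed by VCF sample ID; output subjects are
#' aligned to the VCF sample order.
#'
#' Requires the Bioconductor package \pkg{VariantAnnotation}.
#'
#' @param path path to a VCF file.
#' @param phenotype_path path to the phenotype TSV.
#' @return As [read_genotype_tsv()].
#' @export
read_vcf <- function(path, phenotype_path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altl <- VariantAnnotation::alt(vcf)
  alt1 <- vapply(seq_along(altl), function(i) {
    a <- as.character(altl[[i]])
    if (length(a) == 1L) a else NA_character_
  }, "")
  keep <- !is.na(alt1) & nchar(ref) == 1L & nchar(alt1) == 1L &
    ref %in% VALID_ALLELES & alt1 %in% VALID_ALLELES
  n_skip <- sum(!keep)
  if (n_skip) message(n_skip, " non-biallelic-SNP record(s) skipped")
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  gt <- gt[keep, , drop = FALSE]
  ref <- ref[keep]; alt1 <- alt1[keep]

  # dosage of the ALT allele, unphased or phased
  alt_dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  alt_dose[gt %in% c("0/0", "0|0")] <- 0L
  alt_dose[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  alt_dose[gt %in% c("1/1", "1|1")] <- 2L

  # lexicographic (A, B): flip the dosage where ALT sorts before REF
  a <- pmin(ref, alt1); b <- pmax(ref, alt1)
  flip <- alt1 < ref
  code <- t(alt_dose)                      # subjects x SNPs
  code[, flip] <- 2L - code[, flip]

  snp_ids <- rownames(gt)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_along(ref))
  samples <- colnames(gt)

  ph <- utils::read.table(phenotype_path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer"))
  idx <- match(samples, ph[[1L]])
  if (anyNA(idx))
    stop("VCF sample '", samples[which(is.na(idx))[1L]],
         "' absent from phenotype file")
  list(genotypes = genotype_matrix(code, samples, snp_ids, cbind(a, b)),
       phenotype = phenotype_vector(ph[[2L]][idx], samples))
}

#' Write a per-SNP effect table as TSV
#'
#' @param effects a `snp_effects` data frame from [fit_genotypic()] or
#'   [fit_additive()], optionally merged with ranking output.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_effects_tsv <- function(effects, path) {
  utils::write.table(as.data.frame(effects), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize / restore a GRS weight scheme
#'
#' TSV with a `# case=...` header line (plus `# gamma0=`, `# gamma1=` when a
#' calibrated model is supplied) and one row per SNP.
#'
#' @param scheme a [build_weights()] result, or a calibrated `grs_model`.
#' @param path file path.
#' @return `write_weights_tsv`: `path` invisibly; `read_weights_tsv`: a
#'   `weight_scheme` (with `gamma0`/`gamma1` attributes when present).
#' @export
write_weights_tsv <- function(scheme, path) {
  hdr <- character()
  if (inherits(scheme, "grs_model")) {
    hdr <- c(sprintf("# gamma0=%.17g", scheme$gamma0),
             sprintf("# gamma1=%.17g", scheme$gamma1))
    scheme <- scheme$scheme
  }
  stopifnot(inherits(scheme, "weight_scheme"))
  hdr <- c(sprintf("# case=%s", attr(scheme, "case")), hdr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(scheme), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_weights_tsv
#' @export
read_weights_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# ", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", meta), "=", fixed = TRUE))
  vals <- stats::setNames(kv[, 2L], kv[, 1L])
  df <- utils::read.table(text = lines[!startsWith(lines, "# ")],
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  sch <- structure(df, class = c("weight_scheme", "data.frame"),
                   case = vals[["case"]])
  if ("gamma0" %in% names(vals)) {
    attr(sch, "gamma0") <- as.numeric(vals[["gamma0"]])
    attr(sch, "gamma1") <- as.numeric(vals[["gamma1"]])
  }
  sch
}

#' Serialize / restore a fitted Naive Bayes classifier
#'
#' TSV with `# prior_T=` and `# smoothing=` header lines and one row per
#' SNP holding the six conditional genotype probabilities.
#'
#' @param model an [fit_nbc()] result.
#' @param path file path.
#' @return `write_nbc_tsv`: `path` invisibly; `read_nbc_tsv`: an
#'   `nbc_model`.
#' @export
write_nbc_tsv <- function(model, path) {
  stopifnot(inherits(model, "nbc_model"))
  df <- data.frame(snp_id = model$snp_id,
                   T_AA = model$cond_T[, 1L], T_AB = model$cond_T[, 2L],
                   T_BB = model$cond_T[, 3L],
                   N_AA = model$cond_notT[, 1L],
                   N_AB = model$cond_notT[, 2L],
                   N_BB = model$cond_notT[, 3L])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# prior_T=%.17g", model$prior_T),
               sprintf("# smoothing=%.17g", model$smoothing)), con)
  utils::write.table(format(df, digits = 17), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nbc_tsv
#' @export
read_nbc_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# ", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", meta), "=", fixed = TRUE))
  vals <- stats::setNames(as.numeric(kv[, 2L]), kv[, 1L])
  df <- utils::read.table(text = lines[!startsWith(lines, "# ")],
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  new_nbc_model(snp_id = df$snp_id,
                cond_T = as.matrix(df[, c("T_AA", "T_AB", "T_BB")]),
                cond_notT = as.matrix(df[, c("N_AA", "N_AB", "N_BB")]),
                prior_T = vals[["prior_T"]], smoothing = vals[["smoothing"]])
}
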