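# Shared fixtures and independent oracles, all built in code.

# A well-formed 3-subject, 2-SNP genotype TSV.
tiny_tsv <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c(
    "subject_id\tphenotype\tsnp1:A/G\tsnp2:C/T",
    "s1\t1\tAA\tCT",
    "s2\t0\tGA\tTT",
    "s3\t1\t..\tCC"), path)
  path
}

# Count table builder: rows are (AA, AB, BB) counts.
make_counts <- function(t_row, n_row, snp_id = "snp1") {
  genotype_counts(snp_id, matrix(t_row, nrow = 1), matrix(n_row, nrow = 1))
}

# A random genotype_matrix + phenotype, optionally with missing calls.
random_dataset <- function(n = 100, k = 5, p_missing = 0, seed = 1) {
  set.seed(seed)
  geno <- matrix(sample(0:2, n * k, replace = TRUE), n, k)
  if (p_missing > 0)
    geno[matrix(runif(n * k) < p_missing, n, k)] <- NA_integer_
  G <- genotype_matrix(geno, sprintf("s%03d", 1:n), sprintf("snp%02d", 1:k),
                       matrix(rep(c("A", "G"), each = k), ncol = 2))
  y <- phenotype_vector(sample(0:1, n, replace = TRUE), G$subject_ids)
  list(genotypes = G, phenotype = y)
}

# Independent oracle for the additive logistic MLE on a 2x3 table:
# two-stage grid search over (intercept, slope) maximizing the grouped
# binomial log-likelihood. Never calls glm.
oracle_additive_mle <- function(t_row, n_row) {
  ll <- function(a, b) {
    eta <- a + b * (0:2)
    sum(t_row * eta - (t_row + n_row) * log1p(exp(eta)))
  }
  a_grid <- seq(-4, 4, length.out = 81)
  b_grid <- seq(-4, 4, length.out = 81)
  best <- c(0, 0)
  for (pass in 1:4) {
    vals <- outer(a_grid, b_grid, Vectorize(ll))
    ij <- arrayInd(which.max(vals), dim(vals))
    best <- c(a_grid[ij[1]], b_grid[ij[2]])
    span_a <- diff(range(a_grid)) / 10
    span_b <- diff(range(b_grid)) / 10
    a_grid <- seq(best[1] - span_a, best[1] + span_a, length.out = 41)
    b_grid <- seq(best[2] - span_b, best[2] + span_b, length.out = 41)
  }
  best
}

# Brute-force AUC oracle: fraction of concordant case-control pairs,
# counting ties half.
oracle_auc <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) tot <- tot + sum(a > ct) + 0.5 * sum(a == ct)
  tot / (length(cs) * length(ct))
}

# All 27 genotype profiles over 3 SNPs as a 27 x 3 code matrix.
all_profiles_3snp <- function() {
  as.matrix(expand.grid(0:2, 0:2, 0:2))
}

# A small mixed-mode simulated discovery/replication pair with models
# built from the identical smoothed discovery counts.
equivalence_fixture <- function(n = 500, seed = 11, n_null = 5,
                                modes = c("additive", "recessive",
                                          "dominant")) {
  d <- simulation_design(n_cases = n, n_controls = n,
                         or_grid = c(1.3, 1.6), maf_grid = c(0.2, 0.4),
                         modes = modes, n_null = n_null,
                         n_replicates = 1, seed = seed)
  disc <- simulate_dataset(d, "discovery", 1)
  repl <- simulate_dataset(d, "replication", 1)
  counts <- count_genotypes(disc$genotypes, disc$phenotype)
  scheme <- build_weights("case3", fit_genotypic(counts))
  gm <- calibrate(compute_grs(disc$genotypes, scheme), disc$phenotype,
                  scheme = scheme)
  list(design = d, discovery = disc, replication = repl, counts = counts,
       scheme = scheme, grs_model = gm, nbc = fit_nbc(counts))
}
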