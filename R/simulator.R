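SIM_MODES <- c("additive", "recessive", "dominant")

#' Case-control simulation design
#'
#' Describes a case-control genotype simulation: a grid of causal SNPs
#' (every combination of odds ratio, minor-allele frequency and inheritance
#' mode), a panel of null SNPs in Hardy-Weinberg equilibrium with MAFs
#' drawn uniformly from `null_maf_range`, and independent discovery and
#' replication sets per replicate. The defaults reproduce the reference
#' design: 3000 cases / 3000 controls, ORs 1.2-1.6 by 0.1, MAFs 0.1-0.5 by
#' 0.1, all three modes (75 causal SNPs), 500,000 null SNPs with MAF ~
#' Uniform(0.05, 0.5), 5 replicates.
#'
#' @param n_cases,n_controls group sample sizes.
#' @param or_grid odds ratios of the causal grid (> 0).
#' @param maf_grid minor-allele frequencies of the causal grid, in
#'   (0, 0.5].
#' @param modes subset of `"additive"`, `"recessive"`, `"dominant"`.
#' @param n_null number of null SNPs.
#' @param null_maf_range (low, high) for the uniform null-MAF draw.
#' @param n_replicates number of independent simulation replicates.
#' @param seed root seed; all randomness expands deterministically from it
#'   via per-(replicate, split, stream) subseeds.
#' @param risk_on_minor if `FALSE` (default), the odds-ratio tilt follows
#'   the reference parameterization literally and multiplies the major-
#'   allele homozygote `(1-p)^2` term (making B, the major allele, the risk
#'   allele); if `TRUE` the tilt is transposed onto the minor-allele side.
#'   AUC results are unaffected by the choice.
#' @return A `simulation_design` list.
#' @export
simulation_design <- function(n_cases = 3000, n_controls = 3000,
                              or_grid = c(1.2, 1.3, 1.4, 1.5, 1.6),
                              maf_grid = c(0.1, 0.2, 0.3, 0.4, 0.5),
                              modes = SIM_MODES,
                              n_null = 500000,
                              null_maf_range = c(0.05, 0.5),
                              n_replicates = 5,
                              seed = 1,
                              risk_on_minor = FALSE) {
  modes <- match.arg(modes, SIM_MODES, several.ok = TRUE)
  stopifnot(n_cases >= 1, n_controls >= 1, all(or_grid > 0),
            all(maf_grid > 0), all(maf_grid <= 0.5), n_null >= 0,
            length(null_maf_range) == 2L, null_maf_range[1L] > 0,
            null_maf_range[2L] <= 0.5,
            null_maf_range[1L] <= null_maf_range[2L],
            n_replicates >= 1)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 or_grid = or_grid, maf_grid = maf_grid, modes = modes,
                 n_null = as.integer(n_null),
                 null_maf_range = null_maf_range,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 risk_on_minor = isTRUE(risk_on_minor)),
            class = "simulation_design")
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf(paste0("simulation_design: %d/%d cases/controls, %d causal ",
                     "(%d OR x %d MAF x %d modes), %d null SNPs, ",
                     "%d replicates, seed %d\n"),
              x$n_cases, x$n_controls,
              length(x$or_grid) * length(x$maf_grid) * length(x$modes),
              length(x$or_grid), length(x$maf_grid), length(x$modes),
              x$n_null, x$n_replicates, x$seed))
  invisible(x)
}

n_causal <- function(design) {
  length(design$or_grid) * length(design$maf_grid) * length(design$modes)
}

# deterministic subseed in [0, 2^31-2]; multiply-accumulate mod 2^31-1
# (exact in doubles: intermediate values stay far below 2^53)
sub_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p)) else as.numeric(p)
  }, numeric(1L))
  h <- (as.numeric(seed) + 1) %% 2147483647
  for (p in parts) h <- (h * 48271 + p + 1) %% 2147483647
  as.integer(h)
}

split_code <- function(split) {
  match(match.arg(split, c("discovery", "replication")),
        c("discovery", "replication"))
}

#' Hardy-Weinberg genotype frequencies
#'
#' `(p^2, 2p(1-p), (1-p)^2)` over (AA, AB, BB) for allele-A frequency `p`;
#' the genotype distribution of control subjects and of null SNPs in both
#' groups.
#'
#' @param p allele frequency in (0, 1).
#' @return Probability triple over (AA, AB, BB).
#' @export
control_genotype_freqs <- function(p) {
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)")
  cbind(p^2, 2 * p * (1 - p), (1 - p)^2)[, , drop = TRUE]
}

#' Case genotype frequencies under an odds-ratio tilt
#'
#' The control HWE triple with the odds-ratio tilt of the inheritance mode
#' applied and renormalized to sum to 1:
#' additive `(p^2, 2*OR*p(1-p), OR^2*(1-p)^2)`,
#' recessive `(p^2, 2p(1-p), OR*(1-p)^2)`,
#' dominant `(p^2, 2*OR*p(1-p), OR*(1-p)^2)`
#' (each divided by its sum). With `risk_on_minor = TRUE` the tilt is
#' transposed onto the `p^2` side instead.
#'
#' @param p allele frequency in (0, 1).
#' @param odds_ratio positive odds ratio.
#' @param mode `"additive"`, `"recessive"` or `"dominant"`.
#' @param risk_on_minor see [simulation_design()].
#' @return Probability triple over (AA, AB, BB).
#' @export
case_genotype_freqs <- function(p, odds_ratio, mode = SIM_MODES,
                                risk_on_minor = FALSE) {
  mode <- match.arg(mode)
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)")
  if (any(odds_ratio <= 0)) stop("odds_ratio must be > 0")
  case_freq_matrix(p, odds_ratio, mode, risk_on_minor)[, , drop = TRUE]
}

# vectorized over (p, or, mode); returns a length(p) x 3 matrix
case_freq_matrix <- function(p, or, mode, risk_on_minor = FALSE) {
  tilt_ab <- ifelse(mode == "recessive", 1, or)
  tilt_hom <- ifelse(mode == "additive", or^2, or)
  f <- cbind(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (risk_on_minor) f[, 1L] <- f[, 1L] * tilt_hom
  else f[, 3L] <- f[, 3L] * tilt_hom
  f[, 2L] <- f[, 2L] * tilt_ab
  f / rowSums(f)
}

# Ground truth + per-group genotype-frequency matrices for one replicate.
# Null-SNP MAFs are drawn once per replicate (stream keyed by replicate
# only) and therefore shared between the discovery and replication splits.
design_truth <- function(design, replicate) {
  grid <- expand.grid(maf = design$maf_grid, or = design$or_grid,
                      mode = design$modes, stringsAsFactors = FALSE)
  kc <- nrow(grid)
  set.seed(sub_seed(design$seed, replicate, "null_maf"))
  null_maf <- stats::runif(design$n_null, design$null_maf_range[1L],
                           design$null_maf_range[2L])
  truth <- data.frame(
    snp_id = c(sprintf("causal_%03d", seq_len(kc)),
               if (design$n_null)
                 sprintf("null_%06d", seq_len(design$n_null))),
    is_causal = rep(c(TRUE, FALSE), c(kc, design$n_null)),
    mode = c(grid$mode, rep(NA_character_, design$n_null)),
    or = c(grid$or, rep(NA_real_, design$n_null)),
    maf = c(grid$maf, null_maf),
    stringsAsFactors = FALSE, row.names = NULL)
  p <- truth$maf
  ctrl <- cbind(p^2, 2 * p * (1 - p), (1 - p)^2)
  cas <- ctrl
  if (kc) {
    cas[seq_len(kc), ] <- case_freq_matrix(grid$maf, grid$or, grid$mode,
                                           design$risk_on_minor)
  }
  list(truth = truth, ctrl = ctrl, case = cas)
}

#' Simulated truth table
#'
#' One row per SNP of a replicate's panel: causal flag, inheritance mode,
#' true OR and MAF (null MAFs are the replicate's uniform draws).
#'
#' @param design a [simulation_design()].
#' @param replicate replicate index (1-based).
#' @return A data frame.
#' @export
truth_table <- function(design, replicate = 1L) {
  design_truth(design, replicate)$truth
}

# multinomial draw per SNP via the binomial chain, vectorized over SNPs
sample_group_counts <- function(n, P) {
  aa <- stats::rbinom(nrow(P), n, P[, 1L])
  p_ab <- ifelse(P[, 1L] < 1, pmin(P[, 2L] / (1 - P[, 1L]), 1), 0)
  ab <- stats::rbinom(nrow(P), n - aa, p_ab)
  cbind(aa, ab, n - aa - ab)
}

#' Simulate per-SNP genotype count tables
#'
#' Count-mode generator: per-SNP (phenotype x genotype) counts are drawn
#' directly from three-category multinomials with the design's genotype
#' frequency triples, which is distributionally identical to tabulating a
#' subject-level matrix but never materializes one. This is the path that
#' makes genome-scale ranking (500,000 null SNPs) cheap.
#'
#' @param design a [simulation_design()].
#' @param split `"discovery"` or `"replication"`.
#' @param replicate replicate index.
#' @return A [genotype_counts()] object with a `truth` attribute.
#' @export
simulate_counts <- function(design, split = c("discovery", "replication"),
                            replicate = 1L) {
  split <- match.arg(split)
  dt <- design_truth(design, replicate)
  set.seed(sub_seed(design$seed, replicate, split_code(split), "counts"))
  counts_T <- sample_group_counts(design$n_cases, dt$case)
  counts_N <- sample_group_counts(design$n_controls, dt$ctrl)
  out <- genotype_counts(dt$truth$snp_id, counts_T, counts_N,
                         n_cases = design$n_cases,
                         n_controls = design$n_controls)
  attr(out, "truth") <- dt$truth
  out
}

#' Simulate a subject-level case-control dataset
#'
#' Draws each subject's genotype at each SNP independently from the
#' appropriate genotype-frequency triple (cases from the tilted triple,
#' controls from HWE). Each SNP has its own random substream keyed by
#' (seed, replicate, split, SNP index), so the columns produced for a SNP
#' subset are identical to the corresponding columns of the full panel --
#' which is what lets genome-scale experiments rank on counts and then
#' materialize subject-level data only for the top-ranked SNPs.
#'
#' @param design a [simulation_design()].
#' @param split `"discovery"` or `"replication"`.
#' @param replicate replicate index.
#' @param snp_subset optional character vector of SNP ids (in the desired
#'   column order) to materialize; default: the whole panel.
#' @param max_cells refuse to materialize more than this many genotype
#'   calls (default 2e8); use [simulate_counts()] beyond that.
#' @return A list: `genotypes` ([genotype_matrix()]), `phenotype`
#'   ([phenotype_vector()]), `truth` (rows for the selected SNPs).
#' @export
simulate_dataset <- function(design, split = c("discovery", "replication"),
                             replicate = 1L, snp_subset = NULL,
                             max_cells = 2e8) {
  split <- match.arg(split)
  dt <- design_truth(design, replicate)
  idx <- if (is.null(snp_subset)) seq_len(nrow(dt$truth))
         else match(snp_subset, dt$truth$snp_id)
  if (anyNA(idx)) stop("unknown SNP id(s) in snp_subset")
  n_sub <- design$n_cases + design$n_controls
  if (n_sub * length(idx) > max_cells)
    stop("requested ", n_sub * length(idx), " genotype calls exceeds ",
         "max_cells = ", max_cells,
         "; use simulate_counts() or a snp_subset")
  sc <- split_code(split)
  geno <- matrix(NA_integer_, nrow = n_sub, ncol = length(idx))
  for (j in seq_along(idx)) {
    s <- idx[j]
    set.seed(sub_seed(design$seed, replicate, sc, 1000, s))
    geno[, j] <- c(
      sample.int(3L, design$n_cases, replace = TRUE, prob = dt$case[s, ]),
      sample.int(3L, design$n_controls, replace = TRUE,
                 prob = dt$ctrl[s, ])) - 1L
  }
  subj <- c(sprintf("case_%05d", seq_len(design$n_cases)),
            sprintf("control_%05d", seq_len(design$n_controls)))
  alle <- matrix(rep(c("A", "G"), each = length(idx)), ncol = 2L)
  list(genotypes = genotype_matrix(geno, subj, dt$truth$snp_id[idx], alle),
       phenotype = phenotype_vector(
         rep(c(1L, 0L), c(design$n_cases, design$n_controls)), subj),
       truth = dt$truth[idx, , drop = FALSE])
}

#' Read a simulation design from a JSON config file
#'
#' Fields mirror [simulation_design()] arguments; absent fields keep their
#' defaults. Requires \pkg{jsonlite}.
#'
#' @param path path to a JSON file.
#' @return A `simulation_design`.
#' @export
read_design_json <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("read_design_json requires the jsonlite package")
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(simulation_design))
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown design field(s): ", paste(extra, collapse = ", "))
  do.call(simulation_design, cfg)
}
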