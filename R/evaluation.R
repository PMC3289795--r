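#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling: the probability
#' that a random case outscores a random control, counting ties half. This
#' equals the trapezoidal area under the empirical ROC curve and is
#' invariant under strictly increasing transforms of the scores.
#'
#' @param scores numeric per-subject scores (larger = more case-like).
#' @param y an aligned [phenotype_vector()] or plain 0/1 vector.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, y) {
  lab <- if (inherits(y, "phenotype_vector")) y$labels else as.integer(y)
  stopifnot(length(scores) == length(lab))
  n1 <- sum(lab == 1L); n0 <- sum(lab == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both phenotype classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[lab == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

EVAL_METHODS <- c("nbc", "grs_case1", "grs_case2", "grs_case3")

#' Default SNP-count grid for nested models
#'
#' Steps of 1 through the causal range, then steps of 5 for 30 SNPs
#' beyond, truncated to the available SNP count. Resolves the region where
#' the AUC maximum of a nested-model curve occurs.
#'
#' @param n_causal number of causal SNPs in the design.
#' @param k_available total number of ranked SNPs available.
#' @return Increasing integer vector.
#' @export
default_k_grid <- function(n_causal, k_available = Inf) {
  ks <- if (n_causal > 0)
    c(seq_len(n_causal), seq(n_causal + 5, n_causal + 30, by = 5))
  else seq_len(min(30, k_available))
  as.integer(unique(ks[ks <= k_available]))
}

# Shared core: per-method AUC at each k, for SNPs already in rank order.
# counts_top: discovery genotype_counts for the top-k_max ranked SNPs;
# X_rep: replication subjects x SNPs code matrix in the same order.
nested_auc_core <- function(counts_top, X_rep, y_rep, methods, k_values,
                            smoothing = 0.5, prior_T = 0.5) {
  methods <- match.arg(methods, EVAL_METHODS, several.ok = TRUE)
  eff_gen <- fit_genotypic(counts_top, smoothing = smoothing)
  need_add <- any(methods %in% c("grs_case1", "grs_case2"))
  eff_add <- if (need_add) fit_additive(counts_top)
  nbcm <- fit_nbc(counts_top, prior_T = prior_T, smoothing = smoothing)
  L <- nbc_llr(nbcm)
  triple <- function(method) {
    switch(method,
      nbc = list(w = L[, 1L], v = L[, 2L], z = L[, 3L]),
      grs_case3 = list(w = rep(0, nrow(eff_gen)), v = eff_gen$v,
                       z = eff_gen$z),
      grs_case2 = list(w = rep(0, nrow(eff_add)), v = eff_add$v,
                       z = 2 * eff_add$v),
      grs_case1 = {
        r <- risk_allele(eff_add)
        list(w = 2 * (r == "A"), v = rep(1, length(r)), z = 2 * (r == "B"))
      })
  }
  lab <- if (inherits(y_rep, "phenotype_vector")) y_rep$labels else y_rep
  out <- matrix(NA_real_, nrow = length(methods), ncol = length(k_values),
                dimnames = list(methods, k_values))
  for (m in methods) {
    tr <- triple(m)
    C <- weight_contributions(X_rep, tr$w, tr$v, tr$z)
    S <- C
    for (j in seq_len(ncol(C))[-1L]) S[, j] <- S[, j - 1L] + C[, j]
    out[m, ] <- vapply(k_values, function(k) roc_auc(S[, k], lab),
                       numeric(1L))
  }
  out
}

#' Nested-model AUC curves on a discovery/replication pair
#'
#' For each k of `k_values` and each method, estimates weights (and NBC
#' conditionals) on the discovery set using the top-k ranked SNPs, scores
#' the replication subjects, and records the replication AUC. All methods
#' see the identical SNP ordering. Raw scores are used: calibration is a
#' strictly increasing transform, so it cannot change an AUC.
#'
#' @param discovery,replication lists with elements `genotypes` and
#'   `phenotype` (as returned by [simulate_dataset()] or
#'   [read_genotype_tsv()]).
#' @param ranks a [rank_snps()] result computed on the discovery set.
#' @param methods subset of `"nbc"`, `"grs_case1"`, `"grs_case2"`,
#'   `"grs_case3"`.
#' @param k_values increasing SNP counts, all `<=` the number of ranked
#'   SNPs.
#' @param smoothing,prior_T passed to the fitting routines.
#' @return A methods x k matrix of AUC values.
#' @export
nested_curve <- function(discovery, replication, ranks,
                         methods = EVAL_METHODS, k_values,
                         smoothing = 0.5, prior_T = 0.5) {
  stopifnot(inherits(ranks, "rank_statistics"))
  k_values <- sort(unique(as.integer(k_values)))
  if (max(k_values) > nrow(ranks))
    stop("k exceeds the number of ranked SNPs (", nrow(ranks), ")")
  top <- ranks$snp_id[seq_len(max(k_values))]
  counts_top <- subset_counts(
    count_genotypes(discovery$genotypes, discovery$phenotype), top)
  G_top <- subset_snps(replication$genotypes, top)
  nested_auc_core(counts_top, G_top$genotypes, replication$phenotype,
                  methods, k_values, smoothing, prior_T)
}

#' Run a full nested-model simulation experiment
#'
#' Per replicate: simulate the discovery set in count mode, rank all SNPs
#' by genotypic-association evidence on the discovery counts, materialize
#' replication subject-level genotypes for the top-ranked SNPs only, build
#' nested models with increasing k on the discovery counts, and record
#' replication AUCs. Curves are aggregated as the mean AUC per (method, k)
#' across replicates. Deterministic given the design seed.
#'
#' @param design a [simulation_design()].
#' @param k_values SNP-count grid; default [default_k_grid()] for the
#'   design's causal count.
#' @param methods methods to evaluate (see [nested_curve()]).
#' @param ranking ranking statistic, see [rank_snps()].
#' @param smoothing,prior_T passed to the fitting routines.
#' @return A `nested_curves` object: list with `k_values`, `methods`,
#'   `auc` (per method, a replicates x k matrix), `mean_auc` (per method),
#'   `design`, `ranking`.
#' @export
run_experiment <- function(design, k_values = NULL, methods = EVAL_METHODS,
                           ranking = "bic_bayes_factor",
                           smoothing = 0.5, prior_T = 0.5) {
  stopifnot(inherits(design, "simulation_design"))
  methods <- match.arg(methods, EVAL_METHODS, several.ok = TRUE)
  k_total <- n_causal(design) + design$n_null
  if (is.null(k_values))
    k_values <- default_k_grid(n_causal(design), k_total)
  k_values <- sort(unique(as.integer(k_values)))
  if (max(k_values) > k_total)
    stop("k exceeds the number of simulated SNPs (", k_total, ")")
  k_max <- max(k_values)
  auc <- lapply(methods, function(m)
    matrix(NA_real_, nrow = design$n_replicates, ncol = length(k_values),
           dimnames = list(NULL, k_values)))
  names(auc) <- methods
  for (r in seq_len(design$n_replicates)) {
    counts_disc <- simulate_counts(design, "discovery", r)
    ranks <- rank_snps(counts_disc, method = ranking)
    top <- ranks$snp_id[seq_len(k_max)]
    counts_top <- subset_counts(counts_disc, top)
    rep_data <- simulate_dataset(design, "replication", r, snp_subset = top)
    res <- nested_auc_core(counts_top, rep_data$genotypes$genotypes,
                           rep_data$phenotype, methods, k_values,
                           smoothing, prior_T)
    for (m in methods) auc[[m]][r, ] <- res[m, ]
  }
  structure(list(k_values = k_values, methods = methods, auc = auc,
                 mean_auc = lapply(auc, colMeans), design = design,
                 ranking = ranking),
            class = "nested_curves")
}

#' @export
print.nested_curves <- function(x, ...) {
  cat(sprintf("nested_curves: %d method(s), k in [%d, %d] (%d points), %d replicate(s)\n",
              length(x$methods), min(x$k_values), max(x$k_values),
              length(x$k_values), nrow(x$auc[[1L]])))
  for (m in x$methods) {
    am <- curve_argmax(x, m)
    cat(sprintf("  %-10s max mean AUC %.4f at k = %d\n", m,
                max(x$mean_auc[[m]]), am))
  }
  invisible(x)
}

#' Location of the mean-AUC maximum of a nested curve
#'
#' @param curves a [run_experiment()] result.
#' @param method which method's curve.
#' @return The smallest k attaining the maximum mean AUC.
#' @export
curve_argmax <- function(curves, method = "nbc") {
  stopifnot(inherits(curves, "nested_curves"))
  mu <- curves$mean_auc[[method]]
  if (is.null(mu)) stop("method '", method, "' not in curves")
  curves$k_values[which.max(mu)]
}

#' Plot nested AUC curves
#'
#' Mean replication AUC versus number of SNPs, one line per method.
#'
#' @param x a `nested_curves` object.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.nested_curves <- function(x, ...) {
  mu <- do.call(cbind, x$mean_auc)
  graphics::matplot(x$k_values, mu, type = "l", lty = 1,
                    xlab = "number of SNPs", ylab = "mean AUC", ...)
  graphics::legend("bottomright", legend = x$methods, lty = 1,
                   col = seq_along(x$methods))
  invisible(x)
}

#' Export per-replicate and mean curves as a tidy data frame
#'
#' @param curves a [run_experiment()] result.
#' @return Data frame with columns `method`, `k`, `replicate` (0 = mean),
#'   `auc`.
#' @export
curves_to_df <- function(curves) {
  stopifnot(inherits(curves, "nested_curves"))
  do.call(rbind, lapply(curves$methods, function(m) {
    a <- curves$auc[[m]]
    rbind(
      data.frame(method = m, k = rep(curves$k_values, each = nrow(a)),
                 replicate = rep(seq_len(nrow(a)), length(curves$k_values)),
                 auc = as.vector(a)),
      data.frame(method = m, k = curves$k_values, replicate = 0L,
                 auc = curves$mean_auc[[m]]))
  }))
}
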