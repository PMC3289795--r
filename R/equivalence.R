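#' Default loss-ratio grid for rule-equivalence checks
#'
#' 25 logarithmically spaced points on `[1e-3, 1e3]`, covering all
#' practically distinct operating points of the Bayesian rule.
#'
#' @return Numeric vector of lambda values.
#' @export
lambda_grid_default <- function() {
  exp(seq(log(1e-3), log(1e3), length.out = 25L))
}

#' Map an NBC loss ratio to the equivalent GRS threshold
#'
#' For a calibrated GRS score `g0 + g1 * GRS` built from the same genetic
#' model as the NBC, the NBC rule at loss ratio `lambda` equals the GRS
#' rule at threshold
#' `tau = g0 - g1 * sum(aa_log_odds) + g1 * log(lambda)`,
#' where `aa_log_odds` are the per-SNP log-odds of the trait for the AA
#' (referent) genotype ([nbc_aa_log_odds()]). The mapping relies on the
#' additive decomposition of the NBC log-odds, which is exact when
#' `prior_T = 0.5` (for other priors the per-SNP log-odds absorb the prior
#' k times rather than once; the rules remain equivalent but through a
#' different constant).
#'
#' @param g0,g1 GRS calibration intercept and slope (`g1 != 0`).
#' @param aa_log_odds per-SNP AA log-odds (numeric vector).
#' @param lam positive loss ratio.
#' @return The equivalent threshold on the calibrated-score scale.
#' @export
nbc_to_grs_threshold <- function(g0, g1, aa_log_odds, lam) {
  if (any(g1 == 0)) stop("g1 = 0: classification rule is degenerate")
  if (any(lam <= 0)) stop("lambda must be > 0")
  g0 - g1 * sum(aa_log_odds) + g1 * log(lam)
}

#' Verify the GRS/NBC classification-rule equivalence numerically
#'
#' Checks, on a concrete dataset, that an NBC and a case-3 GRS built from
#' the same smoothed count tables are one model in two parameterizations:
#' the NBC posterior log-odds must be exactly affine in the raw case-3 GRS
#' (slope 1, intercept = prior log-odds plus the summed AA
#' log-likelihood-ratios), the two scores must have identical AUC, and the
#' NBC rule at every lambda of the grid must produce the same labels as
#' the calibrated GRS rule at the mapped threshold. The raw (uncalibrated)
#' GRS is used for the affine and AUC comparisons so calibration error
#' cannot masquerade as a failure of the algebraic identity; calibration
#' enters only the threshold mapping.
#'
#' @param nbc_model an [fit_nbc()] model.
#' @param grs_model a calibrated [calibrate()] model whose `scheme` is the
#'   case-3 [build_weights()] scheme from the same counts.
#' @param G a [genotype_matrix()] with the model SNPs.
#' @param y an aligned [phenotype_vector()].
#' @param lambda_grid loss ratios for label-agreement testing.
#' @return An `equivalence_report` list: `n_profiles`, `rank_agreement`
#'   (Spearman correlation of the two scores), `max_label_disagreement`
#'   (worst count over the lambda grid), `auc_nbc`, `auc_grs`,
#'   `affine_fit` (slope, intercept, max_abs_residual).
#' @export
verify_equivalence <- function(nbc_model, grs_model, G, y,
                               lambda_grid = lambda_grid_default()) {
  stopifnot(inherits(nbc_model, "nbc_model"), inherits(grs_model, "grs_model"))
  scheme <- grs_model$scheme
  if (is.null(scheme))
    stop("grs_model must carry its weight scheme (calibrate(..., scheme=))")
  if (!setequal(nbc_model$snp_id, scheme$snp_id))
    stop("NBC and GRS models cover different SNP sets")
  check_aligned(G, y)

  lo <- nbc_log_odds(nbc_model, G)
  grs <- compute_grs(G, scheme)

  # affine fit by least squares, residual measured in the sup norm
  cf <- stats::coef(stats::lm(lo ~ grs))
  resid <- lo - (cf[1L] + cf[2L] * grs)

  labels_disagree <- vapply(lambda_grid, function(lam) {
    nbc_lab <- classify_score(lo, lam, scale = "log_odds")
    tau <- nbc_to_grs_threshold(grs_model$gamma0, grs_model$gamma1,
                                nbc_aa_log_odds(nbc_model), lam)
    grs_lab <- as.integer(grs_model$gamma0 + grs_model$gamma1 * grs > tau)
    sum(nbc_lab != grs_lab)
  }, integer(1L))

  structure(list(
    n_profiles = length(lo),
    rank_agreement = stats::cor(lo, grs, method = "spearman"),
    max_label_disagreement = max(labels_disagree),
    label_disagreement = labels_disagree,
    lambda_grid = lambda_grid,
    auc_nbc = roc_auc(lo, y),
    auc_grs = roc_auc(grs, y),
    affine_fit = c(slope = unname(cf[2L]), intercept = unname(cf[1L]),
                   max_abs_residual = max(abs(resid)))),
    class = "equivalence_report")
}

#' @export
print.equivalence_report <- function(x, ...) {
  cat("equivalence_report\n")
  cat(sprintf("  profiles:               %d\n", x$n_profiles))
  cat(sprintf("  rank agreement (rho):   %.12f\n", x$rank_agreement))
  cat(sprintf("  AUC (NBC / GRS):        %.12f / %.12f\n",
              x$auc_nbc, x$auc_grs))
  cat(sprintf("  max label disagreement: %d (over %d lambda values)\n",
              x$max_label_disagreement, length(x$lambda_grid)))
  cat(sprintf("  affine fit: slope %.10f, intercept %.6f, max |resid| %.3e\n",
              x$affine_fit[["slope"]], x$affine_fit[["intercept"]],
              x$affine_fit[["max_abs_residual"]]))
  invisible(x)
}
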