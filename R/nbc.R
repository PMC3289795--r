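new_nbc_model <- function(snp_id, cond_T, cond_notT, prior_T, smoothing) {
  stopifnot(prior_T > 0, prior_T < 1,
            nrow(cond_T) == length(snp_id),
            nrow(cond_notT) == length(snp_id))
  structure(list(snp_id = as.character(snp_id),
                 cond_T = unname(as.matrix(cond_T)),
                 cond_notT = unname(as.matrix(cond_notT)),
                 prior_T = prior_T, smoothing = smoothing),
            class = "nbc_model")
}

#' Fit a Naive Bayes classifier from genotype counts
#'
#' Estimates, per SNP, the conditional genotype distributions p(S|T) and
#' p(S|not T) as (smoothed) relative frequencies within cases and controls.
#' Conditional independence of SNPs given the trait is structural: nothing
#' about the dependence between SNPs is estimated. The smoothing rule is
#' shared with [fit_genotypic()] (pseudo-count added to every cell of a
#' table containing a zero), so NBC conditionals and case-3 GRS weights
#' derived from the same counts stay exactly compatible.
#'
#' @param counts a [genotype_counts()] object.
#' @param prior_T prior probability of the trait; default 0.5, under which
#'   the posterior is the sigmoid of the summed per-SNP log-likelihood
#'   ratios (the natural choice for case-control data, where the prior is
#'   not estimable anyway and only shifts the threshold).
#' @param smoothing pseudo-count, as in [fit_genotypic()]; default 0.5.
#' @return An `nbc_model` list: `snp_id`, `cond_T` and `cond_notT`
#'   (SNPs x 3 probability matrices over AA/AB/BB), `prior_T`, `smoothing`.
#' @export
fit_nbc <- function(counts, prior_T = 0.5, smoothing = 0.5) {
  cm_raw <- count_matrices(counts)
  if (any(rowSums(cm_raw$T) == 0) || any(rowSums(cm_raw$N) == 0))
    stop("empty phenotype group for some SNP: cannot estimate conditionals")
  cm <- smoothed_count_matrices(counts, smoothing)
  new_nbc_model(counts$snp_id,
                cond_T = cm$T / rowSums(cm$T),
                cond_notT = cm$N / rowSums(cm$N),
                prior_T = prior_T, smoothing = smoothing)
}

#' @export
print.nbc_model <- function(x, ...) {
  cat(sprintf("nbc_model: %d SNPs, prior_T = %g, smoothing = %g\n",
              length(x$snp_id), x$prior_T, x$smoothing))
  invisible(x)
}

# log-likelihood-ratio matrix (SNPs x 3): log p(g|T) - log p(g|not T)
nbc_llr <- function(model) log(model$cond_T) - log(model$cond_notT)

# subjects x SNPs code matrix aligned to the model's SNP order
align_codes <- function(model, G) {
  if (inherits(G, "genotype_matrix")) {
    idx <- match(model$snp_id, G$snp_ids)
    if (anyNA(idx))
      stop("genotype data lacks model SNP(s): ",
           paste(utils::head(model$snp_id[is.na(idx)], 3L), collapse = ", "))
    G$genotypes[, idx, drop = FALSE]
  } else {
    m <- matrix(as.integer(G), ncol = length(model$snp_id))
    if (ncol(m) != length(model$snp_id))
      stop("profile length does not match the model's SNP count")
    m
  }
}

#' NBC posterior probability of the trait
#'
#' `p(T | profile)` under conditional independence, computed in log space
#' so genome-scale products do not underflow. Missing genotypes drop out of
#' both the numerator and denominator products.
#'
#' @param model an [fit_nbc()] model.
#' @param G a [genotype_matrix()] covering the model's SNPs, or an
#'   integer vector/matrix of genotype codes (0/1/2/NA) in model SNP order.
#' @return Numeric vector of posterior probabilities, one per subject.
#' @export
nbc_posterior <- function(model, G) {
  stats::plogis(nbc_log_odds(model, G))
}

#' NBC posterior log-odds
#'
#' `logit p(T | profile) = logit(prior) + sum_i log[p(S_i|T)/p(S_i|not T)]`,
#' the additive decomposition of the NBC score into per-SNP summands. It is
#' exactly `qlogis(nbc_posterior(...))`.
#'
#' @inheritParams nbc_posterior
#' @return Numeric vector of log-odds, one per subject.
#' @export
nbc_log_odds <- function(model, G) {
  X <- align_codes(model, G)
  L <- nbc_llr(model)
  C <- weight_contributions(X, L[, 1L], L[, 2L], L[, 3L])
  unname(stats::qlogis(model$prior_T) + rowSums(C))
}

#' Per-SNP log-odds of the trait for the AA genotype
#'
#' `log p(T|S_i = AA) / (1 - p(T|S_i = AA))` for each model SNP: the prior
#' log-odds plus the AA log-likelihood-ratio. These are the constants the
#' NBC-to-GRS threshold mapping needs.
#'
#' @param model an [fit_nbc()] model.
#' @return Numeric vector, one value per SNP.
#' @export
nbc_aa_log_odds <- function(model) {
  unname(stats::qlogis(model$prior_T) + nbc_llr(model)[, 1L])
}

#' Bayesian classification rule with loss ratio lambda
#'
#' Classify as T when the posterior score exceeds `lambda / (1 + lambda)`
#' (equivalently, when the posterior log-odds exceeds `log(lambda)`).
#' `lambda = 1` is the most-probable-outcome rule with threshold 0.5.
#'
#' @param score numeric scores: posterior probabilities, or log-odds when
#'   `scale = "log_odds"`.
#' @param lambda positive loss ratio.
#' @param scale which scale `score` lives on.
#' @return Integer labels, 1 = T, 0 = not T.
#' @export
classify_score <- function(score, lambda,
                           scale = c("probability", "log_odds")) {
  scale <- match.arg(scale)
  if (!is.numeric(lambda) || any(lambda <= 0))
    stop("lambda must be > 0")
  thr <- if (scale == "probability") lambda / (1 + lambda) else log(lambda)
  as.integer(score > thr)
}
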