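#' Closed-form genotypic logistic effects per SNP
#'
#' For each SNP, estimates the genotypic (2-df) logistic model
#' `logit p(T|S) = a0 + v X_AB + z X_BB` from its 2 x 3 count table. The
#' maximum-likelihood estimates have closed form as cross-product ratios:
#' `v = log[(n_T,AB / n_N,AB) / (n_T,AA / n_N,AA)]` and analogously for `z`
#' with the BB column; the intercept is `log(n_T,AA / n_N,AA)`. When any
#' cell of a SNP's table is zero, the smoothing pseudo-count is added to
#' every cell of that table before the ratios are formed, keeping the
#' log-odds finite without perturbing clean tables.
#'
#' @param counts a [genotype_counts()] object (or [count_genotypes()]
#'   output).
#' @param smoothing pseudo-count added to all 6 cells of a table that
#'   contains a zero; default 0.5 (Haldane-Anscombe style).
#' @return A `snp_effects` data frame with columns `snp_id`, `model`,
#'   `intercept`, `v`, `z`, `se_v`, `se_z`.
#' @export
fit_genotypic <- function(counts, smoothing = 0.5) {
  cm_raw <- count_matrices(counts)
  bad <- rowSums(cm_raw$T) == 0 | rowSums(cm_raw$N) == 0
  if (any(bad))
    stop("degenerate SNP(s) with an empty phenotype row: ",
         paste(utils::head(counts$snp_id[bad], 3L), collapse = ", "))
  cm <- smoothed_count_matrices(counts, smoothing)
  lor <- function(col) {
    log((cm$T[, col] / cm$N[, col]) / (cm$T[, 1L] / cm$N[, 1L]))
  }
  se <- function(col) {
    sqrt(1 / cm$T[, col] + 1 / cm$N[, col] + 1 / cm$T[, 1L] + 1 / cm$N[, 1L])
  }
  structure(
    data.frame(snp_id = counts$snp_id, model = "genotypic",
               intercept = log(cm$T[, 1L] / cm$N[, 1L]),
               v = lor(2L), z = lor(3L), se_v = se(2L), se_z = se(3L),
               stringsAsFactors = FALSE, row.names = NULL),
    class = c("snp_effects", "data.frame"), model = "genotypic")
}

#' Additive (per-allele) logistic effect per SNP
#'
#' Maximum-likelihood fit of the one-covariate logistic model with
#' B-allele dosage 0/1/2 for AA/AB/BB, on the grouped 2 x 3 counts (the
#' grouped-data likelihood is identical to the subject-level one). Genotype
#' columns unobserved in both groups are dropped, so a table with no BB
#' calls collapses to the corresponding 2 x 2 fit. Perfect separation is
#' flagged with a warning and an infinite-magnitude sentinel estimate.
#'
#' @param counts a [genotype_counts()] object.
#' @return A `snp_effects` data frame with columns `snp_id`, `model`,
#'   `intercept`, `v`, `se_v`, `separated`.
#' @export
fit_additive <- function(counts) {
  cm <- count_matrices(counts)
  k <- nrow(cm$T)
  out <- data.frame(snp_id = counts$snp_id, model = "additive",
                    intercept = NA_real_, v = NA_real_, se_v = NA_real_,
                    separated = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  for (i in seq_len(k)) {
    t_i <- cm$T[i, ]; n_i <- cm$N[i, ]
    keep <- (t_i + n_i) > 0
    if (sum(keep) < 2L)
      stop("SNP '", counts$snp_id[i],
           "': fewer than two genotype categories observed")
    x <- (0:2)[keep]
    fit <- suppressWarnings(
      stats::glm(cbind(t_i[keep], n_i[keep]) ~ x, family = stats::binomial()))
    if (!fit$converged)
      stop("SNP '", counts$snp_id[i], "': additive fit did not converge in ",
           fit$iter, " iterations")
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))[2L]
    # glm stops short of +-Inf under separation; detect via exploding SE
    if (is.na(se) || se > 1e3 || abs(cf[2L]) > 30) {
      warning("SNP '", counts$snp_id[i],
              "': perfect separation in additive fit")
      out$separated[i] <- TRUE
      out$v[i] <- sign(cf[2L]) * Inf
      out$intercept[i] <- cf[1L]
      out$se_v[i] <- Inf
    } else {
      out$intercept[i] <- cf[1L]
      out$v[i] <- cf[2L]
      out$se_v[i] <- se
    }
  }
  structure(out, class = c("snp_effects", "data.frame"), model = "additive")
}

#' Risk allele implied by an additive fit
#'
#' The risk allele is A when the per-B-allele log-odds slope is negative
#' (each B copy lowers the odds of the trait) and B when the slope is zero
#' or positive.
#'
#' @param effects a `snp_effects` data frame from [fit_additive()].
#' @return Character vector of `"A"`/`"B"`, one per SNP.
#' @export
risk_allele <- function(effects) {
  if (!identical(attr(effects, "model"), "additive"))
    stop("risk_allele requires additive-model effects")
  ifelse(effects$v < 0, "A", "B")
}

#' Rank SNPs by genotypic-association evidence
#'
#' Orders SNPs by the strength of their genotypic association with the
#' trait, as used to build nested prediction models. The default evidence
#' is a BIC approximation to the posterior odds of association: the
#' genotypic model (one binomial rate per observed genotype column) is
#' compared to the no-association model by
#' `log BF = (ll_geno - ll_null) - (df/2) log N`, with equal prior odds, so
#' the reported `posterior` is `plogis(log BF)`. Ranking is performed on
#' the log posterior odds scale (`evidence`), which is a strictly monotone
#' transform of the posterior probability but does not saturate in floating
#' point for very strong SNPs. The alternative is the 2-df Pearson
#' chi-square statistic of the 2 x 3 table.
#'
#' @param counts a [genotype_counts()] object.
#' @param method `"bic_bayes_factor"` (default) or `"genotypic_chi2"`.
#' @return A `rank_statistics` data frame sorted by rank, with columns
#'   `snp_id`, `evidence`, `posterior` (BIC method only), `rank`. Ties are
#'   broken by `snp_id` lexicographic order, so the output is invariant to
#'   input order.
#' @export
rank_snps <- function(counts, method = c("bic_bayes_factor",
                                         "genotypic_chi2")) {
  method <- match.arg(method)
  cm <- count_matrices(counts)
  tC <- cm$T; nC <- cm$N
  m <- tC + nC
  Tn <- rowSums(tC); Nn <- rowSums(nC); N <- Tn + Nn
  degenerate <- Tn == 0 | Nn == 0
  xlx <- function(x) ifelse(x > 0, x * log(x), 0)
  if (method == "bic_bayes_factor") {
    # per-column binomial loglik of the genotypic (saturated-by-genotype)
    # model minus the intercept-only model, all closed form
    ll_geno <- rowSums(xlx(tC) + xlx(nC) - xlx(m))
    ll_null <- xlx(Tn) + xlx(Nn) - xlx(N)
    df <- rowSums(m > 0) - 1L
    evidence <- (ll_geno - ll_null) - df / 2 * log(pmax(N, 1))
    posterior <- stats::plogis(evidence)
  } else {
    eT <- m * (Tn / N); eN <- m * (Nn / N)
    sq <- function(o, e) ifelse(e > 0, (o - e)^2 / e, 0)
    evidence <- rowSums(sq(tC, eT) + sq(nC, eN))
    posterior <- NULL
  }
  if (any(degenerate)) {
    message(sum(degenerate), " degenerate SNP(s): evidence set to minimum")
    evidence[degenerate] <- -Inf
  }
  ord <- order(-evidence, counts$snp_id)
  out <- data.frame(snp_id = counts$snp_id[ord], evidence = evidence[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(posterior)) out$posterior <- posterior[ord]
  out$rank <- seq_len(nrow(out))
  structure(out, class = c("rank_statistics", "data.frame"),
            method = method)
}
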