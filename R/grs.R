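#' Build a genetic-risk-score weight scheme
#'
#' Constructs the per-SNP genotype weights (w, v, z) for the three standard
#' GRS weighting schemes:
#' \describe{
#'   \item{case1}{Risk-allele counting ("unweighted" GRS). The heterozygote
#'     always scores 1; the homozygote of the risk allele scores 2 and the
#'     other homozygote 0, i.e. `w = 2*(risk == A)`, `v = 1`,
#'     `z = 2*(risk == B)`. The risk allele comes from the additive fit via
#'     [risk_allele()].}
#'   \item{case2}{Additive log-odds-ratio weights: `w = 0`, `v` = per-B-copy
#'     additive slope, `z = 2v`.}
#'   \item{case3}{Genotypic log-odds-ratio weights: `w = 0`, `v` and `z`
#'     are the AB-vs-AA and BB-vs-AA log-odds-ratios.}
#' }
#'
#' @param case one of `"case1"`, `"case2"`, `"case3"`.
#' @param effects a `snp_effects` data frame: additive ([fit_additive()])
#'   for cases 1-2, genotypic ([fit_genotypic()]) for case 3.
#' @return A `weight_scheme` data frame with columns `snp_id`, `w`, `v`,
#'   `z`, `risk_allele` and attribute `case`.
#' @export
build_weights <- function(case = c("case1", "case2", "case3"), effects) {
  case <- match.arg(case)
  model <- attr(effects, "model")
  need <- if (case == "case3") "genotypic" else "additive"
  if (!identical(model, need))
    stop(case, " weights require ", need, "-model effects, got ", model)
  k <- nrow(effects)
  if (case == "case1") {
    r <- risk_allele(effects)
    df <- data.frame(snp_id = effects$snp_id,
                     w = 2 * (r == "A"), v = rep(1, k), z = 2 * (r == "B"),
                     risk_allele = r, stringsAsFactors = FALSE,
                     row.names = NULL)
  } else if (case == "case2") {
    df <- data.frame(snp_id = effects$snp_id,
                     w = rep(0, k), v = effects$v, z = 2 * effects$v,
                     risk_allele = NA_character_, stringsAsFactors = FALSE,
                     row.names = NULL)
  } else {
    df <- data.frame(snp_id = effects$snp_id,
                     w = rep(0, k), v = effects$v, z = effects$z,
                     risk_allele = NA_character_, stringsAsFactors = FALSE,
                     row.names = NULL)
  }
  structure(df, class = c("weight_scheme", "data.frame"), case = case)
}

# Per-subject, per-SNP weight contributions for a code matrix X
# (subjects x SNPs, codes 0/1/2/NA) and per-SNP weight triples; missing
# genotypes contribute 0.
weight_contributions <- function(X, w, v, z) {
  k <- ncol(X)
  W <- rbind(w, v, z)                          # 3 x k, rows AA/AB/BB
  idx <- cbind(as.vector(X) + 1L, rep(seq_len(k), each = nrow(X)))
  C <- matrix(W[idx], nrow = nrow(X), ncol = k)
  C[is.na(C)] <- 0
  C
}

#' Compute per-subject genetic risk scores
#'
#' `GRS = sum_i w_i X_iAA + v_i X_iAB + z_i X_iBB` over the SNPs of the
#' scheme; a missing genotype omits that SNP's summand.
#'
#' @param G a [genotype_matrix()]; every SNP of `G` must appear in the
#'   scheme.
#' @param scheme a [build_weights()] result.
#' @return Named numeric vector of scores, one per subject.
#' @export
compute_grs <- function(G, scheme) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(scheme, "weight_scheme"))
  idx <- match(G$snp_ids, scheme$snp_id)
  if (anyNA(idx))
    stop("SNP(s) in genotype matrix absent from weight scheme: ",
         paste(utils::head(G$snp_ids[is.na(idx)], 3L), collapse = ", "))
  C <- weight_contributions(G$genotypes, scheme$w[idx], scheme$v[idx],
                            scheme$z[idx])
  stats::setNames(rowSums(C), G$subject_ids)
}

#' Calibrate a univariate logistic model on a GRS
#'
#' Maximum-likelihood fit of `logit p(T|GRS) = gamma0 + gamma1 * GRS`. The
#' calibrated score is the classification score whose threshold `tau` the
#' equivalence mappings operate on; by the slope/intercept irrelevance
#' properties the calibration constants never change which labels a rule
#' can produce, only where its threshold sits.
#'
#' @param grs_scores numeric per-subject scores.
#' @param y an aligned [phenotype_vector()] (or plain 0/1 vector).
#' @param scheme optional [build_weights()] scheme to carry along.
#' @return A `grs_model` list with elements `gamma0`, `gamma1`, `se`,
#'   `separated`, `scheme`.
#' @export
calibrate <- function(grs_scores, y, scheme = NULL) {
  lab <- if (inherits(y, "phenotype_vector")) y$labels else as.integer(y)
  if (length(unique(grs_scores)) < 2L)
    stop("degenerate scores: need at least two distinct values")
  if (length(unique(lab)) < 2L)
    stop("both phenotype classes must be present")
  fit <- suppressWarnings(
    stats::glm(lab ~ grs_scores, family = stats::binomial()))
  cf <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  separated <- any(is.na(se)) || max(se) > 1e3 || abs(cf[2L]) > 30
  if (separated)
    warning("perfect separation in GRS calibration; estimates are sentinels")
  if (cf[2L] <= 0 && !separated)
    message("calibrated gamma1 <= 0: GRS is not positively associated ",
            "with the trait in this sample")
  structure(list(gamma0 = unname(cf[1L]), gamma1 = unname(cf[2L]),
                 se = unname(se), separated = separated, scheme = scheme),
            class = "grs_model")
}

#' @export
print.grs_model <- function(x, ...) {
  cat(sprintf("grs_model: gamma0 = %.4f, gamma1 = %.4f%s\n", x$gamma0,
              x$gamma1, if (x$separated) " (separated)" else ""))
  invisible(x)
}

#' Threshold shift for an intercept change (intercept irrelevance)
#'
#' Two logistic classification scores that differ only in their intercepts
#' (`alpha0` vs `beta0`) define label-identical rules when the second is
#' thresholded at `tau + beta0 - alpha0` instead of `tau`.
#'
#' @param tau threshold of the first rule (log-odds scale).
#' @param alpha0,beta0 intercepts of the first and second score.
#' @return The equivalent threshold for the second score.
#' @export
shift_threshold_intercept <- function(tau, alpha0, beta0) {
  tau + beta0 - alpha0
}

#' Threshold shift for a slope/intercept change (slope irrelevance)
#'
#' For univariate logistic scores `g0 + g1*GRS` and `b0 + b1*GRS` on the
#' same GRS, the rule "first score > tau" is label-identical to
#' "second score > b0 + b1*(tau - g0)/g1", provided the slopes share a
#' sign (otherwise the rule orientation flips and a warning is issued).
#'
#' @param tau threshold of the first rule.
#' @param g0,g1 intercept and slope of the first score (`g1 != 0`).
#' @param b0,b1 intercept and slope of the second score.
#' @return The equivalent threshold for the second score.
#' @export
shift_threshold_slope <- function(tau, g0, g1, b0, b1) {
  if (any(g1 == 0)) stop("g1 = 0: classification rule is degenerate")
  if (any(sign(b1) != sign(g1)))
    warning("slopes differ in sign: the mapped rule's orientation flips ",
            "(classify as T when the second score is *below* the threshold)")
  b0 + b1 * (tau - g0) / g1
}
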