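additive_effects <- function(v, ids = sprintf("snp%d", seq_along(v))) {
  structure(data.frame(snp_id = ids, v = v, stringsAsFactors = FALSE),
            class = c("snp_effects", "data.frame"), model = "additive")
}

test_that("build_weights implements the three weighting schemes", {
  eff <- additive_effects(c(0.3, -0.2))
  w1 <- build_weights("case1", eff)
  # risk allele B -> (0, 1, 2); risk allele A -> (2, 1, 0)
  expect_equal(unlist(w1[1, c("w", "v", "z")]), c(w = 0, v = 1, z = 2))
  expect_equal(unlist(w1[2, c("w", "v", "z")]), c(w = 2, v = 1, z = 0))
  expect_identical(w1$risk_allele, c("B", "A"))

  w2 <- build_weights("case2", additive_effects(log(1.5)))
  expect_equal(unlist(w2[1, c("w", "v", "z")]),
               c(w = 0, v = log(1.5), z = 2 * log(1.5)))

  cnt <- make_counts(c(10, 20, 10), c(20, 10, 5))
  w3 <- build_weights("case3", fit_genotypic(cnt, smoothing = 0))
  expect_equal(unlist(w3[1, c("w", "v", "z")]),
               c(w = 0, v = log(4), z = log(4)))

  expect_error(build_weights("case3", eff), "genotypic")
  expect_error(build_weights("case1", fit_genotypic(cnt)), "additive")
})

test_that("compute_grs sums genotype weights, skipping missing calls", {
  # case 1 over 3 SNPs, all risk allele B: carrying 1, 2 and 0 risk
  # alleles scores 3
  sch <- build_weights("case1", additive_effects(c(0.1, 0.2, 0.3)))
  G <- genotype_matrix(matrix(c(1L, 2L, 0L), nrow = 1), "s1",
                       sprintf("snp%d", 1:3),
                       matrix(rep(c("A", "G"), each = 3), ncol = 2))
  expect_equal(unname(compute_grs(G, sch)), 3)

  # all-AA subject is the referent under case 2 / case 3
  sch2 <- build_weights("case2", additive_effects(c(0.1, 0.2, 0.3)))
  G0 <- genotype_matrix(matrix(0L, 1, 3), "s1", sprintf("snp%d", 1:3),
                        matrix(rep(c("A", "G"), each = 3), ncol = 2))
  expect_equal(unname(compute_grs(G0, sch2)), 0)

  # case-3 hand sum: genotypes (AB, BB) with (v, z) = (log 2, log 3)
  sch3 <- structure(data.frame(snp_id = c("snp1", "snp2"), w = 0,
                               v = c(log(2), log(9)), z = c(log(7), log(3)),
                               risk_allele = NA),
                    class = c("weight_scheme", "data.frame"), case = "case3")
  Gx <- genotype_matrix(matrix(c(1L, 2L), 1), "s1", c("snp1", "snp2"),
                        matrix(rep(c("A", "G"), each = 2), ncol = 2))
  expect_equal(unname(compute_grs(Gx, sch3)), log(2) + log(3))

  # a missing genotype omits that SNP's summand
  Gm <- genotype_matrix(matrix(c(NA_integer_, 2L), 1), "s1",
                        c("snp1", "snp2"),
                        matrix(rep(c("A", "G"), each = 2), ncol = 2))
  expect_equal(unname(compute_grs(Gm, sch3)), log(3))

  # SNP not covered by the scheme is a usage error
  Gu <- genotype_matrix(matrix(0L, 1, 1), "s1", "other",
                        cbind("A", "G"))
  expect_error(compute_grs(Gu, sch3), "absent")
})

test_that("GRS is additive over disjoint SNP partitions and case 1 counts
           risk alleles", {
  d <- random_dataset(50, 8, p_missing = 0.1, seed = 3)
  eff <- additive_effects(seq(-0.4, 0.3, length.out = 8),
                          d$genotypes$snp_ids)
  for (case in c("case1", "case2")) {
    sch <- build_weights(case, eff)
    full <- compute_grs(d$genotypes, sch)
    part <- compute_grs(subset_snps(d$genotypes, 1:3), sch) +
            compute_grs(subset_snps(d$genotypes, 4:8), sch)
    expect_equal(full, part)
  }
  sch1 <- build_weights("case1", eff)
  s <- compute_grs(d$genotypes, sch1)
  expect_true(all(s >= 0 & s <= 2 * 8))
  # direct risk-allele count oracle
  risk <- risk_allele(eff)
  X <- d$genotypes$genotypes
  cnt <- sapply(seq_len(nrow(X)), function(i) {
    g <- X[i, ]
    sum(ifelse(risk == "B", g, 2 - g)[!is.na(g)])
  })
  expect_equal(unname(s), cnt)
})

test_that("calibrate estimates (gamma0, gamma1) and flags degeneracies", {
  expect_warning(calibrate(c(rep(0, 20), rep(1, 20)),
                           rep(c(0, 1), each = 20)), "separation")
  expect_error(calibrate(rep(1, 20), rep(c(0, 1), 10)), "degenerate")
  expect_error(calibrate(rnorm(20), rep(1, 20)), "classes")

  # independence: gamma1 within its CI of 0, and glm matches a grid oracle
  set.seed(8)
  sc <- rnorm(800); y <- sample(0:1, 800, replace = TRUE)
  m <- calibrate(sc, y)
  expect_lt(abs(m$gamma1) / m$se[2], 3)

  # self-consistency: scoring with the true generating weights gives
  # gamma1 near 1
  fx <- equivalence_fixture(n = 2000, seed = 31, n_null = 0)
  tr <- fx$discovery$truth
  w_true <- data.frame(
    snp_id = tr$snp_id, w = 0,
    v = log(ifelse(tr$mode == "recessive", 1, tr$or)),
    z = log(ifelse(tr$mode == "additive", tr$or^2, tr$or)),
    risk_allele = NA)
  sch_true <- structure(w_true, class = c("weight_scheme", "data.frame"),
                        case = "case3")
  m2 <- calibrate(compute_grs(fx$discovery$genotypes, sch_true),
                  fx$discovery$phenotype)
  expect_lt(abs(m2$gamma1 - 1) / m2$se[2], 3.5)
})

test_that("threshold shifts reproduce the stated algebra", {
  expect_equal(shift_threshold_intercept(0, 1, 1), 0)
  expect_equal(shift_threshold_intercept(0.5, 0, 2), 2.5)
  expect_equal(shift_threshold_slope(1, 0, 2, 1, 4), 3)
  g0 <- 0.3
  expect_equal(shift_threshold_slope(g0, g0, 1.7, -2.2, 0.9), -2.2)
  expect_error(shift_threshold_slope(1, 0, 0, 1, 1), "degenerate")
  expect_warning(shift_threshold_slope(1, 0, 2, 1, -4), "orientation")
})

test_that("intercept and slope shifts give label-identical rules on random
           draws (Properties 1-2 by enumeration)", {
  set.seed(15)
  for (rep in 1:20) {
    grs <- rnorm(1000)
    tau <- rnorm(1)
    a0 <- rnorm(1); b0 <- rnorm(1)
    lab1 <- (a0 + grs) > tau
    lab2 <- (b0 + grs) > shift_threshold_intercept(tau, a0, b0)
    expect_identical(lab1, lab2)

    g0 <- rnorm(1); g1 <- abs(rnorm(1)) + 0.1
    b0 <- rnorm(1); b1 <- abs(rnorm(1)) + 0.1
    lab1 <- (g0 + g1 * grs) > tau
    lab2 <- (b0 + b1 * grs) > shift_threshold_slope(tau, g0, g1, b0, b1)
    expect_identical(lab1, lab2)
  }
})

test_that("case 2 equals case 3 when the genotypic fit is exactly
           additive", {
  # force z = 2v in a count table, so the two schemes coincide
  cnt <- genotype_counts("s1", rbind(c(100, 100, 25)),
                         rbind(c(100, 50, 100 / 16)))
  effg <- fit_genotypic(cnt, smoothing = 0)
  expect_equal(effg$z, 2 * effg$v, tolerance = 1e-12)
  sch3 <- build_weights("case3", effg)
  sch2 <- structure(data.frame(snp_id = "s1", w = 0, v = effg$v,
                               z = 2 * effg$v, risk_allele = NA),
                    class = c("weight_scheme", "data.frame"), case = "case2")
  G <- genotype_matrix(matrix(0:2, 3), paste0("s", 1:3), "s1",
                       cbind("A", "G"))
  expect_equal(compute_grs(G, sch2), compute_grs(G, sch3))
})
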