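test_that("genotype frequency triples follow the stated formulas", {
  expect_equal(control_genotype_freqs(0.5), c(0.25, 0.5, 0.25))
  expect_equal(control_genotype_freqs(0.1), c(0.01, 0.18, 0.81))
  expect_error(control_genotype_freqs(0), "\\(0, 1\\)")
  expect_error(control_genotype_freqs(1.2), "\\(0, 1\\)")

  set.seed(1)
  p <- runif(1000, 0.01, 0.99)
  expect_equal(rowSums(cbind(p^2, 2 * p * (1 - p), (1 - p)^2)),
               rep(1, 1000))

  # OR = 1 collapses every mode to the control triple
  for (m in c("additive", "recessive", "dominant"))
    expect_equal(case_genotype_freqs(0.3, 1, m),
                 control_genotype_freqs(0.3))

  expect_equal(case_genotype_freqs(0.5, 1.2, "additive"),
               c(0.25, 0.6, 0.36) / 1.21)
  expect_equal(case_genotype_freqs(0.5, 2, "recessive"),
               c(0.2, 0.4, 0.4))
  expect_error(case_genotype_freqs(0.5, -1, "additive"), "odds_ratio")
})

test_that("mode-specific odds tilts: dominant AB = BB, additive BB = AB^2", {
  set.seed(2)
  for (i in 1:25) {
    p <- runif(1, 0.05, 0.5); or <- runif(1, 1.1, 2.5)
    ctrl <- control_genotype_freqs(p)
    tilt <- function(mode) {
      cs <- case_genotype_freqs(p, or, mode)
      # odds tilt of each genotype relative to AA (normalizers cancel)
      (cs / ctrl) / (cs[1] / ctrl[1])
    }
    expect_equal(tilt("dominant")[2], tilt("dominant")[3])
    expect_equal(tilt("additive")[3], tilt("additive")[2]^2)
    expect_equal(tilt("recessive")[2], 1)
    expect_equal(tilt("recessive")[3], or)
  }
})

test_that("risk_on_minor transposes the tilt onto the minor homozygote", {
  p <- 0.2; or <- 1.5
  f <- case_genotype_freqs(p, or, "additive", risk_on_minor = TRUE)
  ctrl <- control_genotype_freqs(p)
  tilt <- (f / ctrl) / (f[3] / ctrl[3])
  expect_equal(tilt[1], or^2)
  expect_equal(tilt[2], or)
})

test_that("simulation is deterministic and splits share null MAFs", {
  d <- simulation_design(n_cases = 50, n_controls = 50, or_grid = 1.5,
                         maf_grid = 0.3, modes = "additive", n_null = 20,
                         n_replicates = 2, seed = 99)
  a <- simulate_dataset(d, "discovery", 1)
  b <- simulate_dataset(d, "discovery", 1)
  expect_identical(a$genotypes$genotypes, b$genotypes$genotypes)

  r <- simulate_dataset(d, "replication", 1)
  expect_false(identical(a$genotypes$genotypes, r$genotypes$genotypes))
  expect_equal(a$truth, r$truth)   # same replicate: identical null MAFs

  t2 <- truth_table(d, 2)
  expect_false(isTRUE(all.equal(a$truth$maf, t2$maf)))

  # a SNP subset materializes the very same columns as the full panel
  sub <- simulate_dataset(d, "discovery", 1,
                          snp_subset = c("null_000007", "causal_001"))
  expect_identical(sub$genotypes$genotypes[, "null_000007"],
                   a$genotypes$genotypes[, "null_000007"])
  expect_identical(sub$genotypes$genotypes[, "causal_001"],
                   a$genotypes$genotypes[, "causal_001"])

  expect_error(simulate_dataset(d, "discovery", 1, max_cells = 100),
               "simulate_counts")
})

test_that("null design: case and control frequencies agree within
           binomial error", {
  d <- simulation_design(n_cases = 3000, n_controls = 3000, or_grid = 1,
                         maf_grid = 0.3, modes = "additive", n_null = 0,
                         n_replicates = 1, seed = 5)
  cnt <- simulate_counts(d, "discovery", 1)
  fT <- unlist(cnt[1, c("T_AA", "T_AB", "T_BB")]) / 3000
  fN <- unlist(cnt[1, c("N_AA", "N_AB", "N_BB")]) / 3000
  se <- sqrt(2 * fN * (1 - fN) / 3000)
  expect_true(all(abs(fT - fN) < 4 * se))
})

test_that("genotypic fit on simulated data recovers the causal tilt", {
  d <- simulation_design(n_cases = 3000, n_controls = 3000, or_grid = 1.6,
                         maf_grid = 0.5, modes = "additive", n_null = 0,
                         n_replicates = 1, seed = 19)
  dat <- simulate_dataset(d, "discovery", 1)
  eff <- fit_genotypic(count_genotypes(dat$genotypes, dat$phenotype))
  expect_lt(abs(eff$z - 2 * log(1.6)), 0.15)
  expect_lt(abs(eff$v - log(1.6)), 0.15)
})

test_that("simulate_counts: totals, binomial moments, and null chi-square
           calibration", {
  d <- simulation_design(n_cases = 200, n_controls = 300, or_grid = 1.4,
                         maf_grid = 0.2, modes = "dominant", n_null = 10,
                         n_replicates = 200, seed = 3)
  ab <- numeric(200)
  for (r in 1:200) {
    cnt <- simulate_counts(d, "discovery", r)
    expect_equal(cnt$T_AA + cnt$T_AB + cnt$T_BB, rep(200L, 11))
    expect_equal(cnt$N_AA + cnt$N_AB + cnt$N_BB, rep(300L, 11))
    ab[r] <- cnt$N_AB[1]   # causal SNP, control group: pure HWE
  }
  p_ab <- 2 * 0.2 * 0.8
  se <- sqrt(300 * p_ab * (1 - p_ab) / 200)
  expect_lt(abs(mean(ab) - 300 * p_ab), 3 * se)

  # chi-square evidence of null SNPs follows the 2-df reference
  dn <- simulation_design(n_cases = 1000, n_controls = 1000,
                          or_grid = 1, maf_grid = 0.3, modes = "additive",
                          n_null = 5000, n_replicates = 1, seed = 77)
  cnt <- simulate_counts(dn, "discovery", 1)
  rk <- rank_snps(subset_counts(cnt, grep("^null", cnt$snp_id)),
                  method = "genotypic_chi2")
  ks <- suppressWarnings(ks.test(rk$evidence, pchisq, df = 2))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("count-mode and subject-mode generators agree in distribution", {
  d <- simulation_design(n_cases = 60, n_controls = 60, or_grid = 1.8,
                         maf_grid = 0.3, modes = "recessive", n_null = 0,
                         n_replicates = 120, seed = 55)
  cT_counts <- cT_subj <- matrix(0, 120, 3)
  for (r in 1:120) {
    cnt <- simulate_counts(d, "discovery", r)
    cT_counts[r, ] <- unlist(cnt[1, c("T_AA", "T_AB", "T_BB")])
    dat <- simulate_dataset(d, "discovery", r)
    tab <- count_genotypes(dat$genotypes, dat$phenotype)
    cT_subj[r, ] <- unlist(tab[1, c("T_AA", "T_AB", "T_BB")])
  }
  for (g in 1:3) {
    tt <- t.test(cT_counts[, g], cT_subj[, g])
    expect_gt(tt$p.value, 1e-4)   # no systematic per-cell deviation
  }
})

test_that("design validation and JSON config round-trip", {
  expect_error(simulation_design(maf_grid = 0.6), "maf_grid")
  expect_error(simulation_design(or_grid = -1), "or_grid")
  skip_if_not_installed("jsonlite")
  cfg <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n_cases = 100, n_controls = 120,
                            or_grid = c(1.2, 1.4), maf_grid = 0.25,
                            modes = "dominant", n_null = 10,
                            n_replicates = 2, seed = 42),
                       cfg, auto_unbox = TRUE)
  d <- read_design_json(cfg)
  expect_s3_class(d, "simulation_design")
  expect_equal(d$n_controls, 120L)
  expect_equal(d$or_grid, c(1.2, 1.4))
  jsonlite::write_json(list(n_cases = 10, bogus = 1), cfg,
                       auto_unbox = TRUE)
  expect_error(read_design_json(cfg), "unknown design field")
})
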