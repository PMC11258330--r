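test_that("scenario validation rejects impossible worlds", {
  expect_error(sim_scenario(rho = 1), "rho")
  expect_error(sim_scenario(h2_meth = 1), "h2_meth")
  expect_error(sim_scenario(maf_range = c(0, 0.6)), "maf_range")
  expect_error(sim_scenario(n_blocks = 0), "positive")
  expect_error(sim_scenario(n_gwas = 0), "n_gwas")
  expect_equal(sim_scenario("null", alpha_med = 0.5)$alpha_med, 0)
})

test_that("genotype simulation reproduces the target LD structure", {
  # independence case: rho = 0 at MAF 0.5
  sc0 <- sim_scenario(n_ref = 10000, n_blocks = 1, block_size = 6,
                      rho = 0, maf_range = c(0.5, 0.5), seed = 11)
  g0 <- simulate_genotypes(sc0)
  R <- cor(g0$dosage)
  expect_lt(max(abs(R[upper.tri(R)])), 0.05)
  expect_true(all(g0$dosage %in% 0:2))
  expect_true(all(diff(g0$variants$pos) > 0))
  expect_true(all(g0$variants$maf >= 0, g0$variants$maf <= 0.5))

  # adjacent-variant dosage correlation vs a brute-force Monte-Carlo
  # of the same latent model (independent oracle implementation)
  sc9 <- sim_scenario(n_ref = 10000, n_blocks = 1, block_size = 2,
                      rho = 0.9, maf_range = c(0.3, 0.3), seed = 12)
  g9 <- simulate_genotypes(sc9)
  r_obs <- cor(g9$dosage[, 1], g9$dosage[, 2])
  set.seed(99)
  z1 <- rnorm(200000)
  z2 <- 0.9 * z1 + sqrt(1 - 0.81) * rnorm(200000)
  thr <- function(z, maf) {
    q <- 1 - maf
    (z >= qnorm(q^2)) + (z >= qnorm(q^2 + 2 * maf * q))
  }
  r_oracle <- cor(thr(z1, 0.3), thr(z2, 0.3))
  expect_lt(abs(r_obs - r_oracle), 0.1)

  # determinism: same seed twice, byte-identical
  expect_identical(simulate_genotypes(sc9)$dosage, g9$dosage)
})

test_that("methylation simulation hits the target cis-heritability", {
  # h2 = 0: no genetic signal
  sc <- sim_scenario(n_ref = 500, n_blocks = 2, block_size = 20,
                     h2_meth = 0, cpgs_per_block = 1, seed = 13)
  g <- simulate_genotypes(sc)
  m <- simulate_methylation(g, sc, n_tissues = 1)
  cv <- m$truth$causal_variants
  v1 <- cv$variant_id[cv$cpg_id == "cg0000001"]
  fit <- summary(lm(qlogis(m$tissues[[1]]$beta[1, ]) ~
                      g$dosage[, v1, drop = FALSE]))
  expect_lt(fit$r.squared, 0.02)
  expect_true(all(m$tissues[[1]]$beta > 0 & m$tissues[[1]]$beta < 1))

  # h2 = 0.5, single causal, large n: R^2 of the causal regression
  # matches the analytic variance decomposition within 0.05
  sc5 <- sim_scenario(n_ref = 10000, n_blocks = 1, block_size = 10,
                      h2_meth = 0.5, k_causal = 1, cpgs_per_block = 1,
                      seed = 14)
  g5 <- simulate_genotypes(sc5)
  m5 <- simulate_methylation(g5, sc5, n_tissues = 1)
  v <- m5$truth$causal_variants$variant_id[1]
  r2 <- summary(lm(m5$tissues[[1]]$latent[1, ] ~ g5$dosage[, v]))$r.squared
  expect_lt(abs(r2 - 0.5), 0.05)

  # share_frac = 1: causal effect vectors identical across tissues
  scs <- sim_scenario(n_ref = 200, n_blocks = 2, block_size = 10,
                      share_frac = 1, cpgs_per_block = 1, seed = 15)
  gs <- simulate_genotypes(scs)
  ms <- simulate_methylation(gs, scs, n_tissues = 2)
  cvs <- ms$truth$causal_variants
  t1 <- cvs[cvs$tissue == "tissue1", ]
  t2 <- cvs[cvs$tissue == "tissue2", ]
  expect_equal(t1$effect, t2$effect, tolerance = 1e-12)
})

test_that("GWAS summary statistics behave under null and signal", {
  # null scenario: uniform p over >= 2000 variants
  sc <- sim_scenario("null", n_ref = 300, n_blocks = 100,
                     block_size = 20, cpgs_per_block = 1, seed = 16)
  b <- simulate_bundle(sc, n_tissues = 1)
  expect_gte(nrow(b$gwas), 2000)
  frac <- mean(b$gwas$p < 0.05)
  expect_gte(frac, 0.03); expect_lte(frac, 0.07)

  # replicate draws are unbiased around the generative marginal effect
  sc1 <- sim_scenario("shared_causal", n_ref = 2000, n_blocks = 1,
                      block_size = 10, k_causal = 1, cpgs_per_block = 1,
                      alpha_med = 0.2, flip_frac = 0, seed = 17)
  g1 <- simulate_genotypes(sc1)
  m1 <- simulate_methylation(g1, sc1, n_tissues = 1)
  # generative-mean oracle: LD-propagated causal effect
  delta <- methwas:::.causal_log_odds(g1, m1$truth)
  S <- cov(g1$dosage)
  beta_true <- as.vector(S %*% delta) / diag(S)
  draws <- sapply(1:200, function(i) {
    sci <- sc1; sci$seed <- 100000L + i
    simulate_gwas(g1, m1$truth, sci)$beta
  })
  se <- simulate_gwas(g1, m1$truth, sc1)$se
  ci <- which.max(abs(delta))
  expect_lt(abs(mean(draws[ci, ]) - beta_true[ci]), 3 * se[ci] / sqrt(200))

  # allele-label flip symmetry: beta negated, freq reflected
  scf <- sc1; scf$flip_frac <- 1
  gw0 <- simulate_gwas(g1, m1$truth, sc1)
  gw1 <- simulate_gwas(g1, m1$truth, scf)
  expect_equal(gw1$beta, -gw0$beta)
  expect_equal(gw1$freq, 1 - gw0$freq)
  expect_equal(gw1$effect_allele, gw0$other_allele)
})

test_that("ld_distinct plants a distinct GWAS driver in LD", {
  sc <- sim_scenario("ld_distinct", n_ref = 500, n_blocks = 3,
                     block_size = 40, k_causal = 1, cpgs_per_block = 1,
                     rho = 0.9, maf_range = c(0.15, 0.5), seed = 18)
  g <- simulate_genotypes(sc)
  m <- simulate_methylation(g, sc, n_tissues = 1)
  gd <- m$truth$gwas_direct
  expect_false(any(gd$variant_id == gd$partner_of))
  for (i in seq_len(nrow(gd))) {
    r <- cor(g$dosage[, gd$variant_id[i]], g$dosage[, gd$partner_of[i]])
    expect_gte(abs(r), 0.7)
  }
  expect_true(all(m$truth$true_mediation$alpha == 0))
})

test_that("expression simulation realizes the generative correlation", {
  sc <- sim_scenario("mediated_trio", n_ref = 200, n_blocks = 3,
                     block_size = 15, cpgs_per_block = 1,
                     gamma_eqtm = 0.6, seed = 19)
  g <- simulate_genotypes(sc)
  m <- simulate_methylation(g, sc, n_tissues = 1)
  ex <- simulate_expression(m)
  ga <- ex$gene_annot
  linked <- ga[!is.na(ga$linked_cpg), ]
  for (i in seq_len(nrow(linked))) {
    r <- cor(ex$expr[linked$gene_id[i], ],
             m$tissues[[1]]$latent[linked$linked_cpg[i], ])
    expect_lt(abs(r - 0.6), 0.15)
  }
  # unlinked genes: correlations near zero on average
  decoy <- ga$gene_id[is.na(ga$linked_cpg)]
  rd <- sapply(decoy, function(gn)
    cor(ex$expr[gn, ], m$tissues[[1]]$latent[1, ]))
  expect_lt(mean(abs(rd)), 0.2)
  # determinism
  ex2 <- simulate_expression(m)
  expect_identical(ex2$expr, ex$expr)
  expect_identical(ex2$counts, ex$counts)
})
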