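test_that("harmonization keeps, flips, or drops by allele configuration", {
  m <- make_model(c("rs1", "rs2", "rs3", "rs4"), c(0.5, 0.3, 0.2, 0.1),
                  effect_allele = c("A", "A", "A", "A"),
                  other_allele = c("G", "G", "G", "T"))
  gwas <- make_gwas(c("rs1", "rs2", "rs3", "rs4"),
                    beta = c(0.2, 0.2, 0.2, 0.2), se = 0.05,
                    effect_allele = c("A", "G", "A", "A"),
                    other_allele = c("G", "A", "C", "T"))
  h <- harmonize(m, gwas)
  expect_identical(h$pairs$variant_id, c("rs1", "rs2"))
  expect_equal(h$pairs$beta, c(0.2, -0.2))           # swap rule negates
  expect_equal(h$pairs$freq[2], 1 - 0.3)
  expect_setequal(h$dropped$reason, c("allele mismatch", "palindromic"))
})

test_that("the weighted Z statistic reduces to hand-computable cases", {
  # identity reduction: one variant, W = 1, sigma_S = sigma_m
  m1 <- make_model("rs1", 1)
  g1 <- make_gwas("rs1", beta = 3.1 * 0.05, se = 0.05)
  ref1 <- list(sigma_s = c(rs1 = 0.6), sigma_m = 0.6, n_ref = 100)
  rec1 <- mwas_z(m1, g1, ref1)
  expect_equal(rec1$zscore, 3.1, tolerance = 1e-12)

  # two independent variants: Z = 2 * (0.5 / sqrt(0.5)) * 2 = 2.828
  m2 <- make_model(c("rs1", "rs2"), c(1, 1))
  g2 <- make_gwas(c("rs1", "rs2"), beta = c(0.1, 0.1), se = 0.05)
  ref2 <- list(sigma_s = c(rs1 = 0.5, rs2 = 0.5), sigma_m = sqrt(0.5),
               n_ref = 100)
  expect_equal(mwas_z(m2, g2, ref2)$zscore, 2 * (0.5 / sqrt(0.5)) * 2,
               tolerance = 1e-12)

  # all variants dropped: untestable record, no error
  g_bad <- make_gwas("rs1", beta = 0.1, se = 0.05, effect_allele = "C",
                     other_allele = "T")
  expect_identical(mwas_z(m1, g_bad, ref1)$status, "untestable")
})

test_that("Eq. 1 is invariant to splitting weight across perfect duplicates", {
  set.seed(31)
  x <- rbinom(300, 2, 0.3)
  geno <- make_panel(cbind(va = x, vb = x))
  gwas <- make_gwas(c("va", "vb"), beta = c(0.12, 0.12), se = 0.03)
  m_one <- make_model("va", 0.8)
  m_split <- make_model(c("va", "vb"), c(0.4, 0.4))
  z1 <- mwas_z(m_one, gwas, reference_moments(m_one, geno))$zscore
  z2 <- mwas_z(m_split, gwas, reference_moments(m_split, geno))$zscore
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("Z-to-P uses an accurate log-scale normal tail", {
  expect_equal(z_to_p(0), 1)
  expect_equal(z_to_p(-5.75), 2 * pnorm(-5.75))
  # finite far beyond naive underflow
  expect_gt(z_to_p(38), 0)
  expect_equal(z_to_p(c(1.96, -1.96)), rep(2 * pnorm(-1.96), 2))
})

test_that("odds-ratio back-transform is consistent and symmetric", {
  pairs <- data.frame(variant_id = "rs1", weight = 0.8, beta = 0.12,
                      se = 0.03, freq = 0.3)
  sig_s <- c(rs1 = 0.6); sig_m <- 0.48
  z <- 0.8 * (0.6 / 0.48) * (0.12 / 0.03)
  eo <- effect_or(pairs, sig_s, sig_m, z)
  expect_gt(eo[1], 1)
  expect_true(eo[2] < eo[1] && eo[1] < eo[3])
  # sign flip: OR -> 1/OR with swapped reciprocal CI
  pairs_neg <- pairs; pairs_neg$beta <- -0.12
  eo_neg <- effect_or(pairs_neg, sig_s, sig_m, -z)
  expect_equal(eo_neg[1], 1 / eo[1], tolerance = 1e-12)
  expect_equal(eo_neg[2], 1 / eo[3], tolerance = 1e-12)
  expect_equal(eo_neg[3], 1 / eo[2], tolerance = 1e-12)
  # Z = 0: CI flagged undefined
  expect_true(all(is.na(effect_or(pairs, sig_s, sig_m, 0)[2:3])))
})

test_that("single-variant OR per SD matches an individual-level fit", {
  sc <- sim_scenario("shared_causal", n_ref = 400, n_gwas = 20000,
                     n_blocks = 1, block_size = 10, k_causal = 1,
                     cpgs_per_block = 1, flip_frac = 0,
                     palindromic_frac = 0, alpha_med = 0.2, seed = 32)
  b <- simulate_bundle(sc, n_tissues = 1)
  gw <- simulate_gwas(b$geno, b$truth, sc, method = "cohort",
                      keep_cohort = TRUE)
  coh <- attr(gw, "cohort")
  cv <- b$truth$causal_variants
  vrow <- b$geno$variants[match(cv$variant_id[1],
                                b$geno$variants$variant_id), ]
  m <- make_model(vrow$variant_id, 1, effect_allele = vrow$effect_allele,
                  other_allele = vrow$other_allele)
  ref <- reference_moments(m, b$geno)
  rec <- mwas_z(m, gw, ref)
  pred <- coh$G[, cv$variant_id[1]]
  slope <- coef(lm(coh$y ~ pred))[2]
  or_ind <- exp(slope * ref$sigma_m)
  expect_lt(abs(rec$or_per_sd - or_ind) / or_ind, 0.05)
})

test_that("Bonferroni gate reproduces the per-cancer thresholds", {
  rec <- data.frame(pvalue = c(4e-7, 6e-7, NA))
  out <- bonferroni_gate(rec, 101497)
  expect_equal(signif(attr(out, "threshold"), 3), 4.93e-7)
  expect_identical(out$significant, c(TRUE, FALSE, FALSE))
  expect_equal(signif(attr(bonferroni_gate(rec, 152341), "threshold"), 3),
               3.28e-7)
  expect_equal(attr(bonferroni_gate(rec, 1), "threshold"), 0.05)
  # strict inequality at the boundary
  at_thr <- data.frame(pvalue = 0.05 / 10)
  expect_false(bonferroni_gate(at_thr, 10)$significant)
  expect_error(bonferroni_gate(rec, 0), "n_models")
})

test_that("association Z is calibrated under the null scenario", {
  sc <- sim_scenario("null", n_ref = 250, n_blocks = 50, block_size = 10,
                     cpgs_per_block = 10, n_gwas = 5e4, seed = 55)
  b <- simulate_bundle(sc, n_tissues = 1)
  g <- b$geno
  ca <- b$meth$cpg_annot
  zs <- vapply(seq_len(nrow(ca)), function(k) {
    idx <- cis_variants(g, ca$chrom[k], ca$pos[k])
    y <- resid_meth(b$meth, k)
    m <- train_elastic_net(y, g$dosage[, idx], g$variants[idx, ],
                           seed = 55, cpg_id = ca$cpg_id[k])
    if (!nrow(m$weights)) return(NA_real_)
    mwas_z(m, b$gwas, reference_moments(m, g))$zscore
  }, numeric(1))
  zs <- zs[!is.na(zs)]
  expect_gte(length(zs), 450)
  expect_lt(abs(mean(zs)), 0.15)
  expect_gte(var(zs), 0.8)
  expect_lte(var(zs), 1.2)
})
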