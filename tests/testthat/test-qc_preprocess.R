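test_that("HWE chi-square test matches hand-computed cases", {
  # exact HWE proportions: statistic 0
  expect_equal(hwe_test(25, 50, 25), 1)
  # no heterozygotes at p = q = 0.5: chi-square = 100 (hand: 25+50+25)
  expect_equal(hwe_test(50, 0, 50),
               pchisq(100, df = 1, lower.tail = FALSE))
  expect_lt(hwe_test(50, 0, 50), 1e-22)
  # monomorphic after frequency estimation
  expect_equal(hwe_test(0, 0, 100), 1)
  expect_error(hwe_test(0, 0, 0), "no genotyped")
})

test_that("variant filter applies the four QC rules strictly", {
  set.seed(1)
  n <- 200
  clean <- rbinom(n, 2, 0.3)
  missing6 <- rbinom(n, 2, 0.3); missing6[1:12] <- NA        # 6% missing
  rare <- rbinom(n, 2, 0.02)                                 # MAF ~2%
  hwe_bad <- rep(c(0, 2), n / 2)                             # no hets
  pal <- rbinom(n, 2, 0.3)                                   # A/T pair
  geno <- make_panel(cbind(v_clean = clean, v_miss = missing6,
                           v_rare = rare, v_hwe = hwe_bad, v_pal = pal),
                     effect_allele = c("A", "A", "A", "A", "A"),
                     other_allele = c("G", "G", "G", "G", "T"))
  out <- filter_variants(geno)
  expect_identical(out$variants$variant_id, "v_clean")
  log <- attr(out, "qc_log")
  expect_equal(log$removed[log$rule == "palindromic"], 1)
  expect_equal(log$removed[log$rule == "hwe"], 1)

  # disabled thresholds: identity
  all_kept <- filter_variants(geno, miss_max = 1.01, maf_min = -1,
                              hwe_min = 0, drop_palindromic = FALSE,
                              impute_missing = FALSE)
  expect_identical(all_kept$variants$variant_id, geno$variants$variant_id)

  # empty panel passes through
  empty <- geno
  empty$dosage <- empty$dosage[, 0, drop = FALSE]
  empty$variants <- empty$variants[0, ]
  expect_silent(filter_variants(empty))

  # idempotence
  twice <- filter_variants(out)
  expect_equal(twice$dosage, out$dosage)
})

test_that("inverse-normal transform follows the Blom formula", {
  # n = 3 distinct values: ranks map through (r - 3/8)/(n - 3/4 + 1)
  got <- inverse_normal(c(10, 30, 20))
  expected <- qnorm((c(1, 3, 2) - 3 / 8) / (3 - 2 * 3 / 8 + 1))
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(got[1], -got[2])   # symmetric
  expect_equal(got[3], 0)

  # rank invariance under monotone transforms
  x <- rexp(50)
  expect_equal(inverse_normal(x), inverse_normal(log(x)))

  # ties share the averaged-rank value
  tied <- inverse_normal(c(1, 2, 2, 5))
  expect_equal(tied[2], tied[3])

  # missing stays missing
  xm <- c(3, NA, 1, 2)
  expect_true(is.na(inverse_normal(xm)[2]))

  # all identical: zeros with warning
  expect_warning(z <- inverse_normal(rep(1, 5)), "identical")
  expect_equal(z, rep(0, 5))

  # near-normal output at n >= 100
  y <- inverse_normal(rexp(200))
  skew <- mean(y^3) / sd(y)^3
  expect_lt(abs(skew), 0.2)
  expect_lt(abs(mean(y)), 0.05)
})

test_that("residualization matches the normal-equation oracle", {
  set.seed(2)
  n <- 50
  covar <- matrix(rnorm(n * 3), n, 3)
  y <- matrix(rnorm(4 * n), 4, n)
  res <- residualize(y, covar)
  # brute-force least squares per feature
  X <- cbind(1, covar)
  oracle <- t(sapply(1:4, function(i) {
    b <- solve(t(X) %*% X, t(X) %*% y[i, ])
    y[i, ] - as.vector(X %*% b)
  }))
  expect_equal(res, oracle, ignore_attr = TRUE, tolerance = 1e-8)
  # orthogonal to every covariate column
  expect_lt(max(abs(res %*% covar)), 1e-8 * n)
  # intercept only: demeaning
  expect_equal(residualize(y), y - rowMeans(y), ignore_attr = TRUE)
  # y exactly linear in covariates: zero residuals
  ylin <- matrix(2 + covar %*% c(1, -1, 0.5), 1, n)
  expect_lt(max(abs(residualize(ylin, covar))), 1e-10)
  # idempotence
  expect_equal(residualize(res, covar), res, tolerance = 1e-10)
  # rank deficiency is an error
  expect_error(residualize(y, cbind(covar, covar[, 1])), "rank")
})

test_that("hidden factors recover planted structure", {
  set.seed(3)
  n <- 60
  f1 <- rnorm(n)
  # rank-1 matrix: single factor recovered
  m1 <- outer(rnorm(30), f1)
  hf <- hidden_factors(m1, 1)
  expect_gt(abs(cor(hf[, 1], f1)), 0.999)

  # two-factor data: recovered subspace canonically aligned with truth
  f2 <- rnorm(n)
  m2 <- outer(rnorm(40, sd = 2), f1) + outer(rnorm(40, sd = 1.5), f2) +
    matrix(rnorm(40 * n, sd = 0.1), 40, n)
  hf2 <- hidden_factors(m2, 2)
  cc <- cancor(hf2, cbind(f1, f2))$cor
  expect_true(all(cc > 0.95))

  # permuting samples permutes factor rows identically
  perm <- sample(n)
  hf_p <- hidden_factors(m2[, perm], 2)
  expect_equal(unname(hf_p), unname(hf2[perm, ]), tolerance = 1e-8)

  expect_error(hidden_factors(m2, 60), "k must be")
})

test_that("quantile normalization forces a common sample distribution", {
  # hand-computed 2x2 case: reference is (1.5, 4.5)
  m <- cbind(s1 = c(1, 3), s2 = c(2, 6))
  qn <- quantile_normalize_samples(m)
  expect_equal(unname(qn), cbind(c(1.5, 4.5), c(1.5, 4.5)))

  set.seed(4)
  big <- matrix(rexp(200 * 5), 200, 5)
  qb <- quantile_normalize_samples(big)
  # all columns share the same sorted values exactly
  sorted <- apply(qb, 2, sort)
  expect_equal(sorted, sorted[, c(1, 1, 1, 1, 1)], ignore_attr = TRUE)
  # identically distributed columns are unchanged up to reordering
  perm_cols <- cbind(big[, 1], sample(big[, 1]))
  qp <- quantile_normalize_samples(perm_cols)
  expect_equal(sort(qp[, 1]), sort(big[, 1]))
})
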