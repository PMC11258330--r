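test_that("cis window membership is inclusive and chromosome-aware", {
  dos <- matrix(rbinom(20 * 10, 2, 0.3), 20, 10)
  pos <- c(99999, 100000, 250000, 400000, 600000, 800000, 1000000,
           1100000, 1100001, 2000000)
  geno <- make_panel(dos, pos = pos)
  # CpG at 600000: [100000, 1100000] inclusive
  idx <- cis_variants(geno, "1", 600000)
  expect_identical(idx, 2:8)
  expect_warning(none <- cis_variants(geno, "2", 600000), "chromosome")
  expect_length(none, 0)
  # enumeration on a constructed fixture: 7 of 10 in window
  expect_length(cis_variants(geno, "1", 600000), 7)
  expect_equal(cis_window(100), c(1, 500100))   # clipped at position 1
})

test_that("elastic net recovers a noiseless signal and prunes at the path end", {
  set.seed(21)
  n <- 100
  X <- matrix(rbinom(n * 8, 2, 0.3), n, 8)
  y <- 2 * X[, 1]
  m <- train_elastic_net(y, X, seed = 1)
  expect_true("v1" %in% m$weights$variant_id ||
                any(grepl("1$", m$weights$variant_id)))
  # fold-centered out-of-fold predictions concede the between-fold mean
  # variance, so even a noiseless fit tops out slightly below 1
  expect_gt(m$cv_R, 0.95)
  expect_true(m$reliable)
  # penalty limit: the first (largest) path lambda zeroes every coefficient
  lam <- methwas:::.lambda_path(X, y + rnorm(n), 0.5)
  fit <- glmnet::glmnet(X, y + rnorm(n), alpha = 0.5, lambda = lam,
                        standardize = FALSE)
  expect_equal(sum(coef(fit)[-1, 1] != 0), 0)
})

test_that("stored elastic-net solution satisfies the KKT conditions", {
  set.seed(22)
  n <- 150; p <- 20
  X <- matrix(rbinom(n * p, 2, 0.35), n, p)
  y <- 0.4 * X[, 3] - 0.3 * X[, 10] + rnorm(n)
  m <- train_elastic_net(y, X, seed = 2)
  b <- numeric(p)
  names(b) <- colnames(X) <- paste0("v", seq_len(p))
  b[m$weights$variant_id] <- m$weights$weight
  lam <- m$lambda
  b0 <- mean(y) - sum(colMeans(X) * b)
  r <- y - b0 - as.vector(X %*% b)
  g <- -as.vector(crossprod(X, r)) / n + lam * 0.5 * b
  nz <- b != 0
  expect_lt(max(abs(g[nz] + lam * 0.5 * sign(b[nz]))), 1e-4)
  if (any(!nz)) expect_lt(max(abs(g[!nz])) - lam * 0.5, 1e-4)
})

test_that("out-of-fold predictions never see their own fold's outcomes", {
  set.seed(23)
  n <- 100
  X <- matrix(rbinom(n * 15, 2, 0.3), n, 15)
  y <- 0.5 * X[, 2] + rnorm(n)
  fold <- methwas:::make_folds(n, 5, 42)
  m1 <- train_elastic_net(y, X, seed = 42)
  y2 <- y; y2[fold == 1] <- sample(y[fold == 1])
  m2 <- train_elastic_net(y2, X, seed = 42)
  expect_identical(m1$cv_pred[fold == 1], m2$cv_pred[fold == 1])
  # same for the best-mQTL baseline
  b1 <- train_best_mqtl(y, X, seed = 42)
  b2 <- train_best_mqtl(y2, X, seed = 42)
  expect_identical(b1$cv_pred[fold == 1], b2$cv_pred[fold == 1])
})

test_that("best-mQTL baseline finds the causal variant and is honest on noise", {
  sc <- sim_scenario(n_ref = 10000, n_blocks = 1, block_size = 10,
                     h2_meth = 0.5, k_causal = 1, cpgs_per_block = 1,
                     rho = 0.3, seed = 24)
  g <- simulate_genotypes(sc)
  m <- simulate_methylation(g, sc, n_tissues = 1)
  y <- m$tissues[[1]]$latent[1, ]
  fit <- train_best_mqtl(y, g$dosage, g$variants, seed = 3)
  expect_identical(fit$weights$variant_id,
                   m$truth$causal_variants$variant_id[1])
  # cv_R ~ sqrt(h2) = 0.707 from the generative decomposition
  expect_lt(abs(fit$cv_R - sqrt(0.5)), 0.05)

  # two spread causal variants: the multi-variant model wins
  set.seed(25)
  n <- 2000
  X2 <- matrix(rbinom(n * 10, 2, 0.3), n, 10)
  g_eff <- 0.5 * X2[, 2] + 0.5 * X2[, 7]
  y2 <- g_eff + rnorm(n, sd = sd(g_eff) * sqrt(0.6 / 0.4))
  en <- train_elastic_net(y2, X2, seed = 4)
  bm <- train_best_mqtl(y2, X2, seed = 4)
  expect_gt(en$cv_R, bm$cv_R)

  # pure noise: reliable almost never
  rel <- replicate(100, {
    yn <- rnorm(60)
    train_best_mqtl(yn, X2[1:60, ], seed = sample.int(1e6, 1))$reliable
  })
  expect_gte(mean(!rel), 0.9)
})

test_that("cross-tissue fit is symmetric, prunable, and leakage-free", {
  set.seed(26)
  n <- 80
  X <- matrix(rbinom(n * 12, 2, 0.3), n, 12)
  y <- 0.6 * X[, 5] + rnorm(n)
  ct <- train_cross_tissue(list(t1 = y, t2 = y), list(X, X), seed = 5)
  expect_identical(ct$t1$weights$variant_id, ct$t2$weights$variant_id)
  expect_lt(abs(ct$t1$cv_R - ct$t2$cv_R), 0.02)

  # huge group penalty zeroes every tissue's coefficients
  Xs <- scale(X) * sqrt(n / (n - 1))
  G <- list(crossprod(Xs) / n, crossprod(Xs) / n)
  cvec <- list(as.vector(crossprod(Xs, y - mean(y))) / n,
               as.vector(crossprod(Xs, y - mean(y))) / n)
  B <- methwas:::sgl_solve(G, cvec, 1e6, 0, matrix(0, 12, 2), 100L, 1e-8)
  expect_true(all(B == 0))

  # a tissue with too few samples is dropped with a warning
  expect_warning(
    ct3 <- train_cross_tissue(list(a = y, b = y, c = y[1:5]),
                              list(X, X, X[1:5, , drop = FALSE]),
                              seed = 5),
    "dropping")
  expect_named(ct3, c("a", "b"))
})

test_that("cross-tissue solver satisfies its KKT subgradient conditions", {
  set.seed(27)
  n <- 100; p <- 15; TT <- 3
  Xs <- lapply(1:TT, function(t) scale(matrix(rnorm(n * p), n, p)) *
                 sqrt(n / (n - 1)))
  ys <- lapply(1:TT, function(t) rnorm(n))
  G <- lapply(Xs, function(x) crossprod(x) / n)
  cvec <- lapply(1:TT, function(t)
    as.vector(crossprod(Xs[[t]], ys[[t]])) / n)
  l1 <- 0.05; l2 <- 0.02
  B <- methwas:::sgl_solve(G, cvec, l1, l2, matrix(0, p, TT), 5000L, 1e-11)
  viol <- 0
  for (j in 1:p) {
    gr <- sapply(1:TT, function(t) (G[[t]] %*% B[, t])[j] - cvec[[t]][j])
    bj <- B[j, ]
    if (all(bj == 0)) {
      u <- pmax(abs(gr) - l2, 0)
      viol <- max(viol, sqrt(sum(u^2)) - l1)
    } else {
      nrm <- sqrt(sum(bj^2))
      for (t in 1:TT) {
        if (bj[t] != 0) {
          viol <- max(viol, abs(gr[t] + l1 * bj[t] / nrm + l2 * sign(bj[t])))
        } else {
          viol <- max(viol, abs(gr[t]) - l2)
        }
      }
    }
  }
  expect_lt(viol, 1e-6)
})

test_that("model selection follows the higher-R rule among reliable models", {
  en <- make_model("v1", 0.5); en$cv_R <- 0.15; en$method <- "elastic_net"
  ct <- make_model("v1", 0.5); ct$cv_R <- 0.25; ct$method <- "cross_tissue"
  bm <- make_model("v1", 0.5); bm$cv_R <- 0.90; bm$method <- "best_mqtl"
  expect_identical(select_model(list(en, ct, bm))$method, "cross_tissue")
  ct_bad <- ct; ct_bad$reliable <- FALSE
  expect_identical(select_model(list(en, ct_bad))$method, "elastic_net")
  en_bad <- en; en_bad$reliable <- FALSE
  expect_null(select_model(list(en_bad, ct_bad)))
  expect_null(select_model(list(bm)))   # baseline is never selected
})

test_that("paired method comparison matches the textbook t formula", {
  set.seed(28)
  a <- runif(10, 0.2, 0.6)
  b <- a - 0.05 + rnorm(10, sd = 0.02)
  cmp <- compare_methods(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(10))
  expect_equal(cmp$t, t_hand, tolerance = 1e-6)
  expect_equal(cmp$p, 2 * pt(-abs(t_hand), df = 9), tolerance = 1e-6)
  # consistent shift: decisive
  jit <- c(0.1001, 0.0999, 0.1002, 0.0998)
  expect_lt(compare_methods(c(0.3, 0.4, 0.5, 0.6),
                            c(0.3, 0.4, 0.5, 0.6) - jit)$p, 1e-3)
  # zero-variance differences are flagged, not mis-tested
  deg <- compare_methods(c(0.1, 0.2), c(0.1, 0.2))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
})

test_that("fold assignment is deterministic and shared across methods", {
  f1 <- methwas:::make_folds(100, 5, 7)
  f2 <- methwas:::make_folds(100, 5, 7)
  expect_identical(f1, f2)
  expect_equal(as.vector(table(f1)), rep(20, 5))
  set.seed(29)
  X <- matrix(rbinom(60 * 6, 2, 0.3), 60, 6)
  y <- rnorm(60)
  expect_identical(train_elastic_net(y, X, seed = 7)$fold,
                   train_best_mqtl(y, X, seed = 7)$fold)
})
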