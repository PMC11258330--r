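# Cis-genetic methylation prediction models: single-tissue elastic net,
# cross-tissue sparse-group penalized regression, best-single-mQTL
# baseline; model selection and method comparison.

#' Cis window around a CpG
#'
#' The 500 kb flanking region: `[pos - 500000, pos + 500000]`, 1-based
#' inclusive, clipped at position 1, same chromosome.
#'
#' @param pos CpG position (1-based).
#' @param flank Flank size in bp.
#' @return Numeric `c(start, end)`.
#' @export
cis_window <- function(pos, flank = 500000) {
  c(max(1, pos - flank), pos + flank)
}

#' Indices of variants within a CpG's cis window
#'
#' @param geno A `genotype_matrix`.
#' @param cpg_chrom,cpg_pos CpG chromosome and 1-based position.
#' @param flank Flank size in bp (500 kb).
#' @return Integer vector of column indices into `geno$dosage`.
#' @export
cis_variants <- function(geno, cpg_chrom, cpg_pos, flank = 500000) {
  v <- geno$variants
  chrom <- sub("^chr", "", as.character(cpg_chrom))
  same <- sub("^chr", "", v$chrom) == chrom
  if (!any(same)) {
    warnf("no variants on chromosome %s", chrom)
    return(integer(0))
  }
  w <- cis_window(cpg_pos, flank)
  which(same & v$pos >= w[1] & v$pos <= w[2])
}

# Deterministic fold assignment from a seed; same (n, seed) => same folds,
# so the three training methods are compared on identical splits.
make_folds <- function(n, n_folds, seed) {
  set.seed(child_seed(seed, "folds"))
  fold <- rep_len(seq_len(n_folds), n)
  sample(fold)
}

.new_model <- function(cpg_id, tissue, method, weights, cv_R, cv_P,
                       n_train, extra = list()) {
  reliable <- isTRUE(cv_R > 0.10 && cv_P < 0.05 && nrow(weights) > 0)
  structure(c(list(cpg_id = cpg_id, tissue = tissue, method = method,
                   weights = weights, cv_R = cv_R, cv_P = cv_P,
                   n_train = n_train, reliable = reliable), extra),
            class = "prediction_model")
}

.empty_weights <- function() data.frame(
  variant_id = character(0), effect_allele = character(0),
  other_allele = character(0), weight = numeric(0),
  stringsAsFactors = FALSE)

# correlation of pooled out-of-fold predictions with observed y
.cv_cor <- function(pred, y) {
  if (stats::sd(pred) < 1e-12 || stats::sd(y) < 1e-12)
    return(list(R = 0, P = 1))
  ct <- suppressWarnings(cor.test(pred, y))
  list(R = unname(ct$estimate), P = ct$p.value)
}

# coordinate-descent polish of an elastic-net solution to tight KKT
# tolerance (glmnet's own stopping rule leaves ~1e-4-scale subgradient
# residuals at small lambda)
.enet_polish <- function(X, y, b, lambda, alpha, maxit = 500,
                         tol = 1e-8) {
  n <- length(y)
  b0 <- mean(y - as.vector(X %*% b))
  r <- y - b0 - as.vector(X %*% b)
  xx <- colSums(X^2) / n
  for (it in seq_len(maxit)) {
    delta <- 0
    b0_shift <- mean(r)
    r <- r - b0_shift
    b0 <- b0 + b0_shift
    for (j in seq_along(b)) {
      zj <- sum(X[, j] * r) / n + xx[j] * b[j]
      s <- max(abs(zj) - lambda * alpha, 0) * sign(zj)
      bj_new <- s / (xx[j] + lambda * (1 - alpha))
      d <- bj_new - b[j]
      if (d != 0) {
        r <- r - X[, j] * d
        b[j] <- bj_new
        delta <- max(delta, abs(d))
      }
    }
    if (delta < tol && abs(b0_shift) < tol) break
  }
  b
}

# 100-point log-spaced lambda path from the training data only
.lambda_path <- function(X, y, alpha, nlambda = 100, min_ratio = 1e-3) {
  xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  lmax <- max(abs(crossprod(xc, yc))) / (length(y) * max(alpha, 1e-3))
  lmax <- max(lmax, 1e-8)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = nlambda))
}

#' Train a single-tissue elastic-net methylation prediction model
#'
#' Elastic net at `alpha = 0.50` over a 100-point log-spaced lambda path,
#' tuned by `n_folds`-fold cross-validation: each fold's path is computed
#' from its training samples only (held-out samples never influence
#' fitting), paths are aligned by index, and the index minimizing mean
#' out-of-fold squared error is chosen. `cv_R`/`cv_P` are the correlation
#' (and its two-sided test) of the pooled out-of-fold predictions with the
#' observed values; stored weights are the nonzero full-data coefficients
#' at the chosen path index. A model is `reliable` when `cv_R > 0.10` and
#' `cv_P < 0.05`.
#'
#' @param y Residualized (inverse-normalized) methylation vector.
#' @param X Cis dosage matrix (samples x variants), dosage scale.
#' @param variant_info data.frame with variant_id, effect_allele,
#'   other_allele aligned to the columns of `X`.
#' @param alpha Elastic-net mixing parameter.
#' @param n_folds Cross-validation folds.
#' @param seed Fold seed.
#' @param cpg_id,tissue Labels stored in the model.
#' @return A `prediction_model`.
#' @export
train_elastic_net <- function(y, X, variant_info = NULL, alpha = 0.5,
                              n_folds = 5, seed = 1L, cpg_id = "cpg",
                              tissue = "tissue") {
  X <- as.matrix(X)
  n <- length(y)
  if (n < 2 * n_folds) stopf("need at least 2 samples per fold")
  keep <- which(apply(X, 2, stats::sd) > 0)
  if (!length(keep))
    return(.new_model(cpg_id, tissue, "elastic_net", .empty_weights(),
                      0, 1, n))
  Xk <- X[, keep, drop = FALSE]
  vi <- .variant_info(variant_info, colnames(X), ncol(X))[keep, , drop = FALSE]
  fold <- make_folds(n, n_folds, seed)
  nlam <- 100
  fold_err <- matrix(NA_real_, n_folds, nlam)
  pred <- numeric(n)
  for (f in seq_len(n_folds)) {
    tr <- which(fold != f)
    ho <- which(fold == f)
    lam <- .lambda_path(Xk[tr, , drop = FALSE], y[tr], alpha, nlam)
    fit <- glmnet::glmnet(Xk[tr, , drop = FALSE], y[tr], alpha = alpha,
                          lambda = lam, standardize = FALSE)
    pr <- stats::predict(fit, Xk[ho, , drop = FALSE])
    # glmnet may return fewer columns than requested; pad with the last
    if (ncol(pr) < nlam)
      pr <- cbind(pr, matrix(pr[, ncol(pr)], length(ho), nlam - ncol(pr)))
    fold_err[f, ] <- colMeans((pr - y[ho])^2)
    # evaluation lambda for this fold from an inner CV on its training
    # samples only, so the held-out y can never influence its own
    # predictions (leakage-free by construction)
    ifold <- make_folds(length(tr), n_folds, seed + 7919L * f)
    ierr <- matrix(NA_real_, n_folds, nlam)
    for (i in seq_len(n_folds)) {
      itr <- tr[ifold != i]
      iho <- tr[ifold == i]
      ilam <- .lambda_path(Xk[itr, , drop = FALSE], y[itr], alpha, nlam)
      ifit <- glmnet::glmnet(Xk[itr, , drop = FALSE], y[itr],
                             alpha = alpha, lambda = ilam,
                             standardize = FALSE)
      ipr <- stats::predict(ifit, Xk[iho, , drop = FALSE])
      if (ncol(ipr) < nlam)
        ipr <- cbind(ipr, matrix(ipr[, ncol(ipr)], length(iho),
                                 nlam - ncol(ipr)))
      ierr[i, ] <- colMeans((ipr - y[iho])^2)
    }
    kf <- which.min(colMeans(ierr))
    # fold-wise centering removes the training-mean artifact
    pred[ho] <- pr[, kf] - mean(pr[, kf])
  }
  cv <- .cv_cor(pred, y)
  k <- which.min(colMeans(fold_err))   # stored-weight lambda: overall CV
  lam_full <- .lambda_path(Xk, y, alpha, nlam)
  fit_full <- glmnet::glmnet(Xk, y, alpha = alpha, lambda = lam_full,
                             standardize = FALSE, thresh = 1e-10)
  k_eff <- min(k, length(fit_full$lambda))
  b <- as.vector(coef(fit_full)[-1, k_eff])
  b <- .enet_polish(Xk, y, b, lam_full[k_eff], alpha)
  nz <- which(b != 0)
  w <- vi[nz, , drop = FALSE]
  w$weight <- b[nz]
  rownames(w) <- NULL
  .new_model(cpg_id, tissue, "elastic_net", w, cv$R, cv$P, n,
             extra = list(lambda_index = k,
                          lambda = lam_full[min(k, length(lam_full))],
                          fold = fold, cv_pred = pred))
}

.variant_info <- function(variant_info, ids, p = length(ids)) {
  if (is.null(variant_info)) {
    data.frame(variant_id = ids %||% sprintf("v%d", seq_len(p)),
               effect_allele = "A", other_allele = "G",
               stringsAsFactors = FALSE)
  } else {
    variant_info[, c("variant_id", "effect_allele", "other_allele")]
  }
}

#' Train the best-single-mQTL baseline model
#'
#' Within each training fold the cis variant with the smallest marginal
#' regression p-value is picked and its fold-fitted slope/intercept
#' predicts the held-out samples; `cv_R`/`cv_P` pool the out-of-fold
#' predictions. The stored weight is the full-data marginal slope of the
#' variant selected most often across folds (ties broken by smallest
#' full-data p).
#'
#' @inheritParams train_elastic_net
#' @return A `prediction_model` with method `"best_mqtl"`.
#' @export
train_best_mqtl <- function(y, X, variant_info = NULL, n_folds = 5,
                            seed = 1L, cpg_id = "cpg", tissue = "tissue") {
  X <- as.matrix(X)
  n <- length(y)
  if (n < 2 * n_folds) stopf("need at least 2 samples per fold")
  keep <- which(apply(X, 2, stats::sd) > 0)
  if (!length(keep))
    return(.new_model(cpg_id, tissue, "best_mqtl", .empty_weights(), 0, 1, n))
  Xk <- X[, keep, drop = FALSE]
  vi <- .variant_info(variant_info, colnames(X), ncol(X))[keep, , drop = FALSE]
  fold <- make_folds(n, n_folds, seed)
  oof <- numeric(n)
  picked <- integer(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    p_marg <- .marginal_p(y[tr], Xk[tr, , drop = FALSE])
    j <- which.min(p_marg)
    picked[f] <- j
    xt <- Xk[tr, j]
    b <- stats::cov(xt, y[tr]) / stats::var(xt)
    a <- mean(y[tr]) - b * mean(xt)
    oof[!tr] <- a + b * Xk[!tr, j]
    oof[!tr] <- oof[!tr] - mean(oof[!tr])   # fold-wise centering
  }
  cv <- .cv_cor(oof, y)
  tab <- table(picked)
  top <- as.integer(names(tab)[tab == max(tab)])
  if (length(top) > 1) {
    pfull <- .marginal_p(y, Xk[, top, drop = FALSE])
    top <- top[which.min(pfull)]
  }
  b_full <- stats::cov(Xk[, top], y) / stats::var(Xk[, top])
  w <- vi[top, , drop = FALSE]
  w$weight <- b_full
  rownames(w) <- NULL
  .new_model(cpg_id, tissue, "best_mqtl", w, cv$R, cv$P, n,
             extra = list(fold = fold, cv_pred = oof))
}

# vectorized marginal-regression p-values of y on each column of X
.marginal_p <- function(y, X) {
  n <- length(y)
  r <- suppressWarnings(as.vector(cor(X, y)))
  r[is.na(r)] <- 0
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tt), df = n - 2)
}

# vectorized marginal slope/se of y on each column of X
.marginal_stats <- function(y, X) {
  n <- length(y)
  xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  beta <- as.vector(crossprod(xc, yc)) / pmax(sxx, 1e-12)
  rss <- sum(yc^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 1e-12) / ((n - 2) * pmax(sxx, 1e-12)))
  data.frame(variant_id = colnames(X) %||% sprintf("v%d", seq_len(ncol(X))),
             beta = beta, se = se,
             p = 2 * pt(-abs(beta / se), df = n - 2),
             stringsAsFactors = FALSE)
}

#' Per-variant marginal cis-mQTL summary statistics
#'
#' Simple marginal regressions of a (residualized) methylation vector on
#' each cis variant, as consumed by the colocalization step.
#'
#' @param y Methylation residual vector.
#' @param X Cis dosage matrix.
#' @return data.frame: variant_id, beta, se, p.
#' @export
cis_marginal_stats <- function(y, X) {
  X <- as.matrix(X)
  .marginal_stats(y, X)
}

#' Train cross-tissue methylation prediction models
#'
#' Joint penalized regression across tissues sharing the cis variant set:
#' `sum_t (1/(2 n_t)) ||y_t - X_t b_t||^2 + lambda1 sum_j ||b_j.||_2 +
#' lambda2 sum_jt |b_jt|` (a sparse-group penalty whose group structure
#' ties each variant's effects across tissues), solved by block coordinate
#' descent on per-tissue standardized predictors. `(lambda1, lambda2)` is
#' chosen on a 5x5 grid by mean out-of-fold error averaged over tissues;
#' per-tissue `cv_R`/`cv_P` come from that tissue's out-of-fold
#' predictions. Stored weights are rescaled back to the dosage scale.
#' Tissues with fewer samples than folds are dropped with a warning.
#'
#' @param y_by_tissue Named list of residualized methylation vectors.
#' @param X_by_tissue Named list of cis dosage matrices (same columns).
#' @param variant_info As in [train_elastic_net()].
#' @param n_folds,seed,cpg_id As in [train_elastic_net()].
#' @return Named list of `prediction_model`s (method `"cross_tissue"`),
#'   one per retained tissue.
#' @export
train_cross_tissue <- function(y_by_tissue, X_by_tissue, variant_info = NULL,
                               n_folds = 5, seed = 1L, cpg_id = "cpg") {
  stopifnot(length(y_by_tissue) >= 2,
            length(y_by_tissue) == length(X_by_tissue))
  tn <- names(y_by_tissue) %||% sprintf("tissue%d", seq_along(y_by_tissue))
  ns <- vapply(y_by_tissue, length, integer(1))
  keep_t <- ns >= 2 * n_folds
  if (!all(keep_t))
    warnf("dropping %d tissue(s) with n < %d from the joint fit",
          sum(!keep_t), 2 * n_folds)
  if (sum(keep_t) < 2) stopf("need at least 2 tissues with enough samples")
  yb <- y_by_tissue[keep_t]; Xb <- lapply(X_by_tissue[keep_t], as.matrix)
  tn <- tn[keep_t]
  TT <- length(yb)
  p <- ncol(Xb[[1]])
  vi <- .variant_info(variant_info, colnames(Xb[[1]]), p)

  std <- lapply(seq_len(TT), function(t) {
    m <- colMeans(Xb[[t]])
    s <- apply(Xb[[t]], 2, stats::sd) * sqrt((ns_t <- nrow(Xb[[t]])) - 1) /
      sqrt(ns_t)
    s[s < 1e-10] <- 1
    list(m = m, s = s)
  })
  prep <- function(t, rows) {
    Xs <- sweep(sweep(Xb[[t]][rows, , drop = FALSE], 2, std[[t]]$m, "-"),
                2, std[[t]]$s, "/")
    yc <- yb[[t]][rows] - mean(yb[[t]][rows])
    nt <- length(yc)
    list(G = crossprod(Xs) / nt, c = as.vector(crossprod(Xs, yc)) / nt,
         Xs = Xs, yc = yc, mu = mean(yb[[t]][rows]))
  }

  full <- lapply(seq_len(TT), function(t) prep(t, seq_len(ns[keep_t][t])))
  # data-driven 5x5 grid: lambda1 from the group-level gradient norms,
  # lambda2 from the single-coefficient gradients; per-fit grids are
  # recomputed from that fit's own training data (index-aligned)
  grid_from <- function(pr) {
    z0 <- vapply(seq_len(p), function(j)
      sqrt(sum(vapply(pr, function(f) f$c[j]^2, numeric(1)))), numeric(1))
    l1max <- max(z0, 1e-8)
    l2max <- max(abs(unlist(lapply(pr, `[[`, "c"))), 1e-8)
    list(l1 = exp(seq(log(l1max), log(l1max * 0.01), length.out = 5)),
         l2 = l2max * c(0.001, 0.005, 0.02, 0.1, 0.4))
  }
  # errors over the 25-cell grid for one train/test split (warm starts
  # down the lambda1 path within each lambda2 column)
  split_err <- function(tr_prep, test_rows) {
    gr <- grid_from(tr_prep)
    e <- matrix(0, 25, TT)
    for (i2 in seq_len(5)) {
      beta <- matrix(0, p, TT)
      for (i1 in seq_len(5)) {
        beta <- sgl_solve(lapply(tr_prep, `[[`, "G"),
                          lapply(tr_prep, `[[`, "c"),
                          gr$l1[i1], gr$l2[i2], beta, 500L, 1e-7)
        cell <- (i2 - 1) * 5 + i1
        for (t in seq_len(TT)) {
          Xs <- sweep(sweep(Xb[[t]][test_rows[[t]], , drop = FALSE],
                            2, std[[t]]$m, "-"), 2, std[[t]]$s, "/")
          pr_ <- as.vector(Xs %*% beta[, t]) + tr_prep[[t]]$mu
          e[cell, t] <- mean((pr_ - yb[[t]][test_rows[[t]]])^2)
        }
      }
    }
    e
  }
  predict_cells <- function(tr_prep, test_rows) {
    gr <- grid_from(tr_prep)
    pred <- vector("list", 25)
    for (i2 in seq_len(5)) {
      beta <- matrix(0, p, TT)
      for (i1 in seq_len(5)) {
        beta <- sgl_solve(lapply(tr_prep, `[[`, "G"),
                          lapply(tr_prep, `[[`, "c"),
                          gr$l1[i1], gr$l2[i2], beta, 500L, 1e-7)
        cell <- (i2 - 1) * 5 + i1
        pred[[cell]] <- lapply(seq_len(TT), function(t) {
          Xs <- sweep(sweep(Xb[[t]][test_rows[[t]], , drop = FALSE],
                            2, std[[t]]$m, "-"), 2, std[[t]]$s, "/")
          as.vector(Xs %*% beta[, t]) + tr_prep[[t]]$mu
        })
      }
    }
    pred
  }

  folds <- lapply(seq_len(TT), function(t)
    make_folds(length(yb[[t]]), n_folds, seed))
  oof_eval <- lapply(seq_len(TT), function(t) numeric(length(yb[[t]])))
  outer_err <- matrix(0, 25, n_folds)
  for (f in seq_len(n_folds)) {
    tr_rows <- lapply(seq_len(TT), function(t) which(folds[[t]] != f))
    ho_rows <- lapply(seq_len(TT), function(t) which(folds[[t]] == f))
    tr_prep <- lapply(seq_len(TT), function(t) prep(t, tr_rows[[t]]))
    pred_cells <- predict_cells(tr_prep, ho_rows)
    outer_err[, f] <- rowMeans(vapply(seq_len(25), function(cell)
      vapply(seq_len(TT), function(t)
        mean((pred_cells[[cell]][[t]] - yb[[t]][ho_rows[[t]]])^2),
        numeric(1)), numeric(TT)) |> t())
    # evaluation cell for this fold from an inner CV on its training
    # samples only (leakage-free; see train_elastic_net)
    ifolds <- lapply(seq_len(TT), function(t)
      make_folds(length(tr_rows[[t]]), n_folds, seed + 7919L * f))
    ierr <- matrix(0, 25, n_folds)
    for (i in seq_len(n_folds)) {
      itr <- lapply(seq_len(TT), function(t) tr_rows[[t]][ifolds[[t]] != i])
      iho <- lapply(seq_len(TT), function(t) tr_rows[[t]][ifolds[[t]] == i])
      iprep <- lapply(seq_len(TT), function(t) prep(t, itr[[t]]))
      ierr[, i] <- rowMeans(split_err(iprep, iho))
    }
    cell_f <- which.min(rowMeans(ierr))
    for (t in seq_len(TT)) {
      pf <- pred_cells[[cell_f]][[t]]
      oof_eval[[t]][ho_rows[[t]]] <- pf - mean(pf)   # fold-wise centered
    }
  }
  cv_err <- matrix(rowMeans(outer_err), 5, 5)
  best <- which(cv_err == min(cv_err), arr.ind = TRUE)[1, ]

  # final fit on full data at the chosen pair (warm start down the path)
  gr_full <- grid_from(full)
  l1_grid <- gr_full$l1; l2_grid <- gr_full$l2
  beta <- matrix(0, p, TT)
  for (i1 in seq_len(best[1])) {
    beta <- sgl_solve(lapply(full, `[[`, "G"), lapply(full, `[[`, "c"),
                      l1_grid[i1], l2_grid[best[2]], beta, 1000L, 1e-8)
  }
  out <- vector("list", TT)
  for (t in seq_len(TT)) {
    cv <- .cv_cor(oof_eval[[t]], yb[[t]])
    nz <- which(beta[, t] != 0)
    w <- vi[nz, , drop = FALSE]
    w$weight <- beta[nz, t] / std[[t]]$s[nz]   # back to dosage scale
    rownames(w) <- NULL
    out[[t]] <- .new_model(cpg_id, tn[t], "cross_tissue", w, cv$R, cv$P,
                           length(yb[[t]]),
                           extra = list(lambda1 = l1_grid[best[1]],
                                        lambda2 = l2_grid[best[2]],
                                        beta_std = beta[, t],
                                        fold = folds[[t]],
                                        cv_pred = oof_eval[[t]]))
  }
  names(out) <- tn
  out
}

#' Select the model used for association testing
#'
#' Among reliable elastic-net and cross-tissue candidates for one
#' CpG-tissue pair, the one with the larger cross-validation R is used;
#' `NULL` when neither is reliable. The best-mQTL baseline is never
#' selected (comparison only).
#'
#' @param candidates List of `prediction_model`s sharing cpg_id and tissue.
#' @return A `prediction_model` or `NULL`.
#' @export
select_model <- function(candidates) {
  ok <- Filter(function(m) m$method %in% c("elastic_net", "cross_tissue") &&
                 isTRUE(m$reliable), candidates)
  if (!length(ok)) return(NULL)
  ok[[which.max(vapply(ok, `[[`, numeric(1), "cv_R"))]]
}

#' Paired comparison of prediction performance between methods
#'
#' Two-sided paired t-test on per-CpG cross-validation R values.
#'
#' @param R_a,R_b Equal-length vectors of R values (paired by CpG).
#' @return List: t, p, mean_diff, df. Zero-variance differences flag
#'   `degenerate = TRUE` with p = NA.
#' @export
compare_methods <- function(R_a, R_b) {
  stopifnot(length(R_a) == length(R_b), length(R_a) >= 2)
  d <- R_a - R_b
  if (stats::sd(d) < 1e-14)
    return(list(t = NA_real_, p = NA_real_, mean_diff = mean(d),
                df = length(d) - 1, degenerate = TRUE))
  tt <- t.test(R_a, R_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, mean_diff = mean(d),
       df = unname(tt$parameter), degenerate = FALSE)
}

#' Predicted methylation from a model on a dosage panel
#'
#' @param model A `prediction_model`.
#' @param geno A `genotype_matrix` (missing dosages mean-imputed).
#' @return Numeric vector, one value per sample (centered weights only;
#'   no intercept).
#' @export
predict_methylation <- function(model, geno) {
  if (!nrow(model$weights)) return(rep(0, nrow(geno$dosage)))
  idx <- match(model$weights$variant_id, geno$variants$variant_id)
  if (anyNA(idx)) stopf("model variant(s) absent from the panel")
  X <- geno$dosage[, idx, drop = FALSE]
  if (anyNA(X)) {
    cm <- colMeans(X, na.rm = TRUE)
    ii <- which(is.na(X), arr.ind = TRUE)
    X[ii] <- cm[ii[, 2]]
  }
  as.vector(X %*% model$weights$weight)
}
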