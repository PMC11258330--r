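# Variant QC and the normalization / residualization transforms applied
# before model training, eQTM scans and differential analyses.

#' Hardy-Weinberg equilibrium test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed genotype
#' counts against HWE expectations at the sample allele frequency.
#' Monomorphic samples (allele frequency 0 or 1) return p = 1.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts.
#' @return Two-sided p-value.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stopf("negative genotype counts")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stopf("no genotyped samples")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  q <- 1 - p
  if (p == 0 || q == 0) return(1)
  e <- n * c(p^2, 2 * p * q, q^2)
  x2 <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
  pchisq(x2, df = 1, lower.tail = FALSE)
}

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

# genotype counts from (possibly fractional) dosages: round to nearest
.geno_counts <- function(d) {
  d <- d[!is.na(d)]
  r <- pmin(pmax(round(d), 0), 2)
  c(sum(r == 2), sum(r == 1), sum(r == 0))
}

#' Variant quality-control filter
#'
#' Retains variants passing, with strict inequalities: missingness below
#' `miss_max`, minor allele frequency above `maf_min`, HWE p above
#' `hwe_min`, and (optionally) a non-palindromic allele pair. Variant order
#' is preserved, and a per-rule removal log is attached as attribute
#' `"qc_log"`.
#'
#' @param geno A `genotype_matrix`.
#' @param miss_max Maximum missing-call fraction (exclusive).
#' @param maf_min Minimum minor allele frequency (exclusive).
#' @param hwe_min Minimum HWE p-value (exclusive).
#' @param drop_palindromic Drop A/T and C/G variants.
#' @param impute_missing Mean-impute surviving missing dosages.
#' @return The filtered `genotype_matrix`.
#' @export
filter_variants <- function(geno, miss_max = 0.05, maf_min = 0.05,
                            hwe_min = 1e-4, drop_palindromic = TRUE,
                            impute_missing = TRUE) {
  d <- geno$dosage
  v <- geno$variants
  p <- ncol(d)
  if (!p) return(geno)
  n <- nrow(d)
  miss <- colMeans(is.na(d))
  af <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf[is.nan(maf)] <- 0
  hwe <- vapply(seq_len(p), function(j) {
    cnt <- .geno_counts(d[, j])
    if (sum(cnt) == 0) return(0)
    hwe_test(cnt[1], cnt[2], cnt[3])
  }, numeric(1))
  pal <- .is_palindromic(v$effect_allele, v$other_allele)
  pass_miss <- miss < miss_max
  pass_maf <- maf > maf_min
  pass_hwe <- hwe > hwe_min
  pass_pal <- if (drop_palindromic) !pal else rep(TRUE, p)
  keep <- pass_miss & pass_maf & pass_hwe & pass_pal
  out <- geno
  out$dosage <- d[, keep, drop = FALSE]
  out$variants <- v[keep, , drop = FALSE]
  rownames(out$variants) <- NULL
  out$variants$maf <- maf[keep]
  if (impute_missing && anyNA(out$dosage)) {
    cm <- colMeans(out$dosage, na.rm = TRUE)
    idx <- which(is.na(out$dosage), arr.ind = TRUE)
    out$dosage[idx] <- cm[idx[, 2]]
  }
  attr(out, "qc_log") <- data.frame(
    rule = c("missingness", "maf", "hwe", "palindromic"),
    removed = c(sum(!pass_miss), sum(!pass_maf), sum(!pass_hwe),
                sum(!pass_pal)),
    threshold = c(miss_max, maf_min, hwe_min, as.numeric(drop_palindromic)))
  out
}

#' Rank-based inverse-normal transform
#'
#' Blom transform `qnorm((r - 3/8) / (n + 1/4))` on average ranks; ties
#' share a value, missing values stay missing. All-identical input returns
#' zeros with a warning.
#'
#' @param x Numeric vector.
#' @param c_const Rank offset constant (Blom's 3/8).
#' @return Transformed vector, same length and names as `x`.
#' @export
inverse_normal <- function(x, c_const = 3 / 8) {
  ok <- !is.na(x)
  if (sum(ok) < 2) stopf("need at least 2 non-missing values")
  out <- rep(NA_real_, length(x))
  xs <- x[ok]
  if (length(unique(xs)) == 1L) {
    warnf("all values identical; inverse-normal transform returns zeros")
    out[ok] <- 0
    return(out)
  }
  n <- length(xs)
  r <- rank(xs, ties.method = "average")
  out[ok] <- qnorm((r - c_const) / (n - 2 * c_const + 1))
  names(out) <- names(x)
  out
}

#' Residualize features on covariates
#'
#' Ordinary least-squares residuals of each feature (row) on the covariate
#' columns plus an intercept. Residuals are orthogonal to every covariate
#' column.
#'
#' @param y_matrix feature x sample numeric matrix.
#' @param covariates sample x covariate numeric matrix/data.frame (no
#'   intercept column; one is added).
#' @return feature x sample residual matrix.
#' @export
residualize <- function(y_matrix, covariates = NULL) {
  y_matrix <- as.matrix(y_matrix)
  n <- ncol(y_matrix)
  X <- cbind(intercept = rep(1, n))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    X <- cbind(X, cv)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stopf("rank-deficient covariate matrix")
  res <- t(qr.resid(qr_x, t(y_matrix)))
  dimnames(res) <- dimnames(y_matrix)
  res
}

#' Hidden nuisance factors by principal components
#'
#' Top-k principal-component scores of the feature-standardized matrix
#' (a PCA stand-in for PEER-style latent nuisance factors). Each
#' component's sign is fixed so its largest-magnitude feature loading is
#' positive.
#'
#' @param y_matrix feature x sample matrix.
#' @param k Number of factors; must be < min(features, samples).
#' @return sample x k matrix of factor scores.
#' @export
hidden_factors <- function(y_matrix, k) {
  y_matrix <- as.matrix(y_matrix)
  if (k >= min(dim(y_matrix))) stopf("k must be < min(features, samples)")
  ys <- t(scale(t(y_matrix)))            # standardize each feature
  ys[!is.finite(ys)] <- 0                # constant features carry no signal
  sv <- svd(t(ys), nu = k, nv = k)       # rows = samples
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) scores[, j] <- -scores[, j]
  }
  rownames(scores) <- colnames(y_matrix)
  colnames(scores) <- paste0("factor", seq_len(k))
  scores
}

#' Quantile normalization between samples
#'
#' Forces every sample column onto the common distribution given by the
#' row-wise mean of the sorted columns; ties within a column receive the
#' mean of the reference values they span.
#'
#' @param y_matrix feature x sample matrix.
#' @return Matrix of the same shape.
#' @export
quantile_normalize_samples <- function(y_matrix) {
  y_matrix <- as.matrix(y_matrix)
  if (ncol(y_matrix) < 2) stopf("need at least 2 samples")
  srt <- apply(y_matrix, 2, sort)
  ref <- rowMeans(srt)
  out <- apply(y_matrix, 2, function(col) {
    r <- rank(col, ties.method = "average")
    # average rank r maps to mean of ref values it spans
    fl <- floor(r); ce <- ceiling(r)
    (ref[fl] + ref[ce]) / 2
  })
  dimnames(out) <- dimnames(y_matrix)
  out
}
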