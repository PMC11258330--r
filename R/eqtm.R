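# Cis expression-quantitative-trait-methylation scan linking
# cancer-associated CpGs to nearby genes.

#' Expression gene filter
#'
#' Keeps genes with at least `min_reads` reads and strictly more than
#' `min_tpm` TPM in at least `min_frac` of samples (the in-how-many-samples
#' rule is a declared convention; both expression thresholds follow the
#' printed inequalities: reads >= 6, TPM > 0.10).
#'
#' @param read_counts gene x sample read-count matrix.
#' @param tpm gene x sample TPM matrix (same dimnames).
#' @param min_reads Minimum read count (inclusive).
#' @param min_tpm Minimum TPM (exclusive).
#' @param min_frac Fraction of samples that must pass both thresholds.
#' @return Character vector of retained gene ids.
#' @export
filter_genes <- function(read_counts, tpm, min_reads = 6, min_tpm = 0.10,
                         min_frac = 0.2) {
  stopifnot(all(dim(read_counts) == dim(tpm)))
  pass <- (read_counts >= min_reads) & (tpm > min_tpm)
  frac <- rowMeans(pass)
  rn <- rownames(read_counts) %||% as.character(seq_len(nrow(read_counts)))
  rn[frac >= min_frac]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone, order-preserving).
#'
#' @param p Vector of p-values in (0, 1].
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in (0,1]")
  p.adjust(p, method = "BH")
}

#' Cis eQTM scan
#'
#' For every CpG-gene pair whose TSS lies within `window` of the CpG, fits
#' OLS of inverse-normalized expression on inverse-normalized methylation
#' with `k_factors[1]` methylation and `k_factors[2]` expression hidden
#' factors (plus intercept) as covariates; two-sided t-test p-values are
#' BH-FDR adjusted over all tested pairs in the tissue.
#'
#' @param meth_norm CpG x sample matrix, already normalized
#'   (quantile-between-samples then inverse-normal per CpG).
#' @param expr_norm gene x sample matrix, normalized the same way, same
#'   sample columns.
#' @param cpg_annot data.frame: cpg_id, chrom, pos.
#' @param gene_annot data.frame: gene_id, chrom, tss.
#' @param tissue Tissue label for the output.
#' @param window Cis window (bp) around the CpG; genes anchored at TSS.
#' @param k_factors Hidden-factor counts `c(methylation, expression)`.
#' @return data.frame: cpg_id, gene_id, tissue, beta, se, p, q, n_samples.
#' @export
eqtm_scan <- function(meth_norm, expr_norm, cpg_annot, gene_annot,
                      tissue = "tissue", window = 500000,
                      k_factors = c(5, 5)) {
  stopifnot(ncol(meth_norm) == ncol(expr_norm))
  n <- ncol(meth_norm)
  if (n < 10) stopf("need at least 10 shared samples")
  k1 <- min(k_factors[1], nrow(meth_norm) - 1, n - 1)
  k2 <- min(k_factors[2], nrow(expr_norm) - 1, n - 1)
  covar <- cbind(
    if (k1 > 0) hidden_factors(meth_norm, k1),
    if (k2 > 0) hidden_factors(expr_norm, k2))
  pairs <- list(); pi <- 0L
  for (i in seq_len(nrow(cpg_annot))) {
    w <- cis_window(cpg_annot$pos[i], window)
    hit <- which(sub("^chr", "", gene_annot$chrom) ==
                   sub("^chr", "", cpg_annot$chrom[i]) &
                 gene_annot$tss >= w[1] & gene_annot$tss <= w[2])
    for (g in hit) {
      pi <- pi + 1L
      pairs[[pi]] <- c(i, g)
    }
  }
  if (!pi) {
    return(data.frame(cpg_id = character(0), gene_id = character(0),
                      tissue = character(0), beta = numeric(0),
                      se = numeric(0), p = numeric(0), q = numeric(0),
                      n_samples = integer(0)))
  }
  X0 <- cbind(1, covar)
  qr0 <- qr(X0)
  if (qr0$rank < ncol(X0)) stopf("rank-deficient covariate matrix")
  out <- data.frame(
    cpg_id = character(pi), gene_id = character(pi), tissue = tissue,
    beta = numeric(pi), se = numeric(pi), p = numeric(pi),
    q = NA_real_, n_samples = n, stringsAsFactors = FALSE)
  df_res <- n - ncol(X0) - 1
  for (k in seq_len(pi)) {
    i <- pairs[[k]][1]; g <- pairs[[k]][2]
    m <- meth_norm[i, ]; e <- expr_norm[g, ]
    # Frisch-Waugh: residualize both on covariates, then simple OLS
    mr <- qr.resid(qr0, m)
    er <- qr.resid(qr0, e)
    sxx <- sum(mr^2)
    if (sxx < 1e-12 || sum(er^2) < 1e-12) {
      # degenerate pair (constant methylation or expression residual)
      out$beta[k] <- 0; out$se[k] <- NA; out$p[k] <- 1
    } else {
      b <- sum(mr * er) / sxx
      rss <- sum((er - b * mr)^2)
      se <- sqrt(rss / df_res / sxx)
      if (!is.finite(se) || se < 1e-12) {
        out$beta[k] <- b; out$se[k] <- NA; out$p[k] <- 1
      } else {
        out$beta[k] <- b; out$se[k] <- se
        out$p[k] <- 2 * pt(-abs(b / se), df = df_res)
      }
    }
    out$cpg_id[k] <- cpg_annot$cpg_id[i]
    out$gene_id[k] <- gene_annot$gene_id[g]
  }
  out$q <- bh_fdr(pmax(out$p, .Machine$double.xmin))
  out
}
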