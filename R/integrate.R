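# Differential methylation (tumor vs adjacent normal), gene-level
# evidence gating, and assembly of direction-consistent
# CpG-gene-cancer trios.

#' Tumor-versus-normal differential methylation
#'
#' Per CpG, a linear model of normalized methylation (quantile-normalized
#' between samples, then inverse-normalized per CpG — apply
#' [quantile_normalize_samples()]/[inverse_normal()] upstream) on tissue
#' status plus covariates. The status effect sign is tumor minus normal.
#' Status is modeled as a fixed effect: a two-level factor of interest is
#' not estimable as a random effect.
#'
#' @param beta_norm CpG x sample normalized methylation matrix.
#' @param status Per-sample labels, `"tumor"` or `"normal"`.
#' @param covariates Optional sample x covariate table (age, race, sex,
#'   sample-type indicators, ...).
#' @return data.frame: cpg_id, effect, se, p.
#' @export
differential_methylation <- function(beta_norm, status, covariates = NULL) {
  status <- as.character(status)
  if (!all(status %in% c("tumor", "normal")))
    stopf("status must be 'tumor' or 'normal'")
  if (!any(status == "tumor") || !any(status == "normal"))
    stopf("both tumor and normal samples are required")
  x <- as.numeric(status == "tumor")
  n <- ncol(beta_norm)
  X <- cbind(1, x)
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cv <- as.matrix(as.data.frame(covariates)); storage.mode(cv) <- "double"
    X <- cbind(X, cv)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stopf("rank-deficient design")
  df_res <- n - ncol(X)
  co <- qr.coef(qr_x, t(beta_norm))
  res <- qr.resid(qr_x, t(beta_norm))
  rss <- colSums(res^2)
  XtXinv22 <- chol2inv(qr.R(qr_x))[2, 2]
  se <- sqrt(rss / df_res * XtXinv22)
  eff <- co[2, ]
  data.frame(cpg_id = rownames(beta_norm) %||%
               sprintf("cpg%d", seq_len(nrow(beta_norm))),
             effect = as.vector(eff), se = se,
             p = 2 * pt(-abs(eff / se), df = df_res),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Direction-consistent differential-methylation validation
#'
#' A CpG-cancer association is validated when the tumor-vs-normal
#' differential effect is significant at two-sided p < 0.05 and its sign
#' matches the association Z score.
#'
#' @param dm_effect,dm_p Differential-methylation effect and p-value.
#' @param assoc_z Association Z score.
#' @param p_max Significance gate.
#' @return Logical.
#' @export
validate_direction <- function(dm_effect, dm_p, assoc_z, p_max = 0.05) {
  is.finite(dm_effect) & is.finite(assoc_z) & dm_p < p_max &
    sign(dm_effect) == sign(assoc_z) & sign(assoc_z) != 0
}

#' Essential genes from a CERES matrix
#'
#' Genes whose median CERES score across cell lines is strictly below
#' -0.50 (missing values excluded from the median).
#'
#' @param ceres gene x cell-line matrix of CERES scores.
#' @param threshold Median cutoff (strict).
#' @return Character vector of essential gene ids.
#' @export
essentiality_filter <- function(ceres, threshold = -0.50) {
  med <- apply(ceres, 1, median, na.rm = TRUE)
  rn <- rownames(ceres) %||% as.character(seq_len(nrow(ceres)))
  rn[!is.na(med) & med < threshold]
}

#' Usable gene-expression prediction models
#'
#' Per gene, among models with R^2 > 0.01 and two-sided P < 0.05, keep
#' the one with the larger R^2 (ties broken by declared method order:
#' elastic_net before cross_tissue); genes with no qualifying model are
#' dropped.
#'
#' @param models data.frame: gene_id, method, r2, p.
#' @return data.frame with one row per usable gene.
#' @export
gene_expression_gate <- function(models, r2_min = 0.01, p_max = 0.05) {
  ok <- models[models$r2 > r2_min & models$p < p_max, , drop = FALSE]
  if (!nrow(ok)) return(ok)
  method_rank <- match(ok$method, c("elastic_net", "cross_tissue"),
                       nomatch = 99L)
  ok <- ok[order(ok$gene_id, -ok$r2, method_rank), , drop = FALSE]
  ok[!duplicated(ok$gene_id), , drop = FALSE]
}

#' Gene-level evidence direction
#'
#' Combines the predicted-expression association channel (sign of Z when
#' q < 0.05) with the external differential-expression channel (sign of
#' logFC when q < 0.05). Both significant and concordant: that shared
#' sign; both significant and discordant: direction 0 with a conflict
#' flag; one significant: its sign; none: direction 0.
#'
#' @param gene_evidence data.frame: gene_id, cancer, and optional columns
#'   assoc_z, assoc_q, diffexpr_logfc, diffexpr_q.
#' @return The input with `direction` (+1/-1/0) and `conflict` columns.
#' @export
gene_direction <- function(gene_evidence) {
  g <- gene_evidence
  n <- nrow(g)
  az <- g$assoc_z %||% rep(NA_real_, n)
  aq <- g$assoc_q %||% rep(NA_real_, n)
  dl <- g$diffexpr_logfc %||% rep(NA_real_, n)
  dq <- g$diffexpr_q %||% rep(NA_real_, n)
  s1 <- ifelse(!is.na(aq) & aq < 0.05, sign(az), 0)
  s2 <- ifelse(!is.na(dq) & dq < 0.05, sign(dl), 0)
  conflict <- s1 != 0 & s2 != 0 & s1 != s2
  dir <- ifelse(conflict, 0, ifelse(s1 != 0, s1, s2))
  g$direction <- as.integer(dir)
  g$conflict <- conflict
  g
}

#' Assemble direction-consistent CpG-gene-cancer trios
#'
#' For every Bonferroni-significant CpG-cancer association and every
#' q < 0.05 CpG-gene eQTM pair, emits a trio; it is `consistent` when the
#' gene has a nonzero evidence direction and
#' `sign(CpG-cancer) = sign(CpG-gene) * sign(gene-cancer)`.
#'
#' @param cpg_cancer Association records (with `significant`, `zscore`,
#'   `cpg_id`, `cancer`).
#' @param cpg_gene eQTM results (with `q`, `beta`, `cpg_id`, `gene_id`).
#' @param gene_cancer Gene evidence after [gene_direction()] (with
#'   `gene_id`, `cancer`, `direction`).
#' @param q_max eQTM significance gate.
#' @return data.frame, one row per trio.
#' @export
assemble_trios <- function(cpg_cancer, cpg_gene, gene_cancer,
                           q_max = 0.05) {
  cc <- cpg_cancer[isTRUE_vec(cpg_cancer$significant), , drop = FALSE]
  cg <- cpg_gene[!is.na(cpg_gene$q) & cpg_gene$q < q_max, , drop = FALSE]
  out <- list(); k <- 0L
  for (i in seq_len(nrow(cc))) {
    links <- cg[cg$cpg_id == cc$cpg_id[i], , drop = FALSE]
    for (j in seq_len(nrow(links))) {
      ge <- gene_cancer[gene_cancer$gene_id == links$gene_id[j] &
                          gene_cancer$cancer == cc$cancer[i], ,
                        drop = FALSE]
      dir_gene <- if (nrow(ge)) ge$direction[1] else 0L
      s_cc <- sign(cc$zscore[i]); s_cg <- sign(links$beta[j])
      k <- k + 1L
      out[[k]] <- data.frame(
        cpg_id = cc$cpg_id[i], gene_id = links$gene_id[j],
        cancer = cc$cancer[i],
        sign_cpg_cancer = s_cc, sign_cpg_gene = s_cg,
        sign_gene_cancer = dir_gene,
        p_cpg_cancer = cc$pvalue[i], q_cpg_gene = links$q[j],
        consistent = dir_gene != 0 && s_cg != 0 &&
          s_cc == s_cg * dir_gene,
        stringsAsFactors = FALSE)
    }
  }
  if (!k) {
    return(data.frame(cpg_id = character(0), gene_id = character(0),
                      cancer = character(0), sign_cpg_cancer = numeric(0),
                      sign_cpg_gene = numeric(0),
                      sign_gene_cancer = numeric(0),
                      p_cpg_cancer = numeric(0), q_cpg_gene = numeric(0),
                      consistent = logical(0)))
  }
  do.call(rbind, out)
}

isTRUE_vec <- function(x) !is.na(x) & x
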