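# Summary-statistics stepwise selection of independent GWAS signals,
# conditional re-testing of CpG-cancer associations, and novelty
# classification by distance to known GWAS hits.

#' LD correlation matrix from a reference panel
#'
#' @param geno A `genotype_matrix`.
#' @param variant_ids Variants to include (default all).
#' @return Correlation matrix with unit diagonal (monomorphic variants get
#'   zero off-diagonals).
#' @export
ld_matrix <- function(geno, variant_ids = NULL) {
  ids <- variant_ids %||% geno$variants$variant_id
  idx <- match(ids, geno$variants$variant_id)
  if (anyNA(idx)) stopf("variant(s) absent from the reference panel")
  X <- geno$dosage[, idx, drop = FALSE]
  if (anyNA(X)) {
    cm <- colMeans(X, na.rm = TRUE)
    ii <- which(is.na(X), arr.ind = TRUE)
    X[ii] <- cm[ii[, 2]]
  }
  R <- suppressWarnings(stats::cor(X))
  R[is.na(R)] <- 0
  diag(R) <- 1
  dimnames(R) <- list(ids, ids)
  R
}

# joint model of a variant set on the z/LD scale with ridge regularization
.joint_z <- function(z, R, ridge = 1e-6) {
  A <- R + diag(ridge, nrow(R))
  Ainv <- solve(A)
  b <- as.vector(Ainv %*% z)
  se <- sqrt(pmax(diag(Ainv), 1e-12))
  list(b = b, z = b / se, Ainv = Ainv)
}

#' Stepwise selection of independently associated variants
#'
#' Forward selection from GWAS summary statistics plus reference LD:
#' start from the smallest-p variant reaching `p_enter`; at each step the
#' candidate with the smallest joint-model conditional p below `p_enter`
#' is added, skipping candidates with `r^2 > r2_collinear` against any
#' selected variant. Joint effects are recomputed each step on the
#' z-score/LD scale with ridge-regularized normal equations. Variants
#' whose N differs more than 20% from the locus median are dropped first
#' (sample-size heterogeneity guard).
#'
#' @param gwas_locus GWAS summary data.frame for the locus.
#' @param ld LD correlation matrix over (at least) the locus variants.
#' @param p_enter Genome-wide entry threshold.
#' @param r2_collinear Collinearity cutoff.
#' @param ridge Diagonal regularization.
#' @return Character vector of selected variant ids (possibly empty).
#' @export
stepwise_select <- function(gwas_locus, ld, p_enter = 5e-8,
                            r2_collinear = 0.9, ridge = 1e-6) {
  g <- gwas_locus
  n_med <- median(g$N)
  g <- g[abs(g$N - n_med) <= 0.2 * n_med, , drop = FALSE]
  if (!nrow(g)) return(character(0))
  z <- g$beta / g$se
  names(z) <- g$variant
  p <- z_to_p(z)
  if (min(p) >= p_enter) return(character(0))
  sel <- g$variant[which.min(p)]
  repeat {
    cand <- setdiff(g$variant, sel)
    if (!length(cand)) break
    r2max <- apply(ld[cand, sel, drop = FALSE]^2, 1, max)
    cand <- cand[r2max <= r2_collinear]
    if (!length(cand)) break
    best_p <- Inf; best_v <- NULL
    for (v in cand) {
      ids <- c(sel, v)
      jz <- .joint_z(z[ids], ld[ids, ids, drop = FALSE], ridge)
      pv <- z_to_p(jz$z[length(ids)])
      if (pv < best_p) { best_p <- pv; best_v <- v }
    }
    if (best_p < p_enter) sel <- c(sel, best_v) else break
  }
  sel
}

#' Conditional summary statistics given a selected variant set
#'
#' Standard summary-statistic conditional decomposition on the z/LD
#' scale: for target t, `z_c = (z_t - R_tS R_SS^{-1} z_S) /
#' sqrt(1 - R_tS R_SS^{-1} R_St)`, with `se_c = se_t * sqrt(1 - h)` and
#' `beta_c = z_c * se_c`. Conditioning on the empty set returns the
#' marginal statistics unchanged; a target inside the selected set gets
#' conditional Z exactly 0.
#'
#' @param targets Variant ids to re-test.
#' @param selected Selected (conditioning) variant ids.
#' @param gwas GWAS summary data.frame covering targets and selected.
#' @param ld LD correlation matrix covering `union(targets, selected)`.
#' @param ridge Diagonal regularization.
#' @return data.frame: variant, beta, se, z, p (conditional).
#' @export
conditional_stats <- function(targets, selected, gwas, ld, ridge = 1e-6) {
  i <- match(targets, gwas$variant)
  if (anyNA(i)) stopf("target variant(s) absent from GWAS")
  bt <- gwas$beta[i]; st <- gwas$se[i]
  zt <- bt / st
  if (!length(selected)) {
    return(data.frame(variant = targets, beta = bt, se = st, z = zt,
                      p = z_to_p(zt), stringsAsFactors = FALSE))
  }
  js <- match(selected, gwas$variant)
  if (anyNA(js)) stopf("selected variant(s) absent from GWAS")
  zs <- gwas$beta[js] / gwas$se[js]
  Rss <- ld[selected, selected, drop = FALSE] + diag(ridge, length(selected))
  Rinv <- solve(Rss)
  proj <- Rinv %*% zs
  out <- data.frame(variant = targets, beta = NA_real_, se = NA_real_,
                    z = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_along(targets)) {
    if (targets[k] %in% selected) {
      out$beta[k] <- 0; out$se[k] <- st[k]; out$z[k] <- 0; out$p[k] <- 1
      next
    }
    rts <- ld[targets[k], selected]
    h <- as.numeric(rts %*% Rinv %*% rts)
    d <- max(1 - h, 1e-10)
    zc <- (zt[k] - as.numeric(rts %*% proj)) / sqrt(d)
    sec <- st[k] * sqrt(d)
    out$z[k] <- zc; out$se[k] <- sec; out$beta[k] <- zc * sec
    out$p[k] <- z_to_p(zc)
  }
  out
}

#' Conditional methylome-wide association
#'
#' Re-evaluates the weighted association Z with conditional GWAS
#' statistics (given the stepwise-selected known-signal variants) in
#' place of the marginal ones.
#'
#' @param model A `prediction_model`.
#' @param gwas GWAS summary data.frame.
#' @param selected Selected conditioning variant ids (possibly empty).
#' @param ld LD matrix covering the model's variants and `selected`.
#' @param ref [reference_moments()] for the model.
#' @param cancer Cancer label.
#' @param ridge Diagonal regularization.
#' @return Association record data.frame (as [mwas_z()]).
#' @export
conditional_mwas <- function(model, gwas, selected, ld, ref,
                             cancer = "cancer", ridge = 1e-6) {
  if (!length(selected)) return(mwas_z(model, gwas, ref, cancer))
  targets <- intersect(model$weights$variant_id, gwas$variant)
  if (!length(targets)) return(mwas_z(model, gwas, ref, cancer))
  cond <- conditional_stats(targets, selected, gwas, ld, ridge)
  g2 <- gwas
  i <- match(cond$variant, g2$variant)
  g2$beta[i] <- cond$beta
  g2$se[i] <- cond$se
  mwas_z(model, g2, ref, cancer)
}

#' Classify a CpG's distance-based novelty
#'
#' Distance to the nearest known GWAS hit on the same chromosome;
#' `putative_novel` when strictly greater than 1 Mb (or no hit on the
#' chromosome).
#'
#' @param cpg_chrom,cpg_pos CpG coordinates.
#' @param known_hits data.frame with `chrom`, `pos` (and optionally
#'   `variant_id`).
#' @param novel_bp Distance threshold (1 Mb).
#' @return data.frame: nearest_known_variant, distance_bp, class.
#' @export
classify_novelty <- function(cpg_chrom, cpg_pos, known_hits,
                             novel_bp = 1e6) {
  chrom <- sub("^chr", "", as.character(cpg_chrom))
  hits <- known_hits[sub("^chr", "", as.character(known_hits$chrom)) ==
                       chrom, , drop = FALSE]
  if (!nrow(hits)) {
    return(data.frame(nearest_known_variant = NA_character_,
                      distance_bp = Inf, class = "putative_novel",
                      stringsAsFactors = FALSE))
  }
  d <- abs(hits$pos - cpg_pos)
  k <- which.min(d)
  data.frame(
    nearest_known_variant =
      if ("variant_id" %in% names(hits)) hits$variant_id[k]
      else sprintf("%s:%d", chrom, hits$pos[k]),
    distance_bp = d[k],
    class = if (d[k] > novel_bp) "putative_novel" else "known_locus",
    stringsAsFactors = FALSE)
}
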