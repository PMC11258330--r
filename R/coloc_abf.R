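# Approximate-Bayes-factor colocalization of CpG methylation and GWAS
# signals over a cis region, with moderate/high PP.H4 tiers.

#' Wakefield approximate log Bayes factor
#'
#' For a variant with effect `beta`, standard error `se` and prior effect
#' variance `W`: with `V = se^2`, `r = W/(V+W)`, `z = beta/se`,
#' `log ABF = 0.5 * (log(1 - r) + r * z^2)`.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), positive.
#' @param W Prior variance of the true effect (0.15^2 for quantitative
#'   traits, 0.2^2 for case-control log-odds, the cited method's defaults).
#' @return log ABF vector.
#' @export
wakefield_log_abf <- function(beta, se, W = 0.15^2) {
  if (any(se <= 0)) stopf("se must be positive")
  if (W < 0) stopf("prior variance W must be non-negative")
  V <- se^2
  r <- W / (V + W)
  z <- beta / se
  0.5 * (log1p(-r) + r * z^2)
}

#' Colocalization posteriors from two log-ABF vectors
#'
#' Single-causal-variant colocalization: per-hypothesis evidence is
#' accumulated by log-sum-exp over single-variant configurations (H1, H2,
#' H4) and over ordered variant pairs excluding the diagonal (H3), with
#' prior per-variant probabilities `p1`, `p2` (trait-specific causal) and
#' `p12` (shared causal). Posteriors are normalized and a tier is
#' assigned from PP.H4 (`high` > 0.80, `moderate` > 0.50, else `none`;
#' strict).
#'
#' @param labf1,labf2 Equal-length log-ABF vectors over the same variants
#'   (trait 1 = methylation, trait 2 = cancer).
#' @param p1,p2,p12 Prior probabilities.
#' @return A `coloc_result` list: `pp` (named H0..H4), `n_variants`,
#'   `priors`, `tier`.
#' @export
coloc_posteriors <- function(labf1, labf2, p1 = 1e-4, p2 = 1e-4,
                             p12 = 1e-5) {
  if (length(labf1) != length(labf2)) stopf("log-ABF length mismatch")
  if (!length(labf1)) stopf("need at least one variant")
  s1 <- logsumexp(labf1)
  s2 <- logsumexp(labf2)
  s12 <- logsumexp(labf1 + labf2)
  # sum over i != j of exp(l1_i + l2_j) = exp(s1 + s2) - exp(s12)
  if (length(labf1) == 1L) {
    l_h3 <- -Inf
  } else {
    m <- max(s1 + s2, s12)
    diff <- exp(s1 + s2 - m) - exp(s12 - m)
    l_h3 <- if (diff <= 0) -Inf else m + log(diff)
  }
  lw <- c(H0 = 0,
          H1 = log(p1) + s1,
          H2 = log(p2) + s2,
          H3 = log(p1) + log(p2) + l_h3,
          H4 = log(p12) + s12)
  pp <- exp(lw - logsumexp(lw))
  pp <- pp / sum(pp)
  structure(list(pp = pp, n_variants = length(labf1),
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 tier = classify_tier(pp[["H4"]])),
            class = "coloc_result")
}

#' Colocalization tier from PP.H4
#'
#' `high` when PP.H4 > 0.80, `moderate` when 0.50 < PP.H4 <= 0.80,
#' `none` otherwise (strict inequalities).
#'
#' @param pp_h4 Posterior probability of a shared causal variant.
#' @return One of `"none"`, `"moderate"`, `"high"`.
#' @export
classify_tier <- function(pp_h4) {
  stopifnot(pp_h4 >= 0, pp_h4 <= 1)
  if (pp_h4 > 0.80) "high" else if (pp_h4 > 0.50) "moderate" else "none"
}

#' Colocalize a CpG's cis-mQTL and GWAS statistics
#'
#' Convenience wrapper: computes Wakefield log ABFs for both traits over
#' the shared variant list and runs [coloc_posteriors()].
#'
#' @param cpg_stats data.frame (variant_id, beta, se) of marginal cis-mQTL
#'   regressions.
#' @param gwas GWAS summary data.frame restricted to the same region.
#' @param W1,W2 Prior effect variances (quantitative, case-control).
#' @param p1,p2,p12 Priors.
#' @return A `coloc_result`.
#' @export
coloc_region <- function(cpg_stats, gwas, W1 = 0.15^2, W2 = 0.2^2,
                         p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  i <- match(cpg_stats$variant_id, gwas$variant)
  ok <- !is.na(i)
  if (!any(ok)) stopf("no shared variants between cpg_stats and gwas")
  l1 <- wakefield_log_abf(cpg_stats$beta[ok], cpg_stats$se[ok], W1)
  l2 <- wakefield_log_abf(gwas$beta[i[ok]], gwas$se[i[ok]], W2)
  coloc_posteriors(l1, l2, p1, p2, p12)
}
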