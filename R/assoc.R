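# Summary-statistics association of genetically predicted methylation
# with cancer risk: harmonization, the weighted Z statistic, effect-size
# back-transforms, Bonferroni gating.

#' Reference moments for a prediction model
#'
#' Per-variant dosage standard deviations and the standard deviation of
#' the model-predicted methylation over the reference panel. The predicted
#' value's SD is computed from `X %*% W`, so it captures LD between model
#' variants.
#'
#' @param model A `prediction_model`.
#' @param geno Reference `genotype_matrix`.
#' @return List: `sigma_s` (named per variant), `sigma_m`, `n_ref`.
#' @export
reference_moments <- function(model, geno) {
  if (!nrow(model$weights))
    return(list(sigma_s = numeric(0), sigma_m = 0, n_ref = nrow(geno$dosage)))
  idx <- match(model$weights$variant_id, geno$variants$variant_id)
  if (anyNA(idx)) stopf("model variant(s) absent from the reference panel")
  X <- geno$dosage[, idx, drop = FALSE]
  if (anyNA(X)) {
    cm <- colMeans(X, na.rm = TRUE)
    ii <- which(is.na(X), arr.ind = TRUE)
    X[ii] <- cm[ii[, 2]]
  }
  sigma_s <- apply(X, 2, stats::sd)
  names(sigma_s) <- model$weights$variant_id
  list(sigma_s = sigma_s,
       sigma_m = stats::sd(as.vector(X %*% model$weights$weight)),
       n_ref = nrow(geno$dosage))
}

#' Harmonize model weights with GWAS summary statistics
#'
#' Matches model variants into the GWAS table by id. Matching effect
#' alleles keep the GWAS beta; swapped alleles negate beta and reflect the
#' frequency; entirely mismatched or palindromic pairs are dropped with a
#' logged reason.
#'
#' @param model A `prediction_model`.
#' @param gwas GWAS summary data.frame (variant, effect_allele,
#'   other_allele, freq, beta, se, ...).
#' @return List: `pairs` (data.frame: variant_id, weight, beta, se, freq)
#'   and `dropped` (variant_id, reason).
#' @export
harmonize <- function(model, gwas) {
  w <- model$weights
  drop <- data.frame(variant_id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  if (!nrow(w))
    return(list(pairs = data.frame(variant_id = character(0),
                                   weight = numeric(0), beta = numeric(0),
                                   se = numeric(0), freq = numeric(0)),
                dropped = drop))
  i <- match(w$variant_id, gwas$variant)
  keep <- logical(nrow(w)); beta <- se <- freq <- numeric(nrow(w))
  for (k in seq_len(nrow(w))) {
    if (is.na(i[k])) {
      drop <- rbind(drop, data.frame(variant_id = w$variant_id[k],
                                     reason = "absent from GWAS"))
      next
    }
    g <- gwas[i[k], ]
    if (.is_palindromic(w$effect_allele[k], w$other_allele[k])) {
      drop <- rbind(drop, data.frame(variant_id = w$variant_id[k],
                                     reason = "palindromic"))
      next
    }
    if (w$effect_allele[k] == g$effect_allele &&
        w$other_allele[k] == g$other_allele) {
      keep[k] <- TRUE; beta[k] <- g$beta; se[k] <- g$se; freq[k] <- g$freq
    } else if (w$effect_allele[k] == g$other_allele &&
               w$other_allele[k] == g$effect_allele) {
      keep[k] <- TRUE; beta[k] <- -g$beta; se[k] <- g$se
      freq[k] <- 1 - g$freq
    } else {
      drop <- rbind(drop, data.frame(variant_id = w$variant_id[k],
                                     reason = "allele mismatch"))
    }
  }
  list(pairs = data.frame(variant_id = w$variant_id[keep],
                          weight = w$weight[keep], beta = beta[keep],
                          se = se[keep], freq = freq[keep],
                          stringsAsFactors = FALSE),
       dropped = drop)
}

#' Two-sided p-value from a Z score
#'
#' `2 * Phi(-|z|)` evaluated on the log scale so extreme scores (|z| well
#' past double-precision tail underflow of the naive formula) remain
#' accurate.
#'
#' @param z Z score(s).
#' @return Two-sided p-value(s).
#' @export
z_to_p <- function(z) {
  exp(pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2))
}

#' Methylome-wide association Z score from summary statistics
#'
#' The weighted statistic
#' `Z_m = sum_s W_{S-m} * (sigma_S / sigma_m) * (beta_S / se(beta_S))`
#' over the model's harmonized variants, where `sigma_S` is the reference
#' dosage SD of variant S and `sigma_m` the reference SD of the model's
#' predicted methylation.
#'
#' @param model A `prediction_model`.
#' @param gwas GWAS summary data.frame.
#' @param ref Output of [reference_moments()] for this model.
#' @param cancer Cancer label stored in the record.
#' @return A one-row data.frame (association record): cpg_id, tissue,
#'   cancer, zscore, pvalue, or_per_sd, ci_low, ci_high, n_snps_used,
#'   n_snps_in_model, status.
#' @export
mwas_z <- function(model, gwas, ref, cancer = "cancer") {
  h <- harmonize(model, gwas)
  rec <- data.frame(cpg_id = model$cpg_id, tissue = model$tissue,
                    cancer = cancer, zscore = NA_real_, pvalue = NA_real_,
                    or_per_sd = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, n_snps_used = nrow(h$pairs),
                    n_snps_in_model = nrow(model$weights),
                    status = "ok", stringsAsFactors = FALSE)
  if (!nrow(h$pairs) || ref$sigma_m <= 0) {
    rec$status <- "untestable"
    return(rec)
  }
  ss <- ref$sigma_s[h$pairs$variant_id]
  z <- sum(h$pairs$weight * (ss / ref$sigma_m) *
             (h$pairs$beta / h$pairs$se))
  rec$zscore <- z
  rec$pvalue <- z_to_p(z)
  eo <- effect_or(h$pairs, ss, ref$sigma_m, z)
  rec$or_per_sd <- eo[1]; rec$ci_low <- eo[2]; rec$ci_high <- eo[3]
  rec
}

#' Odds ratio per SD of genetically predicted methylation
#'
#' The effect-size back-transform: `lnOR = sigma_m * sum_s W_s *
#' (sigma_S^2 / sigma_m^2) * beta_S` (log-odds per SD increase in
#' predicted methylation), with `se(lnOR) = lnOR / Z` and a normal 95% CI.
#'
#' @param pairs Harmonized pairs (from [harmonize()]).
#' @param sigma_s Reference dosage SDs for those variants.
#' @param sigma_m Reference SD of predicted methylation.
#' @param z The association Z score (for the CI; consistent sign).
#' @return Numeric `c(or, ci_low, ci_high)`; CI is NA when z = 0.
#' @export
effect_or <- function(pairs, sigma_s, sigma_m, z) {
  lnor <- sigma_m * sum(pairs$weight * (sigma_s^2 / sigma_m^2) * pairs$beta)
  if (z == 0) return(c(exp(lnor), NA_real_, NA_real_))
  se <- abs(lnor / z)
  exp(c(lnor, lnor - 1.96 * se, lnor + 1.96 * se))
}

#' Reconstruct an OR confidence interval from OR and Z
#'
#' Convenience used to check printed tables: `se = |ln OR| / |Z|`,
#' CI `exp(ln OR +/- 1.96 se)`.
#'
#' @param or Odds ratio per SD.
#' @param z Association Z score.
#' @return Numeric `c(ci_low, ci_high)`.
#' @export
or_ci_from_z <- function(or, z) {
  lnor <- log(or)
  se <- abs(lnor / z)
  exp(c(lnor - 1.96 * se, lnor + 1.96 * se))
}

#' Per-cancer Bonferroni threshold and gating
#'
#' Threshold `0.05 / n_models`; associations are flagged significant when
#' `p < threshold` (strict).
#'
#' @param records Association records (data.frame with `pvalue`).
#' @param n_models Number of methylation models tested for this cancer.
#' @param alpha Family-wise error target.
#' @return `records` with a `significant` column; the threshold is
#'   attached as attribute `"threshold"`.
#' @export
bonferroni_gate <- function(records, n_models, alpha = 0.05) {
  if (n_models < 1) stopf("n_models must be >= 1")
  thr <- alpha / n_models
  records$significant <- !is.na(records$pvalue) & records$pvalue < thr
  attr(records, "threshold") <- thr
  records
}
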