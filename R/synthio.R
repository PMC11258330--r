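# Synthetic-data generator: LD-block genotypes, multi-tissue methylation with
# shared/private cis effects, methylation-driven expression, and GWAS summary
# statistics under named scenarios with recorded ground truth.

#' Define a simulation scenario
#'
#' A scenario bundles every tunable of the synthetic world. The named
#' scenarios encode the ground-truth regimes used throughout the test
#' suite:
#' \describe{
#'   \item{shared_causal}{the same cis variant drives both CpG methylation
#'     and the GWAS signal (methylation-mediated, `alpha_med` nonzero).}
#'   \item{ld_distinct}{two distinct variants in LD (|r| >= 0.7) drive
#'     methylation and disease respectively; no mediation.}
#'   \item{null}{methylation is cis-heritable but has no effect on disease;
#'     all GWAS effects are exactly zero.}
#'   \item{mediated_trio}{shared_causal plus a methylation-driven cis gene,
#'     planting a complete variant -> CpG -> gene -> disease chain.}
#' }
#'
#' @param name Scenario name, one of `shared_causal`, `ld_distinct`,
#'   `null`, `mediated_trio`.
#' @param n_ref Reference-panel (training) sample count.
#' @param n_gwas Effective GWAS sample count.
#' @param n_blocks Number of independent LD blocks.
#' @param block_size Variants per block.
#' @param rho Within-block adjacent-variant latent correlation, in `[0,1)`.
#' @param maf_range Range the per-variant minor allele frequency is drawn
#'   from, within `(0, 0.5]`.
#' @param h2_meth Cis-heritability of the methylation latent trait, `[0,1)`.
#' @param k_causal Causal variants per CpG.
#' @param share_frac Fraction of causal effects identical across tissues.
#' @param alpha_med Methylation-to-liability effect (per SD of the latent
#'   methylation trait, log-odds scale).
#' @param gamma_eqtm Methylation-to-expression effect for linked CpG-gene
#'   pairs, expressed as the target correlation (|gamma| < 1).
#' @param cpgs_per_block CpGs simulated per LD block (CpGs cluster within
#'   loci, as on real arrays).
#' @param n_decoy_genes Unlinked genes added per linked gene.
#' @param palindromic_frac Fraction of variants given A/T or C/G allele
#'   pairs, so harmonization code paths are exercised.
#' @param flip_frac Fraction of GWAS rows emitted with swapped
#'   effect/other allele labels (beta negated, freq reflected).
#' @param missing_rate Fraction of dosages set missing in the emitted panel.
#' @param seed Integer run seed; all child streams derive from it.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(name = c("shared_causal", "ld_distinct", "null",
                                  "mediated_trio"),
                         n_ref = 500L, n_gwas = 1e5, n_blocks = 10L,
                         block_size = 50L, rho = 0.85,
                         maf_range = c(0.05, 0.5), h2_meth = 0.3,
                         k_causal = 2L, share_frac = 0.8, alpha_med = 0.15,
                         gamma_eqtm = 0.5, cpgs_per_block = 3L,
                         n_decoy_genes = 3L, palindromic_frac = 0.1,
                         flip_frac = 0.1, missing_rate = 0, seed = 1L) {
  name <- match.arg(name)
  if (n_ref <= 0 || n_blocks <= 0 || block_size <= 0)
    stopf("scenario dimensions must be positive")
  if (rho < 0 || rho >= 1) stopf("rho must lie in [0,1)")
  if (h2_meth < 0 || h2_meth >= 1) stopf("h2_meth must lie in [0,1)")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stopf("maf_range must lie within (0, 0.5]")
  if (n_gwas <= 0) stopf("n_gwas must be positive")
  if (abs(gamma_eqtm) >= 1) stopf("gamma_eqtm is a correlation; |gamma| < 1")
  if (name == "null") alpha_med <- 0
  structure(list(
    name = name, n_ref = as.integer(n_ref), n_gwas = n_gwas,
    n_blocks = as.integer(n_blocks), block_size = as.integer(block_size),
    rho = rho, maf_range = maf_range, h2_meth = h2_meth,
    k_causal = as.integer(k_causal), share_frac = share_frac,
    alpha_med = alpha_med, gamma_eqtm = gamma_eqtm,
    cpgs_per_block = as.integer(cpgs_per_block),
    n_decoy_genes = as.integer(n_decoy_genes),
    palindromic_frac = palindromic_frac, flip_frac = flip_frac,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "sim_scenario")
}

# draw one AR(1) latent block: n x m, corr rho^|i-j|
.ar1_latent <- function(n, m, rho) {
  z <- matrix(rnorm(n * m), n, m)
  if (rho > 0 && m > 1) {
    w <- sqrt(1 - rho^2)
    for (j in 2:m) z[, j] <- rho * z[, j - 1] + w * z[, j]
  }
  z
}

# threshold standard-normal latents into {0,1,2} by HWE genotype frequencies
.latent_to_dosage <- function(z, maf) {
  q <- 1 - maf
  t0 <- qnorm(q^2)                 # below: homozygous major
  t1 <- qnorm(q^2 + 2 * maf * q)   # below: heterozygous
  d <- matrix(0, nrow(z), ncol(z))
  for (j in seq_len(ncol(z))) {
    d[, j] <- (z[, j] >= t0[j]) + (z[, j] >= t1[j])
  }
  d
}

.BASES <- c("A", "C", "G", "T")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Simulate an LD-block genotype panel
#'
#' Dosages in `{0,1,2}` are produced by thresholding a latent multivariate
#' normal with within-block correlation `rho^|i-j|` at Hardy-Weinberg
#' genotype frequencies for a minor allele frequency drawn per variant from
#' `maf_range`. Positions are 1-based, strictly increasing, with blocks
#' spaced 2 Mb apart so cis windows never straddle blocks. The counted
#' (effect) allele is the minor-at-generation allele.
#'
#' @param scenario A [sim_scenario()].
#' @return A `genotype_matrix`: list with `dosage` (sample x variant,
#'   possibly with `NA` under `missing_rate`), `variants` (data.frame:
#'   variant_id, chrom, pos, effect_allele, other_allele, maf, block) and
#'   `samples`.
#' @export
simulate_genotypes <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(child_seed(scenario$seed, "genotypes"))
  n <- scenario$n_ref; B <- scenario$n_blocks; m <- scenario$block_size
  p <- B * m
  maf <- runif(p, scenario$maf_range[1], scenario$maf_range[2])
  dos <- matrix(0, n, p)
  for (b in seq_len(B)) {
    idx <- ((b - 1) * m + 1):(b * m)
    z <- .ar1_latent(n, m, scenario$rho)
    dos[, idx] <- .latent_to_dosage(z, maf[idx])
  }
  # positions: blocks 2 Mb apart, ~1 kb spacing within a block
  pos <- integer(p)
  for (b in seq_len(B)) {
    idx <- ((b - 1) * m + 1):(b * m)
    gaps <- sample(500:1500, m, replace = TRUE)
    pos[idx] <- as.integer((b - 1) * 2000000 + 10000 + cumsum(gaps))
  }
  # alleles: a configurable fraction palindromic (A/T or C/G)
  set.seed(child_seed(scenario$seed, "alleles"))
  pal <- runif(p) < scenario$palindromic_frac
  ea <- character(p); oa <- character(p)
  for (j in seq_len(p)) {
    a <- sample(.BASES, 1)
    ea[j] <- a
    oa[j] <- if (pal[j]) .COMPLEMENT[[a]]
             else sample(setdiff(.BASES, c(a, .COMPLEMENT[[a]])), 1)
  }
  if (scenario$missing_rate > 0) {
    miss <- runif(n * p) < scenario$missing_rate
    dos[miss] <- NA
  }
  variants <- data.frame(
    variant_id = sprintf("rs%06d", seq_len(p)), chrom = "1", pos = pos,
    effect_allele = ea, other_allele = oa,
    maf = pmin(colMeans(dos, na.rm = TRUE) / 2,
               1 - colMeans(dos, na.rm = TRUE) / 2),
    block = rep(seq_len(B), each = m), stringsAsFactors = FALSE
  )
  colnames(dos) <- variants$variant_id
  samples <- sprintf("S%04d", seq_len(n))
  rownames(dos) <- samples
  structure(list(dosage = dos, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' Simulate multi-tissue methylation with a recorded truth ledger
#'
#' Per tissue, each CpG's latent trait is the sum of its causal dosage
#' effects, small fixed covariate effects (sex, platform, batch) and
#' Gaussian noise, rescaled so the cis-genetic fraction of latent variance
#' equals `h2_meth`; the emitted beta value is the inverse-logit of the
#' latent. A `share_frac` fraction of causal effects is identical across
#' tissues, the remainder tissue-private.
#'
#' @param geno A `genotype_matrix`.
#' @param scenario The [sim_scenario()] used to build `geno`.
#' @param n_tissues Number of tissues.
#' @return List with `tissues` (per-tissue list: `beta` CpG x sample,
#'   `latent`, `covariates`, `tissue` label), `cpg_annot` (cpg_id, chrom,
#'   pos, block) and `truth` (a `truth_ledger`).
#' @export
simulate_methylation <- function(geno, scenario, n_tissues = 2L) {
  stopifnot(inherits(geno, "genotype_matrix"))
  if (scenario$h2_meth >= 1) stopf("h2_meth must be < 1")
  if (!nrow(geno$dosage)) stopf("empty genotype panel")
  set.seed(child_seed(scenario$seed, "methylation"))
  B <- scenario$n_blocks; m <- scenario$block_size
  n <- nrow(geno$dosage)
  cpb <- scenario$cpgs_per_block
  n_cpg <- B * cpb
  dos <- geno$dosage
  dos[is.na(dos)] <- rep(colMeans(dos, na.rm = TRUE), each = n)[is.na(dos)]

  cpg_annot <- data.frame(
    cpg_id = sprintf("cg%07d", seq_len(n_cpg)),
    chrom = "1",
    pos = geno$variants$pos[(rep(seq_len(B), each = cpb) - 1) * m +
                              pmin(m, 1 + (seq_len(cpb) - 1) * 3)] + 57L,
    block = rep(seq_len(B), each = cpb), stringsAsFactors = FALSE
  )

  # covariates shared across tissues (same donors), batch per tissue
  set.seed(child_seed(scenario$seed, "covariates"))
  sex <- rbinom(n, 1, 0.5)
  platform <- rbinom(n, 1, 0.3)

  causal <- vector("list", n_cpg)
  tissues <- vector("list", n_tissues)
  lat_store <- array(0, c(n_cpg, n, n_tissues))
  for (k in seq_len(n_cpg)) {
    blk <- cpg_annot$block[k]
    vidx <- sort(sample(((blk - 1) * m + 1):(blk * m),
                        min(scenario$k_causal, m)))
    base_eff <- rnorm(length(vidx), 0, 1)
    shared <- runif(length(vidx)) < scenario$share_frac
    eff_t <- matrix(0, length(vidx), n_tissues)
    for (t in seq_len(n_tissues)) {
      e <- base_eff
      if (any(!shared)) e[!shared] <- rnorm(sum(!shared), 0, 1)
      eff_t[, t] <- e
    }
    causal[[k]] <- list(vidx = vidx, eff = eff_t, shared = shared)
  }

  for (t in seq_len(n_tissues)) {
    batch <- rbinom(n, 1, 0.5)
    covt <- data.frame(sample = geno$samples, sex = sex,
                       platform = platform, batch = batch,
                       stringsAsFactors = FALSE)
    lat <- matrix(0, n_cpg, n,
                  dimnames = list(cpg_annot$cpg_id, geno$samples))
    for (k in seq_len(n_cpg)) {
      ci <- causal[[k]]
      g <- dos[, ci$vidx, drop = FALSE] %*% ci$eff[, t]
      cov_eff <- 0.2 * sex + 0.1 * platform + 0.15 * batch
      vg <- var(as.vector(g))
      # analytic covariate variance so the scale factor is identical
      # across tissues when effects are shared
      vrest <- 0.2^2 * 0.25 + 0.1^2 * 0.21 + 0.15^2 * 0.25 + 1
      s <- if (scenario$h2_meth == 0 || vg < 1e-12) 0 else
        sqrt(scenario$h2_meth / (1 - scenario$h2_meth) * vrest / vg)
      causal[[k]]$eff[, t] <- ci$eff[, t] * s   # latent-scale effect
      lat[k, ] <- as.vector(g) * s + cov_eff + rnorm(n)
    }
    mu <- rnorm(n_cpg, 0, 0.8)
    beta <- plogis(lat + mu)
    tissues[[t]] <- list(tissue = sprintf("tissue%d", t), beta = beta,
                         latent = lat, covariates = covt)
    lat_store[, , t] <- lat
  }

  causal_df <- do.call(rbind, lapply(seq_len(n_cpg), function(k) {
    ci <- causal[[k]]
    do.call(rbind, lapply(seq_len(n_tissues), function(t) data.frame(
      cpg_id = cpg_annot$cpg_id[k],
      variant_id = geno$variants$variant_id[ci$vidx],
      tissue = sprintf("tissue%d", t), effect = ci$eff[, t],
      shared = ci$shared, stringsAsFactors = FALSE)))
  }))

  mediation <- data.frame(
    cpg_id = cpg_annot$cpg_id,
    alpha = if (scenario$name %in% c("shared_causal", "mediated_trio"))
      scenario$alpha_med else 0,
    stringsAsFactors = FALSE)

  # ld_distinct: disease driven by a distinct variant in LD (|r| >= 0.7)
  gwas_direct <- NULL
  if (scenario$name == "ld_distinct") {
    gwas_direct <- do.call(rbind, lapply(seq_len(n_cpg), function(k) {
      ci <- causal[[k]]
      v0 <- ci$vidx[1]
      blk <- cpg_annot$block[k]
      cand <- setdiff(((blk - 1) * m + 1):(blk * m), ci$vidx)
      r <- suppressWarnings(cor(dos[, v0], dos[, cand, drop = FALSE]))
      ok <- cand[!is.na(r) & abs(r) >= 0.7]
      if (!length(ok)) ok <- cand[which.max(abs(r))]
      rr <- abs(r[match(ok, cand)])
      v1 <- ok[which.min(abs(rr - 0.75))]
      sdm <- stats::sd(lat_store[k, , 1])
      data.frame(cpg_id = cpg_annot$cpg_id[k],
                 variant_id = geno$variants$variant_id[v1],
                 partner_of = geno$variants$variant_id[v0],
                 beta = scenario$alpha_med * abs(ci$eff[1, 1]) / max(sdm, 1e-8),
                 stringsAsFactors = FALSE)
    }))
  }

  # mediated_trio: one linked gene per CpG plus decoys (wired by
  # simulate_expression)
  genes <- NULL
  if (scenario$name == "mediated_trio") {
    linked <- data.frame(
      gene_id = sprintf("GENE%04d", seq_len(n_cpg)),
      chrom = "1", tss = cpg_annot$pos + 10000L,
      linked_cpg = cpg_annot$cpg_id, gamma = scenario$gamma_eqtm,
      stringsAsFactors = FALSE)
    nd <- scenario$n_decoy_genes * n_cpg
    decoy <- data.frame(
      gene_id = sprintf("GENE%04d", n_cpg + seq_len(nd)),
      chrom = "1",
      tss = cpg_annot$pos[rep(seq_len(n_cpg), scenario$n_decoy_genes)] +
        sample(c(-1L, 1L), nd, TRUE) * sample(20000:400000, nd, TRUE),
      linked_cpg = NA_character_, gamma = 0, stringsAsFactors = FALSE)
    genes <- rbind(linked, decoy)
    genes <- genes[order(genes$tss), ]
    rownames(genes) <- NULL
  }

  truth <- structure(list(
    causal_variants = causal_df, true_mediation = mediation,
    gwas_direct = gwas_direct, genes = genes,
    disease_tissue = "tissue1", scenario = scenario), class = "truth_ledger")
  list(tissues = tissues, cpg_annot = cpg_annot, truth = truth)
}

# dosage-scale causal log-odds effects implied by the truth ledger
# (disease tissue; mediation alpha applies per SD of the latent trait)
.causal_log_odds <- function(geno, truth) {
  sc <- truth$scenario
  p <- nrow(geno$variants)
  delta <- numeric(p)
  if (!is.null(truth$gwas_direct)) {
    i <- match(truth$gwas_direct$variant_id, geno$variants$variant_id)
    ok <- !is.na(i)   # causal variants may have been removed by QC
    delta[i[ok]] <- delta[i[ok]] + truth$gwas_direct$beta[ok]
    return(delta)
  }
  cv <- truth$causal_variants
  cv <- cv[cv$tissue == truth$disease_tissue, , drop = FALSE]
  med <- truth$true_mediation
  if (!nrow(cv)) return(delta)
  # scale: alpha is per SD of latent; latent has residual var 1 + covar,
  # total sd ~= sqrt(1/(1-h2)*(1+var_cov)); use the analytic latent sd
  for (k in seq_len(nrow(med))) {
    a <- med$alpha[k]
    if (a == 0) next
    rows <- cv[cv$cpg_id == med$cpg_id[k], , drop = FALSE]
    i <- match(rows$variant_id, geno$variants$variant_id)
    ok <- !is.na(i)   # causal variants may have been removed by QC
    delta[i[ok]] <- delta[i[ok]] + a * rows$effect[ok]
  }
  delta
}

#' Simulate GWAS summary statistics
#'
#' Analytic mode (the default) propagates the truth ledger's causal
#' log-odds effects to every variant through the reference panel's LD
#' (`beta_s = sum_c cor-weighted effects`), sets
#' `se = 1/sqrt(n_gwas * 2 p (1-p))`, and draws `beta-hat ~ N(beta, se^2)`
#' with LD-correlated noise across variants within a block (marginal
#' estimates from a single cohort are LD-correlated). Cohort mode simulates
#' an individual-level quantitative liability `y = G delta + e` on a fresh
#' genotype cohort and computes per-variant marginal regressions; it exists
#' as the individual-level oracle and additionally returns the cohort.
#'
#' @param geno Reference `genotype_matrix`.
#' @param truth A `truth_ledger` from [simulate_methylation()].
#' @param scenario The scenario.
#' @param method `"analytic"` or `"cohort"`.
#' @param keep_cohort If TRUE (cohort mode), attach the simulated cohort.
#' @return A data.frame (GWAS summary: variant, chrom, pos, effect_allele,
#'   other_allele, freq, beta, se, p, N); cohort mode with `keep_cohort`
#'   adds attribute `cohort` = list(G, y).
#' @export
simulate_gwas <- function(geno, truth, scenario,
                          method = c("analytic", "cohort"),
                          keep_cohort = FALSE) {
  method <- match.arg(method)
  if (scenario$n_gwas <= 0) stopf("n_gwas must be positive")
  set.seed(child_seed(scenario$seed, "gwas"))
  v <- geno$variants
  p <- nrow(v)
  dos <- geno$dosage
  dos[is.na(dos)] <- rep(colMeans(dos, na.rm = TRUE),
                         each = nrow(dos))[is.na(dos)]
  delta <- .causal_log_odds(geno, truth)
  freq <- colMeans(dos) / 2
  n_eff <- scenario$n_gwas

  if (method == "analytic") {
    beta <- numeric(p)
    se <- 1 / sqrt(n_eff * 2 * freq * (1 - freq))
    zn <- numeric(p)
    for (b in unique(v$block)) {
      idx <- which(v$block == b)
      G <- dos[, idx, drop = FALSE]
      if (any(delta[idx] != 0)) {
        S <- stats::cov(G)
        beta[idx] <- as.vector(S %*% delta[idx]) / pmax(diag(S), 1e-12)
      }
      R <- suppressWarnings(stats::cor(G))
      R[is.na(R)] <- 0; diag(R) <- 1
      # exact-LD noise: a diagonal ridge would add an uncorrelated noise
      # component that does not cancel in LD-canceling weighted sums and
      # visibly inflates downstream association statistics
      L <- tryCatch(chol(R), error = function(e) NULL)
      if (is.null(L)) {
        ei <- eigen(R, symmetric = TRUE)
        L <- t(ei$vectors %*% (sqrt(pmax(ei$values, 0)) * t(ei$vectors)))
      }
      zn[idx] <- as.vector(t(L) %*% rnorm(length(idx)))
    }
    bhat <- beta + se * zn
  } else {
    sc2 <- scenario; sc2$seed <- child_seed(scenario$seed, "gwas")
    sc2$n_ref <- as.integer(n_eff); sc2$missing_rate <- 0
    cohort <- simulate_genotypes(sc2)
    # align to the (possibly QC-filtered) reference panel's variants
    G <- cohort$dosage[, match(v$variant_id, cohort$variants$variant_id),
                       drop = FALSE]
    y <- as.vector(G %*% delta) + rnorm(nrow(G))
    n <- nrow(G)
    gm <- colMeans(G); vy <- var(y)
    vg <- apply(G, 2, var)
    cy <- as.vector(crossprod(scale(G, center = TRUE, scale = FALSE),
                              y - mean(y))) / (n - 1)
    bhat <- cy / pmax(vg, 1e-12)
    sig2 <- pmax(vy - bhat * cy, 1e-12) * (n - 1) / (n - 2)
    se <- sqrt(sig2 / (vg * (n - 1)))
    freq <- gm / 2
    n_eff <- n
  }
  pval <- 2 * pnorm(-abs(bhat / se))
  out <- data.frame(
    variant = v$variant_id, chrom = v$chrom, pos = v$pos,
    effect_allele = v$effect_allele, other_allele = v$other_allele,
    freq = freq, beta = bhat, se = se, p = pval, N = n_eff,
    stringsAsFactors = FALSE)
  # emit a fraction with swapped allele labels (harmonization exercise)
  if (scenario$flip_frac > 0) {
    fl <- runif(p) < scenario$flip_frac
    out$beta[fl] <- -out$beta[fl]
    out$freq[fl] <- 1 - out$freq[fl]
    tmp <- out$effect_allele[fl]
    out$effect_allele[fl] <- out$other_allele[fl]
    out$other_allele[fl] <- tmp
  }
  rownames(out) <- NULL
  if (method == "cohort" && keep_cohort)
    attr(out, "cohort") <- list(G = G, y = y)
  out
}

#' Simulate a methylation-driven expression matrix
#'
#' For CpG-gene pairs linked in the truth ledger, the inverse-normal-scale
#' expression value is `gamma * std(latent methylation) + sqrt(1-gamma^2) *
#' noise`, so `gamma` is the generative correlation; unlinked genes are
#' pure noise. Raw read counts (Poisson around a lognormal per-gene depth)
#' and TPM-like values are also emitted for gene-filter testing.
#'
#' @param meth Result of [simulate_methylation()].
#' @param truth The `truth_ledger` (defaults to `meth$truth`).
#' @param tissue_index Which tissue's methylation drives expression.
#' @return List: `expr` (gene x sample, normal scale), `counts`, `tpm`,
#'   `gene_annot` (gene_id, chrom, tss, linked_cpg, gamma).
#' @export
simulate_expression <- function(meth, truth = meth$truth, tissue_index = 1L) {
  sc <- truth$scenario
  set.seed(child_seed(sc$seed, "expression"))
  genes <- truth$genes
  if (is.null(genes)) {
    # non-trio scenarios: decoy-only gene set near each CpG
    ca <- meth$cpg_annot
    genes <- data.frame(
      gene_id = sprintf("GENE%04d", seq_len(nrow(ca))), chrom = "1",
      tss = ca$pos + 10000L, linked_cpg = NA_character_,
      gamma = 0, stringsAsFactors = FALSE)
  }
  tis <- meth$tissues[[tissue_index]]
  n <- ncol(tis$beta)
  G <- nrow(genes)
  expr <- matrix(rnorm(G * n), G, n,
                 dimnames = list(genes$gene_id, colnames(tis$beta)))
  for (g in seq_len(G)) {
    if (!is.na(genes$linked_cpg[g]) && genes$gamma[g] != 0) {
      lat <- tis$latent[genes$linked_cpg[g], ]
      z <- (lat - mean(lat)) / stats::sd(lat)
      gam <- genes$gamma[g]
      expr[g, ] <- gam * z + sqrt(1 - gam^2) * rnorm(n)
    }
  }
  base_tpm <- exp(rnorm(G, mean = 1.5, sd = 2))     # some genes < 0.1 TPM
  tpm <- exp(sweep(0.3 * expr, 1, log(base_tpm), "+"))
  depth <- 30
  counts <- matrix(rpois(G * n, lambda = as.vector(tpm) * depth / 10), G, n,
                   dimnames = dimnames(expr))
  list(expr = expr, counts = counts, tpm = tpm, gene_annot = genes)
}

#' Generate a full synthetic input bundle
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_methylation()], [simulate_gwas()] and (for trio scenarios)
#' [simulate_expression()] from one scenario.
#'
#' @param scenario A [sim_scenario()].
#' @param n_tissues Number of methylation tissues.
#' @param gwas_method Passed to [simulate_gwas()].
#' @return List: `geno`, `meth`, `gwas`, `expr` (NULL unless trio),
#'   `truth`, `scenario`.
#' @export
simulate_bundle <- function(scenario, n_tissues = 2L,
                            gwas_method = "analytic") {
  geno <- simulate_genotypes(scenario)
  meth <- simulate_methylation(geno, scenario, n_tissues)
  gwas <- simulate_gwas(geno, meth$truth, scenario, method = gwas_method)
  expr <- if (identical(scenario$name, "mediated_trio"))
    simulate_expression(meth) else NULL
  list(geno = geno, meth = meth, gwas = gwas, expr = expr,
       truth = meth$truth, scenario = scenario)
}
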