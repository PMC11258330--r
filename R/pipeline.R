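# End-to-end orchestration over a synthetic bundle: QC -> normalization ->
# model training -> association -> colocalization -> conditional analysis
# -> eQTM -> trio assembly.

#' Gene-level evidence table implied by a truth ledger
#'
#' For simulation studies: linked genes receive a differential-expression
#' channel whose sign is `sign(gamma) * sign(alpha)` (methylation is the
#' common driver of expression and liability) with a tiny q-value; decoy
#' genes get q = 1.
#'
#' @param truth A `truth_ledger` with a gene table.
#' @param cancer Cancer label.
#' @return data.frame usable as `gene_cancer` evidence (after
#'   [gene_direction()], applied here).
#' @export
synthetic_gene_evidence <- function(truth, cancer = "cancer") {
  genes <- truth$genes
  if (is.null(genes)) stopf("truth ledger has no gene table")
  med <- truth$true_mediation
  a <- med$alpha[match(genes$linked_cpg, med$cpg_id)]
  linked <- !is.na(genes$linked_cpg) & genes$gamma != 0 &
    !is.na(a) & a != 0
  ev <- data.frame(
    gene_id = genes$gene_id, cancer = cancer,
    diffexpr_logfc = ifelse(linked, sign(genes$gamma) * sign(ifelse(is.na(a), 0, a)), 0),
    diffexpr_q = ifelse(linked, 1e-6, 1),
    stringsAsFactors = FALSE)
  gene_direction(ev)
}

#' Known GWAS hits implied by a truth ledger
#'
#' The disease-driving variants (mediation causal variants, or the LD
#' partners in the `ld_distinct` scenario), as a known-hits table for the
#' conditional stage.
#'
#' @param geno The `genotype_matrix`.
#' @param truth A `truth_ledger`.
#' @return data.frame: variant_id, chrom, pos.
#' @export
truth_known_hits <- function(geno, truth) {
  ids <- if (!is.null(truth$gwas_direct)) {
    unique(truth$gwas_direct$variant_id)
  } else {
    med <- truth$true_mediation
    cpgs <- med$cpg_id[med$alpha != 0]
    cv <- truth$causal_variants
    unique(cv$variant_id[cv$cpg_id %in% cpgs &
                           cv$tissue == truth$disease_tissue])
  }
  v <- geno$variants
  i <- match(ids, v$variant_id)
  data.frame(variant_id = ids, chrom = v$chrom[i], pos = v$pos[i],
             stringsAsFactors = FALSE)[!is.na(i), , drop = FALSE]
}

# normalized residual matrix for training: inverse-normal per CpG, then
# residualize on covariates (+ genetic PCs + methylation hidden factors)
.train_residuals <- function(tis, geno, k_pc = 5, k_hidden = 5) {
  beta <- tis$beta
  inb <- t(apply(beta, 1, inverse_normal))
  dimnames(inb) <- dimnames(beta)
  covar <- as.matrix(tis$covariates[, setdiff(names(tis$covariates),
                                              "sample"), drop = FALSE])
  if (k_pc > 0 && nrow(geno$dosage) > k_pc + 1) {
    d <- geno$dosage
    if (anyNA(d)) {
      cm <- colMeans(d, na.rm = TRUE)
      ii <- which(is.na(d), arr.ind = TRUE)
      d[ii] <- cm[ii[, 2]]
    }
    pc <- stats::prcomp(d, rank. = k_pc)$x
    colnames(pc) <- paste0("PC", seq_len(ncol(pc)))
    covar <- cbind(covar, pc)
  }
  if (k_hidden > 0 && k_hidden < min(dim(inb))) {
    hf <- hidden_factors(inb, k_hidden)
    covar <- cbind(covar, hf)
  }
  residualize(inb, covar)
}

#' Run the full analysis pipeline on a synthetic scenario
#'
#' Executes, in order: genotype simulation and QC, per-tissue methylation
#' normalization and residualization, model training (elastic net and,
#' with >= 2 tissues, the cross-tissue method) with per-CpG model
#' selection, association against the simulated GWAS with per-cancer
#' Bonferroni gating, colocalization of significant CpGs, stepwise
#' conditional analysis against known hits with novelty classification,
#' the eQTM scan (trio scenarios), and trio assembly. A manifest of
#' per-stage counts is attached.
#'
#' @param scenario A [sim_scenario()].
#' @param n_tissues Tissues to simulate.
#' @param methods Training methods to run (subset of `"elastic_net"`,
#'   `"cross_tissue"`).
#' @param k_pc,k_hidden Genetic-PC and hidden-factor covariate counts.
#' @param known_hits Known-hits table; `NULL` derives it from the truth
#'   ledger (empty for the null scenario).
#' @param cancer Cancer label.
#' @param out_dir If non-NULL, stage outputs are written there as TSVs.
#' @return List: `models`, `selected`, `assoc`, `coloc`, `conditional`,
#'   `novelty`, `eqtm`, `trios`, `truth`, `manifest`.
#' @export
run_pipeline <- function(scenario, n_tissues = 2L,
                         methods = c("elastic_net", "cross_tissue"),
                         k_pc = 5, k_hidden = 5, known_hits = NULL,
                         cancer = "cancer", out_dir = NULL) {
  bundle <- simulate_bundle(scenario, n_tissues = n_tissues)
  geno <- filter_variants(bundle$geno)
  manifest <- list(seed = scenario$seed, scenario = scenario$name,
                   n_variants_raw = ncol(bundle$geno$dosage),
                   n_variants_qc = ncol(geno$dosage))
  meth <- bundle$meth
  gwas <- bundle$gwas
  truth <- bundle$truth
  ca <- meth$cpg_annot

  # training: disease tissue models are carried to association
  res_by_tissue <- lapply(meth$tissues, .train_residuals, geno = geno,
                          k_pc = k_pc, k_hidden = k_hidden)
  models <- list()
  selected <- list()
  for (k in seq_len(nrow(ca))) {
    idx <- cis_variants(geno, ca$chrom[k], ca$pos[k])
    if (!length(idx)) next
    X <- geno$dosage[, idx, drop = FALSE]
    vi <- geno$variants[idx, , drop = FALSE]
    cand <- list()
    if ("elastic_net" %in% methods) {
      for (t in seq_along(meth$tissues)) {
        m <- train_elastic_net(res_by_tissue[[t]][k, ], X, vi,
                               seed = scenario$seed,
                               cpg_id = ca$cpg_id[k],
                               tissue = meth$tissues[[t]]$tissue)
        models <- c(models, list(m))
        if (t == 1L) cand <- c(cand, list(m))
      }
    }
    if ("cross_tissue" %in% methods && length(meth$tissues) >= 2) {
      yb <- lapply(res_by_tissue, function(r) r[k, ])
      names(yb) <- vapply(meth$tissues, `[[`, character(1), "tissue")
      ct <- train_cross_tissue(yb, rep(list(X), length(yb)), vi,
                               seed = scenario$seed,
                               cpg_id = ca$cpg_id[k])
      models <- c(models, unname(ct))
      if (names(yb)[1] %in% names(ct))
        cand <- c(cand, list(ct[[names(yb)[1]]]))
    }
    sel <- select_model(cand)
    if (!is.null(sel)) selected <- c(selected, list(sel))
  }
  manifest$n_models <- length(models)
  manifest$n_reliable_selected <- length(selected)

  # association + Bonferroni over the per-cancer model count
  assoc <- do.call(rbind, lapply(selected, function(m)
    mwas_z(m, gwas, reference_moments(m, geno), cancer)))
  if (is.null(assoc)) {
    assoc <- bonferroni_gate(
      data.frame(cpg_id = character(0), tissue = character(0),
                 cancer = character(0), zscore = numeric(0),
                 pvalue = numeric(0), or_per_sd = numeric(0),
                 ci_low = numeric(0), ci_high = numeric(0),
                 n_snps_used = integer(0), n_snps_in_model = integer(0),
                 status = character(0)), 1)
  } else {
    assoc <- bonferroni_gate(assoc, max(length(selected), 1))
  }
  manifest$n_significant <- sum(assoc$significant)

  # colocalization for significant CpG-cancer pairs
  coloc <- NULL
  sig <- assoc[assoc$significant, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    k <- match(sig$cpg_id[i], ca$cpg_id)
    idx <- cis_variants(geno, ca$chrom[k], ca$pos[k])
    cst <- cis_marginal_stats(res_by_tissue[[1]][k, ],
                              geno$dosage[, idx, drop = FALSE])
    cst$variant_id <- geno$variants$variant_id[idx]
    cr <- coloc_region(cst, gwas)
    coloc <- rbind(coloc, data.frame(
      cpg_id = sig$cpg_id[i], cancer = cancer,
      pp_h0 = cr$pp[["H0"]], pp_h1 = cr$pp[["H1"]], pp_h2 = cr$pp[["H2"]],
      pp_h3 = cr$pp[["H3"]], pp_h4 = cr$pp[["H4"]],
      n_variants = cr$n_variants, tier = cr$tier,
      stringsAsFactors = FALSE))
  }
  manifest$n_coloc_high <- if (is.null(coloc)) 0L
    else sum(coloc$tier == "high")

  # conditional analysis and novelty against known hits
  if (is.null(known_hits)) known_hits <- truth_known_hits(geno, truth)
  conditional <- NULL; novelty <- NULL
  for (i in seq_len(nrow(sig))) {
    k <- match(sig$cpg_id[i], ca$cpg_id)
    nov <- classify_novelty(ca$chrom[k], ca$pos[k], known_hits)
    novelty <- rbind(novelty, cbind(cpg_id = sig$cpg_id[i], nov))
    m <- selected[[match(sig$cpg_id[i],
                         vapply(selected, `[[`, character(1), "cpg_id"))]]
    if (nrow(known_hits) && is.finite(nov$distance_bp)) {
      hit <- known_hits[which.min(abs(known_hits$pos - ca$pos[k])), ]
      locus <- gwas[gwas$chrom == hit$chrom &
                      abs(gwas$pos - hit$pos) <= 1e6, , drop = FALSE]
      ids <- union(locus$variant, m$weights$variant_id)
      ld <- ld_matrix(geno, intersect(ids, geno$variants$variant_id))
      sel_v <- stepwise_select(locus[locus$variant %in% rownames(ld), ],
                               ld)
      rec <- conditional_mwas(m, gwas, sel_v, ld,
                              reference_moments(m, geno), cancer)
    } else {
      rec <- sig[i, setdiff(names(sig), "significant"), drop = FALSE]
      sel_v <- character(0)
    }
    rec$n_conditioned <- length(sel_v)
    conditional <- rbind(conditional, rec)
  }
  if (!is.null(conditional))
    conditional <- bonferroni_gate(conditional, max(length(selected), 1))
  manifest$n_conditional_significant <-
    if (is.null(conditional)) 0L else sum(conditional$significant)

  # eQTM + trios (scenarios with an expression layer)
  eqtm <- NULL; trios <- NULL
  if (!is.null(bundle$expr)) {
    expr_n <- quantile_normalize_samples(bundle$expr$tpm)
    expr_n <- t(apply(expr_n, 1, inverse_normal))
    dimnames(expr_n) <- dimnames(bundle$expr$tpm)
    keep_g <- filter_genes(bundle$expr$counts, bundle$expr$tpm)
    expr_n <- expr_n[rownames(expr_n) %in% keep_g, , drop = FALSE]
    meth_n <- quantile_normalize_samples(meth$tissues[[1]]$beta)
    meth_n <- t(apply(meth_n, 1, inverse_normal))
    dimnames(meth_n) <- dimnames(meth$tissues[[1]]$beta)
    ga <- bundle$expr$gene_annot
    ga <- ga[ga$gene_id %in% keep_g, , drop = FALSE]
    eqtm <- eqtm_scan(meth_n, expr_n, ca, ga,
                      tissue = meth$tissues[[1]]$tissue)
    gene_ev <- synthetic_gene_evidence(truth, cancer)
    trios <- assemble_trios(assoc, eqtm, gene_ev)
    manifest$n_eqtm_significant <- sum(eqtm$q < 0.05)
    manifest$n_trios_consistent <- sum(trios$consistent)
  }

  out <- list(geno = geno, models = models, selected = selected,
              assoc = assoc, coloc = coloc, conditional = conditional,
              novelty = novelty, eqtm = eqtm, trios = trios,
              truth = truth, manifest = manifest)
  if (!is.null(out_dir)) .write_pipeline_outputs(out, out_dir, scenario)
  out
}

.write_pipeline_outputs <- function(out, out_dir, scenario) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_scenario(scenario, file.path(out_dir, "scenario.txt"))
  write_model_store(out$models, file.path(out_dir, "models"))
  tsv <- function(x, f) if (!is.null(x))
    data.table::fwrite(x, file.path(out_dir, f), sep = "\t", quote = FALSE)
  tsv(out$assoc, "associations.tsv")
  tsv(out$coloc, "coloc.tsv")
  tsv(out$conditional, "conditional.tsv")
  tsv(out$novelty, "novelty.tsv")
  tsv(out$eqtm, "eqtm.tsv")
  tsv(out$trios, "trios.tsv")
  man <- out$manifest
  writeLines(vapply(names(man), function(k)
    paste0(k, ": ", paste(man[[k]], collapse = ",")), character(1)),
    file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
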