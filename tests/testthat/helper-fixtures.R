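# Shared helpers: hand-built genotype panels and normalized methylation
# residuals used across test files.

# a genotype_matrix built directly from a dosage matrix
make_panel <- function(dosage, pos = NULL, chrom = "1",
                       effect_allele = NULL, other_allele = NULL) {
  p <- ncol(dosage)
  v <- data.frame(
    variant_id = colnames(dosage) %||% sprintf("v%03d", seq_len(p)),
    chrom = chrom,
    pos = pos %||% seq(1000, by = 1000, length.out = p),
    effect_allele = effect_allele %||% rep("A", p),
    other_allele = other_allele %||% rep("G", p),
    stringsAsFactors = FALSE)
  af <- colMeans(dosage, na.rm = TRUE) / 2
  v$maf <- pmin(af, 1 - af)
  colnames(dosage) <- v$variant_id
  structure(list(dosage = dosage, variants = v,
                 samples = sprintf("S%04d", seq_len(nrow(dosage)))),
            class = "genotype_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# inverse-normalized, covariate-residualized methylation vector for CpG k
resid_meth <- function(meth, k, tissue = 1) {
  tis <- meth$tissues[[tissue]]
  y <- inverse_normal(tis$beta[k, ])
  covt <- as.matrix(tis$covariates[, setdiff(names(tis$covariates),
                                             "sample"), drop = FALSE])
  as.vector(residualize(matrix(y, 1), covt))
}

# one-row prediction model built by hand
make_model <- function(variant_id, weight, effect_allele = "A",
                       other_allele = "G", cpg_id = "cg1",
                       tissue = "tissue1", cv_R = 0.5, cv_P = 1e-4) {
  w <- data.frame(variant_id = variant_id, effect_allele = effect_allele,
                  other_allele = other_allele, weight = weight,
                  stringsAsFactors = FALSE)
  methwas:::.new_model(cpg_id, tissue, "elastic_net", w, cv_R, cv_P, 100)
}

# minimal GWAS summary table
make_gwas <- function(variant, beta, se, effect_allele = "A",
                      other_allele = "G", freq = 0.3, N = 10000,
                      chrom = "1", pos = NULL) {
  data.frame(variant = variant, chrom = chrom,
             pos = pos %||% seq_along(variant) * 1000,
             effect_allele = effect_allele, other_allele = other_allele,
             freq = freq, beta = beta, se = se,
             p = 2 * pnorm(-abs(beta / se)), N = N,
             stringsAsFactors = FALSE)
}
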