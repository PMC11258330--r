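# Readers and writers for the package's plain-text interchange formats:
# dosage TSV / VCF, matrix TSVs, GWAS summary TSV, model store, scenario
# config.

#' Write a genotype panel as a dosage TSV
#'
#' Columns: variant_id, chrom, pos, effect_allele, other_allele, then one
#' dosage column per sample.
#'
#' @param geno A `genotype_matrix`.
#' @param path Output path.
#' @export
write_dosage_tsv <- function(geno, path) {
  dt <- data.table::data.table(geno$variants[, c("variant_id", "chrom",
                                                 "pos", "effect_allele",
                                                 "other_allele")])
  dos <- t(geno$dosage)
  colnames(dos) <- geno$samples
  data.table::fwrite(cbind(dt, data.table::as.data.table(dos)), path,
                     sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a dosage TSV into a genotype panel
#'
#' @param path Path written by [write_dosage_tsv()].
#' @return A `genotype_matrix`.
#' @export
read_dosage_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  meta <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele")
  if (!all(meta %in% names(dt))) stopf("missing dosage TSV columns")
  samples <- setdiff(names(dt), meta)
  dos <- t(as.matrix(dt[, samples, with = FALSE]))
  colnames(dos) <- dt$variant_id
  rownames(dos) <- samples
  variants <- as.data.frame(dt[, meta, with = FALSE])
  variants$chrom <- sub("^chr", "", as.character(variants$chrom))
  af <- colMeans(dos, na.rm = TRUE) / 2
  variants$maf <- pmin(af, 1 - af)
  structure(list(dosage = dos, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' Write a genotype panel as a VCF with DS dosages
#'
#' Minimal VCF v4.2 with GT (rounded dosage) and DS FORMAT fields.
#'
#' @param geno A `genotype_matrix`.
#' @param path Output path (plain text).
#' @export
write_vcf_dosages <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples), collapse = "\t")), con)
  v <- geno$variants
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(v))) {
    d <- geno$dosage[, j]
    gt <- ifelse(is.na(d), "./.",
                 gt_codes[pmin(pmax(round(d), 0), 2) + 1])
    ds <- ifelse(is.na(d), ".", format(d, trim = TRUE, digits = 6))
    writeLines(paste(c(v$chrom[j], v$pos[j], v$variant_id[j],
                       v$other_allele[j], v$effect_allele[j], ".", "PASS",
                       ".", "GT:DS", paste(gt, ds, sep = ":")),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read dosages from a VCF
#'
#' DS FORMAT values are preferred; GT alt-allele counts are the fallback.
#' The effect allele is ALT. Malformed records are skipped with a count.
#'
#' @param path VCF path (plain text or gzipped).
#' @return A `genotype_matrix`.
#' @export
read_vcf_dosages <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr)) stopf("no #CHROM header line in %s", path)
  cols <- strsplit(lines[hdr[1]], "\t")[[1]]
  samples <- cols[-(1:9)]
  body <- lines[-seq_len(hdr[1])]
  body <- body[nzchar(body)]
  recs <- strsplit(body, "\t")
  ok <- vapply(recs, length, integer(1)) == length(cols)
  skipped <- sum(!ok)
  recs <- recs[ok]
  # drop multi-allelic records
  alt <- vapply(recs, `[[`, character(1), 5)
  multi <- grepl(",", alt)
  skipped <- skipped + sum(multi)
  recs <- recs[!multi]
  if (!length(recs)) stopf("no usable VCF records in %s", path)
  if (skipped) warnf("skipped %d malformed/multi-allelic VCF record(s)",
                     skipped)
  p <- length(recs)
  dos <- matrix(NA_real_, length(samples), p)
  meta <- matrix("", p, 5)
  for (j in seq_len(p)) {
    r <- recs[[j]]
    meta[j, ] <- r[c(1, 2, 3, 4, 5)]
    fmt <- strsplit(r[9], ":")[[1]]
    ids <- which(fmt == "DS")
    igt <- which(fmt == "GT")
    vals <- strsplit(r[-(1:9)], ":")
    if (length(ids)) {
      d <- suppressWarnings(as.numeric(vapply(vals, `[[`, character(1),
                                              ids[1])))
    } else if (length(igt)) {
      gt <- vapply(vals, `[[`, character(1), igt[1])
      d <- vapply(strsplit(gt, "[/|]"), function(a) {
        a <- suppressWarnings(as.numeric(a))
        if (anyNA(a)) NA_real_ else sum(a)
      }, numeric(1))
    } else {
      d <- rep(NA_real_, length(samples))
    }
    dos[, j] <- d
  }
  variants <- data.frame(
    variant_id = meta[, 3], chrom = sub("^chr", "", meta[, 1]),
    pos = as.integer(meta[, 2]), effect_allele = meta[, 5],
    other_allele = meta[, 4], stringsAsFactors = FALSE)
  af <- colMeans(dos, na.rm = TRUE) / 2
  variants$maf <- pmin(af, 1 - af)
  colnames(dos) <- variants$variant_id
  rownames(dos) <- samples
  structure(list(dosage = dos, variants = variants, samples = samples),
            class = "genotype_matrix")
}

.GWAS_ALIASES <- list(
  variant = c("variant", "snp", "rsid", "id", "variant_id", "markername"),
  chrom = c("chrom", "chr", "chromosome"),
  pos = c("pos", "position", "bp", "base_pair_location"),
  effect_allele = c("effect_allele", "a1", "ea", "allele1"),
  other_allele = c("other_allele", "a2", "oa", "allele2", "ref_allele"),
  freq = c("freq", "eaf", "af", "effect_allele_frequency", "frq"),
  beta = c("beta", "b", "effect", "effect_size"),
  se = c("se", "stderr", "standard_error", "sebeta"),
  p = c("p", "pval", "pvalue", "p_value"),
  N = c("n", "samplesize", "n_total"))

#' Read a GWAS summary-statistics TSV
#'
#' Case-insensitive header aliases are mapped to the canonical schema
#' (variant, chrom, pos, effect_allele, other_allele, freq, beta, se, p,
#' N); rows with `se <= 0` or `p` outside (0,1] are dropped with a count.
#'
#' @param path TSV path.
#' @return Validated GWAS summary data.frame; dropped-row count in
#'   attribute `"n_dropped"`.
#' @export
read_gwas <- function(path) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t"))
  lower <- tolower(names(dt))
  out <- list()
  for (canon in names(.GWAS_ALIASES)) {
    hit <- which(lower %in% .GWAS_ALIASES[[canon]])
    if (!length(hit)) {
      if (canon %in% c("variant", "effect_allele", "other_allele",
                       "beta", "se", "p"))
        stopf("required GWAS column '%s' not found", canon)
      out[[canon]] <- NA
    } else {
      out[[canon]] <- dt[[hit[1]]]
    }
  }
  g <- as.data.frame(out, stringsAsFactors = FALSE)
  bad <- !is.finite(g$se) | g$se <= 0 | !is.finite(g$p) | g$p <= 0 |
    g$p > 1
  g <- g[!bad, , drop = FALSE]
  rownames(g) <- NULL
  attr(g, "n_dropped") <- sum(bad)
  g
}

#' Write a model store (PredictDB-like TSV pair)
#'
#' `<prefix>_weights.tsv`: cpg_id, variant_id, effect_allele,
#' other_allele, weight. `<prefix>_extra.tsv`: cpg_id, tissue, method,
#' cv_R, cv_P, n_snps, n_train, reliable.
#'
#' @param models List of `prediction_model`s.
#' @param prefix Output path prefix.
#' @export
write_model_store <- function(models, prefix) {
  w <- do.call(rbind, lapply(models, function(m)
    if (nrow(m$weights)) cbind(cpg_id = m$cpg_id, m$weights) else NULL))
  e <- do.call(rbind, lapply(models, function(m) data.frame(
    cpg_id = m$cpg_id, tissue = m$tissue, method = m$method,
    cv_R = m$cv_R, cv_P = m$cv_P, n_snps = nrow(m$weights),
    n_train = m$n_train, reliable = m$reliable,
    stringsAsFactors = FALSE)))
  data.table::fwrite(w %||% data.frame(), paste0(prefix, "_weights.tsv"),
                     sep = "\t", quote = FALSE)
  data.table::fwrite(e, paste0(prefix, "_extra.tsv"), sep = "\t",
                     quote = FALSE)
  invisible(prefix)
}

#' Read a model store written by [write_model_store()]
#'
#' @param prefix Path prefix.
#' @return List of `prediction_model`s.
#' @export
read_model_store <- function(prefix) {
  w <- as.data.frame(data.table::fread(paste0(prefix, "_weights.tsv")))
  e <- as.data.frame(data.table::fread(paste0(prefix, "_extra.tsv")))
  lapply(seq_len(nrow(e)), function(i) {
    wi <- w[w$cpg_id == e$cpg_id[i], c("variant_id", "effect_allele",
                                       "other_allele", "weight"),
            drop = FALSE]
    rownames(wi) <- NULL
    .new_model(e$cpg_id[i], e$tissue[i], e$method[i], wi, e$cv_R[i],
               e$cv_P[i], e$n_train[i])
  })
}

#' Write a scenario as a flat key:value config file
#'
#' @param scenario A [sim_scenario()].
#' @param path Output path.
#' @export
write_scenario <- function(scenario, path) {
  kv <- vapply(names(scenario), function(k)
    paste0(k, ": ", paste(scenario[[k]], collapse = ",")), character(1))
  writeLines(kv, path)
  invisible(path)
}

#' Read a scenario config written by [write_scenario()]
#'
#' @param path Config path.
#' @return A `sim_scenario`.
#' @export
read_scenario <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines[nzchar(lines)], ":\\s*")
  vals <- lapply(kv, function(x) {
    v <- strsplit(x[2], ",")[[1]]
    n <- suppressWarnings(as.numeric(v))
    if (anyNA(n)) v else n
  })
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  do.call(sim_scenario, vals)
}
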