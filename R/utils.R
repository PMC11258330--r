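#' @useDynLib methwas, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm qnorm rnorm runif rbinom rpois sd var cor cor.test
#'   lm coef pchisq pt t.test p.adjust complete.cases median quantile
#'   rexp plogis qlogis
#' @importFrom utils head
"_PACKAGE"

# Deterministic child seeds: one run seed fans out to per-component streams.
# scheme: child = (seed * 48271 + offset) mod (2^31 - 1), offsets fixed per tag.
.seed_offsets <- c(
  genotypes = 11L, methylation = 23L, gwas = 37L, expression = 41L,
  folds = 53L, covariates = 59L, alleles = 61L, noise = 67L, pipeline = 71L
)

#' Derive a deterministic child seed from a run seed
#'
#' Every stochastic component of the package consumes a child seed derived
#' from the single run seed by a fixed affine map modulo 2^31-1, so that one
#' integer reproduces the whole bundle while components remain decoupled
#' (changing the number of draws in one stage does not shift another stage's
#' stream).
#'
#' @param seed Integer run seed.
#' @param tag One of `names(methwas:::.seed_offsets)`.
#' @return An integer seed in `[1, 2^31-2]`.
#' @keywords internal
child_seed <- function(seed, tag) {
  off <- .seed_offsets[[tag]]
  m <- 2147483647
  x <- (as.numeric(seed) %% m) * 48271 + off
  as.integer(x %% m + 1)
}

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
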