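# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used by
#' the printed diversity tables this package reproduces (base `round()`
#' rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(88.55, 1)  # 88.6, not 88.5
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive a per-stage RNG seed from the study's single master seed so that
# stages can be regenerated independently.  Offsets are fixed primes; the
# result stays below 2^31 - 1 (R integers are 32-bit).
stage_seed <- function(seed, stage, index = 0L) {
  stages <- c("truth", "library", "collection", "sequences", "taxonomy",
              "best_hits", "inoculation", "bootstrap", "effects", "misc")
  i <- match(stage, stages)
  if (is.na(i)) stop("unknown seed stage: ", stage)
  as.integer((as.numeric(seed) + i * 10007 + as.numeric(index) * 131) %%
               2147483647)
}

# Largest-remainder apportionment of n among probabilities p: the
# deterministic ("noiseless") counterpart of a multinomial draw.  Counts sum
# to n exactly and each count is floor(n*p) or floor(n*p)+1.
apportion <- function(p, n) {
  stopifnot(n >= 0, all(p >= 0), sum(p) > 0)
  p <- p / sum(p)
  e <- p * n
  k <- floor(e)
  r <- n - sum(k)
  if (r > 0) {
    extra <- order(e - k, decreasing = TRUE)[seq_len(r)]
    k[extra] <- k[extra] + 1
  }
  as.integer(k)
}

# Validate a square symmetric distance matrix with labelled margins.
check_dist_matrix <- function(m, what = "distance matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(what, " must be a square matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(what, " must have row and column names")
  if (!identical(rownames(m), colnames(m)))
    stop(what, " row and column names differ")
  if (any(!is.finite(m)))
    stop(what, " contains non-finite entries")
  if (any(m < 0))
    stop(what, " contains negative entries")
  if (max(abs(m - t(m))) > 1e-8)
    stop(what, " is not symmetric")
  if (any(abs(diag(m)) > 1e-12))
    stop(what, " has a nonzero diagonal")
  invisible(m)
}

# Natural ordering for ids like "OTU-2" < "OTU-10".
order_otu_ids <- function(ids) {
  num <- suppressWarnings(as.numeric(sub("^.*?(\\d+)$", "\\1", ids)))
  if (any(is.na(num))) order(ids) else order(num, ids)
}
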