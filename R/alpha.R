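# Per-library alpha diversity: observed richness, singletons, Good's
# coverage, Chao1, ACE, Shannon and inverse Simpson.  Formula conventions
# follow the classic clustering tool chain these statistics are usually
# reported from: bias-corrected Chao1, ACE with a rare/abundant split at
# 10, natural-log Shannon, and the unbiased inverse Simpson index.

check_counts <- function(v) {
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("empty abundance vector")
  if (any(v < 0) || any(v != floor(v)))
    stop("abundances must be non-negative integers")
  if (sum(v) == 0) stop("abundance vector sums to zero")
  v[v > 0]
}

#' Good's coverage
#'
#' \eqn{C_x = 1 - n_1/N} where \eqn{n_1} is the number of singletons (OTUs
#' seen exactly once in the library) and N the library size: the estimated
#' fraction of the sampled community captured by the library.
#'
#' @param v integer vector of per-OTU counts for one library.
#' @return coverage in `[0, 1]`.
#' @export
#' @examples
#' goods_coverage(c(20, rep(1, 20), rep(5, 27)))  # toy example
goods_coverage <- function(v) {
  v <- check_counts(v)
  1 - sum(v == 1) / sum(v)
}

#' Bias-corrected Chao1 richness estimate
#'
#' \eqn{S_{chao1} = S_{obs} + n_1(n_1 - 1) / (2 (n_2 + 1))}.
#'
#' @inheritParams goods_coverage
#' @return estimated total richness (>= observed richness).
#' @export
chao1 <- function(v) {
  v <- check_counts(v)
  s <- length(v)
  n1 <- sum(v == 1)
  n2 <- sum(v == 2)
  s + n1 * (n1 - 1) / (2 * (n2 + 1))
}

#' ACE richness estimate
#'
#' Abundance-based coverage estimator with the conventional rare/abundant
#' split at `rare_cutoff` (10).  With no rare OTUs ACE equals the observed
#' richness; if the rare-group coverage is zero (all rare OTUs are
#' singletons) the estimator is undefined and the observed richness is
#' returned with a warning.  The squared coefficient of variation is
#' clamped at zero.
#'
#' @inheritParams goods_coverage
#' @param rare_cutoff counts `<= rare_cutoff` form the rare group.
#' @return estimated total richness.
#' @export
ace <- function(v, rare_cutoff = 10) {
  v <- check_counts(v)
  rare <- v[v <= rare_cutoff]
  s_abund <- sum(v > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0L) return(length(v))
  n_rare <- sum(rare)
  n1 <- sum(rare == 1)
  c_ace <- 1 - n1 / n_rare
  if (c_ace <= 0 || n_rare < 2) {
    warning("ACE undefined (rare-group coverage is zero); returning S_obs")
    return(length(v))
  }
  i <- seq_len(rare_cutoff)
  f <- vapply(i, function(k) sum(rare == k), numeric(1))
  gamma2 <- max(s_rare / c_ace * sum(i * (i - 1) * f) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  s_abund + s_rare / c_ace + n1 / c_ace * gamma2
}

#' Shannon diversity H' (natural log)
#' @inheritParams goods_coverage
#' @return \eqn{H' = -\sum p_i \ln p_i}.
#' @export
shannon <- function(v) {
  v <- check_counts(v)
  p <- v / sum(v)
  -sum(p * log(p))
}

#' Unbiased inverse Simpson index 1/D
#'
#' \eqn{D = \sum n_i (n_i - 1) / (N (N - 1))}; all-singleton libraries make
#' D zero and are signalled as an error of class
#' `beetscreen_simpson_undefined`.
#'
#' @inheritParams goods_coverage
#' @return 1/D, in `[1, Inf)`.
#' @export
inverse_simpson <- function(v) {
  v <- check_counts(v)
  n <- sum(v)
  if (n < 2) stop("inverse Simpson needs a library of at least 2 sequences")
  d <- sum(v * (v - 1)) / (n * (n - 1))
  if (d == 0)
    stop(errorCondition("Simpson D is zero (all OTUs are singletons)",
                        class = c("beetscreen_simpson_undefined", "error",
                                  "condition")))
  1 / d
}

#' Alpha diversity summary per library
#'
#' One row per library with the full statistics block: sequences, observed
#' OTUs, singletons, Good's coverage (percent), Chao1, ACE, Shannon and
#' inverse Simpson.  Values are reported at full precision; use `digits`
#' to reproduce the one-decimal printed style (half away from zero).
#'
#' @param table an `otu_table_bs`.
#' @param digits optional decimal places for the index columns.
#' @return data frame with one row per library.
#' @export
alpha_summary <- function(table, digits = NULL) {
  libs <- table$libraries
  out <- lapply(seq_len(nrow(libs)), function(i) {
    v <- table$counts[, libs$library_id[i]]
    v <- v[v > 0]
    inv <- tryCatch(inverse_simpson(v), error = function(e) NA_real_)
    data.frame(library_id = libs$library_id[i], tissue = libs$tissue[i],
               condition = libs$condition[i], provenance = libs$provenance[i],
               medium = libs$medium[i],
               n_sequences = sum(v), s_obs = length(v),
               n_singletons = sum(v == 1),
               coverage_pct = 100 * goods_coverage(v),
               chao1 = chao1(v), ace = suppressWarnings(ace(v)),
               shannon = shannon(v), inv_simpson = inv,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (!is.null(digits)) {
    num <- c("coverage_pct", "chao1", "ace", "shannon", "inv_simpson")
    out[num] <- lapply(out[num], round_half_up, digits = digits)
  }
  rownames(out) <- NULL
  out
}
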