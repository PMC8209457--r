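# Pairwise evolutionary distances from an alignment and PHYLIP square
# matrix interchange.  Sites where either sequence has a gap ('-', '.') or
# an ambiguous base ('N') are excluded pair by pair ("pairwise deletion");
# 'U' is treated as 'T'.

COMPARABLE_BASES <- c("A", "C", "G", "T")

# character matrix (rows = sequences) from aligned strings
char_matrix <- function(alignment) {
  alignment <- as_alignment(alignment)
  m <- matrix(unlist(strsplit(alignment, "", fixed = TRUE), use.names = FALSE),
              nrow = length(alignment), byrow = TRUE)
  rownames(m) <- names(alignment)
  m[m == "U"] <- "T"
  m
}

jc_transform <- function(p, pair = NULL) {
  if (any(p >= 0.75)) {
    where <- if (is.null(pair)) "" else paste0(" for pair ", pair)
    stop(errorCondition(
      paste0("Jukes-Cantor distance undefined (p >= 0.75)", where),
      class = c("beetscreen_jc_saturation", "error", "condition")))
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Pairwise distance between two aligned sequences
#'
#' Computes the proportion of differing sites over comparable columns
#' (`model = "p"`) or its Jukes-Cantor correction
#' \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)} (`model = "jukes_cantor"`,
#' the default, matching the convention of classic distance tools).
#' Columns where either sequence has a gap or `N` are excluded (pairwise
#' deletion).  A p-distance of 0.75 or more makes the Jukes-Cantor log
#' undefined and is signalled as an error of class
#' `beetscreen_jc_saturation` rather than clamped.
#'
#' @param a,b aligned sequences (equal-length character scalars).
#' @param model `"jukes_cantor"` or `"p"`.
#' @param gap_policy only `"pairwise"` (pairwise deletion) is implemented.
#' @return a single non-negative distance.
#' @export
#' @examples
#' pairwise_distance("ACGT", "ACGA", model = "p")        # 0.25
#' pairwise_distance("AC-T", "ACGT", model = "p")        # 0 (3 comparable)
pairwise_distance <- function(a, b, model = c("jukes_cantor", "p"),
                              gap_policy = "pairwise") {
  model <- match.arg(model)
  gap_policy <- match.arg(gap_policy, "pairwise")
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  ca <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  cb <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  ca[ca == "U"] <- "T"
  cb[cb == "U"] <- "T"
  ok <- ca %in% COMPARABLE_BASES & cb %in% COMPARABLE_BASES
  if (!any(ok)) stop("no comparable (non-gap, non-N) columns")
  p <- mean(ca[ok] != cb[ok])
  if (model == "p") p else jc_transform(p)
}

#' Distance matrix for an alignment
#'
#' Applies [pairwise_distance()] to every pair of rows.  The computation is
#' vectorised through base-indicator cross-products so that alignments of a
#' few thousand sequences remain tractable; a test asserts equality with
#' the literal per-pair loop.
#'
#' @param alignment named character vector of equal-length sequences (or a
#'   character matrix with one row per sequence).
#' @inheritParams pairwise_distance
#' @return symmetric matrix of distances with zero diagonal, labelled by
#'   sequence id.
#' @export
distance_matrix <- function(alignment, model = c("jukes_cantor", "p"),
                            gap_policy = "pairwise") {
  model <- match.arg(model)
  gap_policy <- match.arg(gap_policy, "pairwise")
  m <- if (is.matrix(alignment)) alignment else char_matrix(alignment)
  if (nrow(m) < 2L) stop("alignment must contain at least 2 sequences")
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(m)))
  comp <- matrix(0, nrow(m), ncol(m))
  matches <- matrix(0, nrow(m), nrow(m))
  ind <- m %in% COMPARABLE_BASES
  dim(ind) <- dim(m)
  comp <- ind + 0
  for (b in COMPARABLE_BASES) {
    ab <- (m == b & ind) + 0
    matches <- matches + tcrossprod(ab)
  }
  comparable <- tcrossprod(comp)
  off <- upper.tri(comparable)
  if (any(comparable[off] == 0)) {
    idx <- which(comparable == 0 & off, arr.ind = TRUE)[1, ]
    stop("no comparable columns for pair ", ids[idx[1]], " / ", ids[idx[2]])
  }
  p <- (comparable - matches) / comparable
  p[p < 0] <- 0  # numerical guard
  if (model == "jukes_cantor") {
    if (any(p[off] >= 0.75)) {
      idx <- which(p >= 0.75 & off, arr.ind = TRUE)[1, ]
      jc_transform(p[idx[1], idx[2]],
                   pair = paste(ids[idx[1]], ids[idx[2]], sep = " / "))
    }
    p <- -0.75 * log(1 - 4 * p / 3)
  }
  diag(p) <- 0
  p <- (p + t(p)) / 2
  dimnames(p) <- list(ids, ids)
  p
}

#' Read a PHYLIP square distance matrix
#'
#' Expects the square (full) dialect: a first line with the taxon count,
#' then one row per taxon of `name d1 ... dn` (rows may wrap).  Asymmetric
#' matrices (beyond 1e-6), count mismatches and non-numeric cells are
#' errors.
#'
#' @param path file path.
#' @return symmetric labelled distance matrix.
#' @export
read_phylip_square <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE)
  if (length(tok) < 1L) stop("empty PHYLIP file: ", path)
  n <- suppressWarnings(as.integer(tok[1]))
  if (is.na(n) || n < 1L) stop("invalid taxon count in ", path)
  body <- tok[-1]
  if (length(body) != n * (n + 1L))
    stop("expected ", n * (n + 1L), " tokens for ", n,
         " taxa, found ", length(body))
  rows <- matrix(body, nrow = n, byrow = TRUE)
  ids <- rows[, 1]
  vals <- suppressWarnings(as.numeric(rows[, -1, drop = FALSE]))
  if (any(is.na(vals))) stop("non-numeric distance cell in ", path)
  m <- matrix(vals, nrow = n)
  dimnames(m) <- list(ids, ids)
  if (max(abs(m - t(m))) > 1e-6)
    stop("asymmetric distance matrix in ", path)
  m <- (m + t(m)) / 2
  check_dist_matrix(m)
  m
}

#' Write a PHYLIP square distance matrix
#'
#' Distances are printed with six decimals, which bounds the round-trip
#' error of [read_phylip_square()] at 5e-7.
#'
#' @param matrix symmetric labelled distance matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_phylip_square <- function(matrix, path) {
  check_dist_matrix(matrix)
  ids <- rownames(matrix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(matrix)), con)
  for (i in seq_len(nrow(matrix))) {
    writeLines(paste(formatC(ids[i], width = 10, flag = "-"),
                     paste(sprintf("%.6f", matrix[i, ]), collapse = " ")),
               con)
  }
  invisible(path)
}
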