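#' Read an aligned (or unaligned) FASTA file
#'
#' Sequence ids are taken as the first whitespace-delimited token of each
#' header line.  Residues are uppercased on ingest; only the nucleotide
#' alphabet \code{A C G T U N - .} is accepted.  Duplicate or empty ids and
#' empty records are errors.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == ""))
    stop("FASTA record with an empty id in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L))
    stop("empty FASTA record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  bad <- grepl("[^ACGTUN.-]", seqs)
  if (any(bad))
    stop("non-nucleotide characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  seqs
}

#' Write sequences to FASTA
#'
#' @param records named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (default 60 columns).
#' @return the path, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  if (is.null(names(records)) || any(names(records) == ""))
    stop("all records must be named")
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Assert that records form an alignment (equal, positive lengths) and
# return them unchanged.
as_alignment <- function(records) {
  if (length(records) == 0L) stop("empty alignment")
  len <- unique(nchar(records))
  if (length(len) != 1L)
    stop("alignment rows differ in length (", paste(len, collapse = ", "), ")")
  if (len == 0L) stop("alignment has zero columns")
  records
}
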