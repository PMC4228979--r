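#' Promoter sequence sets
#'
#' Promoters are handled as named upper-case DNA strings anchored at the
#' translation start codon: the last base of each sequence sits at
#' ATG-relative position -1 (there is no position 0), so a window starting
#' `k` bases from the right end starts at coordinate `-k`. Record names are
#' parsed as `"gene<delim>allele"` (default delimiter `"|"`); names without
#' the delimiter are used as both gene and allele label.
#'
#' @param x Named character vector of DNA sequences (A/C/G/T/N) or a
#'   `Biostrings::DNAStringSet`.
#' @param delim Single character separating gene from allele in the names.
#' @param min_len,max_len Accepted sequence-length bounds.
#' @return A `promoter_set`: named character vector with a `gene` attribute.
#' @examples
#' p <- promoter_set(c("GluA1|h1" = "ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTAC"))
#' attr(p, "gene")
#' @export
promoter_set <- function(x, delim = "|", min_len = 50L, max_len = 20000L) {
  if (methods::is(x, "DNAStringSet")) {
    nm <- names(x)
    x <- as.character(x)
    names(x) <- nm
  }
  if (!is.character(x) || is.null(names(x)) || any(!nzchar(names(x))))
    stop("promoters must be a named character vector or DNAStringSet")
  if (anyDuplicated(names(x)))
    stop("duplicate promoter ids: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad))
    stop("sequence(s) with non-ACGTN characters: ",
         paste(names(x)[bad], collapse = ", "))
  len <- nchar(x)
  out_of_bounds <- len < min_len | len > max_len
  if (any(out_of_bounds))
    stop("sequence length outside [", min_len, ", ", max_len, "]: ",
         paste(names(x)[out_of_bounds], collapse = ", "))
  gene <- vapply(strsplit(names(x), delim, fixed = TRUE), `[`, character(1L), 1L)
  structure(x, gene = gene, class = "promoter_set")
}

#' Read promoters from FASTA
#'
#' @param path FASTA file (one record per promoter allele, 3' end at the
#'   start codon).
#' @param delim Gene/allele delimiter in record ids (default `"|"`).
#' @param ... Passed to [promoter_set()].
#' @return A `promoter_set`.
#' @export
read_promoter_fasta <- function(path, delim = "|", ...) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  promoter_set(seqs, delim = delim, ...)
}

#' Write promoters to FASTA
#'
#' @param promoters A `promoter_set` (or named character vector).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_promoter_fasta <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(unclass(promoters))
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' @export
print.promoter_set <- function(x, ...) {
  cat("Promoter set: ", length(x), " sequence(s), ",
      min(nchar(x)), "-", max(nchar(x)), " bp\n", sep = "")
  for (i in seq_along(x))
    cat(sprintf("  %s (%s): %d bp\n", names(x)[i], attr(x, "gene")[i],
                nchar(x[[i]])))
  invisible(x)
}

## index (1-based from left) <-> ATG-relative coordinate
idx_to_atg <- function(idx, L) idx - L - 1L
atg_to_idx <- function(coord, L) coord + L + 1L
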