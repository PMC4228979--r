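#' Aligned promoter sets
#'
#' An alignment is stored as a named character vector of equal-length
#' gapped rows (gap character `-`), anchored so every row ends at the ATG.
#' Ungapping row *i* must reproduce member *i*'s residues exactly.
#'
#' @param rows Named character vector of gapped strings.
#' @return A `promoter_alignment` object.
#' @export
promoter_alignment <- function(rows) {
  if (methods::is(rows, "DNAStringSet")) {
    nm <- names(rows); rows <- as.character(rows); names(rows) <- nm
  }
  if (!is.character(rows) || is.null(names(rows)))
    stop("alignment rows must be a named character vector")
  rows <- toupper(rows)
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows have unequal lengths")
  bad <- grepl("[^ACGTN-]", rows)
  if (any(bad))
    stop("alignment row(s) with invalid characters: ",
         paste(names(rows)[bad], collapse = ", "))
  structure(rows, class = "promoter_alignment")
}

#' @export
print.promoter_alignment <- function(x, ...) {
  cat("Promoter alignment: ", length(x), " rows x ", nchar(x[[1L]]),
      " columns\n", sep = "")
  invisible(x)
}

#' @method as.matrix promoter_alignment
#' @export
as.matrix.promoter_alignment <- function(x, ...) {
  m <- do.call(rbind, strsplit(unclass(x), "", fixed = TRUE))
  rownames(m) <- names(x)
  m
}

#' Ungap alignment rows
#'
#' @param alignment A `promoter_alignment`.
#' @return A `promoter_set` of the ungapped member sequences.
#' @export
ungap_alignment <- function(alignment) {
  promoter_set(gsub("-", "", unclass(alignment), fixed = TRUE))
}

#' Read / write aligned FASTA
#'
#' @param path Aligned FASTA file.
#' @return `read_alignment_fasta`: a `promoter_alignment`.
#' @export
read_alignment_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  promoter_alignment(seqs)
}

#' @rdname read_alignment_fasta
#' @param alignment A `promoter_alignment`.
#' @return `write_alignment_fasta`: `path`, invisibly.
#' @export
write_alignment_fasta <- function(alignment, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unclass(alignment)), path, width = 70L)
  invisible(path)
}

#' Globally align promoter alleles against a reference member
#'
#' Convenience aligner for promoter families whose indels are not already
#' known: each member is aligned to the reference by global (Needleman-
#' Wunsch) alignment with affine gap penalties (match +1, mismatch -1, gap
#' open -5, gap extend -0.5 per base), and the pairwise alignments are
#' stitched into one matrix by merging the insertion columns they induce on
#' the reference (star alignment). A pre-made aligned FASTA, when
#' available, should be preferred: supplied alignments always take
#' precedence downstream.
#'
#' @param promoters A `promoter_set` with at least 2 members.
#' @param reference Member id to align against (default: first member).
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return A `promoter_alignment`; attribute `scores` carries the pairwise
#'   alignment score of each non-reference member against the reference.
#' @export
align_members <- function(promoters, reference = NULL,
                          match = 1, mismatch = -1,
                          gap_open = 5, gap_extend = 0.5) {
  if (!inherits(promoters, "promoter_set")) promoters <- promoter_set(promoters)
  if (length(promoters) < 2L) stop("need at least 2 promoters to align")
  if (is.null(reference)) reference <- names(promoters)[1L]
  if (!reference %in% names(promoters))
    stop("unknown reference member: ", reference)
  n_frac <- vapply(strsplit(unclass(promoters), "", fixed = TRUE),
                   function(ch) mean(ch == "N"), numeric(1))
  if (any(n_frac > 0.1))
    warning("sequence(s) with >10% N content: ",
            paste(names(promoters)[n_frac > 0.1], collapse = ", "))

  ref_seq <- promoters[[reference]]
  others <- setdiff(names(promoters), reference)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)

  ## pairwise alignments, each as two gapped strings (member, reference)
  pw <- list(); scores <- numeric(0)
  for (id in others) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(promoters[[id]]), Biostrings::DNAString(ref_seq),
      type = "global", substitutionMatrix = submat,
      gapOpening = gap_open, gapExtension = gap_extend)
    pw[[id]] <- list(
      member = as.character(Biostrings::alignedPattern(aln)),
      ref = as.character(Biostrings::alignedSubject(aln)))
    scores[id] <- Biostrings::score(aln)
  }

  ## merge: for each reference position, the longest insertion any member
  ## places immediately before it (position Lref+1 collects 3' overhangs)
  Lref <- nchar(ref_seq)
  ins_before <- integer(Lref + 1L)
  ins_runs <- lapply(pw, function(a) {
    refc <- strsplit(a$ref, "", fixed = TRUE)[[1L]]
    runs <- integer(Lref + 1L)
    pos <- 1L; run <- 0L
    for (ch in refc) {
      if (ch == "-") run <- run + 1L
      else { runs[pos] <- run; run <- 0L; pos <- pos + 1L }
    }
    runs[Lref + 1L] <- run
    runs
  })
  for (r in ins_runs) ins_before <- pmax(ins_before, r)

  pad_row <- function(chars_ref, chars_mem) {
    ## rebuild one member row on the master column grid
    out <- character(0)
    pos <- 1L; buf <- character(0)
    flush <- function(buf, slot) {
      c(buf, rep("-", slot - length(buf)))
    }
    for (j in seq_along(chars_ref)) {
      if (chars_ref[j] == "-") {
        buf <- c(buf, chars_mem[j])
      } else {
        out <- c(out, flush(buf, ins_before[pos]), chars_mem[j])
        buf <- character(0); pos <- pos + 1L
      }
    }
    c(out, flush(buf, ins_before[Lref + 1L]))
  }

  rows <- list()
  refc_plain <- strsplit(ref_seq, "", fixed = TRUE)[[1L]]
  rows[[reference]] <- paste(
    pad_row(refc_plain, refc_plain), collapse = "")
  for (id in others) {
    refc <- strsplit(pw[[id]]$ref, "", fixed = TRUE)[[1L]]
    memc <- strsplit(pw[[id]]$member, "", fixed = TRUE)[[1L]]
    rows[[id]] <- paste(pad_row(refc, memc), collapse = "")
  }
  rows <- unlist(rows)[names(promoters)]
  aln <- promoter_alignment(rows)
  attr(aln, "scores") <- scores
  attr(aln, "reference") <- reference
  aln
}

#' Project member coordinates into a reference frame
#'
#' For every member of an alignment, maps each of its ATG-relative
#' coordinates to the reference-frame ATG-relative coordinate of the
#' alignment column holding that base. Where the reference is gapped, the
#' coordinate maps to the nearest reference base 5' (more distal) of the
#' column; insertions before the reference's first base map to its most
#' distal coordinate. Maps are monotone non-decreasing and are the
#' identity for the reference itself (and for all members of a gapless
#' alignment).
#'
#' @param alignment A `promoter_alignment`.
#' @param reference Reference member id (default: first row).
#' @return An `offset_maps` object: named list, one integer vector per
#'   member; element `j` is the reference coordinate of member coordinate
#'   `j - Lm - 1` (`Lm` = ungapped member length).
#' @export
build_offset_maps <- function(alignment, reference = NULL) {
  stopifnot(inherits(alignment, "promoter_alignment"))
  if (is.null(reference)) reference <- names(alignment)[1L]
  if (!reference %in% names(alignment))
    stop("unknown reference member: ", reference)
  mat <- as.matrix(alignment)
  ref_gapped <- mat[reference, ] != "-"
  Lref <- sum(ref_gapped)
  ## reference base index covering each column (0 before the first base)
  ref_idx_at_col <- cumsum(ref_gapped)
  ref_coord_at_col <- pmax(ref_idx_at_col, 1L) - Lref - 1L
  maps <- lapply(rownames(mat), function(id) {
    keep <- mat[id, ] != "-"
    unname(ref_coord_at_col[keep])
  })
  names(maps) <- rownames(mat)
  structure(maps, reference = reference, class = "offset_maps")
}

#' Map member ATG coordinates to the reference frame
#'
#' @param offsets An `offset_maps` object.
#' @param member Member id.
#' @param coords Integer vector of ATG-relative member coordinates.
#' @return Integer vector of reference-frame coordinates.
#' @export
map_to_ref <- function(offsets, member, coords) {
  stopifnot(inherits(offsets, "offset_maps"))
  m <- offsets[[member]]
  if (is.null(m)) stop("no offset map for member: ", member)
  Lm <- length(m)
  j <- coords + Lm + 1L
  if (any(j < 1L | j > Lm))
    stop("coordinate(s) outside member '", member, "' (length ", Lm, ")")
  m[j]
}

#' @export
print.offset_maps <- function(x, ...) {
  cat("Offset maps for ", length(x), " member(s), reference = ",
      attr(x, "reference"), "\n", sep = "")
  invisible(x)
}
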