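#' Scan promoters for degenerate cis-motifs
#'
#' Slides every catalog pattern over each promoter and records all matching
#' windows, including overlapping self-matches, on the requested strand(s).
#' Coordinates are ATG-relative (negative; -1 is the base immediately 5' of
#' the start codon); minus-strand hits are reported in plus-strand
#' orientation (leftmost base = start) with `strand == "-"` and
#' `matched_seq` given as the plus-strand substring. Subject `N` bases
#' match no pattern.
#'
#' @param promoters A `promoter_set` (or coercible named character vector).
#' @param catalog A `motif_catalog` (default preset `"table2"`).
#' @param strands `"both"` (default), `"plus"` or `"minus"`.
#' @return An `annotated_promoters` object: list with `promoters`, `hits`
#'   (data frame: seq_id, motif_id, start, end, strand, matched_seq),
#'   `nested_resolved = FALSE`, `strands` and `catalog`. Hits are sorted by
#'   (seq_id, start, motif_id, strand).
#' @seealso [resolve_nested()], [count_matrix()]
#' @export
scan_promoters <- function(promoters, catalog = load_catalog("table2"),
                           strands = c("both", "plus", "minus")) {
  strands <- match.arg(strands)
  if (!inherits(promoters, "promoter_set")) promoters <- promoter_set(promoters)
  catalog <- if (inherits(catalog, "motif_catalog")) catalog else
    validate_catalog(catalog)
  rx_plus <- vapply(catalog$pattern, iupac_regex, character(1L))
  rx_minus <- vapply(revcomp(catalog$pattern), iupac_regex, character(1L))
  k <- nchar(catalog$pattern)

  res <- vector("list", length(promoters))
  for (s in seq_along(promoters)) {
    subject <- promoters[[s]]
    L <- nchar(subject)
    parts <- list()
    for (m in seq_len(nrow(catalog))) {
      if (k[m] > L) next
      if (strands %in% c("both", "plus")) {
        st <- regex_starts(rx_plus[m], subject)
        if (length(st))
          parts[[length(parts) + 1L]] <- data.frame(
            seq_id = names(promoters)[s], motif_id = catalog$motif_id[m],
            start = idx_to_atg(st, L), end = idx_to_atg(st + k[m] - 1L, L),
            strand = "+", matched_seq = substring(subject, st, st + k[m] - 1L),
            stringsAsFactors = FALSE)
      }
      if (strands %in% c("both", "minus")) {
        st <- regex_starts(rx_minus[m], subject)
        if (length(st))
          parts[[length(parts) + 1L]] <- data.frame(
            seq_id = names(promoters)[s], motif_id = catalog$motif_id[m],
            start = idx_to_atg(st, L), end = idx_to_atg(st + k[m] - 1L, L),
            strand = "-", matched_seq = substring(subject, st, st + k[m] - 1L),
            stringsAsFactors = FALSE)
      }
    }
    res[[s]] <- if (length(parts)) do.call(rbind, parts) else empty_hits()
  }
  hits <- do.call(rbind, c(res, list(empty_hits())))
  hits <- hits[order(match(hits$seq_id, names(promoters)), hits$start,
                     hits$motif_id, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(promoters = promoters, hits = hits, nested_resolved = FALSE,
                 strands = strands, catalog = catalog),
            class = "annotated_promoters")
}

empty_hits <- function() {
  data.frame(seq_id = character(0), motif_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             matched_seq = character(0), stringsAsFactors = FALSE)
}

#' Resolve nested motif hits to the longest motif
#'
#' Removes every hit whose interval is strictly contained within a longer
#' hit on the same strand of the same promoter (chains of containment
#' collapse onto the longest container). Co-extensive hits of equal length
#' are all kept, as are overlapping non-contained hits. Idempotent.
#' Containment is purely positional: the TF families of container and
#' contained motif are not consulted.
#'
#' @param annotated An `annotated_promoters` object.
#' @return The object with nested hits removed and `nested_resolved = TRUE`.
#' @export
resolve_nested <- function(annotated) {
  stopifnot(inherits(annotated, "annotated_promoters"))
  h <- annotated$hits
  if (nrow(h)) {
    keep <- rep(TRUE, nrow(h))
    grp <- split(seq_len(nrow(h)), list(h$seq_id, h$strand), drop = TRUE)
    for (idx in grp) {
      st <- h$start[idx]; en <- h$end[idx]
      w <- en - st + 1L
      for (i in seq_along(idx)) {
        contained <- st <= st[i] & en >= en[i] & w > w[i]
        if (any(contained)) keep[idx[i]] <- FALSE
      }
    }
    h <- h[keep, , drop = FALSE]
    rownames(h) <- NULL
  }
  annotated$hits <- h
  annotated$nested_resolved <- TRUE
  annotated
}

#' Motif-by-promoter count matrix
#'
#' Tabulates surviving hits per motif and promoter, with a `Total` row.
#' Requires nested resolution first (otherwise nested motifs would be
#' double-counted). Counting defaults to plus-strand hits only, mirroring
#' plus-strand annotation tables.
#'
#' @param annotated A nested-resolved `annotated_promoters` object.
#' @param strand_filter `"plus"` (default) or `"both"`.
#' @return Integer matrix (motifs in catalog order x promoters) whose last
#'   row `Total` holds column sums.
#' @export
count_matrix <- function(annotated, strand_filter = c("plus", "both")) {
  stopifnot(inherits(annotated, "annotated_promoters"))
  strand_filter <- match.arg(strand_filter)
  if (!isTRUE(annotated$nested_resolved))
    stop("annotations must be nested-resolved before counting ",
         "(call resolve_nested())")
  h <- annotated$hits
  if (strand_filter == "plus") h <- h[h$strand == "+", , drop = FALSE]
  motifs <- annotated$catalog$motif_id
  proms <- names(annotated$promoters)
  m <- matrix(0L, nrow = length(motifs), ncol = length(proms),
              dimnames = list(motifs, proms))
  if (nrow(h)) {
    tab <- table(factor(h$motif_id, levels = motifs),
                 factor(h$seq_id, levels = proms))
    m[] <- as.integer(tab)
  }
  rbind(m, Total = colSums(m))
}

#' @export
print.annotated_promoters <- function(x, ...) {
  cat("Annotated promoters: ", length(x$promoters), " sequence(s), ",
      nrow(x$hits), " hit(s) [", x$strands, " strand(s), catalog ",
      attr(x$catalog, "name") %||% "custom", ", nested_resolved = ",
      x$nested_resolved, "]\n", sep = "")
  invisible(x)
}

#' Export motif hits as GFF3
#'
#' Hits become `TF_binding_site` features with 1-based positive coordinates
#' within each record (GFF3 forbids negative positions); the ATG-relative
#' start is carried in an `atg_offset` attribute and the motif id in
#' `Name`.
#'
#' @param annotated An `annotated_promoters` object.
#' @param path Output `.gff3` path.
#' @return `path`, invisibly.
#' @export
write_hits_gff3 <- function(annotated, path) {
  stopifnot(inherits(annotated, "annotated_promoters"))
  h <- annotated$hits
  L <- nchar(annotated$promoters)[h$seq_id]
  gr <- GenomicRanges::GRanges(
    seqnames = factor(h$seq_id, levels = names(annotated$promoters)),
    ranges = IRanges::IRanges(start = atg_to_idx(h$start, L),
                              end = atg_to_idx(h$end, L)),
    strand = if (nrow(h)) h$strand else character(0))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = rep("promcis", nrow(h)), type = rep("TF_binding_site", nrow(h)),
    Name = h$motif_id, atg_offset = h$start, matched_seq = h$matched_seq)
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Write motif hits as TSV
#'
#' @param annotated An `annotated_promoters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(annotated, path) {
  utils::write.table(annotated$hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
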