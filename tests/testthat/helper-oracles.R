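## Independent oracles used by the unit and acceptance tests. These
## deliberately avoid the package's scanning/clustering code paths:
## pattern matching goes through exhaustive IUPAC expansion plus
## Biostrings exact matching, containment through an all-pairs check,
## alignment scoring through a textbook affine-gap dynamic program.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

## exhaustive sliding-window scan: every concrete expansion of every
## pattern, matched exactly with Biostrings; minus-strand hits found by
## scanning the reverse complement and reflecting coordinates.
oracle_scan <- function(seqs, catalog, strands = "both") {
  expansions <- lapply(catalog$pattern, iupac_expand)
  rows <- list()
  for (s in seq_along(seqs)) {
    subj <- Biostrings::DNAString(seqs[[s]])
    subj_rc <- Biostrings::reverseComplement(subj)
    L <- length(subj)
    for (m in seq_len(nrow(catalog))) {
      k <- nchar(catalog$pattern[m])
      for (conc in expansions[[m]]) {
        if (strands %in% c("both", "plus")) {
          mt <- Biostrings::matchPattern(conc, subj)
          for (st in BiocGenerics::start(mt))
            rows[[length(rows) + 1L]] <- data.frame(
              seq_id = names(seqs)[s], motif_id = catalog$motif_id[m],
              start = st - L - 1L, end = st + k - 1L - L - 1L,
              strand = "+", stringsAsFactors = FALSE)
        }
        if (strands %in% c("both", "minus")) {
          mt <- Biostrings::matchPattern(conc, subj_rc)
          for (i in BiocGenerics::start(mt)) {
            start_idx <- L - i - k + 2L
            rows[[length(rows) + 1L]] <- data.frame(
              seq_id = names(seqs)[s], motif_id = catalog$motif_id[m],
              start = start_idx - L - 1L, end = start_idx + k - 1L - L - 1L,
              strand = "-", stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_id = character(0), motif_id = character(0),
               start = integer(0), end = integer(0), strand = character(0))
  out[order(out$seq_id, out$start, out$motif_id, out$strand), , drop = FALSE]
}

## hit-set comparison key (ignores matched_seq, row order)
hit_key <- function(h) {
  sort(paste(h$seq_id, h$motif_id, h$start, h$end, h$strand, sep = ":"))
}

## all-pairs strict-containment filter
oracle_resolve <- function(hits) {
  if (!nrow(hits)) return(hits)
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))) {
    for (j in seq_len(nrow(hits))) {
      if (i == j) next
      same <- hits$seq_id[i] == hits$seq_id[j] &&
        hits$strand[i] == hits$strand[j]
      longer <- (hits$end[j] - hits$start[j]) > (hits$end[i] - hits$start[i])
      inside <- hits$start[j] <= hits$start[i] && hits$end[j] >= hits$end[i]
      if (same && longer && inside) keep[i] <- FALSE
    }
  }
  hits[keep, , drop = FALSE]
}

## Gotoh affine-gap global alignment score; a gap of length k costs
## gap_open + gap_extend * k, matching the aligner's convention
oracle_affine_score <- function(a, b, match = 1, mismatch = -1,
                                gap_open = 5, gap_extend = 0.5) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1L, m + 1L)   # last op: substitution
  X <- matrix(NEG, n + 1L, m + 1L)   # last op: gap in b (a consumed)
  Y <- matrix(NEG, n + 1L, m + 1L)   # last op: gap in a (b consumed)
  M[1L, 1L] <- 0
  for (i in seq_len(n) + 1L)
    X[i, 1L] <- -gap_open - gap_extend * (i - 1L)
  for (j in seq_len(m) + 1L)
    Y[1L, j] <- -gap_open - gap_extend * (j - 1L)
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      s <- if (av[i - 1L] == bv[j - 1L]) match else mismatch
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i - 1L, j] - gap_open - gap_extend,
                     X[i - 1L, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1L] - gap_open - gap_extend,
                     Y[i, j - 1L] - gap_extend)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

## per-column projection of member coordinates onto the reference frame,
## walking the alignment matrix directly
oracle_offset_map <- function(alignment, member, reference) {
  mat <- as.matrix(alignment)
  ref_row <- mat[reference, ]; mem_row <- mat[member, ]
  Lref <- sum(ref_row != "-"); Lmem <- sum(mem_row != "-")
  out <- integer(Lmem)
  b <- 0L
  for (col in seq_along(mem_row)) {
    if (mem_row[col] == "-") next
    b <- b + 1L
    ## nearest reference base at or 5' of this column
    rc <- col
    while (rc >= 1L && ref_row[rc] == "-") rc <- rc - 1L
    ref_idx <- if (rc >= 1L) sum(ref_row[seq_len(rc)] != "-") else 1L
    out[b] <- ref_idx - Lref - 1L
  }
  out
}

## small helpers for building fixtures in code
pad_promoter <- function(core, total = 60L, left = "A") {
  paste0(strrep(left, total - nchar(core)), core)
}

## build a validated catalog from a data frame via the file loader
mini_catalog <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  load_catalog(f)
}
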