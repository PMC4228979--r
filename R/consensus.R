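#' Consensus parameters
#'
#' Tunables of the cross-promoter consensus.
#'
#' @param tolerance Coordinate tolerance in bp for calling two hits "at the
#'   same position" after indel correction (default 5: hits within +/- 5 bp
#'   cluster together).
#' @param conserved_support Minimum support fraction for the conserved
#'   class (default 1.0: present in all members).
#' @param majority_support Support threshold (strict inequality) for the
#'   majority class (default 0.5: more than half the members).
#' @param ccrm_max_gap Largest start-to-start gap (bp) between consecutive
#'   conserved motifs inside one conserved cis-regulatory module
#'   (default 100).
#' @param ccrm_min_motifs Minimum motifs per module (default 2).
#' @param merge_tolerance Tolerance (bp) used when merging per-set
#'   consensuses into an overall consensus (default 10).
#' @return A `consensus_params` list.
#' @export
consensus_params <- function(tolerance = 5L, conserved_support = 1.0,
                             majority_support = 0.5, ccrm_max_gap = 100L,
                             ccrm_min_motifs = 2L, merge_tolerance = 10L) {
  stopifnot(tolerance >= 0, merge_tolerance >= 0,
            majority_support > 0, majority_support <= conserved_support,
            conserved_support <= 1, ccrm_max_gap >= 0, ccrm_min_motifs >= 1)
  structure(list(tolerance = as.integer(tolerance),
                 conserved_support = conserved_support,
                 majority_support = majority_support,
                 ccrm_max_gap = as.integer(ccrm_max_gap),
                 ccrm_min_motifs = as.integer(ccrm_min_motifs),
                 merge_tolerance = as.integer(merge_tolerance)),
            class = "consensus_params")
}

## 1-D single-linkage clustering with a spread cap: indices grouped so that
## successive sorted values differ by <= link; any cluster whose spread
## exceeds 2*link is split recursively at its largest internal gap, keeping
## every cluster within the +/- tolerance reading of "same coordinates".
cluster_1d <- function(x, link) {
  ord <- order(x)
  xs <- x[ord]
  split_run <- function(idx) {
    if (length(idx) < 2L) return(list(idx))
    v <- xs[idx]
    gaps <- diff(v)
    brk <- which(gaps > link)
    runs <- if (length(brk)) {
      starts <- c(1L, brk + 1L); ends <- c(brk, length(idx))
      Map(function(s, e) idx[s:e], starts, ends)
    } else list(idx)
    out <- list()
    for (r in runs) {
      if (length(r) >= 2L && (max(xs[r]) - min(xs[r])) > 2L * link) {
        g <- diff(xs[r])
        cut <- which.max(g)
        out <- c(out, split_run(r[seq_len(cut)]),
                 split_run(r[(cut + 1L):length(r)]))
      } else out <- c(out, list(r))
    }
    out
  }
  lapply(split_run(seq_along(xs)), function(idx) ord[idx])
}

## cluster representative: median start, ties rounded toward the start
## codon (i.e. toward -1)
median_toward_atg <- function(x) {
  m <- stats::median(x)
  as.integer(ceiling(m))
}

#' Build a consensus annotation across a promoter set
#'
#' Per (motif, strand), member hit starts are projected into the reference
#' frame through the offset maps (so indels do not break positional
#' matching) and clustered with single linkage at the given tolerance. A
#' cluster's support is the fraction of distinct members contributing to
#' it: clusters with support >= `conserved_support` are *conserved*
#' (present at the same corrected coordinate in all members), those with
#' support > `majority_support` (but below conserved) are *majority* and
#' participate in distance reporting only.
#'
#' @param annotated A nested-resolved `annotated_promoters` object.
#' @param offsets An `offset_maps` covering every member, or `NULL` for
#'   identity mapping (gapless/equal-length sets).
#' @param params A [consensus_params()] list.
#' @param strand Strand(s) whose hits enter the consensus: `"+"` (default,
#'   matching plus-strand annotation plots), `"-"`, or `"both"`.
#' @param set_id Label for the promoter set (e.g. `"x-type"`).
#' @return A `consensus_annotation`: list with `set_id`, `members`,
#'   `conserved` and `majority` data frames (motif_id, strand,
#'   ref_coordinate, width, support, n_members, member_starts list column),
#'   both sorted by ref_coordinate, and `params`.
#' @export
find_conserved <- function(annotated, offsets = NULL,
                           params = consensus_params(),
                           strand = c("+", "-", "both"),
                           set_id = "set1") {
  stopifnot(inherits(annotated, "annotated_promoters"))
  strand <- match.arg(strand)
  if (!isTRUE(annotated$nested_resolved))
    stop("annotations must be nested-resolved before consensus building")
  members <- names(annotated$promoters)
  h <- annotated$hits
  if (strand != "both") h <- h[h$strand == strand, , drop = FALSE]
  if (!is.null(offsets)) {
    miss <- setdiff(members, names(offsets))
    if (length(miss))
      stop("member(s) without an offset map: ", paste(miss, collapse = ", "))
    h$ref_start <- NA_integer_
    for (id in unique(h$seq_id)) {
      sel <- h$seq_id == id
      h$ref_start[sel] <- map_to_ref(offsets, id, h$start[sel])
    }
  } else {
    h$ref_start <- h$start
  }
  clusters_to_consensus(h, members, params, set_id)
}

## shared by find_conserved and merge_consensuses
clusters_to_consensus <- function(h, members, params, set_id) {
  n <- length(members)
  rows <- list()
  if (nrow(h)) {
    h$width <- h$end - h$start + 1L
    grp <- split(seq_len(nrow(h)), list(h$motif_id, h$strand), drop = TRUE)
    for (idx in grp) {
      cl <- cluster_1d(h$ref_start[idx], params$tolerance)
      for (ci in cl) {
        sub <- h[idx[ci], , drop = FALSE]
        supp <- length(unique(sub$seq_id)) / n
        rows[[length(rows) + 1L]] <- data.frame(
          motif_id = sub$motif_id[1L], strand = sub$strand[1L],
          ref_coordinate = median_toward_atg(sub$ref_start),
          width = max(sub$width), support = supp,
          n_members = length(unique(sub$seq_id)),
          stringsAsFactors = FALSE)
        rows[[length(rows)]]$member_starts <-
          list(stats::setNames(sub$ref_start, sub$seq_id))
      }
    }
  }
  all_cl <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif_id = character(0), strand = character(0),
               ref_coordinate = integer(0), width = integer(0),
               support = numeric(0), n_members = integer(0),
               member_starts = I(list()))
  ord <- order(all_cl$ref_coordinate, all_cl$motif_id)
  all_cl <- all_cl[ord, , drop = FALSE]
  rownames(all_cl) <- NULL
  conserved <- all_cl[all_cl$support >= params$conserved_support, , drop = FALSE]
  majority <- all_cl[all_cl$support > params$majority_support &
                     all_cl$support < params$conserved_support, , drop = FALSE]
  rownames(conserved) <- rownames(majority) <- NULL
  structure(list(set_id = set_id, members = members,
                 conserved = conserved, majority = majority,
                 params = params),
            class = "consensus_annotation")
}

#' @export
print.consensus_annotation <- function(x, ...) {
  cat("Consensus annotation '", x$set_id, "': ", length(x$members),
      " member(s), ", nrow(x$conserved), " conserved and ",
      nrow(x$majority), " majority motif(s)\n", sep = "")
  invisible(x)
}

#' Detect conserved cis-regulatory modules (CCRMs)
#'
#' Walks the conserved motifs from the coordinate nearest the start codon
#' outward and opens a new module whenever the start-to-start gap to the
#' previous motif exceeds `ccrm_max_gap`; runs with fewer than
#' `ccrm_min_motifs` motifs are discarded and survivors are numbered 1..k
#' from the start codon.
#'
#' @param consensus A `consensus_annotation`.
#' @param params A [consensus_params()] list (defaults to the consensus's
#'   own parameters).
#' @return A `ccrm_set`: list of modules, each with `index`, `motifs` (rows
#'   of the conserved table) and `span` (`c(min start, max end)` in the
#'   reference frame).
#' @export
detect_ccrms <- function(consensus, params = NULL) {
  stopifnot(inherits(consensus, "consensus_annotation"))
  if (is.null(params)) params <- consensus$params
  cons <- consensus$conserved
  modules <- list()
  if (nrow(cons)) {
    cons <- cons[order(-cons$ref_coordinate), , drop = FALSE]  # -1 outward
    run_start <- 1L
    breaks <- which(-diff(cons$ref_coordinate) > params$ccrm_max_gap)
    starts <- c(1L, breaks + 1L)
    ends <- c(breaks, nrow(cons))
    for (i in seq_along(starts)) {
      rows <- cons[starts[i]:ends[i], , drop = FALSE]
      if (nrow(rows) < params$ccrm_min_motifs) next
      modules[[length(modules) + 1L]] <- list(
        index = length(modules) + 1L,
        motifs = rows,
        span = c(min(rows$ref_coordinate),
                 max(rows$ref_coordinate + rows$width - 1L)))
    }
  }
  structure(modules, class = "ccrm_set")
}

#' @export
print.ccrm_set <- function(x, ...) {
  cat("CCRM set: ", length(x), " module(s)\n", sep = "")
  for (m in x)
    cat(sprintf("  CCRM%d: %d motifs [%d, %d] (%s)\n", m$index,
                nrow(m$motifs), m$span[1L], m$span[2L],
                paste(m$motifs$motif_id, collapse = ", ")))
  invisible(x)
}

#' @method as.data.frame ccrm_set
#' @export
as.data.frame.ccrm_set <- function(x, ...) {
  if (!length(x))
    return(data.frame(ccrm = integer(0), motif_id = character(0),
                      strand = character(0), ref_coordinate = integer(0)))
  do.call(rbind, lapply(x, function(m) {
    data.frame(ccrm = m$index, motif_id = m$motifs$motif_id,
               strand = m$motifs$strand,
               ref_coordinate = m$motifs$ref_coordinate,
               stringsAsFactors = FALSE)
  }))
}

#' Merge per-set consensuses into an overall consensus
#'
#' Each input's conserved motifs become pseudo-hits of one pseudo-member
#' (the set id) with identity offsets; clustering is re-run at
#' `merge_tolerance`. The merged conserved class holds motifs present in
#' every input; motifs in more than half the inputs form the merged
#' majority class. Invariant under input reordering; merging a single
#' consensus is the identity (its motifs and coordinates are returned
#' unchanged, without re-clustering).
#'
#' @param consensuses List of `consensus_annotation` objects.
#' @param params A [consensus_params()] list.
#' @param set_id Label for the merged consensus.
#' @return A `consensus_annotation` over the pseudo-members.
#' @export
merge_consensuses <- function(consensuses, params = consensus_params(),
                              set_id = "overall") {
  stopifnot(length(consensuses) >= 1L,
            all(vapply(consensuses, inherits, logical(1L),
                       "consensus_annotation")))
  ids <- vapply(consensuses, `[[`, character(1L), "set_id")
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  if (length(consensuses) == 1L) {
    out <- consensuses[[1L]]
    out$set_id <- set_id
    out$members <- ids
    return(out)
  }
  h <- do.call(rbind, Map(function(cns, id) {
    cons <- cns$conserved
    if (!nrow(cons)) return(NULL)
    data.frame(seq_id = id, motif_id = cons$motif_id,
               start = cons$ref_coordinate,
               end = cons$ref_coordinate + cons$width - 1L,
               strand = cons$strand, ref_start = cons$ref_coordinate,
               stringsAsFactors = FALSE)
  }, consensuses, ids))
  if (is.null(h))
    h <- data.frame(seq_id = character(0), motif_id = character(0),
                    start = integer(0), end = integer(0),
                    strand = character(0), ref_start = integer(0))
  p <- params
  p$tolerance <- p$merge_tolerance
  clusters_to_consensus(h, ids, p, set_id)
}

#' Distances between consensus motifs
#'
#' Start-to-start distances between consecutive motifs supported by more
#' than half the members (conserved plus majority classes), walking from
#' the start codon outward.
#'
#' @param consensus A `consensus_annotation`.
#' @return Data frame: from_motif, from_coord, to_motif, to_coord,
#'   distance (bp, positive).
#' @export
distance_report <- function(consensus) {
  stopifnot(inherits(consensus, "consensus_annotation"))
  q <- rbind(consensus$conserved, consensus$majority)
  empty <- data.frame(from_motif = character(0), from_coord = integer(0),
                      to_motif = character(0), to_coord = integer(0),
                      distance = integer(0))
  if (nrow(q) < 2L) return(empty)
  q <- q[order(-q$ref_coordinate), , drop = FALSE]  # proximal first
  n <- nrow(q)
  data.frame(from_motif = q$motif_id[-n], from_coord = q$ref_coordinate[-n],
             to_motif = q$motif_id[-1L], to_coord = q$ref_coordinate[-1L],
             distance = q$ref_coordinate[-n] - q$ref_coordinate[-1L],
             stringsAsFactors = FALSE)
}

#' Write a consensus annotation as JSON
#'
#' @param consensus A `consensus_annotation`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_consensus_json <- function(consensus, path) {
  ser <- function(df) {
    if (!nrow(df)) return(list())
    lapply(seq_len(nrow(df)), function(i) list(
      motif_id = df$motif_id[i], strand = df$strand[i],
      ref_coordinate = df$ref_coordinate[i], width = df$width[i],
      support = df$support[i], n_members = df$n_members[i],
      member_starts = as.list(df$member_starts[[i]])))
  }
  obj <- list(set_id = consensus$set_id, members = consensus$members,
              params = unclass(consensus$params),
              conserved = ser(consensus$conserved),
              majority = ser(consensus$majority))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write CCRMs as GFF3
#'
#' Modules become `conserved_region` features (`ID=CCRM1..k`) with 1-based
#' coordinates on a pseudo-record named after the consensus set; the
#' reference-frame span is carried in `atg_start`/`atg_end` attributes.
#'
#' @param ccrms A `ccrm_set`.
#' @param consensus The `consensus_annotation` the modules came from.
#' @param path Output `.gff3` path.
#' @param ref_length Length of the reference frame (default: most distal
#'   motif coordinate).
#' @return `path`, invisibly.
#' @export
write_ccrm_gff3 <- function(ccrms, consensus, path, ref_length = NULL) {
  spans <- lapply(ccrms, `[[`, "span")
  if (is.null(ref_length))
    ref_length <- if (length(spans)) -min(vapply(spans, `[`, integer(1L), 1L))
      else 0L
  n <- length(ccrms)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(consensus$set_id, n),
    ranges = IRanges::IRanges(
      start = vapply(spans, function(s) atg_to_idx(s[1L], ref_length), integer(1L)),
      end = vapply(spans, function(s) atg_to_idx(s[2L], ref_length), integer(1L))),
    strand = rep("+", n))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = rep("promcis", n), type = rep("conserved_region", n),
    ID = paste0("CCRM", vapply(ccrms, `[[`, integer(1L), "index")),
    atg_start = vapply(spans, `[`, integer(1L), 1L),
    atg_end = vapply(spans, `[`, integer(1L), 2L),
    n_motifs = vapply(ccrms, function(m) nrow(m$motifs), integer(1L)))
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}
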