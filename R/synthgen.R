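#' Configure a synthetic promoter family
#'
#' The generator emulates the structure of resequenced promoter-allele
#' panels: an ancestral promoter with cis-motif modules planted at fixed
#' ATG-relative positions, a set of alleles derived from it with roughly
#' one polymorphism per 1/`snp_rate` bases, a singleton-rich haplotype
#' structure (two major haplotypes plus alleles carrying private SNPs),
#' optional 1-bp indels and an optional large (e.g. 54-bp) deletion.
#'
#' @param length Ancestor length in bp (default 1000).
#' @param n_alleles Number of alleles in the family (default 8).
#' @param planted_modules List of modules; each module is a list with
#'   `module_id` and `placements`, a data frame with columns `motif_id`,
#'   `concrete` (an A/C/G/T instance of the motif's pattern), `start`
#'   (ATG-relative, negative) and `strand`. Placements must lie within
#'   `[-length, -1]` and must not overlap.
#' @param snp_rate Per-site probability that a background position is
#'   polymorphic in the family (default 0.01, i.e. ~1 polymorphism per
#'   100 bp).
#' @param singleton_fraction Fraction of polymorphic sites that are
#'   private to a single allele (default 0.5).
#' @param n_singleton_alleles Number of alleles designated to carry the
#'   private SNPs (default `NULL`: about a quarter of the panel, capped at
#'   `n_alleles - 2` and at the number of realised private sites). Private
#'   sites are spread round-robin over these alleles, so the expected
#'   haplotype count is 2 + `n_singleton_alleles` (plus indel effects).
#' @param indel_spec List of deletions, each a list with `length`,
#'   `carriers` (allele indices) and optional `pos` (ATG-relative start of
#'   the deleted run; random when `NULL`).
#' @param haplotype_structure `"two_major_plus_singletons"` (default):
#'   non-private sites split the family into two major haplotype groups;
#'   `"neutral"`: derived-allele counts follow the 1/i neutral frequency
#'   spectrum (infinite-sites, no selection); `"star"`: every mutation is
#'   private to one random allele.
#' @param protect_planted Keep mutations and deletions off the planted
#'   motif spans (default `TRUE`).
#' @param background `"random"` (uniform A/C/G/T) or `"motif_free"`:
#'   iteratively mutates background bases until the ancestor contains no
#'   catalog match outside the planted spans (see
#'   [generate_family()]).
#' @param catalog Catalog used by `background = "motif_free"` scrubbing
#'   (default preset `"table2"`).
#' @param gc Background GC fraction (default 0.5).
#' @param gene Gene label used in allele ids (default `"synth"`).
#' @param seed Integer seed; the generator is deterministic given the
#'   config.
#' @return A `generator_config` list.
#' @export
generator_config <- function(length = 1000L, n_alleles = 8L,
                             planted_modules = list(),
                             snp_rate = 0.01, singleton_fraction = 0.5,
                             n_singleton_alleles = NULL,
                             indel_spec = list(),
                             haplotype_structure = c("two_major_plus_singletons",
                                                     "neutral", "star"),
                             protect_planted = TRUE,
                             background = c("random", "motif_free"),
                             catalog = NULL, gc = 0.5, gene = "synth",
                             seed = 1L) {
  haplotype_structure <- match.arg(haplotype_structure)
  background <- match.arg(background)
  stopifnot(length >= 50L, n_alleles >= 1L, snp_rate >= 0, snp_rate <= 1,
            singleton_fraction >= 0, singleton_fraction <= 1,
            gc > 0, gc < 1)
  ## validate placements: bounds and overlap
  all_pl <- planted_placements(planted_modules)
  if (nrow(all_pl)) {
    ends <- all_pl$start + nchar(all_pl$concrete) - 1L
    if (any(all_pl$start < -length) || any(ends > -1L))
      stop("planted placement(s) outside [-length, -1]")
    ord <- order(all_pl$start)
    s <- all_pl$start[ord]; e <- ends[ord]
    if (any(s[-1L] <= e[-nrow(all_pl)]))
      stop("overlapping planted placements (explicit nesting not supported)")
    for (i in seq_len(nrow(all_pl))) {
      ok <- iupac_matcher(motif_pattern(all_pl$motif_id[i], catalog))(
        all_pl$concrete[i])
      if (!ok)
        stop("concrete sequence '", all_pl$concrete[i],
             "' is not an instance of motif ", all_pl$motif_id[i])
    }
  }
  for (ind in indel_spec) {
    stopifnot(is.list(ind), ind$length >= 1L,
              all(ind$carriers %in% seq_len(n_alleles)),
              length(ind$carriers) >= 1L, length(ind$carriers) < n_alleles)
  }
  structure(list(length = as.integer(length),
                 n_alleles = as.integer(n_alleles),
                 planted_modules = planted_modules, snp_rate = snp_rate,
                 singleton_fraction = singleton_fraction,
                 n_singleton_alleles = n_singleton_alleles,
                 indel_spec = indel_spec,
                 haplotype_structure = haplotype_structure,
                 protect_planted = protect_planted, background = background,
                 catalog = catalog, gc = gc, gene = gene,
                 seed = as.integer(seed)),
            class = "generator_config")
}

## flatten module placements into one data frame (module_id column added)
planted_placements <- function(planted_modules) {
  if (!length(planted_modules))
    return(data.frame(module_id = character(0), motif_id = character(0),
                      concrete = character(0), start = integer(0),
                      strand = character(0)))
  do.call(rbind, lapply(planted_modules, function(m) {
    p <- as.data.frame(m$placements, stringsAsFactors = FALSE)
    data.frame(module_id = m$module_id, motif_id = p$motif_id,
               concrete = toupper(p$concrete), start = as.integer(p$start),
               strand = if (is.null(p$strand)) "+" else p$strand,
               stringsAsFactors = FALSE)
  }))
}

motif_pattern <- function(motif_id, catalog = NULL) {
  cat <- if (is.null(catalog)) load_catalog("table2") else catalog
  i <- match(motif_id, cat$motif_id)
  if (is.na(i)) stop("motif_id not in catalog: ", motif_id)
  cat$pattern[i]
}

## run expr under a seed without disturbing the caller's RNG stream
with_rng <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic promoter family with ground truth
#'
#' Builds an ancestral sequence (uniform-random background at the
#' configured GC, planted motif instances overwritten at their
#' placements), derives alleles according to the haplotype structure,
#' applies the configured deletions, and returns the family together with
#' the exact alignment (gap columns at deletions; the alignment frame is
#' the ancestor frame) and a machine-readable truth record. Replaying the
#' truth's mutation lists on the ancestor reproduces every allele exactly.
#'
#' With `background = "motif_free"` the ancestor background is scrubbed:
#' the catalog is scanned over the whole ancestor (both strands) and any
#' hit not fully contained in a planted placement has one of its
#' background bases mutated, iterating until no such hit remains. This
#' makes planted-motif recovery exact rather than containment-only, at any
#' sequence length.
#'
#' @param config A [generator_config()].
#' @return A `synthetic_family`: list with `promoters` (a `promoter_set`),
#'   `alignment` (a `promoter_alignment`), and `truth` (a
#'   `synthetic_truth`: ancestor, per-allele SNP and deletion lists,
#'   per-allele planted placements with shifted coordinates, expected
#'   conserved set and module composition, the config).
#' @export
generate_family <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_rng(config$seed, generate_family_impl(config))
}

generate_family_impl <- function(config) {
  L <- config$length
  n <- config$n_alleles
  bases <- c("A", "C", "G", "T")
  probs <- c((1 - config$gc) / 2, config$gc / 2, config$gc / 2,
             (1 - config$gc) / 2)
  anc <- sample(bases, L, replace = TRUE, prob = probs)

  pl <- planted_placements(config$planted_modules)
  planted_mask <- rep(FALSE, L)
  if (nrow(pl)) {
    for (i in seq_len(nrow(pl))) {
      idx <- atg_to_idx(pl$start[i], L)
      span <- idx:(idx + nchar(pl$concrete[i]) - 1L)
      anc[span] <- strsplit(pl$concrete[i], "", fixed = TRUE)[[1L]]
      planted_mask[span] <- TRUE
    }
  }
  if (config$background == "motif_free")
    anc <- scrub_background(anc, planted_mask, config$catalog)

  ## eligible sites for SNPs / deletions
  eligible <- rep(TRUE, L)
  if (config$protect_planted) eligible <- eligible & !planted_mask

  ## deletions (positions fixed before SNPs; SNP sites avoid deleted runs
  ## so every called column is clean)
  del_mask_any <- rep(FALSE, L)
  deletions <- list()
  for (ind in config$indel_spec) {
    len <- as.integer(ind$length)
    if (is.null(ind$pos)) {
      ok_start <- which(vapply(seq_len(L - len + 1L), function(s)
        all(eligible[s:(s + len - 1L)]) && !any(del_mask_any[s:(s + len - 1L)]),
        logical(1L)))
      if (!length(ok_start)) stop("no room to place a ", len, "-bp deletion")
      s <- ok_start[sample.int(length(ok_start), 1L)]
    } else {
      s <- atg_to_idx(as.integer(ind$pos), L)
      if (s < 1L || s + len - 1L > L) stop("deletion outside the sequence")
      if (config$protect_planted && any(planted_mask[s:(s + len - 1L)]))
        stop("deletion overlaps a planted placement")
    }
    span <- s:(s + len - 1L)
    del_mask_any[span] <- TRUE
    deletions[[length(deletions) + 1L]] <- list(
      start_idx = s, length = len, carriers = sort(as.integer(ind$carriers)))
  }
  eligible <- eligible & !del_mask_any

  ## polymorphic sites
  site_idx <- which(eligible & stats::runif(L) < config$snp_rate)
  is_single <- stats::runif(length(site_idx)) < config$singleton_fraction
  if (config$haplotype_structure == "star") is_single[] <- TRUE

  ## carriers per site
  snps <- list()
  if (length(site_idx)) {
    if (config$haplotype_structure == "two_major_plus_singletons" && n >= 2L) {
      n_priv <- sum(is_single)
      k <- config$n_singleton_alleles
      ## default: at most a quarter of the panel carries private SNPs, so
      ## the two major groups stay major
      if (is.null(k)) k <- min(n_priv, max(1L, round(n / 4)))
      k <- min(k, max(n - 2L, 0L))
      singleton_alleles <- if (k > 0L) (n - k + 1L):n else integer(0)
      group_b <- if (n - k >= 2L) seq.int(ceiling((n - k) / 2) + 1L, n - k)
        else integer(0)
      priv_seen <- 0L
      for (i in seq_along(site_idx)) {
        if (is_single[i] && k > 0L) {
          carrier <- singleton_alleles[(priv_seen %% k) + 1L]
          priv_seen <- priv_seen + 1L
          carriers <- carrier
        } else if (length(group_b)) {
          carriers <- group_b
        } else {
          carriers <- sample(n, 1L)
        }
        snps[[length(snps) + 1L]] <- list(idx = site_idx[i], carriers = carriers)
      }
    } else if (config$haplotype_structure == "neutral") {
      spectrum <- (1 / seq_len(n - 1L)) / sum(1 / seq_len(n - 1L))
      for (i in seq_along(site_idx)) {
        cnt <- sample(n - 1L, 1L, prob = spectrum)
        snps[[length(snps) + 1L]] <- list(idx = site_idx[i],
                                          carriers = sort(sample(n, cnt)))
      }
    } else {  # star
      for (i in seq_along(site_idx))
        snps[[length(snps) + 1L]] <- list(idx = site_idx[i],
                                          carriers = sample(n, 1L))
    }
    for (i in seq_along(snps)) {
      ref <- anc[snps[[i]]$idx]
      snps[[i]]$from <- ref
      snps[[i]]$to <- sample(setdiff(bases, ref), 1L)
    }
  }

  ## build gapped rows in the ancestor frame
  ids <- paste0(config$gene, "|a", seq_len(n))
  rows <- matrix(rep(anc, n), nrow = n, byrow = TRUE)
  for (s in snps) rows[s$carriers, s$idx] <- s$to
  for (d in deletions)
    rows[d$carriers, d$start_idx:(d$start_idx + d$length - 1L)] <- "-"
  gapped <- apply(rows, 1L, paste, collapse = "")
  names(gapped) <- ids
  alignment <- promoter_alignment(gapped)
  promoters <- ungap_alignment(alignment)

  ## per-allele planted placements after deletion shifts: a deletion 3' of
  ## a motif moves it closer to the ATG in that allele's own frame
  per_allele <- list()
  if (nrow(pl)) {
    for (a in seq_len(n)) {
      shift <- rep(0L, nrow(pl))
      for (d in deletions) {
        if (!(a %in% d$carriers)) next
        del_start_atg <- idx_to_atg(d$start_idx, L)
        affected <- pl$start + nchar(pl$concrete) - 1L < del_start_atg
        shift[affected] <- shift[affected] + d$length
      }
      per_allele[[ids[a]]] <- data.frame(
        module_id = pl$module_id, motif_id = pl$motif_id,
        concrete = pl$concrete, ancestor_start = pl$start,
        start = pl$start + shift, strand = pl$strand,
        stringsAsFactors = FALSE)
    }
  }

  snp_df <- if (length(snps)) do.call(rbind, lapply(snps, function(s)
    data.frame(ref_coordinate = idx_to_atg(s$idx, L), from = s$from,
               to = s$to, carriers = paste(s$carriers, collapse = ","),
               singleton = length(s$carriers) == 1L,
               stringsAsFactors = FALSE))) else
    data.frame(ref_coordinate = integer(0), from = character(0),
               to = character(0), carriers = character(0),
               singleton = logical(0))
  del_df <- if (length(deletions)) do.call(rbind, lapply(deletions,
    function(d) data.frame(ref_coordinate = idx_to_atg(d$start_idx, L),
                           length = d$length,
                           carriers = paste(d$carriers, collapse = ","),
                           stringsAsFactors = FALSE))) else
    data.frame(ref_coordinate = integer(0), length = integer(0),
               carriers = character(0))

  ## realised haplotype structure: distinct mutation profiles
  profile <- vapply(seq_len(n), function(a) paste(
    paste(vapply(snps, function(s) if (a %in% s$carriers) s$to else s$from,
                 character(1L)), collapse = ""),
    paste(vapply(deletions, function(d) as.integer(a %in% d$carriers),
                 integer(1L)), collapse = ""), sep = "|"), character(1L))

  truth <- structure(list(
    ancestor = paste(anc, collapse = ""),
    snps = snp_df, deletions = del_df,
    placements = per_allele,
    expected_conserved = pl,
    expected_modules = pl[, c("module_id", "motif_id", "start")],
    expected_H = length(unique(profile)),
    allele_profiles = stats::setNames(profile, ids),
    config = config), class = "synthetic_truth")

  structure(list(promoters = promoters, alignment = alignment,
                 truth = truth), class = "synthetic_family")
}

## Mutate background bases until no catalog hit survives outside the
## planted spans (hits wholly inside one planted placement are kept).
## For each offending hit a random background base sitting on a non-N
## pattern slot is mutated to a base outside that slot's IUPAC set
## (mutating an N slot can never break a match); randomising both the
## slot and the replacement keeps the search from cycling between two
## mutually recreating motifs.
scrub_background <- function(anc, planted_mask, catalog = NULL,
                             max_rounds = 500L) {
  cat <- if (is.null(catalog)) load_catalog("table2") else catalog
  L <- length(anc)
  bases <- c("A", "C", "G", "T")
  pat_fwd <- lapply(cat$pattern, function(p) strsplit(p, "")[[1L]])
  pat_rev <- lapply(revcomp(cat$pattern), function(p) strsplit(p, "")[[1L]])
  for (round in seq_len(max_rounds)) {
    seq_str <- paste(anc, collapse = "")
    fix_pos <- integer(0); fix_letter <- character(0)
    n_hits <- 0L
    for (m in seq_len(nrow(cat))) {
      k <- nchar(cat$pattern[m])
      if (k > L) next
      for (ori in 1:2) {
        chars <- if (ori == 1L) pat_fwd[[m]] else pat_rev[[m]]
        rx <- paste(vapply(chars, function(ch) {
          set <- IUPAC_SETS[[ch]]
          if (length(set) == 1L) set else
            paste0("[", paste(set, collapse = ""), "]")
        }, character(1L)), collapse = "")
        for (st in regex_starts(rx, seq_str)) {
          span <- st:(st + k - 1L)
          bg <- which(!planted_mask[span] & chars != "N")
          if (all(planted_mask[span])) next  # inside one plant: keep
          n_hits <- n_hits + 1L
          if (length(bg)) {
            pick <- bg[sample.int(length(bg), 1L)]
            fix_pos <- c(fix_pos, span[pick])
            fix_letter <- c(fix_letter, chars[pick])
          }
        }
      }
    }
    if (!n_hits) return(anc)
    if (!length(fix_pos))
      stop("motif-free background infeasible: a catalog hit spans only ",
           "planted bases and pattern wildcards")
    keep <- !duplicated(fix_pos)
    for (i in which(keep)) {
      outside <- setdiff(bases, IUPAC_SETS[[fix_letter[i]]])
      anc[fix_pos[i]] <- outside[sample.int(length(outside), 1L)]
    }
  }
  stop("motif-free background did not converge after ", max_rounds,
       " scrub rounds")
}

#' Replay a truth record into the allele sequences
#'
#' Applies each allele's substitutions and deletions to the recorded
#' ancestor; the result is byte-identical to the generated family
#' (round-trip guarantee).
#'
#' @param truth A `synthetic_truth`.
#' @return A `promoter_set` of the regenerated alleles.
#' @export
replay <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  anc <- strsplit(truth$ancestor, "", fixed = TRUE)[[1L]]
  L <- length(anc)
  n <- truth$config$n_alleles
  ids <- paste0(truth$config$gene, "|a", seq_len(n))
  out <- character(n)
  for (a in seq_len(n)) {
    al <- anc
    if (nrow(truth$snps)) for (i in seq_len(nrow(truth$snps))) {
      carr <- as.integer(strsplit(truth$snps$carriers[i], ",")[[1L]])
      if (a %in% carr) {
        j <- atg_to_idx(truth$snps$ref_coordinate[i], L)
        if (al[j] != truth$snps$from[i])
          stop("corrupted truth record: ancestor base mismatch at ",
               truth$snps$ref_coordinate[i])
        al[j] <- truth$snps$to[i]
      }
    }
    drop <- rep(FALSE, L)
    if (nrow(truth$deletions)) for (i in seq_len(nrow(truth$deletions))) {
      carr <- as.integer(strsplit(truth$deletions$carriers[i], ",")[[1L]])
      if (a %in% carr) {
        j <- atg_to_idx(truth$deletions$ref_coordinate[i], L)
        drop[j:(j + truth$deletions$length[i] - 1L)] <- TRUE
      }
    }
    out[a] <- paste(al[!drop], collapse = "")
  }
  names(out) <- ids
  promoter_set(out)
}

#' Promoter-family presets with planted CCRM-like modules
#'
#' `"ccrm5"` plants five modules echoing the modular organisation of
#' seed-storage-protein gene promoters: a proximal TATA-variant + CAAT
#' pair, a G-box + E-box pair, a GATA-box pair, a five-motif composite box
#' (two GATA+GLM units separated by a third GGATA), and a distal
#' prolamin-box + CAAT pair. `"glm_gata_box"` plants only the composite
#' box. Backgrounds default to `motif_free` so planted-motif recovery is
#' exact.
#'
#' @param preset `"ccrm5"` or `"glm_gata_box"`.
#' @param ... Overrides passed to [generator_config()] (e.g. `n_alleles`,
#'   `snp_rate`, `seed`).
#' @return A `generator_config`.
#' @export
plant_renan_like <- function(preset = c("ccrm5", "glm_gata_box"), ...) {
  preset <- match.arg(preset)
  pm <- function(id, ...) {
    rows <- list(...)
    list(module_id = id, placements = do.call(rbind, lapply(rows, function(r)
      data.frame(motif_id = r[[1L]], concrete = r[[2L]],
                 start = as.integer(r[[3L]]), strand = "+",
                 stringsAsFactors = FALSE))))
  }
  composite <- pm("M4",
    list("GATA2", "GGATA",   -658),
    list("GLM1",  "TGAGTCA", -647),
    list("GATA2", "GGATA",   -638),
    list("GATA2", "GGATA",   -632),
    list("GLM1",  "TGAGTCA", -626))
  modules <- switch(preset,
    ccrm5 = list(
      pm("M1",
         list("TATAvariant", "TATAAA",   -90),
         list("CAAT",        "CAAT",     -70)),
      pm("M2",
         list("Gbox1", "CACGTGGC", -277),
         list("Ebox",  "CACCTG",   -259)),
      pm("M3",
         list("GATA2", "GGATA", -400),
         list("GATA2", "GGATA", -380)),
      composite,
      pm("M5",
         list("Pbox1", "TGCAAAG", -950),
         list("CAAT",  "CAAT",    -920))),
    glm_gata_box = list(composite))
  defaults <- list(length = 1000L, n_alleles = 8L, planted_modules = modules,
                   background = "motif_free")
  args <- utils::modifyList(defaults, list(...))
  do.call(generator_config, args)
}

#' Write a synthetic family (FASTA, aligned FASTA, truth JSON)
#'
#' @param family A `synthetic_family`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix (default the config's gene label).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_family <- function(family, dir, prefix = NULL) {
  stopifnot(inherits(family, "synthetic_family"))
  if (is.null(prefix)) prefix <- family$truth$config$gene
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    alleles = file.path(dir, paste0(prefix, "_alleles.fasta")),
    aligned = file.path(dir, paste0(prefix, "_aligned.fasta")),
    truth = file.path(dir, paste0(prefix, "_truth.json")))
  write_promoter_fasta(family$promoters, paths[["alleles"]])
  write_alignment_fasta(family$alignment, paths[["aligned"]])
  tr <- family$truth
  cfg <- unclass(tr$config)
  cfg$planted_modules <- lapply(cfg$planted_modules, function(m)
    list(module_id = m$module_id, placements = m$placements))
  cfg$catalog <- NULL
  obj <- list(seed = cfg$seed, config = cfg, ancestor = tr$ancestor,
              snps = tr$snps, deletions = tr$deletions,
              expected_conserved = tr$expected_conserved,
              expected_H = tr$expected_H)
  jsonlite::write_json(obj, paths[["truth"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
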