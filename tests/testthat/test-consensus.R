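make_family <- function(...) generate_family(plant_renan_like("ccrm5", ...))

test_that("offset maps are identity on gapless alignments", {
  al <- promoter_alignment(c(a = strrep("ACGT", 20), b = strrep("ACGT", 20)))
  om <- build_offset_maps(al)
  expect_equal(map_to_ref(om, "a", c(-80L, -40L, -1L)), c(-80L, -40L, -1L))
  expect_equal(map_to_ref(om, "b", c(-80L, -1L)), c(-80L, -1L))
})

test_that("a deletion shifts 5' member coordinates by its length", {
  set.seed(11)
  ref <- random_dna(300)
  ## member lacks ancestor positions 101..154 (54 bp)
  gapped <- paste0(substr(ref, 1, 100), strrep("-", 54), substr(ref, 155, 300))
  al <- promoter_alignment(c(ref = ref, del = gapped))
  om <- build_offset_maps(al, reference = "ref")
  ## member coord -246 is its first base = ancestor -300
  expect_equal(map_to_ref(om, "del", -246L), -300L)
  ## coordinates 3' of the deletion are unshifted
  expect_equal(map_to_ref(om, "del", c(-146L, -1L)), c(-146L, -1L))
  ## 5' of the deletion: shifted 54 bp more distal
  expect_equal(map_to_ref(om, "del", -147L), -201L)
  ## maps are monotone non-decreasing
  for (id in names(al))
    expect_true(all(diff(map_to_ref(om, id,
      seq(-nchar(gsub("-", "", al[[id]])), -1L))) >= 0L))
})

test_that("offset maps equal the per-column projection oracle", {
  set.seed(12)
  base <- random_dna(200)
  rows <- c(
    r1 = base,
    r2 = paste0(substr(base, 1, 50), strrep("-", 10), substr(base, 61, 200)),
    r3 = paste0(strrep("-", 5), substr(base, 6, 120), strrep("-", 7),
                substr(base, 128, 200)))
  al <- promoter_alignment(rows)
  om <- build_offset_maps(al, reference = "r1")
  for (id in names(rows)) {
    Lm <- nchar(gsub("-", "", rows[[id]]))
    expect_equal(map_to_ref(om, id, seq(-Lm, -1L)),
                 oracle_offset_map(al, id, "r1"))
  }
  ## reference maps to itself
  expect_equal(map_to_ref(om, "r1", seq(-200L, -1L)), seq(-200L, -1L))
})

test_that("the internal aligner recovers known indels and matches a DP oracle", {
  set.seed(13)
  a <- random_dna(150)
  identical_pair <- promoter_set(c(x = a, y = a), min_len = 50L)
  al0 <- align_members(identical_pair)
  expect_false(grepl("-", al0[["x"]], fixed = TRUE))
  expect_false(grepl("-", al0[["y"]], fixed = TRUE))

  ## reference vs reference-with-54-bp-deletion: one 54-column gap run
  ref <- random_dna(400)
  del <- paste0(substr(ref, 1, 150), substr(ref, 205, 400))
  al1 <- align_members(promoter_set(c(ref = ref, del = del), min_len = 50L),
                       reference = "ref")
  gaps <- gregexpr("-+", al1[["del"]])[[1L]]
  expect_equal(length(gaps), 1L)
  expect_equal(attr(gaps, "match.length"), 54L)
  expect_false(grepl("-", al1[["ref"]], fixed = TRUE))

  ## alignment score equals the affine-gap dynamic-programming oracle
  for (i in 1:3) {
    s1 <- random_dna(80)
    s2chars <- strsplit(s1, "")[[1L]]
    mut <- sample(80, 6)
    s2chars[mut] <- sample(c("A", "C", "G", "T"), 6, replace = TRUE)
    s2 <- paste(c(s2chars[1:40], s2chars[46:80]), collapse = "")  # 5-bp del
    al <- align_members(promoter_set(c(a = s1, b = s2), min_len = 30L))
    expect_equal(unname(attr(al, "scores")["b"]),
                 oracle_affine_score(s1, s2))
  }
})

test_that("single and identical promoter sets give trivially conserved sets", {
  set.seed(14)
  seq1 <- random_dna(300)
  one <- resolve_nested(scan_promoters(promoter_set(c("g|a" = seq1))))
  cons1 <- find_conserved(one)
  expect_true(all(cons1$conserved$support == 1))
  expect_equal(nrow(cons1$majority), 0L)
  ## every plus-strand hit start sits in some conserved cluster
  plus_hits <- one$hits[one$hits$strand == "+", ]
  in_cluster <- unlist(lapply(seq_len(nrow(cons1$conserved)), function(i)
    paste(cons1$conserved$motif_id[i],
          cons1$conserved$member_starts[[i]])))
  expect_true(all(paste(plus_hits$motif_id, plus_hits$start) %in% in_cluster))

  two <- resolve_nested(scan_promoters(promoter_set(
    c("g|a" = seq1, "g|b" = seq1))))
  cons2 <- find_conserved(two)
  cols <- c("motif_id", "strand", "ref_coordinate", "support")
  expect_equal(cons2$conserved[cols], cons1$conserved[cols])
  expect_equal(nrow(cons2$majority), 0L)
})

test_that("planted modules survive an indel through offset correction", {
  cfg <- plant_renan_like("ccrm5", snp_rate = 0, seed = 21,
                          indel_spec = list(list(length = 10L,
                                                 carriers = c(2L, 5L))))
  fam <- generate_family(cfg)
  ann <- resolve_nested(scan_promoters(fam$promoters))
  cons <- find_conserved(ann, build_offset_maps(fam$alignment))
  planted <- fam$truth$expected_conserved
  got <- paste(cons$conserved$motif_id, cons$conserved$ref_coordinate)
  want <- paste(planted$motif_id, planted$start)
  expect_setequal(got, want)
  expect_true(all(cons$conserved$support == 1))
  ## indel shorter than the inter-module gap: module membership unchanged
  ccrms <- detect_ccrms(cons)
  expect_equal(length(ccrms), 5L)
  for (i in 1:5) {
    truth_mod <- planted[planted$module_id == paste0("M", i), ]
    expect_setequal(ccrms[[i]]$motifs$motif_id, truth_mod$motif_id)
  }
})

test_that("consensus is invariant under member permutation", {
  fam <- make_family(snp_rate = 0.01, seed = 22)
  om <- build_offset_maps(fam$alignment)
  perm <- c(5L, 3L, 8L, 1L, 7L, 2L, 6L, 4L)
  shuffled <- promoter_set(unclass(fam$promoters)[perm])
  c1 <- find_conserved(resolve_nested(scan_promoters(fam$promoters)), om)
  c2 <- find_conserved(resolve_nested(scan_promoters(shuffled)), om)
  cols <- c("motif_id", "strand", "ref_coordinate", "support")
  expect_equal(c1$conserved[cols], c2$conserved[cols])
  expect_equal(c1$majority[cols], c2$majority[cols])
})

test_that("widening the tolerance never loses conserved membership", {
  fam <- make_family(snp_rate = 0.02, seed = 23,
                     indel_spec = list(list(length = 3L, carriers = 4L)))
  ann <- resolve_nested(scan_promoters(fam$promoters))
  om <- build_offset_maps(fam$alignment)
  lo <- find_conserved(ann, om, consensus_params(tolerance = 2L))
  hi <- find_conserved(ann, om, consensus_params(tolerance = 6L))
  for (i in seq_len(nrow(lo$conserved))) {
    starts <- lo$conserved$member_starts[[i]]
    match_hi <- hi$conserved$motif_id == lo$conserved$motif_id[i] &
      abs(hi$conserved$ref_coordinate - lo$conserved$ref_coordinate[i]) <= 12L
    expect_true(any(match_hi))
    covered <- any(vapply(which(match_hi), function(j) {
      hs <- hi$conserved$member_starts[[j]]
      all(paste(names(starts), starts) %in% paste(names(hs), hs))
    }, logical(1L)))
    expect_true(covered)
  }
})

test_that("CCRM detection applies the gap and size rules from the ATG outward", {
  toy_consensus <- function(coords, motif = "CAAT", width = 4L) {
    h <- data.frame(seq_id = "g|a", motif_id = motif, start = coords,
                    end = coords + width - 1L, strand = "+",
                    matched_seq = "CAAT", stringsAsFactors = FALSE)
    p <- promoter_set(stats::setNames(random_dna(1100), "g|a"))
    ann <- structure(list(promoters = p, hits = h, nested_resolved = TRUE,
                          strands = "plus", catalog = load_catalog("table2")),
                     class = "annotated_promoters")
    find_conserved(ann)
  }
  set.seed(24)
  ## two motifs 7 bp apart -> one module numbered 1
  cc <- detect_ccrms(toy_consensus(c(-95L, -88L)))
  expect_equal(length(cc), 1L)
  expect_equal(cc[[1L]]$index, 1L)
  expect_equal(nrow(cc[[1L]]$motifs), 2L)
  ## two isolated singletons -> no module
  expect_equal(length(detect_ccrms(toy_consensus(c(-100L, -900L)))), 0L)
  ## numbering increases with distality
  cc3 <- detect_ccrms(toy_consensus(c(-80L, -72L, -500L, -490L, -950L, -940L)))
  expect_equal(vapply(cc3, `[[`, integer(1L), "index"), 1:3)
  expect_true(all(diff(vapply(cc3, function(m) min(m$motifs$ref_coordinate),
                              integer(1L))) < 0))
})

test_that("merging consensuses is an identity for one input and symmetric", {
  fam <- make_family(snp_rate = 0, seed = 25)
  ann <- resolve_nested(scan_promoters(fam$promoters))
  cons <- find_conserved(ann, build_offset_maps(fam$alignment),
                         set_id = "x-type")
  m1 <- merge_consensuses(list(cons))
  expect_equal(m1$conserved$ref_coordinate, cons$conserved$ref_coordinate)
  expect_equal(m1$conserved$motif_id, cons$conserved$motif_id)

  fam2 <- generate_family(plant_renan_like("glm_gata_box", snp_rate = 0,
                                           seed = 26))
  cons2 <- find_conserved(
    resolve_nested(scan_promoters(fam2$promoters)),
    build_offset_maps(fam2$alignment), set_id = "y-type")
  ab <- merge_consensuses(list(cons, cons2))
  ba <- merge_consensuses(list(cons2, cons))
  cols <- c("motif_id", "strand", "ref_coordinate", "support")
  expect_equal(ab$conserved[cols], ba$conserved[cols])
  ## overall conserved = motifs present in both inputs: every composite-box
  ## placement is covered by a merged cluster within merge_tolerance, and
  ## every merged cluster has full support
  planted <- fam2$truth$expected_conserved
  for (i in seq_len(nrow(planted))) {
    near <- ab$conserved$motif_id == planted$motif_id[i] &
      abs(ab$conserved$ref_coordinate - planted$start[i]) <=
        cons$params$merge_tolerance
    expect_true(any(near))
  }
  expect_true(all(ab$conserved$support == 1))
  ## nothing outside the composite box is conserved in both sets
  expect_true(all(ab$conserved$ref_coordinate <= -620L &
                  ab$conserved$ref_coordinate >= -660L))
})

test_that("distance_report lists consecutive above-majority distances", {
  set.seed(27)
  seq1 <- random_dna(200)
  one <- resolve_nested(scan_promoters(promoter_set(c("g|a" = seq1))))
  cons <- find_conserved(one)
  d <- distance_report(cons)
  q <- cons$conserved[order(-cons$conserved$ref_coordinate), ]
  expect_equal(nrow(d), max(nrow(q) - 1L, 0L))
  if (nrow(q) >= 2L)
    expect_equal(d$distance, -diff(q$ref_coordinate))

  ## two motifs at -90 and -130 -> one row, distance 40
  h <- data.frame(seq_id = "g|a", motif_id = c("CAAT", "CCAAT"),
                  start = c(-90L, -130L), end = c(-87L, -126L),
                  strand = "+", matched_seq = c("CAAT", "CCAAT"),
                  stringsAsFactors = FALSE)
  ann <- structure(list(promoters = promoter_set(c("g|a" = random_dna(200))),
                        hits = h, nested_resolved = TRUE, strands = "plus",
                        catalog = load_catalog("table2")),
                   class = "annotated_promoters")
  d2 <- distance_report(find_conserved(ann))
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$distance, 40L)
  expect_equal(d2$from_motif, "CAAT")
})
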