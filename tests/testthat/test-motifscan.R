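test_that("built-in presets carry the expected motif sets", {
  t2 <- load_catalog("table2")
  expect_s3_class(t2, "motif_catalog")
  expect_equal(nrow(t2), 24L)
  expect_true(all(c("TATAWA", "AACNNA") %in% t2$pattern))
  expect_equal(t2$pattern[t2$motif_id == "RYcore"], "CATGCAY")
  expect_false(anyDuplicated(t2$motif_id) > 0)

  t6 <- load_catalog("table6")
  expect_equal(nrow(t6), 19L)
  expect_true("CATGCA" %in% t6$pattern)          # RY without the pyrimidine
  expect_false("ACATGTCATCATGT" %in% t6$pattern) # no ESP
  expect_false("TGTAAAG" %in% t6$pattern)        # no Pbox2
  expect_setequal(t6$pattern, c(
    "AAAG", "TGCAAAG", "TGHAAARK", "ACGT", "ACGTG", "RTGAGTCAT", "TGAGTCA",
    "YACGTGGC", "CAAT", "AAACAAA", "WAACCA", "AACNNA", "GGATA", "CATGCA",
    "CANNTG", "CCAAT", "TATAWA", "CAANNNNATC", "CCGTCC"))
})

test_that("catalog files round-trip and malformed catalogs are rejected", {
  tsv <- tempfile(fileext = ".tsv")
  write_catalog(load_catalog("table6"), tsv)
  again <- load_catalog(tsv)
  expect_equal(again$pattern, load_catalog("table6")$pattern)

  dup <- data.frame(motif_id = c("a", "a"), place_name = "x",
                    pattern = c("ACGT", "CAAT"), tf_family = "OTHER")
  f <- tempfile(fileext = ".tsv")
  write.table(dup, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_catalog(f), "duplicate motif_id")

  badpat <- data.frame(motif_id = "a", place_name = "x",
                       pattern = "ACGJ", tf_family = "OTHER")
  write.table(badpat, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_catalog(f), "entry 'a'.*invalid IUPAC.*'J'")

  expect_error(load_catalog("table7"), "unknown preset")
})

test_that("IUPAC matching follows the code semantics and the N rule", {
  m <- iupac_matcher("TATAWA")
  expect_equal(m(c("TATATA", "TATAAA", "TATAGA", "TATATT")),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(length(iupac_expand("CANNTG")), 16L)
  expect_equal(length(iupac_expand("RTGASTCAT")), 4L)
  expect_false(iupac_matcher("CANNTG")("CANNTG"))  # subject N never matches
  expect_error(check_iupac("ACGTX"), "invalid IUPAC")
  expect_error(check_iupac("AC"), "shorter")
})

test_that("scan reports every window with ATG-relative coordinates", {
  ## GGATA planted at known offsets; -1 is the base 5' of the ATG
  core <- paste0(strrep("C", 20), "GGATA", strrep("C", 10), "GGATA",
                 strrep("C", 20))
  p <- promoter_set(c("g|x" = core), min_len = 10L)
  cat <- mini_catalog(data.frame(
    motif_id = "GATA2", place_name = "MYBST1", pattern = "GGATA",
    tf_family = "GATA-MYB"))
  ann <- scan_promoters(p, cat, strands = "plus")
  L <- nchar(core)
  expect_equal(ann$hits$start, c(21L - L - 1L, 36L - L - 1L))
  expect_equal(ann$hits$end, ann$hits$start + 4L)
  expect_equal(ann$hits$matched_seq, c("GGATA", "GGATA"))

  ## overlapping self-matches are all counted (TATAWA in a TA repeat)
  p2 <- promoter_set(c("g|y" = paste0(strrep("C", 40), "TATATATA")),
                     min_len = 10L)
  cat2 <- mini_catalog(data.frame(
    motif_id = "TATAvariant", place_name = "p", pattern = "TATAWA",
    tf_family = "OTHER"))
  ann2 <- scan_promoters(p2, cat2, strands = "plus")
  expect_equal(ann2$hits$start, c(-8L, -6L))

  ## a C homopolymer matches nothing in the full catalog
  p3 <- promoter_set(c("g|z" = strrep("C", 200)))
  expect_equal(nrow(scan_promoters(p3, load_catalog("table2"))$hits), 0L)

  ## sequences shorter than the shortest pattern give empty annotations
  p4 <- promoter_set(c("g|w" = "AC"), min_len = 0L)
  expect_equal(nrow(scan_promoters(p4, load_catalog("table2"))$hits), 0L)
})

test_that("scan equals the exhaustive expansion oracle on random sequences", {
  cat <- load_catalog("table2")
  set.seed(101)
  for (rep in 1:8) {
    p <- promoter_set(stats::setNames(
      random_dna(sample(100:400, 1L)), paste0("g|r", rep)), min_len = 50L)
    got <- scan_promoters(p, cat, strands = "both")$hits
    want <- oracle_scan(p, cat, strands = "both")
    expect_equal(hit_key(got), hit_key(want))
  }
})

test_that("reverse-complementing the sequence mirrors the hit set", {
  cat <- load_catalog("table2")
  set.seed(77)
  seq1 <- random_dna(300)
  L <- nchar(seq1)
  p <- promoter_set(c("g|f" = seq1))
  prc <- promoter_set(c("g|f" = revcomp(seq1)))
  h_fwd <- scan_promoters(p, cat)$hits
  h_rev <- scan_promoters(prc, cat)$hits
  ## reflect: plus-strand idx i..j becomes (L+1-j)..(L+1-i), strand flips
  mirrored <- data.frame(
    seq_id = h_fwd$seq_id, motif_id = h_fwd$motif_id,
    stringsAsFactors = FALSE)
  mirrored$start <- (L + 1L - (h_fwd$end + L + 1L)) - L - 1L
  mirrored$end <- (L + 1L - (h_fwd$start + L + 1L)) - L - 1L
  mirrored$strand <- ifelse(h_fwd$strand == "+", "-", "+")
  expect_equal(hit_key(h_rev), hit_key(mirrored))
})

test_that("subject N bases match no pattern", {
  ## TANATA would match TATAWA if subject N were treated as a wildcard
  with_n <- promoter_set(c("g|n" = paste0(strrep("C", 30), "TANATA",
                                          strrep("C", 30))), min_len = 10L)
  no_n <- promoter_set(c("g|n" = paste0(strrep("C", 30), "TATATA",
                                        strrep("C", 30))), min_len = 10L)
  cat <- mini_catalog(data.frame(
    motif_id = "TATAvariant", place_name = "custom", pattern = "TATAWA",
    tf_family = "OTHER"))
  expect_equal(nrow(scan_promoters(with_n, cat, strands = "plus")$hits), 0L)
  expect_equal(nrow(scan_promoters(no_n, cat, strands = "plus")$hits), 1L)
})

test_that("nested resolution keeps only the longest motif", {
  ## Pbox1 TGCAAAG contains the DofCore AAAG
  p <- promoter_set(c("g|a" = paste0(strrep("C", 40), "TGCAAAG",
                                     strrep("C", 13))), min_len = 10L)
  ann <- resolve_nested(scan_promoters(p, load_catalog("table2"),
                                       strands = "plus"))
  expect_equal(ann$hits$motif_id, "Pbox1")
  expect_equal(ann$hits$start, -20L)
  expect_true(ann$nested_resolved)

  ## co-extensive equal-length hits of different motifs are all kept
  cat_eq <- mini_catalog(data.frame(
    motif_id = c("m1", "m2"), place_name = "p",
    pattern = c("ACGT", "AYGT"), tf_family = "OTHER"))
  p2 <- promoter_set(c("g|b" = paste0(strrep("T", 40), "ACGT")),
                     min_len = 10L)
  ann2 <- resolve_nested(scan_promoters(p2, cat_eq, strands = "plus"))
  expect_setequal(ann2$hits$motif_id, c("m1", "m2"))
})

test_that("nested resolution equals the containment oracle and is idempotent", {
  cat <- load_catalog("table2")
  set.seed(202)
  for (rep in 1:6) {
    p <- promoter_set(stats::setNames(random_dna(300), paste0("g|c", rep)))
    ann <- scan_promoters(p, cat)
    res <- resolve_nested(ann)
    expect_equal(hit_key(res$hits), hit_key(oracle_resolve(ann$hits)))
    expect_lte(nrow(res$hits), nrow(ann$hits))
    res2 <- resolve_nested(res)
    expect_identical(res2$hits, res$hits)
    ## post-condition: no strict same-strand containment survives
    h <- res$hits
    for (i in seq_len(nrow(h))) {
      cont <- h$strand == h$strand[i] & h$start <= h$start[i] &
        h$end >= h$end[i] & (h$end - h$start) > (h$end[i] - h$start[i])
      expect_false(any(cont))
    }
  }
})

test_that("scanning is deterministic", {
  set.seed(5)
  p <- promoter_set(c("g|d" = random_dna(500)))
  a1 <- scan_promoters(p, load_catalog("table2"))
  a2 <- scan_promoters(p, load_catalog("table2"))
  expect_identical(a1$hits, a2$hits)
})

test_that("count_matrix tabulates resolved plus-strand hits with totals", {
  p <- promoter_set(c(
    "g1|a" = paste0(strrep("C", 40), "TATAAA", strrep("C", 10), "GGATA"),
    "g2|a" = paste0(strrep("C", 45), "TATATA", strrep("C", 10), "GGATA")),
    min_len = 10L)
  ann <- scan_promoters(p, load_catalog("table6"))
  expect_error(count_matrix(ann), "nested-resolved")
  ann <- resolve_nested(ann)
  cm <- count_matrix(ann)
  expect_equal(unname(cm["TATAvariant", ]), c(1L, 1L))
  expect_equal(unname(cm["GATA2", ]), c(1L, 1L))
  expect_equal(unname(cm["Total", ]), unname(colSums(cm[rownames(cm) != "Total", ])))
  ## both-strand counting picks up the extra minus-strand content
  cm2 <- count_matrix(ann, strand_filter = "both")
  expect_true(all(cm2 >= cm))
})
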