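#' Motif catalogs
#'
#' A motif catalog is a data frame with one row per degenerate cis-motif:
#' `motif_id` (short unique label), `place_name` (name in the PLACE
#' database, or `"custom"`), `pattern` (IUPAC string), `tf_family` (one of
#' DOF, bZIP, RY, AACA-MYB, GATA-MYB, OTHER) and `source_note` (free text).
#'
#' Two built-in presets cover the seed-storage-protein regulatory lexicon:
#' \describe{
#'   \item{`table2`}{24 motifs: 22 PLACE entries known to act in
#'     seed-storage-protein regulation (plus one light-responsive and one
#'     circadian motif) and two non-PLACE additions, the GAMYB-binding
#'     AACNNA and the TATA-variant TATAWA of SSP gene promoters. The RY
#'     repeat is carried as CATGCAY here.}
#'   \item{`table6`}{the 19-pattern counting preset used for per-gene motif
#'     tabulation; it drops GATA, AACAAAC, RTGASTCAT, TGTAAAG and ESP and
#'     carries the RY repeat as CATGCA. The two RY forms are deliberately
#'     kept distinct between presets rather than merged.}
#' }
#' @name motif_catalog
NULL

builtin_table2 <- function() {
  e <- function(id, place, pat, fam, note = "")
    data.frame(motif_id = id, place_name = place, pattern = pat,
               tf_family = fam, source_note = note, stringsAsFactors = FALSE)
  cat <- rbind(
    e("DofCore",    "DOFCOREZM",           "AAAG",           "DOF",  "DOF core"),
    e("Pbox1",      "PROLAMINBOXOSGLUB1",  "TGCAAAG",        "DOF",  "prolamin box"),
    e("Pbox2",      "300CORE",             "TGTAAAG",        "DOF",  "prolamin box"),
    e("Pbox3",      "-300ELEMENT",         "TGHAAARK",       "DOF",  "prolamin box"),
    e("GLM1",       "GCN4OSGLUB1",         "TGAGTCA",        "bZIP", "GCN4-like motif"),
    e("GLM2",       "-300MOTIFZMZEIN",     "RTGAGTCAT",      "bZIP", "GCN4-like motif"),
    e("GLM3",       "GLMHVCHORD",          "RTGASTCAT",      "bZIP", "GCN4-like motif"),
    e("ACGTcore",   "ACGTATERD1",          "ACGT",           "bZIP", "ACGT core"),
    e("Gbox1",      "ABREATCONSENSUS",     "YACGTGGC",       "bZIP", "G-box"),
    e("Gbox2",      "ABRELATERDI",         "ACGTG",          "bZIP", "G-box"),
    e("CAAT",       "CAATBOX1",            "CAAT",           "bZIP", "CAAT box"),
    e("RYcore",     "RYREPEATLEGUMINBOX",  "CATGCAY",        "RY",   "RY repeat / FUSCA3"),
    e("AACA1",      "AACACOREOSGLUB1",     "AACAAAC",        "AACA-MYB", "AACA core"),
    e("AACA2",      "ANAERO1CONSENSUS",    "AAACAAA",        "AACA-MYB", ""),
    e("MYB1AT",     "MYB1AT",              "WAACCA",         "AACA-MYB", ""),
    e("AACA3",      "custom",              "AACNNA",         "AACA-MYB", "GAMYB-binding, non-PLACE"),
    e("GATA1",      "GATABOX",             "GATA",           "GATA-MYB", "GATA box"),
    e("GATA2",      "MYBST1",              "GGATA",          "GATA-MYB", "GATA box"),
    e("Ebox",       "EBOXBNNAPA",          "CANNTG",         "OTHER", "E box / bHLH"),
    e("CCAAT",      "CCAATBOX1",           "CCAAT",          "OTHER", "HAP/CBF"),
    e("ESP",        "ESPASGL01",           "ACATGTCATCATGT", "OTHER", "endosperm-specific"),
    e("TATAvariant","custom",              "TATAWA",         "OTHER", "SSP TATA variant, non-PLACE"),
    e("Circadian",  "CIACADIANLELHC",      "CAANNNNATC",     "OTHER", "circadian"),
    e("Abox",       "PALBOXAPC",           "CCGTCC",         "OTHER", "light responsive")
  )
  cat
}

builtin_table6 <- function() {
  t2 <- builtin_table2()
  keep <- c("DofCore", "Pbox1", "Pbox3", "ACGTcore", "Gbox2", "GLM2",
            "GLM1", "Gbox1", "CAAT", "AACA2", "MYB1AT", "AACA3",
            "GATA2", "RYcore", "Ebox", "CCAAT", "TATAvariant",
            "Circadian", "Abox")
  cat <- t2[match(keep, t2$motif_id), ]
  ## counting preset prints the RY repeat without the trailing pyrimidine
  cat$pattern[cat$motif_id == "RYcore"] <- "CATGCA"
  rownames(cat) <- NULL
  cat
}

validate_catalog <- function(cat, name = "catalog") {
  req <- c("motif_id", "place_name", "pattern", "tf_family")
  miss <- setdiff(req, names(cat))
  if (length(miss))
    stop(name, " is missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(cat)) stop(name, " has no entries")
  dup <- cat$motif_id[duplicated(cat$motif_id)]
  if (length(dup))
    stop("duplicate motif_id in ", name, ": ", paste(unique(dup), collapse = ", "))
  for (i in seq_len(nrow(cat))) {
    cat$pattern[i] <- tryCatch(check_iupac(cat$pattern[i]),
      error = function(e) stop("entry '", cat$motif_id[i], "': ",
                               conditionMessage(e), call. = FALSE))
  }
  fams <- c("DOF", "bZIP", "RY", "AACA-MYB", "GATA-MYB", "OTHER")
  bad <- setdiff(unique(cat$tf_family), fams)
  if (length(bad))
    stop("unknown tf_family in ", name, ": ", paste(bad, collapse = ", "),
         " (expected one of ", paste(fams, collapse = ", "), ")")
  if (is.null(cat$source_note)) cat$source_note <- ""
  cat <- cat[, c(req, "source_note")]
  class(cat) <- c("motif_catalog", "data.frame")
  cat
}

#' Load a motif catalog
#'
#' @param source Either a preset name (`"table2"` or `"table6"`, see
#'   [motif_catalog]) or a path to a catalog file: a 4/5-column TSV with a
#'   header (`motif_id`, `place_name`, `pattern`, `tf_family`, optional
#'   `source_note`) or a JSON array of objects with those fields.
#' @return A `motif_catalog` data frame (attribute `name` carries the
#'   preset or file name).
#' @examples
#' cat2 <- load_catalog("table2")
#' nrow(cat2)  # 24
#' @export
load_catalog <- function(source = "table2") {
  if (!is.character(source) || length(source) != 1L)
    stop("source must be a preset name or a file path")
  if (source %in% c("table2", "table6")) {
    cat <- if (source == "table2") builtin_table2() else builtin_table6()
    cat <- validate_catalog(cat, paste0("preset '", source, "'"))
    attr(cat, "name") <- source
    return(cat)
  }
  if (!file.exists(source))
    stop("unknown preset or missing file: '", source,
         "' (presets: table2, table6)")
  ext <- tolower(tools::file_ext(source))
  raw <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(source), stringsAsFactors = FALSE)
  } else {
    utils::read.delim(source, stringsAsFactors = FALSE, comment.char = "#")
  }
  cat <- validate_catalog(raw, paste0("catalog file '", basename(source), "'"))
  attr(cat, "name") <- basename(source)
  cat
}

#' Write a motif catalog to TSV
#'
#' @param catalog A `motif_catalog`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(as.data.frame(catalog), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.motif_catalog <- function(x, ...) {
  cat("Motif catalog '", attr(x, "name") %||% "custom", "': ",
      nrow(x), " motifs\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
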