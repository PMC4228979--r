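#' @keywords internal
"_PACKAGE"

## IUPAC nucleotide code -> base set. N deliberately expands to ACGT only:
## an N in a *subject* sequence therefore never satisfies a pattern position
## (conservative rule; keeps accession-derived counts stable).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_CODES <- names(IUPAC_SETS)

## complement map covering all ambiguity codes
IUPAC_FROM <- "ACGTRYWSKMBDHVN"
IUPAC_TO   <- "TGCAYRWSMKVHDBN"

#' Validate an IUPAC pattern
#'
#' Checks that a motif pattern is a non-empty string of valid IUPAC
#' nucleotide codes of length >= 3 (the shortest catalog motifs are
#' tetramers; a 2-mer "motif" would match a quarter of all dinucleotides).
#'
#' @param pattern Character scalar, e.g. `"TGHAAARK"`.
#' @param min_len Minimum allowed length (default 3).
#' @return The validated, upper-cased pattern (invisibly usable).
#' @examples
#' check_iupac("TATAWA")
#' @export
check_iupac <- function(pattern, min_len = 3L) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern))
    stop("pattern must be a single character string")
  pattern <- toupper(pattern)
  if (nchar(pattern) < min_len)
    stop("pattern '", pattern, "' is shorter than ", min_len, " nt")
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), IUPAC_CODES)
  if (length(bad))
    stop("invalid IUPAC code(s) '", paste(bad, collapse = "', '"),
         "' in pattern '", pattern, "'")
  pattern
}

#' Compile an IUPAC pattern to a regular expression
#'
#' Each ambiguity code becomes a character class over its base set, so a
#' subject `N` (not in any class) matches nothing.
#'
#' @param pattern IUPAC pattern string.
#' @return A regex string matching exactly the pattern's concrete instances.
#' @export
iupac_regex <- function(pattern) {
  pattern <- check_iupac(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  paste(vapply(chars, function(ch) {
    set <- IUPAC_SETS[[ch]]
    if (length(set) == 1L) set else paste0("[", paste(set, collapse = ""), "]")
  }, character(1L)), collapse = "")
}

#' Enumerate all concrete instances of an IUPAC pattern
#'
#' @param pattern IUPAC pattern string.
#' @return Character vector of all concrete A/C/G/T strings matching the
#'   pattern (cartesian expansion of the ambiguity codes).
#' @examples
#' length(iupac_expand("CANNTG"))  # 16
#' @export
iupac_expand <- function(pattern) {
  pattern <- check_iupac(pattern)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  grid <- expand.grid(lapply(chars, function(ch) IUPAC_SETS[[ch]]),
                      stringsAsFactors = FALSE)
  apply(grid, 1L, paste, collapse = "")
}

#' Reverse-complement an IUPAC string
#'
#' Handles all ambiguity codes (R<->Y, K<->M, B<->V, D<->H; W, S, N are
#' self-complementary). Gaps (`-`) are preserved.
#'
#' @param x Character vector of DNA/IUPAC strings.
#' @return The reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr(paste0(IUPAC_FROM, tolower(IUPAC_FROM)),
                 paste0(IUPAC_TO, tolower(IUPAC_TO)), x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1L))
}

#' Build a window matcher for one IUPAC pattern
#'
#' Returns a predicate over equal-length windows: `TRUE` when the window is
#' a concrete instance of the pattern. A window containing `N` (or any
#' non-ACGT character) matches nothing.
#'
#' @param pattern IUPAC pattern string.
#' @return A function `f(window)` vectorised over character windows.
#' @examples
#' m <- iupac_matcher("TATAWA")
#' m(c("TATATA", "TATAGA"))  # TRUE FALSE
#' @export
iupac_matcher <- function(pattern) {
  rx <- paste0("^", iupac_regex(pattern), "$")
  k <- nchar(check_iupac(pattern))
  function(window) {
    ok <- nchar(window) == k
    ok & grepl(rx, window, perl = TRUE)
  }
}

## all overlapping start indices of a perl regex in a string
regex_starts <- function(rx, subject) {
  m <- gregexpr(paste0("(?=", rx, ")"), subject, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}
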