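#' Call polymorphic sites from an aligned promoter set
#'
#' SNP sites are alignment columns where every row carries a base (A/C/G/T)
#' and at least two distinct bases occur. Columns containing a gap in any
#' row are excluded from the per-site denominator `L_valid`
#' (complete-deletion rule); maximal runs of gap columns sharing an
#' identical presence/absence pattern across rows are collapsed into one
#' indel event each, with the run length recorded. Columns containing `N`
#' are treated as unusable and excluded from both SNP calling and
#' `L_valid`. A site is a singleton when one of its minor alleles is
#' carried by exactly one sequence.
#'
#' Site coordinates are ATG-relative in the alignment frame (the last
#' column is position -1).
#'
#' @param alignment A `promoter_alignment` with >= 2 rows.
#' @return A `polymorphism_table`: list with `sites` (data frame:
#'   ref_coordinate, type, alleles, counts, singleton), `indels` (data
#'   frame: ref_coordinate, length, carriers), `n`, `L_valid`,
#'   `snp_columns` (alignment column indices of SNP sites).
#' @export
call_sites <- function(alignment) {
  stopifnot(inherits(alignment, "promoter_alignment"))
  mat <- as.matrix(alignment)
  n <- nrow(mat); L <- ncol(mat)
  if (n < 2L) stop("need at least 2 aligned sequences")
  has_gap <- colSums(mat == "-") > 0L
  has_n <- colSums(mat == "N") > 0L
  usable <- !has_gap & !has_n
  L_valid <- sum(usable)

  sites <- list(); snp_cols <- integer(0)
  for (j in which(usable)) {
    col <- mat[, j]
    tab <- table(col)
    if (length(tab) < 2L) next
    cnt <- sort(as.integer(tab), decreasing = TRUE)
    sites[[length(sites) + 1L]] <- data.frame(
      ref_coordinate = idx_to_atg(j, L), type = "SNP",
      alleles = paste(names(sort(tab, decreasing = TRUE)), collapse = "/"),
      counts = paste(cnt, collapse = "/"),
      singleton = any(cnt[-1L] == 1L), stringsAsFactors = FALSE)
    snp_cols <- c(snp_cols, j)
  }
  snp_df <- if (length(sites)) do.call(rbind, sites) else
    data.frame(ref_coordinate = integer(0), type = character(0),
               alleles = character(0), counts = character(0),
               singleton = logical(0))

  ## indel events: maximal gap-column runs with a shared carrier pattern
  indels <- list()
  j <- 1L
  while (j <= L) {
    if (has_gap[j]) {
      pat <- mat[, j] == "-"
      k <- j
      while (k < L && has_gap[k + 1L] && identical(mat[, k + 1L] == "-", pat))
        k <- k + 1L
      indels[[length(indels) + 1L]] <- data.frame(
        ref_coordinate = idx_to_atg(j, L), length = k - j + 1L,
        carriers = paste(rownames(mat)[pat], collapse = ","),
        singleton = sum(pat) == 1L || sum(pat) == n - 1L,
        stringsAsFactors = FALSE)
      j <- k + 1L
    } else j <- j + 1L
  }
  indel_df <- if (length(indels)) do.call(rbind, indels) else
    data.frame(ref_coordinate = integer(0), length = integer(0),
               carriers = character(0), singleton = logical(0))

  structure(list(sites = snp_df, indels = indel_df, n = n,
                 L_valid = L_valid, snp_columns = snp_cols),
            class = "polymorphism_table")
}

#' @export
print.polymorphism_table <- function(x, ...) {
  cat("Polymorphisms: n = ", x$n, ", S = ", nrow(x$sites), " SNP site(s) (",
      sum(x$sites$singleton), " singleton), ", nrow(x$indels),
      " indel event(s), L_valid = ", x$L_valid, "\n", sep = "")
  invisible(x)
}

#' Assign haplotypes over the polymorphic sites
#'
#' A member's haplotype is its allele vector over all polymorphic sites
#' (SNP bases plus indel presence/absence); identical vectors share a
#' label. Labels h1..hH are ordered by descending haplotype frequency,
#' ties broken by first occurrence in the alignment.
#'
#' @param alignment A `promoter_alignment`.
#' @return A `haplotype_table`: list with `assignment` (named character
#'   vector member -> label), `counts` (named integer vector per label) and
#'   `H`.
#' @export
assign_haplotypes <- function(alignment) {
  stopifnot(inherits(alignment, "promoter_alignment"))
  mat <- as.matrix(alignment)
  n <- nrow(mat)
  if (n >= 2L) {
    ps <- call_sites(alignment)
    snp_part <- if (length(ps$snp_columns))
      apply(mat[, ps$snp_columns, drop = FALSE], 1L, paste, collapse = "")
      else rep("", n)
    indel_part <- if (nrow(ps$indels)) {
      carrier_sets <- strsplit(ps$indels$carriers, ",", fixed = TRUE)
      vapply(rownames(mat), function(id) paste(
        vapply(carrier_sets, function(cs) as.integer(id %in% cs),
               integer(1L)), collapse = ""), character(1L))
    } else rep("", n)
    key <- paste(snp_part, indel_part, sep = "|")
  } else key <- "0"
  first_seen <- !duplicated(key)
  uniq <- key[first_seen]
  cnt <- as.integer(table(key)[uniq])
  ord <- order(-cnt, seq_along(uniq))
  labels <- stats::setNames(paste0("h", order(ord)), uniq)
  assignment <- stats::setNames(labels[key], rownames(mat))
  counts <- sort(table(assignment), decreasing = TRUE)
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts <- counts[order(as.integer(sub("^h", "", names(counts))))]
  structure(list(assignment = assignment, counts = counts,
                 H = length(counts)), class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("Haplotypes: H = ", x$H, " (",
      paste(sprintf("%s:%d", names(x$counts), x$counts), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Nucleotide diversity (pi) per site
#'
#' Mean number of pairwise nucleotide differences per gap-free site:
#' the sum over all unordered sequence pairs of their differences at
#' complete (gap- and N-free) columns, divided by `C(n,2) * L_valid`.
#'
#' @param alignment A `promoter_alignment` with >= 2 rows.
#' @return Numeric scalar, per-site pi.
#' @export
nucleotide_diversity <- function(alignment) {
  k <- mean_pairwise_differences(alignment)
  ps <- call_sites(alignment)
  if (ps$L_valid == 0L) stop("no gap-free columns (L_valid = 0)")
  k / ps$L_valid
}

## mean pairwise differences (total over sites, not per site), gap-excluded
## columns only
mean_pairwise_differences <- function(alignment) {
  stopifnot(inherits(alignment, "promoter_alignment"))
  mat <- as.matrix(alignment)
  n <- nrow(mat)
  if (n < 2L) stop("need at least 2 aligned sequences")
  usable <- colSums(mat == "-" | mat == "N") == 0L
  sub <- mat[, usable, drop = FALSE]
  total <- 0L
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      total <- total + sum(sub[i, ] != sub[j, ])
  total / choose(n, 2L)
}

#' Watterson's theta per site
#'
#' `theta_W = S / (a1 * L)` with `a1 = sum_{i=1}^{n-1} 1/i`.
#'
#' @param S Number of segregating sites.
#' @param n Number of sequences (>= 2).
#' @param L_valid Number of sites in the denominator (>= 1).
#' @return Numeric scalar, per-site Watterson estimate.
#' @examples
#' watterson_theta(3, 4, 100)  # 0.016364
#' @export
watterson_theta <- function(S, n, L_valid) {
  stopifnot(S >= 0, n >= 2, L_valid >= 1)
  a1 <- sum(1 / seq_len(n - 1L))
  S / (a1 * L_valid)
}

#' Haplotype diversity
#'
#' `Hd = n/(n-1) * (1 - sum p_i^2)` over haplotype frequencies `p_i`.
#'
#' @param counts Integer vector of haplotype counts.
#' @param n Total number of sequences (default `sum(counts)`).
#' @return Numeric scalar in [0, 1].
#' @examples
#' haplotype_diversity(c(2, 1, 1))  # 0.8333
#' @export
haplotype_diversity <- function(counts, n = sum(counts)) {
  stopifnot(sum(counts) == n, n >= 2)
  p <- counts / n
  (n / (n - 1)) * (1 - sum(p^2))
}

#' Tajima's D with significance class
#'
#' Computes `D = (k - S/a1) / sqrt(e1*S + e2*S*(S-1))` where `k` is the
#' mean pairwise difference count (total over sites) and the constants
#' a1, a2, b1, b2, c1, c2, e1, e2 follow Tajima's (1989) variance
#' approximation. Significance is classed from the beta-distribution
#' confidence limits of the same paper (D rescaled onto
#' `[Dmin, Dmax]` follows an approximate beta law with mean 0 and variance
#' 1): `NS`, `P<0.05` or `P<0.01` by the two-tailed beta probability.
#' With no segregating sites D is undefined (`NA`, class `"undefined"`).
#'
#' @param alignment A `promoter_alignment` (n >= 4 recommended).
#' @return List with `D`, `tajima_class`, `p_beta`, `S`, `k`.
#' @export
tajimas_d <- function(alignment) {
  stopifnot(inherits(alignment, "promoter_alignment"))
  ps <- call_sites(alignment)
  n <- ps$n
  S <- nrow(ps$sites)
  if (S == 0L)
    return(list(D = NA_real_, tajima_class = "undefined", p_beta = NA_real_,
                S = 0L, k = 0))
  k <- mean_pairwise_differences(alignment)
  d <- tajima_constants(n)
  D <- (k - S / d$a1) / sqrt(d$e1 * S + d$e2 * S * (S - 1))
  ## beta approximation over the attainable range of D
  Dmin <- (2 / n - 1 / d$a1) / sqrt(d$e2)
  Dmax <- ((n + 1) / (2 * n) - 1 / d$a1) / sqrt(d$e2)
  alpha <- -(1 + Dmin * Dmax) * Dmax / (Dmax - Dmin)
  beta <- (1 + Dmin * Dmax) * Dmin / (Dmax - Dmin)
  x <- (D - Dmin) / (Dmax - Dmin)
  x <- min(max(x, 0), 1)
  p <- 2 * min(stats::pbeta(x, beta, alpha), 1 - stats::pbeta(x, beta, alpha))
  cls <- if (p < 0.01) "P<0.01" else if (p < 0.05) "P<0.05" else "NS"
  list(D = D, tajima_class = cls, p_beta = p, S = S, k = k)
}

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1L))
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Full diversity summary for one aligned promoter set
#'
#' Composes [call_sites()], [assign_haplotypes()],
#' [nucleotide_diversity()], [watterson_theta()],
#' [haplotype_diversity()] and [tajimas_d()] into one record shaped like a
#' per-gene diversity table row.
#'
#' @param alignment A `promoter_alignment` with >= 2 rows.
#' @return A `diversity_summary`: list with n, L_valid, S, indel_count,
#'   singleton_count, H, Hd, pi, theta_w, tajima_D, tajima_class.
#' @export
diversity_report <- function(alignment) {
  ps <- call_sites(alignment)
  hap <- assign_haplotypes(alignment)
  S <- nrow(ps$sites)
  pi <- nucleotide_diversity(alignment)
  th <- watterson_theta(S, ps$n, ps$L_valid)
  hd <- if (ps$n >= 2L) haplotype_diversity(hap$counts) else 0
  td <- tajimas_d(alignment)
  structure(list(n = ps$n, L_valid = ps$L_valid, S = S,
                 indel_count = nrow(ps$indels),
                 singleton_count = sum(ps$sites$singleton),
                 H = hap$H, Hd = hd, pi = pi, theta_w = th,
                 tajima_D = td$D, tajima_class = td$tajima_class),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf(paste0("Diversity: n=%d L=%d S=%d (%d singleton) indels=%d ",
                     "H=%d Hd=%.3f pi=%.3g theta=%.3g D=%s (%s)\n"),
              x$n, x$L_valid, x$S, x$singleton_count, x$indel_count, x$H,
              x$Hd, x$pi, x$theta_w,
              ifelse(is.na(x$tajima_D), "NA", sprintf("%.3f", x$tajima_D)),
              x$tajima_class))
  invisible(x)
}

#' @method as.data.frame diversity_summary
#' @export
as.data.frame.diversity_summary <- function(x, ...) {
  data.frame(n = x$n, L_valid = x$L_valid, S = x$S,
             indel_count = x$indel_count,
             singleton_count = x$singleton_count, H = x$H, Hd = x$Hd,
             pi = x$pi, theta_w = x$theta_w, tajima_D = x$tajima_D,
             tajima_class = x$tajima_class, stringsAsFactors = FALSE)
}
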