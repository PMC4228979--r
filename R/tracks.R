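#' Render promoter annotation tracks as SVG
#'
#' Draws one horizontal track per promoter with a tick at the start
#' coordinate of every motif hit (colour-coded by TF family), plus a
#' consensus track when a `consensus_annotation` is supplied. The x axis
#' is the ATG-relative coordinate (start codon at the right edge). SVG is
#' written directly as text, so no graphics device is required.
#'
#' @param annotated An `annotated_promoters` object.
#' @param path Output `.svg` path.
#' @param consensus Optional `consensus_annotation` drawn as a final track.
#' @param width,track_height Figure geometry in pixels.
#' @return `path`, invisibly.
#' @export
write_track_svg <- function(annotated, path, consensus = NULL,
                            width = 900, track_height = 26) {
  stopifnot(inherits(annotated, "annotated_promoters"))
  fam_col <- c(DOF = "#e41a1c", bZIP = "#377eb8", RY = "#4daf4a",
               `AACA-MYB` = "#984ea3", `GATA-MYB` = "#ff7f00",
               OTHER = "#666666")
  fam_of <- stats::setNames(annotated$catalog$tf_family,
                            annotated$catalog$motif_id)
  members <- names(annotated$promoters)
  n_tracks <- length(members) + as.integer(!is.null(consensus))
  margin_l <- 110; margin_r <- 20; margin_t <- 30
  height <- margin_t + n_tracks * track_height + 40
  xmin <- -max(nchar(annotated$promoters))
  x_of <- function(coord)
    margin_l + (coord - xmin) / (0 - xmin) * (width - margin_l - margin_r)

  esc <- function(s) gsub("&", "&amp;", gsub("<", "&lt;", s, fixed = TRUE),
                          fixed = TRUE)
  out <- c(sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" ',
                          'width="%d" height="%d" font-family="sans-serif" ',
                          'font-size="10">'), width, height))
  ## axis
  ax_y <- margin_t + n_tracks * track_height + 14
  out <- c(out, sprintf(
    '<line x1="%.1f" y1="%d" x2="%.1f" y2="%d" stroke="black"/>',
    x_of(xmin), ax_y, x_of(0), ax_y))
  for (tick in pretty(c(xmin, 0), n = 8)) {
    if (tick < xmin || tick > 0) next
    out <- c(out, sprintf(
      '<line x1="%.1f" y1="%d" x2="%.1f" y2="%d" stroke="black"/>',
      x_of(tick), ax_y, x_of(tick), ax_y + 4),
      sprintf('<text x="%.1f" y="%d" text-anchor="middle">%d</text>',
              x_of(tick), ax_y + 15, as.integer(tick)))
  }
  draw_track <- function(label, row, starts, motif_ids, Lrow) {
    y <- margin_t + (row - 1L) * track_height + track_height / 2
    c(sprintf('<text x="4" y="%.1f" dominant-baseline="middle">%s</text>',
              y, esc(label)),
      sprintf('<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#bbbbbb"/>',
              x_of(-Lrow), y, x_of(0), y),
      if (length(starts)) sprintf(
        paste0('<rect x="%.1f" y="%.1f" width="3" height="%.1f" ',
               'fill="%s"><title>%s</title></rect>'),
        x_of(starts) - 1.5, y - track_height * 0.35, track_height * 0.7,
        fam_col[fam_of[motif_ids]],
        esc(sprintf("%s @ %d", motif_ids, starts))))
  }
  for (i in seq_along(members)) {
    h <- annotated$hits[annotated$hits$seq_id == members[i] &
                        annotated$hits$strand == "+", , drop = FALSE]
    out <- c(out, draw_track(members[i], i, h$start, h$motif_id,
                             nchar(annotated$promoters[[i]])))
  }
  if (!is.null(consensus)) {
    cons <- consensus$conserved
    out <- c(out, draw_track(paste0(consensus$set_id, " (consensus)"),
                             length(members) + 1L, cons$ref_coordinate,
                             cons$motif_id, -xmin))
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}
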