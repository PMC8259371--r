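#' Build an idiogram drawing specification
#'
#' One drawing record per haploid chromosome, ordered left-to-right by
#' decreasing total length.  Each chromosome is a vertical bar split at the
#' centromere: the short arm is drawn above the centromere line and the
#' long arm below, with segment heights proportional to the mean arm
#' lengths.
#'
#' @param karyotype a [mean_karyotype()].
#' @param scale drawing units per micrometre (default 24).  Pass the same
#'   value (e.g. from [cohort_scale()]) across accessions to make a cohort
#'   of idiograms directly comparable.
#' @return object of class `idiogram_spec`: list with `chromosomes` (data
#'   frame `position`, `p`, `q`, `cl`, `levan`), `scale`, `accession_id`.
#' @export
build_idiogram <- function(karyotype, scale = 24) {
  k <- as_karyotype_df(karyotype)
  ord <- order(k$cl, decreasing = TRUE)
  chromosomes <- data.frame(position = seq_along(ord), p = k$p[ord],
                            q = k$q[ord], cl = k$cl[ord],
                            levan = k$levan[ord], stringsAsFactors = FALSE)
  structure(list(chromosomes = chromosomes, scale = scale,
                 accession_id = attr(karyotype, "accession_id")),
            class = "idiogram_spec")
}

#' Common idiogram scale for a cohort
#'
#' Chooses one micrometre-to-unit scale so the longest chromosome of the
#' whole cohort fits a target bar height; applying it to every accession
#' keeps all idiograms on identical physical scale.
#'
#' @param karyotypes list of [mean_karyotype()] objects.
#' @param max_bar tallest allowed arm-to-arm bar, drawing units.
#' @return scale (units per um).
#' @export
cohort_scale <- function(karyotypes, max_bar = 160) {
  if (!length(karyotypes)) stop("empty cohort")
  max_bar / max(vapply(karyotypes, function(k) max(as_karyotype_df(k)$cl),
                       numeric(1)))
}

num <- function(x) sprintf("%.4f", x)

#' Render an idiogram as SVG
#'
#' Deterministic vector output: element order and coordinate formatting
#' are stable, so identical specs give byte-identical SVG.
#'
#' @param spec an [build_idiogram()] specification.
#' @param path optional file to write to.
#' @return SVG document as a character vector of lines (invisibly when
#'   written to `path`).
#' @export
render_idiogram <- function(spec, path = NULL) {
  chr <- spec$chromosomes
  bar_w <- 14; gap <- 12; margin <- 30; cent_gap <- 3
  n <- nrow(chr)
  max_p <- if (n) max(chr$p) * spec$scale else 0
  max_q <- if (n) max(chr$q) * spec$scale else 0
  width <- 2 * margin + if (n) n * bar_w + (n - 1) * gap else 0
  base_y <- margin + max_p + cent_gap
  height <- base_y + max_q + 2 * margin
  lines <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s">',
                     num(width), num(height)),
             sprintf('<!-- idiogram %s -->',
                     if (is.null(spec$accession_id)) "" else spec$accession_id))
  for (i in seq_len(n)) {
    x <- margin + (i - 1) * (bar_w + gap)
    hp <- chr$p[i] * spec$scale
    hq <- chr$q[i] * spec$scale
    lines <- c(lines,
      sprintf('<rect class="short-arm" x="%s" y="%s" width="%s" height="%s" rx="3" fill="#6b7fb3" stroke="#223"/>',
              num(x), num(base_y - cent_gap - hp), num(bar_w), num(hp)),
      sprintf('<rect class="long-arm" x="%s" y="%s" width="%s" height="%s" rx="3" fill="#9db3d6" stroke="#223"/>',
              num(x), num(base_y), num(bar_w), num(hq)),
      sprintf('<text x="%s" y="%s" font-size="10" text-anchor="middle">%d</text>',
              num(x + bar_w / 2), num(base_y + max_q + 14), chr$position[i]),
      sprintf('<text x="%s" y="%s" font-size="9" text-anchor="middle">%s</text>',
              num(x + bar_w / 2), num(base_y + max_q + 26), chr$levan[i]))
  }
  lines <- c(lines, "</svg>")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Render an asymmetry scatter as SVG
#'
#' @param spec an [asymmetry_scatter()] specification.
#' @param path optional file to write to.
#' @param width,height canvas size in drawing units.
#' @return SVG lines (invisibly when written to `path`).
#' @export
render_scatter <- function(spec, path = NULL, width = 480, height = 360) {
  pts <- spec$points
  margin <- 50
  lines <- sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                   width, height)
  lines <- c(lines,
    sprintf('<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="#000"/>',
            margin, height - margin, width - margin %/% 2, height - margin),
    sprintf('<line x1="%d" y1="%d" x2="%d" y2="%d" stroke="#000"/>',
            margin, height - margin, margin, margin %/% 2),
    sprintf('<text x="%d" y="%d" font-size="11" text-anchor="middle">%s</text>',
            width %/% 2, height - 10, spec$xlab),
    sprintf('<text x="14" y="%d" font-size="11" text-anchor="middle" transform="rotate(-90 14 %d)">%s</text>',
            height %/% 2, height %/% 2, spec$ylab))
  if (nrow(pts)) {
    xr <- range(pts$x); yr <- range(pts$y)
    pad <- function(r) if (diff(r) == 0) r + c(-1, 1) else r + diff(r) * c(-0.06, 0.06)
    xr <- pad(xr); yr <- pad(yr)
    sx <- function(v) margin + (v - xr[1]) / diff(xr) * (width - 1.5 * margin)
    sy <- function(v) (height - margin) - (v - yr[1]) / diff(yr) * (height - 1.5 * margin)
    for (i in seq_len(nrow(pts))) {
      lines <- c(lines,
        sprintf('<circle cx="%s" cy="%s" r="3.5" fill="#35618f"/>',
                num(sx(pts$x[i])), num(sy(pts$y[i]))),
        sprintf('<text x="%s" y="%s" font-size="9">%s</text>',
                num(sx(pts$x[i]) + 5), num(sy(pts$y[i]) - 4), pts$label[i]))
    }
  }
  lines <- c(lines, "</svg>")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Render a dendrogram as SVG
#'
#' Rectangular layout with leaves on the bottom and a height axis on the
#' left; an optional horizontal line marks a cut height.
#'
#' @param tree an `hclust`-structured tree (e.g. [upgma()]).
#' @param path optional file to write to.
#' @param cut optional cut height to draw as a dashed line.
#' @param width,height canvas size in drawing units.
#' @return SVG lines (invisibly when written to `path`).
#' @export
render_dendrogram <- function(tree, path = NULL, cut = NULL,
                              width = 560, height = 420) {
  n <- length(tree$labels)
  margin <- 55
  leaf_x <- numeric(n)
  leaf_x[tree$order] <- margin + (seq_len(n) - 1) /
    max(1, n - 1) * (width - 2 * margin)
  top <- max(tree$height)
  sy <- function(h) (height - margin) - h / top * (height - 2 * margin)
  node_x <- numeric(n - 1)
  lines <- sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
                   width, height)
  pos <- function(v) if (v < 0) c(leaf_x[-v], sy(0)) else c(node_x[v], sy(tree$height[v]))
  for (k in seq_len(n - 1)) {
    a <- pos(tree$merge[k, 1]); b <- pos(tree$merge[k, 2])
    y <- sy(tree$height[k])
    node_x[k] <- (a[1] + b[1]) / 2
    lines <- c(lines,
      sprintf('<polyline points="%s,%s %s,%s %s,%s %s,%s" fill="none" stroke="#223"/>',
              num(a[1]), num(a[2]), num(a[1]), num(y),
              num(b[1]), num(y), num(b[1]), num(b[2])))
  }
  for (i in seq_len(n)) {
    lines <- c(lines,
      sprintf('<text x="%s" y="%s" font-size="9" text-anchor="middle">%s</text>',
              num(leaf_x[i]), num(height - margin + 14), tree$labels[i]))
  }
  ticks <- pretty(c(0, top), 5)
  ticks <- ticks[ticks >= 0 & ticks <= top]
  for (t in ticks) {
    lines <- c(lines,
      sprintf('<text x="%d" y="%s" font-size="9" text-anchor="end">%s</text>',
              margin - 8, num(sy(t) + 3), format(t)))
  }
  if (!is.null(cut)) {
    lines <- c(lines,
      sprintf('<line x1="%d" y1="%s" x2="%d" y2="%s" stroke="#b33" stroke-dasharray="5,4"/>',
              margin, num(sy(cut)), width - margin, num(sy(cut))))
  }
  lines <- c(lines, "</svg>")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
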