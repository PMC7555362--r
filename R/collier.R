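# Collier de Perles layout (one- and two-layer) and deterministic SVG
# rendering of numbered domains.

# front/back sheet membership for the two-layer display
.layer_of <- function(kind, segment) {
  front <- if (kind == "V") c("G", "F", "C", "C'", "C''") else
    c("G", "F", "C")
  loops <- c("BC", "C'C''", "FG")
  if (segment %in% front) "front"
  else if (segment %in% loops) "loop"
  else if (segment == "CD") "transversal"
  else "back"
}

#' Lay out a numbered domain as a Collier de Perles
#'
#' Places one glyph ("pearl") per canonical position: occupied positions
#' carry their residue, unoccupied canonical positions are hatched. Glyph
#' coordinates follow a fixed per-segment serpentine grid (strands run
#' vertically, alternating direction; loops arc over the top row). The
#' layout is a pure function of the domain and `layers`: the contract is
#' strand membership and ordering, not absolute geometry. On two layers
#' the G, F, C (+C', C'' for V domains) strands form the front sheet and
#' A, B, E, D the back sheet; the C-domain CD strand is transversal.
#'
#' @param domain a `numbered_domain`.
#' @param layers 1 or 2.
#' @param rearrangement `"VDJ"` or `"VJ"`; selects the CDR colour variant
#'   used at rendering (heavy- vs light-chain palette).
#' @param bonds optional data.frame of position pairs (`from`, `to`) to draw
#'   as hydrogen bonds; bonds are input data, never computed.
#' @return object of class `perle_layout`: list with `glyphs` (data.frame:
#'   `position`, `aa`, `segment`, `x`, `y`, `layer`, `shape`, `fill_class`,
#'   `gap`), `layers`, `kind`, `rearrangement`, `bonds`.
#' @export
layout_domain <- function(domain, layers = 1, rearrangement = c("VDJ", "VJ"),
                          bonds = NULL) {
  stopifnot(inherits(domain, "numbered_domain"))
  rearrangement <- match.arg(rearrangement)
  if (!layers %in% c(1, 2)) stop("layers must be 1 or 2", call. = FALSE)
  kind <- domain$kind
  topo <- domain_topology(kind)
  res <- domain$residues
  # glyph table: occupied residues plus hatched canonical gaps
  gap_seg <- vapply(as.integer(domain$gaps), function(b) {
    labs <- topo$segments$label
    for (lab in labs) {
      rng <- .segment_base_range(kind, lab)
      if (!is.null(rng) && b >= rng[1] && b <= rng[2]) return(lab)
    }
    NA_character_
  }, character(1))
  g <- rbind(
    data.frame(position = res$position, aa = res$aa, segment = res$segment,
               region = res$region, anchor = res$anchor, gap = FALSE,
               stringsAsFactors = FALSE),
    if (length(domain$gaps)) {
      data.frame(position = domain$gaps, aa = "", segment = gap_seg,
                 region = NA_character_,
                 anchor = domain$gaps %in% as.character(topo$anchors),
                 gap = TRUE, stringsAsFactors = FALSE)
    })
  g <- g[order(imgt_position_key(g$position)), , drop = FALSE]
  rownames(g) <- NULL
  # serpentine coordinates: each segment is a column, residues stack in y;
  # strand direction alternates with segment index
  seg_order <- topo$segments$label
  seg_idx <- match(g$segment, seg_order)
  g$layer <- vapply(g$segment, function(s) .layer_of(kind, s), character(1))
  x0 <- ifelse(g$layer == "back" & layers == 2, 0.45, 0)
  g$x <- seg_idx * 2 + x0
  g$y <- NA_real_
  for (s in unique(g$segment)) {
    i <- which(g$segment == s)
    n <- length(i)
    up <- match(s, seg_order) %% 2L == 0L
    ys <- seq_len(n)
    if (up) ys <- rev(ys)
    ty <- topo$segments$type[match(s, seg_order)]
    if (ty == "loop") {
      # arc over the top: first half ascends, apex, second half descends
      half <- ceiling(n / 2)
      ys <- c(seq_len(half), rev(seq_len(n - half)))
      ys <- max(ys) + 1 - ys
    }
    g$y[i] <- ys
  }
  hyd <- c(.hydrophobic_set(), "W")
  g$fill_class <- ifelse(
    !is.na(g$region) & g$region == "CDR1", "cdr1",
    ifelse(!is.na(g$region) & g$region == "CDR2", "cdr2",
      ifelse(!is.na(g$region) & g$region == "CDR3", "cdr3",
        ifelse(g$gap, "gap",
          ifelse(g$aa == "P", "proline",
            ifelse(g$aa %in% hyd, "hydrophobic", "plain"))))))
  g$shape <- ifelse(g$anchor, "square", "circle")
  if (!is.null(bonds)) {
    stopifnot(all(c("from", "to") %in% names(bonds)))
  }
  structure(list(glyphs = g, layers = layers, kind = kind,
                 rearrangement = rearrangement, bonds = bonds),
            class = "perle_layout")
}

#' @export
print.perle_layout <- function(x, ...) {
  cat(sprintf("<perle_layout> %s domain, %d layer(s), %d glyphs (%d hatched)\n",
              x$kind, x$layers, nrow(x$glyphs), sum(x$glyphs$gap)))
  invisible(x)
}

# palettes: heavy-chain (V-D-J) CDRs red/orange/purple; light-chain (V-J)
# blue/green/bluegreen
.perle_palette <- function(rearrangement) {
  cdr <- if (rearrangement == "VDJ") {
    c(cdr1 = "#cc0000", cdr2 = "#ff8800", cdr3 = "#7700aa")
  } else {
    c(cdr1 = "#0044cc", cdr2 = "#008833", cdr3 = "#008888")
  }
  c(cdr, hydrophobic = "#99bbee", proline = "#eedd44", plain = "#ffffff",
    gap = "#ffffff")
}

#' Render a Collier de Perles layout as SVG
#'
#' Deterministic rendering: identical layouts give byte-identical SVG.
#' Anchors are drawn as squares, gaps with hatching, the 23-104 disulfide
#' bridge when both cysteine positions are occupied, and any supplied
#' hydrogen bonds.
#'
#' @param layout a `perle_layout`.
#' @param path optional output file; when `NULL` the SVG text is returned.
#' @param scale grid-to-pixel factor (default 22).
#' @return the SVG document as a single character string (invisibly when
#'   written to `path`).
#' @export
render_svg <- function(layout, path = NULL, scale = 22) {
  stopifnot(inherits(layout, "perle_layout"))
  g <- layout$glyphs
  pal <- .perle_palette(layout$rearrangement)
  r <- scale * 0.42
  px <- function(v) sprintf("%.1f", v * scale + 2 * scale)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" height=\"%d\">",
            as.integer((max(g$x, 0) + 4) * scale),
            as.integer((max(g$y, 0) + 4) * scale)),
    "<defs><pattern id=\"hatch\" width=\"4\" height=\"4\" patternUnits=\"userSpaceOnUse\">",
    "<path d=\"M0,4 L4,0\" stroke=\"#888888\" stroke-width=\"1\"/>",
    "</pattern></defs>")
  # disulfide bridge 23-104 when both occupied
  i23 <- which(g$position == "23" & !g$gap)
  i104 <- which(g$position == "104" & !g$gap)
  if (length(i23) == 1L && length(i104) == 1L) {
    lines <- c(lines, sprintf(
      "<line class=\"disulfide\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#ee7700\" stroke-width=\"2\"/>",
      px(g$x[i23]), px(g$y[i23]), px(g$x[i104]), px(g$y[i104])))
  }
  if (!is.null(layout$bonds)) {
    for (k in seq_len(nrow(layout$bonds))) {
      a <- which(g$position == as.character(layout$bonds$from[k]))
      b <- which(g$position == as.character(layout$bonds$to[k]))
      if (length(a) == 1L && length(b) == 1L) {
        lines <- c(lines, sprintf(
          "<line class=\"bond\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" stroke=\"#44aa44\" stroke-width=\"1\"/>",
          px(g$x[a]), px(g$y[a]), px(g$x[b]), px(g$y[b])))
      }
    }
  }
  for (i in seq_len(nrow(g))) {
    fill <- if (g$gap[i]) "url(#hatch)" else unname(pal[g$fill_class[i]])
    cls <- sprintf("glyph %s%s", g$fill_class[i],
                   if (g$gap[i]) " gap" else "")
    if (g$shape[i] == "square") {
      lines <- c(lines, sprintf(
        "<rect class=\"%s\" data-position=\"%s\" x=\"%.1f\" y=\"%.1f\" width=\"%.1f\" height=\"%.1f\" fill=\"%s\" stroke=\"#222222\"/>",
        cls, g$position[i],
        as.numeric(px(g$x[i])) - r, as.numeric(px(g$y[i])) - r, 2 * r,
        2 * r, fill))
    } else {
      lines <- c(lines, sprintf(
        "<circle class=\"%s\" data-position=\"%s\" cx=\"%s\" cy=\"%s\" r=\"%.1f\" fill=\"%s\" stroke=\"#222222\"/>",
        cls, g$position[i], px(g$x[i]), px(g$y[i]), r, fill))
    }
    if (!g$gap[i] && nzchar(g$aa[i])) {
      lines <- c(lines, sprintf(
        "<text x=\"%s\" y=\"%s\" text-anchor=\"middle\" dominant-baseline=\"middle\" font-size=\"%.1f\">%s</text>",
        px(g$x[i]), px(g$y[i]), scale * 0.55, g$aa[i]))
    }
  }
  lines <- c(lines, "</svg>")
  doc <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Glyph table of a layout as JSON
#'
#' @param layout a `perle_layout`.
#' @param path optional output file.
#' @return JSON string (invisibly when written).
#' @export
layout_json <- function(layout, path = NULL) {
  stopifnot(inherits(layout, "perle_layout"))
  js <- jsonlite::toJSON(layout$glyphs, dataframe = "rows", digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
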