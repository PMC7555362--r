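# Human IG locus gene tables: loading/validation, summaries, combinatorial
# diversity arithmetic, protein displays and the membrane-anchor exon model.

.repertoire_env <- new.env(parent = emptyenv())

#' Parse an IMGT gene name
#'
#' Splits a gene name into locus, group, subgroup and localization parts.
#' V/D/J genes carry the group letter after the locus (`IGHV1-69D` ->
#' group IGHV, subgroup 1, localization "69D"); constant genes (IGHM,
#' IGHG3, IGKC, IGLC7, IGHEP1, IGHGP) belong to the C group of their locus.
#'
#' @param name character vector of gene names.
#' @return data.frame with `name`, `locus`, `group`, `subgroup`,
#'   `localization`.
#' @export
parse_gene_name <- function(name) {
  out <- lapply(as.character(name), function(nm) {
    locus <- substr(nm, 1, 3)
    if (!locus %in% c("IGH", "IGK", "IGL")) {
      stop("cannot parse gene name '", nm, "': unknown locus", call. = FALSE)
    }
    rest <- substring(nm, 4)
    type <- substr(rest, 1, 1)
    if (type %in% c("V", "D", "J") &&
        grepl("^[VDJ][0-9]", rest)) {
      m <- regmatches(rest, regexec("^([VDJ])([0-9]+)(D?)(?:-(.+))?$",
                                    rest))[[1]]
      if (length(m) == 0L) {
        stop("cannot parse gene name '", nm, "'", call. = FALSE)
      }
      data.frame(name = nm, locus = locus, group = paste0(locus, m[2]),
                 subgroup = as.integer(m[3]),
                 localization = if (is.na(m[5]) || m[5] == "") m[4] else
                   paste0(m[4], m[5], if (nzchar(m[4])) "" else ""),
                 stringsAsFactors = FALSE)
    } else if (type %in% c("V", "D", "J") && nchar(rest) > 1L &&
               grepl("^[VDJ]", rest)) {
      # J genes without subgroup (IGHJ4, IGKJ1, IGLJ2) and NL-style names
      m <- regmatches(rest, regexec("^([VDJ])(.*)$", rest))[[1]]
      data.frame(name = nm, locus = locus, group = paste0(locus, m[2]),
                 subgroup = NA_integer_, localization = m[3],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(name = nm, locus = locus, group = paste0(locus, "C"),
                 subgroup = NA_integer_, localization = rest,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Load the packaged human IG locus gene tables
#'
#' Reads the transcribed gene tables (one record per gene: subgroup, CDR
#' lengths for V genes, allele counts by functionality, CNV tags, cluster,
#' gene order) and the per-group totals, parse-checks every gene name, and
#' validates record counts against the totals for the groups whose detailed
#' table is complete (IGHD, IGHC, IGKJ, IGKC, IGLJ, IGLC; the V tables list
#' only subgroups with at least one functional or ORF allele).
#'
#' @return named list of three `locus_table` objects (`IGH`, `IGK`, `IGL`),
#'   each with `locus`, `records` (data.frame), `totals` (data.frame).
#' @export
load_locus_tables <- function() {
  if (!is.null(.repertoire_env$tables)) return(.repertoire_env$tables)
  genes <- .read_fixture("ig_locus_genes.tsv")
  for (col in c("n_f", "n_f_prov", "n_orf", "n_p")) {
    genes[[col]] <- as.integer(genes[[col]])
  }
  genes$gene_order <- suppressWarnings(as.integer(genes$gene_order))
  totals <- .read_fixture("ig_locus_totals.tsv")
  for (col in c("genes_major", "genes_orphon", "alleles_major",
                "alleles_orphon")) {
    totals[[col]] <- as.integer(totals[[col]])
  }
  parsed <- parse_gene_name(genes$gene)
  if (!identical(parsed$group, genes$group)) {
    bad <- genes$gene[parsed$group != genes$group]
    stop("gene table parse check failed for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  # groups with complete detailed tables must match the printed totals
  complete <- c("IGHD", "IGHC", "IGKJ", "IGKC", "IGLJ", "IGLC")
  for (g in complete) {
    n_detail <- sum(genes$group == g)
    n_total <- totals$genes_major[totals$group == g]
    if (n_detail > n_total) {
      stop(sprintf("gene table for %s lists %d genes but the locus total is %d",
                   g, n_detail, n_total), call. = FALSE)
    }
  }
  # gene order indices unique within each locus
  for (loc in c("IGH", "IGK", "IGL")) {
    ords <- genes$gene_order[genes$locus == loc]
    ords <- ords[!is.na(ords)]
    if (anyDuplicated(ords)) {
      stop("duplicate gene order indices in ", loc, call. = FALSE)
    }
  }
  tabs <- lapply(c(IGH = "IGH", IGK = "IGK", IGL = "IGL"), function(loc) {
    structure(list(locus = loc,
                   records = genes[genes$locus == loc, , drop = FALSE],
                   totals = totals[totals$locus == loc, , drop = FALSE],
                   # printed cluster totals (the detailed V tables list only
                   # subgroups with functional/ORF alleles)
                   cluster_totals = if (loc == "IGK") {
                     data.frame(cluster = c("proximal", "distal"),
                                n_genes = c(40L, 36L),
                                stringsAsFactors = FALSE)
                   }),
              class = "locus_table")
  })
  .repertoire_env$tables <- tabs
  tabs
}

#' @export
print.locus_table <- function(x, ...) {
  cat(sprintf("<locus_table> %s: %d gene records, %d major-locus genes in totals\n",
              x$locus, nrow(x$records), sum(x$totals$genes_major)))
  invisible(x)
}

#' Summarize locus gene content
#'
#' @param tables list returned by [load_locus_tables()].
#' @param locus optional locus filter (`"IGH"`, `"IGK"`, `"IGL"`).
#' @param functional_only when TRUE, count only genes with at least one
#'   functional allele in the detailed tables.
#' @return list with `per_group` (data.frame: group, n_genes from the
#'   detailed table, totals columns) and `major_locus_total` (sum of the
#'   per-group major-locus gene totals over the selected loci).
#' @export
summarize_locus <- function(tables = load_locus_tables(), locus = NULL,
                            functional_only = FALSE) {
  sel <- if (is.null(locus)) names(tables) else {
    stopifnot(all(locus %in% names(tables)))
    locus
  }
  recs <- do.call(rbind, lapply(tables[sel], `[[`, "records"))
  tots <- do.call(rbind, lapply(tables[sel], `[[`, "totals"))
  if (functional_only) {
    recs <- recs[recs$n_f + recs$n_f_prov > 0L, , drop = FALSE]
  }
  n_genes <- tapply(rep(1L, nrow(recs)), recs$group, sum)
  per_group <- data.frame(group = tots$group,
                          n_detail = as.integer(n_genes[tots$group]),
                          genes_major = tots$genes_major,
                          genes_orphon = tots$genes_orphon,
                          alleles_major = tots$alleles_major,
                          stringsAsFactors = FALSE)
  per_group$n_detail[is.na(per_group$n_detail)] <- 0L
  list(per_group = per_group,
       major_locus_total = sum(tots$genes_major),
       orphon_total = sum(tots$genes_orphon))
}

#' Combinatorial diversity of a locus
#'
#' Raw product of functional V x D x J (IGH) or V x J (IGK, IGL) gene
#' counts from the detailed tables; no junctional diversity factor is
#' applied. A gene counts as functional when it has at least one functional
#' allele.
#'
#' @param tables list returned by [load_locus_tables()].
#' @param locus `"IGH"`, `"IGK"` or `"IGL"`.
#' @return list with the per-group functional counts and `product`.
#' @export
combinatorial_product <- function(tables = load_locus_tables(),
                                  locus = c("IGH", "IGK", "IGL")) {
  locus <- match.arg(locus)
  recs <- tables[[locus]]$records
  fun_count <- function(g) {
    r <- recs[recs$group == g, , drop = FALSE]
    sum(r$n_f + r$n_f_prov > 0L)
  }
  if (locus == "IGH") {
    counts <- c(V = fun_count("IGHV"), D = fun_count("IGHD"),
                J = fun_count("IGHJ"))
  } else {
    counts <- c(V = fun_count(paste0(locus, "V")),
                J = fun_count(paste0(locus, "J")))
  }
  list(counts = counts, product = prod(counts))
}

#' Membrane-anchor exon model of the IGHM gene
#'
#' The C-terminal anchor region of the membrane H-mu chain is encoded by
#' two exons: M1 (39 amino acids) and M2 (2 amino acids), 41 residues in
#' total, spanning the connecting region (CO, 13 aa), the transmembrane
#' region (TM, 27 aa) and the cytoplasmic region (CY, 1 aa). The secreted
#' H-mu chain ends in the 20-aa CHS tailpiece instead.
#'
#' @return list with `exons` (data.frame M1/M2), `regions` (data.frame
#'   CO/TM/CY), `anchor_length` (41), `chs_length` (20).
#' @export
ighm_membrane_exon_model <- function() {
  exons <- data.frame(exon = c("M1", "M2"), n_aa = c(39L, 2L),
                      stringsAsFactors = FALSE)
  regions <- data.frame(region = c("CO", "TM", "CY"),
                        n_aa = c(13L, 27L, 1L), stringsAsFactors = FALSE)
  stopifnot(sum(exons$n_aa) == sum(regions$n_aa))
  list(exons = exons, regions = regions,
       anchor_length = sum(exons$n_aa), chs_length = 20L)
}

#' Render a protein display of IMGT-gapped sequences
#'
#' Produces the fixed-width text block used for germline region displays:
#' a 7-line header for V domains (regions, region spans, strands/loops,
#' strand spans, arrows, positions, pipes) or a 5-line header for C domains
#' (strands/turns/loops, spans, arrows, positions, pipes), followed by one
#' line per sequence. Conserved columns 23, 41, 89 and 104 are marked with
#' `*` in the pipe line; asparagines of potential N-glycosylation motifs
#' N-X-S/T (X != P) are reported per sequence.
#'
#' @param seqs named character vector of IMGT-gapped sequences (gaps `.`),
#'   all the same width.
#' @param kind `"V"` or `"C"`.
#' @param scaffold optional per-column position labels (from
#'   [gapped_scaffold()]); required when columns include sub-positions
#'   (C-domain turns, long CDR3).
#' @return list of class `protein_display` with `header` (character lines),
#'   `body` (named lines), `glycosylation` (per-sequence column indices),
#'   printed by its `print` method.
#' @export
render_protein_display <- function(seqs, kind = c("V", "C"),
                                   scaffold = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("all gapped sequences must have equal width", call. = FALSE)
  }
  if (!any(grepl(".", seqs, fixed = TRUE)) && kind == "V" &&
      widths[1] < 100L) {
    stop("sequences do not look IMGT-gapped (no '.' and short width)",
         call. = FALSE)
  }
  width <- widths[1]
  topo <- domain_topology(kind)
  if (is.null(scaffold)) {
    # base-position scaffold; sub-position columns need an explicit one
    base_univ <- .base_universe(kind)
    if (length(base_univ) < width) {
      stop("gapped width ", width, " exceeds the base scaffold; pass the ",
           "domain's gapped_scaffold()", call. = FALSE)
    }
    scaffold <- as.character(base_univ[seq_len(width)])
  }
  if (length(scaffold) != width) {
    stop("scaffold length must equal the gapped width", call. = FALSE)
  }
  universe <- as.integer(floor(imgt_position_key(scaffold)))
  seg_of <- function(b) {
    segs <- topo$segments$label
    for (lab in segs) {
      rng <- .segment_base_range(kind, lab)
      if (!is.null(rng) && b >= rng[1] && b <= rng[2]) return(lab)
    }
    NA_character_
  }
  seg <- vapply(universe, seg_of, character(1))
  line_chr <- function(f) {
    paste(vapply(seq_along(universe), f, character(1)), collapse = "")
  }
  seg_line <- {
    # segment label printed at the first column of each segment
    out <- character(length(universe))
    prev <- ""
    for (i in seq_along(universe)) {
      out[i] <- if (!is.na(seg[i]) && seg[i] != prev) substr(seg[i], 1, 1)
        else " "
      if (!is.na(seg[i])) prev <- seg[i]
    }
    paste(out, collapse = "")
  }
  span_line <- {
    out <- rep(" ", length(universe))
    prev <- ""
    for (i in seq_along(universe)) {
      if (!is.na(seg[i]) && seg[i] != prev) out[i] <- "("
      if (!is.na(seg[i]) && (i == length(universe) ||
                             is.na(seg[i + 1]) || seg[i + 1] != seg[i])) {
        out[i] <- if (out[i] == "(") "|" else ")"
      }
      if (!is.na(seg[i])) prev <- seg[i]
    }
    paste(out, collapse = "")
  }
  arrow_line <- line_chr(function(i) {
    if (!is.na(seg[i]) &&
        topo$segments$type[match(seg[i], topo$segments$label)] == "strand")
      ">" else " "
  })
  pos_line <- line_chr(function(i) as.character(universe[i] %% 10L))
  pipe_line <- line_chr(function(i) {
    if (universe[i] %in% c(23L, 41L, 89L, 104L)) "*"
    else if (universe[i] %in% topo$anchors) "|"
    else "."
  })
  header <- if (kind == "V") {
    region <- topo$segments$region[match(seg, topo$segments$label)]
    region_line <- {
      out <- character(length(universe))
      prev <- ""
      for (i in seq_along(universe)) {
        out[i] <- if (!is.na(region[i]) && region[i] != prev)
          substr(region[i], 1, 1) else " "
        if (!is.na(region[i])) prev <- region[i]
      }
      paste(out, collapse = "")
    }
    region_span <- span_line
    c(region_line, region_span, seg_line, span_line, arrow_line, pos_line,
      pipe_line)
  } else {
    c(seg_line, span_line, arrow_line, pos_line, pipe_line)
  }
  glyc <- lapply(seqs, .glycosylation_columns)
  structure(list(header = header, body = seqs, glycosylation = glyc,
                 kind = kind),
            class = "protein_display")
}

# N-X-S/T motif columns (X != P) on the gapped sequence; returns the column
# index of each motif asparagine
.glycosylation_columns <- function(gapped) {
  chars <- strsplit(gapped, "")[[1]]
  idx <- which(chars != ".")
  aa <- chars[idx]
  hits <- integer(0)
  for (k in seq_len(length(aa) - 2L)) {
    if (aa[k] == "N" && aa[k + 1L] != "P" && aa[k + 2L] %in% c("S", "T")) {
      hits <- c(hits, idx[k])
    }
  }
  hits
}

#' @export
print.protein_display <- function(x, ...) {
  for (l in x$header) cat(l, "\n")
  for (nm in names(x$body)) cat(x$body[[nm]], " ", nm, "\n")
  invisible(x)
}

# base-position range of a segment (NULL for sub-position-only turns)
.segment_base_range <- function(kind, label) {
  v <- list("A" = c(1, 15), "B" = c(16, 26), "BC" = c(27, 38),
            "C" = if (kind == "V") c(39, 46) else c(39, 45),
            "C'" = c(47, 55), "C'C''" = c(56, 65), "C''" = c(66, 74),
            "D" = if (kind == "V") c(75, 84) else c(77, 84),
            "E" = c(85, 96), "F" = c(97, 104), "FG" = c(105, 117),
            "G" = c(118, 128))
  v[[label]]
}
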