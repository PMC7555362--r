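# Assignment of IMGT unique numbering to domain sequences, region
# delimitation, hallmark verification and identity percentages.

#' Assign IMGT numbering to a domain sequence
#'
#' Binds every residue of `sequence` to an IMGT position given the occupied
#' length of each region (V domain) or segment (C domain), applying the
#' topology gap rules: FR1/A-strand gap at 10 when one position short, C''
#' gap at 73, D-strand gaps at 81/82 (V) or 82 (C), loop gaps from the apex,
#' CDR3 insertions between 111 and 112, and ascending turn sub-positions
#' (15.x, 45.x, 96.x; the DE turn fills 84.x then 85.x from both ends).
#'
#' @param sequence amino-acid string (one-letter codes, no gaps).
#' @param boundaries integer vector of per-region lengths. For `kind = "V"`:
#'   7 values (FR1, CDR1, FR2, CDR2, FR3, CDR3, FR4). For `kind = "C"`:
#'   13 values, one per segment (A, AB, B, BC, C, CD, D, DE, E, EF, F, FG,
#'   G); turns may be 0.
#' @param kind `"V"` or `"C"`.
#' @return object of class `numbered_domain`: list with `kind`, `residues`
#'   (data.frame: `position`, `aa`, `region`, `segment`, `anchor`,
#'   `conserved`), and `gaps` (unoccupied canonical base positions).
#' @examples
#' vh <- assign_numbering(strrep("A", 120), c(25, 8, 17, 8, 38, 13, 11), "V")
#' nrow(vh$residues)
#' @export
assign_numbering <- function(sequence, boundaries, kind = c("V", "C")) {
  kind <- match.arg(kind)
  aa <- strsplit(toupper(sequence), "")[[1]]
  boundaries <- as.integer(boundaries)
  if (any(is.na(boundaries)) || any(boundaries < 0L)) {
    stop("boundaries must be non-negative integers", call. = FALSE)
  }
  if (sum(boundaries) != length(aa)) {
    stop(sprintf("sum of boundaries (%d) != sequence length (%d)",
                 sum(boundaries), length(aa)), call. = FALSE)
  }
  topo <- domain_topology(kind)
  if (kind == "V") {
    if (length(boundaries) != 7L) {
      stop("V-domain boundaries must give 7 region lengths", call. = FALSE)
    }
    seg_lens <- .v_region_to_segments(boundaries)
  } else {
    if (length(boundaries) != 13L) {
      stop("C-domain boundaries must give 13 segment lengths", call. = FALSE)
    }
    seg_lens <- stats::setNames(boundaries, topo$segments$label)
  }
  pos <- character(0)
  seg <- character(0)
  for (lab in topo$segments$label) {
    p <- .segment_positions(kind, lab, unname(seg_lens[lab]))
    pos <- c(pos, p)
    seg <- c(seg, rep(lab, length(p)))
  }
  stopifnot(length(pos) == length(aa))
  region <- topo$segments$region[match(seg, topo$segments$label)]
  if (kind == "C") region <- seg
  base <- floor(imgt_position_key(pos))
  residues <- data.frame(
    position = pos,
    aa = aa,
    region = region,
    segment = seg,
    anchor = pos %in% as.character(topo$anchors),
    conserved = pos %in% names(topo$conserved),
    stringsAsFactors = FALSE)
  key <- imgt_position_key(pos)
  if (is.unsorted(key, strictly = TRUE)) {
    stop("internal error: positions not strictly increasing", call. = FALSE)
  }
  gaps <- setdiff(as.character(.base_universe(kind)), pos[base == key])
  gaps <- gaps[order(as.integer(gaps))]
  # only gaps inside the occupied span are meaningful for display
  span <- range(key)
  gaps <- gaps[as.integer(gaps) > span[1] & as.integer(gaps) < span[2]]
  structure(list(kind = kind, residues = residues, gaps = gaps),
            class = "numbered_domain")
}

# split V region lengths into strand-level segment lengths
.v_region_to_segments <- function(b) {
  names(b) <- c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")
  if (b["FR1"] < 12L || b["FR1"] > 26L) {
    stop("FR1 length must be 12-26 (B strand is fixed at 11)", call. = FALSE)
  }
  if (b["FR2"] != 17L) {
    stop("FR2 length must be 17 (C and C' strands admit no gaps)",
         call. = FALSE)
  }
  cd <- switch(as.character(b["FR3"]),
               "39" = c(9L, 10L), "38" = c(8L, 10L),
               "37" = c(9L, 8L), "36" = c(8L, 8L),
               stop("FR3 length must be 36-39", call. = FALSE))
  c(A = unname(b["FR1"]) - 11L, B = 11L, BC = unname(b["CDR1"]), C = 8L,
    "C'" = 9L, "C'C''" = unname(b["CDR2"]), "C''" = cd[1], D = cd[2],
    E = 12L, F = 8L, FG = unname(b["CDR3"]), G = unname(b["FR4"]))
}

#' @export
print.numbered_domain <- function(x, ...) {
  cat(sprintf("<numbered_domain> %s domain, %d residues, %d canonical gaps\n",
              x$kind, nrow(x$residues), length(x$gaps)))
  if (x$kind == "V") {
    d <- delimit_regions(x)
    cat(sprintf("  CDR-IMGT %s  FR-IMGT %s\n", d$cdr_notation,
                d$fr_notation))
  }
  invisible(x)
}

#' Region delimitation of a numbered V domain
#'
#' @param domain a `numbered_domain` of kind `"V"`.
#' @return list with `cdr_lengths` (length-3 integer), `fr_lengths`
#'   (length-4 integer), `junction_length` (`cdr3 + 2`, for the junction
#'   spanning anchors 104 and 118), and the bracketed notations
#'   `cdr_notation` / `fr_notation` (e.g. `"[8.8.13]"`).
#' @export
delimit_regions <- function(domain) {
  stopifnot(inherits(domain, "numbered_domain"))
  if (domain$kind != "V") {
    stop("region delimitation is defined for V domains only", call. = FALSE)
  }
  tab <- table(factor(domain$residues$region,
                      levels = c("FR1", "CDR1", "FR2", "CDR2", "FR3",
                                 "CDR3", "FR4")))
  cdr <- as.integer(tab[c("CDR1", "CDR2", "CDR3")])
  fr <- as.integer(tab[c("FR1", "FR2", "FR3", "FR4")])
  list(cdr_lengths = cdr, fr_lengths = fr,
       junction_length = cdr[3] + 2L,
       cdr_notation = sprintf("[%d.%d.%d]", cdr[1], cdr[2], cdr[3]),
       fr_notation = sprintf("[%d.%d.%d.%d]", fr[1], fr[2], fr[3], fr[4]))
}

#' Verify conserved hallmarks of a numbered domain
#'
#' Checks 23 (1st-CYS), 41 (CONSERVED-TRP), 89 (hydrophobic), 104 (2nd-CYS)
#' and, for V domains, 118 (J-PHE/J-TRP) and the J motif F/W-G-X-G at
#' 118-121. Deviations are reported, not fatal.
#'
#' @param domain a `numbered_domain`.
#' @return data.frame with columns `check`, `position`, `expected`,
#'   `observed`, `pass`.
#' @export
verify_hallmarks <- function(domain) {
  stopifnot(inherits(domain, "numbered_domain"))
  res <- domain$residues
  at <- function(p) {
    i <- match(as.character(p), res$position)
    if (is.na(i)) NA_character_ else res$aa[i]
  }
  hyd <- .hydrophobic_set()
  rows <- list(
    c("1st-CYS", "23", "C", at(23), identical(at(23), "C")),
    c("CONSERVED-TRP", "41", "W", at(41), identical(at(41), "W")),
    c("hydrophobic-89", "89", paste(hyd, collapse = "/"), at(89),
      isTRUE(at(89) %in% hyd)),
    c("2nd-CYS", "104", "C", at(104), identical(at(104), "C")))
  if (domain$kind == "V") {
    rows <- c(rows, list(
      c("J-PHE/J-TRP", "118", "F/W", at(118), isTRUE(at(118) %in% c("F", "W"))),
      c("J-MOTIF", "118-121", "F/W-G-X-G",
        paste(vapply(118:121, at, character(1)), collapse = ""),
        isTRUE(at(118) %in% c("F", "W")) && identical(at(119), "G") &&
          !is.na(at(120)) && identical(at(121), "G"))))
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(check = r[[1]], position = r[[2]], expected = r[[3]],
               observed = if (is.na(r[[4]])) NA_character_ else r[[4]],
               pass = as.logical(r[[5]]), stringsAsFactors = FALSE)
  }))
  out$pass[is.na(out$pass)] <- FALSE
  out
}

#' Identity percentage between two numbered domains over a region
#'
#' Identity is computed over positions occupied in *both* domains (gaps in
#' either sequence are excluded from the denominator), as
#' `100 * identical / shared`, reported to one decimal.
#'
#' @param query,reference `numbered_domain` objects of the same kind.
#' @param region a region/segment label (e.g. `"FR3"`, `"CDR3"`) or `"all"`.
#' @return numeric percentage (one decimal).
#' @export
region_identity <- function(query, reference, region = "all") {
  stopifnot(inherits(query, "numbered_domain"),
            inherits(reference, "numbered_domain"))
  if (query$kind != reference$kind) {
    stop("query and reference must share the same domain kind", call. = FALSE)
  }
  pick <- function(d) {
    r <- d$residues
    if (!identical(region, "all")) r <- r[r$region == region, , drop = FALSE]
    r
  }
  q <- pick(query)
  r <- pick(reference)
  if (nrow(q) == 0L || nrow(r) == 0L) {
    stop(sprintf("region '%s' is empty in query or reference; identity undefined",
                 region), call. = FALSE)
  }
  shared <- intersect(q$position, r$position)
  if (length(shared) == 0L) {
    stop("no shared occupied positions; identity undefined", call. = FALSE)
  }
  same <- sum(q$aa[match(shared, q$position)] ==
                r$aa[match(shared, r$position)])
  round(100 * same / length(shared), 1)
}

#' Infer region boundaries of a query by alignment to a numbered reference
#'
#' Globally aligns `sequence` to the reference's residue string (affine
#' gaps; identity scoring +5/-4, gap open 12, extend 2), transfers the
#' reference's IMGT positions across the alignment, and reads region lengths
#' off the transferred positions. Query insertions are attributed to the
#' region of the preceding aligned reference residue.
#'
#' @param sequence amino-acid string (70-150 residues).
#' @param reference a fully numbered `numbered_domain`.
#' @return list with `boundaries` (named integer vector usable with
#'   [assign_numbering()]), `identity` (overall %), `region_identity`
#'   (named numeric), and the aligned strings.
#' @export
infer_boundaries <- function(sequence, reference) {
  stopifnot(inherits(reference, "numbered_domain"))
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 70L || n > 150L) {
    stop("query length ", n, " outside the plausible domain range 70-150",
         call. = FALSE)
  }
  ref <- reference$residues
  ref_seq <- paste(ref$aa, collapse = "")
  mat <- matrix(-4L, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(mat) <- 5L
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(sequence),
    subject = Biostrings::AAString(ref_seq),
    substitutionMatrix = mat, gapOpening = 12, gapExtension = 2,
    type = "global")
  qa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  region_levels <- if (reference$kind == "V") {
    c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4")
  } else {
    domain_topology("C")$segments$label
  }
  counts <- stats::setNames(integer(length(region_levels)), region_levels)
  ri <- 0L
  last_region <- region_levels[1]
  q_region <- character(0)
  q_pos <- character(0)
  for (k in seq_along(qa)) {
    if (ra[k] != "-") {
      ri <- ri + 1L
      last_region <- ref$region[ri]
    }
    if (qa[k] != "-") {
      counts[last_region] <- counts[last_region] + 1L
      q_region <- c(q_region, last_region)
      q_pos <- c(q_pos, if (ra[k] != "-") ref$position[ri] else NA_character_)
    }
  }
  # hallmark cysteines must transfer for a confident numbering
  qc <- q_pos[!is.na(q_pos)]
  qaa <- strsplit(sequence, "")[[1]][!is.na(q_pos)]
  c23 <- any(qc == "23" & qaa == "C")
  c104 <- any(qc == "104" & qaa == "C")
  if (!c23 || !c104) {
    stop("low-confidence alignment: no cysteine alignable to position ",
         paste(c("23", "104")[!c(c23, c104)], collapse = " or "),
         call. = FALSE)
  }
  matched <- !is.na(q_pos)
  ident <- round(100 * sum(qaa == ref$aa[match(qc, ref$position)]) /
                   length(qc), 1)
  per_region <- vapply(region_levels, function(rg) {
    sel <- matched & q_region == rg
    if (!any(sel)) return(NA_real_)
    p <- q_pos[sel]
    a <- strsplit(sequence, "")[[1]][sel]
    round(100 * sum(a == ref$aa[match(p, ref$position)]) / length(p), 1)
  }, numeric(1))
  list(boundaries = counts, identity = ident, region_identity = per_region,
       aligned_query = paste(qa, collapse = ""),
       aligned_reference = paste(ra, collapse = ""))
}

#' Gapped representation of a numbered domain
#'
#' Returns the sequence over the canonical position scaffold with `.` at
#' unoccupied (gap) positions, as used in IMGT-gapped FASTA and alignments.
#'
#' @param domain a `numbered_domain`.
#' @param span optional integer range of base positions (default: full
#'   canonical universe from position 1 to 128).
#' @return single character string.
#' @export
gapped_sequence <- function(domain, span = NULL) {
  stopifnot(inherits(domain, "numbered_domain"))
  res <- domain$residues
  key <- imgt_position_key(res$position)
  universe <- .base_universe(domain$kind)
  if (!is.null(span)) {
    universe <- universe[universe >= span[1] & universe <= span[2]]
  }
  out <- character(0)
  for (b in universe) {
    # a mirror base (112, 85) owns the keys in (b-0.5, b]; any other base
    # owns [b, b+0.5) when the next base is a mirror base, else [b, b+1)
    here <- if (b %in% .mirror_bases) {
      which(key > b - 0.5 & key <= b)
    } else if ((b + 1L) %in% .mirror_bases) {
      which(key >= b & key < b + 0.5)
    } else {
      which(key >= b & key < b + 1L)
    }
    if (length(here) == 0L) {
      out <- c(out, ".")
    } else {
      out <- c(out, res$aa[here])
    }
  }
  paste(out, collapse = "")
}

#' Column scaffold of the gapped representation
#'
#' Position labels aligned column-by-column with [gapped_sequence()]:
#' occupied sub-positions expand their base column, unoccupied canonical
#' positions keep the base label.
#'
#' @param domain a `numbered_domain`.
#' @param span optional integer range of base positions.
#' @return character vector of position labels.
#' @export
gapped_scaffold <- function(domain, span = NULL) {
  stopifnot(inherits(domain, "numbered_domain"))
  res <- domain$residues
  key <- imgt_position_key(res$position)
  universe <- .base_universe(domain$kind)
  if (!is.null(span)) {
    universe <- universe[universe >= span[1] & universe <= span[2]]
  }
  out <- character(0)
  for (b in universe) {
    here <- if (b %in% .mirror_bases) {
      which(key > b - 0.5 & key <= b)
    } else if ((b + 1L) %in% .mirror_bases) {
      which(key >= b & key < b + 0.5)
    } else {
      which(key >= b & key < b + 1L)
    }
    if (length(here) == 0L) {
      out <- c(out, as.character(b))
    } else {
      out <- c(out, res$position[here])
    }
  }
  out
}

#' Write numbered domains as IMGT-gapped FASTA
#'
#' @param domains named list of `numbered_domain` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gapped_fasta <- function(domains, path) {
  stopifnot(is.list(domains), length(names(domains)) == length(domains))
  seqs <- vapply(domains, gapped_sequence, character(1))
  xs <- Biostrings::AAStringSet(seqs)
  names(xs) <- names(domains)
  Biostrings::writeXStringSet(xs, filepath = path)
  invisible(path)
}

#' Per-residue annotation table of a numbered domain
#'
#' @param domain a `numbered_domain`.
#' @param path optional output TSV; when `NULL` the data.frame is returned
#'   only.
#' @return the annotation data.frame, invisibly when written.
#' @export
domain_annotation <- function(domain, path = NULL) {
  stopifnot(inherits(domain, "numbered_domain"))
  tab <- domain$residues
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
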