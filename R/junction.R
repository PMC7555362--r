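# V-(D)-J junction decomposition: germline 3'V / D / 5'J matching, exonuclease
# trims, palindromic P nucleotides and N regions, plus the decryption-string
# format (lengths in parentheses, N in braces, signed trim/P marks).

.revcomp <- function(x) {
  chartr("acgtACGT", "tgcaTGCA",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

.lc_prefix <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(a, "")[[1]][seq_len(n)]
  bv <- strsplit(b, "")[[1]][seq_len(n)]
  d <- which(av != bv)
  if (length(d) == 0L) n else d[1] - 1L
}

.lc_suffix <- function(a, b) {
  .lc_prefix(paste(rev(strsplit(a, "")[[1]]), collapse = ""),
             paste(rev(strsplit(b, "")[[1]]), collapse = ""))
}

# maximal exact matches (runs) between junction and one D reference:
# data.frame(s, e, ds, de) in 1-based junction / reference coordinates
.d_runs <- function(jv, dv) {
  L <- length(jv)
  Ld <- length(dv)
  runs <- list()
  for (diag in (-(Ld - 1L)):(L - 1L)) {
    i0 <- max(1L, 1L + diag)
    j0 <- i0 - diag
    len <- min(L - i0, Ld - j0) + 1L
    if (len < 1L) next
    m <- jv[i0:(i0 + len - 1L)] == dv[j0:(j0 + len - 1L)]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      runs[[length(runs) + 1L]] <-
        c(s = i0 + starts[k] - 1L, e = i0 + ends[k] - 1L,
          ds = j0 + starts[k] - 1L, de = j0 + ends[k] - 1L)
    }
  }
  if (length(runs) == 0L) {
    return(data.frame(s = integer(0), e = integer(0), ds = integer(0),
                      de = integer(0)))
  }
  as.data.frame(do.call(rbind, runs))
}

# longest k <= max_k such that gap[1..k] == revcomp of the last k nt of the
# intact end `end_seq` (P nucleotides read 5'->3' in the junction)
.p_len_after <- function(gap, end_seq, max_k = 3L) {
  max_k <- min(max_k, nchar(gap), nchar(end_seq))
  best <- 0L
  for (k in seq_len(max_k)) {
    p <- .revcomp(substr(end_seq, nchar(end_seq) - k + 1L, nchar(end_seq)))
    if (substr(gap, 1L, k) == p) best <- k
  }
  best
}

# longest k such that the last k nt of `gap` == revcomp of the first k nt of
# the intact end `start_seq`
.p_len_before <- function(gap, start_seq, max_k = 3L) {
  max_k <- min(max_k, nchar(gap), nchar(start_seq))
  best <- 0L
  for (k in seq_len(max_k)) {
    p <- .revcomp(substr(start_seq, 1L, k))
    if (substr(gap, nchar(gap) - k + 1L, nchar(gap)) == p) best <- k
  }
  best
}

#' Decompose a V-(D)-J junction against germline references
#'
#' Finds the decomposition `3'V + vP + N1 + d5P + D + d3P + N2 + jP + 5'J`
#' that maximizes the number of germline-matched nucleotides
#' (`v_len + d_len + j_len`), then the total P length. Trimmed nucleotides
#' and P nucleotides are mutually exclusive at each coding end: P segments
#' (1-3 nt, palindromic to the intact coding end) are only assigned when the
#' corresponding end is untrimmed. A D gene is only called when the best D
#' match reaches `min_d_length`; otherwise the decomposition is V-J-like
#' with a single N region.
#'
#' @param junction_nt junction nucleotide string (codon 104 through codon
#'   118), lower- or upper-case.
#' @param v3_ref germline 3'V nucleotides aligned to the junction start
#'   (5'->3').
#' @param d_refs named character vector/list of candidate D gene sequences
#'   (5'->3'), in gene order; may be empty for V-J loci.
#' @param j5_ref germline 5'J nucleotides aligned to the junction end.
#' @param min_d_length minimum accepted D match (default 5 nt).
#' @return object of class `junction_decomposition`: list with `v_len`,
#'   `d_len`, `j_len`, trims (`v_trim`, `d5_trim`, `d3_trim`, `j_trim`),
#'   P lengths (`v_p`, `d5_p`, `d3_p`, `j_p`), N strings `n1`, `n2`,
#'   `d_call`, and the segment strings.
#' @export
decompose_junction <- function(junction_nt, v3_ref, d_refs = character(0),
                               j5_ref, min_d_length = 5L) {
  jnt <- tolower(junction_nt)
  v3 <- tolower(v3_ref)
  j5 <- tolower(j5_ref)
  if (nchar(jnt) < 6L) {
    stop("junction shorter than 6 nt", call. = FALSE)
  }
  if (nchar(v3) == 0L || nchar(j5) == 0L) {
    stop("empty V or J reference", call. = FALSE)
  }
  d_refs <- vapply(as.list(d_refs), tolower, character(1))
  L <- nchar(jnt)
  jv <- strsplit(jnt, "")[[1]]
  maxv <- .lc_prefix(jnt, v3)
  maxj <- .lc_suffix(jnt, j5)

  cands <- list()
  add <- function(vl, jl, gene = NA_character_, ds = NA_integer_,
                  de = NA_integer_, s = NA_integer_) {
    if (vl < 0L || jl < 0L || vl + jl > L) return(invisible(NULL))
    cands[[length(cands) + 1L]] <<-
      list(vl = vl, jl = jl, gene = gene, ds = ds, de = de, s = s)
    invisible(NULL)
  }
  # no-D candidates
  add(maxv, min(maxj, L - maxv))
  add(min(maxv, L - maxj), maxj)
  # one candidate family per maximal exact match against each D gene
  for (g in names(d_refs)) {
    dv <- strsplit(d_refs[[g]], "")[[1]]
    runs <- .d_runs(jv, dv)
    for (r in seq_len(nrow(runs))) {
      s <- runs$s[r]; e <- runs$e[r]
      for (vl in unique(pmin(maxv, c(s - 1L, maxv)))) {
        for (jl in unique(pmin(maxj, c(L - e, maxj)))) {
          jl2 <- min(jl, L - vl)
          a <- vl + 1L
          b <- L - jl2
          dl <- min(e, b) - max(s, a) + 1L
          if (dl >= 1L) {
            off <- max(s, a) - s
            add(vl, jl2, gene = g, ds = runs$ds[r] + off,
                de = runs$ds[r] + off + dl - 1L, s = max(s, a))
          } else {
            add(vl, jl2)
          }
        }
      }
    }
  }

  gene_order <- names(d_refs)
  best <- NULL
  for (cand in cands) {
    dl <- if (!is.na(cand$gene)) cand$de - cand$ds + 1L else 0L
    if (dl < min_d_length) {
      cand$gene <- NA_character_
      cand$ds <- cand$de <- cand$s <- NA_integer_
      dl <- 0L
    }
    sc <- .score_candidate(cand, dl, jnt, v3, j5, d_refs, L, gene_order)
    if (is.null(best) || .better_candidate(sc, best)) best <- sc
  }
  .finalize_decomposition(best, jnt, v3, j5, d_refs, L)
}

# compute score, P lengths and ordering keys for one candidate
.score_candidate <- function(cand, dl, jnt, v3, j5, d_refs, L, gene_order) {
  vl <- cand$vl; jl <- cand$jl
  has_d <- !is.na(cand$gene)
  d_seq <- if (has_d) d_refs[[cand$gene]] else ""
  v_untrimmed <- vl == nchar(v3)
  j_untrimmed <- jl == nchar(j5)
  d5_untrimmed <- has_d && cand$ds == 1L
  d3_untrimmed <- has_d && cand$de == nchar(d_seq)
  # gap regions
  g1 <- if (has_d) substr(jnt, vl + 1L, cand$s - 1L) else
    substr(jnt, vl + 1L, L - jl)
  g2 <- if (has_d) substr(jnt, cand$s + dl, L - jl) else ""
  v_p <- if (v_untrimmed && nchar(g1)) .p_len_after(g1, v3) else 0L
  d5_p <- if (d5_untrimmed && nchar(g1)) {
    .p_len_before(substr(g1, v_p + 1L, nchar(g1)), d_seq)
  } else 0L
  d3_p <- if (d3_untrimmed && nchar(g2)) .p_len_after(g2, d_seq) else 0L
  j_gap <- if (has_d) substr(g2, d3_p + 1L, nchar(g2)) else
    substr(g1, v_p + 1L, nchar(g1))
  j_p <- if (j_untrimmed && nchar(j_gap)) .p_len_before(j_gap, j5) else 0L
  c(cand,
    list(dl = dl, v_p = v_p, d5_p = d5_p, d3_p = d3_p, j_p = j_p,
         score = vl + jl + dl, p_total = v_p + d5_p + d3_p + j_p,
         gene_rank = if (has_d) match(cand$gene, gene_order) else
           length(gene_order) + 1L))
}

.better_candidate <- function(a, b) {
  if (a$score != b$score) return(a$score > b$score)
  if (a$p_total != b$p_total) return(a$p_total > b$p_total)
  if (a$dl != b$dl) return(a$dl > b$dl)
  if (a$gene_rank != b$gene_rank) return(a$gene_rank < b$gene_rank)
  if (a$vl != b$vl) return(a$vl > b$vl)
  a$jl > b$jl
}

.finalize_decomposition <- function(c0, jnt, v3, j5, d_refs, L) {
  vl <- c0$vl; jl <- c0$jl; dl <- c0$dl
  has_d <- !is.na(c0$gene)
  d_seq <- if (has_d) d_refs[[c0$gene]] else ""
  s <- if (has_d) c0$s else NA_integer_
  v_seg <- substr(jnt, 1L, vl)
  j_seg <- if (jl > 0L) substr(jnt, L - jl + 1L, L) else ""
  d_seg <- if (has_d) substr(jnt, s, s + dl - 1L) else ""
  if (has_d) {
    g1 <- substr(jnt, vl + 1L, s - 1L)
    g2 <- substr(jnt, s + dl, L - jl)
    vp <- substr(g1, 1L, c0$v_p)
    d5p <- if (c0$d5_p > 0L)
      substr(g1, nchar(g1) - c0$d5_p + 1L, nchar(g1)) else ""
    n1 <- substr(g1, c0$v_p + 1L, nchar(g1) - c0$d5_p)
    d3p <- substr(g2, 1L, c0$d3_p)
    jp <- if (c0$j_p > 0L)
      substr(g2, nchar(g2) - c0$j_p + 1L, nchar(g2)) else ""
    n2 <- substr(g2, c0$d3_p + 1L, nchar(g2) - c0$j_p)
  } else {
    g1 <- substr(jnt, vl + 1L, L - jl)
    vp <- substr(g1, 1L, c0$v_p)
    jp <- if (c0$j_p > 0L)
      substr(g1, nchar(g1) - c0$j_p + 1L, nchar(g1)) else ""
    n1 <- substr(g1, c0$v_p + 1L, nchar(g1) - c0$j_p)
    d5p <- d3p <- n2 <- ""
  }
  structure(list(
    v_len = vl, d_len = dl, j_len = jl,
    v_trim = nchar(v3) - vl,
    d5_trim = if (has_d) c0$ds - 1L else NA_integer_,
    d3_trim = if (has_d) nchar(d_seq) - c0$de else NA_integer_,
    j_trim = nchar(j5) - jl,
    v_p = c0$v_p, d5_p = c0$d5_p, d3_p = c0$d3_p, j_p = c0$j_p,
    n1 = n1, n2 = n2,
    d_call = if (has_d) c0$gene else NA_character_,
    segments = list(v = v_seg, v_p = vp, n1 = n1, d5_p = d5p, d = d_seg,
                    d3_p = d3p, n2 = n2, j_p = jp, j = j_seg),
    junction = jnt),
    class = "junction_decomposition")
}

#' @export
print.junction_decomposition <- function(x, ...) {
  cat("<junction_decomposition>", format_decryption(x), "\n")
  invisible(x)
}

#' Reconstruct the junction from a decomposition
#'
#' @param d a `junction_decomposition`.
#' @return the concatenated nucleotide string; always equal to the input
#'   junction (reconstruction invariant).
#' @export
reconstruct_junction <- function(d) {
  stopifnot(inherits(d, "junction_decomposition"))
  paste0(d$segments$v, d$segments$v_p, d$segments$n1, d$segments$d5_p,
         d$segments$d, d$segments$d3_p, d$segments$n2, d$segments$j_p,
         d$segments$j)
}

# end mark: trims negative, P positive, zero omitted
.end_mark <- function(trim, p) {
  if (!is.na(trim) && trim > 0L) sprintf("-%d", trim)
  else if (p > 0L) sprintf("+%d", p)
  else ""
}

#' Format a decomposition as a decryption string
#'
#' Germline segment lengths appear in parentheses, N region lengths in
#' braces, and each coding end carries a signed mark: trimmed nucleotides as
#' a negative value, P nucleotides as a positive value (mutually exclusive);
#' zero marks are omitted. A V-D-J junction reads
#' `(v)mark{n1}mark(d)mark{n2}mark(j)`; a V-J junction has a single `{n}`.
#'
#' @param d a `junction_decomposition`.
#' @return character string.
#' @examples
#' # a fully germline V-D-J junction with N regions of 3 and 2 nt:
#' # "(7){3}(5){2}(15)"
#' @export
format_decryption <- function(d) {
  stopifnot(inherits(d, "junction_decomposition"))
  if (!is.na(d$d_call)) {
    paste0("(", d$v_len, ")", .end_mark(d$v_trim, d$v_p),
           "{", nchar(d$n1), "}", .end_mark(d$d5_trim, d$d5_p),
           "(", d$d_len, ")", .end_mark(d$d3_trim, d$d3_p),
           "{", nchar(d$n2), "}", .end_mark(d$j_trim, d$j_p),
           "(", d$j_len, ")")
  } else {
    paste0("(", d$v_len, ")", .end_mark(d$v_trim, d$v_p),
           "{", nchar(d$n1), "}", .end_mark(d$j_trim, d$j_p),
           "(", d$j_len, ")")
  }
}

#' Parse a decryption string (lengths-only form)
#'
#' @param s string produced by [format_decryption()].
#' @return list of class `junction_decryption_lengths` with the germline and
#'   N lengths and the signed end marks; sequence fields are empty.
#' @export
parse_decryption <- function(s) {
  tokens <- list()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    if (ch == "(") {
      m <- regmatches(substr(s, i, n), regexec("^\\(([0-9]+)\\)",
                                               substr(s, i, n)))[[1]]
      if (length(m) == 0L) stop("parse error at offset ", i, call. = FALSE)
      tokens[[length(tokens) + 1L]] <- list(type = "paren",
                                            value = as.integer(m[2]))
      i <- i + nchar(m[1])
    } else if (ch == "{") {
      m <- regmatches(substr(s, i, n), regexec("^\\{([0-9]+)\\}",
                                               substr(s, i, n)))[[1]]
      if (length(m) == 0L) stop("parse error at offset ", i, call. = FALSE)
      tokens[[length(tokens) + 1L]] <- list(type = "brace",
                                            value = as.integer(m[2]))
      i <- i + nchar(m[1])
    } else if (ch %in% c("-", "+")) {
      m <- regmatches(substr(s, i, n), regexec("^([-+][0-9]+)",
                                               substr(s, i, n)))[[1]]
      if (length(m) == 0L) stop("parse error at offset ", i, call. = FALSE)
      tokens[[length(tokens) + 1L]] <- list(type = "mark",
                                            value = as.integer(m[2]))
      i <- i + nchar(m[1])
    } else {
      stop("parse error at offset ", i, ": unexpected '", ch, "'",
           call. = FALSE)
    }
  }
  types <- vapply(tokens, `[[`, character(1), "type")
  vals <- vapply(tokens, `[[`, integer(1), "value")
  parens <- vals[types == "paren"]
  braces <- vals[types == "brace"]
  if (!(length(parens) == 3L && length(braces) == 2L) &&
      !(length(parens) == 2L && length(braces) == 1L)) {
    stop("parse error: expected (v){n}(j) or (v){n1}(d){n2}(j) shape",
         call. = FALSE)
  }
  structure(list(
    v_len = parens[1],
    d_len = if (length(parens) == 3L) parens[2] else NA_integer_,
    j_len = parens[length(parens)],
    n1_len = braces[1],
    n2_len = if (length(braces) == 2L) braces[2] else NA_integer_,
    marks = vals[types == "mark"]),
    class = "junction_decryption_lengths")
}
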