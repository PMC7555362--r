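# Domain topologies: strand/loop/turn segments, position universes, anchors
# and conserved hallmark positions for V and C domains.

#' Domain topology
#'
#' Segment layout of an immunoglobulin(-superfamily) domain under the IMGT
#' unique numbering. A V domain has nine antiparallel beta strands
#' (A, B, C, C', C'', D, E, F, G) and three loops (BC, C'C'', FG = CDR1-3 in
#' a V-DOMAIN); a C domain has seven strands, a transversal CD strand, two
#' loops (BC, FG) and three turns (AB, DE, EF). Six anchor positions flank
#' the loops: 26/39, 55/66 (V) or 45/77 (C), and 104/118.
#'
#' @param kind `"V"` or `"C"`.
#' @return list of class `domain_topology` with elements `kind`, `segments`
#'   (data.frame: `label`, `type`, `region`, `max_len`), `anchors` (integer
#'   positions), `conserved` (named character: hallmark positions).
#' @export
domain_topology <- function(kind = c("V", "C")) {
  kind <- match.arg(kind)
  if (kind == "V") {
    segments <- data.frame(
      label = c("A", "B", "BC", "C", "C'", "C'C''", "C''", "D", "E", "F",
                "FG", "G"),
      type = c("strand", "strand", "loop", "strand", "strand", "loop",
               "strand", "strand", "strand", "strand", "loop", "strand"),
      region = c("FR1", "FR1", "CDR1", "FR2", "FR2", "CDR2", "FR3", "FR3",
                 "FR3", "FR3", "CDR3", "FR4"),
      max_len = c(15L, 11L, 12L, 8L, 9L, 10L, 9L, 10L, 12L, 8L, 13L, 11L),
      stringsAsFactors = FALSE)
    anchors <- c(26L, 39L, 55L, 66L, 104L, 118L)
    conserved <- c(`23` = "1st-CYS", `41` = "CONSERVED-TRP",
                   `89` = "hydrophobic", `104` = "2nd-CYS",
                   `118` = "J-PHE/J-TRP")
  } else {
    segments <- data.frame(
      label = c("A", "AB", "B", "BC", "C", "CD", "D", "DE", "E", "EF", "F",
                "FG", "G"),
      type = c("strand", "turn", "strand", "loop", "strand", "strand",
               "strand", "turn", "strand", "turn", "strand", "loop",
               "strand"),
      region = NA_character_,
      max_len = c(15L, 3L, 11L, 10L, 7L, 9L, 8L, 14L, 12L, 2L, 8L, 13L,
                  11L),
      stringsAsFactors = FALSE)
    anchors <- c(26L, 39L, 45L, 77L, 104L, 118L)
    conserved <- c(`23` = "1st-CYS", `41` = "CONSERVED-TRP",
                   `89` = "hydrophobic", `104` = "2nd-CYS")
  }
  structure(list(kind = kind, segments = segments, anchors = anchors,
                 conserved = conserved),
            class = "domain_topology")
}

# canonical base-position universe (integer positions only; sub-positions
# are created on demand and are never counted as gaps)
.base_universe <- function(kind) {
  if (kind == "V") {
    seq_len(128L)
  } else {
    # C domains lack 32, 33 (BC loop) and 46-76 (replaced by the CD strand)
    setdiff(seq_len(128L), c(32L, 33L, 46:76))
  }
}

# positions of one segment at a given occupied length, applying the gap /
# insertion rules of the topology tables
.segment_positions <- function(kind, label, len) {
  err <- function(max) {
    stop(sprintf("%s-domain segment %s: length %d violates topology (max %s)",
                 kind, label, len, max), call. = FALSE)
  }
  fixed <- function(from, to) {
    n <- to - from + 1L
    if (len != n) err(n)
    as.character(seq.int(from, to))
  }
  lead_trim <- function(from, to, gap10) {
    # A strand: full, or gap at 10; shorter still drops N-terminal positions
    # (leader-truncation convention)
    n <- to - from + 1L
    if (len > n) err(n)
    keep <- as.character(seq.int(from, to))
    if (len < n && gap10) keep <- setdiff(keep, "10")
    if (len < length(keep)) keep <- keep[(length(keep) - len + 1L):length(keep)]
    keep
  }
  turn_asc <- function(base, max) {
    if (len > max) err(max)
    if (len == 0L) return(character(0))
    sprintf("%d.%d", base, seq_len(len))
  }
  switch(label,
    "A" = lead_trim(1L, 15L, gap10 = TRUE),
    "AB" = turn_asc(15L, 3L),
    "B" = fixed(16L, 26L),
    "BC" = if (kind == "V") {
      loop_position_sequence("BC", len)
    } else {
      .c_bc_loop(len)
    },
    "C" = if (kind == "V") fixed(39L, 46L) else fixed(39L, 45L),
    "C'" = fixed(47L, 55L),
    "C'C''" = loop_position_sequence("C'C''", len),
    "C''" = {  # 9, or 8 with gap at 73
      if (len == 9L) as.character(66:74)
      else if (len == 8L) as.character(setdiff(66:74, 73L))
      else err("9 (or 8 if gap at 73)")
    },
    "CD" = turn_asc(45L, 9L),
    "D" = if (kind == "V") {
      # 10, or 8 with gaps at 81, 82
      if (len == 10L) as.character(75:84)
      else if (len == 8L) as.character(setdiff(75:84, c(81L, 82L)))
      else err("10 (or 8 if gaps at 81, 82)")
    } else {
      if (len == 8L) as.character(77:84)
      else if (len == 7L) as.character(setdiff(77:84, 82L))
      else err("8 (or 7 if gap at 82)")
    },
    "DE" = {  # fill 84.1..84.k then 85.m..85.1 from both ends of the turn
      if (len > 14L) err(14L)
      k <- (len + 1L) %/% 2L
      m <- len - k
      pos <- c(if (k > 0L) sprintf("84.%d", seq_len(k)),
               if (m > 0L) sprintf("85.%d", seq_len(m)))
      order_positions(pos)
    },
    "E" = fixed(85L, 96L),
    "EF" = turn_asc(96L, 2L),
    "F" = fixed(97L, 104L),
    "FG" = cdr3_position_sequence(len),
    "G" = {  # trailing positions trimmed
      if (len > 11L || len < 1L) err("11 (or less)")
      as.character(seq.int(118L, 117L + len))
    },
    stop("unknown segment label: ", label, call. = FALSE))
}

# C-domain BC loop: universe 27-31, 34-38 (apex pair 31|34), gapped from the
# apex by the same alternation as the V loops
.c_bc_loop <- function(len) {
  base <- c(27:31, 34:38)
  if (len > 10L) {
    stop("C-domain BC loop: length ", len, " violates topology (max 10)",
         call. = FALSE)
  }
  n_drop <- 10L - len
  if (n_drop > 0L) {
    highs <- c(34:38, NA)
    lows <- c(31:27, NA)
    inter <- as.vector(rbind(highs, lows))
    inter <- inter[!is.na(inter)]
    base <- setdiff(base, inter[seq_len(n_drop)])
  }
  as.character(base)
}
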