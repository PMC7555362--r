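# IMGT unique-numbering positions: dotted-decimal labels ("111.2"), a structural
# total order, and the loop gap/insertion rules.

#' IMGT position labels
#'
#' IMGT positions are integers 1-128, optionally with a dotted sub-position
#' (`"111.2"`, `"45.3"`, `"84.4"`). Positions are represented as character
#' strings; comparison is structural (base, then sub-position under the
#' loop/turn mirror rules), never lexical.
#'
#' The total order places sub-positions of a "left" base (e.g. 111, 84, 15,
#' 45, 96) ascending *after* the base, and sub-positions of a "right" base
#' (112, 85) descending immediately *before* the base, so that an insertion
#' block reads `111 < 111.1 < ... < 112.2 < 112.1 < 112` as at the top of the
#' CDR3 loop, and the DE turn reads `84 < 84.1 < ... < 85.2 < 85.1 < 85`.
#'
#' @param x character vector of position labels.
#' @return `imgt_position_key()`: a numeric sort key; `order_positions()`:
#'   `x` sorted under the IMGT order; `validate_positions()`: `x` invisibly,
#'   or an error.
#' @examples
#' order_positions(c("112", "111.1", "112.1", "111"))
#' @name imgt-positions
NULL

# bases whose sub-positions run backwards toward the base (right flank of an
# insertion block or turn)
.mirror_bases <- c(112L, 85L)

.parse_position <- function(x) {
  parts <- regmatches(x, regexec("^([0-9]+)(?:\\.([0-9]+))?$", x))
  bad <- vapply(parts, length, integer(1)) == 0L
  if (any(bad)) {
    stop("malformed IMGT position label(s): ",
         paste(x[bad], collapse = ", "), call. = FALSE)
  }
  base <- vapply(parts, function(p) as.integer(p[2]), integer(1))
  sub <- vapply(parts, function(p) {
    if (is.na(p[3]) || p[3] == "") 0L else as.integer(p[3])
  }, integer(1))
  list(base = base, sub = sub)
}

#' @rdname imgt-positions
#' @export
imgt_position_key <- function(x) {
  p <- .parse_position(as.character(x))
  key <- p$base + p$sub / 100
  mirror <- p$base %in% .mirror_bases & p$sub > 0L
  key[mirror] <- p$base[mirror] - p$sub[mirror] / 100
  key
}

#' @rdname imgt-positions
#' @export
order_positions <- function(x) {
  x[order(imgt_position_key(x))]
}

#' @rdname imgt-positions
#' @export
validate_positions <- function(x) {
  p <- .parse_position(as.character(x))
  if (any(p$base < 1L | p$base > 128L)) {
    stop("IMGT base positions must lie in 1-128", call. = FALSE)
  }
  invisible(x)
}

#' CDR3 (FG loop) position sequence for a given length
#'
#' The FG loop spans positions 105-117 (13 positions). Shorter loops gap from
#' the top of the loop in the order 111, 112, 110, 113, 109, 114, ...; longer
#' loops insert sub-positions between 111 and 112 in the order 112.1, 111.1,
#' 112.2, 111.2, ...
#'
#' @param length loop length in amino acids (>= 1).
#' @return character vector of `length` position labels in ascending IMGT
#'   order.
#' @examples
#' cdr3_position_sequence(13)
#' cdr3_position_sequence(14)  # gains 112.1
#' cdr3_position_sequence(11)  # 111 and 112 absent
#' @export
cdr3_position_sequence <- function(length) {
  .loop_positions(105L, 117L, length, apex_low = 111L, apex_high = 112L,
                  allow_insert = TRUE, first_flank = "low")
}

#' Position sequence for the BC or C'C'' loop
#'
#' BC (CDR1) spans 27-38 (max 12), C'C'' (CDR2) spans 56-65 (max 10). Gaps
#' are created from the loop apex by the same alternation as the FG loop
#' (apex pairs 32|33 and 60|61; removal order 33, 32, 34, 31, ... and
#' 61, 60, 62, 59, ...). These loops admit no insertions.
#'
#' @param loop `"BC"` or `"C'C''"`.
#' @param length loop length in amino acids.
#' @return character vector of position labels in ascending IMGT order.
#' @export
loop_position_sequence <- function(loop = c("BC", "C'C''"), length) {
  loop <- match.arg(loop)
  if (loop == "BC") {
    .loop_positions(27L, 38L, length, apex_low = 32L, apex_high = 33L,
                    allow_insert = FALSE, first_flank = "high")
  } else {
    .loop_positions(56L, 65L, length, apex_low = 60L, apex_high = 61L,
                    allow_insert = FALSE, first_flank = "high")
  }
}

# shared apex-alternation engine. Gap removal alternates between the two
# flanks of the apex pair, outward; `first_flank` selects which apex goes
# first (the FG loop removes 111 before 112, the BC loop removes 33 before
# 32). Insertions (FG loop only): apex_high.1, apex_low.1, apex_high.2, ...
.loop_positions <- function(from, to, length, apex_low, apex_high,
                            allow_insert, first_flank = c("low", "high")) {
  first_flank <- match.arg(first_flank)
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length < 1L || length != floor(length)) {
    stop("loop length must be a positive integer", call. = FALSE)
  }
  length <- as.integer(length)
  base <- seq.int(from, to)
  max_len <- length(base)
  if (length <= max_len) {
    n_drop <- max_len - length
    drop <- character(0)
    if (n_drop > 0L) {
      lows <- seq.int(apex_low, from)
      highs <- seq.int(apex_high, to)
      k <- max(length(lows), length(highs))
      lows <- c(lows, rep(NA, k - length(lows)))
      highs <- c(highs, rep(NA, k - length(highs)))
      inter <- if (first_flank == "low") {
        as.vector(rbind(lows, highs))
      } else {
        as.vector(rbind(highs, lows))
      }
      inter <- inter[!is.na(inter)]
      drop <- as.character(inter[seq_len(n_drop)])
    }
    keep <- setdiff(as.character(base), drop)
    return(order_positions(keep))
  }
  if (!allow_insert) {
    stop(sprintf("loop length %d exceeds the maximum of %d and this loop admits no insertions",
                 length, max_len), call. = FALSE)
  }
  n_ins <- length - max_len
  # growth order 112.1, 111.1, 112.2, 111.2, ...
  ins <- character(n_ins)
  for (i in seq_len(n_ins)) {
    b <- if (i %% 2L == 1L) apex_high else apex_low
    ins[i] <- sprintf("%d.%d", b, (i + 1L) %/% 2L)
  }
  order_positions(c(as.character(base), ins))
}
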