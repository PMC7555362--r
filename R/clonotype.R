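# Clonotype (AA/nt) identification from rearrangement records, diversity and
# expression tables, and pairwise set comparison with multiple-testing
# adjustment.

# strip the "*NN" allele suffix; multi-valued calls collapse to unique genes
.gene_of <- function(call, level = c("gene", "allele")) {
  level <- match.arg(level)
  vapply(strsplit(as.character(call), "[,;]\\s*|\\s+or\\s+"), function(parts) {
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0L) return(NA_character_)
    if (level == "gene") parts <- sub("\\*.*$", "", parts)
    paste(sort(unique(parts)), collapse = ",")
  }, character(1))
}

#' Identify clonotypes (AA) from rearrangement records
#'
#' A clonotype (AA) is the set of rearrangements sharing the V and J calls,
#' the CDR3 amino-acid sequence, and conserved junction anchors C104 with
#' W118 or F118. Records with non-conserved anchors or missing calls are
#' excluded and reported. Within each clonotype (AA), nucleotide-level
#' children (clonotypes (nt)) are grouped by CDR3 nucleotide sequence.
#'
#' @param records data.frame of rearrangement records (see
#'   [read_rearrangements()]); required columns: `sequence_id`, `v_call`,
#'   `j_call`, `cdr3_aa`, `anchor104`, `anchor118`; optional: `d_call`,
#'   `cdr3_nt`, `v_identity`, `sequence`.
#' @param call_level `"gene"` (default; alleles collapsed, ambiguity kept as
#'   metadata) or `"allele"`.
#' @return list of class `clonotype_set` with `clonotypes` (data.frame, one
#'   row per clonotype (AA)), `members` (record-to-clonotype map),
#'   `excluded` (records with reasons), `call_level`.
#' @export
call_clonotypes <- function(records, call_level = c("gene", "allele")) {
  call_level <- match.arg(call_level)
  req <- c("sequence_id", "v_call", "j_call", "cdr3_aa", "anchor104",
           "anchor118")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols)) {
    stop("records lack required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  if (n == 0L) {
    return(structure(list(clonotypes = data.frame(), members = data.frame(),
                          excluded = data.frame(), call_level = call_level),
                     class = "clonotype_set"))
  }
  reason <- rep(NA_character_, n)
  ok_call <- !is.na(records$v_call) & nzchar(records$v_call) &
    !is.na(records$j_call) & nzchar(records$j_call)
  ok_cdr3 <- !is.na(records$cdr3_aa) & nzchar(records$cdr3_aa)
  ok_anchor <- records$anchor104 == "C" & records$anchor118 %in% c("W", "F")
  ok_anchor[is.na(ok_anchor)] <- FALSE
  reason[!ok_call] <- "missing V or J call"
  reason[ok_call & !ok_cdr3] <- "missing CDR3 (AA)"
  reason[ok_call & ok_cdr3 & !ok_anchor] <- "non-conserved anchors"
  keep <- is.na(reason)
  excluded <- cbind(records[!keep, , drop = FALSE],
                    reason = reason[!keep])
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0L) {
    return(structure(list(clonotypes = data.frame(), members = data.frame(),
                          excluded = excluded, call_level = call_level),
                     class = "clonotype_set"))
  }
  v_key <- .gene_of(rec$v_call, call_level)
  j_key <- .gene_of(rec$j_call, call_level)
  key <- paste(v_key, j_key, rec$cdr3_aa, rec$anchor104, rec$anchor118,
               sep = "|")
  cdr3_nt <- if ("cdr3_nt" %in% names(rec)) tolower(rec$cdr3_nt) else
    rep(NA_character_, nrow(rec))
  v_ident <- if ("v_identity" %in% names(rec))
    suppressWarnings(as.numeric(rec$v_identity)) else rep(NA_real_, nrow(rec))
  seq_len_rec <- if ("sequence" %in% names(rec)) nchar(rec$sequence) else
    rep(0L, nrow(rec))

  groups <- split(seq_len(nrow(rec)), key)
  clonos <- lapply(names(groups), function(k) {
    idx <- groups[[k]]
    nt <- cdr3_nt[idx]
    nt_tab <- table(nt, useNA = "ifany")
    # copies: members whose CDR3 (nt) is seen once vs in multi-copy groups
    one_copy <- sum(nt_tab == 1L)
    more <- sum(nt_tab[nt_tab > 1L])
    ident <- v_ident[idx]
    ident[is.na(ident)] <- -Inf
    o <- order(-ident, -seq_len_rec[idx], rec$sequence_id[idx])
    rep_id <- rec$sequence_id[idx][o[1]]
    d_calls <- if ("d_call" %in% names(rec)) {
      dc <- .gene_of(rec$d_call[idx], call_level)
      dc <- dc[!is.na(dc) & nzchar(dc)]
      if (length(dc)) paste(sort(unique(dc)), collapse = ",") else
        NA_character_
    } else NA_character_
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    data.frame(
      clonotype_id = NA_integer_,
      v_call = parts[1], j_call = parts[2], cdr3_aa = parts[3],
      anchor104 = parts[4], anchor118 = parts[5],
      d_call = d_calls,
      cdr3_length = nchar(parts[3]),
      n_members = length(idx),
      n_nt_clonotypes = length(nt_tab),
      one_copy = one_copy, more_than_one = more,
      representative = rep_id,
      allele_ambiguity = paste(sort(unique(c(rec$v_call[idx],
                                             rec$j_call[idx]))),
                               collapse = ";"),
      stringsAsFactors = FALSE)
  })
  clonotypes <- do.call(rbind, clonos)
  o <- order(-clonotypes$n_members, clonotypes$v_call, clonotypes$cdr3_aa)
  clonotypes <- clonotypes[o, , drop = FALSE]
  clonotypes$clonotype_id <- seq_len(nrow(clonotypes))
  rownames(clonotypes) <- NULL
  member_key <- paste(v_key, j_key, rec$cdr3_aa, rec$anchor104,
                      rec$anchor118, sep = "|")
  clono_key <- paste(clonotypes$v_call, clonotypes$j_call,
                     clonotypes$cdr3_aa, clonotypes$anchor104,
                     clonotypes$anchor118, sep = "|")
  members <- data.frame(sequence_id = rec$sequence_id,
                        clonotype_id = clonotypes$clonotype_id[
                          match(member_key, clono_key)],
                        cdr3_nt = cdr3_nt,
                        stringsAsFactors = FALSE)
  structure(list(clonotypes = clonotypes, members = members,
                 excluded = excluded, call_level = call_level),
            class = "clonotype_set")
}

#' @export
print.clonotype_set <- function(x, ...) {
  cat(sprintf("<clonotype_set> %d clonotypes (AA), %d records (%d excluded)\n",
              nrow(x$clonotypes), nrow(x$members), nrow(x$excluded)))
  invisible(x)
}

#' Diversity and expression tables of a clonotype set
#'
#' Diversity counts clonotypes (AA); expression counts member sequences.
#' Tables are produced per V gene, per J gene and per CDR3 (AA) length.
#'
#' @param cs a `clonotype_set`.
#' @return list of class `clonotype_tables` with data.frames `v_gene`,
#'   `j_gene`, `cdr3_length`, each with columns `category`, `diversity`,
#'   `expression`, plus `totals`.
#' @export
clonotype_tables <- function(cs) {
  stopifnot(inherits(cs, "clonotype_set"))
  cl <- cs$clonotypes
  per <- function(cat) {
    if (nrow(cl) == 0L) {
      return(data.frame(category = character(0), diversity = integer(0),
                        expression = integer(0)))
    }
    d <- tapply(rep(1L, nrow(cl)), cl[[cat]], sum)
    e <- tapply(cl$n_members, cl[[cat]], sum)
    data.frame(category = names(d), diversity = as.integer(d),
               expression = as.integer(e), stringsAsFactors = FALSE)
  }
  out <- list(v_gene = per("v_call"), j_gene = per("j_call"),
              cdr3_length = per("cdr3_length"),
              totals = c(diversity = nrow(cl),
                         expression = sum(cl$n_members)))
  class(out) <- "clonotype_tables"
  out
}

# one-sided Sidak step-down is not in stats::p.adjust; single-step Sidak
.p_adjust_sidak <- function(p) {
  pmin(1, 1 - (1 - p)^length(p))
}

.procedures <- c("bonferroni", "holm", "sidak", "hochberg", "hommel", "BH",
                 "BY")

#' Compare two clonotype sets gene by gene
#'
#' For each shared category (gene), tests the difference in proportions of
#' the chosen measure between the two sets with a pooled two-proportion
#' z-test and an unpooled 95% confidence interval, adjusts p-values with the
#' seven procedures (Bonferroni, Holm, Sidak, Hochberg, Hommel,
#' Benjamini-Hochberg, Benjamini-Yekutieli), and classes each row by how
#' many adjusted procedures agree: `non-significant` < `rawp` < `Only_BH`
#' (one procedure) < `Min_2p` (two or more) < `All_p` (all seven).
#'
#' @param tables_a,tables_b `clonotype_tables` objects.
#' @param table which table to compare (`"v_gene"`, `"j_gene"`,
#'   `"cdr3_length"`).
#' @param measure `"diversity"` or `"expression"`.
#' @param alpha significance level (default 0.05).
#' @param procedures character subset of the seven procedures to apply.
#' @return data.frame with one row per category: proportions, `diff`,
#'   `ci_low`, `ci_high`, `z`, `raw_p`, one logical column per procedure,
#'   `n_agree`, `significance`.
#' @export
compare_clonotype_sets <- function(tables_a, tables_b,
                                   table = c("v_gene", "j_gene",
                                             "cdr3_length"),
                                   measure = c("diversity", "expression"),
                                   alpha = 0.05,
                                   procedures = .procedures) {
  stopifnot(inherits(tables_a, "clonotype_tables"),
            inherits(tables_b, "clonotype_tables"))
  table <- match.arg(table)
  measure <- match.arg(measure)
  procedures <- match.arg(procedures, .procedures, several.ok = TRUE)
  ta <- tables_a[[table]]
  tb <- tables_b[[table]]
  na <- tables_a$totals[[measure]]
  nb <- tables_b$totals[[measure]]
  if (na == 0L || nb == 0L) {
    stop("zero total in one of the sets; proportions undefined",
         call. = FALSE)
  }
  cats <- sort(union(ta$category, tb$category))
  xa <- ta[[measure]][match(cats, ta$category)]
  xb <- tb[[measure]][match(cats, tb$category)]
  xa[is.na(xa)] <- 0L
  xb[is.na(xb)] <- 0L
  pa <- xa / na
  pb <- xb / nb
  diff <- pa - pb
  pooled <- (xa + xb) / (na + nb)
  se_pooled <- sqrt(pooled * (1 - pooled) * (1 / na + 1 / nb))
  z <- ifelse(se_pooled == 0, 0, diff / se_pooled)
  raw_p <- 2 * stats::pnorm(-abs(z))
  se_un <- sqrt(pa * (1 - pa) / na + pb * (1 - pb) / nb)
  zc <- stats::qnorm(0.975)
  out <- data.frame(category = cats, count_a = xa, count_b = xb,
                    prop_a = pa, prop_b = pb, diff = diff,
                    ci_low = diff - zc * se_un, ci_high = diff + zc * se_un,
                    z = z, raw_p = raw_p, stringsAsFactors = FALSE)
  for (pr in procedures) {
    adj <- if (pr == "sidak") .p_adjust_sidak(raw_p) else
      stats::p.adjust(raw_p, method = pr)
    out[[paste0("sig_", pr)]] <- adj < alpha
  }
  sig_cols <- paste0("sig_", procedures)
  out$n_agree <- rowSums(out[, sig_cols, drop = FALSE])
  out$significance <- ifelse(
    out$raw_p >= alpha, "non-significant",
    ifelse(out$n_agree == length(procedures), "All_p",
           ifelse(out$n_agree >= 2L, "Min_2p",
                  ifelse(out$n_agree == 1L, "Only_BH", "rawp"))))
  out
}
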