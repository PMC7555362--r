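# Allotype / isotype-marker inference from constant-domain residues,
# Eu <-> IMGT position correspondence, and engineered-variant naming.

.allotype_env <- new.env(parent = emptyenv())

.read_fixture <- function(file) {
  path <- system.file("extdata", file, package = "igkit", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Packaged marker rule and allele tables
#'
#' `allotype_rules()` returns the residue rules, one row per
#' (marker, domain, position, residue); a marker is called when *all* its
#' rows are satisfied. `allotype_alleles()` returns the combination-to-
#' allele map (e.g. allotypes \{G1m17, G1m1\} -> allele `G1m17,1`, carried
#' by IGHG1*01/*02/*05). Provisional rows (alleles expected but not yet
#' sequenced) are flagged.
#'
#' @return data.frame.
#' @export
allotype_rules <- function() {
  if (is.null(.allotype_env$rules)) {
    .allotype_env$rules <- .read_fixture("allotype_rules.tsv")
  }
  .allotype_env$rules
}

#' @rdname allotype_rules
#' @export
allotype_alleles <- function() {
  if (is.null(.allotype_env$alleles)) {
    .allotype_env$alleles <- .read_fixture("allotype_alleles.tsv")
  }
  .allotype_env$alleles
}

#' Residue table of numbered constant domains
#'
#' Convenience constructor for [call_markers()]: flattens named
#' `numbered_domain` objects (names = domain labels such as `"CH1"`,
#' `"CH3"`, `"CL"`) into a (domain, position, aa) table.
#'
#' @param ... named `numbered_domain` objects.
#' @return data.frame with columns `domain`, `position`, `aa`.
#' @export
chain_residues <- function(...) {
  doms <- list(...)
  stopifnot(length(names(doms)) == length(doms), all(nzchar(names(doms))))
  do.call(rbind, lapply(names(doms), function(nm) {
    d <- doms[[nm]]
    stopifnot(inherits(d, "numbered_domain"))
    data.frame(domain = nm, position = d$residues$position,
               aa = d$residues$aa, stringsAsFactors = FALSE)
  }))
}

#' Call allotype and isotype markers from constant-domain residues
#'
#' Evaluates every packaged rule for `gene` against the supplied residues.
#' A marker is reported only when all its rule positions match; rule
#' positions absent from the input are reported as unresolved. When no
#' marker matches at fully-covered positions, an explicit no-call is
#' returned listing the unmatched positions. For genes with an allele map
#' (IGKC Km, IGHG1 G1m, IGHG3 G3m haplotype), the called allotype
#' combination is translated to the allele label. Isoallotypes (nG1m1,
#' nG3m11, ...) are reported in a separate field from allotypes. For IGHG2,
#' CH2 M45.1 is the determining rule; CH1 T92 is reported as corroborating
#' evidence only.
#'
#' @param gene constant gene context (`"IGKC"`, `"IGLC"`, `"IGHG1"`,
#'   `"IGHG2"`, `"IGHG3"`).
#' @param residues data.frame with columns `domain`, `position`, `aa` (see
#'   [chain_residues()]).
#' @return list of class `marker_call`: `gene`, `markers` (character),
#'   `isoallotypes`, `isotype_markers`, `allele` (label or `NA`),
#'   `evidence` (data.frame of matched rule rows), `unresolved` (rule
#'   positions absent from input), `no_call` (logical),
#'   `unmatched_positions` (for no-calls), `corroborating`.
#' @examples
#' \dontrun{
#' call_markers("IGKC", data.frame(domain = "CL",
#'   position = c("45.1", "101"), aa = c("A", "V")))
#' }
#' @export
call_markers <- function(gene, residues) {
  rules <- allotype_rules()
  rules <- rules[rules$gene == gene, , drop = FALSE]
  if (nrow(rules) == 0L) {
    stop("no marker rules packaged for gene '", gene, "'", call. = FALSE)
  }
  stopifnot(all(c("domain", "position", "aa") %in% names(residues)))
  res_key <- paste(residues$domain, residues$position)
  aa_at <- function(dom, pos) {
    i <- match(paste(dom, pos), res_key)
    if (is.na(i)) NA_character_ else toupper(residues$aa[i])
  }
  rules$observed <- mapply(aa_at, rules$domain, rules$position)
  by_marker <- split(rules, rules$marker)
  status <- lapply(by_marker, function(r) {
    covered <- !is.na(r$observed)
    matched <- covered & r$observed == r$aa
    list(satisfied = all(matched),
         unresolved = r[!covered, c("domain", "position"), drop = FALSE],
         rows = r)
  })
  satisfied <- names(status)[vapply(status, `[[`, logical(1), "satisfied")]
  type_of <- vapply(satisfied, function(m) {
    by_marker[[m]]$type[1]
  }, character(1))
  markers <- satisfied[type_of %in% c("allotype", "allele")]
  isoallo <- satisfied[type_of == "isoallotype"]
  isomark <- satisfied[type_of == "isotype_marker"]
  unresolved <- unique(do.call(rbind, lapply(status, `[[`, "unresolved")))
  evidence <- do.call(rbind, lapply(status[satisfied], function(s) {
    s$rows[, c("marker", "domain", "position", "aa")]
  }))
  # corroborating evidence (IGHG2: CH1 T92 linked to G2m23)
  corroborating <- character(0)
  if (gene == "IGHG2") {
    t92 <- aa_at("CH1", "92")
    if (identical(t92, "T")) corroborating <- "CH1 T92 (linked to G2m23)"
  }
  # allele mapping from the allotype combination
  allele <- NA_character_
  alleles <- allotype_alleles()
  am <- alleles[alleles$gene == gene, , drop = FALSE]
  if (nrow(am)) {
    allo_set <- sort(markers)
    hit <- which(vapply(strsplit(am$markers, ";"), function(m) {
      setequal(sort(m), allo_set)
    }, logical(1)))
    if (length(hit) == 1L) allele <- am$allele_label[hit]
  }
  no_call <- length(satisfied) == 0L
  unmatched <- if (no_call) {
    r <- do.call(rbind, lapply(status, `[[`, "rows"))
    r <- r[!is.na(r$observed) & r$observed != r$aa,
           c("domain", "position", "observed"), drop = FALSE]
    unique(r)
  } else NULL
  structure(list(gene = gene, markers = markers, isoallotypes = isoallo,
                 isotype_markers = isomark, allele = allele,
                 evidence = evidence, unresolved = unresolved,
                 no_call = no_call, unmatched_positions = unmatched,
                 corroborating = corroborating),
            class = "marker_call")
}

#' @export
print.marker_call <- function(x, ...) {
  cat(sprintf("<marker_call> %s: %s\n", x$gene,
              if (x$no_call) "no-call" else
                paste(c(x$markers, x$isoallotypes, x$isotype_markers),
                      collapse = ", ")))
  if (!is.na(x$allele)) cat("  allele:", x$allele, "\n")
  invisible(x)
}

#' Eu / IMGT position correspondence
#'
#' Maps between the Eu numbering of the gamma heavy chain and IMGT
#' C-domain positions, using the packaged correspondence table (hinge,
#' CH2 and CH3 pairs). The table round-trips: imgt -> eu -> imgt is the
#' identity on all mapped positions.
#'
#' @param domain `"h"`, `"CH2"` or `"CH3"` (required for
#'   `direction = "imgt_to_eu"`; ignored for `eu_to_imgt`, where Eu
#'   positions are chain-unique).
#' @param position position label (IMGT dotted string or Eu integer).
#' @param direction `"imgt_to_eu"` or `"eu_to_imgt"`.
#' @return for `imgt_to_eu`: the Eu position (integer); for `eu_to_imgt`: a
#'   list with `domain` and `imgt`.
#' @examples
#' map_eu_imgt("CH2", "84.4", "imgt_to_eu")  # 297
#' @export
map_eu_imgt <- function(domain = NULL, position,
                        direction = c("imgt_to_eu", "eu_to_imgt")) {
  direction <- match.arg(direction)
  if (is.null(.allotype_env$eu_map)) {
    .allotype_env$eu_map <- .read_fixture("eu_imgt_map.tsv")
  }
  map <- .allotype_env$eu_map
  position <- as.character(position)
  if (direction == "imgt_to_eu") {
    if (is.null(domain)) stop("domain required for imgt_to_eu",
                              call. = FALSE)
    i <- which(map$domain == domain & map$imgt == position)
    if (length(i) == 1L) return(as.integer(map$eu[i]))
    sub <- map[map$domain == domain, , drop = FALSE]
    keys <- imgt_position_key(sub$imgt)
    near <- sub$imgt[order(abs(keys - imgt_position_key(position)))]
    stop(sprintf("IMGT position %s %s is not in the correspondence table; nearest mapped: %s",
                 domain, position,
                 paste(utils::head(near, 3), collapse = ", ")),
         call. = FALSE)
  }
  i <- which(map$eu == position)
  if (length(i) == 1L) {
    return(list(domain = map$domain[i], imgt = map$imgt[i]))
  }
  eus <- as.integer(map$eu)
  near <- map$eu[order(abs(eus - as.integer(position)))]
  stop(sprintf("Eu position %s is not in the correspondence table; nearest mapped: %s",
               position, paste(utils::head(near, 3), collapse = ", ")),
       call. = FALSE)
}

#' Packaged engineered-variant catalogue
#'
#' @return data.frame with `gene`, `variant`, `changes`
#'   (`domain:AAposition` tokens separated by `;`), `properties`.
#' @export
ighg_variant_table <- function() {
  if (is.null(.allotype_env$variants)) {
    .allotype_env$variants <- .read_fixture("ighg_variants.tsv")
  }
  .allotype_env$variants
}

# tiny deterministic FNV-1a hash (hex8) for novel-variant labels; 32-bit
# arithmetic kept exact by splitting into 16-bit halves
.fnv1a <- function(x) {
  h <- 2166136261
  m <- 16777619
  for (b in utf8ToInt(x)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * m) %% 65536) * 65536 + h0 * m) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Name an engineered variant from its change set
#'
#' Changes are expressed relative to the *01 allele of `gene`, as
#' `domain:AAposition` tokens (e.g. `"CH2:A114"` for alanine at CH2 IMGT
#' position 114). An exact set match against the catalogue returns the
#' catalogued variant id; an empty change set is the reference allele; any
#' other set returns a deterministic novel label `vNEW-<hash>` together
#' with the nearest catalogued variant by change-set overlap.
#'
#' @param gene IGHG gene (`"IGHG1"`, ..., `"IGHG4"`).
#' @param changes character vector of `domain:AAposition` tokens.
#' @return list with `variant`, `novel` (logical), `nearest` (for novel
#'   labels), `properties` (for catalogued variants).
#' @examples
#' name_variant("IGHG1", "CH2:A114")$variant  # "IGHG1v4"
#' @export
name_variant <- function(gene, changes) {
  changes <- sort(unique(as.character(changes)))
  if (length(changes) == 0L) {
    return(list(variant = paste0(gene, "*01"), novel = FALSE,
                nearest = NA_character_, properties = "reference allele"))
  }
  tab <- ighg_variant_table()
  tab <- tab[tab$gene == gene, , drop = FALSE]
  sets <- lapply(strsplit(tab$changes, ";"), function(x) sort(unique(x)))
  hit <- which(vapply(sets, identical, logical(1), y = changes))
  if (length(hit) >= 1L) {
    return(list(variant = tab$variant[hit[1]], novel = FALSE,
                nearest = NA_character_, properties = tab$properties[hit[1]]))
  }
  overlap <- vapply(sets, function(s) length(intersect(s, changes)),
                    integer(1))
  nearest <- if (nrow(tab)) {
    tab$variant[order(-overlap, tab$variant)][1]
  } else NA_character_
  list(variant = paste0("vNEW-", .fnv1a(paste(gene, paste(changes,
                                                          collapse = ";")))),
       novel = TRUE, nearest = nearest, properties = NA_character_)
}
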