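# Rearrangement table readers/writers and tool configuration.

.default_mapping <- list(
  sequence_id = "sequence_id", v_call = "v_call", d_call = "d_call",
  j_call = "j_call", sequence = "sequence", junction = "junction",
  junction_aa = "junction_aa", cdr3_aa = "cdr3_aa", cdr3_nt = "cdr3_nt",
  v_identity = "v_identity", productive = "productive")

#' Read an AIRR-style rearrangement table
#'
#' Reads a tab- or comma-separated rearrangement table, renames columns via
#' `mapping` (internal name -> file column), derives junction anchors from
#' `junction_aa` when no anchor columns are present, and routes rows missing
#' mandatory fields (`sequence_id`, `v_call`, `j_call` and a CDR3) to a
#' reject report instead of dropping them silently.
#'
#' @param path input file.
#' @param mapping named list overriding entries of the default column
#'   mapping.
#' @return data.frame of typed records; the reject report (rows + reasons)
#'   is attached as `attr(x, "rejects")`.
#' @export
read_rearrangements <- function(path, mapping = list()) {
  if (!file.exists(path)) {
    stop("cannot read rearrangement table: ", path, call. = FALSE)
  }
  map <- utils::modifyList(.default_mapping, mapping)
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0L) "\t"
    else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  present <- vapply(map, function(col) col %in% names(raw), logical(1))
  if (!any(present)) {
    stop("no mappable columns found in ", path, call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (nm in names(map)[present]) out[[nm]] <- raw[[map[[nm]]]]
  if (!"anchor104" %in% names(out) && "junction_aa" %in% names(out)) {
    out$anchor104 <- substr(out$junction_aa, 1L, 1L)
    out$anchor118 <- substr(out$junction_aa, nchar(out$junction_aa),
                            nchar(out$junction_aa))
  }
  need <- c("sequence_id", "v_call", "j_call")
  miss <- rep(FALSE, nrow(out))
  why <- rep(NA_character_, nrow(out))
  for (nm in need) {
    bad <- if (nm %in% names(out)) is.na(out[[nm]]) | !nzchar(out[[nm]])
      else rep(TRUE, nrow(out))
    why[bad & !miss] <- paste("missing", nm)
    miss <- miss | bad
  }
  has_cdr3 <- ("cdr3_aa" %in% names(out) &&
                 any(!is.na(out$cdr3_aa))) | ("junction_aa" %in% names(out))
  if ("cdr3_aa" %in% names(out)) {
    bad <- is.na(out$cdr3_aa) | !nzchar(out$cdr3_aa)
    if ("junction_aa" %in% names(out)) {
      fix <- bad & !is.na(out$junction_aa) & nchar(out$junction_aa) > 2L
      out$cdr3_aa[fix] <- substr(out$junction_aa[fix], 2L,
                                 nchar(out$junction_aa[fix]) - 1L)
      bad <- is.na(out$cdr3_aa) | !nzchar(out$cdr3_aa)
    }
    why[bad & !miss] <- "missing CDR3"
    miss <- miss | bad
  }
  rejects <- cbind(out[miss, , drop = FALSE], reason = why[miss])
  records <- out[!miss, , drop = FALSE]
  rownames(records) <- NULL
  attr(records, "rejects") <- rejects
  records
}

#' Write a rearrangement table (deterministic TSV)
#'
#' Stable column order and fixed formatting (percentages to two decimals),
#' so identical inputs give byte-identical files.
#'
#' @param records data.frame of records.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(records, path) {
  cols <- intersect(names(.default_mapping), names(records))
  cols <- c(cols, setdiff(names(records), cols))
  out <- records[, cols, drop = FALSE]
  if ("v_identity" %in% names(out)) {
    out$v_identity <- sprintf("%.2f", as.numeric(out$v_identity))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.known_config_keys <- c("columns", "fixtures", "procedures", "outdir",
                        "seed", "min_d_length", "alpha")

#' Read and validate a tool configuration file
#'
#' YAML with keys: `columns` (rearrangement column mapping), `fixtures`
#' (override fixture paths), `procedures` (multiple-testing toggles),
#' `outdir`, `seed`, `min_d_length`, `alpha`. Unknown keys are rejected.
#'
#' @param path YAML file.
#' @return named list of class `tool_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  unknown <- setdiff(names(cfg), .known_config_keys)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)
  if (!is.null(cfg$procedures)) {
    bad <- setdiff(cfg$procedures, .procedures)
    if (length(bad)) {
      stop("unknown procedure(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(cfg, class = "tool_config")
}
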