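# Amino-acid property classes (hydropathy / volume / chemical) and the
# four-type amino-acid change similarity scheme.

.aa_class_env <- new.env(parent = emptyenv())

#' Amino-acid class table
#'
#' Per-residue class assignments on three axes: hydropathy (3 classes),
#' side-chain volume (5 classes) and chemical characteristics (11 classes).
#' The hydrophobic hydropathy class is exactly \{I, V, L, F, C, M, A\} (the
#' residues with positive hydropathy index); tryptophan is classed neutral
#' and is highlighted separately in displays. Volume uses the standard five
#' side-chain-volume bands; the 11 chemical classes are packaged data and
#' can be swapped by editing `extdata/aa_classes.tsv`.
#'
#' @return data.frame with columns `residue`, `hydropathy`, `volume`,
#'   `chem`, one row per standard residue.
#' @export
aa_class_table <- function() {
  if (is.null(.aa_class_env$table)) {
    path <- system.file("extdata", "aa_classes.tsv", package = "igkit",
                        mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    stopifnot(nrow(tab) == 20L, !anyDuplicated(tab$residue))
    .aa_class_env$table <- tab
  }
  .aa_class_env$table
}

#' Classify a residue on the three class axes
#'
#' @param residue one-letter code of a standard amino acid.
#' @return named list with `hydropathy`, `volume`, `chem`, and `proline_flag`
#'   (TRUE for P, which displays carry as a dedicated colour).
#' @examples
#' classify_aa("I")$hydropathy  # "hydrophobic"
#' @export
classify_aa <- function(residue) {
  tab <- aa_class_table()
  if (!is.character(residue) || length(residue) != 1L ||
      !(residue %in% tab$residue)) {
    stop(sprintf("'%s' is not a standard one-letter amino-acid code",
                 paste(residue, collapse = ",")), call. = FALSE)
  }
  row <- tab[tab$residue == residue, ]
  list(hydropathy = row$hydropathy, volume = row$volume, chem = row$chem,
       proline_flag = identical(residue, "P"))
}

#' Classify an amino-acid change
#'
#' Compares two residues per class axis and maps the (hydropathy, volume,
#' chem) agreement pattern to the four similarity types: `+++` very similar;
#' `++-`/`+-+` similar; `--+`/`-+-`/`+--` dissimilar; `---` very dissimilar.
#' Identical residues return type `identical`.
#'
#' @param from_aa,to_aa one-letter codes.
#' @return list with logical `hydropathy_same`, `volume_same`, `chem_same`,
#'   the `signature` string (e.g. `"++-"`) and `similarity_type`.
#' @examples
#' classify_change("S", "G")$similarity_type  # "similar" (++-)
#' @export
classify_change <- function(from_aa, to_aa) {
  a <- classify_aa(from_aa)
  b <- classify_aa(to_aa)
  same <- c(hydropathy = a$hydropathy == b$hydropathy,
            volume = a$volume == b$volume,
            chem = a$chem == b$chem)
  sig <- paste(ifelse(same, "+", "-"), collapse = "")
  type <- if (identical(from_aa, to_aa)) {
    "identical"
  } else {
    # one disagreeing axis -> similar, two -> dissimilar; the packaged
    # class table admits "-++" (e.g. F vs W), graded by agreement count
    switch(sig,
           "+++" = "very similar",
           "++-" = ,
           "+-+" = ,
           "-++" = "similar",
           "--+" = ,
           "-+-" = ,
           "+--" = "dissimilar",
           "---" = "very dissimilar")
  }
  list(hydropathy_same = unname(same[1]), volume_same = unname(same[2]),
       chem_same = unname(same[3]), signature = sig, similarity_type = type)
}

# hydrophobic set used by hallmark checks and Collier shading
.hydrophobic_set <- function() {
  tab <- aa_class_table()
  tab$residue[tab$hydropathy == "hydrophobic"]
}
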