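# fixture domains built in code: diverse seeded residues with the conserved
# hallmarks planted at their positions

vh_boundaries <- c(25L, 8L, 17L, 8L, 38L, 13L, 11L)
vl_boundaries <- c(26L, 6L, 17L, 3L, 36L, 9L, 10L)

make_test_v <- function(boundaries = vh_boundaries, seed = 11,
                        aa118 = "W") {
  set.seed(seed)
  n <- sum(boundaries)
  aa <- sample(strsplit("ADEFGHIKLMNPQRSTVY", "")[[1]], n, replace = TRUE)
  scaffold <- assign_numbering(paste(rep("A", n), collapse = ""),
                               boundaries, "V")$residues$position
  fix <- c(`23` = "C", `41` = "W", `89` = "L", `104` = "C",
           `118` = aa118, `119` = "G", `121` = "G")
  for (p in names(fix)) {
    i <- match(p, scaffold)
    if (!is.na(i)) aa[i] <- fix[[p]]
  }
  assign_numbering(paste(aa, collapse = ""), boundaries, "V")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# residues of each IGHG1 allele at CH1 103/120 and CH3 12/14/101/110/115/116,
# with the corresponding G1m allele label
g1_rows <- list(
  "IGHG1*01" = list(aa = c("I", "K", "D", "L", "V", "A", "H", "Y"),
                    allele = "G1m17,1"),
  "IGHG1*03" = list(aa = c("I", "R", "E", "M", "V", "A", "H", "Y"),
                    allele = "G1m3"),
  "IGHG1*04" = list(aa = c("I", "K", "D", "L", "I", "A", "H", "Y"),
                    allele = "G1m17,1,27"),
  "IGHG1*05p" = list(aa = c("I", "K", "D", "L", "V", "A", "R", "Y"),
                     allele = "G1m17,1,28"),
  "IGHG1*06p" = list(aa = c("I", "K", "D", "L", "I", "A", "R", "Y"),
                     allele = "G1m17,1,27,28"),
  "IGHG1*07p" = list(aa = c("I", "K", "D", "L", "V", "G", "H", "Y"),
                     allele = "G1m17,1,2"),
  "IGHG1*08p" = list(aa = c("I", "R", "D", "L", "V", "A", "H", "Y"),
                     allele = "G1m3,1"))

make_test_c <- function(boundaries = c(14L, 2L, 11L, 8L, 7L, 4L, 8L, 7L,
                                       12L, 2L, 8L, 12L, 11L),
                        seed = 12, overrides = NULL) {
  set.seed(seed)
  n <- sum(boundaries)
  aa <- sample(strsplit("ADEFGHIKLMNPQRSTVY", "")[[1]], n, replace = TRUE)
  scaffold <- assign_numbering(paste(rep("A", n), collapse = ""),
                               boundaries, "C")$residues$position
  fix <- c(`23` = "C", `41` = "W", `89` = "V", `104` = "C")
  if (!is.null(overrides)) fix <- c(fix, overrides)
  for (p in names(fix)) {
    i <- match(p, scaffold)
    if (!is.na(i)) aa[i] <- fix[[p]]
  }
  assign_numbering(paste(aa, collapse = ""), boundaries, "C")
}
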