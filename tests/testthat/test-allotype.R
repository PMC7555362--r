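test_that("Km alleles follow the 45.1/101 residue pairs", {
  km3 <- call_markers("IGKC", data.frame(domain = "CL",
                                         position = c("45.1", "101"),
                                         aa = c("A", "V")))
  expect_identical(km3$allele, "Km3")
  km12 <- call_markers("IGKC", data.frame(domain = "CL",
                                          position = c("45.1", "101"),
                                          aa = c("A", "L")))
  expect_identical(km12$allele, "Km1,2")
  km1 <- call_markers("IGKC", data.frame(domain = "CL",
                                         position = c("45.1", "101"),
                                         aa = c("V", "L")))
  expect_identical(km1$allele, "Km1")
  # V45.1 + V101 matches no rule: explicit no-call with positions listed
  nc <- call_markers("IGKC", data.frame(domain = "CL",
                                        position = c("45.1", "101"),
                                        aa = c("V", "V")))
  expect_true(nc$no_call)
  expect_true(all(c("45.1", "101") %in% nc$unmatched_positions$position))
  # Km3 corresponds to exactly four IGKC alleles
  am <- allotype_alleles()
  km3_alleles <- strsplit(am$gene_alleles[am$allele_label == "Km3"],
                          ",")[[1]]
  expect_length(km3_alleles, 4L)
})

test_that("lambda isotype markers Mcg/Ke/Oz read from positions 1,3,45,100", {
  mcg_pos <- call_markers("IGLC", data.frame(
    domain = "CL", position = c("1", "3", "45", "100"),
    aa = c("N", "T", "G", "K")))
  expect_setequal(mcg_pos$isotype_markers, c("Mcg+", "Ke+", "Oz+"))
  mcg_neg <- call_markers("IGLC", data.frame(
    domain = "CL", position = c("1", "3", "45", "100"),
    aa = c("A", "S", "S", "R")))
  expect_setequal(mcg_neg$isotype_markers, c("Mcg-", "Ke-", "Oz-"))
})

test_that("every IGHG1 allele row returns its printed G1m allele", {
  for (nm in names(g1_rows)) {
    row <- g1_rows[[nm]]
    res <- data.frame(domain = c("CH1", "CH1", rep("CH3", 6)),
                      position = c("103", "120", "12", "14", "101", "110",
                                   "115", "116"),
                      aa = row$aa, stringsAsFactors = FALSE)
    got <- call_markers("IGHG1", res)
    expect_identical(got$allele, row$allele)
  }
  # isoallotypes live in their own field
  g1m3 <- call_markers("IGHG1", data.frame(
    domain = c("CH1", "CH1", "CH3", "CH3"),
    position = c("103", "120", "12", "14"),
    aa = c("I", "R", "E", "M")))
  expect_setequal(g1m3$isoallotypes, c("nG1m17", "nG1m1"))
  expect_identical(g1m3$markers, "G1m3")
})

test_that("marker calling is monotone under irrelevant residues", {
  base <- data.frame(domain = c("CH1", "CH3", "CH3"),
                     position = c("120", "12", "14"),
                     aa = c("K", "D", "L"))
  got <- call_markers("IGHG1", base)
  more <- rbind(base, data.frame(domain = "CH2",
                                 position = c("50", "84.4"),
                                 aa = c("Q", "N")))
  got2 <- call_markers("IGHG1", more)
  expect_identical(got$markers, got2$markers)
  expect_identical(got$allele, got2$allele)
})

test_that("G2m23 is determined by CH2 45.1 with CH1 92 as corroboration", {
  pos <- call_markers("IGHG2", data.frame(
    domain = c("CH2", "CH1"), position = c("45.1", "92"),
    aa = c("M", "T")))
  expect_identical(pos$markers, "G2m23")
  expect_true(length(pos$corroborating) == 1L)
  neg <- call_markers("IGHG2", data.frame(domain = "CH2",
                                          position = "45.1", aa = "V"))
  expect_true(neg$no_call)
})

test_that("thirteen G3m allotypes are encoded and IGHG3*01 maps to G3m5*", {
  rules <- allotype_rules()
  g3 <- unique(rules$marker[rules$gene == "IGHG3" &
                              rules$type == "allotype"])
  expect_length(g3, 13L)
  # IGHG3*01: CH3 S44, M84, Q98, I101, R115, F116
  got <- call_markers("IGHG3", data.frame(
    domain = "CH3", position = c("44", "84", "98", "101", "115", "116"),
    aa = c("S", "M", "Q", "I", "R", "F")))
  expect_setequal(got$markers,
                  c("G3m5", "G3m10", "G3m11", "G3m13", "G3m14", "G3m26",
                    "G3m27"))
  expect_identical(got$allele, "G3m5*")
})

test_that("Eu/IMGT correspondence is bijective and round-trips", {
  expect_identical(map_eu_imgt("CH2", "84.4", "imgt_to_eu"), 297L)
  back <- map_eu_imgt(position = "234", direction = "eu_to_imgt")
  expect_identical(back$domain, "CH2")
  expect_identical(back$imgt, "1.3")
  map <- igkit:::.read_fixture("eu_imgt_map.tsv")
  for (i in seq_len(nrow(map))) {
    eu <- map_eu_imgt(map$domain[i], map$imgt[i], "imgt_to_eu")
    rt <- map_eu_imgt(position = as.character(eu),
                      direction = "eu_to_imgt")
    expect_identical(rt$imgt, map$imgt[i])
    expect_identical(rt$domain, map$domain[i])
  }
  expect_false(anyDuplicated(paste(map$domain, map$imgt)) > 0)
  expect_false(anyDuplicated(map$eu) > 0)
  err <- tryCatch(map_eu_imgt("CH1", "50", "imgt_to_eu"),
                  error = conditionMessage)
  expect_match(err, "not in the correspondence table")
})

test_that("variant naming: exact catalogue matches, reference, novel labels", {
  expect_identical(name_variant("IGHG1", "CH2:A114")$variant, "IGHG1v4")
  expect_identical(name_variant("IGHG4", "h:P10")$variant, "IGHG4v5")
  v22 <- name_variant("IGHG1", c("CH3:K113", "CH2:Y15.1", "CH2:T16",
                                 "CH2:E18", "CH3:F114", "CH3:H116"))
  expect_identical(v22$variant, "IGHG1v22")
  ref <- name_variant("IGHG1", character(0))
  expect_false(ref$novel)
  expect_identical(ref$variant, "IGHG1*01")
  nov1 <- name_variant("IGHG1", c("CH2:A114", "CH3:Q1"))
  nov2 <- name_variant("IGHG1", c("CH3:Q1", "CH2:A114"))
  expect_true(nov1$novel)
  expect_identical(nov1$variant, nov2$variant)
  expect_match(nov1$variant, "^vNEW-[0-9a-f]{8}$")
  expect_identical(nov1$nearest, "IGHG1v4")
})
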