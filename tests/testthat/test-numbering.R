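test_that("canonical VH and VL number completely with the documented gaps", {
  vh <- make_test_v(vh_boundaries)
  expect_identical(nrow(vh$residues), 120L)
  expect_false(anyDuplicated(vh$residues$position) > 0)
  d <- delimit_regions(vh)
  expect_identical(d$fr_lengths, c(25L, 17L, 38L, 11L))
  expect_identical(d$cdr_lengths, c(8L, 8L, 13L))
  expect_identical(d$cdr_notation, "[8.8.13]")
  # FR1 of 25 puts the gap at 10; FR3 of 38 at 73
  expect_false("10" %in% vh$residues$position)
  expect_false("73" %in% vh$residues$position)
  vl <- make_test_v(vl_boundaries, seed = 21, aa118 = "F")
  dl <- delimit_regions(vl)
  expect_identical(dl$fr_lengths, c(26L, 17L, 36L, 10L))
  expect_identical(sum(dl$fr_lengths), 89L)
})

test_that("numbering round-trips: strip then re-assign is the identity", {
  for (dom in list(make_test_v(), make_test_v(vl_boundaries, 21, "F"),
                   make_test_c())) {
    seq <- paste(dom$residues$aa, collapse = "")
    b <- if (dom$kind == "V") {
      tab <- table(factor(dom$residues$region,
                          c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3",
                            "FR4")))
      as.integer(tab)
    } else {
      tab <- table(factor(dom$residues$segment,
                          domain_topology("C")$segments$label))
      as.integer(tab)
    }
    redo <- assign_numbering(seq, b, dom$kind)
    expect_identical(redo, dom)
  }
})

test_that("boundary violations and malformed inputs are topology errors", {
  expect_error(assign_numbering(strrep("A", 120),
                                c(25, 8, 16, 9, 38, 13, 11), "V"),
               "FR2")
  expect_error(assign_numbering(strrep("A", 120),
                                c(25, 8, 17, 8, 35, 16, 11), "V"),
               "FR3")
  expect_error(assign_numbering(strrep("A", 100),
                                c(25, 8, 17, 8, 38, 13, 11), "V"),
               "sequence length")
  expect_error(assign_numbering(strrep("A", 121),
                                c(25, 13, 17, 8, 38, 13, 7), "V"),
               "max")
})

test_that("junction length always exceeds CDR3 length by two", {
  for (c3 in c(5L, 9L, 13L, 17L, 21L)) {
    b <- c(25L, 8L, 17L, 8L, 38L, c3, 11L)
    dom <- assign_numbering(strrep("A", sum(b)), b, "V")
    d <- delimit_regions(dom)
    expect_identical(d$junction_length - d$cdr_lengths[3], 2L)
  }
  expect_error(delimit_regions(make_test_c()), "V domains")
})

test_that("hallmark verification reports conservation and deviations", {
  vh <- make_test_v()
  h <- verify_hallmarks(vh)
  expect_true(all(h$pass))
  # camelid-style arginine at 118 is a deviation, not an error
  llama <- make_test_v(seed = 31, aa118 = "R")
  h2 <- verify_hallmarks(llama)
  expect_false(h2$pass[h2$position == "118"])
  expect_false(h2$pass[h2$check == "J-MOTIF"])
  expect_true(all(h2$pass[h2$position %in% c("23", "41", "89", "104")]))
  # missing 2nd-CYS flagged
  aa <- vh$residues$aa
  aa[match("104", vh$residues$position)] <- "Y"
  broken <- assign_numbering(paste(aa, collapse = ""), vh_boundaries, "V")
  h3 <- verify_hallmarks(broken)
  expect_false(h3$pass[h3$check == "2nd-CYS"])
})

test_that("identity percentages count shared occupied positions only", {
  vh <- make_test_v()
  expect_identical(region_identity(vh, vh), 100.0)
  aa <- vh$residues$aa
  i <- match("50", vh$residues$position)
  aa[i] <- if (aa[i] == "G") "H" else "G"
  mut <- assign_numbering(paste(aa, collapse = ""), vh_boundaries, "V")
  expect_identical(region_identity(mut, vh),
                   round(100 * 119 / 120, 1))
  expect_identical(region_identity(mut, vh, "FR2"),
                   round(100 * 16 / 17, 1))
  expect_identical(region_identity(mut, vh, "CDR1"), 100.0)
  # denominator excludes positions absent from either domain
  short <- make_test_v(c(25L, 6L, 17L, 8L, 38L, 13L, 11L), seed = 11)
  expect_error(region_identity(vh, make_test_c()), "kind")
})

test_that("boundaries transfer by alignment, with indels placed in regions", {
  ref <- make_test_v()
  seq <- paste(ref$residues$aa, collapse = "")
  same <- infer_boundaries(seq, ref)
  expect_identical(unname(same$boundaries), vh_boundaries)
  expect_identical(same$identity, 100.0)
  # deleting two CDR1 residues shortens CDR1 only
  cdr1_idx <- which(ref$residues$region == "CDR1")[3:4]
  del <- paste(ref$residues$aa[-cdr1_idx], collapse = "")
  got <- infer_boundaries(del, ref)
  expect_identical(unname(got$boundaries),
                   c(25L, 6L, 17L, 8L, 38L, 13L, 11L))
  # a cysteine-free string cannot anchor the numbering
  set.seed(5)
  junk <- paste(sample(strsplit("GSTPNQDEKR", "")[[1]], 100,
                       replace = TRUE), collapse = "")
  expect_error(infer_boundaries(junk, ref), "low-confidence")
  expect_error(infer_boundaries(strrep("A", 30), ref), "70-150")
})

test_that("C domains number with turn sub-positions filled from both ends", {
  cd <- make_test_c()
  pos <- cd$residues$position
  expect_true(all(c("15.1", "15.2", "45.1", "45.4", "96.1", "96.2") %in%
                    pos))
  # DE turn of 7: 84.1-84.4 then 85.3-85.1 before 85
  de <- pos[grepl("^8[45]\\.", pos)]
  expect_identical(de, c("84.1", "84.2", "84.3", "84.4",
                         "85.3", "85.2", "85.1"))
  expect_true(!is.unsorted(imgt_position_key(pos), strictly = TRUE))
  # A strand of 14 leaves position 10 unoccupied
  expect_false("10" %in% pos)
  expect_true(all(as.character(c(32, 33, 46:76)) %in%
                    setdiff(as.character(1:128), pos)))
})

test_that("gapped sequences align to the canonical scaffold and write as FASTA", {
  vh <- make_test_v()
  g <- gapped_sequence(vh)
  expect_identical(nchar(g), 128L)
  chars <- strsplit(g, "")[[1]]
  expect_identical(chars[10], ".")
  expect_identical(sum(chars != "."), 120L)
  sc <- gapped_scaffold(vh)
  expect_identical(length(sc), nchar(g))
  tf <- withr::local_tempfile(fileext = ".fasta")
  write_gapped_fasta(list(vh1 = vh), tf)
  back <- Biostrings::readAAStringSet(tf)
  expect_identical(as.character(back[[1]]), g)
})
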