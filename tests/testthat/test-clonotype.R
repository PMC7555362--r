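mk_record <- function(id, v = "IGHV6-1*01", d = "IGHD2-8*02",
                      j = "IGHJ2*01", cdr3 = "TRDGPVAVHWFFAL",
                      nt = NULL, a104 = "C", a118 = "W", ident = 97.64) {
  data.frame(sequence_id = id, v_call = v, d_call = d, j_call = j,
             cdr3_aa = cdr3,
             cdr3_nt = nt %||% paste(rep("acg", nchar(cdr3)), collapse = ""),
             junction_aa = paste0(a104, cdr3, a118),
             anchor104 = a104, anchor118 = a118, v_identity = ident,
             sequence = strrep("acgt", 100), productive = TRUE,
             stringsAsFactors = FALSE)
}

test_that("a single record defines one clonotype with its full key", {
  cs <- call_clonotypes(mk_record("S1"))
  expect_identical(nrow(cs$clonotypes), 1L)
  cl <- cs$clonotypes
  expect_identical(cl$v_call, "IGHV6-1")
  expect_identical(cl$j_call, "IGHJ2")
  expect_identical(cl$cdr3_aa, "TRDGPVAVHWFFAL")
  expect_identical(cl$cdr3_length, 14L)
  expect_identical(cl$anchor104, "C")
  expect_identical(cl$anchor118, "W")
  # allele-level keying is available as an option
  cs2 <- call_clonotypes(mk_record("S1"), call_level = "allele")
  expect_identical(cs2$clonotypes$v_call, "IGHV6-1*01")
})

test_that("same AA key with different CDR3 nt gives 1 AA / 2 nt clonotypes", {
  nt1 <- "tgcagagatggccctgtagcagtacattggtttttcgctctg"
  nt2 <- nt1
  for (p in c(9, 12, 30, 33)) {
    substr(nt2, p, p) <- if (substr(nt1, p, p) == "c") "t" else "c"
  }
  recs <- rbind(mk_record("S1", nt = nt1), mk_record("S2", nt = nt2))
  cs <- call_clonotypes(recs)
  expect_identical(nrow(cs$clonotypes), 1L)
  expect_identical(cs$clonotypes$n_nt_clonotypes, 2L)
  expect_identical(cs$clonotypes$one_copy, 2L)
  expect_identical(cs$clonotypes$more_than_one, 0L)
})

test_that("records violating anchor conservation are excluded with a reason", {
  recs <- rbind(mk_record("S1"), mk_record("S2", a104 = "Y"),
                mk_record("S3", a118 = "L"), mk_record("S4", v = NA))
  cs <- call_clonotypes(recs)
  expect_identical(nrow(cs$clonotypes), 1L)
  expect_identical(sort(cs$excluded$sequence_id), c("S2", "S3", "S4"))
  expect_setequal(unique(cs$excluded$reason),
                  c("non-conserved anchors", "missing V or J call"))
  expect_identical(nrow(call_clonotypes(mk_record("S0")[0, ])$clonotypes),
                   0L)
})

test_that("clonotype calling is permutation-invariant and conserves counts", {
  cfg <- sim_config(seed = 23, n_clones = 25)
  rep <- simulate_repertoire(cfg)
  cs1 <- call_clonotypes(rep$records)
  perm <- rep$records[sample(nrow(rep$records)), ]
  cs2 <- call_clonotypes(perm)
  k1 <- cs1$clonotypes[order(cs1$clonotypes$cdr3_aa),
                       c("v_call", "j_call", "cdr3_aa", "n_members")]
  k2 <- cs2$clonotypes[order(cs2$clonotypes$cdr3_aa),
                       c("v_call", "j_call", "cdr3_aa", "n_members")]
  rownames(k1) <- rownames(k2) <- NULL
  expect_identical(k1, k2)
  # one_copy + members of multi-copy groups == included records
  cl <- cs1$clonotypes
  expect_identical(sum(cl$one_copy) + sum(cl$more_than_one),
                   nrow(cs1$members))
})

test_that("representative selection prefers identity, then length, then id", {
  recs <- rbind(mk_record("S2", ident = 95),
                mk_record("S1", ident = 99),
                mk_record("S3", ident = 99))
  recs$sequence[2] <- strrep("acgt", 90)
  cs <- call_clonotypes(recs)
  # S3 has top identity and the longer sequence
  expect_identical(cs$clonotypes$representative, "S3")
})

test_that("diversity and expression tables reconcile with their totals", {
  cfg <- sim_config(seed = 29, n_clones = 40)
  rep <- simulate_repertoire(cfg)
  cs <- call_clonotypes(rep$records)
  tab <- clonotype_tables(cs)
  expect_identical(sum(tab$v_gene$diversity), nrow(cs$clonotypes))
  expect_identical(sum(tab$j_gene$diversity), nrow(cs$clonotypes))
  expect_identical(sum(tab$cdr3_length$expression), nrow(cs$members))
  # on a simulated repertoire the diversity table equals the clone table
  truth <- rep$truth[!duplicated(rep$truth$clone_id), ]
  want <- table(truth$v_gene)
  got <- setNames(tab$v_gene$diversity, tab$v_gene$category)
  # strip allele suffix from truth names for the gene-level key
  names(want) <- sub("\\*.*$", "", names(want))
  expect_identical(as.integer(got[names(want)]), as.integer(want))
})

test_that("two-proportion comparisons match closed-form arithmetic", {
  mk_tab <- function(x, n) {
    structure(list(
      v_gene = data.frame(category = c("G1", "G2"),
                          diversity = c(x, n - x),
                          expression = c(x, n - x)),
      j_gene = data.frame(), cdr3_length = data.frame(),
      totals = c(diversity = n, expression = n)),
      class = "clonotype_tables")
  }
  cmp <- compare_clonotype_sets(mk_tab(30, 100), mk_tab(10, 100), "v_gene")
  row <- cmp[cmp$category == "G1", ]
  expect_equal(row$diff, 0.20)
  pp <- 40 / 200
  z <- 0.20 / sqrt(pp * (1 - pp) * (1 / 100 + 1 / 100))
  expect_equal(row$z, z)
  expect_equal(row$raw_p, 2 * pnorm(-abs(z)))
  se <- sqrt(0.3 * 0.7 / 100 + 0.1 * 0.9 / 100)
  expect_equal(row$ci_low, 0.20 - qnorm(0.975) * se)
  expect_equal(row$ci_high, 0.20 + qnorm(0.975) * se)
  expect_true(row$ci_low <= row$diff && row$diff <= row$ci_high)
  # identical tables: all diffs zero, all non-significant
  same <- compare_clonotype_sets(mk_tab(30, 100), mk_tab(30, 100), "v_gene")
  expect_true(all(same$diff == 0))
  expect_true(all(same$significance == "non-significant"))
  expect_error(compare_clonotype_sets(mk_tab(0, 0), mk_tab(10, 100),
                                      "v_gene"),
               "zero total")
})

test_that("adjustments match brute-force definitions; Bonferroni implies BH", {
  set.seed(101)
  for (rep_i in 1:5) {
    p <- round(runif(10)^3, 4)
    bh <- oracle_bh_reject(p, 0.05)
    bonf <- oracle_bonferroni_reject(p, 0.05)
    expect_identical(unname(p.adjust(p, "BH") <= 0.05), bh)
    expect_identical(unname(p.adjust(p, "bonferroni") <= 0.05), bonf)
    # dominance: Bonferroni-significant implies BH-significant
    expect_true(all(!bonf | bh))
  }
})

test_that("significance classes follow the agreement-count taxonomy", {
  mk_tab <- function(counts, n) {
    structure(list(
      v_gene = data.frame(category = paste0("G", seq_along(counts)),
                          diversity = counts, expression = counts),
      j_gene = data.frame(), cdr3_length = data.frame(),
      totals = c(diversity = n, expression = n)),
      class = "clonotype_tables")
  }
  a <- mk_tab(c(60, 10, 12, 18), 100)
  b <- mk_tab(c(20, 30, 25, 25), 100)
  cmp <- compare_clonotype_sets(a, b, "v_gene")
  expect_true(all(cmp$significance %in%
                    c("non-significant", "rawp", "Only_BH", "Min_2p",
                      "All_p")))
  # class is monotone in the number of agreeing procedures among raw hits
  rank <- c("rawp" = 1, "Only_BH" = 2, "Min_2p" = 3, "All_p" = 4)
  hits <- cmp[cmp$raw_p < 0.05, ]
  o <- order(hits$n_agree)
  expect_true(all(diff(rank[hits$significance[o]]) >= 0))
  expect_identical(cmp$significance[cmp$n_agree == 7 & cmp$raw_p < 0.05],
                   rep("All_p", sum(cmp$n_agree == 7 & cmp$raw_p < 0.05)))
  strong <- cmp[cmp$category == "G1", ]
  expect_identical(strong$significance, "All_p")
})
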