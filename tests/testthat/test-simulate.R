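test_that("toy germline sets are seed-reproducible and hallmark-correct", {
  cfg <- sim_config(seed = 5, n_v = 3, n_d = 4, n_j = 2)
  g1 <- make_toy_germline(cfg)
  g2 <- make_toy_germline(cfg)
  expect_identical(g1, g2)
  expect_identical(nrow(g1$v), 3L)
  expect_identical(nrow(g1$d), 4L)
  expect_identical(nrow(g1$j), 2L)
  # different seeds give different sets
  expect_false(identical(g1, make_toy_germline(sim_config(seed = 6,
                                                          n_v = 3,
                                                          n_d = 4,
                                                          n_j = 2))))
  # a rearranged domain built from the toy genes passes hallmark checks
  rep <- simulate_repertoire(cfg, g1)
  r <- rep$records[1, ]
  aa <- igkit:::.translate_nt(r$sequence)
  cdr3 <- nchar(r$cdr3_aa)
  dom <- assign_numbering(aa, c(25, 8, 17, 8, 38, cdr3, 11), "V")
  h <- verify_hallmarks(dom)
  expect_true(all(h$pass))
  tf <- withr::local_tempdir()
  write_germline_fasta(g1, tf)
  expect_true(all(file.exists(file.path(tf, c("V.fasta", "D.fasta",
                                              "J.fasta")))))
})

test_that("zero trims, N and SHM give pure germline V+D+J junctions", {
  cfg <- sim_config(seed = 9, trim_mean = 0, p_prob = 0, n_mean = 0,
                    shm_rate = 0, n_clones = 10, enforce_frame = FALSE)
  germ <- make_toy_germline(cfg)
  rep <- simulate_repertoire(cfg, germ)
  for (i in which(!duplicated(rep$truth$clone_id))) {
    t1 <- rep$truth[i, ]
    vi <- match(t1$v_gene, germ$v$name)
    di <- match(t1$d_gene, germ$d$name)
    ji <- match(t1$j_gene, germ$j$name)
    core <- paste0(germ$v$v3_nt[vi], germ$d$nt[di], germ$j$j5_nt[ji])
    expect_identical(t1$junction, core)
    expect_identical(t1$v_trim + t1$d5_trim + t1$d3_trim + t1$j_trim, 0L)
    expect_identical(t1$n1, "")
    expect_identical(t1$n2, "")
  }
})

test_that("same seed reproduces the repertoire byte for byte", {
  cfg <- sim_config(seed = 13, n_clones = 15, shm_rate = 0.01)
  r1 <- simulate_repertoire(cfg)
  r2 <- simulate_repertoire(cfg)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$truth, r2$truth)
})

test_that("emitted sequences reconstruct from truth before SHM", {
  cfg <- sim_config(seed = 19, n_clones = 20, shm_rate = 0.01)
  germ <- make_toy_germline(cfg)
  rep <- simulate_repertoire(cfg, germ)
  m <- merge(rep$records, rep$truth, by = "sequence_id")
  for (i in seq_len(min(nrow(m), 30))) {
    r <- m[i, ]
    vi <- match(r$v_gene, germ$v$name)
    ji <- match(r$j_gene, germ$j$name)
    v_nt <- germ$v$nt[vi]
    pre <- paste0(substr(v_nt, 1, nchar(v_nt) - 9), r$junction.y,
                  substring(germ$j$nt[ji], 13))
    # SHM positions are the only differences from the reconstruction
    a <- strsplit(pre, "")[[1]]
    b <- strsplit(r$sequence, "")[[1]]
    expect_identical(length(a), length(b))
    diffs <- which(a != b)
    shm <- if (nzchar(r$shm_positions)) {
      as.integer(strsplit(r$shm_positions, ",")[[1]])
    } else integer(0)
    expect_true(all(diffs %in% shm))
  }
})

test_that("N nucleotides follow the configured g bias (binomial check)", {
  cfg <- sim_config(seed = 101, n_clones = 400, clone_size_mean = 1,
                    g_bias = 0.7, n_mean = 6, trim_mean = 1)
  rep <- simulate_repertoire(cfg)
  tr <- rep$truth[!duplicated(rep$truth$clone_id), ]
  nts <- strsplit(paste0(paste(tr$n1, collapse = ""),
                         paste(tr$n2, collapse = "")), "")[[1]]
  n <- length(nts)
  g <- sum(nts == "g")
  bounds <- qbinom(c(0.005, 0.995), n, 0.7)
  expect_gte(g, bounds[1])
  expect_lte(g, bounds[2])
  expect_gte(n, 2000L)
})

test_that("hotspot motifs concentrate SHM when upweighted", {
  cfg <- sim_config(seed = 7, n_clones = 48, clone_size_mean = 8,
                    shm_rate = 0.01, hotspot_multiplier = 5)
  germ <- make_toy_germline(cfg)
  rep <- simulate_repertoire(cfg, germ)
  hot_mut <- hot_n <- cold_mut <- cold_n <- 0
  for (i in seq_len(nrow(rep$records))) {
    r <- rep$records[i, ]
    t1 <- rep$truth[i, ]
    # reconstruct the pre-SHM sequence to locate hotspots and the junction
    vi <- match(t1$v_gene, germ$v$name)
    ji <- match(t1$j_gene, germ$j$name)
    v_nt <- germ$v$nt[vi]
    pre <- paste0(substr(v_nt, 1, nchar(v_nt) - 9), t1$junction,
                  substring(germ$j$nt[ji], 13))
    j_span <- (nchar(v_nt) - 9 + 1):(nchar(v_nt) - 9 + nchar(t1$junction))
    eligible <- setdiff(seq_len(nchar(pre)), j_span)
    hot <- intersect(igkit:::.hotspot_sites(pre), eligible)
    cold <- setdiff(eligible, hot)
    shm <- if (nzchar(t1$shm_positions)) {
      as.integer(strsplit(t1$shm_positions, ",")[[1]])
    } else integer(0)
    hot_mut <- hot_mut + sum(shm %in% hot)
    cold_mut <- cold_mut + sum(shm %in% cold)
    hot_n <- hot_n + length(hot)
    cold_n <- cold_n + length(cold)
  }
  expect_gte(hot_n + cold_n, 1e5)
  ratio <- (hot_mut / hot_n) / (cold_mut / cold_n)
  expect_gt(ratio, 1)
  ct <- prop.test(c(hot_mut, cold_mut), c(hot_n, cold_n),
                  conf.level = 0.99)
  expect_gt(ct$conf.int[1], 0)
})

test_that("clonotype calling recovers the planted clone partition exactly", {
  cfg <- sim_config(seed = 37, n_clones = 50, clone_size_mean = 4,
                    shm_rate = 0.01)
  rep <- simulate_repertoire(cfg)
  cs <- call_clonotypes(rep$records)
  m <- merge(cs$members, rep$records[, c("sequence_id", "clone_id")])
  ari <- oracle_ari(m$clonotype_id, m$clone_id)
  expect_identical(ari, 1)
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(mclust::adjustedRandIndex(m$clonotype_id, m$clone_id), 1)
  }
})
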