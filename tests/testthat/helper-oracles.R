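# Independent oracles, coded without reuse of package internals.

# longest common prefix / suffix by direct character comparison
oracle_lcp <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  k <- 0L
  while (k < n && substr(a, k + 1L, k + 1L) == substr(b, k + 1L, k + 1L)) {
    k <- k + 1L
  }
  k
}

oracle_lcs_suffix <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  n <- min(na, nb)
  k <- 0L
  while (k < n && substr(a, na - k, na - k) == substr(b, nb - k, nb - k)) {
    k <- k + 1L
  }
  k
}

# longest common substring via row-by-row dynamic programming
oracle_lcsub <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) return(0L)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  prev <- integer(length(bv))
  best <- 0L
  for (i in seq_along(av)) {
    cur <- as.integer(av[i] == bv) * (c(0L, prev[-length(prev)]) + 1L)
    best <- max(best, cur)
    prev <- cur
  }
  best
}

# exhaustive enumeration of (v_len, j_len) with the best D window found by
# longest-common-substring search in the remaining middle region; returns
# the maximum germline-matched total
oracle_junction_score <- function(junction, v3, d_refs, j5, min_d = 5L) {
  jnt <- tolower(junction)
  L <- nchar(jnt)
  maxv <- oracle_lcp(jnt, tolower(v3))
  maxj <- oracle_lcs_suffix(jnt, tolower(j5))
  best <- 0L
  for (vl in 0:maxv) {
    for (jl in 0:min(maxj, L - vl)) {
      middle <- substr(jnt, vl + 1L, L - jl)
      d_best <- 0L
      for (d in d_refs) {
        d_best <- max(d_best, oracle_lcsub(middle, tolower(d)))
      }
      if (d_best < min_d) d_best <- 0L
      best <- max(best, vl + jl + d_best)
    }
  }
  best
}

# step-up Benjamini-Hochberg from the definition: reject all p(i) with
# i <= k where k is the largest i such that p(i) <= i * q / m
oracle_bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0L
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  reject <- rep(FALSE, m)
  if (k > 0L) reject[o[seq_len(k)]] <- TRUE
  reject
}

oracle_bonferroni_reject <- function(p, q) {
  p <= q / length(p)
}

# adjusted Rand index from the contingency table definition
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_ij <- sum_a * sum_b / n
  (sum_ij - exp_ij) / ((sum_a + sum_b) / 2 - exp_ij)
}
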