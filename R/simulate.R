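# Synthetic germline sets and V-(D)-J rearrangement simulator: D-J then V-DJ
# joining, exonuclease trimming, palindromic P nucleotides at untrimmed ends,
# g-biased N addition, and hotspot-targeted somatic hypermutation, with full
# ground truth recorded per record.

#' Simulation configuration
#'
#' @param seed integer seed fixing the full output.
#' @param n_v,n_d,n_j toy germline set sizes.
#' @param trim_mean mean of the geometric trim-length distribution (nt).
#' @param p_prob probability of P nucleotides at an untrimmed coding end.
#' @param n_mean mean N-region length (Poisson).
#' @param g_bias probability that an N nucleotide is `g` (the remaining
#'   mass is uniform over a, c, t); template-independent N addition
#'   preferentially inserts g.
#' @param shm_rate per-site somatic hypermutation probability.
#' @param hotspot_multiplier SHM rate multiplier inside hotspot motifs
#'   ((a/t)a, t(a/t), (a/g)g(c/t)(a/t), (a/t)(a/g)c(c/t)).
#' @param n_clones number of clones.
#' @param clone_size_mean mean clone size (shifted Poisson, >= 1).
#' @param shm_in_junction apply SHM inside the junction (default FALSE so
#'   clonotype keys stay intact).
#' @param enforce_frame pad N2 with 0-2 nt so the junction stays in frame
#'   (productive rearrangements); disable to emit raw joins.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_v = 4L, n_d = 5L, n_j = 3L,
                       trim_mean = 2, p_prob = 0.5, n_mean = 4,
                       g_bias = 0.4, shm_rate = 0, hotspot_multiplier = 1,
                       n_clones = 50L, clone_size_mean = 3,
                       shm_in_junction = FALSE, enforce_frame = TRUE) {
  cfg <- list(seed = as.integer(seed), n_v = as.integer(n_v),
              n_d = as.integer(n_d), n_j = as.integer(n_j),
              trim_mean = trim_mean, p_prob = p_prob, n_mean = n_mean,
              g_bias = g_bias, shm_rate = shm_rate,
              hotspot_multiplier = hotspot_multiplier,
              n_clones = as.integer(n_clones),
              clone_size_mean = clone_size_mean,
              shm_in_junction = isTRUE(shm_in_junction),
              enforce_frame = isTRUE(enforce_frame))
  probs <- c(p_prob = cfg$p_prob, g_bias = cfg$g_bias,
             shm_rate = cfg$shm_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_v < 1L || cfg$n_d < 1L || cfg$n_j < 1L) {
    stop("germline set sizes must be >= 1", call. = FALSE)
  }
  if (cfg$hotspot_multiplier < 0) {
    stop("hotspot_multiplier must be >= 0", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# one fixed codon per amino acid (back-translation)
.codon_of <- c(A = "gct", C = "tgt", D = "gat", E = "gaa", F = "ttt",
               G = "ggt", H = "cat", I = "att", K = "aaa", L = "ctg",
               M = "atg", N = "aat", P = "cct", Q = "caa", R = "aga",
               S = "agc", T = "act", V = "gtt", W = "tgg", Y = "tat")

.translate_nt <- function(nt) {
  as.character(Biostrings::translate(Biostrings::DNAString(toupper(nt)),
                                     no.init.codon = TRUE))
}

#' Generate a toy germline set
#'
#' Builds `n_v` V genes, `n_d` D genes and `n_j` J genes. Every V encodes
#' 1st-CYS 23, CONSERVED-TRP 41, a hydrophobic residue at 89 and 2nd-CYS
#' 104 at the correct gapped positions (FR lengths 25/17/38, CDR1/CDR2
#' lengths 8/8, two germline CDR3 codons); every J encodes the F/W-G-X-G
#' motif at 118-121 after three CDR3 codons. Same seed, same FASTA.
#'
#' @param config a `sim_config`.
#' @return list of class `toy_germline` with data.frames `v`, `d`, `j`
#'   (columns: `name`, `nt`, and the junction-facing ends `v3_nt`/`j5_nt`).
#' @export
make_toy_germline <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  aa_pool <- setdiff(names(.codon_of), c("C", "W"))
  v_positions <- c(.segment_positions("V", "A", 14L),
                   .segment_positions("V", "B", 11L),
                   loop_position_sequence("BC", 8L),
                   .segment_positions("V", "C", 8L),
                   .segment_positions("V", "C'", 9L),
                   loop_position_sequence("C'C''", 8L),
                   .segment_positions("V", "C''", 8L),
                   .segment_positions("V", "D", 10L),
                   .segment_positions("V", "E", 12L),
                   .segment_positions("V", "F", 8L))
  mk_v <- function(i) {
    aa <- sample(aa_pool, length(v_positions), replace = TRUE)
    aa[match("23", v_positions)] <- "C"
    aa[match("41", v_positions)] <- "W"
    aa[match("89", v_positions)] <- sample(c("V", "L", "I", "F", "M"), 1)
    aa[match("104", v_positions)] <- "C"
    aa <- c(aa, sample(aa_pool, 2, replace = TRUE))  # germline CDR3 codons
    nt <- paste(.codon_of[aa], collapse = "")
    list(name = sprintf("TOYV%d*01", i), aa = paste(aa, collapse = ""),
         nt = nt, v3_nt = substr(nt, nchar(nt) - 8L, nchar(nt)))
  }
  mk_j <- function(i) {
    cdr3 <- sample(aa_pool, 3, replace = TRUE)
    fr4 <- c(sample(c("W", "F"), 1), "G", sample(aa_pool, 1), "G",
             sample(aa_pool, 7, replace = TRUE))
    aa <- c(cdr3, fr4)
    nt <- paste(.codon_of[aa], collapse = "")
    list(name = sprintf("TOYJ%d*01", i), aa = paste(aa, collapse = ""),
         nt = nt, j5_nt = substr(nt, 1L, 12L))
  }
  mk_d <- function(i) {
    len <- sample(12:20, 1)
    list(name = sprintf("TOYD%d*01", i),
         nt = paste(sample(c("a", "c", "g", "t"), len, replace = TRUE),
                    collapse = ""))
  }
  v <- do.call(rbind, lapply(seq_len(config$n_v), function(i)
    as.data.frame(mk_v(i), stringsAsFactors = FALSE)))
  j <- do.call(rbind, lapply(seq_len(config$n_j), function(i)
    as.data.frame(mk_j(i), stringsAsFactors = FALSE)))
  d <- do.call(rbind, lapply(seq_len(config$n_d), function(i)
    as.data.frame(mk_d(i), stringsAsFactors = FALSE)))
  structure(list(v = v, d = d, j = j,
                 v_boundaries = c(25L, 8L, 17L, 8L, 38L)),
            class = "toy_germline")
}

#' Write a toy germline set as FASTA
#'
#' @param germline a `toy_germline`.
#' @param dir output directory; writes `V.fasta`, `D.fasta`, `J.fasta`.
#' @return the directory, invisibly.
#' @export
write_germline_fasta <- function(germline, dir) {
  stopifnot(inherits(germline, "toy_germline"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (set in c("v", "d", "j")) {
    xs <- Biostrings::DNAStringSet(toupper(germline[[set]]$nt))
    names(xs) <- germline[[set]]$name
    Biostrings::writeXStringSet(xs, file.path(dir,
                                              paste0(toupper(set),
                                                     ".fasta")))
  }
  invisible(dir)
}

# positions covered by any SHM hotspot motif occurrence
.hotspot_sites <- function(nt) {
  motifs <- c("[at]a", "t[at]", "[ag]g[ct][at]", "[at][ag]c[ct]")
  covered <- logical(nchar(nt))
  for (m in motifs) {
    hits <- gregexpr(paste0("(?=", m, ")"), nt, perl = TRUE)[[1]]
    if (hits[1] == -1L) next
    mlen <- nchar(gsub("\\[[^]]*\\]", "N", m))
    for (h in hits) covered[h:(h + mlen - 1L)] <- TRUE
  }
  which(covered[seq_len(nchar(nt))])
}

# draw a point mutation with transitions favored 2:1 over transversions
.mutate_nt <- function(base) {
  transitions <- c(a = "g", g = "a", c = "t", t = "c")
  transversions <- list(a = c("c", "t"), g = c("c", "t"),
                        c = c("a", "g"), t = c("a", "g"))
  if (stats::runif(1) < 2 / 3) unname(transitions[base])
  else sample(transversions[[base]], 1)
}

.rgeom_mean <- function(n, mean) {
  if (mean <= 0) return(integer(n))
  stats::rgeom(n, prob = 1 / (1 + mean))
}

.sample_n_region <- function(len, g_bias) {
  if (len == 0L) return("")
  paste(sample(c("g", "a", "c", "t"), len, replace = TRUE,
               prob = c(g_bias, rep((1 - g_bias) / 3, 3))), collapse = "")
}

#' Simulate a rearranged repertoire with ground truth
#'
#' For each clone, joins a D to a J and then a V to the D-J (12/23-style
#' pairing honoured structurally), with geometric trims, P nucleotides
#' (1-3 nt, reverse complement of the intact coding end, only when the end
#' is untrimmed), g-biased N regions, and per-member SHM with hotspot
#' upweighting. The N2 length is padded by 0-2 nt so the junction stays in
#' frame (productive rearrangements).
#'
#' @param config a `sim_config`.
#' @param germline a `toy_germline` (default: built from `config`).
#' @return list of class `sim_repertoire` with `records` (AIRR-style
#'   data.frame) and `truth` (per-record data.frame including a
#'   `degenerate` flag marking records whose junction admits an equally- or
#'   better-scoring alternative germline explanation by chance).
#' @export
simulate_repertoire <- function(config = sim_config(),
                                germline = make_toy_germline(config)) {
  stopifnot(inherits(config, "sim_config"),
            inherits(germline, "toy_germline"))
  set.seed(config$seed + 1L)
  d_refs <- stats::setNames(as.list(germline$d$nt), germline$d$name)
  recs <- list()
  truths <- list()
  rid <- 0L
  for (cl in seq_len(config$n_clones)) {
    vi <- sample.int(nrow(germline$v), 1)
    di <- sample.int(nrow(germline$d), 1)
    ji <- sample.int(nrow(germline$j), 1)
    v3 <- germline$v$v3_nt[vi]
    j5 <- germline$j$j5_nt[ji]
    dnt <- germline$d$nt[di]
    v_trim <- min(.rgeom_mean(1, config$trim_mean), nchar(v3) - 3L)
    j_trim <- min(.rgeom_mean(1, config$trim_mean), nchar(j5) - 4L)
    d5_trim <- min(.rgeom_mean(1, config$trim_mean), 3L)
    d3_trim <- min(.rgeom_mean(1, config$trim_mean),
                   nchar(dnt) - d5_trim - 5L)
    d3_trim <- max(d3_trim, 0L)
    p_draw <- function(trim, end_seq, side) {
      if (trim > 0L || stats::runif(1) >= config$p_prob) return("")
      k <- sample.int(3L, 1)
      if (side == "after") {
        .revcomp(substr(end_seq, nchar(end_seq) - k + 1L, nchar(end_seq)))
      } else {
        .revcomp(substr(end_seq, 1L, k))
      }
    }
    v_seg <- substr(v3, 1L, nchar(v3) - v_trim)
    j_seg <- substr(j5, j_trim + 1L, nchar(j5))
    d_seg <- substr(dnt, d5_trim + 1L, nchar(dnt) - d3_trim)
    v_p <- p_draw(v_trim, v_seg, "after")
    d5_p <- p_draw(d5_trim, d_seg, "before")
    d3_p <- p_draw(d3_trim, d_seg, "after")
    j_p <- p_draw(j_trim, j_seg, "before")
    n1 <- .sample_n_region(stats::rpois(1, config$n_mean), config$g_bias)
    n2 <- .sample_n_region(stats::rpois(1, config$n_mean), config$g_bias)
    junction <- paste0(v_seg, v_p, n1, d5_p, d_seg, d3_p, n2, j_p, j_seg)
    pad <- (3L - nchar(junction) %% 3L) %% 3L
    if (pad > 0L && config$enforce_frame) {
      n2 <- paste0(n2, .sample_n_region(pad, config$g_bias))
      junction <- paste0(v_seg, v_p, n1, d5_p, d_seg, d3_p, n2, j_p, j_seg)
    }
    v_rest <- substr(germline$v$nt[vi], 1L,
                     nchar(germline$v$nt[vi]) - nchar(v3))
    j_rest <- substring(germline$j$nt[ji], nchar(j5) + 1L)
    seq0 <- paste0(v_rest, junction, j_rest)
    junction_aa <- .translate_nt(substr(junction, 1L,
                                        3L * (nchar(junction) %/% 3L)))
    s_truth <- nchar(v_seg) + nchar(v_p) + nchar(n1) + nchar(d5_p) + 1L
    degenerate <- .is_degenerate_junction(junction, v3, d_refs, j5,
                                          germline$d$name[di],
                                          nchar(v_seg), nchar(d_seg),
                                          nchar(j_seg), d5_trim,
                                          nchar(v_p), nchar(d5_p),
                                          nchar(d3_p), nchar(j_p),
                                          s_truth)
    size <- 1L + stats::rpois(1, max(config$clone_size_mean - 1, 0))
    j_start <- nchar(v_rest) + 1L
    j_end <- nchar(v_rest) + nchar(junction)
    for (m in seq_len(size)) {
      rid <- rid + 1L
      nt <- strsplit(seq0, "")[[1]]
      shm_pos <- integer(0)
      if (config$shm_rate > 0) {
        eligible <- seq_along(nt)
        if (!config$shm_in_junction) {
          eligible <- setdiff(eligible, j_start:j_end)
        }
        hot <- intersect(.hotspot_sites(seq0), eligible)
        cold <- setdiff(eligible, hot)
        p_hot <- min(1, config$shm_rate * config$hotspot_multiplier)
        mut <- c(hot[stats::runif(length(hot)) < p_hot],
                 cold[stats::runif(length(cold)) < config$shm_rate])
        for (p in mut) nt[p] <- .mutate_nt(nt[p])
        shm_pos <- sort(mut)
      }
      seq_m <- paste(nt, collapse = "")
      v_len_full <- nchar(v_rest) + nchar(v_seg)
      v_germ <- substr(germline$v$nt[vi], 1L, v_len_full)
      v_obs <- substr(seq_m, 1L, v_len_full)
      v_identity <- round(100 * sum(strsplit(v_germ, "")[[1]] ==
                                      strsplit(v_obs, "")[[1]]) /
                            v_len_full, 2)
      recs[[rid]] <- data.frame(
        sequence_id = sprintf("SIM%05d", rid),
        clone_id = cl,
        v_call = germline$v$name[vi],
        d_call = germline$d$name[di],
        j_call = germline$j$name[ji],
        sequence = seq_m,
        junction = substr(seq_m, j_start, j_end),
        junction_aa = junction_aa,
        cdr3_nt = substr(junction, 4L, nchar(junction) - 3L),
        cdr3_aa = substr(junction_aa, 2L, nchar(junction_aa) - 1L),
        anchor104 = substr(junction_aa, 1L, 1L),
        anchor118 = substr(junction_aa, nchar(junction_aa),
                           nchar(junction_aa)),
        v_identity = v_identity,
        productive = TRUE,
        stringsAsFactors = FALSE)
      truths[[rid]] <- data.frame(
        sequence_id = sprintf("SIM%05d", rid),
        clone_id = cl,
        v_gene = germline$v$name[vi], d_gene = germline$d$name[di],
        j_gene = germline$j$name[ji],
        v_len = nchar(v_seg), d_len = nchar(d_seg), j_len = nchar(j_seg),
        v_trim = v_trim, d5_trim = d5_trim, d3_trim = d3_trim,
        j_trim = j_trim,
        v_p = nchar(v_p), d5_p = nchar(d5_p), d3_p = nchar(d3_p),
        j_p = nchar(j_p),
        n1 = n1, n2 = n2,
        junction = junction,
        n_shm = length(shm_pos),
        shm_positions = paste(shm_pos, collapse = ","),
        degenerate = degenerate,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  truth <- do.call(rbind, truths)
  structure(list(records = records, truth = truth, config = config,
                 germline = germline),
            class = "sim_repertoire")
}

# a simulated junction is degenerate when chance matches allow an
# alternative germline explanation at least as good as the truth: V or J
# accidental extension, a competing or extendable D placement, or an
# ambiguous P assignment
.is_degenerate_junction <- function(junction, v3, d_refs, j5, d_name,
                                    v_len, d_len, j_len, d5_trim,
                                    v_p, d5_p, d3_p, j_p, s_truth) {
  if (d_len < 5L) return(TRUE)
  if (.lc_prefix(junction, v3) != v_len) return(TRUE)
  if (.lc_suffix(junction, j5) != j_len) return(TRUE)
  jv <- strsplit(junction, "")[[1]]
  L <- length(jv)
  e_truth <- s_truth + d_len - 1L
  a <- v_len + 1L
  b <- L - j_len
  for (g in names(d_refs)) {
    runs <- .d_runs(jv, strsplit(d_refs[[g]], "")[[1]])
    for (r in seq_len(nrow(runs))) {
      ov <- min(runs$e[r], b) - max(runs$s[r], a) + 1L
      if (ov < 1L) next
      is_truth <- g == d_name && runs$s[r] <= s_truth &&
        runs$e[r] >= e_truth &&
        runs$ds[r] + (s_truth - runs$s[r]) == d5_trim + 1L
      if (is_truth) {
        # truth run must not extend beyond the planted segment
        if (runs$s[r] < s_truth || runs$e[r] > e_truth) return(TRUE)
      } else if (ov >= d_len) {
        return(TRUE)
      }
    }
  }
  # P assignments must be recoverable exactly on the truth segmentation
  g1 <- substr(junction, v_len + 1L, s_truth - 1L)
  g2 <- substr(junction, e_truth + 1L, L - j_len)
  v_untrimmed <- v_len == nchar(v3)
  d_seq <- d_refs[[d_name]]
  d_core <- substr(d_seq, d5_trim + 1L, d5_trim + d_len)
  ok <- TRUE
  if (v_untrimmed) {
    ok <- ok && .p_len_after(g1, v3) == v_p
  } else {
    ok <- ok && v_p == 0L
  }
  if (d5_trim == 0L) {
    ok <- ok && .p_len_before(substr(g1, v_p + 1L, nchar(g1)),
                              d_core) == d5_p
  }
  d3_untrimmed <- d5_trim + d_len == nchar(d_seq)
  if (d3_untrimmed) {
    ok <- ok && .p_len_after(g2, d_core) == d3_p
  }
  if (j_len == nchar(j5)) {
    ok <- ok && .p_len_before(substr(g2, d3_p + 1L, nchar(g2)), j5) == j_p
  }
  !ok
}
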