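# Independent brute-force oracles and tiny fixture builders shared across
# the suite. The oracles deliberately avoid the package's interval machinery
# (plain quadratic scans over data frames).

# quadratic one-to-one maximal-overlap matcher mirroring the documented
# pairing semantics: A peaks in catalog order, per A peak the unmatched B
# peak of maximal overlap, ties to the leftmost (then first) B peak
oracle_pair <- function(a, b, min_overlap_bp = 1L) {
  used_b <- logical(nrow(b))
  pairs <- NULL
  for (i in seq_len(nrow(a))) {
    ov <- ifelse(b$chrom == a$chrom[i],
                 pmin(a$end[i], b$end) - pmax(a$start[i], b$start),
                 -Inf)
    ov[used_b | ov < min_overlap_bp] <- -Inf
    if (all(ov == -Inf)) next
    best <- max(ov)
    cand <- which(ov == best)
    j <- cand[order(b$start[cand], cand)][1]
    used_b[j] <- TRUE
    pairs <- rbind(pairs, data.frame(idx_a = i, idx_b = j, overlap_bp = best))
  }
  list(pairs = pairs,
       unique_a = setdiff(seq_len(nrow(a)),
                          if (is.null(pairs)) integer() else pairs$idx_a),
       unique_b = which(!used_b))
}

# quadratic membership scan for the Venn partition
oracle_venn_membership <- function(sets, min_overlap_bp = 1L) {
  lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    vapply(seq_len(nrow(s)), function(p) {
      member <- logical(length(sets))
      member[i] <- TRUE
      for (j in seq_along(sets)) {
        if (j == i) next
        o <- sets[[j]]
        ov <- ifelse(o$chrom == s$chrom[p],
                     pmin(s$end[p], o$end) - pmax(s$start[p], o$start), 0)
        if (any(ov >= min_overlap_bp)) member[j] <- TRUE
      }
      paste(names(sets)[member], collapse = "&")
    }, character(1))
  })
}

# exhaustive hypergeometric upper tail via binomial coefficients
oracle_fisher_greater <- function(k, n_target, n_signature, n_universe) {
  j <- max(0L, n_target + n_signature - n_universe):min(n_target, n_signature)
  probs <- choose(n_signature, j) * choose(n_universe - n_signature,
                                           n_target - j) /
    choose(n_universe, n_target)
  sum(probs[j >= k])
}

# random peak set on a couple of chromosomes for property tests
random_peaks <- function(n, label = "r", max_pos = 10000L,
                         chroms = c("chr1", "chr2")) {
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample(10:300, n, replace = TRUE)
  df <- data.frame(chrom = sample(chroms, n, replace = TRUE),
                   start = start, end = start + width)
  df <- df[!duplicated(df[, c("chrom", "start", "end")]), , drop = FALSE]
  peak_set(df$chrom, df$start, df$end, sample_label = label)
}

# two genes on opposite strands for compartment and nearest-gene tests
tiny_annotation <- function() {
  gene_annotation(
    name = c("Aplus", "Bminus"),
    chrom = c("chr1", "chr1"),
    strand = c("+", "-"),
    tx_start = c(100000, 300000),
    tx_end = c(110000, 312000),
    exon_starts = list(c(100000, 104000), c(300000, 308000)),
    exon_ends = list(c(101000, 110000), c(302000, 312000))
  )
}

# default-scale simulation (the reference scenario); cached per session
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_experiment(sim_params())
    cache
  }
})

# small simulation used by several suites; cached per session
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_experiment(sim_params(
        n_genes = 200L, chrom_length = 200 * 30000, n_common = 400L,
        n_diff_ko = 40L, n_diff_wt = 40L, signature_size = 60L))
    }
    cache
  }
})
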