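# Shared fixture builders: everything is generated in code, no data files.

# A motif whose matrix is fully determined by a consensus string
# (deterministic columns).
consensus_motif <- function(id, consensus) {
  bases <- strsplit(consensus, "")[[1]]
  mat <- t(vapply(bases, function(b) {
    f <- numeric(4)
    f[match(b, c("A", "C", "G", "T"))] <- 1
    f
  }, numeric(4)))
  motif(id, mat)
}

# A motif with arbitrary frequencies; rows is a list of length-4 vectors.
freq_motif <- function(id, rows) motif(id, do.call(rbind, rows))

# Random valid frequency matrix (Dirichlet-ish via normalized uniforms).
random_freq_motif <- function(id, width) {
  mat <- matrix(stats::runif(width * 4), ncol = 4)
  motif(id, mat / rowSums(mat))
}

# Exhaustive-enumeration oracle for hit p-values: all 4^width windows.
brute_force_tail <- function(dist, bg) {
  w <- nrow(dist$sint)
  grid <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- apply(grid, 1L, function(r)
    sum(dist$sint[cbind(seq_len(w), r)]))
  probs <- apply(grid, 1L, function(r) prod(as.numeric(bg)[r]))
  list(scores = scores, probs = probs,
       pvalue = function(s) {
      if (is.na(s)) return(1)
      sum(probs[!is.na(scores) & scores >= s])
    })
}

# Direct binomial-tail oracle: P(X >= k) by summing the pmf.
binom_tail_sum <- function(k, n, p) sum(stats::dbinom(k:n, n, p))

# Hypergeometric upper tail by enumerating every possible draw.
hyper_enum <- function(positive, universe, draws, observed) {
  if (observed == 0) return(1)
  members <- utils::combn(universe, draws)
  hits <- colSums(members <= positive)  # successes are items 1..positive
  mean(hits >= observed)
}

# A small planted universe for pair tests: two sharp motifs planted
# together in the first `n_pos` promoters.
small_planted_universe <- function(n = 120, len = 300, n_pos = 30,
                                   seed = 7) {
  withr::local_seed(seed)
  ma <- random_motif("A", 8)
  mb <- random_motif("B", 8)
  u <- random_promoters(n, len)
  genes <- names(u)[seq_len(n_pos)]
  for (g in genes) {
    sa <- sample.int(len - 40, 1L) - 1L
    u <- motifpairs:::plant_at(u, g, sa,
                               motifpairs:::sample_instance(ma), "+")
    u <- motifpairs:::plant_at(u, g, sa + 20L,
                               motifpairs:::sample_instance(mb), "+")
  }
  list(universe = u, motif_a = ma, motif_b = mb, planted = genes)
}
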