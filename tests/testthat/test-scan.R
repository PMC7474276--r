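test_that("single-position score distribution matches direct enumeration", {
  mA <- freq_motif("A1", list(c(1, 0, 0, 0)))
  d <- score_distribution(mA, background(), pseudocount = 0)
  # only A can match; its tail probability is the background probability
  h <- scan_promoter(mA, "ACGT", dist = d)
  expect_equal(h$pvalue[h$start == 0 & h$strand == "+"], 0.25)
  expect_equal(h$pvalue[h$start == 3 & h$strand == "-"], 0.25)  # T on minus
  expect_true(all(h$pvalue[-(1:2)] == 1))

  # a uniform motif scores 0 everywhere with p-value 1
  mu <- freq_motif("U", list(rep(.25, 4), rep(.25, 4)))
  hu <- scan_promoter(mu, "ACGTAC")
  expect_true(all(hu$score == 0))
  expect_true(all(hu$pvalue == 1))
})

test_that("the DP tail function is a valid survival function", {
  withr::local_seed(1)
  for (i in 1:5) {
    m <- random_freq_motif(paste0("m", i), sample(3:10, 1))
    d <- score_distribution(m, background(c(.3, .2, .2, .3)))
    expect_true(all(diff(d$tail) <= 1e-12))
    expect_equal(d$tail[1], 1)
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  }
})

test_that("hit p-values equal the exhaustive enumeration oracle", {
  withr::local_seed(7)
  bg <- background(c(.35, .15, .15, .35))
  for (w in 2:4) {
    m <- random_freq_motif(paste0("bf", w), w)
    d <- score_distribution(m, bg)
    oracle <- brute_force_tail(d, bg)
    prom <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    hits <- scan_promoter(m, prom, bg = bg, dist = d)
    code <- motifpairs:::encode_promoters(
      Biostrings::DNAStringSet(prom))[[1]]
    for (r in seq_len(nrow(hits))) {
      win <- code[(hits$start[r] + 1):(hits$start[r] + w)]
      s <- if (hits$strand[r] == "+") sum(d$sint[cbind(1:w, win)])
           else sum(d$sint_rc[cbind(1:w, win)])
      expect_equal(hits$pvalue[r], oracle$pvalue(s), tolerance = 1e-12)
    }
  }
})

test_that("N-containing windows and short promoters are handled", {
  m <- random_motif("n1", 4, seed = 3)
  expect_true(all(scan_promoter(m, "NNNNNN")$pvalue == 1))
  expect_equal(nrow(scan_promoter(m, "ACG")), 0)  # shorter than the motif
  h <- scan_promoter(m, "ACGTNACGTACGT")
  has_n <- h$start <= 4 & h$start + 4 > 4
  expect_true(all(h$pvalue[has_n] == 1))
})

test_that("scanning a promoter and its reverse complement mirrors hits", {
  withr::local_seed(21)
  m <- random_freq_motif("mir", 5)
  prom <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(prom)))
  h1 <- scan_promoter(m, prom)
  h2 <- scan_promoter(m, rc)
  # hit at (start, +) maps to (L - end, -) on the reverse complement
  key1 <- sprintf("%d:%s", h1$start, h1$strand)
  key2 <- sprintf("%d:%s", 60 - h2$end, ifelse(h2$strand == "+", "-", "+"))
  expect_setequal(
    paste(key1, format(h1$pvalue, digits = 12)),
    paste(key2, format(h2$pvalue, digits = 12)))
})

test_that("top non-overlapping selection is greedy by p-value", {
  hits <- data.frame(start = c(0L, 3L, 10L), end = c(5L, 8L, 15L),
                     strand = "+", score = 0,
                     pvalue = c(0.001, 0.01, 0.02))
  sel <- top_nonoverlapping(hits)
  expect_equal(sel$pvalue, c(0.001, 0.02))  # middle conflicts with best

  many <- data.frame(start = seq(0L, 60L, by = 10L),
                     end = seq(0L, 60L, by = 10L) + 5L, strand = "+",
                     score = 0, pvalue = (7:1) / 100)
  sel <- top_nonoverlapping(many, max_k = 5)
  expect_equal(nrow(sel), 5L)
  expect_equal(sel$pvalue, (1:5) / 100)  # the 5 best of 7

  # property: pairwise non-overlap; any skipped better hit conflicts with
  # an earlier selection
  withr::local_seed(9)
  for (i in 1:20) {
    n <- sample(3:25, 1)
    st <- sample(0:80, n, replace = TRUE)
    h <- data.frame(start = st, end = st + sample(3:8, n, TRUE),
                    strand = sample(c("+", "-"), n, TRUE), score = 0,
                    pvalue = round(stats::runif(n), 3))
    sel <- top_nonoverlapping(h, max_k = 5)
    if (nrow(sel) > 1) {
      ov <- outer(sel$start, sel$end, `<`) & outer(sel$end, sel$start, `>`)
      diag(ov) <- FALSE
      expect_false(any(ov))
    }
    if (nrow(sel) < 5) {
      skipped <- h[!paste(h$start, h$strand, h$pvalue) %in%
                     paste(sel$start, sel$strand, sel$pvalue), , drop = FALSE]
      for (r in seq_len(nrow(skipped))) {
        conflicts <- any(skipped$start[r] < sel$end &
                           skipped$end[r] > sel$start)
        better <- skipped$pvalue[r] < max(sel$pvalue)
        expect_true(conflicts || !better ||
                      any(sel$pvalue == skipped$pvalue[r]))
      }
    }
  }
})

test_that("binomial promoter score minimizes over k with exact tails", {
  one <- data.frame(start = 0L, end = 5L, strand = "+", score = 0,
                    pvalue = 0.5)
  ps <- promoter_score(one, promoter_length = 5, motif_width = 5,
                       strands = "+")
  expect_equal(ps$k_star, 1L)
  expect_equal(ps$binom_score, 0.5)  # 1 - (1 - p)^N with N = 1

  none <- one[integer(0), ]
  ps0 <- promoter_score(none, 100, 5)
  expect_equal(ps0$k_star, 0L)
  expect_equal(ps0$binom_score, 1)

  # promoter shorter than the motif
  expect_equal(promoter_score(one, 3, 5)$binom_score, 1)

  # two equal hits against the direct pmf-summation oracle
  two <- data.frame(start = c(0L, 10L), end = c(2L, 12L), strand = "+",
                    score = 0, pvalue = c(0.01, 0.01))
  ps2 <- promoter_score(two, promoter_length = 100, motif_width = 2,
                        strands = "both")
  expect_equal(ps2$trials, 198L)
  tails <- c(binom_tail_sum(1, 198, 0.01), binom_tail_sum(2, 198, 0.01))
  expect_equal(ps2$k_star, which.min(tails))
  expect_equal(ps2$binom_score, min(tails), tolerance = 1e-12)
})

test_that("random hit configurations match the binomial oracle", {
  withr::local_seed(123)
  for (i in 1:100) {
    k <- sample(1:5, 1)
    p <- sort(round(stats::runif(k, 1e-6, 0.3), 6))
    st <- seq(0L, by = 12L, length.out = k)
    h <- data.frame(start = st, end = st + 8L, strand = "+", score = 0,
                    pvalue = p)
    L <- sample(50:1000, 1)
    ps <- promoter_score(h, L, 8, strands = "both")
    N <- 2L * (L - 8L + 1L)
    gm <- exp(cumsum(log(p)) / seq_len(k))
    tails <- vapply(seq_len(k), function(kk)
      binom_tail_sum(kk, N, gm[kk]), numeric(1))
    # the chosen k attains the minimal tail (argmin ties are float dust)
    expect_lte(tails[ps$k_star], min(tails) + 1e-12)
    expect_equal(ps$binom_score, min(tails), tolerance = 1e-9)
  }
})

test_that("a better extra hit never worsens the promoter score", {
  withr::local_seed(5)
  for (i in 1:25) {
    k <- sample(1:4, 1)
    p <- sort(stats::runif(k, 1e-5, 0.5))
    st <- seq(0L, by = 15L, length.out = k)
    h <- data.frame(start = st, end = st + 6L, strand = "+", score = 0,
                    pvalue = p)
    extra <- rbind(h, data.frame(start = 90L, end = 96L, strand = "+",
                                 score = 0, pvalue = min(p) / 2))
    s1 <- promoter_score(h, 100, 6)$binom_score
    s2 <- promoter_score(extra, 100, 6)$binom_score
    expect_lte(s2, s1 + 1e-15)
  }
})

test_that("the motif index keeps the n best promoters with a recorded threshold", {
  withr::local_seed(31)
  u <- random_promoters(30, 120)
  m <- random_motif("ix", 6)
  idx <- index_motif(m, u, n = 5000)
  expect_equal(nrow(idx$scores), 30L)           # n exceeds the universe
  expect_equal(idx$threshold, max(idx$scores$binom_score))

  idx5 <- index_motif(m, u, n = 5)
  expect_equal(nrow(idx5$scores), 5L)
  expect_true(all(idx5$scores$binom_score <= idx$scores$binom_score[
    !idx$scores$gene_id %in% idx5$scores$gene_id]))
  expect_equal(idx5$threshold, max(idx5$scores$binom_score))
  # scores are sorted ascending and deterministic across reruns
  expect_false(is.unsorted(idx5$scores$binom_score))
  idx5b <- index_motif(m, u, n = 5)
  expect_identical(idx5$scores, idx5b$scores)
  expect_error(index_motif(m, u, n = 0), "n must be")
})

test_that("boundary ties in the index resolve by gene id", {
  # all-N promoters all score exactly 1: membership must follow gene id
  u <- Biostrings::DNAStringSet(setNames(rep(strrep("N", 50), 6),
                                         c("g4", "g2", "g6", "g1", "g5", "g3")))
  m <- random_motif("tie", 5, seed = 8)
  idx <- index_motif(m, u, n = 3)
  expect_identical(idx$scores$gene_id, c("g1", "g2", "g3"))
  idx2 <- index_motif(m, u, n = 3)
  expect_identical(idx$scores, idx2$scores)
})
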