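test_that("hit overlaps record genomic intersections and motif-local positions", {
  ha <- data.frame(start = 0L, end = 10L, strand = "+")
  hb <- data.frame(start = 8L, end = 14L, strand = "+")
  ov <- find_hit_overlaps(ha, hb)
  expect_length(ov, 1L)
  expect_equal(ov[[1]]$ostart, 8L)
  expect_equal(ov[[1]]$oend, 10L)
  expect_equal(ov[[1]]$positions_a, c(9L, 10L))  # 1-based motif positions
  expect_equal(ov[[1]]$positions_b, c(1L, 2L))

  # disjoint hits give no records
  expect_length(find_hit_overlaps(ha, data.frame(start = 20L, end = 25L,
                                                 strand = "+")), 0L)

  # minus-strand positions are mirrored: genomic g maps to end - 1 - g
  hbm <- data.frame(start = 8L, end = 14L, strand = "-")
  ovm <- find_hit_overlaps(ha, hbm)
  # genomic {8, 9}; motif B width 6, minus strand: 13-8=5, 13-9=4 -> 1-based {5, 6}
  expect_equal(ovm[[1]]$positions_b, c(5L, 6L))
  expect_equal(ovm[[1]]$positions_a, c(9L, 10L))
})

test_that("overlap removal depends on IC only, with a strict cutoff", {
  # motif A is fully uniform (IC 0 everywhere); B has a deterministic core
  uni <- rep(.25, 4)
  det <- c(1, 0, 0, 0)
  mA <- freq_motif("A", rep(list(uni), 6))
  mB <- freq_motif("B", list(det, det, det, uni, uni, uni))
  L <- 60

  mk <- function(sa, sb, stb = "+") {
    list(a = data.frame(start = sa, end = sa + 6L, strand = "+", score = 0,
                        pvalue = 1e-4),
         b = data.frame(start = sb, end = sb + 6L, strand = stb, score = 0,
                        pvalue = 1e-4))
  }

  # overlap {4,5}: A positions {5,6} (IC 0); B positions {1,2} (IC 4)
  h <- mk(0L, 4L)
  r <- resolve_overlaps(h$a, h$b, mA, mB, L)
  expect_equal(r$overlaps[[1]]$ic_a, 0)
  expect_equal(r$overlaps[[1]]$ic_b, 4)
  expect_length(r$removed_a, 0L)        # IC exactly 4 is retained
  expect_length(r$removed_b, 0L)
  expect_equal(r$rescored_a$binom_score,
               promoter_score(h$a, L, 6)$binom_score)

  # overlap {3..5}: B positions {1,2,3} are the IC-6 core -> both removed
  h2 <- mk(0L, 3L)
  r2 <- resolve_overlaps(h2$a, h2$b, mA, mB, L)
  expect_equal(r2$overlaps[[1]]$ic_a, 0)
  expect_equal(r2$overlaps[[1]]$ic_b, 6)
  expect_equal(r2$removed_a, 1L)
  expect_equal(r2$removed_b, 1L)
  expect_equal(r2$rescored_a$binom_score, 1)  # no hits left
  expect_equal(r2$rescored_a$k_star, 0L)
})

test_that("equal-IC overlaps of different lengths decide identically", {
  # IC 4.5 packed into 3 positions vs spread over 5 positions
  sharp <- c(0.9, 0.1 / 3, 0.1 / 3, 0.1 / 3)
  ic1 <- 2 + sum(sharp * log2(sharp))
  # choose q so that 5 q-columns give the same total IC as 3 sharp columns
  f <- function(q) {
    v <- c(q, (1 - q) / 3, (1 - q) / 3, (1 - q) / 3)
    5 * (2 + sum(v * log2(v))) - 3 * ic1
  }
  q <- stats::uniroot(f, c(0.3, 0.9), tol = 1e-12)$root
  soft <- c(q, (1 - q) / 3, (1 - q) / 3, (1 - q) / 3)

  mshort <- freq_motif("S", rep(list(sharp), 3))
  mlong <- freq_motif("L", rep(list(soft), 5))
  uni <- freq_motif("U", rep(list(rep(.25, 4)), 8))

  expect_equal(interval_ic(mshort, 1:3), interval_ic(mlong, 1:5),
               tolerance = 1e-9)

  hit <- function(s, w) data.frame(start = s, end = s + w, strand = "+",
                                   score = 0, pvalue = 1e-4)
  r_short <- resolve_overlaps(hit(0L, 8L), hit(5L, 3L), uni, mshort, 60)
  r_long <- resolve_overlaps(hit(0L, 8L), hit(3L, 5L), uni, mlong, 60)
  expect_equal(length(r_short$removed_b) > 0, length(r_long$removed_b) > 0)
  # both totals exceed 4 bits here, so both overlaps are removed
  expect_equal(r_short$removed_b, 1L)
  expect_equal(r_long$removed_b, 1L)
})

test_that("colocalization requires joint membership and surviving scores", {
  fx <- small_planted_universe()
  idx <- build_index(list(fx$motif_a, fx$motif_b), fx$universe, n = 35)
  ia <- idx[[1]]; ib <- idx[[2]]
  shared <- intersect(ia$scores$gene_id, ib$scores$gene_id)
  expect_gt(length(shared), 5)
  g <- shared[1]
  rec <- colocalization_test(g, ia, ib,
                             Biostrings::width(fx$universe[g]))
  expect_true(rec$colocalized)  # planted 20 bp apart: no overlap, passes
  expect_equal(rec$rescored_a, ia$scores$binom_score[ia$scores$gene_id == g])

  only_a <- setdiff(ia$scores$gene_id, ib$scores$gene_id)[1]
  expect_null(colocalization_test(only_a, ia, ib, 300))
})

test_that("colocalization decisions and p-values are symmetric in pair order", {
  fx <- small_planted_universe()
  idx <- build_index(list(fx$motif_a, fx$motif_b), fx$universe, n = 35)
  lens <- setNames(Biostrings::width(fx$universe), names(fx$universe))
  ab <- pair_positive_genes(idx[[1]], idx[[2]], lens)
  ba <- pair_positive_genes(idx[[2]], idx[[1]], lens)
  expect_identical(ab, ba)
  expect_gte(length(ab), 1)

  withr::local_seed(77)
  gs <- sample(names(fx$universe), 40)
  r1 <- test_gene_set(idx, gs, fx$universe)
  idx_rev <- idx[c(2, 1)]
  r2 <- test_gene_set(idx_rev, gs, fx$universe)
  expect_equal(r1$raw_p, r2$raw_p)
  expect_equal(r1$pair_positive_universe, r2$pair_positive_universe)
})

test_that("hypergeometric pair test matches enumeration and closed forms", {
  expect_equal(hypergeom_pair_test(5, 20, 5, 5), 1 / choose(20, 5))
  expect_equal(hypergeom_pair_test(4, 10, 5, 0), 1)
  expect_equal(hypergeom_pair_test(4, 10, 5, 2),
               hyper_enum(4, 10, 5, 2), tolerance = 1e-12)
  expect_error(hypergeom_pair_test(6, 5, 3, 2), "inconsistent")
  expect_error(hypergeom_pair_test(3, 10, 5, 4), "inconsistent")

  # monotonicity: more observed successes never increases the p-value
  p <- vapply(0:5, function(o) hypergeom_pair_test(8, 30, 5, o), numeric(1))
  expect_true(all(diff(p) <= 0))
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.001, 50), 0.05)
  expect_equal(bonferroni_adjust(0.5, 10), 1)
  expect_equal(bonferroni_adjust(0.123, 1), 0.123)
  expect_error(bonferroni_adjust(0.1, 0), "m must be")
})

test_that("pair matrices are symmetric with NA for untested cells", {
  res <- data.frame(motif_a = c("m1", "m1", "m2"),
                    motif_b = c("m2", "m3", "m3"),
                    adj_p = c(1e-4, 1, 1))
  mat <- pair_matrix(res, c("m1", "m2", "m3"))
  expect_equal(mat["m1", "m2"], 4)
  expect_equal(mat["m2", "m1"], 4)
  expect_equal(mat["m2", "m3"], 0)
  expect_true(is.na(mat["m1", "m1"]))
  expect_error(pair_matrix(res, c("m1", "m2")), "absent")

  path <- withr::local_tempfile(fileext = ".tsv")
  write_pair_matrix(mat, path)
  back <- read_pair_matrix(path)
  expect_equal(back, mat, tolerance = 1e-6)
})
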