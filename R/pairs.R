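#' Find overlaps between the retained hits of two motifs on one promoter
#'
#' For every intersecting pair of hit intervals, records the genomic
#' intersection and the motif-local position indices it covers in each
#' motif, respecting hit strand (a minus-strand hit maps genomic positions
#' to mirrored matrix positions).
#'
#' @param hits_a,hits_b Hit data.frames (columns `start`, `end`, `strand`)
#'   for motifs A and B on the same promoter.
#' @return A list of overlap records, each a list with `ia`, `ib` (row
#'   indices into `hits_a`/`hits_b`), `ostart`, `oend` (genomic
#'   intersection, 0-based half-open), `positions_a`, `positions_b`
#'   (1-based motif position indices).
#' @export
find_hit_overlaps <- function(hits_a, hits_b) {
  out <- list()
  if (!nrow(hits_a) || !nrow(hits_b)) return(out)
  for (i in seq_len(nrow(hits_a))) {
    for (j in seq_len(nrow(hits_b))) {
      os <- max(hits_a$start[i], hits_b$start[j])
      oe <- min(hits_a$end[i], hits_b$end[j])
      if (os >= oe) next
      g <- os:(oe - 1L)
      pos_a <- if (hits_a$strand[i] == "+") g - hits_a$start[i]
               else (hits_a$end[i] - 1L) - g
      pos_b <- if (hits_b$strand[j] == "+") g - hits_b$start[j]
               else (hits_b$end[j] - 1L) - g
      out[[length(out) + 1L]] <-
        list(ia = i, ib = j, ostart = os, oend = oe,
             positions_a = sort(pos_a) + 1L,
             positions_b = sort(pos_b) + 1L)
    }
  }
  out
}

#' Resolve overlapping hits of a motif pair by information content
#'
#' For each overlap, the total information content of the overlapped
#' positions is computed in each motif. If it exceeds `ic_cutoff` bits in
#' either motif — meaning highly conserved bases fall inside the overlap —
#' both participating hits are removed. The decision depends only on the
#' IC, never directly on the overlap length. Binomial scores are then
#' recomputed from the remaining hits (k re-optimized over what remains,
#' trial count unchanged).
#'
#' @param hits_a,hits_b Retained hit data.frames for the two motifs.
#' @param motif_a,motif_b The corresponding [motif()] objects.
#' @param promoter_length Promoter length in bp.
#' @param ic_cutoff Removal threshold in bits (default 4); an overlap with
#'   IC exactly equal to the cutoff is retained.
#' @param strands,trials_a,trials_b Scoring geometry, as used when the
#'   index was built.
#' @return A list with `hits_a`, `hits_b` (retained hits), `removed_a`,
#'   `removed_b` (row indices removed), `rescored_a`, `rescored_b`
#'   ([promoter_score()] objects) and `overlaps` (the overlap records with
#'   `ic_a`, `ic_b` filled in).
#' @export
resolve_overlaps <- function(hits_a, hits_b, motif_a, motif_b,
                             promoter_length, ic_cutoff = 4,
                             strands = "both", trials_a = NULL,
                             trials_b = NULL) {
  recs <- find_hit_overlaps(hits_a, hits_b)
  drop_a <- logical(nrow(hits_a))
  drop_b <- logical(nrow(hits_b))
  for (k in seq_along(recs)) {
    recs[[k]]$ic_a <- interval_ic(motif_a, recs[[k]]$positions_a)
    recs[[k]]$ic_b <- interval_ic(motif_b, recs[[k]]$positions_b)
    if (recs[[k]]$ic_a > ic_cutoff || recs[[k]]$ic_b > ic_cutoff) {
      drop_a[recs[[k]]$ia] <- TRUE
      drop_b[recs[[k]]$ib] <- TRUE
      recs[[k]]$removed <- TRUE
    } else {
      recs[[k]]$removed <- FALSE
    }
  }
  ra <- hits_a[!drop_a, , drop = FALSE]
  rb <- hits_b[!drop_b, , drop = FALSE]
  list(hits_a = ra, hits_b = rb,
       removed_a = which(drop_a), removed_b = which(drop_b),
       rescored_a = promoter_score(ra, promoter_length, motif_a$width,
                                   strands = strands, trials = trials_a),
       rescored_b = promoter_score(rb, promoter_length, motif_b$width,
                                   strands = strands, trials = trials_b),
       overlaps = recs)
}

#' Decide colocalization of a motif pair on one promoter
#'
#' A promoter must be a member of both motif indexes. Overlapping hits are
#' resolved by [resolve_overlaps()]; the pair is colocalized when both
#' recomputed binomial scores are still at or below their motifs' recorded
#' index thresholds. A motif left without hits rescores to 1 and cannot
#' pass.
#'
#' @param gene_id A promoter/gene identifier.
#' @param index_a,index_b `motif_index` objects from [index_motif()].
#' @param promoter_length Length of this promoter in bp.
#' @param ic_cutoff Overlap removal threshold in bits (default 4).
#' @return A list with `gene_id`, `motif_a`, `motif_b`, `removed_a`,
#'   `removed_b`, `rescored_a`, `rescored_b` (binomial scores) and
#'   `colocalized`; or `NULL` when the gene is not a member of both
#'   indexes.
#' @export
colocalization_test <- function(gene_id, index_a, index_b, promoter_length,
                                ic_cutoff = 4) {
  ha <- index_a$hits[[gene_id]]
  hb <- index_b$hits[[gene_id]]
  if (is.null(ha) || is.null(hb)) return(NULL)
  res <- resolve_overlaps(ha, hb, index_a$motif, index_b$motif,
                          promoter_length, ic_cutoff = ic_cutoff,
                          strands = index_a$strands,
                          trials_a = index_a$trials,
                          trials_b = index_b$trials)
  sa <- res$rescored_a$binom_score
  sb <- res$rescored_b$binom_score
  coloc <- res$rescored_a$k_star > 0L && res$rescored_b$k_star > 0L &&
    sa <= index_a$threshold && sb <= index_b$threshold
  list(gene_id = gene_id, motif_a = index_a$motif$id,
       motif_b = index_b$motif$id,
       removed_a = res$removed_a, removed_b = res$removed_b,
       rescored_a = sa, rescored_b = sb, colocalized = coloc)
}

#' Promoters on which a motif pair colocalizes
#'
#' Intersects the two index memberships and applies
#' [colocalization_test()] to each shared promoter. Promoters whose hits do
#' not intersect keep their original (passing) scores and are colocalized
#' without rescoring.
#'
#' @param index_a,index_b `motif_index` objects.
#' @param promoter_lengths Named integer vector of promoter lengths
#'   (names are gene ids).
#' @param ic_cutoff Overlap removal threshold in bits (default 4).
#' @return Character vector of gene ids, sorted (C locale).
#' @export
pair_positive_genes <- function(index_a, index_b, promoter_lengths,
                                ic_cutoff = 4) {
  shared <- intersect(index_a$scores$gene_id, index_b$scores$gene_id)
  if (!length(shared)) return(character(0))
  pos <- vapply(shared, function(g) {
    ha <- index_a$hits[[g]]
    hb <- index_b$hits[[g]]
    if (is.null(ha) || !nrow(ha) || is.null(hb) || !nrow(hb)) return(FALSE)
    # fast path: no intersecting intervals, scores unchanged, both pass
    if (all(outer(ha$start, hb$end, ">=") | outer(ha$end, hb$start, "<=")))
      return(TRUE)
    colocalization_test(g, index_a, index_b, promoter_lengths[[g]],
                        ic_cutoff = ic_cutoff)$colocalized
  }, logical(1))
  sort(shared[pos], method = "radix")
}

#' Upper-tail hypergeometric test for paired-motif enrichment
#'
#' Probability of drawing at least `observed` pair-positive promoters when
#' `set_size` promoters are drawn without replacement from a universe of
#' `universe_size` containing `positive_universe` pair-positive ones.
#'
#' @param positive_universe Number of pair-positive promoters in the
#'   universe.
#' @param universe_size Size of the promoter universe.
#' @param set_size Number of genes drawn (the gene set, after dropping ids
#'   absent from the universe).
#' @param observed Pair-positive promoters observed in the gene set.
#' @return The raw upper-tail p-value; 1 when `observed` is 0.
#' @examples
#' hypergeom_pair_test(5, 20, 5, 5)  # 1 / choose(20, 5)
#' @export
hypergeom_pair_test <- function(positive_universe, universe_size, set_size,
                                observed) {
  if (any(c(positive_universe, universe_size, set_size, observed) < 0) ||
      positive_universe > universe_size || set_size > universe_size ||
      observed > min(set_size, positive_universe))
    stop("inconsistent hypergeometric counts")
  if (observed == 0) return(1)
  phyper(observed - 1, positive_universe,
         universe_size - positive_universe, set_size, lower.tail = FALSE)
}

#' Bonferroni adjustment over the motif pairs tested for one gene set
#'
#' @param raw_p Raw p-value(s).
#' @param m Number of motif pairs tested for this gene set.
#' @return `min(1, raw_p * m)`, vectorized over `raw_p`.
#' @export
bonferroni_adjust <- function(raw_p, m) {
  if (m < 1) stop("m must be >= 1")
  pmin(1, raw_p * m)
}

#' Test a gene set for enrichment of every motif pair
#'
#' For each unordered pair of distinct motifs, counts the pair-positive
#' promoters (colocalized pair, [pair_positive_genes()]) in the universe
#' and in the gene set, computes the upper-tail hypergeometric p-value and
#' applies a Bonferroni correction over the number of pairs tested for
#' this gene set. Gene ids absent from the promoter universe are dropped
#' from the set (with a message).
#'
#' @param index Named list of `motif_index` objects ([build_index()]), all
#'   built over the same universe.
#' @param gene_set A [gene_set()] or character vector of gene ids.
#' @param promoters The promoter universe the index was built from (used
#'   for promoter lengths and the universe gene list), or a named integer
#'   vector of promoter lengths.
#' @param ic_cutoff Overlap removal threshold in bits (default 4).
#' @param alpha Significance level on the adjusted p-value (default 0.05).
#' @param include_self Also test each motif paired with itself
#'   (default `FALSE`).
#' @param positives Optional precomputed result of
#'   [all_pair_positives()], reused across gene sets.
#' @return A data.frame sorted by adjusted p-value with columns `motif_a`,
#'   `motif_b`, `universe_size`, `pair_positive_universe`, `set_size`,
#'   `pair_positive_in_set`, `raw_p`, `adj_p`, `significant`.
#' @export
test_gene_set <- function(index, gene_set, promoters, ic_cutoff = 4,
                          alpha = 0.05, include_self = FALSE,
                          positives = NULL) {
  lens <- promoter_lengths(promoters)
  if (is.null(positives))
    positives <- all_pair_positives(index, lens, ic_cutoff = ic_cutoff,
                                    include_self = include_self)
  ids <- if (inherits(gene_set, "gene_set")) gene_set$ids
         else as.character(gene_set)
  ids <- unique(ids)
  known <- ids %in% names(lens)
  if (any(!known))
    message(sum(!known), " gene id(s) absent from the promoter universe ",
            "dropped from the set")
  ids <- ids[known]
  U <- length(lens)
  m <- length(positives)
  res <- lapply(positives, function(pp) {
    obs <- sum(ids %in% pp$genes)
    raw <- hypergeom_pair_test(length(pp$genes), U, length(ids), obs)
    data.frame(motif_a = pp$motif_a, motif_b = pp$motif_b,
               universe_size = U,
               pair_positive_universe = length(pp$genes),
               set_size = length(ids), pair_positive_in_set = obs,
               raw_p = raw, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  rownames(res) <- NULL
  res$adj_p <- bonferroni_adjust(res$raw_p, m)
  res$significant <- res$adj_p < alpha
  res[order(res$adj_p, res$raw_p, res$motif_a, res$motif_b,
            method = "radix"), , drop = FALSE]
}

#' Colocalized promoter lists for every motif pair
#'
#' The expensive, gene-set independent half of the pair test: for each
#' unordered motif pair, the promoters on which the pair colocalizes.
#' Compute once per index and reuse across gene sets.
#'
#' @param index Named list of `motif_index` objects.
#' @param promoter_lengths Named integer vector of promoter lengths, or
#'   the promoter universe itself.
#' @param ic_cutoff Overlap removal threshold in bits (default 4).
#' @param include_self Include homotypic pairs (default `FALSE`).
#' @return A list of records `list(motif_a, motif_b, genes)`, pairs in
#'   lexicographic motif-id order.
#' @export
all_pair_positives <- function(index, promoter_lengths, ic_cutoff = 4,
                               include_self = FALSE) {
  lens <- promoter_lengths(promoter_lengths)
  ids <- sort(names(index), method = "radix")
  out <- list()
  for (i in seq_along(ids)) {
    jmin <- if (include_self) i else i + 1L
    if (jmin > length(ids)) next
    for (j in jmin:length(ids)) {
      a <- ids[i]; b <- ids[j]
      out[[length(out) + 1L]] <- list(
        motif_a = a, motif_b = b,
        genes = pair_positive_genes(index[[a]], index[[b]], lens,
                                    ic_cutoff = ic_cutoff))
    }
  }
  out
}

promoter_lengths <- function(promoters) {
  if (inherits(promoters, "XStringSet"))
    setNames(Biostrings::width(promoters), names(promoters))
  else if (is.numeric(promoters) && !is.null(names(promoters)))
    promoters
  else stop("promoters must be a named DNAStringSet or named lengths")
}

#' Assemble a motif-pair significance matrix
#'
#' Square symmetric matrix of `-log10(adjusted p)` over a motif order, the
#' values behind pair-enrichment heatmaps. Untested cells (including the
#' diagonal when homotypic pairs were not tested) are `NA`.
#'
#' @param results A result data.frame from [test_gene_set()].
#' @param motif_order Character vector of motif ids defining row/column
#'   order; every motif appearing in `results` must be present.
#' @return A numeric matrix with dimnames `motif_order`.
#' @export
pair_matrix <- function(results, motif_order) {
  missing <- setdiff(unique(c(results$motif_a, results$motif_b)),
                     motif_order)
  if (length(missing))
    stop("motif(s) in results absent from motif_order: ",
         paste(missing, collapse = ", "))
  mat <- matrix(NA_real_, length(motif_order), length(motif_order),
                dimnames = list(motif_order, motif_order))
  v <- -log10(pmax(results$adj_p, 1e-300))
  for (r in seq_len(nrow(results))) {
    mat[results$motif_a[r], results$motif_b[r]] <- v[r]
    mat[results$motif_b[r], results$motif_a[r]] <- v[r]
  }
  mat
}

#' Write / read a pair matrix as TSV
#'
#' @param mat A matrix from [pair_matrix()].
#' @param path Output path.
#' @return `path` invisibly; `read_pair_matrix()` returns the matrix.
#' @export
write_pair_matrix <- function(mat, path) {
  df <- data.frame(motif = rownames(mat),
                   apply(mat, 2L, function(x) sprintf("%.6f", x)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  df[df == "NA"] <- "NA"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_matrix
#' @export
read_pair_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  mode(mat) <- "numeric"
  rownames(mat) <- df$motif
  mat
}
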