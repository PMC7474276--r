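#' Exact null distribution of motif log-odds scores
#'
#' Builds the discrete distribution of a motif's log-odds match score under
#' the 0-order background by dynamic-programming convolution of the
#' per-position score distributions, exactly as FIMO-style scanners derive
#' their hit p-values. Scores are discretized to an integer grid of bin
#' width `granularity` (log2-odds units); the window scoring code uses the
#' same integer grid, so p-value lookup is exact on the grid rather than
#' subject to an extra rounding error.
#'
#' A small additive pseudocount is applied to the matrix frequencies before
#' taking log-odds (scanning only; information content never uses a
#' pseudocount).
#'
#' @param m A [motif()].
#' @param bg A [background()].
#' @param granularity Score bin width in log2-odds units (default 1e-3).
#' @param pseudocount Additive pseudocount on matrix frequencies
#'   (default 0.001); each row is renormalized after addition.
#' @return An object of class `"score_dist"` with elements:
#'   `sint` (width x 4 integer score matrix, forward strand),
#'   `sint_rc` (same for the reverse-complement motif),
#'   `offset` (integer score of the first bin),
#'   `prob` (bin probabilities), `tail` (upper-tail function
#'   `Q[i] = P(score >= offset + i - 1)`, non-increasing, `Q[1] = 1`),
#'   plus `granularity` and `pseudocount`.
#' @examples
#' m <- motif("ex", rbind(c(1, 0, 0, 0)))
#' d <- score_distribution(m, background())
#' # P(score >= score of "A") = 0.25 up to the pseudocount
#' @export
score_distribution <- function(m, bg = background(), granularity = 1e-3,
                               pseudocount = 0.001) {
  stopifnot(inherits(m, "motif"), inherits(bg, "background"),
            granularity > 0, pseudocount >= 0)
  f <- m$mat + pseudocount
  f <- f / rowSums(f)
  lod <- log2(sweep(f, 2L, as.numeric(bg), "/"))
  # a zero frequency with zero pseudocount can never match: NA score,
  # carrying p-value 1; such windows are excluded from the finite tail
  si <- round(lod / granularity)
  si[!is.finite(si)] <- NA
  sint <- matrix(as.integer(si), nrow = m$width)
  w <- m$width

  prob <- 1
  curlo <- 0L
  for (j in seq_len(w)) {
    mn <- min(sint[j, ], na.rm = TRUE); mx <- max(sint[j, ], na.rm = TRUE)
    new <- numeric(length(prob) + mx - mn)
    for (b in 1:4) {
      if (is.na(sint[j, b])) next
      off <- sint[j, b] - mn
      idx <- seq_along(prob) + off
      new[idx] <- new[idx] + prob * bg[[b]]
    }
    prob <- new
    curlo <- curlo + mn
  }
  lo <- curlo
  tail <- rev(cumsum(rev(prob)))
  tail <- pmin(pmax(tail, 0), 1)
  if (!anyNA(sint)) tail[1L] <- 1
  sint_rc <- sint[rev(seq_len(w)), COMP, drop = FALSE]
  structure(list(motif_id = m$id, sint = sint, sint_rc = sint_rc,
                 offset = lo, prob = prob, tail = tail,
                 granularity = granularity, pseudocount = pseudocount),
            class = "score_dist")
}

# Upper-tail p-value for integer grid scores (vectorized; NA, from N
# windows or zero-frequency bases, gives p-value 1).
score_pvalue <- function(dist, s) {
  idx <- s - dist$offset + 1L
  na <- is.na(idx)
  idx[na] <- 1L
  idx <- pmin(pmax(idx, 1L), length(dist$tail))
  p <- dist$tail[idx]
  p[na] <- 1
  p
}

#' Scan one promoter for occurrences of a motif
#'
#' Scores every window on both strands (minus strand uses the
#' reverse-complement matrix at the same forward coordinates) and assigns
#' each candidate the exact upper-tail p-value of its score under the
#' background null. Windows containing `N` get p-value 1. No p-value
#' threshold is applied; stringency comes from downstream top-k selection.
#'
#' @param m A [motif()].
#' @param promoter A DNA sequence: character string, `DNAString`, or a
#'   length-1 `DNAStringSet`.
#' @param bg A [background()]; ignored when `dist` is supplied.
#' @param dist Optional precomputed [score_distribution()] for `m`.
#' @param strands `"both"` (default) or `"+"`.
#' @return A data.frame of hits sorted by ascending p-value, then start,
#'   then strand (`+` first), with columns `start` (0-based), `end`
#'   (half-open), `strand`, `score` (log2-odds), `pvalue`. Zero rows when
#'   the promoter is shorter than the motif.
#' @export
scan_promoter <- function(m, promoter, bg = background(), dist = NULL,
                          strands = c("both", "+")) {
  strands <- match.arg(strands)
  if (is.null(dist)) dist <- score_distribution(m, bg)
  if (inherits(promoter, "DNAStringSet")) promoter <- promoter[[1L]]
  promoter <- toupper(as.character(promoter))
  code <- encode_promoters(Biostrings::DNAStringSet(promoter))[[1L]]
  sc <- window_scores(code, dist$sint, dist$sint_rc)
  nw <- ncol(sc)
  if (nw == 0L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      pvalue = numeric()))
  both <- strands == "both"
  s <- if (both) c(sc[1L, ], sc[2L, ]) else sc[1L, ]
  start <- if (both) c(seq_len(nw), seq_len(nw)) - 1L else seq_len(nw) - 1L
  strand <- if (both) rep(c("+", "-"), each = nw) else rep("+", nw)
  p <- score_pvalue(dist, s)
  o <- order(p, start, strand, method = "radix")
  data.frame(start = start[o], end = start[o] + m$width,
             strand = strand[o],
             score = ifelse(is.na(s[o]), NA_real_,
                            s[o] * dist$granularity),
             pvalue = p[o])
}

#' Select the top non-overlapping hits of a motif on a promoter
#'
#' Greedy selection in ascending p-value order (ties: start, then strand,
#' `+` first): a hit is kept unless its interval intersects an already
#' selected hit, irrespective of strand; selection stops after `max_k`
#' hits. This realizes the "top k non-overlapping hits" used by the
#' binomial promoter score.
#'
#' @param hits A hit data.frame from [scan_promoter()] (any row order).
#' @param max_k Maximum number of hits to keep (default 5).
#' @return The selected rows, in selection (ascending p-value) order.
#' @export
top_nonoverlapping <- function(hits, max_k = 5) {
  if (!nrow(hits)) return(hits)
  o <- order(hits$pvalue, hits$start, hits$strand, method = "radix")
  hits <- hits[o, , drop = FALSE]
  sel_start <- integer(0)
  sel_end <- integer(0)
  keep <- integer(0)
  for (i in seq_len(nrow(hits))) {
    if (length(keep) >= max_k) break
    s <- hits$start[i]; e <- hits$end[i]
    if (!length(keep) || all(s >= sel_end | e <= sel_start)) {
      keep <- c(keep, i)
      sel_start <- c(sel_start, s)
      sel_end <- c(sel_end, e)
    }
  }
  hits[keep, , drop = FALSE]
}

#' Binomial promoter score from selected hits
#'
#' For each k from 1 to the number of selected hits, takes the geometric
#' mean p of the k best hit p-values and computes the binomial probability
#' of observing at least k hits of probability p among `trials` candidate
#' placements; the k minimizing this probability (smallest k on ties) is
#' the estimated number of binding sites and the minimized probability is
#' the promoter's motif score. No hits gives k = 0 and score 1.
#'
#' By default `trials` is the number of candidate placements actually
#' scanned, `(L - w + 1)` per strand; a fixed value (e.g. 1000 for a
#' literal 1 kb reading) may be supplied instead.
#'
#' @param selected Hits from [top_nonoverlapping()] (or any data.frame with
#'   a `pvalue` column, ascending).
#' @param promoter_length Promoter length L in bp.
#' @param motif_width Motif width w in bp.
#' @param strands `"both"` (default) or `"+"`, determining the trial count.
#' @param trials Override for the number of binomial trials (default
#'   `NULL`: computed from the scan geometry).
#' @return A list of class `"promoter_score"`: `k_star`, `geom_mean_p`,
#'   `binom_score`, `trials`, `selected` (the k_star retained hits).
#' @examples
#' h <- data.frame(start = 0L, end = 5L, strand = "+", score = 1,
#'                 pvalue = 0.5)
#' promoter_score(h, promoter_length = 5, motif_width = 5,
#'                strands = "+")$binom_score  # 1 - (1 - 0.5)^1 = 0.5
#' @export
promoter_score <- function(selected, promoter_length, motif_width,
                           strands = c("both", "+"), trials = NULL) {
  strands <- match.arg(strands)
  if (is.null(trials)) {
    nw <- max(promoter_length - motif_width + 1L, 0L)
    trials <- nw * if (strands == "both") 2L else 1L
  }
  trials <- as.integer(trials)
  empty <- list(k_star = 0L, geom_mean_p = NA_real_, binom_score = 1,
                trials = trials,
                selected = selected[integer(0), , drop = FALSE])
  class(empty) <- "promoter_score"
  if (!nrow(selected) || trials < 1L) return(empty)
  p <- sort(selected$pvalue)
  K <- length(p)
  # geometric means of the k best p-values, clamped away from 0
  gm <- exp(cumsum(log(pmax(p, .Machine$double.xmin))) / seq_len(K))
  gm <- pmin(gm, 1)
  sc <- pbinom(seq_len(K) - 1L, trials, gm, lower.tail = FALSE)
  k <- which.min(sc)  # first minimum: smallest k on ties
  o <- order(selected$pvalue, selected$start, selected$strand,
             method = "radix")
  res <- list(k_star = as.integer(k), geom_mean_p = gm[k],
              binom_score = max(sc[k], .Machine$double.xmin),
              trials = trials,
              selected = selected[o[seq_len(k)], , drop = FALSE])
  class(res) <- "promoter_score"
  res
}
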