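#' Background base composition for motif scanning
#'
#' A 0-order background model: one probability per base. The background is
#' strand-symmetrized (A/T and C/G probabilities averaged) so the null score
#' distribution of a motif and of its reverse complement coincide and both
#' strands share one p-value function, as in standard motif scanners.
#'
#' @param freq Numeric vector of 4 probabilities in A, C, G, T order.
#'   Default uniform.
#' @param symmetrize Average complementary bases (default `TRUE`).
#' @return Named numeric vector of class `"background"`, summing to 1, all
#'   entries positive.
#' @examples
#' background()                      # uniform
#' background(c(0.3, 0.2, 0.2, 0.3)) # AT-rich
#' @export
background <- function(freq = rep(0.25, 4), symmetrize = TRUE) {
  freq <- as.numeric(freq)
  if (length(freq) != 4L || anyNA(freq) || any(freq <= 0))
    stop("background must be 4 positive probabilities (A, C, G, T)")
  freq <- freq / sum(freq)
  if (abs(sum(freq) - 1) > 1e-9) stop("background does not sum to 1")
  if (symmetrize) freq <- (freq + freq[COMP]) / 2
  structure(setNames(freq, DNA_BASES), class = "background")
}

#' Estimate a scanning background from promoter sequences
#'
#' Tallies base frequencies over all promoters (ignoring `N`) and returns
#' the symmetrized 0-order [background()].
#'
#' @param promoters A promoter universe (named `DNAStringSet`), e.g. from
#'   [extract_promoters()] or [read_promoters()].
#' @return A [background()].
#' @export
estimate_background <- function(promoters) {
  counts <- colSums(Biostrings::alphabetFrequency(promoters)[, DNA_BASES,
                                                             drop = FALSE])
  if (sum(counts) == 0) stop("no A/C/G/T bases in promoter set")
  background(counts / sum(counts))
}
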