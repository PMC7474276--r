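#' Generate random background promoters
#'
#' I.i.d. sequences under a 0-order base composition, named `G000001`,
#' `G000002`, ... A fixed seed makes the output fully deterministic.
#'
#' @param count Number of promoters.
#' @param length Promoter length in bp (default 1000).
#' @param composition A [background()] (default uniform). Note the
#'   constructor symmetrizes by default; pass `symmetrize = FALSE` there
#'   for skewed compositions.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A named `DNAStringSet`.
#' @export
random_promoters <- function(count, length = 1000,
                             composition = background(), seed = NULL) {
  stopifnot(count >= 1, length >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  bases <- sample(DNA_BASES, count * length, replace = TRUE,
                  prob = as.numeric(composition))
  seqs <- vapply(seq_len(count), function(i)
    paste(bases[((i - 1L) * length + 1L):(i * length)], collapse = ""),
    character(1))
  names(seqs) <- sprintf("G%06d", seq_len(count))
  Biostrings::DNAStringSet(seqs)
}

# Sample one instance sequence from a motif's letter-probability matrix.
sample_instance <- function(m, consensus_only = FALSE) {
  if (consensus_only) return(consensus(m))
  paste(vapply(seq_len(m$width), function(j)
    sample(DNA_BASES, 1L, prob = m$mat[j, ]), character(1)),
    collapse = "")
}

plant_at <- function(seqs, gene, start0, instance, strand) {
  if (strand == "-")
    instance <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(instance)))
  s <- as.character(seqs[[gene]])
  substr(s, start0 + 1L, start0 + nchar(instance)) <- instance
  seqs[gene] <- Biostrings::DNAStringSet(s)
  seqs
}

#' Plant motif instances into promoters
#'
#' Writes sampled instances of a motif (drawn from its letter-probability
#' matrix, or the consensus) into the chosen promoters at random
#' non-overlapping positions (or fixed positions), on random or fixed
#' strands. Returns the modified universe and a truth table of every
#' planted interval.
#'
#' @param promoters A named `DNAStringSet`.
#' @param m A [motif()].
#' @param genes Gene ids of the promoters to plant into.
#' @param count Instances per promoter (default 1).
#' @param strand `"random"` (default), `"+"`, or `"-"`.
#' @param at Optional 0-based start position(s), recycled per instance;
#'   `NULL` places uniformly at random without overlap among this call's
#'   instances.
#' @param consensus_only Plant the consensus sequence instead of sampling
#'   (default `FALSE`).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A list: `promoters` (modified universe) and `truth`
#'   (data.frame `gene_id`, `motif_id`, `start`, `end`, `strand`).
#' @export
plant_motif <- function(promoters, m, genes, count = 1,
                        strand = c("random", "+", "-"), at = NULL,
                        consensus_only = FALSE, seed = NULL) {
  strand <- match.arg(strand)
  if (!is.null(seed)) withr::local_seed(seed)
  stopifnot(all(genes %in% names(promoters)))
  w <- m$width
  truth <- list()
  for (g in genes) {
    L <- Biostrings::width(promoters[names(promoters) == g])
    if (L < w * count)
      stop("cannot place ", count, " instance(s) of width ", w,
           " in promoter '", g, "' of length ", L)
    if (is.null(at)) {
      starts <- integer(0)
      tries <- 0L
      while (length(starts) < count) {
        cand <- sample.int(L - w + 1L, 1L) - 1L
        if (!length(starts) ||
            all(cand + w <= starts | cand >= starts + w)) {
          starts <- c(starts, cand)
        }
        tries <- tries + 1L
        if (tries > 1000L * count)
          stop("could not place ", count, " non-overlapping instances in '",
               g, "'")
      }
    } else {
      starts <- rep_len(as.integer(at), count)
      if (any(starts < 0L | starts + w > L))
        stop("requested position out of bounds in promoter '", g, "'")
    }
    for (s0 in starts) {
      st <- if (strand == "random") sample(c("+", "-"), 1L) else strand
      inst <- sample_instance(m, consensus_only)
      promoters <- plant_at(promoters, g, s0, inst, st)
      truth[[length(truth) + 1L]] <-
        data.frame(gene_id = g, motif_id = m$id, start = s0, end = s0 + w,
                   strand = st, stringsAsFactors = FALSE)
    }
  }
  list(promoters = promoters,
       truth = if (length(truth)) do.call(rbind, truth)
               else data.frame(gene_id = character(), motif_id = character(),
                               start = integer(), end = integer(),
                               strand = character()))
}

#' Plant a motif pair with a forced genomic overlap
#'
#' Places one instance of each motif so their intervals intersect over
#' exactly `overlap` bp (motif B planted second, so its bases win inside
#' the intersection). Used to exercise the overlap-resolution rule.
#'
#' @param promoters A named `DNAStringSet`.
#' @param motif_a,motif_b [motif()] objects.
#' @param genes Gene ids to plant into.
#' @param overlap Genomic intersection length in bp (1 to
#'   `min(width_a, width_b)`).
#' @param start_a 0-based start of the A instance (recycled); `NULL` for
#'   random.
#' @param strand Strand for both instances: `"+"` (default) or `"-"`.
#' @param consensus_only Plant consensus sequences (default `FALSE`).
#' @param seed Integer seed.
#' @return As [plant_motif()]: modified universe plus truth table with one
#'   row per planted instance.
#' @export
plant_overlapping_pair <- function(promoters, motif_a, motif_b, genes,
                                   overlap, start_a = NULL, strand = "+",
                                   consensus_only = FALSE, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  wa <- motif_a$width; wb <- motif_b$width
  if (overlap < 1 || overlap > min(wa, wb))
    stop("overlap must be in 1..min(width_a, width_b)")
  truth <- list()
  for (g in genes) {
    L <- Biostrings::width(promoters[names(promoters) == g])
    span <- wa + wb - overlap
    if (span > L) stop("pair span ", span, " exceeds promoter length ", L)
    sa <- if (is.null(start_a)) sample.int(L - span + 1L, 1L) - 1L
          else as.integer(start_a)
    sb <- sa + wa - overlap
    promoters <- plant_at(promoters, g, sa,
                          sample_instance(motif_a, consensus_only), strand)
    promoters <- plant_at(promoters, g, sb,
                          sample_instance(motif_b, consensus_only), strand)
    truth[[length(truth) + 1L]] <-
      data.frame(gene_id = g, motif_id = c(motif_a$id, motif_b$id),
                 start = c(sa, sb), end = c(sa + wa, sb + wb),
                 strand = strand, stringsAsFactors = FALSE)
  }
  list(promoters = promoters, truth = do.call(rbind, truth))
}

#' Generate a random TF-like motif
#'
#' Each column has one dominant base with frequency drawn uniformly from
#' `dominance`, the rest of the mass spread evenly — the sharp, specific
#' column profile typical of plant TF binding motifs.
#'
#' @param id Motif id.
#' @param width Motif width (default 8).
#' @param dominance Range of the dominant base frequency
#'   (default `c(0.8, 0.97)`).
#' @param seed Integer seed.
#' @return A [motif()].
#' @export
random_motif <- function(id, width = 8, dominance = c(0.8, 0.97),
                         seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  mat <- t(vapply(seq_len(width), function(j) {
    d <- stats::runif(1, dominance[1L], dominance[2L])
    f <- rep((1 - d) / 3, 4)
    f[sample.int(4L, 1L)] <- d
    f
  }, numeric(4)))
  motif(id, mat)
}

#' Build an on-disk benchmark scenario with a planted motif pair
#'
#' Generates a motif library of `n_motifs` random width-`motif_width`
#' motifs, a universe of `universe_size` i.i.d. promoters, plants the first
#' two motifs together (non-overlapping, random strands, a fixed gap apart)
#' in `n_planted` promoters, and draws a ranked gene set of `set_size`
#' genes of which `n_set_positive` are planted promoters. Writes four
#' files: `motifs.meme`, `promoters.fa`, `geneset.txt` and `truth.json`
#' (the planted pair, planted gene ids, and plan parameters). Byte-stable
#' under a fixed seed.
#'
#' @param dir Output directory (created).
#' @param universe_size Number of promoters (default 5000).
#' @param promoter_length Promoter length in bp (default 1000).
#' @param n_motifs Library size (default 16; the first two are planted).
#' @param motif_width Motif width (default 8).
#' @param n_planted Promoters carrying both planted motifs (default 200).
#' @param set_size Gene set size (default 300).
#' @param n_set_positive Planted promoters inside the gene set
#'   (default 150).
#' @param gap Gap in bp between the two planted instances (default 10).
#' @param dominance Dominant-base frequency range for the generated
#'   motifs (default `c(0.85, 0.97)`, sharp and specific).
#' @param seed Integer seed (default 1).
#' @return Invisibly, a list with the file paths and the truth list.
#' @export
make_benchmark_scenario <- function(dir, universe_size = 5000,
                                    promoter_length = 1000, n_motifs = 16,
                                    motif_width = 8, n_planted = 200,
                                    set_size = 300, n_set_positive = 150,
                                    gap = 10, dominance = c(0.85, 0.97),
                                    seed = 1) {
  stopifnot(n_motifs >= 2, n_planted <= universe_size,
            n_set_positive <= min(set_size, n_planted),
            2 * motif_width + gap <= promoter_length)
  withr::local_seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  motifs <- lapply(seq_len(n_motifs), function(i)
    random_motif(sprintf("M%02d", i), width = motif_width,
                 dominance = dominance))
  universe <- random_promoters(universe_size, promoter_length)

  planted_genes <- sort(sample(names(universe), n_planted), method = "radix")
  truth_rows <- list()
  for (g in planted_genes) {
    span <- 2L * motif_width + gap
    sa <- sample.int(promoter_length - span + 1L, 1L) - 1L
    sb <- sa + motif_width + gap
    sta <- sample(c("+", "-"), 1L)
    stb <- sample(c("+", "-"), 1L)
    universe <- plant_at(universe, g, sa, sample_instance(motifs[[1L]]), sta)
    universe <- plant_at(universe, g, sb, sample_instance(motifs[[2L]]), stb)
    truth_rows[[g]] <- data.frame(
      gene_id = g, motif_id = c(motifs[[1L]]$id, motifs[[2L]]$id),
      start = c(sa, sb), end = c(sa + motif_width, sb + motif_width),
      strand = c(sta, stb), stringsAsFactors = FALSE)
  }

  in_set_pos <- sort(sample(planted_genes, n_set_positive), method = "radix")
  others <- setdiff(names(universe), planted_genes)
  in_set_neg <- sort(sample(others, set_size - n_set_positive),
                     method = "radix")
  # ranked: planted (true positive) genes first
  set_ids <- c(in_set_pos, in_set_neg)

  paths <- list(motifs = file.path(dir, "motifs.meme"),
                promoters = file.path(dir, "promoters.fa"),
                geneset = file.path(dir, "geneset.txt"),
                truth_json = file.path(dir, "truth.json"))
  write_meme(motifs, paths$motifs)
  write_promoters(universe, paths$promoters)
  write_gene_set(gene_set("benchmark", set_ids, ranked = TRUE),
                 paths$geneset)
  truth <- list(planted_pair = c(motifs[[1L]]$id, motifs[[2L]]$id),
                planted_genes = planted_genes,
                set_positive_genes = in_set_pos,
                plan = list(universe_size = universe_size,
                            promoter_length = promoter_length,
                            n_motifs = n_motifs, motif_width = motif_width,
                            n_planted = n_planted, set_size = set_size,
                            n_set_positive = n_set_positive, gap = gap,
                            dominance = dominance, seed = seed),
                instances = do.call(rbind, unname(truth_rows)))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(c(paths, list(truth = truth)))
}
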