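#' Index a motif over a promoter universe
#'
#' Scores every promoter for the motif (scan, top non-overlapping hit
#' selection, binomial score), orders promoters by increasing binomial
#' score, and keeps the top `n` as the promoters "containing" the motif.
#' The binomial score of the n-th member is recorded as the motif's
#' threshold: after overlap removal a promoter must still score at or below
#' this threshold to count as containing the motif. Using one `n` for all
#' motifs makes pair p-values comparable across motifs of different
#' specificity. Ties at the boundary are broken by gene id (C locale), so
#' the index is reproducible.
#'
#' @param m A [motif()].
#' @param promoters A named `DNAStringSet` (the promoter universe), or the
#'   result of [encode_promoters()] on one (with `widths` supplied).
#' @param n Index size (default 5000). If the universe is smaller than `n`
#'   all promoters are members.
#' @param bg A [background()].
#' @param max_k Maximum hits per promoter (default 5).
#' @param strands `"both"` or `"+"`.
#' @param trials Binomial trial override, see [promoter_score()].
#' @param granularity,pseudocount Passed to [score_distribution()].
#' @return An object of class `"motif_index"`: list with `motif` (the
#'   [motif()]), `n`, `threshold`, `universe_size`, `scores` (data.frame
#'   `gene_id`, `k_star`, `geom_mean_p`, `binom_score` for members, in
#'   rank order) and `hits` (named list, per member gene, of the retained
#'   hit data.frame).
#' @export
index_motif <- function(m, promoters, n = 5000, bg = background(),
                        max_k = 5, strands = c("both", "+"), trials = NULL,
                        granularity = 1e-3, pseudocount = 0.001) {
  strands <- match.arg(strands)
  if (n < 1) stop("index size n must be >= 1")
  stopifnot(inherits(m, "motif"))
  gene_ids <- names(promoters)
  if (is.null(gene_ids) || anyDuplicated(gene_ids))
    stop("promoter universe must carry unique gene ids as names")
  codes <- encode_promoters(promoters)
  lens <- lengths(codes)
  dist <- score_distribution(m, bg, granularity = granularity,
                             pseudocount = pseudocount)
  w <- m$width
  both <- strands == "both"
  U <- length(codes)

  k_star <- integer(U)
  gmp <- rep(NA_real_, U)
  bscore <- rep(1, U)
  hitlist <- vector("list", U)
  for (i in seq_len(U)) {
    sc <- window_scores(codes[[i]], dist$sint, dist$sint_rc)
    nw <- ncol(sc)
    if (nw == 0L) next
    s <- if (both) c(sc[1L, ], sc[2L, ]) else sc[1L, ]
    p <- score_pvalue(dist, s)
    start <- if (both) rep.int(seq_len(nw) - 1L, 2L) else seq_len(nw) - 1L
    strand <- if (both) rep(c("+", "-"), each = nw) else rep("+", nw)
    o <- order(p, start, strand, method = "radix")
    # greedy non-overlapping selection over the ordered candidates
    keep <- integer(0); ke <- integer(0); ks <- integer(0)
    for (j in o) {
      sj <- start[j]; ej <- sj + w
      if (!length(keep) || all(sj >= ke | ej <= ks)) {
        keep <- c(keep, j); ks <- c(ks, sj); ke <- c(ke, ej)
        if (length(keep) >= max_k) break
      }
    }
    sel <- data.frame(start = start[keep], end = start[keep] + w,
                      strand = strand[keep],
                      score = s[keep] * granularity,
                      pvalue = p[keep])
    ps <- promoter_score(sel, lens[i], w, strands = strands, trials = trials)
    k_star[i] <- ps$k_star
    gmp[i] <- ps$geom_mean_p
    bscore[i] <- ps$binom_score
    hitlist[[i]] <- ps$selected
  }

  o <- order(bscore, gene_ids, method = "radix")
  members <- o[seq_len(min(n, U))]
  scores <- data.frame(gene_id = gene_ids[members],
                       k_star = k_star[members],
                       geom_mean_p = gmp[members],
                       binom_score = bscore[members],
                       stringsAsFactors = FALSE)
  hits <- setNames(hitlist[members], gene_ids[members])
  structure(list(motif = m, n = as.integer(n),
                 threshold = max(scores$binom_score),
                 universe_size = U,
                 strands = strands,
                 trials = trials,
                 scores = scores, hits = hits),
            class = "motif_index")
}

#' @export
print.motif_index <- function(x, ...) {
  cat("motif_index '", x$motif$id, "': ", nrow(x$scores), " of ",
      x$universe_size, " promoters, threshold ",
      format(x$threshold, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Index every motif of a library over a promoter universe
#'
#' @inheritParams index_motif
#' @param motifs List of [motif()] objects (unique ids).
#' @param verbose Report progress to stderr.
#' @return Named list of [index_motif()] results, one per motif.
#' @export
build_index <- function(motifs, promoters, n = 5000, bg = background(),
                        max_k = 5, strands = c("both", "+"), trials = NULL,
                        granularity = 1e-3, pseudocount = 0.001,
                        verbose = FALSE) {
  strands <- match.arg(strands)
  ids <- vapply(motifs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate motif ids in library")
  res <- lapply(motifs, function(m) {
    if (verbose) message("indexing motif ", m$id)
    index_motif(m, promoters, n = n, bg = bg, max_k = max_k,
                strands = strands, trials = trials,
                granularity = granularity, pseudocount = pseudocount)
  })
  setNames(res, ids)
}

format_hits <- function(h) {
  if (is.null(h) || !nrow(h)) return("")
  paste(sprintf("%d:%d:%s:%s", h$start, h$end, h$strand,
                sprintf("%.10e", h$pvalue)), collapse = ",")
}

parse_hits <- function(s) {
  if (is.na(s) || s == "")
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), score = numeric(),
                      pvalue = numeric()))
  parts <- strsplit(strsplit(s, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(start = as.integer(vapply(parts, `[`, "", 1L)),
             end = as.integer(vapply(parts, `[`, "", 2L)),
             strand = vapply(parts, `[`, "", 3L),
             score = NA_real_,
             pvalue = as.numeric(vapply(parts, `[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Write a motif index to disk
#'
#' One TSV per motif (columns `gene_id`, `k_star`, `geom_mean_p`,
#' `binom_score`, `hits` with hits comma-joined as `start:end:strand:p`)
#' plus a JSON sidecar holding the motif id, letter-probability matrix,
#' index size, threshold and scan parameters. Output is byte-stable for
#' identical inputs.
#'
#' @param index A named list of `motif_index` objects from [build_index()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_index <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ix in index) {
    stub <- file.path(dir, paste0(ix$motif$id, ".index"))
    df <- ix$scores
    df$geom_mean_p <- sprintf("%.10e", df$geom_mean_p)
    df$binom_score <- sprintf("%.10e", df$binom_score)
    df$hits <- vapply(ix$hits[df$gene_id], format_hits, character(1))
    write.table(df, paste0(stub, ".tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    side <- list(motif_id = ix$motif$id,
                 tf_name = ix$motif$name,
                 matrix = unname(apply(ix$motif$mat, 1L, as.numeric,
                                       simplify = FALSE)),
                 n = ix$n,
                 threshold = ix$threshold,
                 universe_size = ix$universe_size,
                 strands = ix$strands,
                 trials = ix$trials)
    jsonlite::write_json(side, paste0(stub, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  invisible(dir)
}

#' Read a motif index directory written by [write_index()]
#'
#' @param dir Index directory.
#' @return Named list of `motif_index` objects.
#' @export
read_index <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "\\.index\\.json$",
                              full.names = TRUE))
  if (!length(sidecars)) stop("no index files in ", dir)
  res <- lapply(sidecars, function(js) {
    side <- jsonlite::read_json(js, simplifyVector = TRUE)
    mat <- side$matrix
    if (!is.matrix(mat)) mat <- do.call(rbind, mat)
    m <- motif(side$motif_id, mat,
               name = if (is.null(side$tf_name) || is.na(side$tf_name)) NULL
                      else side$tf_name)
    df <- read.table(sub("\\.json$", ".tsv", js), header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE,
                     colClasses = c("character", "integer", "numeric",
                                    "numeric", "character"))
    hits <- setNames(lapply(df$hits, parse_hits), df$gene_id)
    df$hits <- NULL
    structure(list(motif = m, n = as.integer(side$n),
                   threshold = as.numeric(side$threshold),
                   universe_size = as.integer(side$universe_size),
                   strands = side$strands,
                   trials = if (is.null(side$trials)) NULL
                            else as.integer(side$trials),
                   scores = df, hits = hits),
              class = "motif_index")
  })
  setNames(res, vapply(res, function(ix) ix$motif$id, character(1)))
}
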