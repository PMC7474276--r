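#' Pipeline configuration
#'
#' Collects every tunable parameter with its shipped default: 1000 bp
#' promoters, index size n = 5000, at most k = 5 hits per promoter,
#' overlap-IC cutoff 4 bits, significance at corrected P < 0.05 — plus the
#' scanning knobs (background mode, pseudocount, score granularity,
#' strands, binomial trial mode).
#'
#' @param promoter_length Promoter window length in bp (default 1000).
#' @param n Motif index size (default 5000).
#' @param max_k Maximum hits per promoter (default 5).
#' @param ic_cutoff Overlap removal threshold in bits (default 4).
#' @param alpha Significance level on adjusted p-values (default 0.05).
#' @param background `"uniform"` (default) or `"promoters"` (0-order
#'   composition estimated from the promoter set, symmetrized).
#' @param pseudocount Additive pseudocount for scanning log-odds
#'   (default 0.001; never used for information content).
#' @param granularity Score discretization in log2-odds units
#'   (default 1e-3).
#' @param strands `"both"` (default) or `"+"`.
#' @param trials `"auto"` (candidate placements actually scanned) or a
#'   fixed integer (e.g. 1000 for a literal 1 kb reading).
#' @param include_self Test homotypic pairs (default `FALSE`).
#' @param excluded_seqids Chromosomes excluded from promoter extraction.
#' @param seed Integer seed recorded in the manifest.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(promoter_length = 1000, n = 5000, max_k = 5,
                       ic_cutoff = 4, alpha = 0.05,
                       background = c("uniform", "promoters"),
                       pseudocount = 0.001, granularity = 1e-3,
                       strands = c("both", "+"),
                       trials = "auto", include_self = FALSE,
                       excluded_seqids = DEFAULT_EXCLUDED_SEQIDS,
                       seed = 1) {
  background <- match.arg(background)
  strands <- match.arg(strands)
  if (!identical(trials, "auto")) trials <- as.integer(trials)
  structure(list(promoter_length = promoter_length, n = n, max_k = max_k,
                 ic_cutoff = ic_cutoff, alpha = alpha,
                 background = background, pseudocount = pseudocount,
                 granularity = granularity, strands = strands,
                 trials = trials, include_self = include_self,
                 excluded_seqids = excluded_seqids, seed = seed),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

file_md5 <- function(paths) {
  h <- tools::md5sum(paths)
  setNames(unname(h), basename(paths))
}

#' Build and serialize the motif index for a promoter universe
#'
#' The expensive precomputation stage: parses the motif library, obtains
#' the promoter universe (pre-extracted FASTA, or genome + GFF3), builds
#' the per-motif top-n index and writes it to `out_dir` together with a
#' JSON manifest (parameter hash, input checksums, package version).
#' Reruns on identical inputs are byte-identical.
#'
#' @param config A [run_config()].
#' @param motif_file Path to a MEME minimal motif file (or `.tsv` dialect).
#' @param promoter_file Path to a promoter FASTA (mutually exclusive with
#'   `genome`/`annotation`).
#' @param genome,annotation Genome FASTA and GFF3 paths for promoter
#'   extraction.
#' @param out_dir Output directory.
#' @param verbose Report progress to stderr (default `TRUE`).
#' @return Invisibly, the index (named list of `motif_index`).
#' @export
run_index <- function(config, motif_file, promoter_file = NULL,
                      genome = NULL, annotation = NULL, out_dir,
                      verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  inputs <- c(motif_file, promoter_file, genome, annotation)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  if (is.null(promoter_file) == (is.null(genome) || is.null(annotation)))
    stop("supply either promoter_file or genome + annotation")

  motifs <- if (grepl("\\.tsv$", motif_file)) read_motif_tsv(motif_file)
            else read_meme(motif_file)
  if (verbose) message(length(motifs), " motif(s) read")
  promoters <- if (!is.null(promoter_file))
    read_promoters(promoter_file, config$promoter_length)
  else extract_promoters(genome, annotation,
                         promoter_length = config$promoter_length,
                         excluded_seqids = config$excluded_seqids)
  if (verbose) message(length(promoters), " promoter(s) in the universe")
  bg <- if (config$background == "uniform") background()
        else estimate_background(promoters)
  trials <- if (identical(config$trials, "auto")) NULL else config$trials
  index <- build_index(motifs, promoters, n = config$n, bg = bg,
                       max_k = config$max_k, strands = config$strands,
                       trials = trials, granularity = config$granularity,
                       pseudocount = config$pseudocount, verbose = verbose)
  write_index(index, out_dir)
  manifest <- list(tool = "motifpairs",
                   version = as.character(utils::packageVersion("motifpairs")),
                   config = unclass(config),
                   config_hash = config_hash(config),
                   inputs = as.list(file_md5(inputs)),
                   n_motifs = length(motifs),
                   universe_size = length(promoters),
                   background = as.numeric(bg))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  # promoter lengths are needed at the pair stage
  lens <- data.frame(gene_id = names(promoters),
                     length = Biostrings::width(promoters))
  write.table(lens, file.path(out_dir, "promoter_lengths.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(index)
}

#' Test gene sets against an index directory
#'
#' Loads an index written by [run_index()], computes the colocalized
#' promoter list of every motif pair once, then tests each gene set with
#' the Bonferroni-corrected hypergeometric test. Writes one results TSV
#' and one significance-matrix TSV per gene set, named after the set.
#'
#' @param config A [run_config()]; its hash must match the index manifest.
#' @param index_dir Directory from [run_index()].
#' @param gene_set_files Paths to gene set files ([read_gene_set()]).
#' @param out_dir Output directory.
#' @param equalize Truncate all sets to the smallest set's size before
#'   testing (default `FALSE`).
#' @param ranked Treat one-column gene set files as ranked
#'   (default `TRUE`).
#' @param verbose Log counts to stderr (default `TRUE`).
#' @return Invisibly, a named list of result data.frames.
#' @export
run_pair_tests <- function(config, index_dir, gene_set_files, out_dir,
                           equalize = FALSE, ranked = TRUE,
                           verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  manifest <- jsonlite::read_json(file.path(index_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  if (!identical(manifest$config_hash, config_hash(config)))
    stop("config does not match the index manifest (hash mismatch); ",
         "rebuild the index or reuse its config")
  index <- read_index(index_dir)
  lens_df <- read.table(file.path(index_dir, "promoter_lengths.tsv"),
                        header = TRUE, sep = "\t",
                        colClasses = c("character", "integer"))
  lens <- setNames(lens_df$length, lens_df$gene_id)

  sets <- lapply(gene_set_files, read_gene_set, ranked = ranked)
  if (equalize) sets <- equalize_gene_sets(sets)

  if (verbose) message("computing colocalized promoters for ",
                       choose(length(index), 2L) +
                         if (config$include_self) length(index) else 0L,
                       " motif pair(s)")
  positives <- all_pair_positives(index, lens,
                                  ic_cutoff = config$ic_cutoff,
                                  include_self = config$include_self)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  motif_order <- sort(names(index), method = "radix")
  out <- lapply(sets, function(gs) {
    res <- test_gene_set(index, gs, lens, ic_cutoff = config$ic_cutoff,
                         alpha = config$alpha,
                         include_self = config$include_self,
                         positives = positives)
    if (verbose)
      message("gene set '", gs$name, "': ", res$set_size[1L], " genes, ",
              nrow(res), " pairs tested, ", sum(res$significant),
              " significant at adjusted p < ", config$alpha)
    fres <- res
    fres$raw_p <- sprintf("%.10e", fres$raw_p)
    fres$adj_p <- sprintf("%.10e", fres$adj_p)
    write.table(fres, file.path(out_dir, paste0(gs$name, "_pairs.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_pair_matrix(pair_matrix(res, motif_order),
                      file.path(out_dir, paste0(gs$name, "_matrix.tsv")))
    res
  })
  invisible(setNames(out, vapply(sets, `[[`, character(1), "name")))
}
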