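#' A gene set of interest
#'
#' @param name Set name.
#' @param ids Character vector of gene ids, most significant first when
#'   ranked; duplicates are an error.
#' @param ranked Whether the order of `ids` is a significance ranking
#'   (default `FALSE`). Only ranked sets may be truncated by
#'   [equalize_gene_sets()].
#' @return An object of class `"gene_set"`.
#' @export
gene_set <- function(name, ids, ranked = FALSE) {
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("gene set '", name, "': duplicate id ", ids[duplicated(ids)][1L])
  structure(list(name = as.character(name), ids = ids,
                 ranked = isTRUE(ranked)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("gene_set '", x$name, "': ", length(x$ids), " genes",
      if (x$ranked) " (ranked)", "\n", sep = "")
  invisible(x)
}

#' Read a gene set from a plain-text file
#'
#' Accepts either one gene id per line, or a two-column TSV (id, rank
#' statistic). With a rank statistic, ids are ordered ascending by the
#' statistic (smaller = more significant, e.g. an adjusted p-value) and
#' the set is marked ranked.
#'
#' @param path File path.
#' @param name Set name; defaults to the file name without extension.
#' @param ranked For one-column input: treat line order as a significance
#'   ranking (default `FALSE`). Two-column input is always ranked.
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, name = NULL,
                          ranked = FALSE) {
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("gene set file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- unique(lengths(fields))
  if (length(ncols) != 1L)
    stop("gene set file mixes column counts: ", path)
  if (ncols == 1L)
    return(gene_set(name, trimws(lines), ranked = ranked))
  if (ncols != 2L)
    stop("gene set file must have 1 or 2 columns: ", path)
  id <- trimws(vapply(fields, `[`, "", 1L))
  stat <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  if (is.na(stat[1L]) && !anyNA(suppressWarnings(
        as.numeric(vapply(fields[-1L], `[`, "", 2L))))) {
    id <- id[-1L]                       # header line
    stat <- stat[-1L]
  }
  if (anyNA(stat))
    stop("non-numeric rank statistic in gene set file: ", path)
  o <- order(stat, id, method = "radix")
  gene_set(name, id[o], ranked = TRUE)
}

#' Write a gene set (one id per line)
#'
#' @param gs A [gene_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(gs, path) {
  writeLines(gs$ids, path)
  invisible(path)
}

#' Equalize gene set sizes for comparable p-values
#'
#' Truncates every set to the size K of the smallest set by keeping each
#' larger set's top K genes, so that enrichment p-values are comparable
#' across conditions. A larger set that carries no significance ranking
#' cannot be truncated meaningfully and is an error.
#'
#' @param sets A list of [gene_set()] objects.
#' @return The list with every set of size `K = min(sizes)`; already equal
#'   sized input is returned unchanged.
#' @export
equalize_gene_sets <- function(sets) {
  stopifnot(length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1), "gene_set")))
  sizes <- vapply(sets, function(s) length(s$ids), integer(1))
  K <- min(sizes)
  lapply(sets, function(s) {
    if (length(s$ids) == K) return(s)
    if (!s$ranked)
      stop("gene set '", s$name, "' must carry a significance ranking to ",
           "be truncated from ", length(s$ids), " to ", K, " genes")
    gene_set(s$name, s$ids[seq_len(K)], ranked = TRUE)
  })
}
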