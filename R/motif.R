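#' Construct a motif from a letter-probability matrix
#'
#' A motif is the binding preference of a transcription factor, represented as
#' a letter-probability matrix: one row per position, columns `A`, `C`, `G`,
#' `T` holding the probability of observing each base at that position.
#'
#' @param id Motif identifier (unique within a library).
#' @param mat Numeric matrix, width x 4. Columns are taken in A, C, G, T
#'   order; column names, if present, are checked. Each row must sum to 1
#'   within `tol`; rows are renormalized to sum exactly to 1.
#' @param name Optional transcription factor name.
#' @param tol Largest tolerated deviation of a row sum from 1 before the
#'   matrix is rejected.
#' @return An object of class `"motif"`: a list with elements `id`, `name`,
#'   `mat` (the renormalized matrix) and `width`.
#' @examples
#' m <- motif("ex", rbind(c(1, 0, 0, 0), c(0.25, 0.25, 0.25, 0.25)))
#' m$width
#' @export
motif <- function(id, mat, name = NULL, tol = 1e-3) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4L)
    stop("motif '", id, "': matrix must have 4 columns (A, C, G, T), got ",
         ncol(mat))
  if (nrow(mat) < 1L)
    stop("motif '", id, "': matrix must have at least one position")
  if (!is.null(colnames(mat))) {
    if (!identical(toupper(colnames(mat)), DNA_BASES))
      stop("motif '", id, "': columns must be A, C, G, T in order")
  }
  if (any(mat < 0) || any(mat > 1 + tol))
    stop("motif '", id, "': frequencies must lie in [0, 1]")
  rs <- rowSums(mat)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad))
    stop("motif '", id, "': position ", bad[1L], " frequencies sum to ",
         format(rs[bad[1L]]), ", expected 1 within ", tol)
  mat <- mat / rs
  dimnames(mat) <- list(NULL, DNA_BASES)
  structure(list(id = as.character(id),
                 name = if (is.null(name)) NA_character_ else as.character(name),
                 mat = mat,
                 width = nrow(mat)),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat("motif '", x$id, "'", sep = "")
  if (!is.na(x$name)) cat(" (", x$name, ")", sep = "")
  cat(": width ", x$width, ", consensus ", consensus(x), "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a motif (most probable base per position)
#'
#' @param m A [motif()].
#' @return A character string of length `m$width`. Ties resolve to the
#'   first base in A, C, G, T order.
#' @export
consensus <- function(m) {
  stopifnot(inherits(m, "motif"))
  paste(DNA_BASES[max.col(m$mat, ties.method = "first")], collapse = "")
}

#' Information content of one motif position
#'
#' The information content of position `i` is
#' `2 + sum_b f[b, i] * log2(f[b, i])` bits, with `0 * log2(0)` taken as 0.
#' A uniform position carries 0 bits; a fully conserved one carries 2.
#' No pseudocount is applied.
#'
#' @param m A [motif()].
#' @param i Position index, 1-based, in `1..width`.
#' @return Information content in bits, in `[0, 2]`.
#' @examples
#' m <- motif("ex", rbind(c(1, 0, 0, 0), c(0.5, 0.5, 0, 0)))
#' column_ic(m, 1)  # 2
#' column_ic(m, 2)  # 1
#' @export
column_ic <- function(m, i) {
  stopifnot(inherits(m, "motif"))
  if (length(i) != 1L || is.na(i) || i < 1L || i > m$width)
    stop("position index ", i, " out of range 1..", m$width)
  f <- m$mat[i, ]
  f <- f[f > 0]
  ic <- 2 + sum(f * log2(f))
  # guard against float dust just below 0
  max(ic, 0)
}

#' Total information content over a set of motif positions
#'
#' Sums [column_ic()] over the given positions; used to judge whether an
#' overlap between two motif hits covers conserved bases.
#'
#' @param m A [motif()].
#' @param positions Integer vector of 1-based position indices (a set;
#'   duplicates are removed). May be empty, giving 0.
#' @return Total information content in bits.
#' @export
interval_ic <- function(m, positions) {
  stopifnot(inherits(m, "motif"))
  positions <- unique(as.integer(positions))
  if (!length(positions)) return(0)
  if (any(positions < 1L | positions > m$width))
    stop("position indices out of range 1..", m$width)
  sum(vapply(positions, function(i) column_ic(m, i), numeric(1)))
}

#' Reverse complement of a motif
#'
#' Reverses the position order and swaps A with T and C with G, giving the
#' matrix that scores the minus strand at the same forward coordinates.
#' Applying it twice returns the original motif.
#'
#' @param m A [motif()].
#' @return A [motif()] with id suffixed `"_rc"` (double application restores
#'   the original id).
#' @export
motif_rc <- function(m) {
  stopifnot(inherits(m, "motif"))
  mat <- m$mat[rev(seq_len(m$width)), COMP, drop = FALSE]
  dimnames(mat) <- list(NULL, DNA_BASES)
  id <- if (endsWith(m$id, "_rc")) sub("_rc$", "", m$id) else paste0(m$id, "_rc")
  structure(list(id = id, name = m$name, mat = mat, width = m$width),
            class = "motif")
}

#' Read motifs from a MEME minimal motif file
#'
#' Parses the MEME minimal motif format: `MOTIF` lines followed by a
#' `letter-probability matrix:` block of width rows with 4 whitespace
#' separated frequencies (A, C, G, T). Header lines (`MEME version`,
#' `ALPHABET`, `strands`, `Background letter frequencies`) are skipped.
#'
#' @param path Path to the motif file.
#' @param tol Row-sum tolerance passed to [motif()].
#' @return A list of [motif()] objects, in file order. An empty file gives
#'   an empty list.
#' @seealso [write_meme()], [read_motif_tsv()]
#' @export
read_meme <- function(path, tol = 1e-3) {
  lines <- readLines(path, warn = FALSE)
  motifs <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "MOTIF")) {
      toks <- strsplit(ln, "\\s+")[[1]]
      if (length(toks) < 2L)
        stop("line ", i, ": MOTIF line without an identifier")
      id <- toks[2L]
      nm <- if (length(toks) >= 3L) toks[3L] else NULL
      # advance to the letter-probability matrix header (rows may also
      # follow the MOTIF line directly in some dialects)
      j <- i + 1L
      repeat {
        if (j > n)
          stop("motif '", id, "': no letter-probability matrix found")
        rl <- trimws(lines[j])
        if (grepl("^letter-probability matrix", rl)) {
          j <- j + 1L
          break
        }
        if (startsWith(rl, "MOTIF"))
          stop("motif '", id, "': no letter-probability matrix found")
        vals <- suppressWarnings(as.numeric(strsplit(rl, "\\s+")[[1]]))
        if (rl != "" && !anyNA(vals)) break
        j <- j + 1L
      }
      rows <- list()
      while (j <= n) {
        rl <- trimws(lines[j])
        if (rl == "" || startsWith(rl, "MOTIF") || startsWith(rl, "URL")) break
        vals <- suppressWarnings(as.numeric(strsplit(rl, "\\s+")[[1]]))
        if (anyNA(vals)) break
        if (length(vals) != 4L)
          stop("motif '", id, "', line ", j, ": expected 4 frequencies, got ",
               length(vals))
        if (any(vals < 0))
          stop("motif '", id, "', line ", j, ": negative frequency")
        rows[[length(rows) + 1L]] <- vals
        j <- j + 1L
      }
      if (!length(rows))
        stop("motif '", id, "': letter-probability matrix has no rows")
      motifs[[length(motifs) + 1L]] <-
        motif(id, do.call(rbind, rows), name = nm, tol = tol)
      i <- j
    } else {
      i <- i + 1L
    }
  }
  motifs
}

#' Write motifs to a MEME minimal motif file
#'
#' @param motifs A list of [motif()] objects.
#' @param path Output path.
#' @param background Optional [background()] written to the header.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path, background = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", ""), con)
  if (!is.null(background)) {
    writeLines(c("Background letter frequencies",
                 paste(rbind(DNA_BASES, sprintf("%.6f", background)),
                       collapse = " "), ""), con)
  }
  for (m in motifs) {
    hdr <- if (is.na(m$name)) paste("MOTIF", m$id)
           else paste("MOTIF", m$id, m$name)
    writeLines(hdr, con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d", m$width),
               con)
    writeLines(apply(m$mat, 1L, function(r)
      paste(sprintf("%.10f", r), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from a simple tabular dialect
#'
#' A 5-column TSV with header `motif_id A C G T`; consecutive rows with the
#' same `motif_id` form one matrix, positions in file order.
#'
#' @param path Path to the TSV file.
#' @param tol Row-sum tolerance passed to [motif()].
#' @return A list of [motif()] objects in order of first appearance.
#' @export
read_motif_tsv <- function(path, tol = 1e-3) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("motif_id", "A", "C", "G", "T")
  if (!all(need %in% names(df)))
    stop("motif TSV must have columns: ", paste(need, collapse = ", "))
  ids <- unique(df$motif_id)
  lapply(ids, function(id) {
    rows <- df[df$motif_id == id, c("A", "C", "G", "T"), drop = FALSE]
    motif(id, as.matrix(rows), tol = tol)
  })
}

#' Write motifs as the tabular dialect read by [read_motif_tsv()]
#'
#' @param motifs A list of [motif()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_tsv <- function(motifs, path) {
  df <- do.call(rbind, lapply(motifs, function(m)
    data.frame(motif_id = m$id, m$mat, check.names = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
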