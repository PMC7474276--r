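#' Default chromosome names excluded from the promoter universe
#'
#' Organellar (mitochondrial and plastid) sequences under their common
#' names; matching is case-insensitive and exact.
#' @export
DEFAULT_EXCLUDED_SEQIDS <- c("ChrM", "ChrC", "Mt", "Pt", "MT", "PT",
                             "mitochondria", "chloroplast", "M", "C")

#' Extract promoter sequences from a genome and its annotation
#'
#' Collects the region upstream of each gene's transcription start site:
#' for a plus-strand gene the `promoter_length` bases ending just before the
#' gene start, for a minus-strand gene the bases just after the gene end,
#' reverse complemented. Every promoter is therefore oriented 5'->3' toward
#' the TSS. Windows are truncated at chromosome boundaries; genes on
#' excluded chromosomes (organelles by default) are omitted; overlaps with
#' neighboring genes are deliberately not trimmed.
#'
#' @param genome Path to a genome FASTA file, or a named `DNAStringSet`.
#' @param annotation Path to a GFF3 file, or a `GRanges` of gene features.
#'   Only features with `type == "gene"` are used; gene identifiers come
#'   from the `ID` attribute (a `gene:` prefix is stripped), falling back
#'   to `Name`.
#' @param promoter_length Window length in bp upstream of the TSS
#'   (default 1000).
#' @param excluded_seqids Chromosome names to exclude (case-insensitive
#'   exact match); default [DEFAULT_EXCLUDED_SEQIDS].
#' @return A named `DNAStringSet` (names are gene ids, sequences
#'   uppercased) with `mcols` columns `seqnames`, `start`, `end` (0-based
#'   half-open genomic interval) and `strand`.
#' @examples
#' gen <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 500),
#'                                                collapse = "")))
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1501, 1700),
#'                              strand = "+", type = "gene", ID = "g1")
#' pu <- extract_promoters(gen, gr)
#' Biostrings::width(pu)  # 1000
#' @export
extract_promoters <- function(genome, annotation, promoter_length = 1000,
                              excluded_seqids = DEFAULT_EXCLUDED_SEQIDS) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (is.character(annotation))
    annotation <- rtracklayer::import(annotation, format = "gff3")
  genes <- annotation[S4Vectors::mcols(annotation)$type == "gene"]
  if (!length(genes)) stop("annotation contains no gene features")

  ids <- S4Vectors::mcols(genes)$ID
  if (is.null(ids)) ids <- S4Vectors::mcols(genes)$Name
  if (is.null(ids) || anyNA(ids))
    stop("gene features lack ID/Name attributes")
  ids <- sub("^gene:", "", as.character(ids))

  keep <- !(tolower(as.character(GenomicRanges::seqnames(genes))) %in%
              tolower(excluded_seqids))
  genes <- genes[keep]
  ids <- ids[keep]

  str <- as.character(GenomicRanges::strand(genes))
  if (any(str == "*")) {
    warning(sum(str == "*"), " gene feature(s) without strand skipped")
    ids <- ids[str != "*"]
    genes <- genes[str != "*"]
    str <- str[str != "*"]
  }
  if (anyDuplicated(ids))
    stop("duplicate gene identifiers in annotation: ",
         ids[duplicated(ids)][1L])

  chr <- as.character(GenomicRanges::seqnames(genes))
  missing_chr <- setdiff(unique(chr), names(genome))
  if (length(missing_chr))
    stop("annotation seqid(s) absent from genome FASTA: ",
         paste(missing_chr, collapse = ", "))
  chrlen <- setNames(Biostrings::width(genome), names(genome))[chr]

  gstart <- GenomicRanges::start(genes)  # 1-based
  gend <- GenomicRanges::end(genes)
  # 1-based closed promoter coordinates, truncated at chromosome ends
  ps <- ifelse(str == "+", pmax(1L, gstart - promoter_length), gend + 1L)
  pe <- ifelse(str == "+", gstart - 1L, pmin(chrlen, gend + promoter_length))

  ok <- pe >= ps
  if (!all(ok)) {
    ids <- ids[ok]; chr <- chr[ok]; str <- str[ok]
    ps <- ps[ok]; pe <- pe[ok]
  }
  if (!length(ids)) stop("no promoters could be extracted")

  seqs <- Biostrings::DNAStringSet(lapply(seq_along(ids), function(i)
    Biostrings::subseq(genome[[chr[i]]], ps[i], pe[i])))
  minus <- str == "-"
  if (any(minus))
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  names(seqs) <- ids
  S4Vectors::mcols(seqs) <- S4Vectors::DataFrame(
    seqnames = chr, start = ps - 1L, end = pe, strand = str)
  seqs
}

#' Load a pre-extracted promoter FASTA
#'
#' Record identifiers must be gene ids (the description after the first
#' whitespace is dropped). Sequences are uppercased. Records longer than
#' `promoter_length` are rejected: they cannot have been produced by the
#' fixed upstream-window convention this package uses.
#'
#' @param path Path to a promoter FASTA file.
#' @param promoter_length Maximum allowed record length (default 1000).
#' @return A named `DNAStringSet`.
#' @export
read_promoters <- function(path, promoter_length = 1000) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate promoter record id: ",
         names(seqs)[duplicated(names(seqs))][1L])
  too_long <- Biostrings::width(seqs) > promoter_length
  if (any(too_long))
    stop(sum(too_long), " record(s) longer than the promoter length ",
         promoter_length, " (first: ", names(seqs)[too_long][1L], ")")
  Biostrings::DNAStringSet(toupper(seqs))
}

#' Write a promoter universe to FASTA
#'
#' @param promoters A named `DNAStringSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(promoters, path) {
  Biostrings::writeXStringSet(promoters, path)
  invisible(path)
}

# Integer-encode promoter sequences for scanning: A,C,G,T -> 1..4, anything
# else (N etc.) -> 0. Returns a list of integer vectors.
encode_promoters <- function(promoters) {
  map <- integer(256)
  map[utf8ToInt("A")] <- 1L; map[utf8ToInt("C")] <- 2L
  map[utf8ToInt("G")] <- 3L; map[utf8ToInt("T")] <- 4L
  map[utf8ToInt("a")] <- 1L; map[utf8ToInt("c")] <- 2L
  map[utf8ToInt("g")] <- 3L; map[utf8ToInt("t")] <- 4L
  chr <- as.character(promoters)
  lapply(chr, function(s) map[utf8ToInt(s)])
}
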