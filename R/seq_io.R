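#' @useDynLib plvscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import tibble
#' @importFrom dplyr %>% filter mutate arrange group_by ungroup summarise
#'   bind_rows left_join select n slice_max distinct across all_of
NULL

# All in-memory coordinates in this package are 0-based half-open
# (start inclusive, end exclusive). GFF3 on disk is 1-based inclusive,
# BED is 0-based half-open; conversion happens only at the I/O boundary.

VALID_KINDS <- c("gene", "TIR", "TSD", "element", "retroelement", "marker")

#' Read a FASTA file into a contig table
#'
#' Sequences are uppercased and any character outside A/C/G/T/N is
#' replaced by N (the detection stages treat N as a universal mismatch).
#' The number of substituted characters is reported via a message.
#'
#' @param path Path to a (multi-)FASTA file.
#' @return A tibble with columns `id`, `seq`, `length`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) {
    warning("empty FASTA file: ", path)
    return(tibble::tibble(id = character(), seq = character(),
                          length = integer()))
  }
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA header(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(x))
  n_bad <- sum(vapply(seqs, function(s) {
    nchar(s) - nchar(gsub("[^ACGTN]", "", s))
  }, numeric(1)))
  if (n_bad > 0) {
    message(n_bad, " non-ACGTN character(s) replaced by N")
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  tibble::tibble(id = ids, seq = unname(seqs),
                 length = unname(nchar(seqs)))
}

#' Write a contig table as FASTA
#'
#' @param contigs Tibble with `id` and `seq` columns (as from [read_fasta()]).
#' @param path Output path.
#' @param width Line width for sequence wrapping (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path, width = 60L) {
  x <- Biostrings::DNAStringSet(stats::setNames(contigs$seq, contigs$id))
  Biostrings::writeXStringSet(x, filepath = path, width = width)
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' N maps to N; any character outside A/C/G/T/N is an error.
#'
#' @param seq Nucleotide string over A/C/G/T/N.
#' @return The reverse complement string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (grepl("[^ACGTN]", seq)) {
    stop("non-nucleotide character in sequence (expected A/C/G/T/N)")
  }
  if (nchar(seq) == 0) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Build a feature record table
#'
#' A feature record is one genomic interval (0-based half-open) with a
#' controlled-vocabulary kind and arbitrary attribute columns.
#'
#' @param contig_id,start,end Interval coordinates (0-based half-open).
#' @param kind One of gene, TIR, TSD, element, retroelement, marker.
#' @param strand "+", "-" or "." (strand-agnostic).
#' @param ... Further attribute columns (recycled as in [tibble::tibble()]).
#' @return A feature tibble.
#' @export
feature_record <- function(contig_id, start, end, kind, strand = ".", ...) {
  stopifnot(all(kind %in% VALID_KINDS))
  stopifnot(all(start >= 0), all(end > start))
  tibble::tibble(contig_id = contig_id, start = as.integer(start),
                 end = as.integer(end), strand = strand, kind = kind, ...)
}

features_to_granges <- function(records) {
  strand <- ifelse(records$strand == ".", "*", records$strand)
  gr <- GenomicRanges::GRanges(
    seqnames = records$contig_id,
    ranges = IRanges::IRanges(start = records$start + 1L, end = records$end),
    strand = strand)
  extra <- setdiff(names(records), c("contig_id", "start", "end", "strand"))
  mc <- as.data.frame(records[, extra, drop = FALSE])
  names(mc)[names(mc) == "kind"] <- "type"
  S4Vectors::mcols(gr) <- mc
  gr
}

granges_to_features <- function(gr) {
  mc <- as.data.frame(S4Vectors::mcols(gr))
  names(mc)[names(mc) == "type"] <- "kind"
  strand <- as.character(BiocGenerics::strand(gr))
  out <- tibble::tibble(
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    strand = ifelse(strand == "*", ".", strand))
  keep <- setdiff(names(mc), c("score", "phase", "source"))
  if (length(keep)) {
    extra <- mc[, keep, drop = FALSE]
    extra[] <- lapply(extra, function(x) if (is.factor(x)) as.character(x) else x)
    out <- dplyr::bind_cols(out, tibble::as_tibble(extra))
  }
  out
}

#' Write feature records to disk
#'
#' GFF3 is emitted 1-based inclusive with a `##gff-version 3` pragma,
#' BED 0-based half-open (BED6), TSV verbatim with internal 0-based
#' half-open coordinates and every attribute as a column.
#'
#' @param records Feature tibble (see [feature_record()]).
#' @param path Output path.
#' @param dialect One of "gff3", "bed", "tsv".
#' @return `path`, invisibly.
#' @export
write_features <- function(records, path, dialect = c("gff3", "bed", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    readr::write_tsv(records, path)
    return(invisible(path))
  }
  gr <- features_to_granges(records)
  if (dialect == "gff3") {
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    mc <- S4Vectors::mcols(gr)
    nm <- if ("element_id" %in% names(mc)) as.character(mc$element_id)
          else as.character(mc$type)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = nm, score = 0L)
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

#' Read feature records written by [write_features()]
#'
#' @param path Input path.
#' @param dialect One of "gff3", "bed", "tsv".
#' @return A feature tibble with 0-based half-open coordinates.
#' @export
read_features <- function(path, dialect = c("gff3", "bed", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    return(readr::read_tsv(path, show_col_types = FALSE))
  }
  gr <- rtracklayer::import(path, format = dialect)
  granges_to_features(gr)
}

# GC fraction of a sequence over non-N bases; NA when no non-N base.
gc_fraction <- function(seq) {
  if (nchar(seq) == 0) return(NA_real_)
  f <- Biostrings::letterFrequency(Biostrings::DNAString(seq),
                                   letters = c("G", "C", "A", "T"))
  tot <- sum(f)
  if (tot == 0) return(NA_real_)
  unname((f[["G"]] + f[["C"]]) / tot)
}
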