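#' Construct an ORF catalog
#'
#' The catalog of predicted protein-encoding open reading frames on assembled
#' contigs: the universe over which all nucleotide counting, taxonomic
#' stratification and functional annotation happens. Coordinates are 0-based
#' half-open internally; GFF3 I/O converts from/to the standard 1-based
#' inclusive convention.
#'
#' @param entries data.frame with columns `orf_id`, `contig_id`, `start`
#'   (0-based inclusive), `end` (exclusive), `strand` (`+`/`-`), and
#'   optionally `family` and `ko` (NA when unannotated).
#' @return A data.frame of class `orf_catalog`.
#' @export
orf_catalog <- function(entries) {
  req <- c("orf_id", "contig_id", "start", "end", "strand")
  missing <- setdiff(req, names(entries))
  if (length(missing))
    stopf("orf_catalog is missing column(s): %s", paste(missing, collapse = ", "))
  if (anyDuplicated(entries$orf_id))
    stopf("orf_id values must be unique")
  if (any(entries$start < 0) || any(entries$start >= entries$end))
    stopf("ORF intervals must satisfy 0 <= start < end")
  if (!all(entries$strand %in% c("+", "-")))
    stopf("strand must be '+' or '-'")
  if (is.null(entries$family)) entries$family <- NA_character_
  if (is.null(entries$ko)) entries$ko <- NA_character_
  rownames(entries) <- NULL
  class(entries) <- c("orf_catalog", "data.frame")
  entries
}

catalog_granges <- function(catalog) {
  GenomicRanges::GRanges(
    seqnames = catalog$contig_id,
    ranges = IRanges::IRanges(start = catalog$start + 1L, end = catalog$end),
    strand = catalog$strand,
    orf_id = catalog$orf_id)
}

#' KO map of a catalog
#'
#' @param catalog An `orf_catalog` carrying a `ko` column.
#' @return Named character vector orf_id -> KO (NA entries dropped).
#' @export
catalog_ko_map <- function(catalog) {
  keep <- !is.na(catalog$ko)
  setNames(catalog$ko[keep], catalog$orf_id[keep])
}

#' Read / write an ORF catalog as GFF3
#'
#' Features are written with type `CDS`; the `ID` attribute carries the ORF
#' id and optional `family` / `ko` attributes carry annotations. GFF3 is
#' 1-based inclusive; the in-memory catalog is 0-based half-open.
#'
#' @param catalog An `orf_catalog`.
#' @param path GFF3 file path.
#' @param contig_lengths Optional named integer vector of contig lengths,
#'   recorded as sequence-region pragmas.
#' @export
write_orf_gff3 <- function(catalog, path, contig_lengths = NULL) {
  gr <- catalog_granges(catalog)
  S4Vectors::mcols(gr) <- NULL
  S4Vectors::mcols(gr)$source <- "mtxprof"
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- catalog$orf_id
  if (!all(is.na(catalog$family))) S4Vectors::mcols(gr)$family <- catalog$family
  if (!all(is.na(catalog$ko))) S4Vectors::mcols(gr)$ko <- catalog$ko
  if (!is.null(contig_lengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(contig_lengths)
    GenomeInfoDb::seqlengths(gr) <- contig_lengths
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_orf_gff3
#' @export
read_orf_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[S4Vectors::mcols(gr)$type %in% "CDS"]
  mc <- S4Vectors::mcols(gr)
  orf_catalog(data.frame(
    orf_id = as.character(mc$ID),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    family = if (!is.null(mc$family)) as.character(mc$family) else NA_character_,
    ko = if (!is.null(mc$ko)) as.character(mc$ko) else NA_character_,
    stringsAsFactors = FALSE))
}

#' Write / read contig sequences as FASTA
#'
#' @param contigs A named [Biostrings::DNAStringSet].
#' @param path FASTA path.
#' @export
write_contigs_fasta <- function(contigs, path) {
  Biostrings::writeXStringSet(contigs, path)
  invisible(path)
}

#' @rdname write_contigs_fasta
#' @export
read_contigs_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
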