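#' Alignment records
#'
#' Read alignments are represented internally as one row per aligned block:
#' `read_id`, `contig_id`, `start` (0-based inclusive on the contig), `end`
#' (exclusive), `sample_id`. A read whose CIGAR contains several
#' reference-consuming match segments contributes several rows. Only
#' aligned (match/mismatch) bases are represented: insertions, clips and
#' reference skips consume no aligned nucleotides.
#'
#' @param df data.frame with the columns above.
#' @return data.frame of class `alignment_records`.
#' @export
alignment_records <- function(df) {
  req <- c("read_id", "contig_id", "start", "end", "sample_id")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stopf("alignment records missing column(s): %s",
          paste(missing, collapse = ", "))
  if (any(df$start < 0) || any(df$start >= df$end))
    stopf("aligned blocks must satisfy 0 <= start < end")
  rownames(df) <- NULL
  class(df) <- c("alignment_records", "data.frame")
  df
}

#' Read alignments from SAM files
#'
#' One SAM file per sample. Aligned blocks are derived from the CIGAR
#' string: only `M`, `=` and `X` operations contribute aligned nucleotides
#' (insertions, soft/hard clips and `N` skips contribute nothing; deletions
#' consume reference but align no read bases and are excluded).
#'
#' @param paths Character vector of SAM file paths.
#' @param sample_ids Sample id per file (defaults to file base names).
#' @return An `alignment_records` data.frame.
#' @export
read_alignments_sam <- function(paths, sample_ids = NULL) {
  if (is.null(sample_ids))
    sample_ids <- sub("\\.sam$", "", basename(paths))
  stopifnot(length(paths) == length(sample_ids))
  out <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    bam <- Rsamtools::asBam(paths[i],
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
    ga <- GenomicAlignments::readGAlignments(
      bam, use.names = TRUE,
      param = Rsamtools::ScanBamParam(what = character(0)))
    blocks <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      GenomicAlignments::cigar(ga),
      pos = GenomicRanges::start(ga),
      ops = c("M", "=", "X"), reduce.ranges = TRUE)
    nb <- S4Vectors::elementNROWS(blocks)
    fl <- unlist(blocks, use.names = FALSE)
    out[[i]] <- data.frame(
      read_id = rep(names(ga), nb),
      contig_id = rep(as.character(GenomicAlignments::seqnames(ga)), nb),
      start = IRanges::start(fl) - 1L,
      end = IRanges::end(fl),
      sample_id = sample_ids[i],
      stringsAsFactors = FALSE)
    unlink(c(bam, paste0(bam, ".bai")))
  }
  alignment_records(do.call(rbind, out))
}

#' Read / write the simplified TSV alignment dialect
#'
#' Columns: `read_id`, `contig_id`, `start0`, `aligned_length`, `sample_id`.
#' Each row is a single gapless aligned block.
#'
#' @param path TSV file.
#' @return An `alignment_records` data.frame.
#' @export
read_alignments_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  alignment_records(data.frame(
    read_id = as.character(df$read_id),
    contig_id = as.character(df$contig_id),
    start = as.integer(df$start0),
    end = as.integer(df$start0) + as.integer(df$aligned_length),
    sample_id = as.character(df$sample_id),
    stringsAsFactors = FALSE))
}

#' @rdname read_alignments_tsv
#' @param records An `alignment_records` data.frame.
#' @export
write_alignments_tsv <- function(records, path) {
  df <- data.frame(read_id = records$read_id,
                   contig_id = records$contig_id,
                   start0 = records$start,
                   aligned_length = records$end - records$start,
                   sample_id = records$sample_id)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write alignment records as SAM, one file per sample
#'
#' Records are written as unpaired, forward-strand alignments with an all-M
#' CIGAR (sequences and qualities are omitted with `*`), which is exactly
#' the information content of the simplified TSV dialect.
#'
#' @param records An `alignment_records` data.frame (single-block reads).
#' @param contig_lengths Named integer vector of contig lengths for the
#'   `@SQ` header lines.
#' @param dir Output directory; files are named `<sample_id>.sam`.
#' @return Named character vector of file paths, one per sample.
#' @export
write_alignments_sam <- function(records, contig_lengths, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  header <- c("@HD\tVN:1.6\tSO:unknown",
              sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                      as.integer(contig_lengths)))
  samples <- sort(unique(records$sample_id))
  paths <- setNames(file.path(dir, paste0(samples, ".sam")), samples)
  for (s in samples) {
    r <- records[records$sample_id == s, , drop = FALSE]
    lines <- sprintf("%s\t0\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*",
                     r$read_id, r$contig_id, r$start + 1L, r$end - r$start)
    writeLines(c(header, lines), paths[[s]])
  }
  paths
}

#' Count aligned nucleotides per ORF and sample
#'
#' Expression levels of individual genes are determined by enumerating the
#' total number of nucleotides aligned within each ORF interval: cell
#' `(o, s)` is the sum over reads of sample `s` of the number of aligned
#' bases overlapping ORF `o`. A read spanning two ORFs contributes its
#' overlap to each; each alignment record is counted where it is reported
#' (multi-mapped reads are not fractionally split). Alignments to contigs
#' absent from the catalog are tallied into a logged per-sample
#' `unassigned` bucket (attribute `"unassigned"`), never an error.
#'
#' @param alignments An `alignment_records` data.frame.
#' @param catalog An `orf_catalog`.
#' @param samples Optional character vector fixing the sample columns (so an
#'   all-zero sample still appears); defaults to the samples observed in
#'   `alignments`.
#' @param per_kb If `TRUE`, divide each ORF row by its length in kilobases
#'   after counting (off by default: the normalization convention is by
#'   sample total only, so longer genes legitimately carry more weight).
#' @return A raw-mode `expr_matrix` (ORF x sample) unless `per_kb`.
#' @export
count_aligned_nucleotides <- function(alignments, catalog, samples = NULL,
                                      per_kb = FALSE) {
  samples <- samples %||% sort(unique(alignments$sample_id))
  orf_ids <- catalog$orf_id
  m <- matrix(0, nrow = length(orf_ids), ncol = length(samples),
              dimnames = list(orf_ids, samples))
  unassigned <- setNames(numeric(length(samples)), samples)
  if (nrow(alignments)) {
    known <- alignments$contig_id %in% unique(catalog$contig_id)
    if (any(!known)) {
      lost <- alignments[!known, , drop = FALSE]
      tot <- tapply(lost$end - lost$start, lost$sample_id, sum)
      unassigned[names(tot)] <- unassigned[names(tot)] + tot
      mtx_log(sprintf(
        "%d aligned block(s) on contig(s) absent from the catalog -> unassigned bucket",
        nrow(lost)))
      alignments <- alignments[known, , drop = FALSE]
    }
  }
  if (nrow(alignments)) {
    blocks <- GenomicRanges::GRanges(
      seqnames = alignments$contig_id,
      ranges = IRanges::IRanges(start = alignments$start + 1L,
                                end = alignments$end))
    orfs <- catalog_granges(catalog)
    hits <- GenomicRanges::findOverlaps(blocks, orfs, ignore.strand = TRUE)
    if (length(hits)) {
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(blocks)[S4Vectors::queryHits(hits)],
        IRanges::ranges(orfs)[S4Vectors::subjectHits(hits)]))
      cell <- paste(orf_ids[S4Vectors::subjectHits(hits)],
                    alignments$sample_id[S4Vectors::queryHits(hits)],
                    sep = "\r")
      sums <- tapply(ov, cell, sum)
      idx <- do.call(rbind, strsplit(names(sums), "\r", fixed = TRUE))
      m[cbind(match(idx[, 1L], orf_ids), match(idx[, 2L], samples))] <- sums
    }
  }
  if (per_kb) {
    m <- m / ((catalog$end - catalog$start) / 1000)
    return(structure(m, mode = "normalized_per_kb", unassigned = unassigned,
                     class = c("expr_matrix", "matrix", "array")))
  }
  out <- expression_matrix(m, "raw")
  attr(out, "unassigned") <- unassigned
  out
}
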