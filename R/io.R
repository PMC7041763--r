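# Flat-file interfaces: every pipeline stage reads and writes plain TSV/FASTA/
# GTF so intermediate products stay inspectable and portable.

#' Write a count matrix as TSV
#'
#' First column `feature_id`, one column per sample. The companion reader
#' [read_count_matrix()] round-trips the result.
#'
#' @param counts integer matrix, features x samples, with dimnames.
#' @param path output file path.
#' @export
write_count_matrix <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, row.names = NULL)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' @param path TSV file with a `feature_id` column followed by sample columns.
#' @return integer matrix with feature row names and sample column names.
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "feature_id")
    stop_config("count matrix %s lacks a leading feature_id column", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$feature_id
  m
}

#' Write a sample sheet (sample_id, group) as TSV
#' @param sample_info data.frame with `sample_id` and `group` columns.
#' @param path output path.
#' @export
write_sample_sheet <- function(sample_info, path) {
  stopifnot(all(c("sample_id", "group") %in% names(sample_info)))
  write.table(sample_info, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample sheet written by [write_sample_sheet()]
#' @param path TSV with `sample_id` and `group` columns.
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop_config("sample sheet %s needs sample_id and group columns", path)
  df
}

#' Write named sequences as FASTA
#'
#' RNA sequences are written with U converted to T, the convention used for
#' sequencing-derived FASTA files.
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  dna <- Biostrings::DNAStringSet(chartr("Uu", "Tt", seqs))
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  setNames(as.character(dna), sub("\\s.*$", "", names(dna)))
}

#' Write transcript models as GTF
#'
#' Emits one `exon` feature per exon with `transcript_id`, `gene_id`, `cov`
#' (assembler coverage) and `samples` (number of samples the transcript was
#' detected in) attributes. Internal 0-based half-open exon coordinates are
#' converted to the 1-based inclusive GTF convention.
#'
#' @param transcripts transcript-model data.frame, see [transcript_models()].
#' @param path output path.
#' @export
write_transcript_gtf <- function(transcripts, path) {
  validate_transcript_models(transcripts)
  rows <- lapply(seq_len(nrow(transcripts)), function(i) {
    ex <- transcripts$exons[[i]]
    GenomicRanges::GRanges(
      seqnames = transcripts$chrom[i],
      ranges = IRanges::IRanges(start = ex[, 1L] + 1L, end = ex[, 2L]),
      strand = transcripts$strand[i],
      type = "exon",
      transcript_id = transcripts$transcript_id[i],
      gene_id = transcripts$gene_id[i],
      cov = transcripts$coverage[i],
      samples = transcripts$samples_detected[i])
  })
  gr <- suppressWarnings(do.call(c, rows))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read transcript models from GTF (+ optional FASTA)
#'
#' Inverse of [write_transcript_gtf()]. Exon rows sharing a `transcript_id`
#' are collapsed into one model; sequences are attached from `fasta` when
#' given (matched by transcript id).
#'
#' @param path GTF file with exon rows carrying `transcript_id`, `gene_id`,
#'   `cov` and `samples` attributes.
#' @param fasta optional FASTA of spliced transcript sequences.
#' @return transcript-model data.frame, see [transcript_models()].
#' @export
read_transcript_gtf <- function(path, fasta = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  seqs <- if (is.null(fasta)) NULL else read_fasta(fasta)
  split_idx <- split(seq_along(gr), gr$transcript_id)
  rows <- lapply(split_idx, function(idx) {
    g <- gr[idx]
    g <- g[order(GenomicRanges::start(g))]
    ex <- cbind(start = GenomicRanges::start(g) - 1L,
                end = GenomicRanges::end(g))
    tid <- g$transcript_id[1L]
    seq <- if (is.null(seqs)) NA_character_ else unname(seqs[tid])
    list(transcript_id = tid,
         gene_id = g$gene_id[1L],
         chrom = as.character(GenomicRanges::seqnames(g)[1L]),
         strand = as.character(GenomicRanges::strand(g)[1L]),
         coverage = as.numeric(g$cov[1L]),
         samples_detected = as.integer(g$samples[1L]),
         exons = ex, sequence = seq)
  })
  transcript_models(
    transcript_id = vapply(rows, `[[`, "", "transcript_id"),
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    coverage = vapply(rows, `[[`, 0, "coverage"),
    samples_detected = vapply(rows, `[[`, 0L, "samples_detected"),
    exons = lapply(rows, `[[`, "exons"),
    sequence = vapply(rows, `[[`, "", "sequence"))
}

#' Write a generic stage table as TSV
#' @param df data.frame.
#' @param path output path.
#' @export
write_stage_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stage table written by [write_stage_table()]
#' @param path TSV path.
#' @export
read_stage_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
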