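# Candidate lncRNA discovery: structural filtering of assembled transcript
# models, an ORF-based coding-potential screen, and biotype classification
# (lincRNA vs antisense) against annotated coding genes.

#' Construct a transcript-model table
#'
#' The container used throughout discovery: one row per assembled transcript,
#' with a list-column of exons. Exon coordinates are 0-based half-open and
#' must be sorted and non-overlapping; the spliced `sequence`, when present,
#' must match the summed exon span.
#'
#' @param transcript_id,gene_id character ids.
#' @param chrom chromosome/contig name.
#' @param strand "+" or "-".
#' @param coverage assembler-reported per-transcript read coverage.
#' @param samples_detected number of samples the transcript was assembled in.
#' @param exons list of two-column matrices (start, end), 0-based half-open.
#' @param sequence spliced transcript sequence (NA when unavailable).
#' @return data.frame of class `transcript_models`.
#' @export
transcript_models <- function(transcript_id, gene_id, chrom, strand, coverage,
                              samples_detected, exons,
                              sequence = NA_character_) {
  df <- data.frame(transcript_id = as.character(transcript_id),
                   gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   strand = as.character(strand),
                   coverage = as.numeric(coverage),
                   samples_detected = as.integer(samples_detected),
                   stringsAsFactors = FALSE)
  df$exons <- unname(exons)
  df$sequence <- as.character(sequence)
  rownames(df) <- NULL
  class(df) <- c("transcript_models", "data.frame")
  validate_transcript_models(df)
}

#' Validate a transcript-model table
#'
#' Checks exon sortedness/non-overlap and, where a sequence is present, that
#' its length equals the summed exon span. Errors name the offending
#' transcript.
#'
#' @param transcripts transcript-model data.frame.
#' @return the input, invisibly validated.
#' @export
validate_transcript_models <- function(transcripts) {
  needed <- c("transcript_id", "gene_id", "chrom", "strand", "coverage",
              "samples_detected", "exons", "sequence")
  missing <- setdiff(needed, names(transcripts))
  if (length(missing))
    stop_config("transcript models lack columns: %s",
                paste(missing, collapse = ", "))
  for (i in seq_len(nrow(transcripts))) {
    id <- transcripts$transcript_id[i]
    ex <- transcripts$exons[[i]]
    if (!is.matrix(ex) || ncol(ex) != 2L || nrow(ex) < 1L)
      stop_config("transcript %s: exons must be a matrix with >= 1 row", id)
    if (any(ex[, 2L] <= ex[, 1L]))
      stop_config("transcript %s: empty or inverted exon interval", id)
    if (nrow(ex) > 1L) {
      if (is.unsorted(ex[, 1L], strictly = TRUE))
        stop_config("transcript %s: exons not sorted by start", id)
      if (any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))
        stop_config("transcript %s: overlapping exons", id)
    }
    if (!is.na(transcripts$sequence[i]) &&
        nchar(transcripts$sequence[i]) != sum(ex[, 2L] - ex[, 1L]))
      stop_config("transcript %s: sequence length != summed exon span", id)
    if (transcripts$samples_detected[i] < 0L)
      stop_config("transcript %s: samples_detected < 0", id)
  }
  invisible(transcripts)
}

#' Spliced length of each transcript model
#' @param transcripts transcript-model data.frame.
#' @return integer vector of summed exon spans.
#' @export
transcript_length <- function(transcripts) {
  vapply(transcripts$exons, function(ex) sum(ex[, 2L] - ex[, 1L]), 0L)
}

#' Filter assembled transcripts to candidate lncRNAs
#'
#' Retains transcripts satisfying all four structural discovery criteria —
#' at least 2 exons, assembler coverage >= 3, spliced length >= 200 nt, and
#' detection in more than one sample — and not annotated as coding. Known
#' noncoding transcripts that pass are labelled `"annotated"` (they bypass the
#' coding-potential screen downstream); the rest are `"novel"`.
#'
#' @param transcripts transcript-model data.frame.
#' @param known_noncoding_ids,known_coding_ids character vectors of annotated
#'   transcript ids.
#' @param min_exons,min_coverage,min_length,min_samples filter thresholds;
#'   defaults are the standard discovery criteria.
#' @return the retained transcripts with an added `annotation` column.
#' @export
filter_candidates <- function(transcripts,
                              known_noncoding_ids = character(),
                              known_coding_ids = character(),
                              min_exons = 2L, min_coverage = 3,
                              min_length = 200L, min_samples = 2L) {
  validate_transcript_models(transcripts)
  if (nrow(transcripts) == 0L) {
    transcripts$annotation <- character()
    return(transcripts)
  }
  n_exons <- vapply(transcripts$exons, nrow, 0L)
  len <- transcript_length(transcripts)
  keep <- n_exons >= min_exons &
    transcripts$coverage >= min_coverage &
    len >= min_length &
    transcripts$samples_detected >= min_samples &
    !(transcripts$transcript_id %in% known_coding_ids)
  out <- transcripts[keep, , drop = FALSE]
  out$annotation <- ifelse(out$transcript_id %in% known_noncoding_ids,
                           "annotated", "novel")
  rownames(out) <- NULL
  out
}

#' Assess coding potential of a transcript sequence
#'
#' Deterministic open-reading-frame surrogate for external coding-potential
#' classifiers: the longest ATG-to-stop ORF (stop codon included) is searched
#' over the three forward frames; the transcript is called `coding` when that
#' ORF is at least `min_orf_nt` long or covers at least `min_orf_frac` of the
#' transcript. Transcript sequences are strand-resolved, so reverse frames
#' are not scanned.
#'
#' @param sequence nucleotide string (A/C/G/T/U/N), length >= 200.
#' @param min_orf_nt ORF length (nt) at or above which the transcript is
#'   called coding (default 300, i.e. 100 codons).
#' @param min_orf_frac ORF/transcript length fraction at or above which the
#'   transcript is called coding (default 0.5).
#' @return list with `longest_orf_nt`, `orf_coverage` and `label`
#'   ("coding" or "noncoding").
#' @export
assess_coding_potential <- function(sequence, min_orf_nt = 300L,
                                    min_orf_frac = 0.5) {
  sequence <- check_nucleotide(sequence)
  if (nchar(sequence) < 200L)
    stop_config("coding-potential assessment needs >= 200 nt (got %d)",
                nchar(sequence))
  sequence <- chartr("U", "T", sequence)
  longest <- longest_orf_nt(sequence)
  cov <- longest / nchar(sequence)
  list(longest_orf_nt = longest,
       orf_coverage = cov,
       label = if (longest >= min_orf_nt || cov >= min_orf_frac)
         "coding" else "noncoding")
}

# longest ATG..stop span (nt, stop included) over the 3 forward frames
longest_orf_nt <- function(sequence) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  best <- 0L
  for (frame in 0:2) {
    starts <- seq.int(frame + 1L, n - 2L, by = 3L)
    if (length(starts) == 0L) next
    codons <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    is_start <- codons == "ATG"
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    open_from <- NA_integer_   # codon index of earliest unclosed ATG
    for (k in seq_along(codons)) {
      if (is_stop[k]) {
        if (!is.na(open_from)) {
          best <- max(best, (k - open_from + 1L) * 3L)
          open_from <- NA_integer_
        }
      } else if (is_start[k] && is.na(open_from)) {
        open_from <- k
      }
    }
  }
  best
}

#' Classify a candidate lncRNA as lincRNA or antisense
#'
#' A candidate is `antisense` when its genomic span overlaps a coding gene's
#' span by at least one nucleotide on the opposite strand of the same
#' chromosome; otherwise it is an intergenic `lincRNA` (same-strand overlap
#' does not count).
#'
#' @param candidate single-row transcript-model data.frame.
#' @param coding_genes transcript-model data.frame of coding gene models.
#' @return "lincRNA" or "antisense".
#' @export
classify_biotype <- function(candidate, coding_genes) {
  stopifnot(nrow(candidate) == 1L)
  if (nrow(coding_genes) == 0L) return("lincRNA")
  span <- function(tr, i) {
    ex <- tr$exons[[i]]
    c(min(ex[, 1L]), max(ex[, 2L]))
  }
  cand_span <- span(candidate, 1L)
  cand <- GenomicRanges::GRanges(
    candidate$chrom, IRanges::IRanges(cand_span[1L] + 1L, cand_span[2L]),
    strand = candidate$strand)
  spans <- t(vapply(seq_len(nrow(coding_genes)),
                    function(i) span(coding_genes, i), c(0, 0)))
  genes <- GenomicRanges::GRanges(
    coding_genes$chrom, IRanges::IRanges(spans[, 1L] + 1L, spans[, 2L]),
    strand = coding_genes$strand)
  # opposite strand only: ignore.strand finds positional overlap, then the
  # strand comparison keeps antisense configurations
  # disjoint chromosome sets between query and subject are expected for
  # intergenic candidates, not a condition worth warning about
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(cand, genes, ignore.strand = TRUE))
  if (length(ov) == 0L) return("lincRNA")
  opp <- as.character(GenomicRanges::strand(genes))[S4Vectors::subjectHits(ov)]
  if (any(opp != as.character(GenomicRanges::strand(cand)))) "antisense"
  else "lincRNA"
}

#' Run discovery on a transcript set
#'
#' Applies [filter_candidates()], screens novel candidates with
#' [assess_coding_potential()] (annotated noncoding transcripts bypass the
#' screen) and classifies surviving lncRNAs with [classify_biotype()].
#'
#' @param transcripts assembled transcript models.
#' @param coding_genes coding gene models used for the antisense test.
#' @inheritParams filter_candidates
#' @inheritParams assess_coding_potential
#' @return data.frame: transcript_id, annotation, longest_orf_nt, label,
#'   biotype — one row per filter-passing candidate; lncRNAs are the rows
#'   with `label == "noncoding"`.
#' @export
discover_lncrnas <- function(transcripts, coding_genes,
                             known_noncoding_ids = character(),
                             known_coding_ids = character(),
                             min_orf_nt = 300L, min_orf_frac = 0.5) {
  cand <- filter_candidates(transcripts, known_noncoding_ids, known_coding_ids)
  if (nrow(cand) == 0L)
    return(data.frame(transcript_id = character(), annotation = character(),
                      longest_orf_nt = integer(), orf_coverage = numeric(),
                      label = character(), biotype = character()))
  res <- lapply(seq_len(nrow(cand)), function(i) {
    if (cand$annotation[i] == "annotated") {
      list(longest_orf_nt = NA_integer_, orf_coverage = NA_real_,
           label = "noncoding")
    } else {
      assess_coding_potential(cand$sequence[i], min_orf_nt, min_orf_frac)
    }
  })
  biotype <- vapply(seq_len(nrow(cand)), function(i) {
    classify_biotype(cand[i, , drop = FALSE], coding_genes)
  }, "")
  data.frame(transcript_id = cand$transcript_id,
             annotation = cand$annotation,
             longest_orf_nt = vapply(res, function(r)
               as.integer(r$longest_orf_nt), 0L),
             orf_coverage = vapply(res, function(r)
               as.numeric(r$orf_coverage), 0),
             label = vapply(res, `[[`, "", "label"),
             biotype = biotype,
             stringsAsFactors = FALSE)
}
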