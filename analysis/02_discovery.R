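#!/usr/bin/env Rscript
# Stage 2: candidate lncRNA discovery.
#
# Reads the assembled transcript models (GTF + spliced FASTA) from stage 1,
# applies the four structural criteria (>= 2 exons, coverage >= 3, length
# >= 200 nt, seen in > 1 sample), screens novel candidates for coding
# potential with the longest-ORF rule, and classifies survivors as lincRNA
# or antisense against the mRNA gene models.

library(cernaforge)

in_dir <- file.path("results", "synthetic")
transcripts <- read_transcript_gtf(file.path(in_dir, "transcripts.gtf"),
                                   file.path(in_dir, "transcripts.fa"))
known_nc <- readLines(file.path(in_dir, "known_noncoding.txt"))
known_cd <- readLines(file.path(in_dir, "known_coding.txt"))
ann <- read_stage_table(file.path(in_dir, "mrna_annotation.tsv"))
mrna_models <- transcript_models(
  transcript_id = ann$transcript_id, gene_id = ann$gene_id,
  chrom = ann$chrom, strand = ann$strand, coverage = 100,
  samples_detected = 6L,
  exons = lapply(seq_len(nrow(ann)), function(i)
    cbind(start = ann$start[i], end = ann$end[i])))

candidates <- discover_lncrnas(transcripts, mrna_models, known_nc, known_cd)
write_stage_table(candidates, file.path("results", "lncrna_candidates.tsv"))

n_nc <- sum(candidates$label == "noncoding")
cat(sprintf("%d transcript models in, %d pass the structural filter, %d called noncoding\n",
            nrow(transcripts), nrow(candidates), n_nc))
cat(sprintf("  biotypes: %d lincRNA, %d antisense\n",
            sum(candidates$biotype == "lincRNA"),
            sum(candidates$biotype == "antisense")))
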