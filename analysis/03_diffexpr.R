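#!/usr/bin/env Rscript
# Stage 3: differential expression, case vs control.
#
# Median-of-ratios size factors, per-feature moments NB dispersion, the
# conditional NB exact test on group sums, BH correction and Up/Down calls —
# separately for mRNAs, lncRNAs and miRNAs, as the three libraries are
# sequenced separately. Also writes log10(x+1) FPKM/TPM matrices for the
# correlation stages and a sample dendrogram check.

library(cernaforge)

in_dir <- file.path("results", "synthetic")
samples <- read_sample_sheet(file.path(in_dir, "samples.tsv"))
cfg <- yaml::read_yaml(file.path(in_dir, "config.yaml"))

kinds <- c("mrna", "lncrna", "mirna")
for (kind in kinds) {
  counts <- read_count_matrix(file.path(in_dir, paste0("counts_", kind,
                                                       ".tsv")))
  de <- de_test(counts, samples$group)
  write_stage_table(de, file.path("results", paste0("de_", kind, ".tsv")))
  cat(sprintf("%-6s %4d features: %d Up, %d Down at q < 0.05\n", kind,
              nrow(de), sum(de$status == "Up"), sum(de$status == "Down")))

  # normalized expression for the correlation stages: FPKM for the long
  # RNAs (length-dependent libraries), TPM for miRNAs
  lens <- if (kind == "mirna") {
    rep(cfg$mirna_length, nrow(counts))
  } else if (kind == "lncrna") {
    tr <- read_transcript_gtf(file.path(in_dir, "transcripts.gtf"))
    transcript_length(tr)[match(rownames(counts), tr$transcript_id)]
  } else {
    ann <- read_stage_table(file.path(in_dir, "mrna_annotation.tsv"))
    ann$length[match(rownames(counts), ann$gene_id)]
  }
  norm <- if (kind == "mirna")
    compute_fpkm_tpm(counts, lens)$tpm else compute_fpkm_tpm(counts, lens)$fpkm
  expr <- log_normalize(norm)
  df <- data.frame(feature_id = rownames(expr), expr, check.names = FALSE)
  write_stage_table(df, file.path("results", paste0("expr_", kind, ".tsv")))
}

# unsupervised clustering should split samples by group
expr <- as.matrix(read_stage_table(file.path("results",
                                             "expr_mrna.tsv"))[, -1])
hc <- hierarchical_cluster(expr)
groups <- samples$group[match(hc$labels, samples$sample_id)]
two <- stats::cutree(hc, 2)
cat("sample dendrogram splits case from control:",
    length(unique(paste(two, groups))) == 2, "\n")
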