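#!/usr/bin/env Rscript
# Stage 4: miRNA binding-site scanning.
#
# Every miRNA is aligned (seed-weighted local complementarity, affine gaps)
# against every candidate-lncRNA transcript and every mRNA scan region —
# the annotated 3'UTR where present, otherwise the first 1,000 nt downstream
# of the stop codon. Sites must clear score > 140 and duplex free energy
# <= -10 kcal/mol.

library(cernaforge)

in_dir <- file.path("results", "synthetic")
mirnas <- read_fasta(file.path(in_dir, "mirna.fa"))
candidates <- read_stage_table(file.path("results", "lncrna_candidates.tsv"))
lnc_ids <- candidates$transcript_id[candidates$label == "noncoding"]
tr_seqs <- read_fasta(file.path(in_dir, "transcripts.fa"))
lnc_regions <- lapply(lnc_ids, function(id)
  list(host_id = id, kind = "lncrna", sequence = unname(tr_seqs[id])))

utr <- read_fasta(file.path(in_dir, "utr3.fa"))
down_path <- file.path(in_dir, "downstream.fa")
down <- if (file.exists(down_path)) read_fasta(down_path) else character()
ann <- read_stage_table(file.path(in_dir, "mrna_annotation.tsv"))
mrna_regions <- lapply(ann$gene_id, function(g) {
  extract_scan_region(list(gene_id = g,
                           utr3_seq = if (g %in% names(utr)) utr[[g]] else NA,
                           downstream_seq = if (g %in% names(down))
                             down[[g]] else NA))
})

hits_lnc <- scan_all(mirnas, lnc_regions)
hits_mrna <- scan_all(mirnas, mrna_regions)
hits <- rbind(hits_lnc, hits_mrna)
write_stage_table(hits, file.path("results", "binding_sites.tsv"))

cat(sprintf("scanned %d miRNAs against %d lncRNAs and %d mRNA regions\n",
            length(mirnas), length(lnc_regions), length(mrna_regions)))
cat(sprintf("  %d sites on lncRNAs, %d on mRNA regions\n",
            nrow(hits_lnc), nrow(hits_mrna)))
truth <- jsonlite::read_json(file.path(in_dir, "ground_truth.json"),
                             simplifyVector = TRUE)
ps <- truth$planted_binding_sites
if (length(ps) && nrow(ps)) {
  found <- vapply(seq_len(nrow(ps)), function(i)
    any(hits$mirna_id == ps$mirna_id[i] & hits$host_id == ps$host_id[i]), TRUE)
  cat(sprintf("  planted-site recall: %.2f (%d/%d)\n", mean(found),
              sum(found), length(found)))
}
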