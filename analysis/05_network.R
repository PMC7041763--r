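#!/usr/bin/env Rscript
# Stage 5: pair inference, tripartite network assembly, and the three
# restrictions.
#
# Pairs combine binding sites with Pearson co-expression at |r| > 0.8 on the
# log-normalized matrices from stage 3; triples are all (lncRNA, miRNA,
# mRNA) sharing a miRNA through both edge types; the restrictions then keep
# jointly significant up/down/up triples, expressed in both groups, whose
# gene is on the disease list.

library(cernaforge)

in_dir <- file.path("results", "synthetic")
read_expr <- function(kind) {
  df <- read_stage_table(file.path("results", paste0("expr_", kind, ".tsv")))
  m <- as.matrix(df[, -1]); rownames(m) <- df$feature_id
  m
}
expr <- lapply(c(mrna = "mrna", lncrna = "lncrna", mirna = "mirna"),
               read_expr)
de <- lapply(c(mrna = "mrna", lncrna = "lncrna", mirna = "mirna"),
             function(k) read_stage_table(file.path("results",
                                                    paste0("de_", k, ".tsv"))))
ann <- read_stage_table(file.path(in_dir, "mrna_annotation.tsv"))
de$mrna$gene_name <- ann$gene_name[match(de$mrna$feature_id, ann$gene_id)]
hits <- read_stage_table(file.path("results", "binding_sites.tsv"))
hits_lnc <- hits[hits$host_id %in% rownames(expr$lncrna), ]
hits_mrna <- hits[hits$host_id %in% rownames(expr$mrna), ]

trans <- trans_lnc_mrna_pairs(expr$lncrna, expr$mrna)
lnc_mi <- lnc_mirna_pairs(expr$lncrna, expr$mirna, hits_lnc)
mi_mrna <- mirna_mrna_pairs(expr$mirna, expr$mrna, hits_mrna)
for (nm in c("trans", "lnc_mi", "mi_mrna"))
  write_stage_table(get(nm), file.path("results", paste0("pairs_", nm,
                                                         ".tsv")))
cat(sprintf("pairs: %d trans lncRNA-mRNA, %d lncRNA-miRNA, %d miRNA-mRNA\n",
            nrow(trans), nrow(lnc_mi), nrow(mi_mrna)))

network <- build_network(lnc_mi, mi_mrna, de)
print(network)
triples <- enumerate_triples(network)

samples <- read_sample_sheet(file.path(in_dir, "samples.tsv"))
expr_means <- do.call(rbind, lapply(names(expr), function(kind) {
  counts <- read_count_matrix(file.path(in_dir, paste0("counts_", kind,
                                                       ".tsv")))
  norm <- sweep(counts, 2, size_factors(counts), "/")
  data.frame(feature_id = rownames(counts),
             mean_case = rowMeans(norm[, samples$group == "case"]),
             mean_control = rowMeans(norm[, samples$group == "control"]))
}))
disease <- readLines(file.path(in_dir, "disease_genes.txt"))
selected <- apply_restrictions(triples, disease, expr_means)

write_stage_table(triples, file.path("results", "triples_enumerated.tsv"))
write_stage_table(selected, file.path("results", "triples_selected.tsv"))
export_network(network, file.path("results", "network_edges.tsv"),
               "edgelist")
export_network(network, file.path("results", "network.graphml"), "graphml")

cat(sprintf("%d triples enumerated, %d pass the three restrictions:\n",
            nrow(triples), nrow(selected)))
print(selected[, c("lncrna_id", "mirna_id", "gene_name", "lnc_status",
                   "mir_status", "mrna_status")])
truth <- jsonlite::read_json(file.path(in_dir, "ground_truth.json"),
                             simplifyVector = TRUE)
pl <- truth$planted_triples
key <- function(df) paste(df$lncrna_id, df$mirna_id, df$mrna_id)
cat(sprintf("recall vs planted truth: %.2f  false discoveries: %d\n",
            mean(key(pl) %in% key(selected)),
            sum(!(key(selected) %in% key(pl)))))
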