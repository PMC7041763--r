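# The printed final-network worked example: the six published ceRNA triples
# (four lncRNAs competing for two miRNAs over six atherosclerosis genes)
# with their statuses and q-values, plus decoy triples that each violate
# exactly one of the three restrictions. The fixture is the acceptance
# surface for the restriction chain.

#' Published ceRNA-network worked example with decoys
#'
#' Returns an in-memory dataset encoding the six published
#' lncRNA-miRNA-mRNA triples of the atherosclerosis rabbit carotid study —
#' XLOC_063297/XLOC_062719 competing for ocu-miR-185-5p over CTSS, EDNRA and
#' CTSB, and XLOC_054118/XLOC_030217 competing for ocu-miR-96-5p over SOAT1,
#' CAPG and CHI3L1, all following the up/down/up pattern — together with 12
#' decoy triples, each constructed to violate exactly one restriction:
#' wrong direction pattern, a member with q >= 0.05, a member with zero
#' expression in one group, or a gene absent from the disease list.
#'
#' @return list with components:
#'   \describe{
#'     \item{triples}{18 candidate triples (6 true + 12 decoys) with
#'       statuses, q-values and a logical `published` flag.}
#'     \item{lnc_mi_pairs, mi_mrna_pairs}{the published pair sets in
#'       [build_network()] form.}
#'     \item{de_tables}{per-kind DE tables covering every fixture feature.}
#'     \item{expr_means}{per-feature group means for the expression floor.}
#'     \item{disease_genes}{disease gene symbols (contains all six published
#'       genes, none of the decoy genes).}
#'   }
#' @export
table4_fixture <- function() {
  lnc <- data.frame(
    feature_id = c("XLOC_063297", "XLOC_062719", "XLOC_054118",
                   "XLOC_030217"),
    status = "Up",
    q_value = c(0.001644, 0.023797, 0.001644, 0.014355),
    stringsAsFactors = FALSE)
  mir <- data.frame(
    feature_id = c("ocu-miR-185-5p", "ocu-miR-96-5p"),
    status = "Down",
    q_value = c(0.035479, 0.022014),
    stringsAsFactors = FALSE)
  mrna <- data.frame(
    feature_id = c("ENSOCUG00000011085", "ENSOCUG00000001250",
                   "ENSOCUG00000016580", "ENSOCUG00000008204",
                   "ENSOCUG00000002341", "ENSOCUG00000026988"),
    gene_name = c("CTSS", "EDNRA", "CTSB", "SOAT1", "CAPG", "CHI3L1"),
    status = "Up",
    q_value = c(0.00164462, 0.0367288, 0.00164462, 0.00164462,
                0.00164462, 0.00164462),
    stringsAsFactors = FALSE)

  published <- data.frame(
    lncrna_id = c("XLOC_063297", "XLOC_063297", "XLOC_062719",
                  "XLOC_054118", "XLOC_054118", "XLOC_030217"),
    mirna_id = rep(c("ocu-miR-185-5p", "ocu-miR-96-5p"), each = 3L),
    mrna_id = mrna$feature_id,
    gene_name = mrna$gene_name,
    stringsAsFactors = FALSE)
  tri <- function(l, m, g) {
    data.frame(
      lncrna_id = l, mirna_id = m, mrna_id = g$feature_id,
      gene_name = g$gene_name,
      lnc_status = lnc$status[match(l, lnc$feature_id)],
      mir_status = mir$status[match(m, mir$feature_id)],
      mrna_status = g$status,
      lnc_q = lnc$q_value[match(l, lnc$feature_id)],
      mir_q = mir$q_value[match(m, mir$feature_id)],
      mrna_q = g$q_value,
      stringsAsFactors = FALSE)
  }
  true_triples <- tri(published$lncrna_id, published$mirna_id,
                      mrna[match(published$mrna_id, mrna$feature_id), ])
  true_triples$published <- TRUE

  # decoys: template rows perturbed so each fails one declared restriction
  base <- true_triples[rep(1L, 12L), ]
  base$published <- FALSE
  decoy_lnc <- sprintf("XLOC_decoy%02d", 1:12)
  base$lncrna_id <- decoy_lnc
  # 1-4: wrong direction pattern
  base$lnc_status[1L] <- "Down"
  base$mir_status[2L] <- "Up"
  base$mrna_status[3L] <- "Down"
  base$lnc_status[4L] <- "Down"; base$mrna_status[4L] <- "Down"
  # 5-8: a member not significant at q < 0.05
  base$lnc_q[5L] <- 0.21
  base$mir_q[6L] <- 0.07; base$mirna_id[6L] <- "ocu-miR-decoy06"
  base$mrna_q[7L] <- 0.5; base$mrna_id[7L] <- "ENSOCUG_decoy07"
  base$gene_name[7L] <- "CTSS"
  base$lnc_q[8L] <- 0.9
  # 9-10: a member with zero expression in one group
  zero_expr_lnc <- decoy_lnc[9:10]
  # 11-12: gene outside the disease list
  base$mrna_id[11L] <- "ENSOCUG_decoy11"; base$gene_name[11L] <- "OR5AC2"
  base$mrna_id[12L] <- "ENSOCUG_decoy12"; base$gene_name[12L] <- "KRT81"
  triples <- rbind(true_triples, base)
  rownames(triples) <- NULL

  lnc_mi_pairs <- data.frame(
    source_id = unique(published$lncrna_id),
    target_id = c("ocu-miR-185-5p", "ocu-miR-185-5p",
                  "ocu-miR-96-5p", "ocu-miR-96-5p"),
    relation = "lnc_mirna_decoy", r = NA_real_, n_sites = 1L,
    stringsAsFactors = FALSE)
  mi_mrna_pairs <- data.frame(
    source_id = published$mirna_id, target_id = published$mrna_id,
    relation = "mirna_mrna", r = NA_real_, n_sites = 1L,
    stringsAsFactors = FALSE)

  all_lnc <- rbind(lnc, data.frame(feature_id = decoy_lnc, status = "Up",
                                   q_value = 0.001, stringsAsFactors = FALSE))
  all_lnc$status[match(c(base$lncrna_id[1L], base$lncrna_id[4L]),
                       all_lnc$feature_id)] <- "Down"
  de_tables <- list(
    lncrna = data.frame(feature_id = all_lnc$feature_id,
                        status = all_lnc$status, q_value = all_lnc$q_value,
                        stringsAsFactors = FALSE),
    mirna = data.frame(feature_id = c(mir$feature_id, "ocu-miR-decoy06"),
                       status = c(mir$status, "Down"),
                       q_value = c(mir$q_value, 0.07),
                       stringsAsFactors = FALSE),
    mrna = data.frame(feature_id = c(mrna$feature_id, "ENSOCUG_decoy07",
                                     "ENSOCUG_decoy11", "ENSOCUG_decoy12"),
                      gene_name = c(mrna$gene_name, "CTSS", "OR5AC2",
                                    "KRT81"),
                      status = "Up",
                      q_value = c(mrna$q_value, 0.5, 0.001, 0.001),
                      stringsAsFactors = FALSE))

  all_ids <- unique(c(triples$lncrna_id, triples$mirna_id, triples$mrna_id))
  expr_means <- data.frame(feature_id = all_ids,
                           mean_case = 50, mean_control = 30,
                           stringsAsFactors = FALSE)
  expr_means$mean_control[expr_means$feature_id %in% zero_expr_lnc] <- 0

  disease_genes <- c("CTSS", "EDNRA", "CTSB", "SOAT1", "CAPG", "CHI3L1",
                     "TIMP1", "VCAM1", "TLR4", "MARCO")

  list(triples = triples, lnc_mi_pairs = lnc_mi_pairs,
       mi_mrna_pairs = mi_mrna_pairs, de_tables = de_tables,
       expr_means = expr_means, disease_genes = disease_genes)
}
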