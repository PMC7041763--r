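# Network assembly, triple enumeration against a brute-force cross product,
# the three restrictions on the published worked example, and export
# round-trips.

fixture_network <- function() {
  fx <- table4_fixture()
  build_network(fx$lnc_mi_pairs, fx$mi_mrna_pairs, fx$de_tables)
}

test_that("networks carry exactly the provided pairs with annotated nodes", {
  net <- fixture_network()
  expect_s3_class(net, "cerna_network")
  expect_equal(nrow(net$lnc_mi), 4L)
  expect_equal(nrow(net$mi_mrna), 6L)
  expect_equal(sum(net$nodes$kind == "lncrna"), 4L)
  expect_equal(sum(net$nodes$kind == "mirna"), 2L)
  expect_equal(sum(net$nodes$kind == "mrna"), 6L)
  expect_true(all(c("CTSS", "SOAT1", "CHI3L1") %in% net$nodes$gene_name))
  # worked-example annotations carried onto nodes
  lnc <- net$nodes[net$nodes$id == "XLOC_054118", ]
  expect_equal(lnc$status, "Up")
  expect_equal(lnc$q_value, 0.001644)
  mrna <- net$nodes[net$nodes$gene_name == "CTSS", ]
  expect_equal(mrna$status, "Up")
  expect_equal(mrna$q_value, 0.00164462)
  # empty input -> empty network
  fx <- table4_fixture()
  empty <- build_network(fx$lnc_mi_pairs[0, ], fx$mi_mrna_pairs[0, ],
                         fx$de_tables)
  expect_equal(nrow(empty$nodes), 0L)
  expect_equal(nrow(enumerate_triples(empty)), 0L)
  # an edge naming an unknown feature is an error listing the id
  bad <- fx$lnc_mi_pairs
  bad$source_id[1] <- "XLOC_unknown"
  expect_error(build_network(bad, fx$mi_mrna_pairs, fx$de_tables),
               "XLOC_unknown")
})

test_that("triples are all shared-miRNA combinations in deterministic order", {
  de <- list(
    lncrna = data.frame(feature_id = c("l1", "l2"), status = "Up",
                        q_value = 0.01),
    mirna = data.frame(feature_id = "m1", status = "Down", q_value = 0.01),
    mrna = data.frame(feature_id = c("g1", "g2", "g3"), status = "Up",
                      q_value = 0.01))
  lnc_mi <- data.frame(source_id = c("l1", "l2"), target_id = "m1",
                       relation = "lnc_mirna_decoy", r = 0.9, n_sites = 1L)
  mi_mrna <- data.frame(source_id = "m1", target_id = c("g1", "g2", "g3"),
                        relation = "mirna_mrna", r = -0.9, n_sites = 1L)
  net <- build_network(lnc_mi, mi_mrna, de)
  tri <- enumerate_triples(net)
  expect_equal(nrow(tri), 6L)  # 2 lncRNAs x 3 mRNAs through one miRNA
  expect_equal(tri, tri[order(tri$lncrna_id, tri$mirna_id, tri$mrna_id), ],
               ignore_attr = TRUE)
  # no shared miRNA -> no triples
  mi_mrna2 <- mi_mrna; mi_mrna2$source_id <- "m2"
  de2 <- de; de2$mirna <- rbind(de2$mirna,
                                data.frame(feature_id = "m2",
                                           status = "Down", q_value = 0.01))
  net2 <- build_network(lnc_mi, mi_mrna2, de2)
  expect_equal(nrow(enumerate_triples(net2)), 0L)
  # the published network contains its flagship triple
  tri_fx <- enumerate_triples(fixture_network())
  expect_true(any(tri_fx$lncrna_id == "XLOC_054118" &
                    tri_fx$mirna_id == "ocu-miR-96-5p" &
                    tri_fx$gene_name == "SOAT1"))
})

test_that("enumeration equals a brute-force cross product on random graphs", {
  set.seed(51)
  for (i in 1:50) {
    lnc_ids <- paste0("l", seq_len(sample(1:5, 1)))
    mi_ids <- paste0("m", seq_len(sample(1:4, 1)))
    g_ids <- paste0("g", seq_len(sample(1:6, 1)))
    lm <- expand.grid(source_id = lnc_ids, target_id = mi_ids,
                      stringsAsFactors = FALSE)
    lm <- lm[runif(nrow(lm)) < 0.4, , drop = FALSE]
    mg <- expand.grid(source_id = mi_ids, target_id = g_ids,
                      stringsAsFactors = FALSE)
    mg <- mg[runif(nrow(mg)) < 0.4, , drop = FALSE]
    if (nrow(lm) == 0 || nrow(mg) == 0) next
    lm$relation <- "lnc_mirna_decoy"; lm$r <- 0.9; lm$n_sites <- 1L
    mg$relation <- "mirna_mrna"; mg$r <- -0.9; mg$n_sites <- 1L
    de <- list(
      lncrna = data.frame(feature_id = lnc_ids, status = "Up",
                          q_value = 0.01),
      mirna = data.frame(feature_id = mi_ids, status = "Down",
                         q_value = 0.01),
      mrna = data.frame(feature_id = g_ids, status = "Up", q_value = 0.01))
    tri <- enumerate_triples(build_network(lm, mg, de))
    got <- sort(paste(tri$lncrna_id, tri$mirna_id, tri$mrna_id, sep = "|"))
    expect_equal(got, oracle_triples(lnc_ids, mi_ids, g_ids, lm, mg))
  }
})

test_that("the restriction chain keeps exactly the published worked example", {
  fx <- table4_fixture()
  expect_gte(sum(!fx$triples$published), 10L)
  step1 <- filter_dysregulated(fx$triples)
  step2 <- filter_expressed(step1, fx$expr_means)
  final <- restrict_to_gene_list(step2, fx$disease_genes)
  expect_equal(nrow(final), 6L)
  expect_true(all(final$published))
  # idempotence and subset property
  expect_equal(filter_dysregulated(step1), step1, ignore_attr = TRUE)
  expect_true(all(paste(step1$lncrna_id, step1$mrna_id) %in%
                    paste(fx$triples$lncrna_id, fx$triples$mrna_id)))
  # every decoy violates at least one declared restriction
  decoys <- fx$triples[!fx$triples$published, ]
  survives <- apply_restrictions(decoys, fx$disease_genes, fx$expr_means)
  expect_equal(nrow(survives), 0L)
})

test_that("restriction operations behave at their boundaries", {
  fx <- table4_fixture()
  tri <- fx$triples[fx$triples$published, ]
  # pattern mismatch and missed significance are both rejected
  up3 <- tri[1, ]; up3$mir_status <- "Up"
  expect_equal(nrow(filter_dysregulated(up3)), 0L)
  lateq <- tri[1, ]; lateq$mrna_q <- 0.2
  expect_equal(nrow(filter_dysregulated(lateq)), 0L)
  # status matching is case-insensitive (printed tables mix Up/up)
  mixed <- tri[1, ]
  mixed$lnc_status <- "up"; mixed$mrna_status <- "UP"
  expect_equal(nrow(filter_dysregulated(mixed)), 1L)
  # gene matching is case-insensitive; empty list passes through with warning
  expect_equal(nrow(restrict_to_gene_list(tri, c("ctsb", "soat1"))), 2L)
  expect_warning(all_through <- restrict_to_gene_list(tri, character(0)),
                 "disabled")
  expect_equal(nrow(all_through), nrow(tri))
  expect_equal(nrow(restrict_to_gene_list(tri, tri$gene_name)), nrow(tri))
  # expression floor removes members silent in one group
  em <- fx$expr_means
  em$mean_control[em$feature_id == tri$lncrna_id[1]] <- 0
  expect_lt(nrow(filter_expressed(tri, em)), nrow(tri))
})

test_that("network exports round-trip and produce well-formed GraphML", {
  net <- fixture_network()
  dir <- withr::local_tempdir()
  edge_path <- file.path(dir, "edges.tsv")
  export_network(net, edge_path, "edgelist")
  back <- read_edge_list(edge_path)
  expect_equal(nrow(back), nrow(net$lnc_mi) + nrow(net$mi_mrna))
  expect_setequal(paste(back$source, back$target),
                  c(paste(net$lnc_mi$source_id, net$lnc_mi$target_id),
                    paste(net$mi_mrna$source_id, net$mi_mrna$target_id)))
  gml_path <- file.path(dir, "net.graphml")
  export_network(net, gml_path, "graphml")
  doc <- xml2::read_xml(gml_path)
  expect_equal(xml2::xml_name(doc), "graphml")
  g <- igraph::read_graph(gml_path, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(back))
  expect_equal(igraph::vcount(g), nrow(net$nodes))
  expect_setequal(igraph::vertex_attr(g, "kind"), net$nodes$kind)
  # empty network -> header-only edge list
  fx <- table4_fixture()
  empty <- build_network(fx$lnc_mi_pairs[0, ], fx$mi_mrna_pairs[0, ],
                         fx$de_tables)
  export_network(empty, edge_path, "edgelist")
  expect_equal(nrow(read_edge_list(edge_path)), 0L)
})
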