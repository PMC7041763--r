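# Tripartite ceRNA network assembly: lncRNA-miRNA and miRNA-mRNA edges with
# DE-annotated nodes, triple enumeration over shared miRNAs, and the three
# restrictions (joint significance + directional pattern, expression floor,
# disease-gene membership) extracting the dysregulated network.

#' Build a ceRNA network from pair sets and DE tables
#'
#' The network contains exactly the union of the provided lncRNA-miRNA and
#' miRNA-mRNA pairs; nodes not on any edge are dropped, and every node is
#' annotated with its DE status and q-value (and, for mRNAs, the gene symbol
#' when the DE table carries a `gene_name` column). An edge referencing a
#' feature absent from the DE tables is an error.
#'
#' @param lnc_mi_pairs,mi_mrna_pairs pair data.frames (source_id, target_id,
#'   relation, r, n_sites) from [lnc_mirna_pairs()] / [mirna_mrna_pairs()].
#' @param de_tables named list of DE tables (`lncrna`, `mirna`, `mrna`) as
#'   returned by [de_test()].
#' @return object of class `cerna_network`: list with `lnc_mi`, `mi_mrna`
#'   edge tables and a `nodes` annotation table (id, kind, status, q_value,
#'   gene_name).
#' @export
build_network <- function(lnc_mi_pairs, mi_mrna_pairs, de_tables) {
  stopifnot(all(c("lncrna", "mirna", "mrna") %in% names(de_tables)))
  node_rows <- function(ids, kind) {
    tab <- de_tables[[kind]]
    if (length(ids) == 0L)
      return(data.frame(id = character(), kind = character(),
                        status = character(), q_value = numeric(),
                        gene_name = character(), stringsAsFactors = FALSE))
    missing <- setdiff(ids, tab$feature_id)
    if (length(missing))
      stop_config("%s feature(s) missing from DE table: %s", kind,
                  paste(missing, collapse = ", "))
    i <- match(ids, tab$feature_id)
    data.frame(id = ids, kind = kind,
               status = tab$status[i], q_value = tab$q_value[i],
               gene_name = if ("gene_name" %in% names(tab))
                 tab$gene_name[i] else ids,
               stringsAsFactors = FALSE)
  }
  lnc_ids <- unique(lnc_mi_pairs$source_id)
  mi_ids <- unique(c(lnc_mi_pairs$target_id, mi_mrna_pairs$source_id))
  mrna_ids <- unique(mi_mrna_pairs$target_id)
  nodes <- rbind(node_rows(lnc_ids, "lncrna"),
                 node_rows(mi_ids, "mirna"),
                 node_rows(mrna_ids, "mrna"))
  structure(list(lnc_mi = lnc_mi_pairs, mi_mrna = mi_mrna_pairs,
                 nodes = nodes),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat("ceRNA network:", nrow(x$lnc_mi), "lncRNA-miRNA edges,",
      nrow(x$mi_mrna), "miRNA-mRNA edges,", nrow(x$nodes), "nodes\n")
  invisible(x)
}

empty_triples <- function() {
  data.frame(lncrna_id = character(), mirna_id = character(),
             mrna_id = character(), gene_name = character(),
             lnc_status = character(), mir_status = character(),
             mrna_status = character(),
             lnc_q = numeric(), mir_q = numeric(), mrna_q = numeric(),
             stringsAsFactors = FALSE)
}

#' Enumerate ceRNA triples sharing a miRNA
#'
#' All (lncRNA, miRNA, mRNA) combinations in which the lncRNA-miRNA and
#' miRNA-mRNA edges both exist, in deterministic order (lncRNA, then miRNA,
#' then mRNA id).
#'
#' @param network a `cerna_network` from [build_network()].
#' @return triple data.frame: ids, gene_name, per-member status and q-value.
#' @export
enumerate_triples <- function(network) {
  lm <- network$lnc_mi
  mg <- network$mi_mrna
  if (nrow(lm) == 0L || nrow(mg) == 0L) return(empty_triples())
  mrna_by_mi <- split(mg$target_id, mg$source_id)
  rows <- lapply(seq_len(nrow(lm)), function(i) {
    genes <- mrna_by_mi[[lm$target_id[i]]]
    if (is.null(genes)) return(NULL)
    data.frame(lncrna_id = lm$source_id[i], mirna_id = lm$target_id[i],
               mrna_id = genes, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) return(empty_triples())
  ann <- function(ids, col) {
    network$nodes[[col]][match(ids, network$nodes$id)]
  }
  out$gene_name <- ann(out$mrna_id, "gene_name")
  out$lnc_status <- ann(out$lncrna_id, "status")
  out$mir_status <- ann(out$mirna_id, "status")
  out$mrna_status <- ann(out$mrna_id, "status")
  out$lnc_q <- ann(out$lncrna_id, "q_value")
  out$mir_q <- ann(out$mirna_id, "q_value")
  out$mrna_q <- ann(out$mrna_id, "q_value")
  out <- out[order(out$lncrna_id, out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

normalize_status <- function(x) {
  x <- tolower(x)
  c(up = "Up", down = "Down", ns = "NS")[x]
}

#' Restriction 1: joint significance and directional pattern
#'
#' Retains triples whose three members all have q < alpha and whose
#' (lncRNA, miRNA, mRNA) statuses equal the pattern — by default the
#' up/down/up configuration in which an upregulated lncRNA sponges a
#' downregulated miRNA, relieving repression of an upregulated mRNA.
#' Status comparison is case-insensitive; the operation is idempotent.
#'
#' @param triples triple data.frame from [enumerate_triples()].
#' @param alpha significance threshold (default 0.05).
#' @param pattern length-3 character vector of statuses.
#' @return the retained subset of `triples`.
#' @export
filter_dysregulated <- function(triples, alpha = 0.05,
                                pattern = c("Up", "Down", "Up")) {
  if (nrow(triples) == 0L) return(triples)
  pat <- normalize_status(pattern)
  keep <- triples$lnc_q < alpha & triples$mir_q < alpha &
    triples$mrna_q < alpha &
    normalize_status(triples$lnc_status) == pat[1L] &
    normalize_status(triples$mir_status) == pat[2L] &
    normalize_status(triples$mrna_status) == pat[3L]
  keep[is.na(keep)] <- FALSE
  out <- triples[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restriction 2: minimum-expression floor
#'
#' Retains triples whose three members all show mean normalized expression
#' strictly above `min_mean` in both groups — the operationalization of the
#' requirement that the concentrations of all chosen members be determined
#' in the tissue.
#'
#' @param triples triple data.frame.
#' @param expr_means data.frame: feature_id, mean_case, mean_control.
#' @param min_mean expression floor (default 0).
#' @return the retained subset of `triples`.
#' @export
filter_expressed <- function(triples, expr_means, min_mean = 0) {
  if (nrow(triples) == 0L) return(triples)
  ok <- function(ids) {
    i <- match(ids, expr_means$feature_id)
    found <- !is.na(i)
    found & expr_means$mean_case[i] > min_mean &
      expr_means$mean_control[i] > min_mean
  }
  keep <- ok(triples$lncrna_id) & ok(triples$mirna_id) & ok(triples$mrna_id)
  keep[is.na(keep)] <- FALSE
  out <- triples[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restriction 3: disease-gene membership
#'
#' Retains triples whose gene symbol appears (case-insensitively) in the
#' disease gene list. An empty list disables the restriction with a warning
#' and passes every triple through.
#'
#' @param triples triple data.frame.
#' @param disease_genes character vector of gene symbols.
#' @return the retained subset of `triples`.
#' @export
restrict_to_gene_list <- function(triples, disease_genes) {
  if (length(disease_genes) == 0L) {
    warning("empty disease-gene list: restriction disabled, passing through",
            call. = FALSE)
    return(triples)
  }
  keep <- tolower(triples$gene_name) %in% tolower(disease_genes)
  out <- triples[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the three restrictions in sequence
#'
#' [filter_dysregulated()] then [filter_expressed()] (when expression means
#' are supplied) then [restrict_to_gene_list()].
#'
#' @inheritParams filter_dysregulated
#' @inheritParams filter_expressed
#' @inheritParams restrict_to_gene_list
#' @return the surviving triples.
#' @export
apply_restrictions <- function(triples, disease_genes, expr_means = NULL,
                               alpha = 0.05, pattern = c("Up", "Down", "Up"),
                               min_mean = 0) {
  out <- filter_dysregulated(triples, alpha, pattern)
  if (!is.null(expr_means)) out <- filter_expressed(out, expr_means, min_mean)
  restrict_to_gene_list(out, disease_genes)
}

#' Export a ceRNA network for external visualization
#'
#' Writes either a tab-separated edge list (source, interaction, target, r)
#' readable by Cytoscape and by [read_edge_list()], or GraphML with node
#' kind/status attributes.
#'
#' @param network a `cerna_network`.
#' @param path output file path.
#' @param format "edgelist" or "graphml".
#' @return the path, invisibly.
#' @export
export_network <- function(network, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  edges <- rbind(
    data.frame(source = network$lnc_mi$source_id,
               interaction = network$lnc_mi$relation,
               target = network$lnc_mi$target_id,
               r = network$lnc_mi$r, stringsAsFactors = FALSE),
    data.frame(source = network$mi_mrna$source_id,
               interaction = network$mi_mrna$relation,
               target = network$mi_mrna$target_id,
               r = network$mi_mrna$r, stringsAsFactors = FALSE))
  if (format == "edgelist") {
    write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      edges[, c("source", "target", "interaction", "r")],
      directed = FALSE, vertices = network$nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an edge list written by [export_network()]
#' @param path edge-list TSV.
#' @return data.frame: source, interaction, target, r.
#' @export
read_edge_list <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
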