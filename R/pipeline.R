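# End-to-end orchestration: discovery -> differential expression -> target
# scanning -> pair inference -> network assembly -> the three restrictions ->
# enrichment, over a synthetic dataset (or one loaded from disk), with a
# machine-readable stage summary and ground-truth scoring in synthetic mode.

#' Pipeline configuration
#'
#' Bundles a [simulation_config()] with every stage threshold. Thresholds
#' default to the published analysis conventions: q < 0.05 significance,
#' |r| > 0.8 correlations, alignment score > 140, duplex free energy
#' <= -10 kcal/mol, and the up/down/up dysregulation pattern.
#'
#' @param simulation a [simulation_config()] (or list of its arguments).
#' @param alpha DE / enrichment significance threshold.
#' @param cor_threshold Pearson correlation magnitude cutoff.
#' @param score_min alignment score cutoff (strict).
#' @param energy_max duplex free-energy cutoff in kcal/mol (inclusive).
#' @param pattern length-3 status pattern (lncRNA, miRNA, mRNA).
#' @param min_mean expression floor for restriction 2.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            alpha = 0.05, cor_threshold = 0.8,
                            score_min = 140, energy_max = -10,
                            pattern = c("Up", "Down", "Up"),
                            min_mean = 0) {
  if (!inherits(simulation, "simulation_config"))
    simulation <- do.call(simulation_config, as.list(simulation))
  if (!(alpha > 0 && alpha < 1))
    stop_config("config: alpha must lie in (0, 1)")
  if (!(cor_threshold >= 0 && cor_threshold <= 1))
    stop_config("config: cor_threshold must lie in [0, 1]")
  if (!is.finite(score_min) || !is.finite(energy_max))
    stop_config("config: thresholds must be finite")
  pattern <- as.character(pattern)
  if (length(pattern) != 3L ||
      !all(tolower(pattern) %in% c("up", "down", "ns")))
    stop_config("config: pattern must be 3 statuses from Up/Down/NS")
  structure(list(simulation = simulation, alpha = alpha,
                 cor_threshold = cor_threshold, score_min = score_min,
                 energy_max = energy_max, pattern = pattern,
                 min_mean = min_mean),
            class = "pipeline_config")
}

#' Read and validate a pipeline configuration file
#'
#' Accepts YAML or JSON with the keys of [pipeline_config()] (stage
#' thresholds, optional `simulation` block). Unknown keys are rejected;
#' missing keys take their defaults.
#'
#' @param path configuration file.
#' @return a validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(raw) || length(raw) == 0L)
    stop_config("config file %s is empty or not a mapping", path)
  allowed <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop_config("unknown config key(s): %s", paste(unknown, collapse = ", "))
  sim_args <- raw$simulation %||% list()
  sim_allowed <- names(formals(simulation_config))
  sim_unknown <- setdiff(names(sim_args), sim_allowed)
  if (length(sim_unknown))
    stop_config("unknown simulation key(s): %s",
                paste(sim_unknown, collapse = ", "))
  raw$simulation <- do.call(simulation_config, sim_args)
  do.call(pipeline_config, raw)
}

#' Run the ceRNA inference pipeline on a dataset
#'
#' Executes every stage in order on a synthetic dataset (generated from
#' `config$simulation` unless `dataset` is supplied): lncRNA discovery,
#' per-kind differential expression, FPKM/TPM + log10(x+1) normalization,
#' miRNA site scanning over lncRNA transcripts and mRNA scan regions, pair
#' inference, tripartite network assembly, the three restrictions, and term
#' enrichment of the final network genes. In synthetic mode the summary
#' additionally scores recall and false discovery against the planted truth.
#'
#' @param config a [pipeline_config()].
#' @param dataset optional pre-generated `cerna_dataset` (defaults to
#'   `generate_dataset(config$simulation)`).
#' @return list with `summary` (per-stage counts, thresholds, recall/FDR),
#'   `de` (per-kind DE tables), `hits`, `pairs`, `network`, `triples`
#'   (enumerated), `selected` (post-restriction triples), `enrichment`,
#'   `discovery`, and `dataset`.
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(dataset)) dataset <- generate_dataset(config$simulation)

  # --- stage 1: lncRNA discovery ---------------------------------------
  mrna_models <- transcript_models(
    transcript_id = dataset$mrna$transcript_id,
    gene_id = dataset$mrna$gene_id,
    chrom = dataset$mrna$chrom, strand = dataset$mrna$strand,
    coverage = 100, samples_detected = nrow(dataset$samples),
    exons = lapply(seq_len(nrow(dataset$mrna)), function(i)
      cbind(start = dataset$mrna$start[i], end = dataset$mrna$end[i])))
  discovery <- discover_lncrnas(dataset$transcripts, mrna_models,
                                dataset$known_noncoding_ids,
                                dataset$known_coding_ids)
  lnc_ids <- discovery$transcript_id[discovery$label == "noncoding"]

  # --- stage 2: differential expression --------------------------------
  group <- dataset$samples$group
  de <- list(
    mrna = de_test(dataset$counts$mrna, group, alpha = config$alpha),
    lncrna = de_test(dataset$counts$lncrna[lnc_ids, , drop = FALSE], group,
                     alpha = config$alpha),
    mirna = de_test(dataset$counts$mirna, group, alpha = config$alpha))
  de$mrna$gene_name <- dataset$mrna$gene_name[
    match(de$mrna$feature_id, dataset$mrna$gene_id)]

  # --- stage 3: normalized expression ----------------------------------
  lnc_len <- transcript_length(dataset$transcripts)[
    match(lnc_ids, dataset$transcripts$transcript_id)]
  expr_mrna <- log_normalize(compute_fpkm_tpm(
    dataset$counts$mrna, dataset$mrna$length)$fpkm)
  expr_lnc <- log_normalize(compute_fpkm_tpm(
    dataset$counts$lncrna[lnc_ids, , drop = FALSE], lnc_len)$fpkm)
  expr_mir <- log_normalize(compute_fpkm_tpm(
    dataset$counts$mirna,
    rep(config$simulation$mirna_length, nrow(dataset$counts$mirna)))$tpm)

  # --- stage 4: miRNA target scanning ----------------------------------
  mirnas <- setNames(dataset$mirna$sequence, dataset$mirna$mirna_id)
  lnc_regions <- lapply(lnc_ids, function(id) {
    list(host_id = id, kind = "lncrna",
         sequence = dataset$transcripts$sequence[
           match(id, dataset$transcripts$transcript_id)])
  })
  mrna_regions <- lapply(seq_len(nrow(dataset$mrna)), function(i)
    extract_scan_region(dataset$mrna[i, ]))
  hits_lnc <- scan_all(mirnas, lnc_regions, config$score_min,
                       config$energy_max)
  hits_mrna <- scan_all(mirnas, mrna_regions, config$score_min,
                        config$energy_max)

  # --- stage 5: pair inference -----------------------------------------
  pairs <- list(
    trans = trans_lnc_mrna_pairs(expr_lnc, expr_mrna, config$cor_threshold),
    lnc_mi = lnc_mirna_pairs(expr_lnc, expr_mir, hits_lnc,
                             config$cor_threshold),
    mi_mrna = mirna_mrna_pairs(expr_mir, expr_mrna, hits_mrna,
                               config$cor_threshold))

  # --- stage 6: network assembly and restrictions ----------------------
  network <- build_network(pairs$lnc_mi, pairs$mi_mrna, de)
  triples <- enumerate_triples(network)
  sf_all <- lapply(dataset$counts, size_factors)
  expr_means <- do.call(rbind, lapply(names(dataset$counts), function(kind) {
    counts <- dataset$counts[[kind]]
    norm <- sweep(counts, 2L, sf_all[[kind]], "/")
    data.frame(feature_id = rownames(counts),
               mean_case = rowMeans(norm[, group == "case", drop = FALSE]),
               mean_control = rowMeans(norm[, group == "control",
                                            drop = FALSE]),
               stringsAsFactors = FALSE)
  }))
  selected <- apply_restrictions(triples, dataset$disease_genes, expr_means,
                                 config$alpha, config$pattern,
                                 config$min_mean)

  # --- stage 7: enrichment over final network genes --------------------
  study_genes <- unique(selected$gene_name)
  enrichment <- if (length(study_genes)) {
    enrich_all(study_genes, unique(dataset$mrna$gene_name), dataset$terms,
               config$alpha)
  } else NULL

  summary <- list(
    thresholds = config[c("alpha", "cor_threshold", "score_min",
                          "energy_max", "min_mean")],
    pattern = config$pattern,
    seed = config$simulation$seed,
    stages = list(
      transcripts_in = nrow(dataset$transcripts),
      lncrna_candidates = nrow(discovery),
      lncrnas = length(lnc_ids),
      de_mrna = sum(de$mrna$status != "NS"),
      de_lncrna = sum(de$lncrna$status != "NS"),
      de_mirna = sum(de$mirna$status != "NS"),
      binding_sites_lnc = nrow(hits_lnc),
      binding_sites_mrna = nrow(hits_mrna),
      trans_pairs = nrow(pairs$trans),
      lnc_mi_pairs = nrow(pairs$lnc_mi),
      mi_mrna_pairs = nrow(pairs$mi_mrna),
      triples_enumerated = nrow(triples),
      triples_selected = nrow(selected),
      enriched_terms = if (is.null(enrichment)) 0L
        else sum(enrichment$significant)))
  summary$truth_scores <- score_against_truth(selected,
                                              rbind(hits_lnc, hits_mrna),
                                              dataset$truth)

  list(summary = summary, discovery = discovery, de = de,
       hits = rbind(hits_lnc, hits_mrna), pairs = pairs, network = network,
       triples = triples, selected = selected, enrichment = enrichment,
       expr_means = expr_means, dataset = dataset)
}

# recall / FDR of selected triples and recall of planted binding sites
score_against_truth <- function(selected, hits, truth) {
  key <- function(df) paste(df$lncrna_id, df$mirna_id, df$mrna_id)
  planted <- truth$planted_triples
  n_planted <- nrow(planted)
  recall <- if (n_planted) sum(key(planted) %in% key(selected)) / n_planted
    else NA_real_
  fdr <- if (nrow(selected)) mean(!(key(selected) %in% key(planted))) else 0
  ps <- truth$planted_binding_sites
  site_found <- if (nrow(ps)) vapply(seq_len(nrow(ps)), function(i) {
    any(hits$mirna_id == ps$mirna_id[i] & hits$host_id == ps$host_id[i] &
          hits$start <= ps$position[i] &
          hits$end >= ps$position[i])
  }, TRUE) else logical(0)
  list(n_planted = n_planted, n_selected = nrow(selected),
       recall = recall, fdr = fdr,
       site_recall = if (length(site_found)) mean(site_found) else NA_real_)
}

#' Write pipeline outputs to a directory
#'
#' Flat TSV tables per stage plus a JSON run summary; the network is written
#' both as an edge list and as GraphML.
#'
#' @param result output of [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_stage_table(result$discovery, p("lncrna_candidates.tsv"))
  for (kind in names(result$de))
    write_stage_table(result$de[[kind]], p(paste0("de_", kind, ".tsv")))
  write_stage_table(result$hits, p("binding_sites.tsv"))
  for (kind in names(result$pairs))
    write_stage_table(result$pairs[[kind]], p(paste0("pairs_", kind, ".tsv")))
  write_stage_table(result$triples, p("triples_enumerated.tsv"))
  write_stage_table(result$selected, p("triples_selected.tsv"))
  if (!is.null(result$enrichment))
    write_stage_table(result$enrichment, p("enrichment.tsv"))
  export_network(result$network, p("network_edges.tsv"), "edgelist")
  export_network(result$network, p("network.graphml"), "graphml")
  jsonlite::write_json(result$summary, p("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
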