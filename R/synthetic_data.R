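# Synthetic ceRNA study generator. Emulates the data-generating process the
# pipeline assumes: a small two-group RNA-seq design (3 case vs 3 control by
# default) with negative-binomial counts, a panel of mRNAs with 3'UTRs, a
# panel of multi-exon lncRNA transcript models satisfying the discovery
# filter, miRNAs, and planted up/down/up ceRNA triples whose lncRNA and mRNA
# each carry an exact-complement binding site for the triple's miRNA.

#' Simulation configuration
#'
#' Validated parameter set for [generate_dataset()]. Defaults define the
#' reference study conditions: a 3-vs-3 design, planted |log2 fold change|
#' of 2 (lncRNA and mRNA up, miRNA down), NB dispersion 0.01, baseline mean
#' 150 counts, 300-nt 3'UTRs and 22-nt miRNAs.
#'
#' @param n_mrna,n_lncrna,n_mirna panel sizes (>= 1). Defaults keep planted
#'   members a small minority of each panel, as median-of-ratios
#'   normalization assumes.
#' @param n_samples_per_group replicates per group (default 3).
#' @param n_planted_triples number of planted ceRNA triples (>= 0, at most
#'   min(n_lncrna, n_mrna)).
#' @param lfc_lncrna,lfc_mrna planted case-vs-control log2 fold changes
#'   (> 0) for lncRNA and mRNA members.
#' @param lfc_mirna planted log2 fold change for miRNA members (< 0).
#' @param dispersion NB dispersion alpha >= 0 (variance = m + alpha m^2).
#' @param mean_expression baseline mean count scale (> 0); per-feature
#'   baselines are drawn log-normally around it (sdlog 0.4).
#' @param sponge_sd standard deviation (log2) of the per-sample latent
#'   miRNA activity coupling planted triple members: within every sample a
#'   planted miRNA fluctuates by 2^u and its bound lncRNA/mRNA by 2^-u,
#'   emulating miRNA-mediated repression and sponging on top of the group
#'   shift (0 disables the coupling).
#' @param utr_length mRNA 3'UTR length in nt.
#' @param mirna_length miRNA length in nt (default 22).
#' @param seed RNG seed making the dataset fully reproducible.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_mrna = 80L, n_lncrna = 30L, n_mirna = 40L,
                              n_samples_per_group = 3L,
                              n_planted_triples = 5L,
                              lfc_lncrna = 2, lfc_mrna = 2, lfc_mirna = -2,
                              dispersion = 0.01, mean_expression = 150,
                              sponge_sd = 0.4,
                              utr_length = 300L, mirna_length = 22L,
                              seed = 1L) {
  cfg <- list(n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
              n_mirna = as.integer(n_mirna),
              n_samples_per_group = as.integer(n_samples_per_group),
              n_planted_triples = as.integer(n_planted_triples),
              lfc_lncrna = lfc_lncrna, lfc_mrna = lfc_mrna,
              lfc_mirna = lfc_mirna, dispersion = dispersion,
              mean_expression = mean_expression, sponge_sd = sponge_sd,
              utr_length = as.integer(utr_length),
              mirna_length = as.integer(mirna_length),
              seed = as.integer(seed))
  for (f in c("n_mrna", "n_lncrna", "n_mirna", "n_samples_per_group",
              "utr_length", "mirna_length"))
    if (!is_count(cfg[[f]])) stop_config("config: %s must be a count >= 1", f)
  if (!is_count(cfg$n_planted_triples, min = 0L))
    stop_config("config: n_planted_triples must be a count >= 0")
  if (cfg$n_planted_triples > min(cfg$n_lncrna, cfg$n_mrna))
    stop_config("config: n_planted_triples exceeds min(n_lncrna, n_mrna) = %d",
                min(cfg$n_lncrna, cfg$n_mrna))
  if (!(cfg$lfc_lncrna > 0)) stop_config("config: lfc_lncrna must be > 0")
  if (!(cfg$lfc_mrna > 0)) stop_config("config: lfc_mrna must be > 0")
  if (!(cfg$lfc_mirna < 0)) stop_config("config: lfc_mirna must be < 0")
  if (!(cfg$dispersion >= 0)) stop_config("config: dispersion must be >= 0")
  if (!(cfg$mean_expression > 0))
    stop_config("config: mean_expression must be > 0")
  if (!(cfg$sponge_sd >= 0)) stop_config("config: sponge_sd must be >= 0")
  structure(cfg, class = "simulation_config")
}

#' Draw negative-binomial counts
#'
#' Samples n integers with mean m = mean * size_factor and variance
#' m + dispersion * m^2; dispersion = 0 degenerates to Poisson.
#'
#' @param mean positive baseline mean.
#' @param dispersion NB dispersion alpha >= 0.
#' @param size_factor positive per-sample scaling (default 1).
#' @param n number of draws.
#' @param seed optional seed set before drawing.
#' @return integer vector of length n.
#' @export
simulate_nb_counts <- function(mean, dispersion, size_factor = 1, n,
                               seed = NULL) {
  if (!is.finite(mean) || mean <= 0) stop_config("mean must be positive")
  if (!is.finite(dispersion) || dispersion < 0)
    stop_config("dispersion must be >= 0")
  if (!is.finite(size_factor) || size_factor <= 0)
    stop_config("size_factor must be positive")
  if (!is.null(seed)) set.seed(seed)
  mu <- mean * size_factor
  if (dispersion == 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# an open reading frame of `n_codons` sense codons framed by ATG .. TAA
random_cds <- function(n_codons) {
  bases <- c("A", "C", "G", "T")
  codons <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cd <- paste(sample(bases, 3L, replace = TRUE), collapse = "")
      if (!cd %in% c("TAA", "TAG", "TGA")) break
    }
    codons[i] <- cd
  }
  paste0("ATG", paste(codons, collapse = ""), "TAA")
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    chartr("U", "T", seq))))
}

insert_site <- function(host, site, pos) {
  # pos: 0-based start of the site within the returned sequence
  paste0(substr(host, 1L, pos), site,
         substr(host, pos + nchar(site) + 1L, nchar(host)))
}

# split a spliced length into k exon intervals separated by random introns
make_exons <- function(total_len, n_exons, offset) {
  cuts <- sort(sample(seq_len(total_len - 1L), n_exons - 1L))
  sizes <- diff(c(0L, cuts, total_len))
  starts <- integer(n_exons)
  pos <- offset
  ex <- matrix(0L, n_exons, 2L)
  for (i in seq_len(n_exons)) {
    ex[i, 1L] <- pos
    ex[i, 2L] <- pos + sizes[i]
    pos <- ex[i, 2L] + sample(200:2000, 1L)
  }
  colnames(ex) <- c("start", "end")
  ex
}

# draw counts from a per-sample mean matrix scaled by size factors
sim_count_matrix <- function(mu_matrix, sf, dispersion) {
  n_feat <- nrow(mu_matrix)
  m <- matrix(0L, n_feat, length(sf))
  for (j in seq_along(sf)) {
    mu <- mu_matrix[, j] * sf[j]
    m[, j] <- as.integer(if (dispersion == 0) {
      rpois(n_feat, mu)
    } else {
      rnbinom(n_feat, mu = mu, size = 1 / dispersion)
    })
  }
  m
}

#' Generate a complete synthetic ceRNA study
#'
#' Produces annotations (GTF-representable transcript models), sequences,
#' count matrices and ground truth under `config`. Planted triples place an
#' exact reverse-complement copy of the triple's miRNA into the lncRNA
#' transcript and the mRNA 3'UTR, and shift the members' group means to
#' mean * 2^(+-lfc/2) so the realized log2 fold change equals the configured
#' value. Generated lncRNAs are constructed to satisfy the discovery filter
#' (>= 2 exons, coverage >= 3, length >= 200, detected in > 1 sample) and to
#' be called noncoding by the ORF screen; a handful of decoy transcript
#' models violating each criterion exercise the filter. All output is fully
#' reproducible given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return object of class `cerna_dataset`: list with `config`, `samples`,
#'   `transcripts` (lncRNA candidates + decoys), `mrna`, `mirna`, `counts`
#'   (matrices `mrna`, `lncrna`, `mirna`), `known_noncoding_ids`,
#'   `known_coding_ids`, `truth` (planted_triples, planted_binding_sites,
#'   de_members), `terms` and `disease_genes`.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, as.list(config))
  set.seed(config$seed)
  n_samples <- 2L * config$n_samples_per_group
  samples <- data.frame(
    sample_id = c(paste0("case_", seq_len(config$n_samples_per_group)),
                  paste0("control_", seq_len(config$n_samples_per_group))),
    group = rep(c("case", "control"), each = config$n_samples_per_group),
    stringsAsFactors = FALSE)
  samples$true_size_factor <- exp(runif(n_samples, log(0.7), log(1.4)))

  # --- miRNAs -----------------------------------------------------------
  mirna_ids <- sprintf("mir_%03d", seq_len(config$n_mirna))
  mirna_seq <- vapply(mirna_ids, function(i) random_seq(config$mirna_length),
                      "")
  mirna <- data.frame(mirna_id = mirna_ids, sequence = unname(mirna_seq),
                      stringsAsFactors = FALSE)

  # --- planted assignments ---------------------------------------------
  npl <- config$n_planted_triples
  planted <- if (npl > 0) data.frame(
    lncrna_id = sprintf("lnc_%03d", seq_len(npl)),
    mirna_id = mirna_ids[(seq_len(npl) - 1L) %% config$n_mirna + 1L],
    mrna_id = sprintf("gene_%03d", seq_len(npl)),
    stringsAsFactors = FALSE) else
    data.frame(lncrna_id = character(), mirna_id = character(),
               mrna_id = character(), stringsAsFactors = FALSE)

  sites <- list()
  add_site <- function(mirna_id, host_id, position) {
    sites[[length(sites) + 1L]] <<- data.frame(
      mirna_id = mirna_id, host_id = host_id, position = position,
      stringsAsFactors = FALSE)
  }

  # --- mRNA gene models -------------------------------------------------
  mrna_ids <- sprintf("gene_%03d", seq_len(config$n_mrna))
  gene_names <- sprintf("GENE%03d", seq_len(config$n_mrna))
  has_utr <- rep(TRUE, config$n_mrna)
  if (config$n_mrna > npl) {
    # a fifth of non-planted genes lack an annotated UTR and use the
    # downstream-of-stop fallback
    no_utr <- seq(npl + 1L, config$n_mrna)
    no_utr <- no_utr[seq_along(no_utr) %% 5L == 0L]
    has_utr[no_utr] <- FALSE
  }
  cds_seq <- vapply(seq_len(config$n_mrna),
                    function(i) random_cds(sample(80:150, 1L)), "")
  utr3_seq <- rep(NA_character_, config$n_mrna)
  downstream_seq <- rep(NA_character_, config$n_mrna)
  for (i in seq_len(config$n_mrna)) {
    if (has_utr[i]) utr3_seq[i] <- random_seq(config$utr_length)
    else downstream_seq[i] <- random_seq(1200L)
  }
  for (t in seq_len(nrow(planted))) {
    g <- match(planted$mrna_id[t], mrna_ids)
    site <- reverse_complement(mirna_seq[planted$mirna_id[t]])
    pos <- sample.int(config$utr_length - nchar(site), 1L) - 1L
    utr3_seq[g] <- insert_site(utr3_seq[g], site, pos)
    add_site(planted$mirna_id[t], planted$mrna_id[t], pos)
  }
  mrna_len <- nchar(cds_seq) + ifelse(has_utr, nchar(utr3_seq), 0L)
  mrna <- data.frame(gene_id = mrna_ids,
                     transcript_id = paste0(mrna_ids, "_t1"),
                     gene_name = gene_names,
                     chrom = "chr1",
                     start = seq_len(config$n_mrna) * 10000L,
                     strand = "+",
                     length = mrna_len,
                     cds_seq = cds_seq, utr3_seq = utr3_seq,
                     downstream_seq = downstream_seq,
                     stringsAsFactors = FALSE)
  mrna$end <- mrna$start + mrna$length

  # --- lncRNA transcript models ----------------------------------------
  lnc_ids <- sprintf("lnc_%03d", seq_len(config$n_lncrna))
  lnc_rows <- vector("list", config$n_lncrna)
  for (i in seq_len(config$n_lncrna)) {
    id <- lnc_ids[i]
    total_len <- sample(350:800, 1L)
    t_idx <- if (npl > 0) match(id, planted$lncrna_id) else NA_integer_
    repeat {
      seq <- random_seq(total_len)
      pos <- NA_integer_
      if (!is.na(t_idx)) {
        site <- reverse_complement(mirna_seq[planted$mirna_id[t_idx]])
        pos <- sample.int(total_len - nchar(site), 1L) - 1L
        seq <- insert_site(seq, site, pos)
      }
      if (assess_coding_potential(seq)$label == "noncoding") break
    }
    if (!is.na(t_idx)) add_site(planted$mirna_id[t_idx], id, pos)
    n_exons <- sample(2:4, 1L)
    # the last two lncRNAs sit antisense inside an mRNA gene span; the rest
    # are intergenic on their own chromosome
    antisense <- i > config$n_lncrna - 2L && i <= config$n_mrna
    if (antisense) {
      chrom <- "chr1"
      offset <- mrna$start[i] + 10L
      strand <- "-"
    } else {
      chrom <- "chr2"
      offset <- i * 50000L
      strand <- "+"
    }
    lnc_rows[[i]] <- list(
      transcript_id = id, gene_id = paste0("XLOC_", id), chrom = chrom,
      strand = strand, coverage = round(runif(1, 5, 50), 2),
      samples_detected = sample(2:n_samples, 1L),
      exons = make_exons(total_len, n_exons, offset), sequence = seq)
  }

  # --- decoy transcripts exercising each discovery criterion ------------
  decoys <- list(
    list(transcript_id = "decoy_single_exon", fail = "exons",
         n_exons = 1L, len = 1500L, cov = 50, det = 4L),
    list(transcript_id = "decoy_short", fail = "length",
         n_exons = 2L, len = 150L, cov = 20, det = 4L),
    list(transcript_id = "decoy_low_cov", fail = "coverage",
         n_exons = 2L, len = 600L, cov = 1, det = 4L),
    list(transcript_id = "decoy_one_sample", fail = "samples",
         n_exons = 3L, len = 600L, cov = 20, det = 1L),
    list(transcript_id = "decoy_known_coding", fail = "annotation",
         n_exons = 3L, len = 600L, cov = 20, det = 4L))
  decoy_rows <- lapply(seq_along(decoys), function(i) {
    d <- decoys[[i]]
    list(transcript_id = d$transcript_id,
         gene_id = paste0("XLOC_", d$transcript_id), chrom = "chr3",
         strand = "+", coverage = d$cov,
         samples_detected = min(d$det, n_samples),
         exons = make_exons(d$len, d$n_exons, i * 20000L),
         sequence = random_seq(d$len))
  })

  all_rows <- c(lnc_rows, decoy_rows)
  transcripts <- transcript_models(
    transcript_id = vapply(all_rows, `[[`, "", "transcript_id"),
    gene_id = vapply(all_rows, `[[`, "", "gene_id"),
    chrom = vapply(all_rows, `[[`, "", "chrom"),
    strand = vapply(all_rows, `[[`, "", "strand"),
    coverage = vapply(all_rows, function(r) as.numeric(r$coverage), 0),
    samples_detected = vapply(all_rows, function(r)
      as.integer(r$samples_detected), 0L),
    exons = lapply(all_rows, `[[`, "exons"),
    sequence = vapply(all_rows, `[[`, "", "sequence"))

  known_coding_ids <- "decoy_known_coding"
  # two of the generated lncRNAs are treated as annotated known lncRNAs
  known_noncoding_ids <- utils::tail(lnc_ids, 2L)

  # --- counts -----------------------------------------------------------
  sf <- samples$true_size_factor
  group <- samples$group
  # group-mean matrices: planted members sit at mean * 2^(+-lfc/2) so the
  # realized log2 fold change equals the configured value
  plant_means <- function(ids, planted_ids, lfc) {
    mu0 <- rlnorm(length(ids), log(config$mean_expression), 0.4)
    shift <- ids %in% planted_ids
    m <- matrix(rep(mu0, n_samples), ncol = n_samples,
                dimnames = list(ids, samples$sample_id))
    m[shift, group == "case"] <- mu0[shift] * 2^(lfc / 2)
    m[shift, group == "control"] <- mu0[shift] * 2^(-lfc / 2)
    m
  }
  mu_mrna <- plant_means(mrna_ids, planted$mrna_id, config$lfc_mrna)
  mu_lnc <- plant_means(lnc_ids, planted$lncrna_id, config$lfc_lncrna)
  mu_mir <- plant_means(mirna_ids, unique(planted$mirna_id), config$lfc_mirna)
  # latent per-sample miRNA activity couples each planted triple: the miRNA
  # fluctuates by 2^u within a sample while its sponged/repressed hosts move
  # by 2^-u, the within-sample signature of miRNA-mediated repression
  if (config$sponge_sd > 0 && nrow(planted) > 0) {
    for (m_id in unique(planted$mirna_id)) {
      u <- stats::rnorm(n_samples, 0, config$sponge_sd)
      mu_mir[m_id, ] <- mu_mir[m_id, ] * 2^u
      hosts <- planted[planted$mirna_id == m_id, ]
      for (l_id in unique(hosts$lncrna_id))
        mu_lnc[l_id, ] <- mu_lnc[l_id, ] * 2^(-u)
      for (g_id in unique(hosts$mrna_id))
        mu_mrna[g_id, ] <- mu_mrna[g_id, ] * 2^(-u)
    }
  }
  counts <- list(
    mrna = sim_count_matrix(mu_mrna, sf, config$dispersion),
    lncrna = sim_count_matrix(mu_lnc, sf, config$dispersion),
    mirna = sim_count_matrix(mu_mir, sf, config$dispersion))
  dimnames(counts$mrna) <- list(mrna_ids, samples$sample_id)
  dimnames(counts$lncrna) <- list(lnc_ids, samples$sample_id)
  dimnames(counts$mirna) <- list(mirna_ids, samples$sample_id)

  # --- ground truth, annotation terms, disease genes --------------------
  planted_sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(mirna_id = character(), host_id = character(),
               position = integer(), stringsAsFactors = FALSE)
  planted$gene_name <- gene_names[match(planted$mrna_id, mrna_ids)]
  truth <- list(planted_triples = planted,
                planted_binding_sites = planted_sites,
                de_members = unique(c(planted$lncrna_id, planted$mirna_id,
                                      planted$mrna_id)))

  planted_genes <- unique(planted$gene_name)
  other_genes <- setdiff(gene_names, planted_genes)
  term_rows <- list(data.frame(
    term_id = "TERM:0001", term_name = "disease-associated process",
    gene_id = unique(c(planted_genes,
                       head(other_genes, min(5L, length(other_genes))))),
    stringsAsFactors = FALSE))
  for (t in 2:8) {
    sz <- min(length(gene_names), sample(5:15, 1L))
    term_rows[[t]] <- data.frame(
      term_id = sprintf("TERM:%04d", t),
      term_name = sprintf("background process %d", t),
      gene_id = sample(gene_names, sz), stringsAsFactors = FALSE)
  }
  terms <- do.call(rbind, term_rows)
  disease_genes <- unique(c(planted_genes,
                            head(other_genes, min(4L, length(other_genes)))))

  structure(list(config = config, samples = samples,
                 transcripts = transcripts, mrna = mrna, mirna = mirna,
                 counts = counts,
                 known_noncoding_ids = known_noncoding_ids,
                 known_coding_ids = known_coding_ids,
                 truth = truth, terms = terms,
                 disease_genes = disease_genes),
            class = "cerna_dataset")
}

#' @export
print.cerna_dataset <- function(x, ...) {
  cat("synthetic ceRNA dataset:", x$config$n_mrna, "mRNAs,",
      x$config$n_lncrna, "lncRNAs,", x$config$n_mirna, "miRNAs,",
      nrow(x$samples), "samples,", nrow(x$truth$planted_triples),
      "planted triples\n")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Serializes every component in plain formats: GTF transcript models, FASTA
#' sequences (transcripts, 3'UTRs, downstream regions, miRNAs; U as T), TSV
#' count matrices and sample sheet, JSON ground truth and YAML config.
#'
#' @param dataset a `cerna_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_transcript_gtf(dataset$transcripts, p("transcripts.gtf"))
  write_fasta(setNames(dataset$transcripts$sequence,
                       dataset$transcripts$transcript_id),
              p("transcripts.fa"))
  write_fasta(setNames(dataset$mirna$sequence, dataset$mirna$mirna_id),
              p("mirna.fa"))
  utr <- dataset$mrna[!is.na(dataset$mrna$utr3_seq), ]
  write_fasta(setNames(utr$utr3_seq, utr$gene_id), p("utr3.fa"))
  down <- dataset$mrna[!is.na(dataset$mrna$downstream_seq), ]
  if (nrow(down))
    write_fasta(setNames(down$downstream_seq, down$gene_id),
                p("downstream.fa"))
  ann <- dataset$mrna[, c("gene_id", "transcript_id", "gene_name", "chrom",
                          "start", "end", "strand", "length")]
  ann$has_utr3 <- !is.na(dataset$mrna$utr3_seq)
  write_stage_table(ann, p("mrna_annotation.tsv"))
  writeLines(dataset$known_noncoding_ids, p("known_noncoding.txt"))
  writeLines(dataset$known_coding_ids, p("known_coding.txt"))
  write_count_matrix(dataset$counts$mrna, p("counts_mrna.tsv"))
  write_count_matrix(dataset$counts$lncrna, p("counts_lncrna.tsv"))
  write_count_matrix(dataset$counts$mirna, p("counts_mirna.tsv"))
  write_sample_sheet(dataset$samples[, c("sample_id", "group")],
                     p("samples.tsv"))
  write_stage_table(dataset$terms, p("terms.tsv"))
  writeLines(dataset$disease_genes, p("disease_genes.txt"))
  jsonlite::write_json(dataset$truth, p("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(unclass(dataset$config), p("config.yaml"))
  invisible(dir)
}
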