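# Generator contracts: configuration validation, NB noise moments,
# reproducibility, and the structural guarantees planted datasets make to
# the downstream stages.

test_that("invalid configurations are rejected with the violated bound named", {
  expect_error(simulation_config(n_mrna = 0), "n_mrna")
  expect_error(simulation_config(n_planted_triples = -1), "n_planted_triples")
  expect_error(simulation_config(n_lncrna = 3, n_mrna = 10,
                                 n_planted_triples = 4),
               "n_planted_triples")
  expect_error(simulation_config(lfc_lncrna = -1), "lfc_lncrna")
  expect_error(simulation_config(lfc_mirna = 1), "lfc_mirna")
  expect_error(simulation_config(dispersion = -0.1), "dispersion")
  expect_error(simulation_config(mean_expression = 0), "mean_expression")
})

test_that("NB draws match their closed-form moments", {
  # Poisson limit: variance approximately equals the mean
  x <- simulate_nb_counts(mean = 5, dispersion = 0, n = 1e4, seed = 42)
  se_var <- stats::sd((x - mean(x))^2) / sqrt(length(x))
  expect_lt(abs(stats::var(x) - mean(x)), 3 * se_var)

  # overdispersed: mean 100, variance 100 + 0.1 * 100^2 = 1100
  y <- simulate_nb_counts(mean = 100, dispersion = 0.1, n = 1e4, seed = 43)
  se_mean <- stats::sd(y) / sqrt(length(y))
  expect_lt(abs(mean(y) - 100), 3 * se_mean)
  se_var_y <- stats::sd((y - mean(y))^2) / sqrt(length(y))
  expect_lt(abs(stats::var(y) - 1100), 3 * se_var_y)

  # size factors scale the mean
  z <- simulate_nb_counts(mean = 50, dispersion = 0.05, size_factor = 2,
                          n = 1e4, seed = 44)
  expect_lt(abs(mean(z) - 100), 3 * stats::sd(z) / sqrt(length(z)))

  expect_error(simulate_nb_counts(mean = 0, dispersion = 0, n = 10), "mean")
  expect_error(simulate_nb_counts(mean = -3, dispersion = 0, n = 10), "mean")
})

small_cfg <- function(seed = 5, ...) {
  args <- utils::modifyList(list(n_mrna = 15L, n_lncrna = 8L, n_mirna = 6L,
                                 n_planted_triples = 2L, seed = seed),
                            list(...))
  do.call(simulation_config, args)
}

test_that("identical seeds give byte-identical datasets", {
  d1 <- generate_dataset(small_cfg(seed = 7))
  d2 <- generate_dataset(small_cfg(seed = 7))
  expect_identical(d1, d2)
  d3 <- generate_dataset(small_cfg(seed = 8))
  expect_false(identical(d1$counts$mrna, d3$counts$mrna))
})

test_that("dataset structure honours the configuration", {
  ds <- generate_dataset(small_cfg())
  # a 3-vs-3 design gives six sample columns in every count matrix
  for (m in ds$counts) expect_equal(ncol(m), 6L)
  expect_equal(nrow(ds$counts$mrna), 15L)
  expect_equal(nrow(ds$counts$lncrna), 8L)
  expect_equal(nrow(ds$counts$mirna), 6L)
  # nothing planted -> empty truth
  ds0 <- generate_dataset(small_cfg(n_planted_triples = 0L))
  expect_equal(nrow(ds0$truth$planted_triples), 0L)
  expect_equal(nrow(ds0$truth$planted_binding_sites), 0L)
  # truth ids resolve in the generated panels
  expect_true(all(ds$truth$planted_triples$lncrna_id %in%
                    rownames(ds$counts$lncrna)))
  expect_true(all(ds$truth$planted_triples$mirna_id %in%
                    rownames(ds$counts$mirna)))
  expect_true(all(ds$truth$planted_triples$mrna_id %in%
                    rownames(ds$counts$mrna)))
  # every planted triple member carries a recorded binding site
  sites <- ds$truth$planted_binding_sites
  for (i in seq_len(nrow(ds$truth$planted_triples))) {
    tr <- ds$truth$planted_triples[i, ]
    expect_true(any(sites$mirna_id == tr$mirna_id &
                      sites$host_id == tr$lncrna_id))
    expect_true(any(sites$mirna_id == tr$mirna_id &
                      sites$host_id == tr$mrna_id))
  }
})

test_that("generated lncRNAs all survive the discovery filter; decoys do not", {
  ds <- generate_dataset(small_cfg())
  kept <- filter_candidates(ds$transcripts, ds$known_noncoding_ids,
                            ds$known_coding_ids)
  lnc_ids <- rownames(ds$counts$lncrna)
  expect_true(all(lnc_ids %in% kept$transcript_id))
  expect_false(any(grepl("^decoy_", kept$transcript_id)))
  # and they are all called noncoding by the ORF screen
  disc <- discover_lncrnas(ds$transcripts, ds$transcripts[0, ],
                           ds$known_noncoding_ids, ds$known_coding_ids)
  expect_true(all(disc$label[disc$transcript_id %in% lnc_ids] == "noncoding"))
})

test_that("planted binding sites are exact reverse complements at the recorded position", {
  ds <- generate_dataset(small_cfg())
  sites <- ds$truth$planted_binding_sites
  for (i in seq_len(nrow(sites))) {
    mir_seq <- ds$mirna$sequence[ds$mirna$mirna_id == sites$mirna_id[i]]
    expected <- revcomp_dna(mir_seq)
    host <- sites$host_id[i]
    host_seq <- if (host %in% ds$transcripts$transcript_id) {
      ds$transcripts$sequence[ds$transcripts$transcript_id == host]
    } else {
      ds$mrna$utr3_seq[ds$mrna$gene_id == host]
    }
    found <- substr(host_seq, sites$position[i] + 1L,
                    sites$position[i] + nchar(expected))
    expect_identical(found, expected)
  }
})

test_that("datasets round-trip through their on-disk formats", {
  ds <- generate_dataset(small_cfg())
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  cnt <- read_count_matrix(file.path(dir, "counts_mrna.tsv"))
  expect_identical(cnt, ds$counts$mrna)
  sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
  expect_identical(sheet$sample_id, ds$samples$sample_id)
  tr <- read_transcript_gtf(file.path(dir, "transcripts.gtf"),
                            file.path(dir, "transcripts.fa"))
  i <- match(ds$transcripts$transcript_id, tr$transcript_id)
  expect_false(anyNA(i))
  expect_identical(tr$sequence[i], ds$transcripts$sequence)
  expect_equal(tr$coverage[i], ds$transcripts$coverage)
  expect_identical(unname(lapply(tr$exons[i], unname)),
                   unname(lapply(ds$transcripts$exons, unname)))
  fa <- read_fasta(file.path(dir, "mirna.fa"))
  expect_identical(unname(fa[ds$mirna$mirna_id]),
                   chartr("U", "T", ds$mirna$sequence))
})
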