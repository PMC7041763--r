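# Candidate filtering, the ORF coding-potential screen against a brute-force
# enumeration oracle, and biotype classification on toy coordinates.

test_that("each discovery criterion excludes its violating transcript", {
  set.seed(101)
  cases <- list(
    list(tr = make_toy_transcript("single_exon", n_exons = 1L, len = 1500L,
                                  coverage = 50), keep = FALSE),
    list(tr = make_toy_transcript("short", n_exons = 2L, len = 199L),
         keep = FALSE),
    list(tr = make_toy_transcript("len200", n_exons = 2L, len = 200L),
         keep = TRUE),
    list(tr = make_toy_transcript("low_cov", coverage = 2.9), keep = FALSE),
    list(tr = make_toy_transcript("cov3", coverage = 3), keep = TRUE),
    list(tr = make_toy_transcript("one_sample", samples = 1L), keep = FALSE),
    list(tr = make_toy_transcript("ok", n_exons = 3L, len = 500L),
         keep = TRUE))
  all_tr <- do.call(rbind, lapply(cases, `[[`, "tr"))
  class(all_tr) <- c("transcript_models", "data.frame")
  kept <- filter_candidates(all_tr)
  for (cs in cases) {
    expect_equal(cs$tr$transcript_id %in% kept$transcript_id, cs$keep,
                 info = cs$tr$transcript_id)
  }
  # known-coding ids are dropped even when structurally fine; known
  # noncoding ids are labelled annotated
  kept2 <- filter_candidates(all_tr, known_noncoding_ids = "ok",
                             known_coding_ids = "len200")
  expect_false("len200" %in% kept2$transcript_id)
  expect_equal(kept2$annotation[kept2$transcript_id == "ok"], "annotated")
  expect_equal(kept2$annotation[kept2$transcript_id == "cov3"], "novel")
})

test_that("filtering is idempotent, order-independent, and empty-safe", {
  set.seed(102)
  trs <- do.call(rbind, lapply(1:6, function(i)
    make_toy_transcript(paste0("t", i), n_exons = sample(1:3, 1),
                        len = sample(c(150L, 400L), 1),
                        coverage = sample(c(1, 10), 1))))
  class(trs) <- c("transcript_models", "data.frame")
  once <- filter_candidates(trs)
  twice <- filter_candidates(once[, names(trs)])
  expect_identical(sort(once$transcript_id), sort(twice$transcript_id))
  shuffled <- trs[sample(nrow(trs)), ]
  expect_identical(sort(filter_candidates(shuffled)$transcript_id),
                   sort(once$transcript_id))
  empty <- filter_candidates(trs[0, ])
  expect_equal(nrow(empty), 0L)
  # malformed exons are reported with the transcript id
  bad <- trs
  bad$exons[[2]] <- matrix(c(10L, 5L), 1L)
  expect_error(filter_candidates(bad), "t2")
})

test_that("ORF screen finds the longest start-to-stop frame", {
  # no start codon anywhere -> no ORF
  no_atg <- paste(rep("C", 300), collapse = "")
  res <- assess_coding_potential(no_atg)
  expect_equal(res$longest_orf_nt, 0L)
  expect_equal(res$label, "noncoding")

  # an exact 100-codon ORF (300 nt including the stop) tips the length rule
  set.seed(103)
  sense <- replicate(98, {
    repeat {
      cd <- paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = "")
      if (!cd %in% c("TAA", "TAG", "TGA") && cd != "ATG") break
    }
    cd
  })
  orf <- paste0("ATG", paste(sense, collapse = ""), "TAA")
  flank <- paste(rep("C", 60), collapse = "")
  seq <- paste0(flank, orf, flank)
  res <- assess_coding_potential(seq)
  expect_equal(res$longest_orf_nt, 300L)
  expect_equal(res$label, "coding")

  # coverage rule: a 120-nt ORF in a 200-nt transcript covers 0.6 >= 0.5
  orf120 <- paste0("ATG", paste(sense[1:38], collapse = ""), "TAA")
  seq2 <- paste0(paste(rep("C", 50), collapse = ""), orf120,
                 paste(rep("C", 200 - 50 - 120), collapse = ""))
  res2 <- assess_coding_potential(seq2)
  expect_equal(res2$longest_orf_nt, 120L)
  expect_equal(res2$label, "coding")

  expect_error(assess_coding_potential("ACGTXX"), "nucleotide")
  expect_error(assess_coding_potential(paste(rep("A", 100), collapse = "")),
               "200")
})

test_that("ORF screen agrees with exhaustive enumeration on random sequences", {
  set.seed(104)
  for (i in 1:100) {
    seq <- paste(sample(c("A", "C", "G", "T"), 250, TRUE), collapse = "")
    res <- assess_coding_potential(seq)
    expect_equal(res$longest_orf_nt, oracle_longest_orf(seq), info = seq)
  }
})

test_that("biotype is antisense only for opposite-strand overlap", {
  set.seed(105)
  gene_plus <- make_toy_transcript("gene1", n_exons = 1L, len = 5000L,
                                  coverage = 100, chrom = "chr9",
                                  strand = "+")
  # candidate fully inside the gene span on the - strand
  inside <- make_toy_transcript("cand_as", n_exons = 2L, len = 400L,
                                chrom = "chr9", strand = "-")
  inside$exons[[1]] <- cbind(start = c(100L, 700L), end = c(300L, 900L))
  inside$sequence <- paste(rep("A", 400), collapse = "")
  expect_equal(classify_biotype(inside, gene_plus), "antisense")
  # same strand only -> lincRNA
  inside_same <- inside
  inside_same$strand <- "+"
  expect_equal(classify_biotype(inside_same, gene_plus), "lincRNA")
  # far away -> lincRNA
  far <- inside
  far$exons[[1]] <- cbind(start = c(1e6L, 1000600L), end = c(1000200L, 1000800L))
  expect_equal(classify_biotype(far, gene_plus), "lincRNA")
  # different chromosome -> lincRNA
  other <- inside
  other$chrom <- "chr10"
  expect_equal(classify_biotype(other, gene_plus), "lincRNA")
})
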