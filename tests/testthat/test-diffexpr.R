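# Normalization, dispersion, the conditional NB exact test against its
# binomial-split enumeration oracle, BH adjustment against the brute-force
# step-up, status calls, FPKM/TPM arithmetic and sample clustering.

test_that("median-of-ratios size factors have the expected symmetries", {
  # all columns identical -> all factors 1
  eq <- matrix(rep(c(10L, 30L), 3), nrow = 2,
               dimnames = list(c("a", "b"), paste0("s", 1:3)))
  expect_equal(unname(size_factors(eq)), c(1, 1, 1))
  # hand-computed 2-feature toy: second sample doubled -> factor ratio 2
  toy <- matrix(c(10L, 30L, 20L, 60L), nrow = 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
  sf_toy <- size_factors(toy)
  expect_equal(unname(sf_toy[2] / sf_toy[1]), 2)
  # scale equivariance: multiplying one sample by 3 multiplies the factor
  # ratio by 3 (the geometric-mean reference absorbs a c^(1/n) share, so the
  # individual factor moves by 3^((n-1)/n); only ratios are equivariant)
  sc <- toy; sc[, 2] <- sc[, 2] * 3L
  sf_sc <- size_factors(sc)
  expect_equal(unname((sf_sc[2] / sf_sc[1]) / (sf_toy[2] / sf_toy[1])), 3)
  expect_equal(unname(size_factors(sc)[2] / sf_toy[2]), 3^(1 / 2))
  # no all-positive feature -> informative error
  zeros <- matrix(c(0L, 5L, 5L, 0L), nrow = 2)
  expect_error(size_factors(zeros), "positive")
})

test_that("moments dispersion inverts the NB variance relation", {
  grp <- rep(c("case", "control"), each = 3)
  # constant counts -> estimate at the floor
  const <- matrix(50L, 2, 6)
  expect_equal(unname(estimate_dispersion(const, rep(1, 6), grp)),
               rep(1e-8, 2))
  # within-group values {60,100,140}: pooled s2 = 1600, mean 100 -> 0.15
  m <- matrix(rep(c(60, 100, 140), 2), nrow = 1)
  expect_equal(unname(estimate_dispersion(m, rep(1, 6), grp)),
               (1600 - 100) / 100^2)
  # mean 100, variance 1100 -> alpha 0.1
  a <- sqrt(1100)
  m2 <- matrix(rep(100 + c(-a, 0, a), 2), nrow = 1)
  expect_equal(unname(estimate_dispersion(m2, rep(1, 6), grp)), 0.1)
  # Poisson data: median estimate near zero
  set.seed(21)
  pois <- matrix(rpois(6 * 5000, 100), ncol = 6)
  disp <- estimate_dispersion(pois, rep(1, 6), grp)
  expect_lte(median(disp), 0.01)
})

test_that("exact test equals binomial-split enumeration at zero dispersion", {
  set.seed(22)
  sf <- exp(runif(6, log(0.7), log(1.4)))
  for (i in 1:25) {
    T_tot <- sample(0:50, 1)
    k <- if (T_tot > 0) as.vector(stats::rmultinom(1, T_tot, rep(1, 6))) else
      rep(0L, 6)
    p_impl <- nb_exact_test(k[1:3], k[4:6], sf[1:3], sf[4:6], alpha = 0)
    p_oracle <- oracle_exact_binomial(k[1:3], k[4:6], sf[1:3], sf[4:6])
    expect_equal(p_impl, p_oracle, tolerance = 1e-10)
  }
  # symmetric observation with equal effective sizes is the mode -> p = 1
  expect_equal(nb_exact_test(c(5, 5, 5), c(5, 5, 5), rep(1, 3), rep(1, 3),
                             alpha = 0), 1)
  expect_equal(nb_exact_test(c(10, 10, 10), c(10, 10, 10), rep(1, 3),
                             rep(1, 3), alpha = 0.1), 1)
  # all-zero feature -> p = 1
  expect_equal(nb_exact_test(c(0, 0, 0), c(0, 0, 0), rep(1, 3), rep(1, 3),
                             alpha = 0.5), 1)
})

test_that("BH adjustment matches the brute-force step-up everywhere", {
  expect_equal(bh_adjust(0.03), 0.03)                     # m = 1
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.1, -0.2)), "\\[0, 1\\]")
  set.seed(23)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"))
  }
})

test_that("status calls follow sign and significance", {
  expect_equal(call_status(-2.4656, 0.0000157), "Down")
  expect_equal(call_status(3.5766, 0.0000101), "Up")
  expect_equal(call_status(1.4, 0.5), "NS")
  expect_warning(st <- call_status(0, 0.001), "zero fold change")
  expect_equal(st, "NS")
  expect_equal(call_status(c(1, -1, 2), c(0.01, 0.01, 0.9)),
               c("Up", "Down", "NS"))
})

test_that("log10(x + 1) transform hits its anchor points", {
  expect_equal(log_normalize(0), 0)
  expect_equal(log_normalize(99), 2)
  expect_equal(log_normalize(9), 1)
  expect_error(log_normalize(-1), "non-negative")
})

test_that("FPKM/TPM normalization follows rate arithmetic", {
  single <- matrix(c(7L, 13L), 1, 2,
                   dimnames = list("f1", c("s1", "s2")))
  tpm1 <- compute_fpkm_tpm(single, 500)$tpm
  expect_equal(unname(tpm1[1, ]), c(1e6, 1e6))
  two <- matrix(c(10L, 10L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  res <- compute_fpkm_tpm(two, c(100, 200))
  expect_equal(unname(res$tpm[1, 1] / res$tpm[2, 1]), 2)
  expect_equal(unname(colSums(res$tpm)), 1e6)
  doubled <- compute_fpkm_tpm(two * 2L, c(100, 200))
  expect_equal(res$tpm, doubled$tpm)
  expect_error(compute_fpkm_tpm(two, c(0, 200)), "positive")
  expect_error(compute_fpkm_tpm(two * 0L, c(100, 200)), "library")
})

test_that("sample clustering uses Euclidean complete linkage", {
  m <- matrix(c(1, 1, 5), nrow = 1, dimnames = list("f", c("a", "b", "c")))
  # identical samples a, b merge first at height 0
  hc <- hierarchical_cluster(rbind(m, m))
  expect_equal(hc$height[1], 0)
  # mutual distances 1, 1, 2: first merge at height 1
  line <- matrix(c(0, 1, -1), nrow = 1,
                 dimnames = list("f", c("a", "b", "c")))
  hc2 <- hierarchical_cluster(line)
  expect_equal(hc2$height[1], 1)
  expect_equal(max(hc2$height), 2)  # complete linkage takes the far pair
  # distances invariant under feature permutation
  set.seed(24)
  mm <- matrix(rnorm(30), 5, 6)
  colnames(mm) <- paste0("s", 1:6); rownames(mm) <- paste0("f", 1:5)
  h1 <- hierarchical_cluster(mm)
  h2 <- hierarchical_cluster(mm[sample(5), ])
  expect_equal(h1$height, h2$height)
  expect_equal(h1$merge, h2$merge)
  bad <- mm; bad[1, 1] <- NaN
  expect_error(hierarchical_cluster(bad), "finite")
})

test_that("de_test recovers planted shifts and controls direction", {
  set.seed(25)
  n <- 200
  mu <- rep(100, n)
  cnt <- sapply(1:6, function(j) rpois(n, mu))
  # plant 10 up, 10 down features at 4-fold
  cnt[1:10, 1:3] <- rpois(30, 400)
  cnt[11:20, 4:6] <- rpois(30, 400)
  rownames(cnt) <- paste0("f", 1:n); colnames(cnt) <- paste0("s", 1:6)
  de <- de_test(cnt, rep(c("case", "control"), each = 3))
  expect_true(all(de$status[1:10] == "Up"))
  expect_true(all(de$status[11:20] == "Down"))
  expect_lt(mean(de$status[21:n] != "NS"), 0.1)
  expect_equal(de$q_value, bh_adjust(de$p_value))
})
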