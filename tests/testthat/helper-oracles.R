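# Independent brute-force oracles. Each recomputes a quantity by direct
# enumeration or a closed form, never through the implementation under test.

# -- step-up FDR adjustment, literal sorted-scan form -------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# -- longest ORF by enumerating every ATG and scanning for its stop -----------
oracle_longest_orf <- function(seq) {
  chars <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  n <- length(chars)
  best <- 0L
  codon_at <- function(i) paste(chars[i:(i + 2L)], collapse = "")
  for (start in seq_len(max(0L, n - 2L))) {
    if (codon_at(start) != "ATG") next
    i <- start
    while (i + 2L <= n) {
      if (codon_at(i) %in% c("TAA", "TAG", "TGA")) {
        best <- max(best, i + 2L - start + 1L)
        break
      }
      i <- i + 3L
    }
  }
  best
}

# -- local duplex alignment by enumerating every monotone pairing -------------
# Columns are substitution positions; residues between consecutive columns
# become contiguous affine gap runs (one run per sequence per interval, which
# is always optimal under affine costs).
oracle_align_score <- function(mirna, target, params = duplex_params()) {
  code <- function(s) {
    x <- match(strsplit(chartr("Uu", "Tt", toupper(s)), "")[[1]],
               c("A", "C", "G", "T"))
    x[is.na(x)] <- 5L
    x
  }
  subst <- function(a, b) {
    if (a > 4L || b > 4L) return(params$mismatch)
    s <- a + b
    if (s == 5L) return(params$match)       # 1-based codes: A=1,C=2,G=3,T=4
    if (s == 7L) return(params$wobble)      # G:T
    params$mismatch
  }
  mir <- rev(code(mirna))                   # process 3'->5'
  L <- length(mir)
  w <- rep(1, L)
  w[L + 1 - (params$seed_from:min(L, params$seed_to))] <- params$seed_weight
  tgt <- code(target)
  n <- length(mir); m <- length(tgt)
  gap_run <- function(len) {
    if (len <= 0) 0 else params$gap_open + (len - 1) * params$gap_extend
  }
  best <- 0
  for (k in seq_len(min(n, m))) {
    I <- utils::combn(n, k)
    J <- utils::combn(m, k)
    for (ci in seq_len(ncol(I))) {
      ii <- I[, ci]
      for (cj in seq_len(ncol(J))) {
        jj <- J[, cj]
        sc <- sum(vapply(seq_len(k), function(c)
          w[ii[c]] * subst(mir[ii[c]], tgt[jj[c]]), 0))
        if (k > 1) {
          di <- diff(ii) - 1L
          dj <- diff(jj) - 1L
          sc <- sc + sum(vapply(di, gap_run, 0)) +
            sum(vapply(dj, gap_run, 0))
        }
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# -- upper-tail hypergeometric by direct pmf summation ------------------------
oracle_hypergeom <- function(k, K, n, N) {
  xs <- max(0, n - (N - K)):min(K, n)
  pmf <- vapply(xs, function(x)
    choose(K, x) * choose(N - K, n - x) / choose(N, n), 0)
  sum(pmf[xs >= k])
}

# -- Wallenius upper tail by dynamic programming over sequential draws --------
oracle_wallenius <- function(k, m1, m2, n, omega) {
  # prob[x1+1, x2+1] = probability of having drawn x1 term and x2 other genes
  prob <- matrix(0, m1 + 1, m2 + 1)
  prob[1, 1] <- 1
  for (draw in seq_len(n)) {
    nxt <- matrix(0, m1 + 1, m2 + 1)
    for (x1 in 0:min(draw - 1, m1)) {
      x2 <- draw - 1 - x1
      if (x2 > m2 || prob[x1 + 1, x2 + 1] == 0) next
      w_term <- omega * (m1 - x1)
      w_other <- m2 - x2
      tot <- w_term + w_other
      if (w_term > 0)
        nxt[x1 + 2, x2 + 1] <- nxt[x1 + 2, x2 + 1] +
          prob[x1 + 1, x2 + 1] * w_term / tot
      if (w_other > 0)
        nxt[x1 + 1, x2 + 2] <- nxt[x1 + 1, x2 + 2] +
          prob[x1 + 1, x2 + 1] * w_other / tot
    }
    prob <- nxt
  }
  total <- 0
  for (x1 in 0:min(n, m1)) {
    x2 <- n - x1
    if (x2 >= 0 && x2 <= m2 && x1 >= k) total <- total + prob[x1 + 1, x2 + 1]
  }
  total
}

# -- conditional exact test at dispersion zero via the binomial split ---------
oracle_exact_binomial <- function(k_case, k_control, sf_case, sf_control) {
  T_tot <- sum(k_case) + sum(k_control)
  if (T_tot == 0) return(1)
  pr <- sum(sf_case) / (sum(sf_case) + sum(sf_control))
  pa <- dbinom(0:T_tot, T_tot, pr)
  obs <- pa[sum(k_case) + 1]
  min(1, sum(pa[pa <= obs * (1 + 1e-7)]))
}

# -- ceRNA triples by triple loop over typed nodes ----------------------------
oracle_triples <- function(lnc_ids, mi_ids, mrna_ids, lnc_mi, mi_mrna) {
  has_edge <- function(df, a, b) any(df$source_id == a & df$target_id == b)
  out <- list()
  for (l in lnc_ids) for (m in mi_ids) for (g in mrna_ids) {
    if (has_edge(lnc_mi, l, m) && has_edge(mi_mrna, m, g))
      out[[length(out) + 1]] <- c(l, m, g)
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, paste, "", collapse = "|"))
}

# -- shared small fixtures ----------------------------------------------------
make_toy_transcript <- function(id = "t1", n_exons = 2L, len = 400L,
                                coverage = 10, samples = 3L, chrom = "chrT",
                                strand = "+", sequence = NULL) {
  sizes <- rep(len %/% n_exons, n_exons)
  sizes[n_exons] <- sizes[n_exons] + len %% n_exons
  starts <- cumsum(c(0L, sizes[-n_exons] + 500L))
  ex <- cbind(start = starts, end = starts + sizes)
  if (is.null(sequence))
    sequence <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  transcript_models(transcript_id = id, gene_id = paste0("g_", id),
                    chrom = chrom, strand = strand, coverage = coverage,
                    samples_detected = samples, exons = list(ex),
                    sequence = sequence)
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, TRUE), collapse = "")
}

revcomp_dna <- function(s) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(chartr("U", "T", s))))
}
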