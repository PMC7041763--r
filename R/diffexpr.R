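# Differential expression for small replicate designs: median-of-ratios
# normalization, per-feature method-of-moments NB dispersion, a conditional
# negative-binomial exact test on group sums, BH correction, and Up/Down
# status calls. Also houses the FPKM/TPM + log10(x+1) normalizations and
# Euclidean complete-linkage sample clustering used for expression overviews.

DISPERSION_FLOOR <- 1e-8

#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median, over features positive
#' in every sample, of the ratio of the sample's count to the feature's
#' geometric mean across samples. Scale-equivariant: multiplying one sample's
#' counts by c multiplies its factor by c.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop_config(paste("no feature has positive counts in every sample;",
                      "supply a pseudo-reference or prefilter"))
  sub <- counts[pos, , drop = FALSE]
  geo <- exp(rowMeans(log(sub)))
  apply(sub, 2L, function(cj) median(cj / geo))
}

#' Per-feature method-of-moments NB dispersion
#'
#' On size-factor-normalized counts, the within-group pooled variance s^2 and
#' overall mean m give alpha = max(0, (s^2 - m) / m^2), floored at 1e-8.
#' No shrinkage or mean-dispersion fitting is applied.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param factors size factors from [size_factors()].
#' @param group per-sample labels (two levels).
#' @return numeric vector of dispersions, one per feature.
#' @export
estimate_dispersion <- function(counts, factors, group) {
  stopifnot(ncol(counts) == length(factors), length(group) == length(factors))
  norm <- sweep(counts, 2L, factors, "/")
  levels <- unique(group)
  ss <- 0
  df <- 0
  for (g in levels) {
    sub <- norm[, group == g, drop = FALSE]
    if (ncol(sub) > 1L) {
      mg <- rowMeans(sub)
      ss <- ss + rowSums((sub - mg)^2)
      df <- df + (ncol(sub) - 1L)
    }
  }
  if (df == 0L)
    stop_config("dispersion estimation needs replicates in >= 1 group")
  s2 <- ss / df
  m <- rowMeans(norm)
  alpha <- (s2 - m) / m^2
  alpha[!is.finite(alpha)] <- 0
  pmax(alpha, DISPERSION_FLOOR)
}

#' Conditional negative-binomial exact test
#'
#' Tests equality of expression between two groups for one feature. Under
#' the null the feature has a common normalized mean q, estimated as
#' T / (S_case + S_control) from the total T of both group sums, with S_g
#' the sum of the group's size factors. Each group sum is modelled as
#' negative binomial with mean q * S_g and variance equal to the sum of the
#' per-sample NB variances (m_j + alpha * m_j^2, m_j = q * s_j). The
#' two-sided p-value sums the probabilities of all splits (a, T - a) no more
#' probable than the observed one, normalized by the total over all splits.
#' alpha = 0 degenerates to the Poisson/binomial split.
#'
#' @param k_case,k_control per-sample counts for the feature.
#' @param sf_case,sf_control per-sample size factors, same order.
#' @param alpha NB dispersion (>= 0).
#' @return two-sided p-value; T = 0 returns 1.
#' @export
nb_exact_test <- function(k_case, k_control, sf_case, sf_control, alpha) {
  stopifnot(length(k_case) == length(sf_case),
            length(k_control) == length(sf_control),
            alpha >= 0)
  K_case <- sum(k_case)
  T_tot <- K_case + sum(k_control)
  if (T_tot == 0) return(1)
  S_case <- sum(sf_case)
  S_ctrl <- sum(sf_control)
  q <- T_tot / (S_case + S_ctrl)
  a <- 0:T_tot
  if (alpha < DISPERSION_FLOOR) {
    lp <- dpois(a, q * S_case, log = TRUE) +
      dpois(T_tot - a, q * S_ctrl, log = TRUE)
  } else {
    # sum of per-sample NBs: mean q*S_g, variance sum_j (m_j + alpha m_j^2),
    # so the group-sum size parameter is S_g^2 / (alpha * sum_j s_j^2)
    size_case <- S_case^2 / (alpha * sum(sf_case^2))
    size_ctrl <- S_ctrl^2 / (alpha * sum(sf_control^2))
    lp <- dnbinom(a, mu = q * S_case, size = size_case, log = TRUE) +
      dnbinom(T_tot - a, mu = q * S_ctrl, size = size_ctrl, log = TRUE)
  }
  p <- exp(lp - max(lp))
  # tolerance absorbs floating ties between symmetric splits
  min(1, sum(p[p <= p[K_case + 1L] * (1 + 1e-7)]) / sum(p))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: for sorted p-values, q_(i) = min over j >= i of
#' p_(j) * m / j, capped at 1, returned in the input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric())
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop_config("p-values must lie in [0, 1]")
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(p_values[o] * m / (m:1)))
  q[ro]
}

#' Call Up/Down/NS status from fold change and q-value
#'
#' Up when q < alpha and log2 fold change > 0; Down when q < alpha and the
#' fold change is negative; NS otherwise. A significant feature with exactly
#' zero fold change is NS with a warning (direction tie).
#'
#' @param log2_fold_change numeric vector.
#' @param q_value numeric vector of BH-adjusted p-values.
#' @param alpha significance threshold (default 0.05).
#' @return character vector in {"Up", "Down", "NS"}.
#' @export
call_status <- function(log2_fold_change, q_value, alpha = 0.05) {
  stopifnot(length(log2_fold_change) == length(q_value))
  status <- rep("NS", length(q_value))
  sig <- q_value < alpha
  status[sig & log2_fold_change > 0] <- "Up"
  status[sig & log2_fold_change < 0] <- "Down"
  if (any(sig & log2_fold_change == 0))
    warning("significant feature(s) with zero fold change called NS",
            call. = FALSE)
  status
}

#' Differential expression over a count matrix
#'
#' Composes [size_factors()], [estimate_dispersion()], [nb_exact_test()],
#' [bh_adjust()] and [call_status()] into a per-feature DE table for a
#' two-group design.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param group per-sample labels; `case_level` names the case group.
#' @param case_level,control_level group labels (defaults "case"/"control").
#' @param alpha significance threshold for the status call.
#' @return data.frame: feature_id, base_mean_case, base_mean_control,
#'   log2_fold_change, p_value, q_value, status.
#' @export
de_test <- function(counts, group, case_level = "case",
                    control_level = "control", alpha = 0.05) {
  stopifnot(is.matrix(counts), ncol(counts) == length(group))
  if (!all(c(case_level, control_level) %in% group))
    stop_config("both groups must be present among samples")
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, sf, group)
  norm <- sweep(counts, 2L, sf, "/")
  is_case <- group == case_level
  is_ctrl <- group == control_level
  m_case <- rowMeans(norm[, is_case, drop = FALSE])
  m_ctrl <- rowMeans(norm[, is_ctrl, drop = FALSE])
  p <- vapply(seq_len(nrow(counts)), function(i) {
    nb_exact_test(counts[i, is_case], counts[i, is_ctrl],
                  sf[is_case], sf[is_ctrl], disp[i])
  }, 0)
  q <- bh_adjust(p)
  lfc <- log2((m_case + DISPERSION_FLOOR) / (m_ctrl + DISPERSION_FLOOR))
  data.frame(feature_id = rownames(counts) %||% as.character(seq_len(nrow(counts))),
             base_mean_case = m_case,
             base_mean_control = m_ctrl,
             log2_fold_change = lfc,
             p_value = p,
             q_value = q,
             status = call_status(lfc, q, alpha),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' log10(x + 1) expression transform
#'
#' The normalization applied to FPKM and TPM values before clustering and
#' correlation: defined (and zero) at x = 0.
#'
#' @param x non-negative expression values.
#' @return log10(x + 1).
#' @export
log_normalize <- function(x) {
  if (any(x < 0, na.rm = TRUE))
    stop_config("expression values must be non-negative")
  log10(x + 1)
}

#' FPKM and TPM from counts and feature lengths
#'
#' FPKM_ij = counts_ij * 1e9 / (length_i * libsize_j); TPM rescales the
#' per-kilobase rate so each sample sums to 1e6.
#'
#' @param counts non-negative matrix, features x samples.
#' @param lengths positive feature lengths (nt), one per row.
#' @return list with matrices `fpkm` and `tpm`.
#' @export
compute_fpkm_tpm <- function(counts, lengths) {
  stopifnot(is.matrix(counts), length(lengths) == nrow(counts))
  if (any(lengths <= 0)) stop_config("feature lengths must be positive")
  lib <- colSums(counts)
  if (any(lib == 0)) stop_config("zero library size in sample(s)")
  fpkm <- sweep(counts / lengths, 2L, lib, "/") * 1e9
  rate <- counts / lengths
  tpm <- sweep(rate, 2L, colSums(rate), "/") * 1e6
  list(fpkm = fpkm, tpm = tpm)
}

#' Hierarchical clustering of samples by expression profile
#'
#' Agglomerative complete-linkage clustering on pairwise Euclidean distances
#' between sample columns; hclust's deterministic merge order breaks ties by
#' sample position.
#'
#' @param matrix normalized expression matrix, features x samples (>= 2).
#' @return an [stats::hclust] object.
#' @export
hierarchical_cluster <- function(matrix) {
  stopifnot(is.matrix(matrix), ncol(matrix) >= 2L)
  if (any(!is.finite(matrix)))
    stop_config("expression matrix contains non-finite values")
  hclust(dist(t(matrix), method = "euclidean"), method = "complete")
}
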