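# Pair inference: Pearson co-expression thresholding combined with predicted
# binding sites to call lncRNA-mRNA trans relations, miRNA-mRNA regulatory
# pairs, and lncRNA-miRNA target/decoy relations. All correlations are meant
# to be computed on log-normalized expression (log10(x + 1) of FPKM/TPM).

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()]: equal-length vectors of at
#' least 3 samples with non-zero variance on both sides.
#'
#' @param x,y numeric vectors.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop_config("correlation needs equal-length vectors of >= 3 samples")
  if (var(x) == 0 || var(y) == 0)
    stop_config("correlation undefined: zero variance")
  cor(x, y, method = "pearson")
}

# correlation matrix between rows of two expression matrices sharing samples
cor_matrix <- function(a, b) {
  if (!identical(colnames(a), colnames(b)))
    stop_config("expression matrices must share identical sample columns")
  cor(t(a), t(b), method = "pearson")
}

empty_pairs <- function() {
  data.frame(source_id = character(), target_id = character(),
             relation = character(), r = numeric(), n_sites = integer(),
             stringsAsFactors = FALSE)
}

#' Trans lncRNA-mRNA co-expression pairs
#'
#' All (lncRNA, mRNA) pairs whose Pearson correlation across shared samples
#' exceeds the threshold in absolute value (strict inequality).
#'
#' @param lnc_expr,mrna_expr log-normalized expression matrices
#'   (features x samples) with identical sample columns.
#' @param threshold absolute-correlation cutoff (default 0.8).
#' @return pair data.frame: source_id (lncRNA), target_id (mRNA),
#'   relation = "trans_lnc_mrna", r, n_sites = 0.
#' @export
trans_lnc_mrna_pairs <- function(lnc_expr, mrna_expr, threshold = 0.8) {
  r <- cor_matrix(lnc_expr, mrna_expr)
  idx <- which(abs(r) > threshold & is.finite(r), arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty_pairs())
  out <- data.frame(source_id = rownames(r)[idx[, 1L]],
                    target_id = colnames(r)[idx[, 2L]],
                    relation = "trans_lnc_mrna",
                    r = r[idx], n_sites = 0L, stringsAsFactors = FALSE)
  out[order(out$source_id, out$target_id), , drop = FALSE]
}

count_sites <- function(hits, mirna_id, host_id) {
  sum(hits$mirna_id == mirna_id & hits$host_id == host_id)
}

#' miRNA-mRNA regulatory pairs
#'
#' Pairs supported by at least one predicted binding site and a strong
#' expression correlation (r > threshold or r < -threshold).
#'
#' @param mirna_expr,mrna_expr log-normalized expression matrices with
#'   identical sample columns.
#' @param hits binding-site table from [scan_all()] (mirna_id, host_id, ...);
#'   host ids refer to mRNA features.
#' @param threshold correlation magnitude cutoff (default 0.8, strict).
#' @return pair data.frame with relation = "mirna_mrna" and per-pair
#'   supporting site counts.
#' @export
mirna_mrna_pairs <- function(mirna_expr, mrna_expr, hits, threshold = 0.8) {
  if (nrow(hits) == 0L) return(empty_pairs())
  cand <- unique(hits[, c("mirna_id", "host_id")])
  cand <- cand[cand$mirna_id %in% rownames(mirna_expr) &
                 cand$host_id %in% rownames(mrna_expr), , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_pairs())
  r <- cor_matrix(mirna_expr, mrna_expr)
  out <- lapply(seq_len(nrow(cand)), function(i) {
    ri <- r[cand$mirna_id[i], cand$host_id[i]]
    if (!is.finite(ri) || abs(ri) <= threshold) return(NULL)
    data.frame(source_id = cand$mirna_id[i], target_id = cand$host_id[i],
               relation = "mirna_mrna", r = ri,
               n_sites = count_sites(hits, cand$mirna_id[i], cand$host_id[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_pairs())
  out <- out[order(out$source_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a binding-supported lncRNA-miRNA relation
#'
#' With no predicted site the relation is `"none"`. With at least one site:
#' `lnc_mirna_target` when the lncRNA-miRNA correlation is strongly negative
#' (r < -threshold, the miRNA represses the lncRNA), otherwise
#' `lnc_mirna_decoy` (the lncRNA sponges the miRNA without being degraded,
#' including positive co-expression). Both classes enter the ceRNA network
#' identically downstream.
#'
#' @param lnc,mirna feature ids.
#' @param hits binding-site table (host ids refer to lncRNAs).
#' @param r Pearson correlation of the pair on shared samples.
#' @param threshold correlation magnitude convention (default 0.8).
#' @return one of "lnc_mirna_target", "lnc_mirna_decoy", "none".
#' @export
classify_lnc_mirna <- function(lnc, mirna, hits, r, threshold = 0.8) {
  n <- count_sites(hits, mirna, lnc)
  if (n == 0L) return("none")
  if (is.finite(r) && r < -threshold) "lnc_mirna_target" else "lnc_mirna_decoy"
}

#' lncRNA-miRNA pairs from binding sites and correlation
#'
#' Applies [classify_lnc_mirna()] to every binding-supported (lncRNA, miRNA)
#' combination.
#'
#' @param lnc_expr,mirna_expr log-normalized expression matrices with
#'   identical sample columns.
#' @param hits binding-site table; host ids refer to lncRNA features.
#' @param threshold correlation magnitude convention (default 0.8).
#' @return pair data.frame: source_id (lncRNA), target_id (miRNA), relation
#'   ("lnc_mirna_target" or "lnc_mirna_decoy"), r, n_sites.
#' @export
lnc_mirna_pairs <- function(lnc_expr, mirna_expr, hits, threshold = 0.8) {
  if (nrow(hits) == 0L) return(empty_pairs())
  cand <- unique(hits[, c("mirna_id", "host_id")])
  cand <- cand[cand$mirna_id %in% rownames(mirna_expr) &
                 cand$host_id %in% rownames(lnc_expr), , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_pairs())
  r <- cor_matrix(lnc_expr, mirna_expr)
  out <- lapply(seq_len(nrow(cand)), function(i) {
    ri <- r[cand$host_id[i], cand$mirna_id[i]]
    rel <- classify_lnc_mirna(cand$host_id[i], cand$mirna_id[i], hits, ri,
                              threshold)
    if (rel == "none") return(NULL)
    data.frame(source_id = cand$host_id[i], target_id = cand$mirna_id[i],
               relation = rel, r = ri,
               n_sites = count_sites(hits, cand$mirna_id[i], cand$host_id[i]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty_pairs())
  out <- out[order(out$source_id, out$target_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
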