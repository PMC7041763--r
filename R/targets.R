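# miRNA binding-site prediction: seed-weighted local complementarity
# alignment (C++ core), nearest-neighbor duplex free energy from a shipped
# stacking table, and a sliding-window scanner applying the score > 140 and
# dG <= -10 kcal/mol acceptance thresholds.

#' Default duplex-alignment scoring parameters
#'
#' Watson-Crick pair +5, G:U wobble +2, mismatch -3, gap open -8, gap
#' extend -2; substitution scores at miRNA seed positions 2-8 (from the 5'
#' end) are doubled. Under this scheme a perfect 22-nt duplex scores
#' 22*5 + 7*5 = 145, so the acceptance threshold of score > 140 admits only
#' perfect or near-perfect seed-paired duplexes and is unreachable by chance
#' short complementarity.
#'
#' @return named list of scoring parameters.
#' @export
duplex_params <- function() {
  list(match = 5, wobble = 2, mismatch = -3,
       gap_open = -8, gap_extend = -2,
       seed_from = 2L, seed_to = 8L, seed_weight = 2)
}

DUPLEX_INITIATION_DG <- 4.09
INTERIOR_UNPAIRED_DG <- 0.5

encode_nt <- function(sequence) {
  x <- chartr("Uu", "Tt", toupper(sequence))
  codes <- match(strsplit(x, "", fixed = TRUE)[[1L]],
                 c("A", "C", "G", "T"))
  codes[is.na(codes)] <- 5L
  codes - 1L
}

seed_weights <- function(n, params) {
  w <- rep(1, n)
  lo <- max(1L, params$seed_from)
  hi <- min(n, params$seed_to)
  if (lo <= hi) w[lo:hi] <- params$seed_weight
  w
}

#' Align a miRNA against a target window
#'
#' Best local alignment of the miRNA (antiparallel, so processed 3'->5')
#' against the target window (5'->3') under [duplex_params()]: Watson-Crick
#' and G:U wobble pairs score positively, mismatches and affine gaps
#' negatively, and miRNA seed positions 2-8 carry doubled substitution
#' scores. T and U are interchangeable.
#'
#' @param mirna miRNA sequence, written 5'->3'.
#' @param window target subsequence, written 5'->3'.
#' @param params scoring parameters, see [duplex_params()].
#' @return list: `score`; `alignment` (three strings: miRNA 3'->5', match
#'   line with `|` for Watson-Crick and `:` for wobble, target 5'->3');
#'   `mirna_start`/`mirna_end` (1-based, 5'->3' miRNA coordinates);
#'   `target_start`/`target_end` (0-based half-open window coordinates).
#' @export
align_duplex <- function(mirna, window, params = duplex_params()) {
  mirna <- check_nucleotide(mirna, "miRNA sequence")
  window <- check_nucleotide(window, "target window")
  mi <- encode_nt(mirna)
  tg <- encode_nt(window)
  L <- length(mi)
  w_rev <- rev(seed_weights(L, params))
  res <- cpp_align_traceback(rev(mi), tg, w_rev,
                             params$match, params$wobble, params$mismatch,
                             params$gap_open, params$gap_extend)
  mir_rev_chars <- rev(strsplit(chartr("T", "U", toupper(mirna)),
                                "", fixed = TRUE)[[1L]])
  tgt_chars <- strsplit(toupper(window), "", fixed = TRUE)[[1L]]
  ops <- res$ops
  mi_pos <- res$mi_start
  tg_pos <- res$tgt_start
  top <- character(length(ops))
  mid <- character(length(ops))
  bot <- character(length(ops))
  for (k in seq_along(ops)) {
    if (ops[k] == 0L) {
      a <- mir_rev_chars[mi_pos]
      b <- tgt_chars[tg_pos]
      top[k] <- a
      bot[k] <- b
      mid[k] <- pair_symbol(a, b)
      mi_pos <- mi_pos + 1L
      tg_pos <- tg_pos + 1L
    } else if (ops[k] == 1L) {
      top[k] <- mir_rev_chars[mi_pos]
      bot[k] <- "-"
      mid[k] <- " "
      mi_pos <- mi_pos + 1L
    } else {
      top[k] <- "-"
      bot[k] <- tgt_chars[tg_pos]
      mid[k] <- " "
      tg_pos <- tg_pos + 1L
    }
  }
  # reversed-miRNA index r corresponds to 5'->3' position L + 1 - r
  list(score = res$score,
       alignment = c(mirna_3to5 = paste(top, collapse = ""),
                     match = paste(mid, collapse = ""),
                     target_5to3 = paste(bot, collapse = "")),
       mirna_start = if (length(ops)) L + 1L - res$mi_end else NA_integer_,
       mirna_end = if (length(ops)) L + 1L - res$mi_start else NA_integer_,
       target_start = res$tgt_start - 1L,
       target_end = res$tgt_end)
}

pair_symbol <- function(mi_char, tgt_char) {
  a <- chartr("T", "U", mi_char)
  b <- chartr("T", "U", tgt_char)
  wc <- c(A = "U", U = "A", C = "G", G = "C")
  if (!is.na(wc[a]) && wc[a] == b) return("|")
  if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(":")
  " "
}

# cached stacking table keyed "XY/ZW": target dinucleotide 5'XY3' over the
# paired miRNA dinucleotide 3'ZW5'
stack_table_env <- new.env(parent = emptyenv())

#' Nearest-neighbor stacking free energies
#'
#' Loads the shipped table of Turner-style RNA/RNA stacking free energies
#' (kcal/mol at 37C). Keys are `XY/ZW`: target strand dinucleotide 5'-XY-3'
#' stacked over the miRNA dinucleotide 3'-ZW-5'. Watson-Crick stacks carry
#' published nearest-neighbor values; stacks involving a G:U wobble pair use
#' a single declared value of -0.5 kcal/mol.
#'
#' @return named numeric vector of stacking free energies.
#' @export
stacking_energies <- function() {
  if (!is.null(stack_table_env$table)) return(stack_table_env$table)
  path <- system.file("extdata", "nn_stacking_dg37.tsv",
                      package = "cernaforge", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  stack_table_env$table <- setNames(df$dg37, df$stack)
  stack_table_env$table
}

#' Duplex free energy of an alignment
#'
#' Sums nearest-neighbor stacking free energies over consecutive paired
#' columns of the alignment (see [stacking_energies()]), adds the duplex
#' initiation penalty of +4.09 kcal/mol, and charges +0.5 kcal/mol for every
#' interior unpaired column (mismatch or gap between the first and last
#' paired columns). More negative values are more stable.
#'
#' @param alignment alignment component of [align_duplex()] output (three
#'   aligned strings), or the full list.
#' @return free energy in kcal/mol.
#' @export
duplex_free_energy <- function(alignment) {
  if (is.list(alignment)) alignment <- alignment$alignment
  stopifnot(length(alignment) == 3L)
  top <- chartr("T", "U", strsplit(alignment[[1L]], "", fixed = TRUE)[[1L]])
  bot <- chartr("T", "U", strsplit(alignment[[3L]], "", fixed = TRUE)[[1L]])
  n <- length(top)
  paired <- vapply(seq_len(n), function(k) {
    top[k] != "-" && bot[k] != "-" && pair_symbol(top[k], bot[k]) != " "
  }, TRUE)
  if (!any(paired))
    stop_config("alignment has no paired columns; free energy undefined")
  tab <- stacking_energies()
  dg <- DUPLEX_INITIATION_DG
  idx <- which(paired)
  for (k in idx[-length(idx)]) {
    if (paired[k + 1L]) {
      key <- paste0(bot[k], bot[k + 1L], "/", top[k], top[k + 1L])
      val <- unname(tab[key])
      if (!is.na(val)) dg <- dg + val
    }
  }
  interior <- seq(min(idx), max(idx))
  dg + INTERIOR_UNPAIRED_DG * sum(!paired[interior])
}

#' Extract the region of a gene model to scan for miRNA sites
#'
#' Returns the annotated 3'UTR when the model has one; otherwise the first
#' 1,000 nt (or to the end of the available sequence) downstream of the stop
#' codon, mirroring the standard fallback for genes lacking a predicted
#' 3'UTR.
#'
#' @param model list/row with `gene_id`, optional `utr3_seq`, optional
#'   `downstream_seq` (sequence immediately 3' of the stop codon).
#' @param downstream_nt fallback length (default 1000).
#' @return list: `host_id`, `kind` ("utr3" or "downstream_1kb"), `sequence`.
#' @export
extract_scan_region <- function(model, downstream_nt = 1000L) {
  utr <- model$utr3_seq %||% NA_character_
  if (!is.na(utr) && nzchar(utr)) {
    return(list(host_id = model$gene_id, kind = "utr3", sequence = utr))
  }
  down <- model$downstream_seq %||% NA_character_
  if (is.na(down) || !nzchar(down))
    stop_config("gene %s has neither an annotated 3'UTR nor downstream sequence",
                model$gene_id)
  list(host_id = model$gene_id, kind = "downstream_1kb",
       sequence = substr(down, 1L, downstream_nt))
}

#' Scan a region for miRNA binding sites
#'
#' Slides a window of length `nchar(mirna) + 10` over the region with step 1,
#' aligns the miRNA in each window, and reports maximal non-overlapping sites
#' with alignment score strictly above `score_min` and duplex free energy at
#' or below `energy_max` kcal/mol. Overlapping candidates are resolved by
#' keeping the higher score (ties: smaller start).
#'
#' @param mirna_id miRNA identifier carried into the output.
#' @param mirna miRNA sequence, 5'->3'.
#' @param region list with `host_id` and `sequence` (see
#'   [extract_scan_region()]), or a plain named sequence via `host_id=`.
#' @param score_min score threshold (default 140, strict inequality).
#' @param energy_max free-energy threshold in kcal/mol (default -10,
#'   inclusive).
#' @param params scoring parameters, see [duplex_params()].
#' @return data.frame: mirna_id, host_id, start, end (0-based half-open on
#'   the region), score, energy — sorted by start. A region shorter than the
#'   miRNA yields zero rows.
#' @export
scan_mirna_sites <- function(mirna_id, mirna, region, score_min = 140,
                             energy_max = -10, params = duplex_params()) {
  mirna <- check_nucleotide(mirna, "miRNA sequence")
  seq <- check_nucleotide(region$sequence, "region sequence")
  empty <- data.frame(mirna_id = character(), host_id = character(),
                      start = integer(), end = integer(),
                      score = numeric(), energy = numeric(),
                      stringsAsFactors = FALSE)
  L <- nchar(mirna)
  if (nchar(seq) < L) return(empty)
  window_len <- min(L + 10L, nchar(seq))
  mi <- encode_nt(mirna)
  rg <- encode_nt(seq)
  w_rev <- rev(seed_weights(L, params))
  scores <- cpp_window_scores(rev(mi), rg, w_rev, window_len,
                              params$match, params$wobble, params$mismatch,
                              params$gap_open, params$gap_extend)
  cand_windows <- which(scores > score_min)
  if (length(cand_windows) == 0L) return(empty)
  hits <- list()
  for (s in cand_windows) {
    win <- substr(seq, s, s + window_len - 1L)
    aln <- align_duplex(mirna, win, params)
    if (aln$score <= score_min) next
    dg <- duplex_free_energy(aln)
    if (dg > energy_max) next
    hits[[length(hits) + 1L]] <- data.frame(
      mirna_id = mirna_id, host_id = region$host_id,
      start = s - 1L + aln$target_start,
      end = s - 1L + aln$target_end,
      score = aln$score, energy = dg, stringsAsFactors = FALSE)
  }
  if (length(hits) == 0L) return(empty)
  out <- unique(do.call(rbind, hits))
  # resolve overlaps: keep the higher score, ties by smaller start
  out <- out[order(-out$score, out$start), , drop = FALSE]
  kept <- logical(nrow(out))
  occupied <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(nrow(out))) {
    s0 <- out$start[i]; e0 <- out$end[i]
    if (nrow(occupied) == 0L ||
        all(e0 <= occupied[, 1L] | s0 >= occupied[, 2L])) {
      kept[i] <- TRUE
      occupied <- rbind(occupied, c(s0, e0))
    }
  }
  out <- out[kept, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan many miRNAs against many regions
#'
#' Convenience wrapper applying [scan_mirna_sites()] over every
#' (miRNA, region) combination and binding the hits.
#'
#' @param mirnas named character vector of miRNA sequences (5'->3').
#' @param regions list of scan regions (each with `host_id`, `sequence`).
#' @inheritParams scan_mirna_sites
#' @return combined hits data.frame.
#' @export
scan_all <- function(mirnas, regions, score_min = 140, energy_max = -10,
                     params = duplex_params()) {
  out <- list()
  for (m in names(mirnas)) {
    for (rg in regions) {
      h <- scan_mirna_sites(m, mirnas[[m]], rg, score_min, energy_max, params)
      if (nrow(h)) out[[length(out) + 1L]] <- h
    }
  }
  if (length(out) == 0L)
    return(data.frame(mirna_id = character(), host_id = character(),
                      start = integer(), end = integer(),
                      score = numeric(), energy = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
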