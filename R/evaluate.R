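# Alignment quality assessment: sum-of-pairs (SP) and F1 against a reference
# pairwise alignment, binning by identity/length, and score-distribution
# sampling over aligned vs random residue pairs.

#' Aligned residue index pairs of an alignment
#'
#' The set of `(i, j)` index pairs (0-based, into the ungapped sequences)
#' for every alignment column holding a residue in both rows; gap columns are
#' excluded. Each `i` and each `j` appears at most once.
#'
#' @param aln An `alignment_result` or [pairwise_reference].
#' @return An object of class `column_pair_set` with element `pairs`
#'   (two-column integer matrix).
#' @export
column_pairs <- function(aln) {
  if (inherits(aln, "alignment_result")) {
    pairs <- aln$pairs
  } else if (inherits(aln, "pairwise_reference")) {
    ca <- strsplit(aln$row_a, "")[[1L]]
    cb <- strsplit(aln$row_b, "")[[1L]]
    ia <- cumsum(ca != "-") - 1L
    ib <- cumsum(cb != "-") - 1L
    keep <- ca != "-" & cb != "-"
    pairs <- cbind(i = ia[keep], j = ib[keep])
  } else {
    stop("column_pairs: unsupported object of class '", class(aln)[1L], "'")
  }
  structure(list(pairs = pairs), class = "column_pair_set")
}

pair_keys <- function(x) {
  p <- if (inherits(x, "column_pair_set")) x$pairs else x
  if (!nrow(p)) return(character(0))
  paste(p[, 1L], p[, 2L], sep = ":")
}

#' Sum-of-pairs score of a test alignment against a reference
#'
#' The proportion of the reference's aligned residue pairs recovered by the
#' test alignment: `|test intersect ref| / |ref|`. For pairwise alignments
#' this equals the total-column score, since every column holds one pair.
#'
#' @param test,ref `column_pair_set` objects (see [column_pairs]); `ref`
#'   must be non-empty.
#' @return SP score in `[0, 1]`.
#' @export
sp_score <- function(test, ref) {
  kr <- pair_keys(ref)
  if (!length(kr)) stop("sp_score: reference pair set is empty")
  kt <- pair_keys(test)
  sum(kt %in% kr) / length(kr)
}

#' F1 score of a test alignment against a reference
#'
#' Harmonic mean of recall (`|intersection| / |ref|`) and precision
#' (`|intersection| / |test|`); 0 when the test alignment is empty.
#'
#' @param test,ref `column_pair_set` objects; `ref` must be non-empty.
#' @return F1 score in `[0, 1]`.
#' @export
f1_score <- function(test, ref) {
  kr <- pair_keys(ref)
  if (!length(kr)) stop("f1_score: reference pair set is empty")
  kt <- pair_keys(test)
  if (!length(kt)) return(0)
  inter <- sum(kt %in% kr)
  recall <- inter / length(kr)
  precision <- inter / length(kt)
  if (recall + precision == 0) return(0)
  2 * recall * precision / (recall + precision)
}

#' Evaluate a test alignment against a reference
#'
#' @param aln An `alignment_result`.
#' @param ref A [pairwise_reference].
#' @return An object of class `evaluation_result`: a one-row data.frame with
#'   columns `sp`, `f1`, `recall`, `precision`, `identity_pct`,
#'   `alignment_length`.
#' @export
evaluate_alignment <- function(aln, ref) {
  tp <- column_pairs(aln)
  rp <- column_pairs(ref)
  kt <- pair_keys(tp); kr <- pair_keys(rp)
  inter <- sum(kt %in% kr)
  recall <- inter / length(kr)
  precision <- if (length(kt)) inter / length(kt) else 0
  f1 <- if (recall + precision > 0) {
    2 * recall * precision / (recall + precision)
  } else 0
  out <- data.frame(sp = recall, f1 = f1, recall = recall,
                    precision = precision,
                    identity_pct = ref$identity_pct,
                    alignment_length = ref$alignment_length)
  class(out) <- c("evaluation_result", class(out))
  out
}

#' Bin evaluation results by identity or alignment length
#'
#' Bins are half-open `[edge_k, edge_{k+1})`; the default identity edges are
#' 0, 10, ..., 100 (percent) and the default length edges 0, 500, ..., 2500
#' (reference alignment columns, residues and gaps). Bins holding fewer than
#' 10 alignments are flagged suppressed and report no means, to avoid skewed
#' averages. Values at or beyond the final edge are clamped into the last bin
#' with a warning.
#'
#' @param results A data.frame of evaluation rows (e.g. rbind-ed
#'   [evaluate_alignment] outputs) with columns `sp`, `f1` and the binning
#'   variable.
#' @param axis `"identity"` (bins `identity_pct`) or `"length"` (bins
#'   `alignment_length`).
#' @param edges Strictly increasing numeric bin boundaries.
#' @param min_count Suppression threshold (default 10).
#' @return A data.frame with one row per bin: `bin`, `lower`, `upper`,
#'   `count`, `n_zero_sp`, `mean_sp`, `mean_f1`, `suppressed`.
#' @export
bin_results <- function(results, axis = c("identity", "length"),
                        edges = NULL, min_count = 10L) {
  axis <- match.arg(axis)
  if (is.null(edges)) {
    edges <- if (axis == "identity") seq(0, 100, by = 10)
             else seq(0, 2500, by = 500)
  }
  if (any(diff(edges) <= 0)) stop("bin_results: edges must be increasing")
  x <- if (axis == "identity") results$identity_pct
       else results$alignment_length
  if (any(x < edges[1L])) stop("bin_results: value below the first edge")
  if (any(x >= edges[length(edges)])) {
    warning("bin_results: ", sum(x >= edges[length(edges)]),
            " value(s) at or beyond the final edge clamped into last bin")
  }
  nb <- length(edges) - 1L
  idx <- findInterval(x, edges)
  idx[idx > nb] <- nb
  lower <- edges[-length(edges)]
  upper <- edges[-1L]
  rows <- lapply(seq_len(nb), function(b) {
    sel <- idx == b
    count <- sum(sel)
    suppressed <- count < min_count
    data.frame(
      bin = paste0("[", lower[b], ",", upper[b], ")"),
      lower = lower[b], upper = upper[b], count = count,
      n_zero_sp = sum(results$sp[sel] == 0),
      mean_sp = if (suppressed) NA_real_ else mean(results$sp[sel]),
      mean_f1 = if (suppressed) NA_real_ else mean(results$f1[sel]),
      suppressed = suppressed)
  })
  do.call(rbind, rows)
}

#' Sample match-score distributions over aligned and random residue pairs
#'
#' Reproduces the diagnostic that motivates scaled-cosine scoring: per MSA,
#' sample `n_pairs` aligned residue pairs from the first `first_k` pairwise
#' reference alignments and score them (the "aligned" distribution), then
#' pick `n_random_res` random residues from each of `n_random_seqs` random
#' sequences and score all residue pairs across distinct sequences (the
#' "random" distribution). With an informative scorer the aligned
#' distribution shifts right of the random one.
#'
#' @param msa_groups A list; each element is a list with `refs` (the MSA's
#'   [pairwise_reference] list, MSA row-pair order) and `embeddings` (named
#'   list of [residue_embeddings], keyed by sequence id) and/or `seqs`
#'   (named list of [protein_seq]).
#' @param scorer Either `"embedding"` (scaled cosine of embedding rows) or a
#'   `substitution_table`.
#' @param n_pairs Aligned pairs sampled per MSA (default 100).
#' @param first_k Pairwise alignments drawn from, per MSA (default 5).
#' @param n_random_seqs,n_random_res Random-protocol sample sizes (5 and 4).
#' @param scale Scale for embedding scoring (default 10).
#' @param seed RNG seed; sampling is reproducible.
#' @return A list with numeric vectors `aligned` and `random`.
#' @export
sample_score_distributions <- function(msa_groups, scorer = "embedding",
                                       n_pairs = 100L, first_k = 5L,
                                       n_random_seqs = 5L, n_random_res = 4L,
                                       scale = 10, seed = 1L) {
  set.seed(seed)
  use_emb <- identical(scorer, "embedding")
  if (!use_emb && !inherits(scorer, "substitution_table")) {
    stop("sample_score_distributions: scorer must be \"embedding\" or a ",
         "substitution_table")
  }
  score_pair <- function(grp, id_a, i0, id_b, j0) {
    if (use_emb) {
      ea <- grp$embeddings[[id_a]]; eb <- grp$embeddings[[id_b]]
      scale * cosine_similarity(ea$matrix[i0 + 1L, ], eb$matrix[j0 + 1L, ])
    } else {
      ra <- substr(grp$seqs[[id_a]]$residues, i0 + 1L, i0 + 1L)
      rb <- substr(grp$seqs[[id_b]]$residues, j0 + 1L, j0 + 1L)
      substitution_score(scorer, ra, rb)
    }
  }
  aligned <- numeric(0)
  random <- numeric(0)
  for (grp in msa_groups) {
    refs <- grp$refs[seq_len(min(first_k, length(grp$refs)))]
    if (length(refs) < first_k) {
      message("sample_score_distributions: only ", length(refs),
              " pairwise alignments available in an MSA group")
    }
    pool <- do.call(rbind, lapply(seq_along(refs), function(r) {
      p <- column_pairs(refs[[r]])$pairs
      if (!nrow(p)) return(NULL)
      cbind(r, p)
    }))
    if (!is.null(pool) && nrow(pool)) {
      take <- sample.int(nrow(pool), min(n_pairs, nrow(pool)))
      for (t in take) {
        ref <- refs[[pool[t, 1L]]]
        aligned <- c(aligned,
                     score_pair(grp, ref$id_a, pool[t, 2L],
                                ref$id_b, pool[t, 3L]))
      }
    }
    ids <- if (use_emb) names(grp$embeddings) else names(grp$seqs)
    ns <- min(n_random_seqs, length(ids))
    if (ns < n_random_seqs) {
      message("sample_score_distributions: only ", ns,
              " sequences available in an MSA group")
    }
    pick <- sample(ids, ns)
    res_len <- function(id) {
      if (use_emb) grp$embeddings[[id]]$length
      else nchar(grp$seqs[[id]]$residues)
    }
    res_idx <- lapply(pick, function(id) {
      L <- res_len(id)
      sample.int(L, min(n_random_res, L)) - 1L
    })
    if (ns >= 2L) {
      for (a in seq_len(ns - 1L)) {
        for (b in seq.int(a + 1L, ns)) {
          for (i0 in res_idx[[a]]) {
            for (j0 in res_idx[[b]]) {
              random <- c(random,
                          score_pair(grp, pick[a], i0, pick[b], j0))
            }
          }
        }
      }
    }
  }
  list(aligned = aligned, random = random)
}
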