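# Affine-gap pairwise alignment over an arbitrary position-specific score
# matrix: Smith-Waterman (local, the default) and Needleman-Wunsch (global),
# plus an exhaustive-enumeration oracle and a score audit used in testing.

#' Affine gap penalties
#'
#' A gap run of length `k` costs `open + (k - 1) * extend` (both values are
#' non-positive; the opening charge covers the first gapped position). The
#' defaults, -11 and -1, are the standard position-independent penalties used
#' with the scaled-cosine scoring function.
#'
#' @param open Gap-open penalty (default -11).
#' @param extend Gap-extend penalty (default -1); must satisfy
#'   `open <= extend <= 0`.
#' @return An object of class `gap_penalties`.
#' @export
gap_penalties <- function(open = -11, extend = -1) {
  if (!(open <= extend && extend <= 0)) {
    stop("gap_penalties: need open <= extend <= 0 (got open = ", open,
         ", extend = ", extend, ")")
  }
  structure(list(open = open, extend = extend), class = "gap_penalties")
}

score_values <- function(S) {
  if (inherits(S, "score_matrix")) S$values else as.matrix(S)
}

# Assemble an alignment_result from the DP/oracle raw output.
# moves: forward string over D (pair), U (query residue vs gap),
# L (reference residue vs gap); start_i/start_j are 0-based.
new_alignment_result <- function(score, start_i, start_j, moves, mode,
                                 qry_id = NULL, ref_id = NULL) {
  mv <- if (nzchar(moves)) strsplit(moves, "")[[1L]] else character(0)
  i <- start_i; j <- start_j
  pairs <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("i", "j")))
  if (length(mv)) {
    pi <- integer(0); pj <- integer(0)
    for (m in mv) {
      if (m == "D") { pi <- c(pi, i); pj <- c(pj, j); i <- i + 1L; j <- j + 1L }
      else if (m == "U") i <- i + 1L
      else j <- j + 1L
    }
    pairs <- cbind(i = pi, j = pj)
  }
  qry_span <- if (length(mv)) c(start_i, i) else c(0L, 0L)
  ref_span <- if (length(mv)) c(start_j, j) else c(0L, 0L)
  structure(list(score = score, pairs = pairs, moves = moves,
                 qry_span = qry_span, ref_span = ref_span, mode = mode,
                 gapped_a = NA_character_, gapped_b = NA_character_,
                 qry_id = qry_id, ref_id = ref_id,
                 qry_residues = NULL, ref_residues = NULL),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat("<alignment_result> ", x$mode, ", score ", format(x$score),
      ", ", nrow(x$pairs), " aligned pairs, query [",
      x$qry_span[1L], ",", x$qry_span[2L], "), reference [",
      x$ref_span[1L], ",", x$ref_span[2L], ")\n", sep = "")
  if (!is.na(x$gapped_a)) cat(" ", x$gapped_a, "\n ", x$gapped_b, "\n")
  invisible(x)
}

#' Attach gapped strings to an alignment result
#'
#' Renders the aligned region of the two residue strings as gapped strings
#' (local alignments cover only their spans; global alignments cover the full
#' sequences).
#'
#' @param aln An `alignment_result`.
#' @param seq_a,seq_b The aligned [protein_seq] objects (query, reference).
#' @return `aln` with `gapped_a`, `gapped_b`, ids and residues filled in.
#' @export
alignment_strings <- function(aln, seq_a, seq_b) {
  stopifnot(inherits(aln, "alignment_result"))
  ca <- strsplit(seq_a$residues, "")[[1L]]
  cb <- strsplit(seq_b$residues, "")[[1L]]
  mv <- if (nzchar(aln$moves)) strsplit(aln$moves, "")[[1L]] else character(0)
  ga <- character(0); gb <- character(0)
  i <- aln$qry_span[1L]; j <- aln$ref_span[1L]
  for (m in mv) {
    if (m == "D") {
      ga <- c(ga, ca[i + 1L]); gb <- c(gb, cb[j + 1L])
      i <- i + 1L; j <- j + 1L
    } else if (m == "U") {
      ga <- c(ga, ca[i + 1L]); gb <- c(gb, "-"); i <- i + 1L
    } else {
      ga <- c(ga, "-"); gb <- c(gb, cb[j + 1L]); j <- j + 1L
    }
  }
  aln$gapped_a <- paste(ga, collapse = "")
  aln$gapped_b <- paste(gb, collapse = "")
  aln$qry_id <- seq_a$id
  aln$ref_id <- seq_b$id
  aln$qry_residues <- seq_a$residues
  aln$ref_residues <- seq_b$residues
  aln
}

run_dp <- function(S, gaps, global) {
  V <- score_values(S)
  if (nrow(V) == 0L || ncol(V) == 0L) {
    return(new_alignment_result(0, 0L, 0L, "",
                                if (global) "global" else "local"))
  }
  res <- affine_align_cpp(V, gaps$open, gaps$extend, global)
  out <- new_alignment_result(res$score, res$start_i, res$start_j,
                              res$moves, if (global) "global" else "local",
                              if (inherits(S, "score_matrix")) S$qry_id,
                              if (inherits(S, "score_matrix")) S$ref_id)
  out
}

#' Smith-Waterman local alignment over a score matrix
#'
#' Optimal local alignment under the three-state affine-gap recurrence
#' (match, gap-in-query, gap-in-reference; cells floored at zero). The score
#' is the maximum cell; traceback runs from that cell until a zero choice.
#' Tie-breaking is deterministic: diagonal, then up, then left at each step;
#' among equal-scoring maximum cells the one with smallest `i + j`, then
#' smallest `i`. An all-non-positive matrix yields the empty alignment with
#' score 0.
#'
#' @param S A `score_matrix` (or plain numeric matrix).
#' @param gaps A [gap_penalties] object.
#' @return An `alignment_result` with `mode = "local"`.
#' @export
smith_waterman <- function(S, gaps = gap_penalties()) {
  run_dp(S, gaps, global = FALSE)
}

#' Needleman-Wunsch global alignment over a score matrix
#'
#' Optimal global alignment consuming both sequences end to end; end gaps are
#' penalized like interior gaps. Same affine convention and tie-breaking as
#' [smith_waterman].
#'
#' @param S A `score_matrix` (or plain numeric matrix).
#' @param gaps A [gap_penalties] object.
#' @return An `alignment_result` with `mode = "global"`.
#' @export
needleman_wunsch <- function(S, gaps = gap_penalties()) {
  run_dp(S, gaps, global = TRUE)
}

gap_run_cost <- function(k, gaps) {
  ifelse(k > 0L, gaps$open + (k - 1L) * gaps$extend, 0)
}

# cost of a concrete interleaving of gap moves, by maximal runs
moves_gap_cost <- function(mv, gaps) {
  if (!length(mv)) return(0)
  runs <- 1L + sum(mv[-1L] != mv[-length(mv)])
  runs * gaps$open + (length(mv) - runs) * gaps$extend
}

# All minimal-cost orderings of ga up-moves and gb left-moves within one
# inter-pair segment (alternation costs extra opens, so when open < extend
# only the two block orders survive; when open == extend all interleavings
# tie and are enumerated).
segment_orderings <- function(ga, gb, gaps) {
  if (ga == 0L && gb == 0L) return(list(character(0)))
  if (ga == 0L) return(list(rep("L", gb)))
  if (gb == 0L) return(list(rep("U", ga)))
  pos <- combn(ga + gb, ga)
  cand <- lapply(seq_len(ncol(pos)), function(k) {
    mv <- rep("L", ga + gb)
    mv[pos[, k]] <- "U"
    mv
  })
  costs <- vapply(cand, moves_gap_cost, numeric(1L), gaps = gaps)
  cand[costs == max(costs)]
}

# Backward-lexicographic preference used by the deterministic traceback:
# compare reversed move sequences with D < U < L; on a tie with one sequence
# a prefix of the other, the shorter wins (the traceback stops on ties).
move_rank <- c(D = 0L, U = 1L, L = 2L)
backward_preferred <- function(x, y) {
  rx <- move_rank[rev(x)]; ry <- move_rank[rev(y)]
  n <- min(length(rx), length(ry))
  if (n > 0L) {
    diffpos <- which(rx[seq_len(n)] != ry[seq_len(n)])
    if (length(diffpos)) {
      return(rx[diffpos[1L]] < ry[diffpos[1L]])
    }
  }
  length(rx) < length(ry)
}

#' Exhaustive-enumeration alignment oracle
#'
#' Computes the exact optimum by enumerating every monotone set of aligned
#' index pairs and charging affine gap costs per maximal gap run, entirely
#' independently of the dynamic-programming recurrences. Tie-breaking among
#' co-optimal alignments replicates the deterministic traceback rule, so
#' score and pair list are both comparable with [smith_waterman] /
#' [needleman_wunsch]. Guarded to small instances (`m * n <= 36`).
#'
#' @param S A `score_matrix` (or plain numeric matrix).
#' @param gaps A [gap_penalties] object.
#' @param mode `"local"` or `"global"`.
#' @return An `alignment_result`.
#' @export
brute_force_align <- function(S, gaps = gap_penalties(),
                              mode = c("local", "global")) {
  mode <- match.arg(mode)
  V <- score_values(S)
  m <- nrow(V); n <- ncol(V)
  if (m * n > 36L) {
    stop("brute_force_align: instance ", m, "x", n,
         " too large for exhaustive enumeration (m*n must be <= 36)")
  }
  global <- mode == "global"
  if (m == 0L || n == 0L) return(new_alignment_result(0, 0L, 0L, "", mode))

  sets <- list()
  scores <- numeric(0)
  add_set <- function(pi, pj) {
    k <- length(pi)
    sc <- if (k) sum(V[cbind(pi, pj)]) else 0
    if (k > 1L) {
      sc <- sc + sum(gap_run_cost(diff(pi) - 1L, gaps)) +
        sum(gap_run_cost(diff(pj) - 1L, gaps))
    }
    if (global) {
      if (k) {
        sc <- sc + gap_run_cost(pi[1L] - 1L, gaps) +
          gap_run_cost(pj[1L] - 1L, gaps) +
          gap_run_cost(m - pi[k], gaps) + gap_run_cost(n - pj[k], gaps)
      } else {
        sc <- gap_run_cost(m, gaps) + gap_run_cost(n, gaps)
      }
    }
    sets[[length(sets) + 1L]] <<- list(pi = pi, pj = pj)
    scores[length(scores) + 1L] <<- sc
  }

  add_set(integer(0), integer(0))
  for (k in seq_len(min(m, n))) {
    ci <- combn(m, k)
    cj <- combn(n, k)
    for (a in seq_len(ncol(ci))) {
      for (b in seq_len(ncol(cj))) {
        add_set(ci[, a], cj[, b])
      }
    }
  }

  best <- max(scores)
  if (!global && best <= 0) {
    return(new_alignment_result(0, 0L, 0L, "", mode))
  }
  co <- which(scores >= best - 1e-9)
  cand_sets <- sets[co]

  if (!global) {
    # end-cell rule: smallest i+j, then smallest i, over the last pair
    ends <- t(vapply(cand_sets, function(s) {
      k <- length(s$pi); c(s$pi[k], s$pj[k])
    }, integer(2L)))
    keep <- ends[, 1L] + ends[, 2L] == min(ends[, 1L] + ends[, 2L])
    ends <- ends[keep, , drop = FALSE]
    cand_sets <- cand_sets[keep]
    keep <- ends[, 1L] == min(ends[, 1L])
    cand_sets <- cand_sets[keep]
  }

  # expand each co-optimal pair set into its minimal-cost move sequences
  best_mv <- NULL; best_start <- NULL
  consider <- function(mv, start) {
    if (is.null(best_mv) || backward_preferred(mv, best_mv)) {
      best_mv <<- mv
      best_start <<- start
    }
  }
  for (s in cand_sets) {
    pi <- s$pi; pj <- s$pj; k <- length(pi)
    segs <- list()
    if (global) {
      segs[[1L]] <- segment_orderings(if (k) pi[1L] - 1L else m,
                                      if (k) pj[1L] - 1L else n, gaps)
    } else {
      segs[[1L]] <- list(character(0))
    }
    if (k > 1L) {
      for (t in seq_len(k - 1L)) {
        segs[[t + 1L]] <- segment_orderings(pi[t + 1L] - pi[t] - 1L,
                                            pj[t + 1L] - pj[t] - 1L, gaps)
      }
    }
    if (global && k > 0L) {
      segs[[k + 1L]] <- segment_orderings(m - pi[k], n - pj[k], gaps)
    }
    start <- if (!global) c(pi[1L] - 1L, pj[1L] - 1L) else c(0L, 0L)
    # cross product of per-segment orderings
    build <- function(t, acc) {
      if (t > length(segs)) { consider(acc, start); return(invisible()) }
      for (seg in segs[[t]]) {
        acc2 <- c(acc, seg)
        if (t <= k) acc2 <- c(acc2, "D")
        if (t <= k || global) build(t + 1L, acc2) else consider(acc2, start)
      }
    }
    if (k == 0L) {
      if (global) for (seg in segs[[1L]]) consider(seg, start)
    } else {
      build(1L, character(0))
    }
  }
  new_alignment_result(best, best_start[1L], best_start[2L],
                       paste(best_mv, collapse = ""), mode)
}

#' Recompute an alignment's score from its structure
#'
#' Walks the alignment's aligned pairs and gap runs and recomputes the raw
#' score under the given score matrix and gap penalties; by construction this
#' must equal the reported DP score (the score-audit property).
#'
#' @param aln An `alignment_result`.
#' @param S The `score_matrix` the alignment was computed from.
#' @param gaps The [gap_penalties] used.
#' @return The recomputed score.
#' @export
score_audit <- function(aln, S, gaps = gap_penalties()) {
  V <- score_values(S)
  p <- aln$pairs
  if (nrow(p)) {
    if (any(p[, 1L] < 0L) || any(p[, 2L] < 0L) ||
        any(p[, 1L] >= nrow(V)) || any(p[, 2L] >= ncol(V))) {
      stop("score_audit: aligned pairs out of matrix bounds")
    }
    if (nrow(p) > 1L &&
        (any(diff(p[, 1L]) <= 0L) || any(diff(p[, 2L]) <= 0L))) {
      stop("score_audit: aligned pairs are not strictly increasing")
    }
  }
  mv <- if (nzchar(aln$moves)) strsplit(aln$moves, "")[[1L]] else character(0)
  pair_sum <- if (nrow(p)) sum(V[cbind(p[, 1L] + 1L, p[, 2L] + 1L)]) else 0
  gap_cost <- 0
  if (length(mv)) {
    runs <- rle(mv)
    gap_runs <- runs$lengths[runs$values != "D"]
    if (length(gap_runs)) {
      gap_cost <- sum(gaps$open + (gap_runs - 1L) * gaps$extend)
    }
  }
  pair_sum + gap_cost
}
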