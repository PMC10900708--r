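# Position-specific score matrices: scaled-cosine scoring of embedding rows
# (the method's core scoring function) and substitution-matrix scoring as
# the classical baseline.

#' Cosine similarity between two vectors
#'
#' `dot(u, v) / (|u| |v|)`, clamped to `[-1, 1]` against floating-point
#' drift. If either vector has zero norm the similarity is defined as 0 with
#' a warning (degenerate-input policy; real language-model embeddings never
#' have zero norm).
#'
#' @param u,v Numeric vectors of equal length.
#' @return A number in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) {
    stop("cosine_similarity: vectors have lengths ", length(u), " and ",
         length(v))
  }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    warning("cosine_similarity: zero-norm vector; similarity set to 0")
    return(0)
  }
  max(-1, min(1, sum(u * v) / (nu * nv)))
}

new_score_matrix <- function(values, origin, scale = NA_real_,
                             qry_id = NULL, ref_id = NULL) {
  structure(list(values = values, origin = origin, scale = scale,
                 qry_len = nrow(values), ref_len = ncol(values),
                 qry_id = qry_id, ref_id = ref_id),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("<score_matrix> ", x$qry_len, " x ", x$ref_len, " (", x$origin,
      if (!is.na(x$scale)) paste0(", scale ", x$scale), ")\n", sep = "")
  invisible(x)
}

#' Scaled-cosine score matrix from two embedding matrices
#'
#' The match score of residues `i` and `j` is
#' `scale * cosine(Emb(x_i), Emb(y_j))`; with the default scale of 10 this
#' is the scoring function used for embedding-based alignment. Entries are
#' bounded by `[-scale, scale]`. Zero-norm rows score 0 against everything
#' (with a warning).
#'
#' @param emb_a,emb_b [residue_embeddings] of equal feature dimension.
#' @param scale Multiplier applied to the cosine similarity (default 10).
#' @return A `score_matrix` with `origin = "embedding"`; dimensions are
#'   `length(a) x length(b)`.
#' @export
embedding_score_matrix <- function(emb_a, emb_b, scale = 10) {
  stopifnot(inherits(emb_a, "residue_embeddings"),
            inherits(emb_b, "residue_embeddings"))
  if (emb_a$dim != emb_b$dim) {
    stop("embedding_score_matrix: feature dimensions differ (",
         emb_a$dim, " vs ", emb_b$dim, ")")
  }
  A <- emb_a$matrix
  B <- emb_b$matrix
  na <- sqrt(rowSums(A^2))
  nb <- sqrt(rowSums(B^2))
  if (any(na == 0) || any(nb == 0)) {
    warning("embedding_score_matrix: zero-norm embedding row(s); ",
            "their scores are set to 0")
    na[na == 0] <- Inf
    nb[nb == 0] <- Inf
  }
  cosm <- tcrossprod(A / na, B / nb)
  cosm[cosm > 1] <- 1
  cosm[cosm < -1] <- -1
  new_score_matrix(scale * cosm, "embedding", scale,
                   emb_a$seq_id, emb_b$seq_id)
}

#' Load a substitution matrix
#'
#' Built-in names `"BLOSUM62"` and `"BLOSUM45"` resolve to the canonical
#' matrices shipped with Biostrings; any other argument is treated as the
#' path of an NCBI-style matrix text file (a header row of residue letters,
#' then one labelled row of integer scores per residue; `#` comments
#' ignored). Residues outside the table's alphabet are scored via the
#' wildcard column `X`.
#'
#' @param name_or_path Matrix name or file path.
#' @return An object of class `substitution_table` with elements `name` and
#'   `scores` (a symmetric named score matrix).
#' @export
load_substitution_table <- function(name_or_path = "BLOSUM62") {
  builtin <- c("BLOSUM62", "BLOSUM45")
  if (name_or_path %in% builtin) {
    env <- new.env()
    utils::data(list = name_or_path, package = "Biostrings", envir = env)
    scores <- get(name_or_path, envir = env)
    name <- name_or_path
  } else if (file.exists(name_or_path)) {
    scores <- parse_ncbi_matrix(name_or_path)
    name <- basename(name_or_path)
  } else {
    stop("load_substitution_table: '", name_or_path,
         "' is neither a built-in matrix name (",
         paste(builtin, collapse = ", "), ") nor an existing file")
  }
  if (!isTRUE(all.equal(scores, t(scores)))) {
    stop("load_substitution_table: matrix '", name, "' is not symmetric")
  }
  structure(list(name = name, scores = scores), class = "substitution_table")
}

#' @export
print.substitution_table <- function(x, ...) {
  cat("<substitution_table> ", x$name, " (", nrow(x$scores),
      " letters)\n", sep = "")
  invisible(x)
}

parse_ncbi_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("parse_ncbi_matrix: malformed file: ", path)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  n <- length(header)
  mat <- matrix(NA_real_, n, n, dimnames = list(header, header))
  for (ln in lines[-1L]) {
    toks <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(toks) != n + 1L) {
      stop("parse_ncbi_matrix: row '", toks[1L], "' has ",
           length(toks) - 1L, " scores, expected ", n)
    }
    vals <- suppressWarnings(as.numeric(toks[-1L]))
    if (anyNA(vals)) stop("parse_ncbi_matrix: non-numeric score in row '",
                          toks[1L], "'")
    mat[toks[1L], ] <- vals
  }
  if (anyNA(mat)) stop("parse_ncbi_matrix: missing rows in ", path)
  mat
}

#' Look up a substitution score
#'
#' Residues absent from the table (e.g. `J`, `U`, `O` against a classic
#' BLOSUM file) are mapped to the wildcard `X`.
#'
#' @param table A `substitution_table`.
#' @param a,b Single residue letters.
#' @return The substitution score.
#' @export
substitution_score <- function(table, a, b) {
  letters_in <- rownames(table$scores)
  map1 <- function(r) if (r %in% letters_in) r else "X"
  table$scores[map1(a), map1(b)]
}

#' Substitution score matrix for two sequences
#'
#' The classical baseline: entry `(i, j)` is the table score of residue
#' `a_i` against `b_j`.
#'
#' @param seq_a,seq_b [protein_seq] objects.
#' @param table A `substitution_table` from [load_substitution_table].
#' @return A `score_matrix` with `origin = "substitution"`.
#' @export
substitution_score_matrix <- function(seq_a, seq_b, table) {
  stopifnot(inherits(seq_a, "protein_seq"), inherits(seq_b, "protein_seq"),
            inherits(table, "substitution_table"))
  ca <- strsplit(seq_a$residues, "")[[1L]]
  cb <- strsplit(seq_b$residues, "")[[1L]]
  letters_in <- rownames(table$scores)
  ca[!ca %in% letters_in] <- "X"
  cb[!cb %in% letters_in] <- "X"
  vals <- table$scores[ca, cb, drop = FALSE]
  dimnames(vals) <- NULL
  new_score_matrix(vals, "substitution", NA_real_, seq_a$id, seq_b$id)
}

#' Dump a score matrix as TSV (debugging aid)
#' @param S A `score_matrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_score_matrix <- function(S, path) {
  write.table(S$values, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
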