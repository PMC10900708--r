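# Per-residue embeddings: container, on-disk text format, the embedder
# adapter contract, and the synthetic generator that plants a known
# alignment into a pair of embedding matrices.

#' Per-residue embedding matrix
#'
#' An `L x d` numeric matrix of contextual embeddings, one row per residue of
#' the associated sequence. `model_tag` records which language model (or
#' `"synthetic"` / `"mock"`) produced the rows.
#'
#' @param seq_id Identifier of the embedded sequence.
#' @param matrix Numeric matrix, rows = residues, columns = features; all
#'   entries must be finite.
#' @param model_tag Provenance tag, e.g. `"prott5-xl-u50"`, `"esm2-t36-3b"`,
#'   `"synthetic"`.
#' @return An object of class `residue_embeddings` with elements `seq_id`,
#'   `matrix`, `model_tag`, `dim` (feature count) and `length` (residue
#'   count).
#' @export
residue_embeddings <- function(seq_id, matrix, model_tag = "unknown") {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (nrow(matrix) < 1L || ncol(matrix) < 1L) {
    stop("residue_embeddings: matrix must have at least one row and column")
  }
  if (!all(is.finite(matrix))) {
    stop("residue_embeddings: non-finite entries in embedding matrix for '",
         seq_id, "'")
  }
  structure(list(seq_id = seq_id, matrix = matrix, model_tag = model_tag,
                 dim = ncol(matrix), length = nrow(matrix)),
            class = "residue_embeddings")
}

#' @export
print.residue_embeddings <- function(x, ...) {
  cat("<residue_embeddings> ", x$seq_id, ": ", x$length, " residues x ",
      x$dim, " features [", x$model_tag, "]\n", sep = "")
  invisible(x)
}

#' Save per-residue embeddings as a text matrix
#'
#' Whitespace-delimited numeric matrix, one row per residue, preceded by
#' `#`-comment header lines carrying `seq_id` and `model_tag`.
#'
#' @param emb A [residue_embeddings].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_embeddings <- function(emb, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# seq_id: ", emb$seq_id),
               paste0("# model_tag: ", emb$model_tag)), con)
  write.table(format(emb$matrix, digits = 17, scientific = TRUE,
                     trim = TRUE),
              con, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load per-residue embeddings from a text matrix
#'
#' Reads the whitespace text matrix written by [save_embeddings] (or any
#' headerless numeric matrix file). If `expected_length` is given, the row
#' count is checked against it.
#'
#' @param path Path to the matrix file.
#' @param seq_id Identifier to attach; defaults to the `seq_id` header in the
#'   file, or the file base name.
#' @param expected_length Optional residue count the matrix must match.
#' @return A [residue_embeddings].
#' @export
load_embeddings <- function(path, seq_id = NULL, expected_length = NULL) {
  if (!file.exists(path)) stop("load_embeddings: file not found: ", path)
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  body <- grep("^#", lines, invert = TRUE, value = TRUE)
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) stop("load_embeddings: no matrix rows in ", path)
  get_meta <- function(key) {
    hit <- grep(paste0("^#\\s*", key, ":"), meta, value = TRUE)
    if (length(hit)) trimws(sub(paste0("^#\\s*", key, ":"), "", hit[1L]))
    else NULL
  }
  rows <- strsplit(trimws(body), "[ \t]+")
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    stop("load_embeddings: ragged matrix rows in ", path)
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals)) stop("load_embeddings: non-numeric content in ", path)
  mat <- matrix(vals, nrow = length(rows), byrow = TRUE)
  if (is.null(seq_id)) {
    seq_id <- get_meta("seq_id")
    if (is.null(seq_id)) seq_id <- sub("\\.[^.]*$", "", basename(path))
  }
  tag <- get_meta("model_tag")
  if (is.null(tag)) tag <- "unknown"
  if (!is.null(expected_length) && nrow(mat) != expected_length) {
    stop("load_embeddings: matrix has ", nrow(mat),
         " rows but the sequence has ", expected_length, " residues")
  }
  residue_embeddings(seq_id, mat, tag)
}

#' Embedder adapter
#'
#' The contract a language-model backend must satisfy: a function mapping a
#' residue string to an `L x d` matrix with exactly one row per residue
#' (padding and special tokens already stripped). Known model dimensions:
#' ProtT5-XL-U50 emits 1024 features per residue, ESM2-T36-3B emits 2560.
#'
#' @param name Adapter/model tag.
#' @param dim Expected output feature count.
#' @param embed_fn `function(residues)` returning an `L x dim` numeric
#'   matrix.
#' @return An object of class `embedder_adapter`.
#' @export
embedder_adapter <- function(name, dim, embed_fn) {
  stopifnot(is.function(embed_fn), dim >= 1L)
  structure(list(name = name, dim = as.integer(dim), embed_fn = embed_fn),
            class = "embedder_adapter")
}

#' Deterministic mock embedder adapter
#'
#' A download-free stand-in for a language-model backend: each row is a
#' pseudo-random unit vector seeded from the residue letter and its position,
#' so identical sequences embed identically. Used to exercise the adapter
#' contract in tests.
#'
#' @param dim Feature count (default 64).
#' @return An [embedder_adapter] with `name = "mock"`.
#' @export
mock_embedder <- function(dim = 64L) {
  embedder_adapter("mock", dim, function(residues) {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old_seed)) {
        assign(".Random.seed", old_seed, envir = globalenv())
      }
    })
    chars <- strsplit(residues, "")[[1L]]
    mat <- matrix(0, nrow = length(chars), ncol = dim)
    for (i in seq_along(chars)) {
      set.seed((utf8ToInt(chars[i]) * 131L + i) %% .Machine$integer.max)
      rng <- rnorm(dim)
      mat[i, ] <- rng / sqrt(sum(rng^2))
    }
    mat
  })
}

#' Embed a sequence through an adapter
#'
#' Runs the adapter and enforces the row-count contract: the output must have
#' exactly one row per residue. A mismatch signals that the backend failed to
#' strip padding/special tokens.
#'
#' @param seq A [protein_seq].
#' @param adapter An [embedder_adapter].
#' @return A [residue_embeddings] with `model_tag = adapter$name`.
#' @export
embed_with_adapter <- function(seq, adapter) {
  stopifnot(inherits(seq, "protein_seq"), inherits(adapter, "embedder_adapter"))
  mat <- adapter$embed_fn(seq$residues)
  mat <- as.matrix(mat)
  if (nrow(mat) != nchar(seq$residues)) {
    stop("embed_with_adapter: adapter '", adapter$name, "' returned ",
         nrow(mat), " rows for a ", nchar(seq$residues),
         "-residue sequence; special tokens were not stripped")
  }
  if (ncol(mat) != adapter$dim) {
    stop("embed_with_adapter: adapter '", adapter$name, "' returned dim ",
         ncol(mat), ", expected ", adapter$dim)
  }
  residue_embeddings(seq$id, mat, adapter$name)
}

#' Synthetic homologous pair specification
#'
#' Defines a planted pairwise alignment between two synthetic embedding
#' matrices: the index pairs that are "homologous", the sequence lengths, the
#' feature count, and the noise level separating planted from background
#' cosine similarity.
#'
#' @param planted_pairs Two-column integer matrix of 0-based `(i, j)` index
#'   pairs, strictly increasing in both coordinates.
#' @param len_a,len_b Sequence lengths.
#' @param dim Feature count.
#' @param noise_sigma Non-negative noise scale; the expected cosine of a
#'   planted pair is approximately `1 / (1 + noise_sigma^2)`.
#' @param seed Integer RNG seed; the construction is fully reproducible.
#' @return An object of class `synthetic_pair_spec`.
#' @export
synthetic_pair_spec <- function(planted_pairs, len_a, len_b, dim = 256L,
                                noise_sigma = 0.2, seed = 1L) {
  planted_pairs <- matrix(as.integer(planted_pairs), ncol = 2L)
  if (nrow(planted_pairs) == 0L) {
    stop("synthetic_pair_spec: at least one planted pair is required")
  }
  i <- planted_pairs[, 1L]; j <- planted_pairs[, 2L]
  if (any(i < 0L) || any(j < 0L) || any(i >= len_a) || any(j >= len_b)) {
    stop("synthetic_pair_spec: planted indices out of range")
  }
  if (nrow(planted_pairs) > 1L &&
      (any(diff(i) <= 0L) || any(diff(j) <= 0L))) {
    stop("synthetic_pair_spec: planted_pairs must be strictly increasing ",
         "in both coordinates")
  }
  if (noise_sigma < 0) stop("synthetic_pair_spec: noise_sigma must be >= 0")
  structure(list(planted_pairs = planted_pairs,
                 len_a = as.integer(len_a), len_b = as.integer(len_b),
                 dim = as.integer(dim), noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "synthetic_pair_spec")
}

#' Random synthetic pair specification
#'
#' Convenience constructor emulating a homologous pair: the `n_pairs`
#' planted aligned positions form long collinear blocks interrupted by a
#' small number of indel events, the way real homologs diverge (a few
#' insertion/deletion events, not independently scattered matches). The
#' residues of each sequence not covered by a planted pair are distributed
#' among the two flanks and `n_indels` randomly placed internal indel sites.
#'
#' @param len_a,len_b Sequence lengths (default 120, the regime of a typical
#'   small protein domain pair).
#' @param n_pairs Number of planted aligned positions (default 100).
#' @param n_indels Number of internal indel events per sequence (default 3);
#'   reduced automatically if the unaligned residue budget is smaller.
#' @param dim,noise_sigma,seed Passed through to [synthetic_pair_spec].
#' @return A [synthetic_pair_spec].
#' @export
random_pair_spec <- function(len_a = 120L, len_b = 120L, n_pairs = 100L,
                             n_indels = 3L, dim = 256L, noise_sigma = 0.2,
                             seed = 1L) {
  if (n_pairs > len_a || n_pairs > len_b) {
    stop("random_pair_spec: n_pairs exceeds a sequence length")
  }
  set.seed(seed)
  place <- function(len) {
    extra <- len - n_pairs
    ni <- min(n_indels, extra)
    # split the unaligned budget across lead flank, ni indels, trail flank
    alloc <- if (extra > 0) {
      as.vector(stats::rmultinom(1L, extra, rep(1, ni + 2L)))
    } else rep(0L, 2L)
    lead <- alloc[1L]
    internal <- if (ni > 0L) alloc[seq.int(2L, ni + 1L)] else integer(0)
    # indel sites: junctions between consecutive planted pairs
    sites <- if (ni > 0L) sort(sample.int(n_pairs - 1L, ni)) else integer(0)
    ins_before <- integer(n_pairs)  # insertions before pair t (t >= 2)
    ins_before[sites + 1L] <- internal
    lead + cumsum(c(0L, rep(1L, n_pairs - 1L)) ) + cumsum(ins_before)
  }
  i <- place(len_a)
  j <- place(len_b)
  synthetic_pair_spec(cbind(i, j), len_a, len_b, dim, noise_sigma, seed)
}

unit_rows <- function(n, d) {
  m <- matrix(rnorm(n * d), nrow = n)
  m / sqrt(rowSums(m^2))
}

#' Generate a synthetic homologous embedding pair with a planted alignment
#'
#' For each planted pair `(i, j)` a shared latent unit vector `z` is drawn;
#' row `i` of matrix A is `normalize(z + e1)` and row `j` of matrix B is
#' `normalize(z + e2)`, with `e1`, `e2` i.i.d. normal with per-component
#' standard deviation `noise_sigma / sqrt(dim)`, so the expected cosine of a
#' planted pair is about `1 / (1 + noise_sigma^2)`. All unplanted rows are
#' independent random unit vectors (expected pairwise cosine near 0 for large
#' `dim`). Sequences are given uniformly random residue letters, so the same
#' fixture can also drive substitution-matrix scoring (where the letters are
#' by construction uninformative about the planted alignment).
#'
#' @param spec A [synthetic_pair_spec].
#' @return A list with elements `emb_a`, `emb_b` ([residue_embeddings]),
#'   `seq_a`, `seq_b` ([protein_seq]) and `reference` (the planted
#'   [pairwise_reference]).
#' @export
generate_synthetic_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_pair_spec"))
  set.seed(spec$seed)
  d <- spec$dim
  sig <- spec$noise_sigma / sqrt(d)
  A <- unit_rows(spec$len_a, d)
  B <- unit_rows(spec$len_b, d)
  pp <- spec$planted_pairs
  for (t in seq_len(nrow(pp))) {
    z <- rnorm(d)
    z <- z / sqrt(sum(z^2))
    ra <- z + rnorm(d, sd = sig)
    rb <- z + rnorm(d, sd = sig)
    A[pp[t, 1L] + 1L, ] <- ra / sqrt(sum(ra^2))
    B[pp[t, 2L] + 1L, ] <- rb / sqrt(sum(rb^2))
  }
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  res_a <- paste(sample(aa, spec$len_a, replace = TRUE), collapse = "")
  res_b <- paste(sample(aa, spec$len_b, replace = TRUE), collapse = "")
  seq_a <- protein_seq("synthA", res_a)
  seq_b <- protein_seq("synthB", res_b)
  ref <- planted_reference(seq_a, seq_b, pp)
  list(emb_a = residue_embeddings("synthA", A, "synthetic"),
       emb_b = residue_embeddings("synthB", B, "synthetic"),
       seq_a = seq_a, seq_b = seq_b, reference = ref)
}

# Build the ground-truth pairwise_reference implied by planted (i, j) pairs:
# planted positions become gapless columns; all other residues appear against
# a gap (unaligned-a columns before unaligned-b columns between consecutive
# planted pairs).
planted_reference <- function(seq_a, seq_b, pairs0) {
  ca <- strsplit(seq_a$residues, "")[[1L]]
  cb <- strsplit(seq_b$residues, "")[[1L]]
  ra <- character(0); rb <- character(0)
  ai <- 0L; bj <- 0L  # next unconsumed 0-based index
  emit_gap <- function(upto_a, upto_b) {
    while (ai < upto_a) {
      ra <<- c(ra, ca[ai + 1L]); rb <<- c(rb, "-"); ai <<- ai + 1L
    }
    while (bj < upto_b) {
      ra <<- c(ra, "-"); rb <<- c(rb, cb[bj + 1L]); bj <<- bj + 1L
    }
  }
  for (t in seq_len(nrow(pairs0))) {
    emit_gap(pairs0[t, 1L], pairs0[t, 2L])
    ra <- c(ra, ca[ai + 1L]); rb <- c(rb, cb[bj + 1L])
    ai <- ai + 1L; bj <- bj + 1L
  }
  emit_gap(length(ca), length(cb))
  pairwise_reference(seq_a$id, seq_b$id,
                     paste(ra, collapse = ""), paste(rb, collapse = ""))
}
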