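# Sequence and alignment I/O: FASTA sequences, gapped-FASTA / MSF multiple
# alignments, extraction of pairwise reference alignments, pairwise identity.
#
# Coordinates are 0-based half-open everywhere internally; 1-based only in
# human-readable output. Gap characters '-' and '.' are accepted on input;
# '-' only is emitted.

#' Protein sequence
#'
#' A lightweight container for one protein sequence: an identifier (the first
#' whitespace-delimited token of a FASTA header) and a residue string over the
#' amino-acid alphabet (20 standard residues plus B, Z, X, U, O and J, which
#' is folded to X at scoring time).
#'
#' @param id Non-empty identifier string.
#' @param residues Non-empty residue string; lowercase is uppercased, a
#'   trailing `*` is stripped, gap characters are rejected.
#' @return An object of class `protein_seq` with elements `id` and `residues`.
#' @export
protein_seq <- function(id, residues) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("protein_seq: 'id' must be a non-empty string")
  }
  if (!is.character(residues) || length(residues) != 1L) {
    stop("protein_seq: 'residues' must be a single string")
  }
  id <- unname(id)
  residues <- unname(toupper(residues))
  residues <- sub("\\*+$", "", residues)
  if (!nzchar(residues)) {
    stop("protein_seq: sequence '", id, "' is empty")
  }
  if (grepl("[-.]", residues)) {
    stop("protein_seq: sequence '", id, "' contains gap characters")
  }
  if (grepl("[^A-Z]", residues)) {
    stop("protein_seq: sequence '", id, "' contains non-letter characters")
  }
  structure(list(id = id, residues = residues), class = "protein_seq")
}

#' @export
print.protein_seq <- function(x, ...) {
  cat("<protein_seq> ", x$id, " (", nchar(x$residues), " aa)\n", sep = "")
  invisible(x)
}

#' Sequence length of a protein sequence
#' @param x A `protein_seq`.
#' @return Integer residue count.
#' @export
seq_length <- function(x) nchar(x$residues)

#' Read protein sequences from a FASTA file
#'
#' Residues are uppercased and a trailing `*` (stop symbol) is stripped from
#' each record. Record order is preserved. Duplicate identifiers are an error.
#'
#' @param path Path to a FASTA file.
#' @return A list of [protein_seq] objects (empty list for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("read_fasta: file not found: ", path)
  if (file.size(path) == 0L) return(list())
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("read_fasta: parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1L), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) {
    bad <- which(is.na(ids) | !nzchar(ids))[1L]
    stop("read_fasta: empty header for record ", bad, " in '", path, "'")
  }
  if (anyDuplicated(ids)) {
    stop("read_fasta: duplicate sequence id '", ids[anyDuplicated(ids)],
         "' in '", path, "'")
  }
  widths <- Biostrings::width(set)
  if (any(widths == 0L)) {
    stop("read_fasta: empty record '", ids[which(widths == 0L)[1L]],
         "' in '", path, "'")
  }
  seqs <- as.character(set)
  lapply(seq_along(seqs), function(k) protein_seq(ids[k], seqs[k]))
}

#' Write protein sequences to a FASTA file
#' @param seqs A list of [protein_seq] objects.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    writeLines(paste0(">", s$id), con)
    r <- s$residues
    starts <- seq(1L, nchar(r), by = width)
    writeLines(substring(r, starts, pmin(starts + width - 1L, nchar(r))), con)
  }
  invisible(path)
}

#' Multiple sequence alignment
#'
#' Ordered rows of equal-length gapped strings. Gap characters `-` and `.`
#' are accepted; `.` is normalized to `-` on construction. De-gapping any row
#' must yield a valid protein sequence.
#'
#' @param ids Character vector of unique row identifiers.
#' @param rows Character vector of gapped strings, same length as `ids`.
#' @return An object of class `multiple_alignment` with elements `ids`,
#'   `rows` and `ncol` (the column count).
#' @export
multiple_alignment <- function(ids, rows) {
  if (length(ids) != length(rows)) {
    stop("multiple_alignment: ids and rows differ in length")
  }
  if (anyDuplicated(ids)) stop("multiple_alignment: duplicate row ids")
  rows <- unname(toupper(gsub(".", "-", rows, fixed = TRUE)))
  ids <- unname(ids)
  widths <- nchar(rows)
  if (length(rows) > 0L && length(unique(widths)) != 1L) {
    stop("multiple_alignment: rows have unequal lengths (",
         paste(widths, collapse = ", "), ")")
  }
  for (k in seq_along(rows)) {
    protein_seq(ids[k], degap(rows[k]))  # validates the de-gapped residues
  }
  structure(list(ids = as.character(ids), rows = rows,
                 ncol = if (length(rows)) widths[1L] else 0L),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat("<multiple_alignment> ", length(x$ids), " rows x ", x$ncol,
      " columns\n", sep = "")
  invisible(x)
}

#' Remove gap characters from a gapped string
#' @param x Character vector of gapped strings.
#' @return Character vector of residue strings.
#' @export
degap <- function(x) gsub("[-.]", "", x)

#' Read a multiple sequence alignment
#'
#' Supports gapped FASTA (the canonical dialect) and GCG MSF (interleaved
#' blocks are concatenated per sequence). `.` gaps are normalized to `-`.
#'
#' @param path Path to the alignment file.
#' @param format `"gapped-fasta"` or `"msf"`.
#' @return A [multiple_alignment].
#' @export
read_msa <- function(path, format = c("gapped-fasta", "msf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read_msa: file not found: ", path)
  if (format == "gapped-fasta") {
    set <- tryCatch(
      Biostrings::readBStringSet(path, format = "fasta"),
      error = function(e) stop("read_msa: parse error in '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    )
    ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1L), 1L)
    multiple_alignment(ids, as.character(set))
  } else {
    aln <- tryCatch(
      seqinr::read.alignment(path, format = "msf"),
      error = function(e) stop("read_msa: MSF parse error in '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    )
    multiple_alignment(aln$nam, toupper(unlist(aln$seq)))
  }
}

#' Write a multiple sequence alignment as gapped FASTA
#' @param msa A [multiple_alignment].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_msa <- function(msa, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(msa$ids)) {
    writeLines(c(paste0(">", msa$ids[k]), msa$rows[k]), con)
  }
  invisible(path)
}

#' Pairwise reference alignment
#'
#' A ground-truth pairwise alignment extracted from a benchmark MSA: two
#' gapped rows with dual-gap columns removed, plus the pairwise identity and
#' the alignment length (columns, residues and gaps).
#'
#' @param id_a,id_b Row identifiers.
#' @param row_a,row_b Equal-length gapped strings with no dual-gap column.
#' @return An object of class `pairwise_reference` with elements `id_a`,
#'   `id_b`, `row_a`, `row_b`, `identity_pct`, `alignment_length`.
#' @export
pairwise_reference <- function(id_a, id_b, row_a, row_b) {
  row_a <- toupper(gsub(".", "-", row_a, fixed = TRUE))
  row_b <- toupper(gsub(".", "-", row_b, fixed = TRUE))
  if (nchar(row_a) != nchar(row_b)) {
    stop("pairwise_reference: rows have unequal lengths")
  }
  ca <- strsplit(row_a, "")[[1L]]
  cb <- strsplit(row_b, "")[[1L]]
  if (any(ca == "-" & cb == "-")) {
    stop("pairwise_reference: dual-gap column present")
  }
  ref <- structure(
    list(id_a = id_a, id_b = id_b, row_a = row_a, row_b = row_b,
         identity_pct = NA_real_, alignment_length = nchar(row_a)),
    class = "pairwise_reference")
  ref$identity_pct <- pairwise_identity(ref)
  ref
}

#' @export
print.pairwise_reference <- function(x, ...) {
  cat("<pairwise_reference> ", x$id_a, " / ", x$id_b, ": ",
      x$alignment_length, " columns, ",
      sprintf("%.1f%%", x$identity_pct), " identity\n", sep = "")
  invisible(x)
}

#' Extract all pairwise reference alignments from an MSA
#'
#' One [pairwise_reference] per unordered row pair, in MSA row order
#' (1-2, 1-3, ..., 2-3, ...). Columns where both rows are gapped are dropped,
#' so each pair contains exactly the residues of its two sequences.
#'
#' @param msa A [multiple_alignment] with at least 2 rows (fewer rows yield
#'   an empty list).
#' @return List of [pairwise_reference] objects, `k*(k-1)/2` of them.
#' @export
extract_pairwise <- function(msa) {
  k <- length(msa$ids)
  if (k < 2L) return(list())
  chars <- strsplit(msa$rows, "")
  out <- vector("list", k * (k - 1L) / 2L)
  idx <- 0L
  for (a in seq_len(k - 1L)) {
    for (b in seq.int(a + 1L, k)) {
      ca <- chars[[a]]
      cb <- chars[[b]]
      keep <- !(ca == "-" & cb == "-")
      idx <- idx + 1L
      out[[idx]] <- pairwise_reference(
        msa$ids[a], msa$ids[b],
        paste(ca[keep], collapse = ""), paste(cb[keep], collapse = ""))
    }
  }
  out
}

#' Pairwise identity of a reference alignment
#'
#' Percentage of gapless columns (columns holding a residue in both rows)
#' whose two residues are identical. A reference with no gapless column has
#' identity 0 with a warning.
#'
#' @param ref A [pairwise_reference].
#' @return Identity percentage in `[0, 100]`.
#' @export
pairwise_identity <- function(ref) {
  ca <- strsplit(ref$row_a, "")[[1L]]
  cb <- strsplit(ref$row_b, "")[[1L]]
  gapless <- ca != "-" & cb != "-"
  n <- sum(gapless)
  if (n == 0L) {
    warning("pairwise_identity: no gapless columns; identity set to 0")
    return(0)
  }
  100 * sum(ca[gapless] == cb[gapless]) / n
}

#' Write a pairwise alignment to disk
#'
#' `gapped-fasta` emits the two gapped rows as FASTA records. `tsv-pairs`
#' emits one line per aligned residue pair with 0-based indices into the
#' ungapped sequences (columns `qry_idx`, `ref_idx`, `qry_res`, `ref_res`).
#'
#' @param aln A [pairwise_reference], or an alignment result from
#'   [smith_waterman]/[needleman_wunsch] carrying gapped strings (see
#'   [alignment_strings]).
#' @param path Output path.
#' @param format `"gapped-fasta"` or `"tsv-pairs"`.
#' @return Invisibly, `path`.
#' @export
write_pairwise_alignment <- function(aln, path,
                                     format = c("gapped-fasta", "tsv-pairs")) {
  format <- match.arg(format)
  if (inherits(aln, "pairwise_reference")) {
    ids <- c(aln$id_a, aln$id_b)
    rows <- c(aln$row_a, aln$row_b)
    pairs <- column_pairs(aln)$pairs
    ca <- strsplit(degap(aln$row_a), "")[[1L]]
    cb <- strsplit(degap(aln$row_b), "")[[1L]]
  } else if (inherits(aln, "alignment_result")) {
    ids <- c(if (is.null(aln$qry_id)) "query" else aln$qry_id,
             if (is.null(aln$ref_id)) "reference" else aln$ref_id)
    rows <- c(aln$gapped_a, aln$gapped_b)
    pairs <- aln$pairs
    ca <- if (is.null(aln$qry_residues)) rep(NA_character_, 0)
          else strsplit(aln$qry_residues, "")[[1L]]
    cb <- if (is.null(aln$ref_residues)) rep(NA_character_, 0)
          else strsplit(aln$ref_residues, "")[[1L]]
  } else {
    stop("write_pairwise_alignment: unsupported object of class '",
         class(aln)[1L], "'")
  }
  if (format == "gapped-fasta") {
    if (any(is.na(rows)) || all(!nzchar(rows))) {
      stop("write_pairwise_alignment: alignment has no gapped strings ",
           "(empty alignment or residues not attached)")
    }
    writeLines(c(paste0(">", ids[1L]), rows[1L],
                 paste0(">", ids[2L]), rows[2L]), path)
  } else {
    df <- data.frame(
      qry_idx = if (nrow(pairs)) pairs[, 1L] else integer(0),
      ref_idx = if (nrow(pairs)) pairs[, 2L] else integer(0))
    df$qry_res <- if (nrow(pairs)) ca[pairs[, 1L] + 1L] else character(0)
    df$ref_res <- if (nrow(pairs)) cb[pairs[, 2L] + 1L] else character(0)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
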