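# Fixture builders shared across the test files. Everything is generated in
# code; no binary fixtures.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_residues <- function(n) paste(sample(AA20, n, replace = TRUE),
                                     collapse = "")

# A random MSA: k rows over ncol columns with a per-cell gap probability,
# retried so every row keeps at least one residue.
random_msa <- function(k, ncol = 12L, gap_p = 0.25) {
  rows <- vapply(seq_len(k), function(r) {
    repeat {
      cells <- ifelse(runif(ncol) < gap_p, "-", sample(AA20, ncol, TRUE))
      if (any(cells != "-")) return(paste(cells, collapse = ""))
    }
  }, character(1L))
  multiple_alignment(paste0("s", seq_len(k)), rows)
}

write_tmp_fasta <- function(records, ext = ".fa") {
  path <- tempfile(fileext = ext)
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

# An MSF rendering of a named list of equal-length gapped rows.
write_tmp_msf <- function(rows) {
  path <- tempfile(fileext = ".msf")
  ncol <- nchar(rows[[1L]])
  lines <- c("PileUp", "",
             sprintf("   MSF: %d  Type: P  Check: 0 ..", ncol), "")
  for (id in names(rows)) {
    lines <- c(lines, sprintf(" Name: %s  Len: %d  Check: 0  Weight: 1.0",
                              id, ncol))
  }
  lines <- c(lines, "", "//", "")
  # two interleaved blocks to exercise block concatenation
  half <- ceiling(ncol / 2)
  for (blk in list(c(1L, half), c(half + 1L, ncol))) {
    for (id in names(rows)) {
      lines <- c(lines,
                 paste(id, substr(rows[[id]], blk[1L], blk[2L])))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  path
}

random_score_matrix <- function(max_dim = 5L, lo = -12, hi = 12) {
  m <- sample.int(max_dim, 1L)
  n <- sample.int(max_dim, 1L)
  matrix(runif(m * n, lo, hi), m, n)
}

expect_same_alignment <- function(dp, bf) {
  expect_equal(dp$score, bf$score, tolerance = 1e-9)
  expect_identical(dp$moves, bf$moves)
  expect_identical(dp$pairs, bf$pairs)
  expect_identical(dp$qry_span, bf$qry_span)
  expect_identical(dp$ref_span, bf$ref_span)
}
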