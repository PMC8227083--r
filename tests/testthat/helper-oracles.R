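# Independent oracles and small fixture builders shared across tests.

# Build a protein_msa object directly from gapped strings.
make_msa <- function(aln, ids = paste0("s", seq_along(aln))) {
  stopifnot(length(unique(nchar(aln))) == 1)
  structure(list(ids = ids, aln = setNames(aln, ids), ncol = nchar(aln[1])),
            class = "protein_msa")
}

# Brute-force longest common substring (enumerate all substrings of a,
# test membership in b).
brute_lcs <- function(a, b) {
  n <- nchar(a)
  best <- ""
  for (w in seq_len(n)) {
    subs <- unique(substring(a, 1:(n - w + 1), w:n))
    hit <- subs[vapply(subs, function(s) grepl(s, b, fixed = TRUE), logical(1))]
    if (length(hit) > 0) best <- sort(hit)[1] else if (w > nchar(best)) break
  }
  best
}

# All common substrings of length >= min_len (brute force).
brute_common <- function(a, b, min_len) {
  n <- nchar(a)
  out <- character(0)
  for (w in min_len:n) {
    if (w > n) break
    subs <- unique(substring(a, 1:(n - w + 1), w:n))
    out <- c(out, subs[vapply(subs, function(s) grepl(s, b, fixed = TRUE),
                              logical(1))])
  }
  unique(out)
}

# Exhaustive-search optimal global alignment score with affine gaps
# (memoized recursion over the full alignment-path space; total gap cost
# for a gap of length L is open + extend * L, end gaps penalized).
oracle_global_score <- function(a, b, mat, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, state) {
    if (i == n && j == m) return(0)
    key <- paste(i, j, state)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i < n && j < m)
      best <- max(best, mat[ca[i + 1], cb[j + 1]] + rec(i + 1, j + 1, "M"))
    if (i < n) {
      cost <- if (state == "X") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i + 1, j, "X"))
    }
    if (j < m) {
      cost <- if (state == "Y") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i, j + 1, "Y"))
    }
    memo[[key]] <- best
    best
  }
  rec(0, 0, "M")
}

# write a seq_set to a temporary FASTA and return the path
tmp_fasta <- function(records, width = 60) {
  p <- tempfile(fileext = ".fasta")
  write_fasta(records, p, width)
  p
}

ncbi_fixture <- function(name) {
  system.file("extdata", "ncbi", paste0(name, ".fasta"), package = "ltpepimap")
}
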