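#' @title Progressive multiple sequence alignment
#' @name progressive_msa
NULL

# A profile is a 21 x L count matrix (rows = 20 residues + gap) plus the
# underlying character matrix of its member rows.
.PROFILE_ALPHA <- c(AA_ALPHABET, "-")

.profile_counts <- function(char_mat) {
  L <- ncol(char_mat)
  counts <- matrix(0L, nrow = length(.PROFILE_ALPHA), ncol = L,
                   dimnames = list(.PROFILE_ALPHA, NULL))
  for (a in .PROFILE_ALPHA) counts[a, ] <- colSums(char_mat == a)
  counts
}

# Extended scoring matrix: BLOSUM-style residue scores, residue-vs-gap -1,
# gap-vs-gap 0 (gap costs proper are handled by the affine DP).
.extended_subst <- function(matrix_name) {
  B <- .subst_matrix(matrix_name)[AA_ALPHABET, AA_ALPHABET]
  E <- matrix(0, 21, 21, dimnames = list(.PROFILE_ALPHA, .PROFILE_ALPHA))
  E[AA_ALPHABET, AA_ALPHABET] <- B
  E[AA_ALPHABET, "-"] <- -1
  E["-", AA_ALPHABET] <- -1
  E
}

# Affine-gap (Gotoh) global alignment of two profiles; returns the two
# column index vectors (0 = gap column inserted).
.align_profiles <- function(ca, cb, E, gap_open, gap_extend) {
  Sa <- .profile_counts(ca); Sb <- .profile_counts(cb)
  na <- colSums(Sa); nb <- colSums(Sb)
  S <- crossprod(Sa, E %*% Sb) / outer(na, nb)   # mean pair score per column pair
  La <- ncol(ca); Lb <- ncol(cb)
  NEG <- -1e9
  M <- matrix(NEG, La + 1, Lb + 1)
  X <- matrix(NEG, La + 1, Lb + 1)  # gap in profile b (consume a column)
  Y <- matrix(NEG, La + 1, Lb + 1)  # gap in profile a
  M[1, 1] <- 0
  if (La >= 1) X[2:(La + 1), 1] <- -gap_open - gap_extend * (0:(La - 1))
  if (Lb >= 1) Y[1, 2:(Lb + 1)] <- -gap_open - gap_extend * (0:(Lb - 1))
  for (i in 2:(La + 1)) {
    Sx <- S[i - 1, ]
    for (j in 2:(Lb + 1)) {
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + Sx[j - 1]
      X[i, j] <- max(M[i - 1, j] - gap_open, X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open, Y[i, j - 1] - gap_extend)
    }
  }
  # traceback, deterministic state preference M > X > Y
  i <- La + 1; j <- Lb + 1
  vals <- c(M[i, j], X[i, j], Y[i, j])
  state <- which.max(vals)
  pa <- integer(0); pb <- integer(0)
  while (i > 1 || j > 1) {
    if (state == 1 && i > 1 && j > 1) {
      pa <- c(i - 1, pa); pb <- c(j - 1, pb)
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if ((state == 2 && i > 1) || (j == 1 && i > 1)) {
      pa <- c(i - 1, pa); pb <- c(0, pb)
      if (i > 2 || j > 1) {
        opts <- c(M[i - 1, j] - gap_open, X[i - 1, j] - gap_extend)
        state <- if (abs(X[i, j] - opts[1]) < 1e-9) 1 else 2
      }
      i <- i - 1
    } else {
      pa <- c(0, pa); pb <- c(j - 1, pb)
      if (j > 2 || i > 1) {
        opts <- c(M[i, j - 1] - gap_open, Y[i, j - 1] - gap_extend)
        state <- if (abs(Y[i, j] - opts[1]) < 1e-9) 1 else 3
      }
      j <- j - 1
    }
  }
  list(a = pa, b = pb)
}

.expand_profile <- function(char_mat, idx) {
  out <- matrix("-", nrow = nrow(char_mat), ncol = length(idx))
  nz <- idx > 0
  out[, nz] <- char_mat[, idx[nz], drop = FALSE]
  rownames(out) <- rownames(char_mat)
  out
}

#' Progressive multiple sequence alignment
#'
#' Progressive alignment in the Clustal style: pairwise identity distances
#' give a UPGMA guide tree, and profiles are merged bottom-up by global
#' profile-profile alignment (affine gaps, mean-of-pairs substitution
#' score).  Deterministic for a fixed input order.
#'
#' @param records a [seq_set()] with at least two rows.
#' @param params an [align_params()] list (matrix and gap penalties).
#' @return an object of class `protein_msa`: list with `ids`, `aln`
#'   (gapped residue strings, equal length, input order) and `ncol`.
#' @export
progressive_msa <- function(records, params = align_params()) {
  n <- nrow(records)
  if (is.null(n) || n < 2) stop("need at least 2 sequences")
  E <- .extended_subst(params$matrix)
  # guide tree from pairwise identity distances
  chars <- lapply(records$residues, function(s) strsplit(s, "")[[1]])
  if (n == 2) {
    profs <- list(matrix(chars[[1]], nrow = 1, dimnames = list(records$id[1], NULL)),
                  matrix(chars[[2]], nrow = 1, dimnames = list(records$id[2], NULL)))
    idx <- .align_profiles(profs[[1]], profs[[2]], E, params$gap_open, params$gap_extend)
    merged <- rbind(.expand_profile(profs[[1]], idx$a),
                    .expand_profile(profs[[2]], idx$b))
  } else {
    d <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      al <- pairwise_align(records$residues[i], records$residues[j], "global", params)
      ca <- strsplit(al$a, "")[[1]]; cb <- strsplit(al$b, "")[[1]]
      d[i, j] <- d[j, i] <- 1 - sum(ca == cb & ca != "-") / length(ca)
    }
    hc <- hclust(as.dist(d), method = "average")
    profs <- vector("list", n - 1)
    get_prof <- function(k) {
      if (k < 0) matrix(chars[[-k]], nrow = 1, dimnames = list(records$id[-k], NULL))
      else profs[[k]]
    }
    for (m in seq_len(n - 1)) {
      p1 <- get_prof(hc$merge[m, 1]); p2 <- get_prof(hc$merge[m, 2])
      idx <- .align_profiles(p1, p2, E, params$gap_open, params$gap_extend)
      profs[[m]] <- rbind(.expand_profile(p1, idx$a), .expand_profile(p2, idx$b))
    }
    merged <- profs[[n - 1]]
  }
  merged <- merged[records$id, , drop = FALSE]
  structure(list(ids = records$id,
                 aln = apply(merged, 1, paste, collapse = ""),
                 ncol = ncol(merged)),
            class = "protein_msa")
}

#' @export
print.protein_msa <- function(x, ...) {
  cat(sprintf("protein_msa: %d sequences x %d columns\n", length(x$ids), x$ncol))
  invisible(x)
}

#' Alignment as a character matrix
#' @param msa a `protein_msa`.
#' @return character matrix, rows = sequences, columns = alignment columns.
#' @export
msa_matrix <- function(msa) {
  stopifnot(inherits(msa, "protein_msa"))
  m <- do.call(rbind, strsplit(unname(msa$aln), ""))
  rownames(m) <- msa$ids
  m
}

#' Write an alignment as gapped FASTA
#' @param msa a `protein_msa`.
#' @param path output path.
#' @param width wrap width.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path, width = 60) {
  df <- data.frame(id = msa$ids, description = "",
                   residues = unname(msa$aln), stringsAsFactors = FALSE)
  write_fasta(df, path, width)
}

#' Clustal-style conservation symbols
#'
#' Per-column symbols as printed under a Clustal alignment: `*` for a
#' gap-free identical column; `:` when every residue falls in one "strong"
#' group (Gonnet PAM250 pair score > 0.5); `.` for one "weak" group; blank
#' otherwise.  Any gap in a column disqualifies all three symbols.
#'
#' @param msa a `protein_msa`.
#' @return character vector of length `msa$ncol` over `c("*", ":", ".", " ")`.
#' @export
conservation_symbols <- function(msa) {
  m <- msa_matrix(msa)
  vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (any(col == "-")) return(" ")
    if (length(unique(col)) == 1L) return("*")
    u <- unique(col)
    if (.in_single_group(u, .strong_lookup)) return(":")
    if (.in_single_group(u, .weak_lookup)) return(".")
    " "
  }, character(1))
}

#' Per-residue percent conservation of a reference sequence
#'
#' For each residue of the chosen reference row, the score is the number of
#' alignment rows carrying that same residue in that column, times 100,
#' divided by the total number of sequences.  Gaps never count as matches.
#' Scores are reported at full precision and floored to integer percent for
#' display (`score_floor`), so 14 of 15 gives 93 and 2 of 15 gives 13.
#'
#' @param msa a `protein_msa`.
#' @param reference_id row id whose residues are scored.
#' @param n_total denominator; defaults to the number of counted rows.
#' @param exclude_reference when TRUE the reference row is only the
#'   coordinate system and is not counted (used when a reference protein
#'   is aligned alongside the N sequences being scored).
#' @return data.frame with `position` (1-based residue number in the
#'   reference), `residue`, `column` (alignment column), `score`,
#'   `score_floor`.
#' @export
conservation_score <- function(msa, reference_id, n_total = NULL,
                               exclude_reference = FALSE) {
  m <- msa_matrix(msa)
  if (!reference_id %in% rownames(m))
    stop("reference id not in alignment: ", reference_id)
  counted <- if (exclude_reference)
    m[setdiff(rownames(m), reference_id), , drop = FALSE] else m
  if (is.null(n_total)) n_total <- nrow(counted)
  ref <- m[reference_id, ]
  cols <- which(ref != "-")
  score <- vapply(cols, function(j) sum(counted[, j] == ref[j]) * 100 / n_total,
                  numeric(1))
  data.frame(position = seq_along(cols), residue = ref[cols],
             column = cols, score = score,
             score_floor = floor(score), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Full conservation profile for a reference sequence
#'
#' Combines [conservation_symbols()] and [conservation_score()] mapped onto
#' the reference residue numbering.
#'
#' @inheritParams conservation_score
#' @return data.frame with `position`, `residue`, `column`, `symbol`,
#'   `score`, `score_floor`.
#' @export
conservation_profile <- function(msa, reference_id, n_total = NULL) {
  sc <- conservation_score(msa, reference_id, n_total)
  sym <- conservation_symbols(msa)
  sc$symbol <- sym[sc$column]
  sc[, c("position", "residue", "column", "symbol", "score", "score_floor")]
}

#' Uncorrected pairwise distance matrix from an alignment
#'
#' d(i, j) = 1 - fractional identity over columns where neither row is
#' gapped (p-distance, no correction), the distance used for
#' neighbor-joining without corrections.
#'
#' @param msa a `protein_msa`.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(msa) {
  m <- msa_matrix(msa)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok))
      stop(sprintf("no comparable columns between '%s' and '%s'",
                   rownames(m)[i], rownames(m)[j]))
    d[i, j] <- d[j, i] <- 1 - sum(m[i, ok] == m[j, ok]) / sum(ok)
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on an uncorrected distance matrix (via
#' [ape::nj()]); negative branch lengths are clamped to zero.
#'
#' @param d symmetric distance matrix with row/col names, >= 3 taxa.
#' @return an [ape::read.tree()] `phylo` object (unrooted).
#' @export
nj_tree <- function(d) {
  if (nrow(d) < 3) stop("need at least 3 taxa for neighbor joining")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Write a tree in Newick format
#' @param tree a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
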