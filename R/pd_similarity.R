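.pd_cache <- new.env(parent = emptyenv())

#' Five-dimensional amino-acid descriptor table
#'
#' Loads the shipped E1-E5 descriptor coordinates (principal-component
#' summary of physicochemical residue properties) used for property-distance
#' peptide similarity.
#'
#' @param path TSV path; defaults to the packaged table.
#' @return 20 x 5 numeric matrix, rownames = residues.
#' @export
aa_descriptors <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pd_cache$desc)) return(.pd_cache$desc)
    path <- system.file("extdata", "aa_descriptors_5d.tsv", package = "ltpepimap")
  }
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, c("E1", "E2", "E3", "E4", "E5")])
  rownames(m) <- df$residue
  if (!all(AA_ALPHABET %in% rownames(m)))
    stop("descriptor table must cover all 20 residues")
  if (any(!is.finite(m))) stop("non-finite descriptor value")
  .pd_cache$desc <- m
  m
}

# 20 x 20 per-residue Euclidean distance matrix in descriptor space
.residue_dist <- function(table) {
  as.matrix(stats::dist(table))
}

#' Shipped PD calibration
#'
#' The calibration constant `c` rescales raw mean per-position descriptor
#' distances onto the conventional PD scale (identity 0, conservative
#' substitutions < 4, unrelated peptides > 10).  It was fixed once by
#' [pd_calibrate()] with the recorded seed/anchor and is shipped as a
#' config file; it is never recomputed silently.
#'
#' @param path JSON path; defaults to the packaged config.
#' @return list with `c`, `anchor`, `seed`, `n_pairs`, `raw_median`.
#' @export
pd_calibration <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.pd_cache$calib)) return(.pd_cache$calib)
    path <- system.file("extdata", "pd_calibration.json", package = "ltpepimap")
  }
  cal <- jsonlite::read_json(path, simplifyVector = TRUE)
  .pd_cache$calib <- cal
  cal
}

#' Property distance between two equal-length peptides
#'
#' PD = c x (1/n) x sum of per-position Euclidean distances in the 5-D
#' descriptor space.  Identical peptides give exactly 0; the distance is a
#' metric (symmetry and the triangle inequality are inherited from the
#' per-position Euclidean distance) and is invariant under concatenating a
#' pair with itself (length normalization).
#'
#' @param pep_a,pep_b equal-length residue strings.
#' @param table descriptor matrix from [aa_descriptors()].
#' @param calibration calibration constant c (default: shipped value).
#' @return non-negative PD value.
#' @export
#' @examples
#' pd_distance("IPYKIS", "IPYKIS")   # 0
pd_distance <- function(pep_a, pep_b, table = aa_descriptors(),
                        calibration = pd_calibration()$c) {
  pep_a <- normalize_motif(pep_a); pep_b <- normalize_motif(pep_b)
  if (!nzchar(pep_a) || nchar(pep_a) != nchar(pep_b))
    stop("peptides must be non-empty and of equal length")
  a <- strsplit(pep_a, "")[[1]]; b <- strsplit(pep_b, "")[[1]]
  if (any(!c(a, b) %in% rownames(table))) stop("unknown residue")
  D <- .residue_dist(table)
  calibration * mean(D[cbind(a, b)])
}

#' Calibrate the PD scale
#'
#' Chooses the constant c so the median PD over `n_pairs` uniformly random
#' unrelated 10-mer pairs equals `anchor`.  With the default anchor 13,
#' identical peptides sit at 0, single conservative substitutions fall
#' below the usual similarity threshold of 4, and random pairs fall above
#' 10.  The result is meant to be persisted and reused, not recomputed per
#' run.
#'
#' @param table descriptor matrix.
#' @param seed RNG seed.
#' @param n_pairs number of random pairs (>= 1000).
#' @param anchor target median PD for random pairs (default 13).
#' @return list with `c`, `anchor`, `seed`, `n_pairs`, `raw_median`.
#' @export
pd_calibrate <- function(table = aa_descriptors(), seed = 42, n_pairs = 10000,
                         anchor = 13) {
  stopifnot(n_pairs >= 1000)
  D <- .residue_dist(table)
  if (max(D) == 0) stop("degenerate descriptor table: all residues identical")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  raw <- vapply(seq_len(n_pairs), function(i) {
    a <- sample(AA_ALPHABET, 10, replace = TRUE)
    b <- sample(AA_ALPHABET, 10, replace = TRUE)
    mean(D[cbind(a, b)])
  }, numeric(1))
  m <- median(raw)
  list(c = anchor / m, anchor = anchor, seed = seed, n_pairs = n_pairs,
       raw_median = m)
}

#' Scan a query peptide against an allergen database
#'
#' Evaluates every window of exactly the query length in every database
#' sequence and reports windows with PD below `threshold`, sorted by PD
#' ascending (ties by subject id then offset).
#'
#' @param query peptide string (non-empty).
#' @param db a [seq_set()] of subject sequences.
#' @param threshold report matches with PD strictly below this value
#'   (default 4, the conventional conservative-similarity cutoff); exact
#'   matches (PD = 0) are always reported, so `threshold = 0` returns
#'   exactly the identity windows; use `Inf` to return all windows.
#' @param table descriptor matrix.
#' @param calibration calibration constant c.
#' @return data.frame: `query`, `subject_id`, `offset` (1-based),
#'   `subject_peptide`, `pd`.
#' @export
pd_scan <- function(query, db, threshold = 4, table = aa_descriptors(),
                    calibration = pd_calibration()$c) {
  stopifnot(threshold >= 0)
  query <- normalize_motif(query)
  if (!nzchar(query)) stop("empty query peptide")
  q <- strsplit(query, "")[[1]]
  if (any(!q %in% rownames(table))) stop("unknown residue in query")
  D <- .residue_dist(table)
  n <- length(q)
  rows <- list(); k <- 0
  for (j in seq_len(nrow(db))) {
    s <- db$residues[j]
    L <- nchar(s)
    if (L < n) next
    sc <- strsplit(s, "")[[1]]
    for (off in seq_len(L - n + 1)) {
      win <- sc[off:(off + n - 1)]
      pd <- calibration * mean(D[cbind(q, win)])
      if (pd < threshold || pd == 0) {
        k <- k + 1
        rows[[k]] <- data.frame(query = query, subject_id = db$id[j],
                                offset = off,
                                subject_peptide = paste(win, collapse = ""),
                                pd = pd, stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0)
    return(data.frame(query = character(0), subject_id = character(0),
                      offset = integer(0), subject_peptide = character(0),
                      pd = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$pd, out$subject_id, out$offset), , drop = FALSE]
}

#' Random peptides
#'
#' Uniform i.i.d. residues over the 20-letter alphabet; used for PD
#' calibration and behavioral checks.
#'
#' @param n number of peptides.
#' @param length peptide length (scalar or vector recycled to `n`).
#' @param seed optional RNG seed.
#' @return character vector of peptides.
#' @export
random_peptides <- function(n, length = 10, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  length <- rep_len(length, n)
  vapply(seq_len(n), function(i)
    paste(sample(AA_ALPHABET, length[i], replace = TRUE), collapse = ""),
    character(1))
}
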