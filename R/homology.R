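#' Alignment scoring parameters
#'
#' Defaults follow common practice for protein allergenicity screening:
#' BLOSUM62 with affine gap penalties (open 10, extend 0.5).  The identity
#' denominator counts every alignment column including gap columns
#' (conservative, as in Codex-style >=35%/80-aa screening); set
#' `denominator = "shorter"` to divide by the shorter sequence length.
#'
#' @param matrix substitution matrix name (any matrix shipped with
#'   Biostrings, e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`).
#' @param gap_open,gap_extend positive gap penalties.
#' @param denominator `"alignment"` or `"shorter"`.
#' @return a list of class `align_params`.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5,
                         denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, denominator = denominator),
            class = "align_params")
}

.subst_matrix <- function(name) {
  e <- new.env()
  data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Optimal pairwise alignment of two protein sequences
#'
#' Needleman-Wunsch (global) or Smith-Waterman (local) alignment with
#' affine gaps, via [Biostrings::pairwiseAlignment()].
#'
#' @param a,b residue strings (non-empty).
#' @param scope `"global"` or `"local"`.
#' @param params an [align_params()] list.
#' @return list with gapped strings `a` and `b` (equal length), `score`,
#'   and `scope`.
#' @export
#' @examples
#' pairwise_align("ACDEFG", "ACDEFH")
pairwise_align <- function(a, b, scope = c("global", "local"),
                           params = align_params()) {
  scope <- match.arg(scope)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  al <- Biostrings::pairwiseAlignment(
    pattern = a, subject = b,
    type = scope,
    substitutionMatrix = .subst_matrix(params$matrix),
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  if (scope == "global") {
    # alignedPattern/Subject keep end gaps; pattern()/subject() trim them
    list(a = as.character(Biostrings::alignedPattern(al)),
         b = as.character(Biostrings::alignedSubject(al)),
         score = Biostrings::score(al), scope = scope)
  } else {
    list(a = as.character(Biostrings::pattern(al)),
         b = as.character(Biostrings::subject(al)),
         score = Biostrings::score(al), scope = scope)
  }
}

#' Percent identity of an alignment
#'
#' 100 x (identical aligned residue pairs) / denominator, rounded half-up
#' to two decimals.  The default denominator is the alignment length
#' including gap columns.
#'
#' @param alignment a list with gapped strings `a` and `b` as returned by
#'   [pairwise_align()].
#' @param denominator `"alignment"` or `"shorter"` (shorter de-gapped
#'   sequence length).
#' @return percent identity (0-100, two decimals).
#' @export
percent_identity <- function(alignment, denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  ca <- strsplit(alignment$a, "")[[1]]
  cb <- strsplit(alignment$b, "")[[1]]
  if (length(ca) != length(cb)) stop("gapped strings differ in length")
  if (length(ca) == 0) return(0)
  matches <- sum(ca == cb & ca != "-")
  denom <- if (denominator == "alignment") length(ca)
           else min(sum(ca != "-"), sum(cb != "-"))
  round_half_up(100 * matches / denom, 2)
}

.hit_row <- function(query_id, subject_id, mode, identity, ws, we, alen) {
  data.frame(query_id = query_id, subject_id = subject_id, mode = mode,
             identity_pct = identity,
             window_start = ws, window_end = we, aligned_length = alen,
             stringsAsFactors = FALSE)
}

.sort_hits <- function(hits) {
  hits[order(-hits$identity_pct, hits$subject_id), , drop = FALSE]
}

#' Full-length homology screen
#'
#' Globally aligns a query protein against every member of a local allergen
#' database and reports percent identity per subject, the first of the two
#' allergen-database search modes (the other is [sliding_window_screen()]).
#'
#' @param query a single-row [seq_set()] (or list with `id` and `residues`).
#' @param db a [seq_set()] of database sequences (may be empty).
#' @param params an [align_params()] list.
#' @return data.frame of hits sorted by identity descending then subject id;
#'   columns `query_id`, `subject_id`, `mode`, `identity_pct`,
#'   `window_start`, `window_end` (NA for full-length), `aligned_length`.
#' @export
full_length_screen <- function(query, db, params = align_params()) {
  if (nrow(db) == 0)
    return(.hit_row(character(0), character(0), character(0),
                    numeric(0), integer(0), integer(0), integer(0)))
  hits <- do.call(rbind, lapply(seq_len(nrow(db)), function(j) {
    al <- pairwise_align(query$residues, db$residues[j], "global", params)
    .hit_row(query$id, db$id[j], "full_length",
             percent_identity(al, params$denominator),
             NA_integer_, NA_integer_, nchar(al$a))
  }))
  .sort_hits(hits)
}

#' 80-amino-acid sliding-window homology screen
#'
#' Every length-`window` query window (step 1) is locally aligned against
#' the full subject; the best-identity window per subject is reported.
#' Queries shorter than `window` are screened as a single window.  This is
#' the Codex-style 80-aa sliding-window allergenicity search mode; window
#' identity is the matched-residue count divided by the window length, so
#' a short high-scoring local segment inside an otherwise unrelated window
#' cannot inflate the percentage.
#'
#' @inheritParams full_length_screen
#' @param window window length in residues (default 80).
#' @param step window step (default 1).
#' @return data.frame of best-window hits sorted by identity descending;
#'   `window_start`/`window_end` give the 1-based query window.
#' @export
sliding_window_screen <- function(query, db, window = 80, step = 1,
                                  params = align_params()) {
  if (nrow(db) == 0)
    return(.hit_row(character(0), character(0), character(0),
                    numeric(0), integer(0), integer(0), integer(0)))
  qlen <- nchar(query$residues)
  w <- min(window, qlen)
  starts <- seq(1, qlen - w + 1, by = step)
  windows <- substring(query$residues, starts, starts + w - 1)
  mat <- .subst_matrix(params$matrix)
  hits <- do.call(rbind, lapply(seq_len(nrow(db)), function(j) {
    al <- Biostrings::pairwiseAlignment(
      pattern = windows, subject = db$residues[j], type = "local",
      substitutionMatrix = mat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    pa <- as.character(Biostrings::pattern(al))
    pb <- as.character(Biostrings::subject(al))
    # window-mode identity is matches over the window length, as in
    # Codex-style >=35%/80-aa screening: a short high-identity local
    # segment must not inflate the window percentage
    ids <- vapply(seq_along(pa), function(k) {
      if (!nzchar(pa[k])) return(0)
      ca <- strsplit(pa[k], "")[[1]]; cb <- strsplit(pb[k], "")[[1]]
      round_half_up(100 * sum(ca == cb & ca != "-") / w, 2)
    }, numeric(1))
    best <- which.max(ids)   # ties -> lowest window start
    .hit_row(query$id, db$id[j], "window80", ids[best],
             starts[best], starts[best] + w - 1L, nchar(pa[best]))
  }))
  .sort_hits(hits)
}

#' Number of sliding windows evaluated for a query
#'
#' `max(1, L - window + 1)` at step 1: a query shorter than the window is
#' screened as a single whole-query window.
#'
#' @param query_length query length in residues.
#' @param window window size (default 80).
#' @param step window step (default 1).
#' @return integer window count.
#' @export
n_windows <- function(query_length, window = 80, step = 1) {
  if (query_length <= window) return(1L)
  length(seq(1, query_length - window + 1, by = step))
}

#' Run both screening modes for a set of queries
#'
#' @param queries a [seq_set()] of query proteins.
#' @param db allergen database [seq_set()].
#' @param modes subset of `c("full_length", "window80")`.
#' @inheritParams sliding_window_screen
#' @return combined hit data.frame.
#' @export
homology_screen <- function(queries, db, modes = c("full_length", "window80"),
                            window = 80, step = 1, params = align_params()) {
  out <- lapply(seq_len(nrow(queries)), function(i) {
    q <- queries[i, , drop = FALSE]
    rows <- list()
    if ("full_length" %in% modes)
      rows <- c(rows, list(full_length_screen(q, db, params)))
    if ("window80" %in% modes)
      rows <- c(rows, list(sliding_window_screen(q, db, window, step, params)))
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}
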