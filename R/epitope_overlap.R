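#' Normalize hyphenated motif notation
#'
#' Turns "I-P-Y-K-I-S" style residue listings into plain strings.
#'
#' @param x character vector of motifs.
#' @return plain upper-case residue strings.
#' @export
normalize_motif <- function(x) toupper(gsub("[-[:space:]]", "", x))

# Accept an epitope collection as a character vector of residue strings or
# as a region data.frame (load_reported_epitopes() / consensus_regions()).
.ep_strings <- function(x) {
  if (is.data.frame(x)) {
    s <- x$residues
    names(s) <- if (!is.null(x$epitope)) as.character(x$epitope) else seq_along(s)
    s
  } else {
    s <- normalize_motif(as.character(x))
    if (is.null(names(s))) names(s) <- seq_along(s)
    s
  }
}

# All maximal common substring occurrences of length >= min_len between
# two strings: data.frame(motif, offset_a, offset_b), 1-based offsets.
.maximal_common <- function(a, b, min_len) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  out <- list(); k <- 0
  L <- integer(m)
  for (i in seq_len(n)) {
    newL <- integer(m)
    match_j <- which(cb == ca[i])
    for (j in match_j) newL[j] <- if (j > 1) L[j - 1] + 1L else 1L
    # a run is maximal to the right where it cannot be extended at (i+1, j+1)
    for (j in match_j) {
      len <- newL[j]
      if (len < min_len) next
      ext <- i < n && j < m && ca[i + 1] == cb[j + 1]
      if (!ext) {
        k <- k + 1
        out[[k]] <- data.frame(
          motif = paste(ca[(i - len + 1):i], collapse = ""),
          offset_a = i - len + 1L, offset_b = j - len + 1L,
          stringsAsFactors = FALSE)
      }
    }
    L <- newL
  }
  if (k == 0)
    data.frame(motif = character(0), offset_a = integer(0),
               offset_b = integer(0), stringsAsFactors = FALSE)
  else do.call(rbind, out)
}

#' Maximal shared substrings between two epitope collections
#'
#' Finds every maximal common substring of length >= `min_len` between any
#' epitope of `set_a` and any epitope of `set_b` (maximal = not extendable
#' on either side in that pair of epitopes), deduplicated by motif and
#' sorted by length descending then lexicographically.
#'
#' @param set_a,set_b epitope collections: character vectors of residue
#'   strings (hyphenated notation accepted) or region data.frames with a
#'   `residues` column.
#' @param min_len minimum motif length (default 4, the shortest shared
#'   epitope region typically reported for LTPs).
#' @return data.frame with `motif`, `length`, and a list-column `members`
#'   of occurrence data.frames (`set`, `epitope`, `offset`).
#' @export
shared_substrings <- function(set_a, set_b, min_len = 4) {
  stopifnot(min_len >= 1)
  ea <- .ep_strings(set_a); eb <- .ep_strings(set_b)
  occ <- list(); k <- 0
  for (i in seq_along(ea)) for (j in seq_along(eb)) {
    mm <- .maximal_common(ea[i], eb[j], min_len)
    if (nrow(mm) == 0) next
    k <- k + 1
    occ[[k]] <- data.frame(
      motif = mm$motif,
      set = rep(c("a", "b"), each = nrow(mm)),
      epitope = rep(c(names(ea)[i], names(eb)[j]), each = nrow(mm)),
      offset = c(mm$offset_a, mm$offset_b),
      stringsAsFactors = FALSE)
  }
  if (k == 0)
    return(data.frame(motif = character(0), length = integer(0),
                      members = I(list()), stringsAsFactors = FALSE))
  occ <- do.call(rbind, occ)
  motifs <- unique(occ$motif)
  motifs <- motifs[order(-nchar(motifs), motifs)]
  data.frame(
    motif = motifs, length = nchar(motifs),
    members = I(lapply(motifs, function(m)
      unique(occ[occ$motif == m, c("set", "epitope", "offset")]))),
    stringsAsFactors = FALSE)
}

.occurs_in_set <- function(motif, set_strings) {
  any(vapply(set_strings, function(s) grepl(motif, s, fixed = TRUE), logical(1)))
}

# keep only strings not a proper substring of another in the vector; dedupe
.maximal_strings <- function(x) {
  x <- unique(x)
  if (length(x) <= 1) return(x)
  keep <- vapply(seq_along(x), function(i) {
    !any(vapply(x[-i], function(y)
      nchar(y) > nchar(x[i]) && grepl(x[i], y, fixed = TRUE), logical(1)))
  }, logical(1))
  x <- x[keep]
  x[order(-nchar(x), x)]
}

# all substrings of length >= min_len of a set of motifs
.all_subs <- function(motifs, min_len) {
  unique(unlist(lapply(motifs, function(m) {
    n <- nchar(m)
    if (n < min_len) return(character(0))
    unlist(lapply(min_len:n, function(w)
      substring(m, 1:(n - w + 1), w:n)))
  })))
}

#' Three-set shared-epitope (Venn triad) partition
#'
#' Partitions shared motifs among three labelled epitope collections into
#' the most-specific Venn cell: the three-way cell holds maximal motifs
#' common to all three sets; each two-way cell holds maximal motifs common
#' to exactly those two (i.e. not occurring anywhere in the third).  Cells
#' are motif-disjoint by construction.
#'
#' @param sets named list of exactly three epitope collections (see
#'   [shared_substrings()] for accepted forms).
#' @param min_len minimum motif length (default 4).
#' @return list of class `triad_partition` with character-vector cells
#'   `abc`, `ab`, `ac`, `bc` and a `labels` element; empty cells are
#'   `character(0)` and render as "0".
#' @export
triad_partition <- function(sets, min_len = 4) {
  if (length(sets) != 3) stop("exactly three epitope sets required")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- c("A", "B", "C")
  s <- lapply(sets, .ep_strings)
  pair_motifs <- function(i, j) shared_substrings(s[[i]], s[[j]], min_len)$motif
  ab <- pair_motifs(1, 2); ac <- pair_motifs(1, 3); bc <- pair_motifs(2, 3)
  # three-way: substrings common to one pair that also occur in the third
  cand <- unique(c(
    Filter(function(m) .occurs_in_set(m, s[[3]]), .all_subs(ab, min_len)),
    Filter(function(m) .occurs_in_set(m, s[[2]]), .all_subs(ac, min_len)),
    Filter(function(m) .occurs_in_set(m, s[[1]]), .all_subs(bc, min_len))))
  abc <- .maximal_strings(unlist(cand))
  only <- function(motifs, third) .maximal_strings(
    Filter(function(m) !.occurs_in_set(m, third), motifs))
  structure(list(
    abc = if (length(abc)) abc else character(0),
    ab = only(ab, s[[3]]), ac = only(ac, s[[2]]), bc = only(bc, s[[1]]),
    labels = names(sets)), class = "triad_partition")
}

#' @export
print.triad_partition <- function(x, ...) {
  lab <- x$labels
  cell <- function(v) if (length(v) == 0) "0" else paste(v, collapse = ", ")
  cat(sprintf("%s & %s & %s : %s\n", lab[1], lab[2], lab[3], cell(x$abc)))
  cat(sprintf("%s & %s       : %s\n", lab[1], lab[2], cell(x$ab)))
  cat(sprintf("%s & %s       : %s\n", lab[1], lab[3], cell(x$ac)))
  cat(sprintf("%s & %s       : %s\n", lab[2], lab[3], cell(x$bc)))
  invisible(x)
}

#' Triad partition as a plain list for serialization
#'
#' Empty cells are rendered as the string "0".
#'
#' @param x a `triad_partition`.
#' @return named list of character vectors (or "0").
#' @export
triad_cells <- function(x) {
  stopifnot(inherits(x, "triad_partition"))
  cell <- function(v) if (length(v) == 0) "0" else v
  lab <- x$labels
  setNames(
    list(cell(x$abc), cell(x$ab), cell(x$ac), cell(x$bc)),
    c(paste(lab, collapse = "&"),
      paste(lab[c(1, 2)], collapse = "&"),
      paste(lab[c(1, 3)], collapse = "&"),
      paste(lab[c(2, 3)], collapse = "&")))
}

#' Check predicted epitopes against validated reference epitopes
#'
#' For each validated epitope, reports all maximal motifs shared with the
#' predicted set, and a per-epitope overlap flag.
#'
#' @param predicted epitope collection (strings or region data.frame).
#' @param validated validated epitope collection, non-empty (defaults to
#'   the packaged peach Pru p 3 epitopes).
#' @param min_len minimum motif length.
#' @return list with `matches` (data.frame: `validated_epitope`, `motif`,
#'   `length`, `predicted_epitope`, `predicted_offset`,
#'   `validated_offset`) and `overlap` (data.frame: `validated_epitope`,
#'   `shared` flag, `longest_motif`).
#' @export
validated_epitope_check <- function(predicted, validated = validated_peach_epitopes(),
                                    min_len = 4) {
  ev <- .ep_strings(validated)
  if (length(ev) == 0) stop("validated epitope set is empty")
  matches <- list(); k <- 0
  flags <- logical(length(ev)); longest <- character(length(ev))
  for (i in seq_along(ev)) {
    sh <- shared_substrings(predicted, ev[i], min_len)
    flags[i] <- nrow(sh) > 0
    longest[i] <- if (nrow(sh) > 0) sh$motif[1] else ""
    if (nrow(sh) == 0) next
    for (r in seq_len(nrow(sh))) {
      mem <- sh$members[[r]]
      pa <- mem[mem$set == "a", , drop = FALSE]
      pb <- mem[mem$set == "b", , drop = FALSE]
      k <- k + 1
      matches[[k]] <- data.frame(
        validated_epitope = names(ev)[i], motif = sh$motif[r],
        length = sh$length[r],
        predicted_epitope = paste(unique(pa$epitope), collapse = ","),
        predicted_offset = pa$offset[1],
        validated_offset = pb$offset[1],
        stringsAsFactors = FALSE)
    }
  }
  list(
    matches = if (k == 0)
      data.frame(validated_epitope = character(0), motif = character(0),
                 length = integer(0), predicted_epitope = character(0),
                 predicted_offset = integer(0), validated_offset = integer(0),
                 stringsAsFactors = FALSE)
    else do.call(rbind, matches),
    overlap = data.frame(validated_epitope = names(ev), shared = flags,
                         longest_motif = longest, stringsAsFactors = FALSE))
}
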