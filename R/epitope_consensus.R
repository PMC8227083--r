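.scales_cache <- new.env(parent = emptyenv())

#' Load the propensity-scale registry
#'
#' @return named list: scale name -> named numeric vector over the 20
#'   residues.
#' @export
propensity_scales <- function() {
  if (is.null(.scales_cache$tab)) {
    path <- system.file("extdata", "propensity_scales.tsv", package = "ltpepimap")
    df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    .scales_cache$tab <- lapply(split(df, df$scale), function(s)
      setNames(s$value, s$residue)[AA_ALPHABET])
  }
  .scales_cache$tab
}

#' Names of the default predictor panel
#' @return character vector of scale names.
#' @export
default_scales <- function() names(propensity_scales())

#' Sliding-window propensity profile for one scale
#'
#' Computes the windowed per-residue statistic for one propensity scale
#' (arithmetic window mean for all scales except `emini_accessibility`,
#' which uses the published product form \eqn{0.37^{-w} \prod s_i}),
#' z-normalizes it over the sequence, and makes a per-residue binary
#' epitope call.  The default call rule is z > `threshold`;
#' `kolaskar_tongaonkar_antigenicity` instead uses its published absolute
#' rule (window propensity mean > 1.0).  Windows are symmetric and
#' truncated at the termini.  A zero-variance profile yields no calls.
#'
#' @param seq residue string.
#' @param scale scale name from [default_scales()], or a named numeric
#'   vector over the 20 residues (custom scale).
#' @param window odd window size (default 7); must not exceed the sequence
#'   length.
#' @param threshold z-score call threshold (default 0).
#' @return object of class `propensity_profile`: list with `scale`,
#'   `window`, `seq`, `raw`, `z`, `call` (logical).
#' @export
scale_profile <- function(seq, scale, window = 7, threshold = 0) {
  stopifnot(nzchar(seq))
  if (window %% 2 != 1) stop("window must be odd")
  n <- nchar(seq)
  if (window > n) stop("window larger than sequence length")
  if (is.character(scale)) {
    reg <- propensity_scales()
    if (!scale %in% names(reg)) stop("unknown scale: ", scale)
    values <- reg[[scale]]
    scale_name <- scale
  } else {
    if (!all(AA_ALPHABET %in% names(scale)))
      stop("custom scale must name all 20 residues")
    values <- scale[AA_ALPHABET]
    scale_name <- "custom"
  }
  res <- strsplit(seq, "")[[1]]
  if (any(!res %in% AA_ALPHABET))
    stop("illegal residue in sequence")
  v <- values[res]
  half <- (window - 1) / 2
  emini <- identical(scale_name, "emini_accessibility")
  raw <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    win <- v[lo:hi]
    if (emini) {
      # product form; truncated terminal windows use the geometric mean
      # raised to the nominal window size, so a homopolymer still gives a
      # flat profile
      (prod(win)^(1 / length(win)) / 0.37)^window
    } else {
      mean(win)
    }
  }, numeric(1))
  s <- stats::sd(raw)
  flat <- is.na(s) || s == 0
  z <- if (flat) rep(0, n) else (raw - mean(raw)) / s
  # a zero-variance profile is uninformative and yields no calls for any
  # rule, including the absolute Kolaskar-Tongaonkar one
  call <- if (flat) {
    rep(FALSE, n)
  } else if (identical(scale_name, "kolaskar_tongaonkar_antigenicity")) {
    raw > 1.0
  } else {
    z > threshold
  }
  structure(list(scale = scale_name, window = window, seq = seq,
                 raw = unname(raw), z = unname(z), call = unname(call)),
            class = "propensity_profile")
}

#' Consensus epitope regions from a predictor panel
#'
#' Per-residue votes are the number of profiles calling that residue.
#' Residues with votes >= `min_votes` are merged into maximal runs; runs
#' shorter than `min_region_length` are dropped.  The default `min_votes`
#' scales the 5-of-8 webserver consensus rule to the panel size,
#' `ceiling(5/8 * n_profiles)`.
#'
#' @param profiles list of [scale_profile()] results over the same
#'   sequence.
#' @param min_votes minimum supporting predictors per residue.
#' @param min_region_length minimum region length in residues (default 6).
#' @param id parent sequence identifier recorded in the output.
#' @param weights optional per-predictor vote weights (default all 1);
#'   votes become weighted sums.
#' @return data.frame of regions: `source`, `epitope`, `start`, `end`,
#'   `residues`, `votes` (max per-residue vote in the region), `kind`.
#' @export
consensus_regions <- function(profiles, min_votes = NULL,
                              min_region_length = 6, id = "query",
                              weights = NULL) {
  stopifnot(length(profiles) >= 1)
  lens <- vapply(profiles, function(p) length(p$call), integer(1))
  if (length(unique(lens)) != 1) stop("profiles have mismatched lengths")
  n <- lens[1]
  if (is.null(weights)) weights <- rep(1, length(profiles))
  stopifnot(length(weights) == length(profiles))
  if (is.null(min_votes)) min_votes <- ceiling(5 / 8 * sum(weights))
  if (min_votes > sum(weights)) stop("min_votes exceeds total vote weight")
  calls <- vapply(profiles, function(p) p$call, logical(n))
  votes <- as.numeric(calls %*% weights)
  keep <- votes >= min_votes
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seq_str <- profiles[[1]]$seq
  rows <- list()
  k <- 0
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] < min_region_length) next
    k <- k + 1
    rows[[k]] <- data.frame(
      source = id, epitope = k, start = starts[i], end = ends[i],
      residues = substr(seq_str, starts[i], ends[i]),
      votes = max(votes[starts[i]:ends[i]]),
      kind = "linear", stringsAsFactors = FALSE)
  }
  if (k == 0)
    return(data.frame(source = character(0), epitope = integer(0),
                      start = integer(0), end = integer(0),
                      residues = character(0), votes = numeric(0),
                      kind = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Predict consensus epitopes for a protein
#'
#' Convenience wrapper: runs the full propensity panel and applies the
#' consensus rule.
#'
#' @param record single-row [seq_set()] (or list with `id`, `residues`).
#' @param scales scale names (default the full panel).
#' @param window odd window size.
#' @param min_votes,min_region_length see [consensus_regions()].
#' @return region data.frame as from [consensus_regions()].
#' @export
predict_epitopes <- function(record, scales = default_scales(), window = 7,
                             min_votes = NULL, min_region_length = 6) {
  profiles <- lapply(scales, function(s) scale_profile(record$residues, s, window))
  consensus_regions(profiles, min_votes, min_region_length, id = record$id)
}

#' Load the packaged reported-epitope fixture
#'
#' Parses the shipped table of consensus-predicted legume-LTP epitope
#' regions and the three experimentally validated peach (Pru p 3) IgE
#' epitopes.  Each row's residue string is checked against its coordinate
#' span; on mismatch the string is taken as authoritative, the row is
#' flagged (`length_mismatch`), and a warning is emitted (or an error if
#' `strict = TRUE`).  One known mismatch exists: validated peach epitope 2
#' spans 15 positions but is printed as 16 residues.
#'
#' @param path TSV path; defaults to the packaged fixture.
#' @param strict error instead of flagging on coordinate/string mismatch.
#' @return data.frame with `source`, `epitope`, `start`, `end`,
#'   `residues`, `kind`, `length_mismatch`.
#' @export
load_reported_epitopes <- function(path = NULL, strict = FALSE) {
  if (is.null(path))
    path <- system.file("extdata", "reported_epitopes.tsv", package = "ltpepimap")
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("source", "epitope", "start", "end", "residues", "kind")
  if (!all(need %in% names(df)))
    stop("epitope fixture missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  span <- df$end - df$start + 1
  df$length_mismatch <- nchar(df$residues) != span
  if (any(df$length_mismatch)) {
    msg <- sprintf("%s epitope %s: range %d-%d spans %d but string has %d residues",
                   df$source[df$length_mismatch], df$epitope[df$length_mismatch],
                   df$start[df$length_mismatch], df$end[df$length_mismatch],
                   span[df$length_mismatch],
                   nchar(df$residues[df$length_mismatch]))
    if (strict) stop(paste(msg, collapse = "; "))
    warning("coordinate/string mismatch (string kept as authoritative): ",
            paste(msg, collapse = "; "))
  }
  df
}

#' Validated peach (Pru p 3) IgE epitopes
#'
#' @return subset of [load_reported_epitopes()] with `kind == "validated"`.
#' @export
validated_peach_epitopes <- function() {
  df <- suppressWarnings(load_reported_epitopes())
  df[df$kind == "validated", , drop = FALSE]
}
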