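#' Default cysteine scaffold for a mature LTP1-like protein
#'
#' Eight invariant cysteine positions on a 93-residue backbone, following
#' the canonical nsLTP1 C...C...CC...CXC...C...C spacing.
#' @return integer vector of 8 positions.
#' @export
ltp_cysteine_positions <- function() c(3L, 13L, 27L, 28L, 48L, 50L, 73L, 87L)

.strong_partners <- local({
  p <- lapply(AA_ALPHABET, function(a) {
    setdiff(unique(unlist(strsplit(
      CLUSTAL_STRONG_GROUPS[vapply(CLUSTAL_STRONG_GROUPS,
                                   function(g) grepl(a, g, fixed = TRUE),
                                   logical(1))], ""))), a)
  })
  names(p) <- AA_ALPHABET
  p
})

# one stochastic substitution of residue r under the strong-group model
.substitute <- function(r, p_strong) {
  partners <- .strong_partners[[r]]
  if (length(partners) > 0 && runif(1) < p_strong)
    sample(partners, 1)
  else
    sample(setdiff(AA_ALPHABET, r), 1)
}

#' Specification of a synthetic LTP-like family
#'
#' Describes an ancestor protein with an invariant cysteine scaffold and a
#' set of descendants mutated away from it at a controlled rate, optionally
#' carrying planted shared motifs.  The defaults emulate a mature ~9 kDa
#' nsLTP1: 93 residues with 8 fixed cysteines.
#'
#' @param n number of descendants.
#' @param identity target mean pairwise identity among the descendants, in
#'   (0, 1].  Because every descendant mutates independently away from the
#'   shared ancestor, the per-site mutation rate is derived from the
#'   pairwise target: with invariant-site fraction f, a non-cysteine site
#'   is identical between two descendants roughly when neither mutated, so
#'   the rate solves `(1 - r)^2 = (identity - f) / (1 - f)` (coincident
#'   double substitutions add a small upward bias, well within the +-0.05
#'   band the generator promises).
#' @param rate optional explicit per-site mutation probability; overrides
#'   the derivation from `identity` (useful for rate-grid experiments).
#' @param length ancestor length (default 93).
#' @param cys_positions invariant cysteine sites (strictly increasing,
#'   within length).
#' @param motifs list of planted motifs, each a list with `motif` (residue
#'   string), `members` (descendant indices), `position` (1-based start),
#'   and optional `overwrite` (allow clobbering cysteine sites; default
#'   FALSE).
#' @param p_strong probability that a substitution stays within the
#'   residue's Clustal strong group (default 0.5).
#' @param seed RNG seed; generation is fully reproducible from it.
#' @return list of class `family_spec`.
#' @export
family_spec <- function(n = 6, identity = 0.7, length = 93,
                        cys_positions = ltp_cysteine_positions(),
                        motifs = list(), p_strong = 0.5, seed = 1,
                        rate = NULL) {
  stopifnot(identity > 0, identity <= 1, n >= 1, length >= 1)
  if (is.null(rate)) {
    f <- base::length(cys_positions) / length
    rate <- 1 - sqrt(max(0, (identity - f) / (1 - f)))
  }
  stopifnot(rate >= 0, rate <= 1)
  if (any(diff(cys_positions) <= 0) || any(cys_positions < 1) ||
      any(cys_positions > length))
    stop("cysteine positions must be strictly increasing and within length")
  for (m in motifs) {
    m$motif <- normalize_motif(m$motif)
    if (m$position < 1 || m$position + nchar(m$motif) - 1 > length)
      stop("motif does not fit within sequence length")
    hits <- cys_positions[cys_positions >= m$position &
                          cys_positions <= m$position + nchar(m$motif) - 1]
    clash <- length(hits) > 0 &&
      any(substring(m$motif, hits - m$position + 1,
                    hits - m$position + 1) != "C")
    if (clash && !isTRUE(m$overwrite))
      stop("motif collides with the cysteine scaffold; set overwrite = TRUE")
  }
  structure(list(n = n, identity = identity, length = length,
                 cys_positions = as.integer(cys_positions),
                 motifs = motifs, p_strong = p_strong, seed = seed,
                 rate = rate),
            class = "family_spec")
}

#' Generate a synthetic LTP-like family
#'
#' Draws a random ancestor (cysteines fixed at the scaffold sites), mutates
#' each descendant i.i.d. per site at rate `1 - identity` (substitutions
#' stay within the residue's Clustal strong group with probability
#' `p_strong`, else are uniform over the other residues; cysteine sites
#' never mutate), then overwrites any planted motifs into their designated
#' descendants.
#'
#' @param spec a [family_spec()].
#' @return list with `records` (a [seq_set()] of descendants `d1..dn`),
#'   `ancestor` (residue string), and `truth` (list: spec echo, per-site
#'   mutation log data.frame with `descendant`, `site`, `from`, `to`, and
#'   planted-motif bookkeeping).
#' @export
generate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  anc <- sample(AA_ALPHABET, spec$length, replace = TRUE)
  anc[spec$cys_positions] <- "C"
  rate <- spec$rate
  log_rows <- list(); lk <- 0
  seqs <- character(spec$n)
  mutable <- setdiff(seq_len(spec$length), spec$cys_positions)
  for (d in seq_len(spec$n)) {
    s <- anc
    hit <- mutable[runif(length(mutable)) < rate]
    for (site in hit) {
      new <- .substitute(s[site], spec$p_strong)
      lk <- lk + 1
      log_rows[[lk]] <- data.frame(descendant = d, site = site,
                                   from = s[site], to = new,
                                   stringsAsFactors = FALSE)
      s[site] <- new
    }
    seqs[d] <- paste(s, collapse = "")
  }
  planted <- list()
  for (m in spec$motifs) {
    mm <- normalize_motif(m$motif)
    for (d in m$members) {
      s <- strsplit(seqs[d], "")[[1]]
      s[m$position:(m$position + nchar(mm) - 1)] <- strsplit(mm, "")[[1]]
      seqs[d] <- paste(s, collapse = "")
    }
    planted[[length(planted) + 1]] <- list(motif = mm, members = m$members,
                                           position = m$position)
  }
  mut_log <- if (lk == 0)
    data.frame(descendant = integer(0), site = integer(0),
               from = character(0), to = character(0), stringsAsFactors = FALSE)
  else do.call(rbind, log_rows)
  list(records = seq_set(paste0("d", seq_len(spec$n)), seqs,
                         rep("synthetic LTP-like family member", spec$n)),
       ancestor = paste(anc, collapse = ""),
       truth = list(spec = unclass(spec), mutations = mut_log,
                    planted = planted))
}

#' Mean pairwise (Hamming) identity of equal-length sequences
#'
#' Ground-truth identity for indel-free synthetic families.
#'
#' @param records a [seq_set()] of equal-length sequences.
#' @return mean over all pairs of the fraction of identical sites.
#' @export
mean_pairwise_identity <- function(records) {
  n <- nrow(records)
  stopifnot(n >= 2, length(unique(nchar(records$residues))) == 1)
  m <- do.call(rbind, strsplit(records$residues, ""))
  vals <- c()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    vals <- c(vals, mean(m[i, ] == m[j, ]))
  mean(vals)
}

#' Evolve a synthetic family down a phylogenetic tree
#'
#' Starting from a random scaffolded ancestor at the root, sequences evolve
#' along each branch under the same per-site substitution model; a site
#' mutates on a branch of length t with probability `1 - exp(-rate * t)`.
#' Leaf-to-leaf distances therefore grow with path length in expectation,
#' which makes these families an oracle for neighbor-joining topology
#' recovery.
#'
#' @param tree an `ape` `phylo` tree with branch lengths >= 0.
#' @param rate expected substitutions per site per unit branch length.
#' @param seed RNG seed.
#' @param length sequence length.
#' @param cys_positions invariant sites (default LTP scaffold, positions
#'   beyond `length` are dropped).
#' @param p_strong within-strong-group substitution probability.
#' @return a [seq_set()] of leaf sequences labelled by the tree tip labels.
#' @export
generate_tree_family <- function(tree, rate, seed = 1, length = 93,
                                 cys_positions = ltp_cysteine_positions(),
                                 p_strong = 0.5) {
  stopifnot(inherits(tree, "phylo"), all(tree$edge.length >= 0), rate >= 0)
  cys_positions <- cys_positions[cys_positions <= length]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  anc <- sample(AA_ALPHABET, length, replace = TRUE)
  anc[cys_positions] <- "C"
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- anc
  mutable <- setdiff(seq_len(length), cys_positions)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    t <- ord$edge.length[e]
    s <- seqs[[parent]]
    p_mut <- 1 - exp(-rate * t)
    hit <- mutable[runif(base::length(mutable)) < p_mut]
    for (site in hit) s[site] <- .substitute(s[site], p_strong)
    seqs[[child]] <- s
  }
  seq_set(tree$tip.label,
          vapply(seqs[seq_len(ntip)], paste, character(1), collapse = ""),
          rep("synthetic tree-evolved LTP-like sequence", ntip))
}
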