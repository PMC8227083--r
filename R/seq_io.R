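#' Construct a protein sequence set
#'
#' A sequence set is a plain `data.frame` (class `seq_set`) with one row per
#' protein and columns `id`, `description`, `residues`.  Residues must use
#' the 20-letter amino-acid alphabet; ambiguity codes (`B`, `Z`, `X`) and
#' gap characters are rejected — gaps exist only inside alignments.
#'
#' @param id character vector of unique identifiers (accession or label).
#' @param residues character vector of upper-case residue strings.
#' @param description optional free-text description per record.
#' @return a `seq_set` data.frame.
#' @export
#' @examples
#' seq_set(c("a", "b"), c("ACDEFG", "ACDEFH"))
seq_set <- function(id, residues, description = rep("", length(id))) {
  stopifnot(length(id) == length(residues),
            length(description) == length(id))
  id <- as.character(id)
  residues <- toupper(gsub("[[:space:]]", "", as.character(residues)))
  if (anyDuplicated(id))
    stop("duplicate sequence id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!nzchar(residues)))
    stop("empty residue string for id(s): ",
         paste(id[!nzchar(residues)], collapse = ", "))
  bad <- regmatches(residues, regexpr(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
                                      residues))
  if (length(bad) > 0) {
    i <- which(grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), residues))[1]
    stop(sprintf("illegal residue '%s' in sequence '%s'", bad[1], id[i]))
  }
  structure(
    data.frame(id = id, description = as.character(description),
               residues = residues, stringsAsFactors = FALSE),
    class = c("seq_set", "data.frame")
  )
}

#' Read a protein FASTA file
#'
#' Parses with line-level validation so malformed input is reported by line
#' number.  Residue lines are upper-cased and stripped of whitespace; the
#' record order of the file is preserved.
#'
#' @param path path to a FASTA file.
#' @return a [seq_set()] data.frame with one row per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  # drop trailing blank lines but keep numbering of the original file
  header_at <- grepl("^>", lines)
  nonblank <- nzchar(trimws(lines))
  if (!any(nonblank))                      # empty file: empty record set
    return(seq_set(character(0), character(0), character(0)))
  if (!any(header_at))
    stop("not FASTA: no '>' header found in ", path)
  first_content <- which(nonblank)[1]
  if (!header_at[first_content])
    stop(sprintf("malformed FASTA: sequence data before first header at line %d",
                 first_content))
  ids <- character(0); descs <- character(0); seqs <- character(0)
  cur_id <- NULL; cur_desc <- NULL; cur_seq <- character(0)
  flush <- function() {
    if (is.null(cur_id)) return()
    ids <<- c(ids, cur_id); descs <<- c(descs, cur_desc)
    seqs <<- c(seqs, paste(cur_seq, collapse = ""))
  }
  legal <- sprintf("^[%s]*$", paste(AA_ALPHABET, collapse = ""))
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (grepl("^>", line)) {
      flush()
      hdr <- sub("^>", "", line)
      if (!nzchar(trimws(hdr)))
        stop(sprintf("malformed FASTA: empty header at line %d", ln))
      cur_id <- sub("\\s.*$", "", trimws(hdr))
      cur_desc <- trimws(sub("^\\S+\\s*", "", trimws(hdr)))
      cur_seq <- character(0)
    } else {
      res <- toupper(gsub("[[:space:]]", "", line))
      if (!nzchar(res)) next
      if (!grepl(legal, res)) {
        bad <- regmatches(res, regexpr(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), res))
        stop(sprintf("illegal residue '%s' at line %d (record '%s')",
                     bad, ln, cur_id))
      }
      cur_seq <- c(cur_seq, res)
    }
  }
  flush()
  if (any(!nzchar(seqs)))
    stop("record(s) with no residues: ", paste(ids[!nzchar(seqs)], collapse = ", "))
  seq_set(ids, seqs, descs)
}

#' Write a protein FASTA file
#'
#' @param records a [seq_set()].
#' @param path output path.
#' @param width line-wrap width in columns (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(inherits(records, "data.frame"), width >= 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$description[i]))
      paste(records$id[i], records$description[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$residues[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Filter records by description-line keywords
#'
#' Keeps records whose description contains at least one of the given
#' phrases, matched case-insensitively as a plain substring (no regex).
#' This mirrors the common curation rule of selecting NCBI records whose
#' definition line names the protein family of interest (e.g. "lipid
#' transfer protein").
#'
#' @param records a [seq_set()].
#' @param keywords character vector of phrases; an empty vector keeps
#'   nothing (vacuous filter).
#' @return the filtered `seq_set`.
#' @export
filter_by_description <- function(records, keywords) {
  if (length(keywords) == 0) return(records[0, , drop = FALSE])
  desc <- tolower(records$description)
  keep <- Reduce(`|`, lapply(tolower(keywords), function(k) {
    vapply(desc, function(d) grepl(k, d, fixed = TRUE), logical(1), USE.NAMES = FALSE)
  }))
  records[keep, , drop = FALSE]
}

#' Default nsLTP description keywords
#'
#' The three description-line phrases used to select LTP records from NCBI.
#' @return character vector of phrases.
#' @export
ltp_keywords <- function() {
  c("lipid transfer protein", "nonspecific lipid transfer protein",
    "lipid transfer like protein")
}
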