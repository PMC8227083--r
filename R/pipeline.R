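#' Pipeline configuration
#'
#' Collects every knob of the end-to-end screen: homology parameters, the
#' consensus-epitope rule, motif and PD thresholds, and output paths.  The
#' homology flag in the summary uses both conventions: a full-length
#' identity above `full_length_flag` (the common 70% structural-similarity
#' remark) or a best-80-aa-window identity at or above `window_flag` (the
#' Codex 35% criterion).
#'
#' @param query_fasta path to the query protein FASTA.
#' @param db_fasta path to the allergen database FASTA.
#' @param out_dir output directory (created if missing).
#' @param validated_epitopes optional TSV path of reference epitopes
#'   (default: the packaged peach set).
#' @param modes homology search modes.
#' @param window,step sliding-window size and step.
#' @param matrix,gap_open,gap_extend alignment scoring.
#' @param full_length_flag,window_flag homology flag thresholds (percent).
#' @param min_votes,min_region_length,scale_window consensus-epitope rule.
#' @param min_motif_length shared-motif minimum length.
#' @param pd_threshold PD match threshold.
#' @param seed RNG seed recorded in the report.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(query_fasta, db_fasta, out_dir,
                            validated_epitopes = NULL,
                            modes = c("full_length", "window80"),
                            window = 80, step = 1,
                            matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5,
                            full_length_flag = 70, window_flag = 35,
                            min_votes = NULL, min_region_length = 6,
                            scale_window = 7,
                            min_motif_length = 4, pd_threshold = 4,
                            seed = 1) {
  stopifnot(window >= 1, step >= 1, pd_threshold >= 0,
            min_region_length >= 1, min_motif_length >= 1,
            full_length_flag >= 0, full_length_flag <= 100,
            window_flag >= 0, window_flag <= 100)
  structure(list(
    query_fasta = query_fasta, db_fasta = db_fasta, out_dir = out_dir,
    validated_epitopes = validated_epitopes, modes = modes,
    window = window, step = step, matrix = matrix,
    gap_open = gap_open, gap_extend = gap_extend,
    full_length_flag = full_length_flag, window_flag = window_flag,
    min_votes = min_votes, min_region_length = min_region_length,
    scale_window = scale_window, min_motif_length = min_motif_length,
    pd_threshold = pd_threshold, seed = seed), class = "pipeline_config")
}

#' Read / write a pipeline configuration
#'
#' YAML round-trip of a [pipeline_config()].
#' @param config a `pipeline_config`.
#' @param path YAML path.
#' @return `read_config` returns a `pipeline_config`; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x[!vapply(x, is.null, logical(1))])
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full allergenicity-screening pipeline
#'
#' Executes, in order: dual-mode homology screening, multiple alignment
#' with conservation annotation and a neighbor-joining tree, the
#' propensity-panel consensus epitope prediction, shared-motif analysis
#' against the validated reference epitopes, and the PD peptide similarity
#' scan of every predicted epitope against the allergen database.  Each
#' stage writes its own table; a summary JSON flags, per query, (a) any
#' full-length identity above `full_length_flag` or window identity at or
#' above `window_flag`, (b) any motif shared with a validated epitope, and
#' (c) any PD match below `pd_threshold`.  Output is deterministic for a
#' fixed config and seed.  A stage failure aborts with the stage name; the
#' manifest records which stages completed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the summary list (also written to
#'   `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(completed = character(0), seed = config$seed)
  finish <- function() jsonlite::write_json(
    manifest, file.path(config$out_dir, "manifest.json"), auto_unbox = TRUE)
  stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e) {
      manifest$incomplete <<- name
      finish()
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    manifest$completed <<- c(manifest$completed, name)
    r
  }
  set.seed(config$seed)
  params <- align_params(config$matrix, config$gap_open, config$gap_extend)

  inputs <- stage("read_inputs", {
    list(queries = read_fasta(config$query_fasta),
         db = read_fasta(config$db_fasta))
  })
  queries <- inputs$queries; db <- inputs$db

  hits <- stage("homology_screen", {
    h <- homology_screen(queries, db, config$modes, config$window,
                         config$step, params)
    .write_tsv(h, file.path(config$out_dir, "homology_hits.tsv"))
    h
  })

  stage("msa_conservation_phylo", {
    all_seqs <- rbind(queries, db)
    if (nrow(all_seqs) >= 2) {
      msa <- progressive_msa(all_seqs, params)
      write_msa_fasta(msa, file.path(config$out_dir, "alignment.fasta"))
      for (qid in queries$id) {
        prof <- conservation_profile(msa, qid)
        .write_tsv(prof, file.path(config$out_dir,
                                   paste0("conservation_", qid, ".tsv")))
      }
      if (nrow(all_seqs) >= 3)
        write_newick(nj_tree(distance_matrix(msa)),
                     file.path(config$out_dir, "tree.nwk"))
    }
    NULL
  })

  regions <- stage("epitope_consensus", {
    r <- do.call(rbind, lapply(seq_len(nrow(queries)), function(i)
      predict_epitopes(queries[i, , drop = FALSE],
                       window = config$scale_window,
                       min_votes = config$min_votes,
                       min_region_length = config$min_region_length)))
    .write_tsv(r, file.path(config$out_dir, "epitope_regions.tsv"))
    r
  })

  validated <- stage("load_validated", {
    if (is.null(config$validated_epitopes)) validated_peach_epitopes()
    else suppressWarnings(load_reported_epitopes(config$validated_epitopes))
  })

  overlap <- stage("epitope_overlap", {
    per_query <- lapply(queries$id, function(qid) {
      pred <- regions[regions$source == qid, , drop = FALSE]
      if (nrow(pred) == 0)
        return(list(matches = NULL,
                    overlap = data.frame(validated_epitope = character(0),
                                         shared = logical(0),
                                         longest_motif = character(0))))
      validated_epitope_check(pred, validated, config$min_motif_length)
    })
    names(per_query) <- queries$id
    mot <- do.call(rbind, lapply(queries$id, function(qid) {
      m <- per_query[[qid]]$matches
      if (is.null(m) || nrow(m) == 0) return(NULL)
      cbind(query_id = qid, m, stringsAsFactors = FALSE)
    }))
    if (is.null(mot)) mot <- data.frame(query_id = character(0))
    .write_tsv(mot, file.path(config$out_dir, "shared_motifs.tsv"))
    per_query
  })

  pd_hits <- stage("pd_scan", {
    p <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i) {
      h <- pd_scan(regions$residues[i], db, config$pd_threshold)
      if (nrow(h) == 0) return(NULL)
      cbind(query_id = regions$source[i], epitope = regions$epitope[i], h,
            stringsAsFactors = FALSE)
    }))
    if (is.null(p))
      p <- data.frame(query_id = character(0), epitope = integer(0),
                      query = character(0), subject_id = character(0),
                      offset = integer(0), subject_peptide = character(0),
                      pd = numeric(0))
    .write_tsv(p, file.path(config$out_dir, "pd_matches.tsv"))
    p
  })

  summary <- stage("summarize", {
    per_query <- lapply(queries$id, function(qid) {
      qh <- hits[hits$query_id == qid, , drop = FALSE]
      fl <- qh[qh$mode == "full_length", , drop = FALSE]
      w8 <- qh[qh$mode == "window80", , drop = FALSE]
      flag_hom <- (nrow(fl) > 0 && any(fl$identity_pct > config$full_length_flag)) ||
        (nrow(w8) > 0 && any(w8$identity_pct >= config$window_flag))
      ov <- overlap[[qid]]$overlap
      flag_motif <- nrow(ov) > 0 && any(ov$shared)
      qpd <- pd_hits[pd_hits$query_id == qid, , drop = FALSE]
      flag_pd <- nrow(qpd) > 0
      list(homology_flag = flag_hom,
           shared_epitope_flag = flag_motif,
           pd_flag = flag_pd,
           n_epitopes = sum(regions$source == qid),
           best_full_length_identity =
             if (nrow(fl)) max(fl$identity_pct) else NA,
           best_window_identity =
             if (nrow(w8)) max(w8$identity_pct) else NA)
    })
    names(per_query) <- queries$id
    s <- list(seed = config$seed, queries = per_query)
    jsonlite::write_json(s, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    s
  })
  finish()
  invisible(summary)
}
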