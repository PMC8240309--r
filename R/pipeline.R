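# End-to-end orchestration: anchors -> subpath filter -> codon search ->
# CDS building -> triplet scoring -> contig filter -> similarity
# classification -> clustering -> representative selection -> reports.

#' Assemble a pipeline configuration
#'
#' Inputs may be file paths (`gfa`, `proteins`, `contig_paths`, `anchors_tsv`,
#' `train_hits`) or in-memory objects (`graph`, `proteins` as a named vector,
#' `contigs` tibble, `anchors` tibble, `model`). All thresholds default to
#' the standard values: protein/model anchor fractions 0.8/0.9, e-value
#' 1e-9, 1000 paths, 3000 nt restorable length, binSize 150, minLength 300,
#' identity 80, PI 90, long edges 1 kb.
#'
#' @param gfa,graph Assembly graph (GFA path or `asm_graph`).
#' @param proteins Protein database: FASTA path or named character vector.
#'   Used both for brute-force anchor search and similarity classification.
#' @param anchor_proteins Optional separate query set for anchor search;
#'   defaults to `proteins`.
#' @param contig_paths,contigs Contig paths (`.paths`/GFA file or tibble).
#' @param anchors_tsv,anchors Externally computed anchors (TSV or tibble).
#' @param train_hits,model Start-distance training table (TSV/data frame with
#'   `model_id`, `distance`) or a fitted `position_model`.
#' @param thresholds,limits,unique_params,sim_thresholds,clust_params
#'   Parameter lists from the respective constructors.
#' @param start_set Accepted start codons.
#' @param max_codon_dist Codon-search bound; default
#'   `limits$max_restorable_length` minus the anchor length (floored at 0),
#'   computed per anchor when `NULL`.
#' @param report_single_contig_hits Keep ORFs found inside a single contig in
#'   the main output (default FALSE).
#' @param report_known Keep 100%-identity known genes in the main output
#'   (default FALSE).
#' @param out_dir Optional output directory for FASTA/TSV/JSON reports.
#' @param max_path_len,max_paths Brute-force anchor search bounds.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(gfa = NULL, graph = NULL, proteins = NULL,
                            anchor_proteins = NULL,
                            contig_paths = NULL, contigs = NULL,
                            anchors_tsv = NULL, anchors = NULL,
                            train_hits = NULL, model = NULL,
                            thresholds = anchor_thresholds(),
                            limits = builder_limits(),
                            unique_params = unique_edge_params(),
                            sim_thresholds = similarity_thresholds(),
                            clust_params = cluster_params(),
                            start_set = START_CODONS,
                            max_codon_dist = NULL,
                            report_single_contig_hits = FALSE,
                            report_known = FALSE,
                            out_dir = NULL,
                            max_path_len = 10000L, max_paths = 10000L) {
  if (is.null(graph)) {
    if (is.null(gfa)) stop("either `gfa` or `graph` is required")
    if (!file.exists(gfa)) stop("GFA file not found: ", gfa)
  }
  if (is.null(proteins)) stop("a protein database is required")
  structure(as.list(environment()), class = "pipeline_config")
}

read_protein_db <- function(proteins) {
  if (is.character(proteins) && length(proteins) == 1 && file.exists(proteins) &&
      is.null(names(proteins))) {
    aa <- Biostrings::readAAStringSet(proteins)
    return(stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa))))
  }
  stopifnot(!is.null(names(proteins)))
  proteins
}

#' Is an ORF contained in a single contig?
#'
#' TRUE when the ORF's step list is a sub-list of some contig path (either
#' orientation). Such easy-to-identify genes are excluded from the main
#' output by default, since any contig-level gene finder would report them.
#'
#' @param orf_path A `graph_path` (or a one-row candidate tibble).
#' @param contigs Contig paths (tibble/list); `NULL` or empty gives FALSE.
#' @return Logical scalar.
#' @export
count_single_contig <- function(orf_path, contigs) {
  if (is.data.frame(orf_path)) orf_path <- orf_path$path[[1]]
  cl <- contig_paths_as_list(contigs)
  if (length(cl) == 0) return(FALSE)
  osteps <- orf_path$steps
  for (cp in cl) {
    cs <- if (inherits(cp, "graph_path")) cp$steps else as.character(cp)
    if (steps_contain(cs, osteps) || steps_contain(rc_steps(cs), osteps))
      return(TRUE)
  }
  FALSE
}

#' Run the full gene-finding pipeline
#'
#' Executes anchor acquisition (external anchors when supplied, otherwise the
#' built-in brute-force aligner), the redundant-anchor filter, start/stop
#' codon search, candidate construction, triplet scoring, the
#' contig-contradiction filter, similarity classification (ORFs under the
#' retain threshold are discarded), clustering and representative selection.
#' When `out_dir` is set, writes representative FASTA files (amino acid and
#' nucleotide), a clusters TSV, a per-ORF CDS report TSV, and a JSON run log
#' with per-stage counts.
#'
#' @param config A [pipeline_config()].
#' @return An `orfgraph_result` list: `anchors`, `candidates` (scored,
#'   classified, clustered), `clusters`, `representatives`, `main_output`,
#'   `counts`, `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", what, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  graph <- stage("graph input", {
    if (!is.null(config$graph)) config$graph else read_gfa(config$gfa)
  })
  db <- stage("protein database", read_protein_db(config$proteins))
  queries <- stage("anchor queries", {
    if (!is.null(config$anchor_proteins)) read_protein_db(config$anchor_proteins) else db
  })
  contigs <- stage("contig paths", {
    if (!is.null(config$contigs)) config$contigs
    else if (!is.null(config$contig_paths)) {
      first <- readLines(config$contig_paths, n = 1)
      if (startsWith(first, "H") || startsWith(first, "S\t"))
        read_gfa_paths(config$contig_paths, graph)
      else read_spades_paths(config$contig_paths, graph)
    } else NULL
  })
  model <- stage("position model", {
    if (!is.null(config$model)) config$model
    else if (!is.null(config$train_hits)) {
      th <- config$train_hits
      if (is.character(th)) th <- readr::read_tsv(th, show_col_types = FALSE)
      train_position_model(th)
    } else NULL
  })

  anchors <- stage("anchor acquisition", {
    if (!is.null(config$anchors)) config$anchors
    else if (!is.null(config$anchors_tsv))
      load_external_anchors(config$anchors_tsv, graph, config$thresholds)
    else find_anchors_bruteforce(graph, queries, config$thresholds,
                                 max_path_len = config$max_path_len,
                                 max_paths = config$max_paths)
  })
  counts <- list(anchors_raw = nrow(anchors))
  if (nrow(anchors) == 0) {
    warning("no anchors found; returning an empty result")
    return(empty_result(graph, anchors, counts, config))
  }
  anchors <- stage("subpath filter", filter_subpath_anchors(anchors, graph))
  counts$anchors_kept <- nrow(anchors)

  cands <- stage("codon search and CDS generation", {
    dplyr::bind_rows(lapply(seq_len(nrow(anchors)), function(i) {
      a <- anchors[i, ]
      md <- config$max_codon_dist
      if (is.null(md))
        md <- max(0L, config$limits$max_restorable_length - a$nt_len[[1]])
      starts <- find_start_codons(graph, a, max_dist = md,
                                  start_set = config$start_set)
      stops <- find_stop_codons(graph, a, max_dist = md)
      build_candidates(graph, a, starts, stops, config$limits, config$start_set)
    }))
  })
  if (nrow(cands) > 0) {
    cands <- cands[!duplicated(cands$aa_seq), ]
    cands$orf_id <- sprintf("orf_%04d", seq_len(nrow(cands)))
  }
  counts$candidates <- nrow(cands)
  if (nrow(cands) == 0) {
    warning("no candidate ORFs constructed; returning an empty result")
    return(empty_result(graph, anchors, counts, config))
  }
  cands <- stage("triplet scoring", score_candidates(cands, graph, model))

  kept <- stage("contig-contradiction filter", {
    if (is.null(contigs)) cands
    else filter_contradicting(cands, contigs, graph, config$unique_params)
  })
  counts$after_contig_filter <- nrow(kept)

  kept <- stage("similarity classification",
                similarity_classify(kept, db, config$sim_thresholds))
  discarded <- kept$best_identity < config$sim_thresholds$retain_identity
  kept$verdict[discarded] <- "discarded"
  kept <- kept[!discarded, ]
  counts$after_retain_filter <- nrow(kept)
  if (nrow(kept) == 0) {
    warning("no ORFs retained after the similarity filter")
    return(empty_result(graph, anchors, counts, config))
  }

  cs <- stage("clustering", cluster_and_select(kept, graph, config$clust_params))
  counts$clusters <- length(unique(cs$clusters$cluster))
  counts$representatives <- nrow(cs$representatives)

  reps <- cs$representatives
  reps$single_contig <- vapply(reps$path, count_single_contig, TRUE,
                               contigs = contigs)
  main <- reps
  if (!config$report_single_contig_hits) main <- main[!main$single_contig, ]
  if (!config$report_known) main <- main[main$verdict != "reliable-known", ]
  counts$main_output <- nrow(main)

  res <- structure(list(
    graph = graph, anchors = anchors, candidates = cands,
    clusters = cs$clusters, representatives = reps, main_output = main,
    counts = tibble::tibble(stage = names(counts),
                            n = unlist(counts, use.names = FALSE)),
    config = config), class = "orfgraph_result")
  if (!is.null(config$out_dir)) write_result(res, config$out_dir)
  res
}

empty_result <- function(graph, anchors, counts, config) {
  empty <- empty_candidates()
  structure(list(graph = graph, anchors = anchors, candidates = empty,
                 clusters = empty, representatives = empty, main_output = empty,
                 counts = tibble::tibble(stage = names(counts),
                                         n = unlist(counts, use.names = FALSE)),
                 config = config),
            class = "orfgraph_result")
}

path_string <- function(p) paste(p$steps, collapse = ",")

#' Write pipeline reports
#'
#' @param result An `orfgraph_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_faa <- function(tb, path, col) {
    seqs <- stats::setNames(tb[[col]], tb$orf_id)
    set <- if (col == "aa_seq") Biostrings::AAStringSet(seqs) else
      Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(set, path)
  }
  if (nrow(result$main_output) > 0) {
    write_faa(result$main_output, file.path(dir, "representatives.faa"), "aa_seq")
    write_faa(result$main_output, file.path(dir, "representatives.fna"), "nt_seq")
  }
  if (nrow(result$representatives) > 0) {
    write_faa(result$representatives, file.path(dir, "representatives_full.faa"),
              "aa_seq")
  }
  if (nrow(result$clusters) > 0) {
    cl <- result$clusters
    readr::write_tsv(tibble::tibble(
      cluster = cl$cluster, orf_id = cl$orf_id, representative = cl$representative,
      verdict = cl$verdict, best_hit = cl$best_hit,
      best_identity = round(cl$best_identity, 2),
      path = vapply(cl$path, path_string, "")),
      file.path(dir, "clusters.tsv"))
    cr <- result$candidates
    readr::write_tsv(tibble::tibble(
      orf_id = cr$orf_id, anchor_id = cr$anchor_id, query_id = cr$query_id,
      nt_len = cr$nt_len, start_codon = cr$start_codon, stop_codon = cr$stop_codon,
      start_distance = cr$start_distance, stop_distance = cr$stop_distance,
      after_stop = cr$after_stop, has_sd = cr$has_sd,
      truncated_enumeration = cr$truncated,
      likelihood = cr$likelihood, coverage = cr$coverage,
      path = vapply(cr$path, path_string, "")),
      file.path(dir, "cds_report.tsv"))
  }
  jsonlite::write_json(
    stats::setNames(as.list(result$counts$n), result$counts$stage),
    file.path(dir, "run_log.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.orfgraph_result <- function(x, ...) {
  cat("<orfgraph_result>\n")
  print(x$counts)
  invisible(x)
}
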