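# Candidate ORF construction: bounded exhaustive enumeration of prefix paths
# (start codon -> anchor start) and suffix paths (anchor end -> stop codon),
# restricted to a DFS-style reachable edge set, concatenated with the anchor
# and screened against the coding-sequence invariants.

#' Path-enumeration limits
#'
#' @param max_paths_per_pair At most this many paths are generated per
#'   (vertex, vertex) enumeration; default 1000.
#' @param max_restorable_length Longest restorable coding sequence in
#'   nucleotides (inclusive bound), default 3000.
#' @return A list of limits.
#' @export
builder_limits <- function(max_paths_per_pair = 1000L, max_restorable_length = 3000L) {
  stopifnot(max_paths_per_pair > 0, max_restorable_length > 0)
  list(max_paths_per_pair = as.integer(max_paths_per_pair),
       max_restorable_length = as.integer(max_restorable_length))
}

# igraph over oriented edges; edge weight = novel length of the target edge.
oriented_igraph <- function(graph) {
  nodes <- c(paste0(names(graph$seqs), "+"), paste0(names(graph$seqs), "-"))
  from <- character(0); to <- character(0)
  for (a in ls(graph$succ)) for (b in graph$succ[[a]]) {
    from <- c(from, a); to <- c(to, b)
  }
  w <- nchar(vapply(to, function(s) oseq(graph, s), "")) - graph$overlap
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, weight = as.numeric(w)),
    directed = TRUE, vertices = data.frame(name = nodes))
  g
}

#' Oriented edges usable between two graph positions
#'
#' Returns exactly the oriented edges lying on at least one walk from `from`
#' to `to` of spelled length at most `max_len`, computed as the intersection
#' of length-bounded forward reachability from `from` and backward
#' reachability from `to` (shortest-path distances over oriented edges).
#'
#' @param graph An `asm_graph`.
#' @param from Position list (`step`, `off`) of the first base.
#' @param to Position of the first base *not* covered (exclusive end):
#'   `step` plus exclusive offset `off`.
#' @param max_len Maximum spelled length in nucleotides.
#' @return Character vector of oriented edge labels (possibly empty).
#' @export
reachable_edges <- function(graph, from, to, max_len) {
  ov <- graph$overlap
  len_f <- edge_len(graph, step_id(from$step))
  keep <- character(0)
  direct <- from$step == to$step && to$off > from$off &&
    (to$off - from$off) <= max_len
  if (direct) keep <- from$step

  ig <- oriented_igraph(graph)
  d_from <- suppressWarnings(igraph::distances(ig, v = from$step, mode = "out"))[1, ]
  d_to <- suppressWarnings(igraph::distances(ig, to = to$step, mode = "out"))[, 1]
  nodes <- names(d_from)
  # A(s): min spelled length from `from` up to the start of s's novel part
  novel <- vapply(nodes, function(s) edge_len(graph, step_id(s)) - ov, 0)
  A <- (len_f - from$off) + d_from - novel
  # B(s): min spelled length from the end of s to the exclusive `to` position
  B <- d_to - (edge_len(graph, step_id(to$step)) - ov) + (to$off - ov)
  mid <- nodes[is.finite(A) & is.finite(B) & (A + novel + B) <= max_len]
  keep <- union(keep, mid)
  # the first edge itself, via any successor chain
  tot_from <- (len_f - from$off) + B[from$step]
  if (is.finite(tot_from) && tot_from <= max_len && tot_from > 0)
    keep <- union(keep, c(from$step, to$step))
  sort(keep)
}

#' Bounded exhaustive path enumeration between two positions
#'
#' Generates walks from position `from` (inclusive) to position `to`
#' (exclusive end), restricted to `whitelist` edges when given, of spelled
#' length in (0, `max_len`]. Edges may repeat as long as the length bound
#' holds. Paths are produced in breadth-then-lexicographic order and
#' truncated at `max_paths` with a truncation flag.
#'
#' @param graph An `asm_graph`.
#' @param from,to Positions as in [reachable_edges()].
#' @param max_len Maximum spelled length (default the 3000-nt restorable bound).
#' @param max_paths Enumeration cap, default 1000.
#' @param whitelist Optional character vector of allowed oriented edges.
#' @param normalize Move path ends out of the final overlap (default TRUE;
#'   internal callers that splice paths keep raw ends).
#' @return `list(paths = list of graph_path, truncated = logical)`.
#' @export
enumerate_paths <- function(graph, from, to, max_len = 3000L, max_paths = 1000L,
                            whitelist = NULL, normalize = TRUE) {
  ov <- graph$overlap
  lens <- new.env(parent = emptyenv())
  elen <- function(s) {
    v <- lens[[s]]
    if (is.null(v)) { v <- edge_len(graph, step_id(s)); lens[[s]] <- v }
    v
  }
  allowed <- function(s) is.null(whitelist) || s %in% whitelist
  if (!allowed(from$step) || !allowed(to$step)) return(list(paths = list(), truncated = FALSE))

  paths <- list()
  truncated <- FALSE
  # queue of partials: list(steps, used) where used = spelled length consumed
  # through the end of the last step
  queue <- list(list(steps = from$step, used = elen(from$step) - from$off))
  expansions <- 0L
  while (length(queue) > 0) {
    nxt <- list()
    for (it in queue) {
      last <- it$steps[length(it$steps)]
      if (last == to$step) {
        n <- length(it$steps)
        plen <- if (n == 1) to$off - from$off else it$used - (elen(last) - to$off)
        if (plen > 0 && plen <= max_len) {
          if (length(paths) >= max_paths) {
            truncated <- TRUE
          } else {
            p <- graph_path(it$steps, from$off, to$off)
            if (normalize) p <- normalize_path(graph, p)
            paths[[length(paths) + 1]] <- p
          }
        }
      }
      if (truncated) break
      # small slack: a completion point may sit inside the final overlap
      if (it$used - ov > max_len + ov) next
      for (s in graph_succ(graph, last)) {
        if (!allowed(s)) next
        used2 <- it$used + elen(s) - ov
        expansions <- expansions + 1L
        if (expansions > 200000L) { truncated <- TRUE; break }
        nxt[[length(nxt) + 1]] <- list(steps = c(it$steps, s), used = used2)
      }
      if (truncated) break
    }
    if (truncated) break
    queue <- nxt
  }
  list(paths = paths, truncated = truncated)
}

#' Translate a coding sequence (bacterial table 11)
#'
#' Translates everything up to (not including) the final stop codon; an
#' alternative initiator (GTG/TTG) is read as methionine, following bacterial
#' convention.
#'
#' @param nt Nucleotide CDS from start codon through stop codon.
#' @param start_set Codons treated as initiators.
#' @return Amino-acid string.
#' @export
translate_cds <- function(nt, start_set = START_CODONS) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1L, nchar(nt) - 3L)),
    genetic.code = Biostrings::getGeneticCode("11")))
  # bacterial convention: alternative initiators read as Met
  if (substr(nt, 1L, 3L) %in% start_set) substr(aa, 1L, 1L) <- "M"
  aa
}

empty_candidates <- function() {
  tibble::tibble(orf_id = character(0), anchor_id = character(0),
                 query_id = character(0), nt_len = integer(0),
                 nt_seq = character(0), aa_seq = character(0),
                 start_codon = character(0), stop_codon = character(0),
                 start_distance = integer(0), stop_distance = integer(0),
                 after_stop = logical(0), has_sd = logical(0),
                 truncated = logical(0), path = list())
}

#' Assemble candidate ORFs from an anchor and its codon sites
#'
#' For every (start, stop) pair, enumerates prefix paths from the start codon
#' to the anchor start and suffix paths from the anchor end to the stop
#' codon (whitelisted by [reachable_edges()], capped at
#' `limits$max_paths_per_pair`), concatenates start codon + prefix + anchor +
#' suffix + stop codon, and keeps concatenates that satisfy the CDS
#' invariants: length a multiple of 3 and at most
#' `limits$max_restorable_length`, begins with a start codon, ends with a
#' stop codon, no internal in-frame stop, no N. Survivors are translated
#' (table 11) and deduplicated on the amino-acid sequence.
#'
#' @param graph An `asm_graph`.
#' @param anchor One-row anchor tibble (from the anchor module) or a
#'   codon-aligned `graph_path`.
#' @param starts,stops Codon-site tibbles from [find_start_codons()] /
#'   [find_stop_codons()].
#' @param limits A [builder_limits()] list.
#' @param start_set Accepted start codons.
#' @return A candidate tibble (`path` list-column holds the full
#'   start-through-stop `graph_path`).
#' @export
build_candidates <- function(graph, anchor, starts, stops,
                             limits = builder_limits(),
                             start_set = START_CODONS) {
  anchor_id <- NA_character_; query_id <- NA_character_
  if (is.data.frame(anchor)) {
    anchor_id <- anchor$anchor_id[[1]]; query_id <- anchor$query_id[[1]]
    anchor <- anchor$path[[1]]
  }
  core <- anchor_core_path(graph, anchor)
  a_start <- path_start_pos(core)
  a_last <- path_last_pos(core)
  max_len <- limits$max_restorable_length
  rows <- list()
  seen_nt <- character(0)
  if (nrow(starts) == 0 || nrow(stops) == 0) return(empty_candidates())

  for (si in seq_len(nrow(starts))) {
    st <- starts[si, ]
    if (st$distance == 0L) {
      prefixes <- list(NULL); pre_trunc <- FALSE
    } else {
      v <- pos(st$step, st$off)
      wl <- reachable_edges(graph, v, a_start, max_len)
      res <- enumerate_paths(graph, v, a_start, max_len = max_len,
                             max_paths = limits$max_paths_per_pair,
                             whitelist = wl, normalize = FALSE)
      prefixes <- res$paths; pre_trunc <- res$truncated
      if (length(prefixes) == 0) next
    }
    for (ti in seq_len(nrow(stops))) {
      sp <- stops[ti, ]
      w <- list(step = sp$end_step, off = sp$end_off + 1L)  # exclusive end
      wl2 <- reachable_edges(graph, a_last, w, max_len)
      res2 <- enumerate_paths(graph, a_last, w, max_len = max_len,
                              max_paths = limits$max_paths_per_pair,
                              whitelist = wl2, normalize = FALSE)
      if (length(res2$paths) == 0) next
      for (P in prefixes) {
        for (S in res2$paths) {
          steps <- c(if (!is.null(P)) P$steps[-length(P$steps)], core$steps,
                     S$steps[-1])
          start_off <- if (is.null(P)) core$start_offset else P$start_offset
          orf <- graph_path(steps, start_off, S$end_offset)
          nt <- spell_path(graph, orf)
          n <- nchar(nt)
          if (n %% 3L != 0L || n > max_len) next
          if (grepl("N", nt, fixed = TRUE)) next
          if (!substr(nt, 1L, 3L) %in% start_set) next
          if (!substr(nt, n - 2L, n) %in% STOP_CODONS) next
          if (has_internal_stop(nt)) next
          if (nt %in% seen_nt) next
          seen_nt <- c(seen_nt, nt)
          rows[[length(rows) + 1]] <- list(
            nt_seq = nt, nt_len = n,
            aa_seq = translate_cds(nt, start_set),
            start_codon = substr(nt, 1L, 3L),
            stop_codon = substr(nt, n - 2L, n),
            start_distance = st$distance, stop_distance = sp$distance,
            after_stop = isTRUE(st$after_stop), has_sd = isTRUE(st$has_sd),
            truncated = pre_trunc || res2$truncated,
            path = normalize_path(graph, orf))
        }
      }
    }
  }
  if (length(rows) == 0) return(empty_candidates())
  tb <- tibble::tibble(
    orf_id = NA_character_,
    anchor_id = anchor_id, query_id = query_id,
    nt_len = vapply(rows, `[[`, 0L, "nt_len"),
    nt_seq = vapply(rows, `[[`, "", "nt_seq"),
    aa_seq = vapply(rows, `[[`, "", "aa_seq"),
    start_codon = vapply(rows, `[[`, "", "start_codon"),
    stop_codon = vapply(rows, `[[`, "", "stop_codon"),
    start_distance = vapply(rows, `[[`, 0L, "start_distance"),
    stop_distance = vapply(rows, `[[`, 0L, "stop_distance"),
    after_stop = vapply(rows, `[[`, TRUE, "after_stop"),
    has_sd = vapply(rows, `[[`, TRUE, "has_sd"),
    truncated = vapply(rows, `[[`, TRUE, "truncated"),
    path = lapply(rows, `[[`, "path"))
  # duplicates are filtered out on the translated sequence; the first (and,
  # by generation order, shortest-prefix) variant is kept
  tb <- tb[!duplicated(tb$aa_seq), ]
  tb$orf_id <- sprintf("orf_%04d", seq_len(nrow(tb)))
  tb
}

# stops strictly between the initiator and the terminator codon
has_internal_stop <- function(nt) {
  n <- nchar(nt)
  if (n < 9L) return(FALSE)
  at <- seq(4L, n - 5L, by = 3L)
  any(substring(nt, at, at + 2L) %in% STOP_CODONS)
}
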