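# Start/stop codon discovery around anchor paths.
#
# A breadth-first search walks the graph base by base, carrying the partial
# codon ("frameshift string") consumed so far. Stop-side exploration halts at
# states whose frameshift string completes a stop codon (no ORF extends past
# an in-frame stop); start-side exploration runs on the reverse-complement
# strand, is not pruned at upstream stops, and annotates starts found beyond
# an in-frame stop (`after_stop`) or downstream of a Shine-Dalgarno-like
# motif (`has_sd`).

#' Stop and (default bacterial) start codon sets
#' @export
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @rdname STOP_CODONS
#' @export
START_CODONS <- c("ATG", "GTG", "TTG")

empty_codon_sites <- function() {
  tibble::tibble(step = character(0), off = integer(0),
                 end_step = character(0), end_off = integer(0),
                 codon = character(0), kind = character(0),
                 distance = integer(0),
                 after_stop = logical(0), has_sd = logical(0))
}

# Generic forward codon BFS from a set of seed positions.
#
# Reads bases in walk order; every completed triple is a codon. `targets` are
# collected; `terminal` codons stop further expansion of that state. Distances
# are counted in bases from the first seed base (0-based); a codon is
# reported with the distance of its first base, kept only when <= max_dist.
# Visited states are keyed by (position, partial codon), bounding the search
# on cyclic graphs.
codon_bfs <- function(graph, seeds, targets, terminal, max_dist) {
  sites <- list()
  site_seen <- character(0)
  visited <- new.env(parent = emptyenv())
  queue <- vector("list", 256); qh <- 1L; qt <- 0L
  push <- function(item) {
    # the codon-start position joins the state key so codon sites that differ
    # only in their first base survive branch merges; it lies at most 2 bases
    # behind the walk head, so the state space stays bounded
    key <- paste0(pos_key(item$p), "|", item$partial, "|",
                  if (is.null(item$cstart)) "" else pos_key(item$cstart))
    if (!is.null(visited[[key]])) return()
    visited[[key]] <- TRUE
    qt <<- qt + 1L
    if (qt > length(queue)) length(queue) <<- 2L * qt
    queue[[qt]] <<- item
  }
  for (s in seeds) push(list(p = s, partial = "", cstart = NULL, dist = 0L))
  while (qh <= qt) {
    it <- queue[[qh]]; qh <- qh + 1L
    base <- pos_base(graph, it$p)
    cstart <- if (it$partial == "") it$p else it$cstart
    partial <- paste0(it$partial, base)
    done <- nchar(partial) == 3L
    expand <- TRUE
    if (done) {
      d0 <- it$dist - 2L
      if (partial %in% targets && d0 <= max_dist) {
        skey <- paste(pos_key(cstart), pos_key(it$p), partial)
        if (!skey %in% site_seen) {
          site_seen <- c(site_seen, skey)
          sites[[length(sites) + 1]] <- list(
            start = cstart, end = it$p, codon = partial, distance = d0)
        }
      }
      if (partial %in% terminal) expand <- FALSE
      partial <- ""
      cstart <- NULL
    }
    if (expand && it$dist + 1L <= max_dist + 2L) {
      for (np in pos_next(graph, it$p))
        push(list(p = np, partial = partial, cstart = cstart, dist = it$dist + 1L))
    }
  }
  sites
}

sites_to_tibble <- function(graph, sites, kind, convert_rc = FALSE) {
  if (length(sites) == 0) return(empty_codon_sites())
  rows <- lapply(sites, function(s) {
    if (convert_rc) {
      first <- rc_pos(graph, s$end)   # genome-forward first base
      last <- rc_pos(graph, s$start)
      codon <- revcomp(s$codon)
    } else {
      first <- s$start; last <- s$end; codon <- s$codon
    }
    list(step = first$step, off = first$off,
         end_step = last$step, end_off = last$off,
         codon = codon, distance = s$distance)
  })
  tb <- tibble::tibble(
    step = vapply(rows, `[[`, "", "step"),
    off = vapply(rows, `[[`, 0L, "off"),
    end_step = vapply(rows, `[[`, "", "end_step"),
    end_off = vapply(rows, `[[`, 0L, "end_off"),
    codon = vapply(rows, `[[`, "", "codon"),
    kind = kind,
    distance = vapply(rows, `[[`, 0L, "distance"),
    after_stop = FALSE, has_sd = FALSE
  )
  tb <- tb[order(tb$distance, tb$step, tb$off), ]
  tb[!duplicated(tb[, c("step", "off", "codon")]), ]
}

# Anchor trimmed so its spelled length is a codon multiple (anchors are
# already frame-0 from anchor_path(); this guards ad-hoc graph_path input).
anchor_core_path <- function(graph, anchor) {
  if (is.data.frame(anchor)) anchor <- anchor$path[[1]]
  len <- path_nt_length(graph, anchor)
  r <- len %% 3L
  if (r == 0L) anchor else subpath_at(graph, anchor, 0L, len - r)
}

#' Find in-frame stop codons reachable from an anchor
#'
#' BFS forward from the first base after the anchor's rightmost position, in
#' the anchor's reading frame. Exploration stops at (but reports) each stop
#' codon; all distinct stops whose first base lies within `max_dist`
#' nucleotides of the anchor boundary are returned.
#'
#' @param graph An `asm_graph`.
#' @param anchor A codon-aligned `graph_path` (or one-row anchor tibble).
#' @param max_dist Maximum distance in nucleotides (>= 0).
#' @return A codon-site tibble: genome-forward position of the codon's first
#'   base (`step`, `off`), last base (`end_step`, `end_off`), `codon`,
#'   `kind`, `distance` (multiple of 3), and the start-only flags
#'   (`after_stop`, `has_sd`, always `FALSE` here).
#' @export
find_stop_codons <- function(graph, anchor, max_dist = 3000L) {
  stopifnot(max_dist >= 0)
  core <- anchor_core_path(graph, anchor)
  seeds <- pos_next(graph, path_last_pos(core))
  sites <- codon_bfs(graph, seeds, targets = STOP_CODONS,
                     terminal = STOP_CODONS, max_dist = max_dist)
  sites_to_tibble(graph, sites, kind = "stop")
}

#' Find in-frame start codons upstream of an anchor
#'
#' Searches backward from the anchor's leftmost position (implemented as a
#' forward BFS on the reverse-complement strand in the complementary frame).
#' The anchor's own first codon is reported at distance 0 when it is a start
#' codon; upstream starts are reported at distance 3, 6, ... (nucleotides
#' from the anchor boundary to the codon's first base). Exploration is not
#' pruned at upstream stop codons. Each start is annotated with:
#' `after_stop` - an in-frame stop codon lies further upstream on some path
#' (so no longer ORF can begin beyond this start on that path); `has_sd` - a
#' Shine-Dalgarno-like motif (>= 4/6 matches to AGGAGG, 5-15 nt upstream)
#' precedes the start on some path.
#'
#' @param graph An `asm_graph`.
#' @param anchor A codon-aligned `graph_path` (or one-row anchor tibble).
#' @param max_dist Maximum distance in nucleotides (>= 0).
#' @param start_set Codons accepted as starts, default `START_CODONS`.
#' @return A codon-site tibble (see [find_stop_codons()]), `kind = "start"`.
#' @export
find_start_codons <- function(graph, anchor, max_dist = 3000L,
                              start_set = START_CODONS) {
  stopifnot(max_dist >= 0)
  core <- anchor_core_path(graph, anchor)
  rc_targets <- revcomp(start_set)
  rc_stops <- revcomp(STOP_CODONS)
  rc_core <- rc_graph_path(graph, core)
  upstream_seeds <- pos_next(graph, path_last_pos(rc_core))

  out <- list()
  first_codon <- substr(spell_path(graph, core), 1L, 3L)
  if (first_codon %in% start_set) {
    sp <- path_start_pos(core)
    lp <- path_last_pos(normalize_path(graph, subpath_at(graph, core, 0L, 3L)))
    out[[length(out) + 1]] <- tibble::tibble(
      step = sp$step, off = sp$off, end_step = lp$step, end_off = lp$off,
      codon = first_codon, kind = "start", distance = 0L,
      after_stop = FALSE, has_sd = FALSE)
  }
  if (max_dist >= 3L) {
    sites <- codon_bfs(graph, upstream_seeds, targets = rc_targets,
                       terminal = character(0), max_dist = max_dist - 3L)
    # walk distance d of the codon's first consumed (rc) base corresponds to a
    # genome distance of d + 3 from the anchor boundary to the codon start
    sites <- lapply(sites, function(s) { s$distance <- s$distance + 3L; s })
    tb <- sites_to_tibble(graph, sites, kind = "start", convert_rc = TRUE)
    out[[length(out) + 1]] <- tb
  }
  tb <- if (length(out) > 0) dplyr::bind_rows(out) else empty_codon_sites()
  if (nrow(tb) == 0) return(tb)
  tb <- tb[order(tb$distance, tb$step, tb$off), ]

  # annotate flags by secondary upstream walks from just beyond each start
  for (i in seq_len(nrow(tb))) {
    first_pos <- pos(tb$step[i], tb$off[i])
    beyond <- pos_next(graph, rc_pos(graph, first_pos))
    budget <- max_dist - tb$distance[i]
    if (budget >= 3L && length(beyond) > 0) {
      hits <- codon_bfs(graph, beyond, targets = rc_stops,
                        terminal = rc_stops, max_dist = budget - 3L)
      tb$after_stop[i] <- length(hits) > 0
    }
    tb$has_sd[i] <- has_sd_motif(graph, beyond)
  }
  tb
}

# Shine-Dalgarno-like motif: >= 4/6 matches to AGGAGG in a window whose 3' end
# lies 5-15 nt upstream of the start codon. `beyond` are rc-strand positions
# of the first base upstream of the start; upstream strings are enumerated
# along all branches up to 21 nt.
has_sd_motif <- function(graph, beyond, motif = "AGGAGG", min_match = 4L,
                         gap_range = c(5L, 15L), max_strings = 200L) {
  if (length(beyond) == 0) return(FALSE)
  strings <- character(0)
  grow <- function(p, acc) {
    if (length(strings) >= max_strings) return()
    acc <- paste0(acc, pos_base(graph, p))
    if (nchar(acc) >= gap_range[2] + nchar(motif)) {
      strings <<- c(strings, acc)
      return()
    }
    nxt <- pos_next(graph, p)
    if (length(nxt) == 0) {
      strings <<- c(strings, acc)
      return()
    }
    for (np in nxt) grow(np, acc)
  }
  for (p in beyond) grow(p, "")
  mot <- strsplit(motif, "")[[1]]
  for (s in strings) {
    for (d in seq(gap_range[1], gap_range[2])) {
      if (nchar(s) < d + length(mot)) next
      win <- revcomp(substr(s, d + 1L, d + length(mot)))
      if (sum(strsplit(win, "")[[1]] == mot) >= min_match) return(TRUE)
    }
  }
  FALSE
}
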