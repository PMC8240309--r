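# Brute-force oracles, independent of the BFS/Dijkstra code paths: explicit
# enumeration of every base-level walk, with per-path codon scanning.

ebase <- function(g, step, off) {
  s <- if (substr(step, nchar(step), nchar(step)) == "+")
    g$seqs[[substr(step, 1, nchar(step) - 1)]]
  else revcomp(g$seqs[[substr(step, 1, nchar(step) - 1)]])
  substr(s, off + 1, off + 1)
}

elen_of <- function(g, step) nchar(g$seqs[[substr(step, 1, nchar(step) - 1)]])

fwd_positions <- function(g, p) {
  if (p$off + 1 < elen_of(g, p$step)) return(list(list(step = p$step, off = p$off + 1)))
  lapply(graph_succ(g, p$step), function(s) list(step = s, off = g$overlap))
}

bwd_positions <- function(g, p) {
  if (p$off > 0) return(list(list(step = p$step, off = p$off - 1)))
  lapply(graph_pred(g, p$step), function(q)
    list(step = q, off = elen_of(g, q) - g$overlap - 1))
}

# all position-paths from each seed, up to max_bases bases (list of lists)
enumerate_walks <- function(g, seeds, max_bases, stepper) {
  out <- list()
  grow <- function(path) {
    if (length(path) >= max_bases) { out[[length(out) + 1]] <<- path; return() }
    nxt <- stepper(g, path[[length(path)]])
    if (length(nxt) == 0) { out[[length(out) + 1]] <<- path; return() }
    for (np in nxt) grow(c(path, list(np)))
  }
  for (s in seeds) grow(list(s))
  out
}

# first in-frame stop per forward walk; set of "step:off:codon:mindist"
oracle_stop_sites <- function(g, anchor_path, max_dist) {
  last <- list(step = anchor_path$steps[length(anchor_path$steps)],
               off = anchor_path$end_offset - 1)
  seeds <- fwd_positions(g, last)
  found <- list()
  for (w in enumerate_walks(g, seeds, max_dist + 3, fwd_positions)) {
    d <- 0
    while (d + 3 <= length(w)) {
      codon <- paste0(ebase(g, w[[d + 1]]$step, w[[d + 1]]$off),
                      ebase(g, w[[d + 2]]$step, w[[d + 2]]$off),
                      ebase(g, w[[d + 3]]$step, w[[d + 3]]$off))
      if (codon %in% c("TAA", "TAG", "TGA")) {
        if (d <= max_dist) {
          key <- paste0(w[[d + 1]]$step, ":", w[[d + 1]]$off, ":", codon)
          if (is.null(found[[key]]) || found[[key]] > d) found[[key]] <- d
        }
        break
      }
      d <- d + 3
    }
  }
  if (length(found) == 0) return(character(0))
  sort(paste0(names(found), ":", unlist(found)))
}

# upstream starts per backward walk (no pruning at stops)
oracle_start_sites <- function(g, anchor_path, max_dist,
                               start_set = c("ATG", "GTG", "TTG")) {
  first <- list(step = anchor_path$steps[1], off = anchor_path$start_offset)
  seeds <- bwd_positions(g, first)
  found <- list()
  for (w in enumerate_walks(g, seeds, max_dist, bwd_positions)) {
    d <- 0
    while (d + 3 <= length(w)) {
      codon <- paste0(ebase(g, w[[d + 3]]$step, w[[d + 3]]$off),
                      ebase(g, w[[d + 2]]$step, w[[d + 2]]$off),
                      ebase(g, w[[d + 1]]$step, w[[d + 1]]$off))
      if (codon %in% start_set && d + 3 <= max_dist) {
        key <- paste0(w[[d + 3]]$step, ":", w[[d + 3]]$off, ":", codon)
        if (is.null(found[[key]]) || found[[key]] > d + 3) found[[key]] <- d + 3
      }
      d <- d + 3
    }
  }
  if (length(found) == 0) return(character(0))
  sort(paste0(names(found), ":", unlist(found)))
}

site_keys <- function(sites) {
  if (nrow(sites) == 0) return(character(0))
  sort(paste0(sites$step, ":", sites$off, ":", sites$codon, ":", sites$distance))
}

# a codon-aligned anchor somewhere in the middle of a graph's first full path
pick_dag_anchor <- function(g, len_codons = 4) {
  steps <- character(0)
  s <- sort(names(g$seqs))[1]
  cur <- paste0(s, "+")
  repeat {
    steps <- c(steps, cur)
    nx <- graph_succ(g, cur)
    if (length(nx) == 0) break
    cur <- nx[1]
  }
  p <- full_path(g, steps)
  total <- path_nt_length(g, p)
  from <- (total %/% 2) - (total %/% 2) %% 3
  to <- from + 3 * len_codons
  if (to > total) return(NULL)
  subpath_at(g, p, from, to)
}
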