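# Small hand-built graphs with consistent overlaps, shared across tests.

# chain of edges from novel segments: edge i = tail_k(edge i-1) ++ novel_i
chain_graph <- function(novels, k = 4L, ids = NULL) {
  if (is.null(ids)) ids <- paste0("e", seq_along(novels))
  segs <- character(0)
  prev_tail <- NULL
  for (i in seq_along(novels)) {
    s <- if (i == 1) novels[[i]] else paste0(prev_tail, novels[[i]])
    segs[[ids[i]]] <- s
    prev_tail <- substr(s, nchar(s) - k + 1L, nchar(s))
  }
  links <- if (length(ids) > 1)
    data.frame(from = paste0(ids[-length(ids)], "+"), to = paste0(ids[-1], "+"))
  else NULL
  asm_graph(segs, links, overlap = k)
}

# a random walk on the graph plus random offsets, for property tests
random_walk_path <- function(g, max_steps = 5L) {
  oriented <- c(paste0(names(g$seqs), "+"), paste0(names(g$seqs), "-"))
  steps <- sample(oriented, 1)
  while (length(steps) < max_steps) {
    nx <- graph_succ(g, steps[length(steps)])
    if (length(nx) == 0) break
    steps <- c(steps, sample(nx, 1))
  }
  len1 <- nchar(g$seqs[[sub("[+-]$", "", steps[1])]])
  lenn <- nchar(g$seqs[[sub("[+-]$", "", steps[length(steps)])]])
  start <- sample.int(len1, 1) - 1L
  lo <- if (length(steps) == 1) start + 1L else g$overlap + 1L
  if (lo > lenn) return(NULL)
  end <- sample(seq(lo, lenn), 1)
  graph_path(steps, start, end)
}

write_tmp_gfa <- function(lines) {
  f <- withr::local_tempfile(fileext = ".gfa", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

# scored candidate rows for clustering / representative tests
fake_orfs <- function(aa, paths = NULL, likelihood = 1, coverage = 1,
                      ids = sprintf("orf_%04d", seq_along(aa))) {
  n <- length(aa)
  tibble::tibble(
    orf_id = ids, anchor_id = "anchor_001", query_id = "q",
    nt_len = nchar(aa) * 3L + 3L, nt_seq = strrep("A", 3), aa_seq = aa,
    start_codon = "ATG", stop_codon = "TAA",
    start_distance = 0L, stop_distance = 0L,
    after_stop = FALSE, has_sd = FALSE, truncated = FALSE,
    path = if (is.null(paths)) replicate(n, graph_path("x+", 0L, 3L),
                                         simplify = FALSE) else paths,
    likelihood = rep_len(likelihood, n), coverage = rep_len(coverage, n))
}

# deterministic protein-like sequences at controlled identity
seq_family <- function(n_codons = 200L, seed = 42L) {
  base <- random_cds(n_codons, seed = seed)
  list(
    A = translate_cds(base),
    B = translate_cds(mutate_cds(base, rate = 0.07, seed = seed + 1L)),
    C = translate_cds(mutate_cds(mutate_cds(base, rate = 0.07, seed = seed + 1L),
                                 rate = 0.07, seed = seed + 2L)),
    far = translate_cds(mutate_cds(base, rate = 0.75, seed = seed + 3L)))
}

aa_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
  Biostrings::pid(aln, type = "PID1")
}
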