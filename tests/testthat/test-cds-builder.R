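# Reachability, bounded path enumeration, and candidate assembly.

test_that("reachable_edges respects topology and the length budget", {
  g1 <- asm_graph(c(e = "ACGTACGTACGT"))
  expect_identical(reachable_edges(g1, list(step = "e+", off = 2L),
                                   list(step = "e+", off = 10L), 100), "e+")

  # diamond: both branches within budget, then the long one priced out
  z1 <- "GGGG"; z2 <- "CCCC"
  g <- asm_graph(
    c(A = paste0("ACGTACGT", z1),
      B1 = paste0(z1, "ACGTACGT", z2),
      B2 = paste0(z1, strrep("AC", 30), z2),
      C = paste0(z2, "ACGTACGTACGT")),
    data.frame(from = c("A+", "A+", "B1+", "B2+"), to = c("B1+", "B2+", "C+", "C+")),
    overlap = 4)
  v <- list(step = "A+", off = 0L)
  w <- list(step = "C+", off = 16L)
  expect_setequal(reachable_edges(g, v, w, 200), c("A+", "B1+", "B2+", "C+"))
  expect_setequal(reachable_edges(g, v, w, 40), c("A+", "B1+", "C+"))
  # agreement with brute-force enumeration at both budgets
  for (budget in c(40, 200)) {
    paths <- enumerate_paths(g, v, w, max_len = budget)$paths
    used <- sort(unique(unlist(lapply(paths, `[[`, "steps"))))
    expect_setequal(reachable_edges(g, v, w, budget), used)
  }
})

test_that("enumerate_paths counts serial bubble combinations exactly", {
  cds <- random_cds(480, seed = 31)
  linear <- generate_fixture(genes = c(gg = cds), n_bubbles = 0, seed = 31)
  tp <- linear$truth$path[[1]]
  v <- list(step = tp$steps[1], off = tp$start_offset)
  lastp <- tp$steps[length(tp$steps)]
  w <- list(step = lastp, off = tp$end_offset)
  expect_length(enumerate_paths(linear$graph, v, w, max_len = 3000)$paths, 1)

  for (n in c(3L, 6L)) {
    fix <- generate_fixture(genes = c(gg = cds), n_bubbles = n, seed = 31)
    tp <- fix$truth$path[[1]]
    v <- list(step = tp$steps[1], off = tp$start_offset)
    w <- list(step = tp$steps[length(tp$steps)], off = tp$end_offset)
    res <- enumerate_paths(fix$graph, v, w, max_len = 3000)
    expect_length(res$paths, 2^n)
    expect_false(res$truncated)
    # spelled lengths all equal the gene length (variant branches are
    # substitutions, not indels)
    expect_true(all(vapply(res$paths, function(p)
      path_nt_length(fix$graph, p), 0L) == nchar(cds)))
  }
})

test_that("enumeration truncates at the 1000-path cap with a flag", {
  cds <- random_cds(500, seed = 33)
  fix <- generate_fixture(genes = c(gg = cds), n_bubbles = 10, seed = 33)
  tp <- fix$truth$path[[1]]
  v <- list(step = tp$steps[1], off = tp$start_offset)
  w <- list(step = tp$steps[length(tp$steps)], off = tp$end_offset)
  res <- enumerate_paths(fix$graph, v, w, max_len = 3000)
  expect_length(res$paths, 1000)
  expect_true(res$truncated)
})

test_that("build_candidates assembles the embedded gene and screens invariants", {
  fix <- generate_fixture(n_bubbles = 0, seed = 35)
  g <- fix$graph
  tr <- fix$truth[1, ]
  an <- find_anchors_bruteforce(g, stats::setNames(tr$aa, tr$gene_id))
  a <- an[1, ]
  starts <- find_start_codons(g, a, max_dist = 300)
  stops <- find_stop_codons(g, a, max_dist = 300)
  cands <- build_candidates(g, a, starts, stops)
  expect_equal(nrow(cands), 1)
  expect_identical(cands$aa_seq[1], tr$aa)
  expect_identical(cands$nt_seq[1], tr$nt)
  # round trip: the stored path spells the stored sequence
  expect_identical(spell_path(g, cands$path[[1]]), cands$nt_seq[1])
  expect_identical(translate_cds(cands$nt_seq[1]), cands$aa_seq[1])
  expect_equal(cands$nt_len[1] %% 3, 0)
})

test_that("the restorable-length bound is inclusive at the boundary", {
  z <- "GGGG"
  mk <- function(n_codons) {
    cds <- random_cds(n_codons, seed = 41)
    g <- asm_graph(c(E = paste0("CCCTAACCC", cds, "CCCCCC")))
    anchor <- subpath_at(g, full_path(g, "E+"), 9 + 3, 9 + nchar(cds) - 3)
    starts <- find_start_codons(g, anchor, max_dist = 60)
    stops <- find_stop_codons(g, anchor, max_dist = 60)
    list(g = g, anchor = anchor, starts = starts, stops = stops, cds = cds)
  }
  x <- mk(11)   # a 33-nt coding sequence
  keep <- build_candidates(x$g, x$anchor, x$starts, x$stops,
                           builder_limits(max_restorable_length = 33))
  expect_true(x$cds %in% keep$nt_seq)
  drop <- build_candidates(x$g, x$anchor, x$starts, x$stops,
                           builder_limits(max_restorable_length = 32))
  expect_false(x$cds %in% drop$nt_seq)
})

test_that("nucleotide variants spelling one protein collapse to one candidate", {
  # CTG/GGA/CCA codons are immune to third-position changes, so the bubble
  # branches spell nucleotide-distinct but protein-identical prefixes
  cds <- paste0("ATG", strrep("CTGGGACTGCCA", 60), "TAA")
  fix <- generate_fixture(genes = c(syn = cds), n_bubbles = 1, divergence = 2,
                          seed = 43)
  g <- fix$graph
  tr <- fix$truth[1, ]
  # anchor over the final third of the gene, downstream of the bubble
  anchor <- subpath_at(g, tr$path[[1]], 510, 690)
  starts <- find_start_codons(g, anchor, max_dist = 600)
  stops <- find_stop_codons(g, anchor, max_dist = 100)
  cands <- build_candidates(g, anchor, starts, stops)
  # two nucleotide-level prefix variants reach the true start; dedup on the
  # translation leaves exactly one candidate for the true protein
  expect_equal(sum(cands$aa_seq == tr$aa), 1)
})

test_that("candidate construction is deterministic", {
  fix <- generate_fixture(n_bubbles = 2, seed = 45)
  g <- fix$graph
  an <- find_anchors_bruteforce(g, stats::setNames(fix$truth$aa[1], "q"))
  run <- function() {
    a <- an[1, ]
    build_candidates(g, a, find_start_codons(g, a, max_dist = 300),
                     find_stop_codons(g, a, max_dist = 300))
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$nt_seq, r2$nt_seq)
  expect_identical(r1$orf_id, r2$orf_id)
})
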