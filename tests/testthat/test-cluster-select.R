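# Single-linkage clustering and representative selection.

test_that("substring pairs and high-identity pairs co-cluster; distant ones split", {
  fam <- seq_family()
  sub <- substr(fam$A, 10, 150)
  orfs <- fake_orfs(c(fam$A, sub, fam$far))
  cl <- cluster_orfs(orfs)
  expect_equal(cl$cluster[cl$aa_seq == fam$A], cl$cluster[cl$aa_seq == sub])
  expect_false(cl$cluster[cl$aa_seq == fam$far][1] ==
                 cl$cluster[cl$aa_seq == fam$A][1])
})

test_that("single linkage is transitive across a chain of similar sequences", {
  fam <- seq_family()
  expect_gt(aa_identity(fam$A, fam$B), 90)
  expect_gt(aa_identity(fam$B, fam$C), 90)
  expect_lt(aa_identity(fam$A, fam$C), 90)
  cl <- cluster_orfs(fake_orfs(c(fam$A, fam$B, fam$C, fam$far)))
  expect_equal(length(unique(cl$cluster[cl$aa_seq != fam$far])), 1)
  expect_equal(length(unique(cl$cluster)), 2)
})

test_that("clustering is invariant to input order", {
  fam <- seq_family()
  seqs <- c(fam$A, fam$B, fam$C, fam$far)
  orfs <- fake_orfs(seqs)
  base <- cluster_orfs(orfs)
  perm <- cluster_orfs(orfs[c(3, 1, 4, 2), ])
  expect_identical(base$orf_id, perm$orf_id)
  expect_identical(base$cluster, perm$cluster)
})

test_that("triplet comparison is lexicographic with a documented tie-break", {
  orfs <- fake_orfs(c("MAAAA", "MCCCC"), likelihood = c(0.9, 0.9),
                    coverage = c(10, 12))
  orfs$nt_len <- c(3000L, 100L)
  expect_equal(reliability_order <- orfgraph:::reliability_order(orfs)[1], 2L)
  orfs2 <- fake_orfs(c("MAAAA", "MCCCC"), likelihood = c(1.0, 0.5),
                     coverage = c(1, 99))
  orfs2$nt_len <- c(1L, 9999L)
  expect_equal(orfgraph:::reliability_order(orfs2)[1], 1L)
  tied <- fake_orfs(c("MAAAA", "MCCCC"))
  expect_equal(orfgraph:::reliability_order(tied)[1], 1L)  # orf_id breaks ties
  expect_length(rank_triplet(orfs[1, ]), 3)
})

test_that("representatives cover every long cluster edge (vs brute-force cover)", {
  # graph with four long edges and connectors; 5-member clusters with known
  # path compositions
  segs <- c(L1 = strrep("A", 1100), L2 = strrep("C", 1100),
            L3 = strrep("G", 1100), L4 = strrep("T", 1100),
            s1 = strrep("AC", 50))
  g <- asm_graph(segs)
  paths <- list(
    m1 = graph_path(c("L1+", "s1+"), 0L, 100L),
    m2 = graph_path(c("L2+"), 0L, 1100L),
    m3 = graph_path(c("L1+", "L3+"), 0L, 1100L),
    m4 = graph_path(c("L4+"), 0L, 1100L),
    m5 = graph_path(c("s1+"), 0L, 100L))
  orfs <- fake_orfs(paste0("M", c("A", "C", "G", "T", "W")),
                    paths = unname(paths),
                    likelihood = c(1, .9, .8, .7, .6))
  orfs$cluster <- 1L
  reps <- select_representatives(orfs, g)
  covered <- unique(unlist(lapply(reps$path, function(p) sub("[+-]$", "", p$steps))))
  long_edges <- c("L1", "L2", "L3", "L4")
  expect_true(all(long_edges %in% covered))
  # brute-force minimal cover oracle: some subset covers all long edges, and
  # the greedy set is one of the covering subsets
  member_edges <- lapply(paths, function(p) intersect(sub("[+-]$", "", p$steps),
                                                      long_edges))
  subsets <- unlist(lapply(seq_along(paths), function(k)
    combn(seq_along(paths), k, simplify = FALSE)), recursive = FALSE)
  covering <- Filter(function(ix) all(long_edges %in% unlist(member_edges[ix])),
                     subsets)
  expect_gt(length(covering), 0)
  min_size <- min(lengths(covering))
  expect_gte(nrow(reps), min_size)
  # greedy scans by reliability: the most reliable member is always kept first
  expect_equal(reps$orf_id[1], "orf_0001")
})

test_that("clusters without long edges emit exactly the most reliable member", {
  g <- asm_graph(c(a = strrep("A", 90), b = strrep("C", 90)))
  orfs <- fake_orfs(c("MAA", "MCC"),
                    paths = list(graph_path("a+", 0L, 90L),
                                 graph_path("b+", 0L, 90L)),
                    likelihood = c(0.2, 0.9))
  orfs$cluster <- 1L
  reps <- select_representatives(orfs, g)
  expect_equal(nrow(reps), 1)
  expect_equal(reps$orf_id, "orf_0002")
  # one long edge shared by every member: one representative
  g2 <- asm_graph(c(L = strrep("G", 1200)))
  orfs2 <- fake_orfs(c("MGG", "MGA"),
                     paths = list(graph_path("L+", 0L, 1200L),
                                  graph_path("L+", 0L, 1100L)),
                     coverage = c(5, 9))
  orfs2$cluster <- 1L
  reps2 <- select_representatives(orfs2, g2)
  expect_equal(nrow(reps2), 1)
  expect_equal(reps2$orf_id, "orf_0002")
})

test_that("the literal ascending scan order is available and still covers", {
  g <- asm_graph(c(L1 = strrep("A", 1100), L2 = strrep("C", 1100)))
  orfs <- fake_orfs(c("MA", "MC", "MW"),
                    paths = list(graph_path("L1+", 0L, 1100L),
                                 graph_path("L2+", 0L, 1100L),
                                 graph_path(c("L1+"), 0L, 900L)),
                    likelihood = c(0.9, 0.8, 0.1))
  orfs$cluster <- 1L
  reps <- select_representatives(orfs, g,
                                 cluster_params(literal_scan_order = TRUE))
  covered <- unique(unlist(lapply(reps$path, function(p) sub("[+-]$", "", p$steps))))
  expect_true(all(c("L1", "L2") %in% covered))
  # ascending order picks the least reliable first
  expect_equal(reps$orf_id[1], "orf_0003")
})
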