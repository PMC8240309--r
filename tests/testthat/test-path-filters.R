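# Position likelihood, unique edges, compatibility, the contig filter, and
# similarity classification.

test_that("distance likelihood is the windowed fraction of trained distances", {
  m <- train_position_model(data.frame(model_id = "M", distance = c(0, 0, 0)))
  expect_equal(distance_likelihood(m, "M", 0), 1.0)
  m2 <- train_position_model(data.frame(model_id = "M", distance = c(0, 1000)))
  expect_equal(distance_likelihood(m2, "M", 0), 0.5)
  m3 <- train_position_model(data.frame(model_id = "M",
                                        distance = c(100, 200, 300)))
  expect_equal(distance_likelihood(m3, "M", 200), 1.0)
  # unknown models impose no penalty
  expect_equal(distance_likelihood(m3, "unseen", 123), 1.0)
  expect_equal(distance_likelihood(NULL, "M", 5), 1.0)
  expect_error(train_position_model(data.frame(model_id = "M", distance = -1)))
})

test_that("likelihood approaches the analytic window fraction on a uniform histogram", {
  m <- train_position_model(data.frame(model_id = "U", distance = 0:3000))
  expected <- (2 * 150 + 1) / 3001
  for (d in c(150, 151, 777, 1500, 2850)) {
    expect_lt(abs(distance_likelihood(m, "U", d) - expected), 1 / 3000)
  }
  expect_true(all(distance_likelihood(m, "U", c(0, 3000)) >= 0 &
                    distance_likelihood(m, "U", c(0, 3000)) <= 1))
})

test_that("unique edges follow the printed length and degree predicate", {
  f9 <- generate_fig9_graph()
  g <- f9$graph
  for (e in c("B1", "D1")) expect_true(is_unique_edge(g, e))
  for (e in c("B2", "D2", "A", "C", "E")) expect_false(is_unique_edge(g, e))
  # B2/D2 fail on length alone, A/C/E on the degree conditions
  expect_true(nchar(g$seqs[["B2"]]) <= 300)
  expect_gt(nchar(g$seqs[["C"]]), 300)
  # the alternative (unitig-style) convention flips the classification
  alt <- unique_edge_params(degree_convention = "unitig")
  expect_false(is_unique_edge(g, "B1", alt))
  expect_true(is_unique_edge(g, "A", alt))
  expect_error(is_unique_edge(g, "nope"), "unknown edge")
})

test_that("path compatibility covers containment, overlap, and orientation", {
  f9 <- generate_fig9_graph()
  p <- f9$paths
  expect_true(paths_compatible(p$yellow, p$green))    # containment
  expect_true(paths_compatible(c("C+", "D1+"), c("A+", "B1+", "C+", "D1+")))
  expect_true(paths_compatible(c("B1+", "C+"), c("C+", "D1+", "E+")))  # overlap
  expect_false(paths_compatible(p$red, p$green))      # shared middle only
  # symmetric, reflexive, reverse-complement aware
  expect_identical(paths_compatible(p$red, p$green),
                   paths_compatible(p$green, p$red))
  expect_true(paths_compatible(p$blue, p$blue))
  rc_green <- c("C-", "B1-", "A-")
  expect_true(paths_compatible(rc_green, c("A+", "B1+", "C+")))
})

test_that("the contig filter removes exactly the contradicting paths", {
  f9 <- generate_fig9_graph()
  g <- f9$graph
  orfs <- fake_orfs(c("MAAA", "MCCC", "MDDD"),
                    paths = list(f9$paths$red, f9$paths$blue, f9$paths$yellow),
                    ids = c("red", "blue", "yellow"))
  out <- filter_contradicting(orfs, f9$contigs, g)
  expect_setequal(out$orf_id, c("blue", "yellow"))
  rep <- attr(out, "report")
  expect_false(is.na(rep$contradicting_contig[rep$orf_id == "red"]))

  # an ORF without unique edges is always kept
  no_uniq <- fake_orfs("MEEE", paths = list(full_path(g, c("A+", "B2+", "C+"))),
                       ids = c("nou"))
  expect_equal(nrow(filter_contradicting(no_uniq, f9$contigs, g)), 1)

  # soundness: a path inside a contig is never removed
  inside <- fake_orfs("MFFF", paths = list(full_path(g, c("B1+", "C+", "D1+"))),
                      ids = "in")
  expect_equal(nrow(filter_contradicting(inside, f9$contigs, g)), 1)
})

test_that("similarity classification bands match the identity thresholds", {
  fam <- seq_family()
  db <- c(known = fam$A)
  orfs <- fake_orfs(c(fam$A, fam$B, fam$far))
  out <- similarity_classify(orfs, db)
  expect_identical(out$verdict[1], "reliable-known")
  expect_gt(out$best_identity[2], 90)
  expect_lt(out$best_identity[2], 100)
  expect_identical(out$verdict[2], "reliable-novel")
  expect_lt(out$best_identity[3], 80)
  expect_identical(out$verdict[3], "candidate")
  expect_error(similarity_classify(orfs, character(0)), "empty")
})

test_that("triplet scoring uses the coverage tags, length-weighted", {
  fix <- generate_fixture(n_bubbles = 1, seed = 51)
  g <- fix$graph
  orfs <- fake_orfs("MAAA", paths = list(fix$truth$path[[1]]))
  orfs$query_id <- "q"
  sc <- score_candidates(orfs, g)
  expect_equal(sc$coverage, 40)      # whole true path at uniform 40x
  expect_equal(sc$likelihood, 1)     # no model trained
})
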