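toy_manifest <- function() {
  benchmark_manifest(
    ids = c("a1", "a2", "a3", "b1", "b2", "c1"),
    groups = c("A", "A", "A", "B", "B", "C")
  )
}

test_that("manifest validation and TSV round-trip", {
  man <- toy_manifest()
  expect_s3_class(man, "benchmark_manifest")
  expect_error(benchmark_manifest(c("x", "x"), c("g", "g")), "unique")
  expect_error(benchmark_manifest("x", ""), "group label")
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_manifest(man, path)
  expect_equal(read_manifest(path)$group, man$group)
})

test_that("ranking is deterministic and matches a sort oracle", {
  set.seed(2)
  db <- lapply(1:6, function(i) manual_descriptor(runif(8)))
  names(db) <- c("a1", "a2", "a3", "b1", "b2", "c1")
  q <- manual_descriptor(runif(8))
  run <- rank_database(q, db, metric = "L1")
  oracle <- vapply(db, compare_descriptors, numeric(1), a = q, metric = "L1")
  expect_identical(run$ranked_ids, names(sort(oracle)))
  expect_true(all(diff(run$scores) >= 0))
  # an exact duplicate of the query ranks first with score zero
  db$dup <- q
  run2 <- rank_database(q, db, metric = "L1")
  expect_identical(run2$ranked_ids[1], "dup")
  expect_equal(run2$scores[1], 0)
  # the query id is excluded from its own ranking
  run3 <- rank_database(q, db, metric = "L1", query_id = "dup")
  expect_false("dup" %in% run3$ranked_ids)
  expect_error(rank_database(q, db["dup"], query_id = "dup"), "empty")
  # a single-entry database is ranked trivially
  expect_identical(rank_database(q, db["a1"])$ranked_ids, "a1")
})

test_that("precision and recall follow the retrieval-size formulas", {
  man <- toy_manifest()
  # query a1: relevant = {a2, a3}; ranking mixes in two misses
  run <- manual_run("a1", c("a2", "b1", "a3", "b2", "c1"))
  pr <- precision_recall(run, man)
  expect_equal(pr$precision, c(1, 1 / 2, 2 / 3, 2 / 4, 2 / 5))
  expect_equal(pr$recall, c(1 / 2, 1 / 2, 1, 1, 1))
  # TP = 3 of 4 retrieved -> precision 0.75
  man2 <- benchmark_manifest(sprintf("s%d", 1:8), rep(c("G", "H"), each = 4))
  run2 <- manual_run("s1", c("s2", "s3", "s5", "s4", "s6", "s7", "s8"))
  pr2 <- precision_recall(run2, man2)
  expect_equal(pr2$precision[4], 0.75)
  # conservation at full retrieval: recall reaches exactly 1
  expect_equal(pr2$recall[7], 1)
  # singleton-group query is skipped with a warning
  expect_warning(expect_null(
    precision_recall(manual_run("c1", c("a1", "a2")), man)), "only member")
})

test_that("perfect retrieval gives the horizontal precision-1 line", {
  man <- toy_manifest()
  runs <- list(manual_run("a1", c("a2", "a3", "b1", "b2", "c1")),
               manual_run("b1", c("b2", "a1", "a2", "a3", "c1")))
  avg <- average_pr(runs, man, recall_levels = seq(0, 1, 0.25))
  expect_equal(avg$precision, rep(1, 5))
})

test_that("E- and F-measure match the harmonic formulas", {
  man2 <- benchmark_manifest(sprintf("s%d", 1:8), rep(c("G", "H"), each = 4))
  # precision = recall = 1 at the relevant-set size -> both measures 1
  perfect <- manual_run("s1", c("s2", "s3", "s4", "s5", "s6", "s7", "s8"))
  expect_equal(f_measure(perfect, man2), 1)
  expect_equal(e_measure(perfect, man2, size = 3), 1)
  half <- manual_run("s1", c("s2", "s5", "s6", "s3", "s4", "s7", "s8"))
  # TP = 1 at size 3: precision = recall = 1/3, harmonic mean = 1/3
  expect_equal(f_measure(half, man2, size = 3), 1 / 3)
  # TP = 1 at size 2: precision = 1/2, recall = 1/3 -> E = 0.4
  expect_equal(e_measure(half, man2, size = 2), 0.4)
  # formula oracle on arbitrary constructed runs
  for (size in c(2, 4, 6)) {
    pr <- precision_recall(half, man2)
    p <- pr$precision[size]; r <- pr$recall[size]
    want <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    expect_equal(e_measure(half, man2, size = size), want)
    expect_equal(f_measure(half, man2, size = size), want)
  }
  # zero hits -> measure 0, not NaN
  none <- manual_run("s1", c("s5", "s6", "s7", "s8", "s2", "s3", "s4"))
  expect_equal(f_measure(none, man2, size = 4), 0)
})

test_that("a random ranking of a half-relevant database gives precision 1/2", {
  ids <- sprintf("x%02d", 1:41)
  man <- benchmark_manifest(ids, c(rep("R", 21), rep("O", 20)))
  set.seed(99)
  precs <- replicate(200, {
    run <- manual_run("x01", sample(ids[-1]))
    pr <- precision_recall(run, man)
    mean(pr$precision[c(5, 10, 20, 40)])
  })
  expect_lt(abs(mean(precs) - 0.5), 0.03)
})
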