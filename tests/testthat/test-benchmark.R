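mk_matrix <- function(ids, pathways, positives) {
  m <- matrix(0L, nrow = length(ids), ncol = length(pathways),
              dimnames = list(ids, pathways))
  for (p in names(positives)) m[positives[[p]], p] <- 1L
  m
}

test_that("matrix TSV round-trips and rejects malformed input", {
  m <- mk_matrix(c("g1", "g2", "g3"), pathway_ids(builtin_ruleset()),
                 list(CBB = c("g1", "g3"), WL = "g2"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, f)
  expect_identical(read_matrix(f), m)

  expect_identical(nrow(read_matrix("genome_id\tCBB\tWL")), 0L)

  expect_error(read_matrix(c("genome_id\tCBB", "g1\t2")),
               "non-binary cell '2'.*'g1'.*'CBB'")
  expect_error(read_matrix(c("genome_id\tCBB", "g1\t1", "g1\t0")),
               "duplicate genome row.*g1")
  expect_error(read_matrix(c("genome_id\tCBB", "g1")),
               "row 1.*expected 2 fields")
  expect_error(read_matrix(c("sample\tCBB", "g1\t1")),
               "must start with 'genome_id'")
})

test_that("confusion counts match by genome id over the matrix intersection", {
  ids <- sprintf("g%d", 1:10)
  truth <- mk_matrix(ids, "CBB", list(CBB = c("g1", "g2", "g3", "g4")))
  expect_identical(confusion_counts(truth, truth, "CBB"),
                   c(tp = 4L, fp = 0L, fn = 0L, tn = 6L))

  none <- mk_matrix(ids, "CBB", list())
  expect_identical(confusion_counts(none, truth, "CBB"),
                   c(tp = 0L, fp = 0L, fn = 4L, tn = 6L))

  # hand-enumerated 6-genome case: pred {g1,g2,g3}, truth {g2,g3,g4}
  ids6 <- sprintf("g%d", 1:6)
  pred <- mk_matrix(ids6, "WL", list(WL = c("g1", "g2", "g3")))
  tru <- mk_matrix(ids6, "WL", list(WL = c("g2", "g3", "g4")))
  expect_identical(confusion_counts(pred, tru, "WL"),
                   c(tp = 2L, fp = 1L, fn = 1L, tn = 2L))

  # row order must not matter: ids, not positions, are joined
  expect_identical(confusion_counts(pred[sample(6), , drop = FALSE],
                                    tru[rev(seq_len(6)), , drop = FALSE],
                                    "WL"),
                   c(tp = 2L, fp = 1L, fn = 1L, tn = 2L))

  # genomes known to one side only are dropped from the counts
  expect_identical(confusion_counts(pred[1:4, , drop = FALSE], tru, "WL"),
                   c(tp = 2L, fp = 1L, fn = 1L, tn = 0L))

  other <- mk_matrix("h1", "WL", list(WL = "h1"))
  expect_error(confusion_counts(other, tru, "WL"), "no genomes in common")
  expect_error(confusion_counts(pred, tru, "CBB"), "absent from")
})

test_that("precision/recall/F1 follow the standard definitions with the 0 convention", {
  expect_equal(precision_recall_f1(4, 1, 1),
               c(precision = 0.8, recall = 0.8, f1 = 0.8))
  expect_equal(precision_recall_f1(0, 0, 0),
               c(precision = 0, recall = 0, f1 = 0))
  for (k in c(1, 5, 100)) {
    expect_equal(precision_recall_f1(k, 0, 0),
                 c(precision = 1, recall = 1, f1 = 1))
  }
  # f1 is the harmonic mean, hence bounded by both components
  set.seed(3)
  for (i in 1:50) {
    m <- precision_recall_f1(sample(0:20, 1), sample(0:20, 1),
                             sample(0:20, 1))
    expect_true(all(m >= 0 & m <= 1))
    expect_lte(m[["f1"]], max(m[["precision"]], m[["recall"]]) + 1e-12)
  }
})

test_that("benchmark scores tools per pathway and flags unsupported pathways", {
  pids <- pathway_ids(builtin_ruleset())
  ids <- sprintf("g%d", 1:8)
  truth <- mk_matrix(ids, pids,
                     list(CBB = c("g1", "g2"), WL = c("g3", "g4"),
                          DC4HB = "g5"))

  perfect <- truth
  noisy <- mk_matrix(ids, setdiff(pids, "DC4HB"),
                     list(CBB = c("g1", "g6"), WL = "g3"))
  out <- benchmark_tools(list(perfect = perfect, partial = noisy), truth)

  expect_identical(nrow(out), 14L)
  pf <- out[out$tool == "perfect", ]
  expect_true(all(pf$supported))
  expect_true(all(pf$f1[pf$pathway %in% c("CBB", "WL", "DC4HB")] == 1))
  # pathways with no positives and no predictions take the 0 convention
  expect_true(all(pf$f1[!pf$pathway %in% c("CBB", "WL", "DC4HB")] == 0))

  dc <- out[out$tool == "partial" & out$pathway == "DC4HB", ]
  expect_false(dc$supported)
  expect_identical(c(dc$precision, dc$recall, dc$f1), c(0, 0, 0))
  cbb <- out[out$tool == "partial" & out$pathway == "CBB", ]
  expect_equal(cbb$precision, 0.5)
  expect_equal(cbb$recall, 0.5)

  # metrics unchanged under simultaneous genome-row permutation
  perm <- sample(ids)
  out2 <- benchmark_tools(list(perfect = perfect[perm, ],
                               partial = noisy[perm, ]),
                          truth[rev(ids), ])
  expect_identical(out2[c("tp", "fp", "fn", "tn", "precision", "recall",
                          "f1")],
                   out[c("tp", "fp", "fn", "tn", "precision", "recall",
                         "f1")])
})

test_that("the long-format benchmark TSV prints metrics to 4 decimals", {
  truth <- mk_matrix(c("a", "b", "c"), "CBB", list(CBB = c("a", "b")))
  pred <- mk_matrix(c("a", "b", "c"), "CBB", list(CBB = c("a", "c")))
  bench <- benchmark_tools(list(tool1 = pred), truth)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_benchmark(bench, f)
  lines <- readLines(f)
  expect_identical(lines[1],
                   "tool\tpathway\ttp\tfp\tfn\ttn\tprecision\trecall\tf1\tsupported")
  expect_identical(lines[2],
                   "tool1\tCBB\t1\t1\t1\t0\t0.5000\t0.5000\t0.5000\ttrue")
})
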