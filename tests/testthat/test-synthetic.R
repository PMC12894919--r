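rules <- builtin_ruleset()

all_variants <- do.call(rbind, lapply(pathway_ids(rules), function(p)
  data.frame(pathway = p, variant = variant_ids(rules, p),
             stringsAsFactors = FALSE)))

test_that("minimal satisfying profiles are minimal and do satisfy", {
  expect_identical(minimal_satisfying_profile(rules, "WL", "WL-I")$kos,
                   c("K00198", "K14138"))
  # first option of each one_of clause
  expect_identical(minimal_satisfying_profile(rules, "DC4HB")$kos,
                   sort(c("K01595", "K01676", "K18861", "K14534")))
  # first min_count of each at_least clause
  expect_identical(minimal_satisfying_profile(rules, "rGly")$kos,
                   sort(c(RGLY_GCS[1:3], RGLY_GR[1:5])))

  for (i in seq_len(nrow(all_variants))) {
    prof <- minimal_satisfying_profile(rules, all_variants$pathway[i],
                                       all_variants$variant[i])
    expect_true(predict_pathways(prof, rules)$calls[[all_variants$pathway[i]]],
                label = all_variants$variant[i])
  }
  expect_error(minimal_satisfying_profile(rules, "WL", "WL-IX"),
               "unknown variant")
})

test_that("near-miss profiles are one KO short of the pathway", {
  set.seed(11)
  for (i in seq_len(nrow(all_variants))) {
    for (rep in 1:5) {
      p <- all_variants$pathway[i]
      nm <- near_miss_profile(rules, p, all_variants$variant[i])
      full <- minimal_satisfying_profile(rules, p, all_variants$variant[i])
      expect_identical(length(nm$kos), length(full$kos) - 1L)
      expect_false(predict_pathways(nm, rules)$calls[[p]])
    }
  }
})

test_that("closed-form variant detection probability matches exhaustive enumeration", {
  # brute force: enumerate all subsets of the variant's KOs, weight each by
  # its independent-dropout probability, sum where the variant is satisfied
  brute <- function(pathway, variant, p) {
    v <- co2fix:::get_variant(rules, pathway, variant)
    kos <- sort(unique(unlist(lapply(v$clauses, `[[`, "kos"))))
    n <- length(kos)
    total <- 0
    for (mask in 0:(2^n - 1)) {
      inc <- kos[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
      w <- (1 - p)^length(inc) * p^(n - length(inc))
      if (eval_variant(v, inc)) total <- total + w
    }
    total
  }
  for (p in c(0, 0.1, 0.35)) {
    expect_equal(variant_detection_prob(rules, "WL", "WL-I", p), (1 - p)^2)
    expect_equal(variant_detection_prob(rules, "rGly", "rGly", p),
                 brute("rGly", "rGly", p))
    expect_equal(variant_detection_prob(rules, "DC4HB", "DC4HB", p),
                 brute("DC4HB", "DC4HB", p))
    expect_equal(variant_detection_prob(rules, "rTCA", "rTCA-II", p),
                 brute("rTCA", "rTCA-II", p))
  }
})

test_that("corpus generation is a pure function of config and seed", {
  c1 <- generate_corpus(rules, n_per_pathway = 5L, seed = 99L)
  c2 <- generate_corpus(rules, n_per_pathway = 5L, seed = 99L)
  expect_identical(c1, c2)
  c3 <- generate_corpus(rules, n_per_pathway = 5L, seed = 100L)
  expect_false(identical(c1$profiles, c3$profiles))

  # decoy pool never collides with marker KOs
  markers <- all_marker_kos(rules)
  for (pr in c1$profiles) {
    extra <- setdiff(pr$kos, markers)
    expect_true(all(grepl("^K90[0-9]{3}$", extra)))
  }
})

test_that("a noise-free corpus is recovered perfectly end to end", {
  corpus <- generate_corpus(rules, n_per_pathway = 4L, dropout_p = 0,
                            background_k = 15L, negatives_per_pathway = 3L,
                            seed = 5L)
  res <- predict_batch(corpus$profiles, rules)
  expect_identical(res$matrix, corpus$truth)
  bench <- benchmark_tools(list(pkg = res$matrix), corpus$truth)
  expect_true(all(bench$precision == 1))
  expect_true(all(bench$recall == 1))
  expect_true(all(bench$f1 == 1))

  # multi-pathway genomes carry both labels
  multi <- corpus$truth[grepl("multi", rownames(corpus$truth)), ]
  expect_true(all(rowSums(multi) == 2L))
})

test_that("dropout degrades recall but never precision", {
  corpus <- generate_corpus(rules, n_per_pathway = 30L, dropout_p = 0.15,
                            background_k = 10L, negatives_per_pathway = 5L,
                            seed = 21L)
  res <- predict_batch(corpus$profiles, rules)
  bench <- benchmark_tools(list(pkg = res$matrix), corpus$truth)
  expect_true(all(bench$fp == 0L))
  expect_true(all(bench$precision[bench$tp > 0] == 1))
  expect_true(any(bench$recall < 1))
})

test_that("written corpora reload into the same profiles and truth", {
  corpus <- generate_corpus(rules, n_per_pathway = 2L,
                            negatives_per_pathway = 1L, seed = 8L)
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)
  expect_identical(read_matrix(file.path(dir, "truth.tsv")), corpus$truth)
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_identical(manifest$seed, 8L)
  expect_identical(manifest$n_genomes, length(corpus$profiles))
  for (pr in corpus$profiles[c(1, length(corpus$profiles))]) {
    back <- read_ko_list(file.path(dir, paste0(pr$genome_id, ".ko")))
    expect_identical(back$kos, pr$kos)
  }
})

test_that("mock KofamScan TSVs round-trip through parse and assign", {
  set.seed(13)
  prof <- minimal_satisfying_profile(rules, "rGly", genome_id = "mock1")
  lines <- write_mock_kofam_tsv(prof, decoy_hits_per_gene = 2L)
  back <- assign_kos(parse_kofam_tsv(lines), "mock1")
  expect_identical(back$kos, prof$kos)

  empty_back <- assign_kos(parse_kofam_tsv(
    write_mock_kofam_tsv(ko_profile("e"))), "e")
  expect_identical(empty_back$kos, character(0))

  # a gene with only sub-threshold hits contributes its best KO via fallback
  lines2 <- write_mock_kofam_tsv(prof, fallback_kos = "K90555")
  back2 <- assign_kos(parse_kofam_tsv(lines2), "mock1")
  expect_identical(back2$kos, sort(c(prof$kos, "K90555")))
})
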