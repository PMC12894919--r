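DECOY_POOL <- sprintf("K90%03d", 0:999)  # disjoint from all real marker KOs

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

variant_ko_union <- function(rules, pathway_id, variant_id) {
  v <- get_variant(rules, pathway_id, variant_id)
  sort(unique(unlist(lapply(v$clauses, function(cl) cl$kos))))
}

#' Minimal KO profile satisfying one pathway variant
#'
#' Builds the smallest profile that satisfies the chosen variant, taking per
#' clause: every KO for `all_of`, the first listed KO for `one_of`, and the
#' first `min_count` KOs for `at_least`.
#'
#' @param rules A `co2fix_ruleset`.
#' @param pathway_id Pathway identifier.
#' @param variant_id Variant identifier; defaults to the pathway's first
#'   variant.
#' @param genome_id Genome id for the profile.
#' @return A [ko_profile()] for which the pathway is called present.
#' @examples
#' minimal_satisfying_profile(builtin_ruleset(), "WL", "WL-I")$kos
#' @export
minimal_satisfying_profile <- function(rules, pathway_id, variant_id = NULL,
                                       genome_id = "synthetic") {
  if (is.null(variant_id)) variant_id <- variant_ids(rules, pathway_id)[1]
  v <- get_variant(rules, pathway_id, variant_id)
  kos <- unlist(lapply(v$clauses, function(cl) {
    switch(cl$quantifier,
           all_of = cl$kos,
           one_of = cl$kos[1],
           at_least = cl$kos[seq_len(cl$min_count)])
  }))
  ko_profile(genome_id, kos)
}

#' Near-miss KO profile for one pathway variant
#'
#' Builds a profile one KO short of satisfying the chosen variant: starting
#' from [minimal_satisfying_profile()], one KO is removed from a randomly
#' chosen clause (for `all_of`, a random member; for `one_of`, its single
#' included member; for `at_least`, one included member, so the present
#' count falls to `min_count - 1`). Since the minimal profile satisfies no
#' other variant, the pathway as a whole becomes absent. Uses the current
#' RNG state; seed beforehand for reproducibility.
#'
#' @inheritParams minimal_satisfying_profile
#' @return A [ko_profile()] for which the pathway is called absent.
#' @export
near_miss_profile <- function(rules, pathway_id, variant_id = NULL,
                              genome_id = "synthetic") {
  if (is.null(variant_id)) variant_id <- variant_ids(rules, pathway_id)[1]
  v <- get_variant(rules, pathway_id, variant_id)
  base <- minimal_satisfying_profile(rules, pathway_id, variant_id, genome_id)
  ci <- if (length(v$clauses) > 1L) sample(length(v$clauses), 1L) else 1L
  cl <- v$clauses[[ci]]
  included <- switch(cl$quantifier,
                     all_of = cl$kos,
                     one_of = cl$kos[1],
                     at_least = cl$kos[seq_len(cl$min_count)])
  drop <- if (length(included) > 1L) sample(included, 1L) else included
  out <- ko_profile(genome_id, setdiff(base$kos, drop))
  stopifnot(!predict_pathways(out, rules)$calls[[pathway_id]])
  out
}

clause_detection_prob <- function(clause, dropout_p) {
  n <- length(clause$kos)
  switch(clause$quantifier,
         all_of = (1 - dropout_p)^n,
         one_of = 1 - dropout_p^n,
         at_least = stats::pbinom(clause$min_count - 1L, n, 1 - dropout_p,
                                  lower.tail = FALSE))
}

#' Closed-form detection probability of a variant under KO dropout
#'
#' For a genome carrying the full KO complement of one variant, with each
#' marker KO independently deleted with probability `dropout_p`, the
#' probability that the variant is still satisfied is the product over its
#' clauses of: `(1-p)^m` for an `all_of` clause over m KOs, `1 - p^r` for a
#' `one_of` clause over r alternatives, and `P[Binomial(n, 1-p) >= k]` for
#' an `at_least(k of n)` clause. Clauses of one variant range over disjoint
#' KO sets, so the product is exact.
#'
#' @param rules A `co2fix_ruleset`.
#' @param pathway_id,variant_id Which variant.
#' @param dropout_p Per-KO deletion probability in `[0, 1)`.
#' @return Probability in `[0, 1]`.
#' @export
variant_detection_prob <- function(rules, pathway_id, variant_id, dropout_p) {
  v <- get_variant(rules, pathway_id, variant_id)
  prod(vapply(v$clauses, clause_detection_prob, numeric(1),
              dropout_p = dropout_p))
}

sanitize_variant <- function(variant_id) gsub("/", "", variant_id, fixed = TRUE)

#' Generate a seeded synthetic genome corpus with known pathway truth
#'
#' Emulates a curated benchmark corpus: for each pathway, positive genomes
#' built from the full KO complement of a variant plus `background_k` decoy
#' KOs (drawn from `K90000`-`K90999`, a pool disjoint from every real marker
#' KO), with each marker KO then independently deleted with probability
#' `dropout_p`; plus `negatives_per_pathway` near-miss genomes (a satisfying
#' profile with one critical KO removed); plus optional multi-pathway
#' genomes formed by unioning two pathways' profiles. Truth labels record
#' the intended pathway composition before dropout, so dropout degrades
#' recall but never precision.
#'
#' @param rules A `co2fix_ruleset`.
#' @param n_per_pathway Positive genomes per pathway (per variant when
#'   `variant_choice = "all"`).
#' @param variant_choice `"first"` (first variant only), `"random"` (variant
#'   sampled per replicate), or `"all"` (every variant exercised).
#' @param dropout_p Independent per-marker-KO deletion probability in
#'   `[0, 1)`.
#' @param background_k Decoy KOs added to every positive genome.
#' @param negatives_per_pathway Near-miss genomes per pathway.
#' @param multi_pairs List of length-2 character vectors of pathway ids;
#'   each generates genomes carrying both pathways. The default mirrors the
#'   co-occurrence observed among chemolithoautotroph genomes: CBB together
#'   with WL, and WL together with rGly.
#' @param n_multi Integer vector (recycled over `multi_pairs`): genomes per
#'   pair; default 3 CBB+WL and 2 WL+rGly.
#' @param seed Integer seed; the corpus is a pure function of the arguments.
#' @return An object of class `co2fix_corpus`: list with `profiles` (list of
#'   [ko_profile()]), `truth` (binary matrix, genomes x pathways),
#'   `meta` (data frame: genome_id, role, pathway, variant) and `config`.
#' @export
generate_corpus <- function(rules = builtin_ruleset(),
                            n_per_pathway = 50L,
                            variant_choice = c("all", "first", "random"),
                            dropout_p = 0,
                            background_k = 20L,
                            negatives_per_pathway = 10L,
                            multi_pairs = list(c("CBB", "WL"),
                                               c("WL", "rGly")),
                            n_multi = c(3L, 2L),
                            seed = 1L) {
  variant_choice <- match.arg(variant_choice)
  stopifnot(n_per_pathway >= 1L, dropout_p >= 0, dropout_p < 1,
            background_k >= 0L, negatives_per_pathway >= 0L)
  pids <- pathway_ids(rules)
  with_seed(seed, {
    profiles <- list()
    meta <- list()
    add_genome <- function(gid, kos, role, pathway, variant_tag) {
      profiles[[length(profiles) + 1L]] <<- ko_profile(gid, kos)
      meta[[length(meta) + 1L]] <<- data.frame(
        genome_id = gid, role = role, pathway = pathway,
        variant = variant_tag, stringsAsFactors = FALSE)
    }
    make_positive <- function(marker_kos) {
      decoys <- if (background_k > 0L)
        sample(DECOY_POOL, background_k) else character(0)
      kept <- marker_kos[stats::runif(length(marker_kos)) >= dropout_p]
      c(kept, decoys)
    }
    for (p in pids) {
      vids <- variant_ids(rules, p)
      pos_variants <- switch(variant_choice,
                             first = list(vids[1]),
                             all = as.list(vids),
                             random = NULL)
      if (variant_choice == "random") {
        for (i in seq_len(n_per_pathway)) {
          v <- sample(vids, 1L)
          gid <- sprintf("%s.%s.pos%03d", p, sanitize_variant(v), i)
          add_genome(gid, make_positive(variant_ko_union(rules, p, v)),
                     "positive", p, sanitize_variant(v))
        }
      } else {
        for (v in pos_variants) {
          full <- variant_ko_union(rules, p, v)
          for (i in seq_len(n_per_pathway)) {
            gid <- sprintf("%s.%s.pos%03d", p, sanitize_variant(v), i)
            add_genome(gid, make_positive(full), "positive", p,
                       sanitize_variant(v))
          }
        }
      }
      if (negatives_per_pathway > 0L) {
        for (i in seq_len(negatives_per_pathway)) {
          v <- if (variant_choice == "first") vids[1] else
            vids[1L + (i - 1L) %% length(vids)]
          gid <- sprintf("%s.%s.neg%03d", p, sanitize_variant(v), i)
          nm <- near_miss_profile(rules, p, v, gid)
          add_genome(gid, nm$kos, "near_miss", p, sanitize_variant(v))
        }
      }
    }
    if (length(multi_pairs)) {
      n_multi <- rep_len(as.integer(n_multi), length(multi_pairs))
      for (k in seq_along(multi_pairs)) {
        pair <- multi_pairs[[k]]
        stopifnot(length(pair) == 2L, all(pair %in% pids))
        v1 <- variant_ids(rules, pair[1])[1]
        v2 <- variant_ids(rules, pair[2])[1]
        full <- union(variant_ko_union(rules, pair[1], v1),
                      variant_ko_union(rules, pair[2], v2))
        for (i in seq_len(n_multi[k])) {
          gid <- sprintf("%s+%s.multi%03d", pair[1], pair[2], i)
          add_genome(gid, make_positive(full), "multi",
                     paste(pair, collapse = "+"), NA_character_)
        }
      }
    }
    meta <- do.call(rbind, meta)
    truth <- matrix(0L, nrow = nrow(meta), ncol = length(pids),
                    dimnames = list(meta$genome_id, pids))
    for (i in seq_len(nrow(meta))) {
      if (meta$role[i] %in% c("positive", "multi")) {
        truth[i, strsplit(meta$pathway[i], "+", fixed = TRUE)[[1]]] <- 1L
      }
    }
    structure(list(profiles = profiles, truth = truth, meta = meta,
                   config = list(n_per_pathway = n_per_pathway,
                                 variant_choice = variant_choice,
                                 dropout_p = dropout_p,
                                 background_k = background_k,
                                 negatives_per_pathway = negatives_per_pathway,
                                 n_multi = n_multi,
                                 seed = seed,
                                 ruleset_version = rules$version)),
              class = "co2fix_corpus")
  })
}

#' @export
print.co2fix_corpus <- function(x, ...) {
  cat("Synthetic KO corpus: ", length(x$profiles), " genomes (",
      sum(x$meta$role == "positive"), " positive, ",
      sum(x$meta$role == "near_miss"), " near-miss, ",
      sum(x$meta$role == "multi"), " multi-pathway)\n", sep = "")
  cat("  dropout_p = ", x$config$dropout_p, ", background_k = ",
      x$config$background_k, ", seed = ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic corpus to disk
#'
#' Materializes per-genome KO-list files (`<genome_id>.ko`, so the file stem
#' recovers the genome id), the truth
#' matrix (`truth.tsv`, predictor TSV dialect) and a JSON manifest
#' (`manifest.json`) recording the generating configuration and seed.
#'
#' @param corpus A `co2fix_corpus`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_corpus <- function(corpus, dir) {
  stopifnot(inherits(corpus, "co2fix_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (pr in corpus$profiles) {
    write_ko_list(pr, file.path(dir, paste0(pr$genome_id, ".ko")))
  }
  write_matrix(corpus$truth, file.path(dir, "truth.tsv"))
  manifest <- c(corpus$config,
                list(n_genomes = length(corpus$profiles)))
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           pretty = TRUE)),
             file.path(dir, "manifest.json"), useBytes = TRUE)
  invisible(dir)
}

#' Write a mock KofamScan detail-TSV for a KO profile
#'
#' Emits one gene per KO of the profile with a significant (starred) hit
#' whose score exceeds a synthetic adaptive threshold, optionally padded
#' with non-significant decoy hits on the same genes (which the assignment
#' rule ignores), so that parsing the file and applying [assign_kos()]
#' recovers exactly `profile$kos`. Genes listed in `fallback_kos` are added
#' with only non-significant hits whose top-scoring KO is the given one;
#' each such gene contributes exactly that KO through the top-hit fallback.
#' Scores are drawn from the current RNG state.
#'
#' @param profile A [ko_profile()].
#' @param path Optional output file path.
#' @param decoy_hits_per_gene Extra non-significant hits added per gene.
#' @param fallback_kos KOs to add via genes with no significant hit.
#' @return Character vector of TSV lines (invisibly when `path` is given).
#' @export
write_mock_kofam_tsv <- function(profile, path = NULL,
                                 decoy_hits_per_gene = 0L,
                                 fallback_kos = character(0)) {
  stopifnot(inherits(profile, "ko_profile"))
  lines <- "#\tgene name\tKO\tthrshld\tscore\tE-value\tKO definition"
  gene_n <- 0L
  emit <- function(star, gene, ko, thr, score, evalue, def) {
    sprintf("%s\t%s\t%s\t%.2f\t%.2f\t%.2g\t%s",
            star, gene, ko, thr, score, evalue, def)
  }
  for (ko in profile$kos) {
    gene_n <- gene_n + 1L
    gene <- sprintf("%s_g%04d", profile$genome_id, gene_n)
    thr <- 100
    score <- thr + stats::runif(1, 50, 200)
    lines <- c(lines, emit("*", gene, ko, thr, score, 1e-50, "marker enzyme"))
    if (decoy_hits_per_gene > 0L) {
      decoys <- sample(DECOY_POOL, decoy_hits_per_gene)
      for (d in decoys) {
        lines <- c(lines, emit(" ", gene, d, thr,
                               stats::runif(1, 10, thr - 10), 1e-3,
                               "weak off-target hit"))
      }
    }
  }
  for (ko in fallback_kos) {
    gene_n <- gene_n + 1L
    gene <- sprintf("%s_g%04d", profile$genome_id, gene_n)
    best <- stats::runif(1, 50, 90)
    lines <- c(lines,
               emit(" ", gene, ko, 100, best, 1e-5, "sub-threshold best hit"),
               emit(" ", gene, sample(DECOY_POOL, 1L), 100,
                    best - stats::runif(1, 5, 20), 1e-2, "weaker hit"))
  }
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}
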