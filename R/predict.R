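#' Evaluate one clause against a KO set
#'
#' The three quantifiers are all monotone in the profile: `one_of` is true
#' when at least one listed KO is present, `all_of` when every listed KO is
#' present, and `at_least` when at least `min_count` of the listed KOs are
#' present.
#'
#' @param clause A clause (list with `quantifier`, `kos`, and `min_count`
#'   for `at_least`).
#' @param kos Character vector of KO ids present in the genome.
#' @return Logical scalar.
#' @export
eval_clause <- function(clause, kos) {
  hit <- sum(clause$kos %in% kos)
  switch(clause$quantifier,
         one_of = hit >= 1L,
         all_of = hit == length(clause$kos),
         at_least = hit >= clause$min_count,
         stop("unknown quantifier '", clause$quantifier, "'", call. = FALSE))
}

#' Evaluate one pathway variant against a KO set
#'
#' A variant is satisfied iff every one of its clauses is satisfied
#' (conjunction).
#'
#' @param variant A variant (list with `variant_id` and `clauses`).
#' @param kos Character vector of KO ids present in the genome.
#' @return Logical scalar.
#' @export
eval_variant <- function(variant, kos) {
  for (cl in variant$clauses) {
    if (!eval_clause(cl, kos)) return(FALSE)
  }
  TRUE
}

#' Predict CO2 fixation pathways for one genome
#'
#' Evaluates every pathway of the rule set against a genome's KO profile.
#' A pathway is called present iff at least one of its variants is satisfied
#' (disjunction over variants, conjunction over each variant's clauses).
#' KOs in the profile that appear in no rule are ignored by the calls but
#' counted in the diagnostics.
#'
#' @param profile A [ko_profile()], or a character vector of KO ids.
#' @param rules A `co2fix_ruleset`; defaults to [builtin_ruleset()].
#' @return An object of class `pathway_prediction` with fields:
#'   \describe{
#'     \item{genome_id}{the genome id}
#'     \item{calls}{named logical vector, one entry per pathway in rule-set
#'       order; `TRUE` = present}
#'     \item{evidence}{named list: pathway id -> character vector of
#'       satisfied variant ids in rule order (empty when absent)}
#'     \item{matched_kos}{named list: pathway id -> KOs of the profile that
#'       occur in any clause of that pathway}
#'     \item{n_unmatched_kos}{count of profile KOs appearing in no rule}
#'   }
#'
#'   The per-variant evidence is an extension over a bare presence/absence
#'   call: it reports which mechanistic type (e.g. rTCA-I vs rTCA-II)
#'   supported the call.
#' @examples
#' p <- predict_pathways(ko_profile("g1", c("K00855", "K01601", "K01783")))
#' p$calls[["CBB"]]
#' @export
predict_pathways <- function(profile, rules = builtin_ruleset()) {
  predict_one(profile, rules, pathway_unions(rules))
}

pathway_unions <- function(rules) {
  pids <- pathway_ids(rules)
  u <- lapply(pids, function(p) marker_ko_union(rules, p))
  names(u) <- pids
  u
}

predict_one <- function(profile, rules, unions) {
  if (is.character(profile)) profile <- ko_profile("genome", profile)
  stopifnot(inherits(profile, "ko_profile"))
  kos <- profile$kos
  pids <- pathway_ids(rules)
  calls <- logical(length(pids))
  names(calls) <- pids
  evidence <- vector("list", length(pids))
  names(evidence) <- pids
  matched <- vector("list", length(pids))
  names(matched) <- pids
  for (i in seq_along(rules$pathways)) {
    pw <- rules$pathways[[i]]
    sat <- character(0)
    for (v in pw$variants) {
      if (eval_variant(v, kos)) sat <- c(sat, v$variant_id)
    }
    calls[i] <- length(sat) > 0L
    evidence[[i]] <- sat
    matched[[i]] <- intersect(kos, unions[[pw$pathway_id]])
  }
  structure(list(genome_id = profile$genome_id,
                 calls = calls,
                 evidence = evidence,
                 matched_kos = matched,
                 n_unmatched_kos =
                   length(setdiff(kos, unique(unlist(unions))))),
            class = "pathway_prediction")
}

#' @export
print.pathway_prediction <- function(x, ...) {
  cat("Pathway prediction for genome '", x$genome_id, "'\n", sep = "")
  for (p in names(x$calls)) {
    cat(sprintf("  %-8s %s", p, if (x$calls[[p]]) "present" else "absent "))
    if (x$calls[[p]]) {
      cat("  [", paste(x$evidence[[p]], collapse = ", "), "]", sep = "")
    }
    cat("\n")
  }
  cat("  (", x$n_unmatched_kos, " profile KOs outside the rule set)\n",
      sep = "")
  invisible(x)
}

#' Predict pathways for a batch of genomes
#'
#' Runs [predict_pathways()] on each profile and additionally summarizes the
#' calls into a binary genome x pathway presence/absence matrix (rows =
#' genomes in input order, columns = pathways in rule-set order, entries
#' 0/1). Genomes may carry several pathways; rows are not constrained to a
#' single 1.
#'
#' @param profiles List of [ko_profile()] objects with unique genome ids.
#' @param rules A `co2fix_ruleset`.
#' @return List with `predictions` (list of `pathway_prediction`) and
#'   `matrix` (integer matrix with genome ids as rownames and pathway ids as
#'   colnames).
#' @export
predict_batch <- function(profiles, rules = builtin_ruleset()) {
  stopifnot(is.list(profiles))
  ids <- vapply(profiles, function(p) p$genome_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate genome_id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  unions <- pathway_unions(rules)
  preds <- lapply(profiles, predict_one, rules = rules, unions = unions)
  pids <- pathway_ids(rules)
  mat <- matrix(0L, nrow = length(preds), ncol = length(pids),
                dimnames = list(ids, pids))
  for (i in seq_along(preds)) {
    mat[i, ] <- as.integer(preds[[i]]$calls)
  }
  list(predictions = preds, matrix = mat)
}

#' Write a binary presence/absence matrix as TSV
#'
#' Header `genome_id` followed by the pathway columns; one 0/1 row per
#' genome.
#'
#' @param mat Integer matrix (genomes x pathways) with dimnames, as produced
#'   by [predict_batch()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(mat, path) {
  df <- data.frame(genome_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
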