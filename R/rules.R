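#' @importFrom stats pbinom runif setNames
#' @importFrom utils write.table
NULL

KO_PATTERN <- "^K[0-9]{5}$"
QUANTIFIERS <- c("one_of", "all_of", "at_least")

is_ko_id <- function(x) {
  is.character(x) & !is.na(x) & grepl(KO_PATTERN, x)
}

clause <- function(quantifier, kos, min_count = NULL) {
  cl <- list(quantifier = quantifier, kos = as.character(kos))
  if (identical(quantifier, "at_least")) cl$min_count <- as.integer(min_count)
  cl
}

variant <- function(variant_id, clauses) {
  list(variant_id = variant_id, clauses = clauses)
}

pathway_def <- function(pathway_id, display_name, variants) {
  list(pathway_id = pathway_id, display_name = display_name,
       variants = variants)
}

#' Built-in marker rule set for the seven CO2 fixation pathways
#'
#' Returns the curated marker-KO rule set shipped with the package, covering
#' the Calvin-Benson-Bassham cycle (CBB), the reductive TCA cycle (rTCA,
#' types I and II), the Wood-Ljungdahl pathway (WL, bacterial and archaeal
#' forms), the 3-hydroxypropionate bicycle (3HP), the
#' 3-hydroxypropionate/4-hydroxybutyrate cycle (3HP/4HB, two enzyme-set
#' variants), the dicarboxylate/4-hydroxybutyrate cycle (DC/4HB), and the
#' reductive glycine pathway (rGly).
#'
#' A pathway is called present when at least one of its variants is
#' satisfied; a variant is satisfied when every one of its clauses is.
#' Clauses use three quantifiers over KO identifiers: `all_of` (multi-subunit
#' complexes, every KO required), `one_of` (alternative enzymes catalysing
#' the same reaction, any KO suffices), and `at_least` (a minimum number of
#' subunits, used for the glycine cleavage system, 3 of 4, and the
#' seven-subunit glycine reductase complex, 5 of 7).
#'
#' @return An object of class `co2fix_ruleset`.
#' @seealso [load_ruleset()], [serialize_ruleset()], [marker_ko_union()]
#' @examples
#' rules <- builtin_ruleset()
#' pathway_ids(rules)
#' marker_ko_union(rules, "CBB")
#' @export
builtin_ruleset <- function() {
  pathways <- list(
    pathway_def("CBB", "CBB", list(
      variant("CBB", list(
        clause("all_of", "K00855"),            # phosphoribulokinase
        clause("all_of", "K01601"),            # RubisCO large chain
        clause("all_of", "K01783")))           # ribulose-phosphate 3-epimerase
    )),
    pathway_def("rTCA", "rTCA", list(
      variant("rTCA-I", list(
        clause("all_of", c("K15230", "K15231")))),   # ATP-citrate lyase
      variant("rTCA-II", list(
        clause("all_of", c("K15233", "K15232")),     # citryl-CoA synthetase
        clause("all_of", "K15234")))                 # citryl-CoA lyase
    )),
    pathway_def("WL", "WL", list(
      variant("WL-I", list(
        clause("all_of", "K00198"),                  # anaerobic CODH catalytic subunit
        clause("all_of", "K14138"))),                # acetyl-CoA synthase
      variant("WL-II", list(
        clause("all_of", c("K00192", "K00195")),     # CODH/ACS alpha + epsilon
        clause("all_of", c("K00193", "K00194", "K00197"))))  # beta + delta + gamma
    )),
    pathway_def("3HP", "3HP", list(
      variant("3HP", list(
        clause("all_of", "K14468"),                  # malonyl-CoA reductase / 3-HP dehydrogenase
        clause("all_of", c("K14471", "K14472"))))    # succinyl-CoA:L-malate CoA-transferase
    )),
    pathway_def("3HP4HB", "3HP/4HB", list(
      variant("3HP/4HB-I", list(
        clause("all_of", "K15017"),                  # malonyl-CoA reductase
        clause("all_of", "K15039"),                  # 3-HP dehydrogenase (NADP+)
        clause("all_of", "K14534"))),                # 4-hydroxybutanoyl-CoA dehydratase
      variant("3HP/4HB-II", list(
        clause("all_of", c("K18603", "K18604", "K18605")),  # acetyl-CoA carboxylase
        clause("all_of", "K18602"),                  # malonic semialdehyde reductase
        clause("all_of", "K14534")))
    )),
    pathway_def("DC4HB", "DC/4HB", list(
      variant("DC4HB", list(
        clause("all_of", "K01595"),                  # PEP carboxylase
        clause("one_of", c("K01676", "K01677", "K01678")),  # fumarate hydratase
        clause("one_of", c("K18861", "K14467")),     # 4-hydroxybutyrate-CoA ligase
        clause("all_of", "K14534")))
    )),
    pathway_def("rGly", "rGly", list(
      variant("rGly", list(
        clause("at_least", c("K00283", "K00282", "K02437", "K00605"),
               min_count = 3),                       # glycine cleavage system
        clause("at_least", c("K10671", "K10672", "K00384", "K21577",
                             "K21576", "K03671", "K10670"),
               min_count = 5)))                      # glycine reductase complex
    ))
  )
  rs <- structure(list(version = "1.0", pathways = pathways),
                  class = "co2fix_ruleset")
  validate_ruleset(rs, quiet = TRUE)
  rs
}

#' Pathway identifiers of a rule set
#'
#' @param rules A `co2fix_ruleset`.
#' @return Character vector of pathway ids in rule-set order.
#' @export
pathway_ids <- function(rules) {
  vapply(rules$pathways, function(p) p$pathway_id, character(1))
}

#' Variant identifiers of one pathway
#'
#' @param rules A `co2fix_ruleset`.
#' @param pathway_id Pathway identifier.
#' @return Character vector of variant ids in rule order.
#' @export
variant_ids <- function(rules, pathway_id) {
  pw <- get_pathway(rules, pathway_id)
  vapply(pw$variants, function(v) v$variant_id, character(1))
}

get_pathway <- function(rules, pathway_id) {
  ids <- pathway_ids(rules)
  i <- match(pathway_id, ids)
  if (is.na(i)) {
    stop("unknown pathway_id '", pathway_id, "'; valid ids: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  rules$pathways[[i]]
}

get_variant <- function(rules, pathway_id, variant_id) {
  pw <- get_pathway(rules, pathway_id)
  ids <- vapply(pw$variants, function(v) v$variant_id, character(1))
  i <- match(variant_id, ids)
  if (is.na(i)) {
    stop("unknown variant '", variant_id, "' for pathway '", pathway_id,
         "'; valid variants: ", paste(ids, collapse = ", "), call. = FALSE)
  }
  pw$variants[[i]]
}

#' Distinct marker KOs of a pathway
#'
#' Collects the set of distinct KO identifiers appearing in any clause of any
#' variant of the given pathway. KOs used by several variants (for example
#' the 4-hydroxybutanoyl-CoA dehydratase KO shared by both 3HP/4HB variants)
#' are counted once.
#'
#' @param rules A `co2fix_ruleset`.
#' @param pathway_id Pathway identifier; must exist in `rules`.
#' @return Sorted character vector of distinct KO ids.
#' @examples
#' length(marker_ko_union(builtin_ruleset(), "rGly"))  # 11
#' @export
marker_ko_union <- function(rules, pathway_id) {
  pw <- get_pathway(rules, pathway_id)
  kos <- unlist(lapply(pw$variants, function(v)
    unlist(lapply(v$clauses, function(cl) cl$kos))))
  sort(unique(kos))
}

#' Distinct marker KOs across the whole rule set
#'
#' @param rules A `co2fix_ruleset`.
#' @return Sorted character vector of all distinct marker KO ids.
#' @export
all_marker_kos <- function(rules) {
  sort(unique(unlist(lapply(pathway_ids(rules), function(p)
    marker_ko_union(rules, p)))))
}

fail_at <- function(path, msg) {
  stop("invalid rule set at ", path, ": ", msg, call. = FALSE)
}

#' Validate a rule set
#'
#' Checks the structural invariants of a rule set: well-formed KO ids
#' (`K` + five digits), valid quantifiers, `min_count` present exactly for
#' `at_least` clauses and within `[1, length(kos)]`, non-empty duplicate-free
#' KO lists, and unique pathway ids. KOs shared between pathways are legal
#' (they do occur among the built-in markers) and are reported, not rejected.
#'
#' @param rules A `co2fix_ruleset` (or bare list with the same structure).
#' @param quiet Suppress the shared-KO message.
#' @return Invisibly, a list with `n_pathways`, `ko_census` (named integer
#'   vector of distinct-KO counts per pathway) and `shared_kos` (named list:
#'   KO id -> pathway ids using it, for KOs in more than one pathway).
#' @export
validate_ruleset <- function(rules, quiet = FALSE) {
  if (!is.list(rules)) fail_at("$", "not a list")
  if (!is.character(rules$version) || length(rules$version) != 1L)
    fail_at("version", "must be a single string")
  if (!is.list(rules$pathways) || length(rules$pathways) < 1L)
    fail_at("pathways", "must be a non-empty list")
  seen_ids <- character(0)
  for (i in seq_along(rules$pathways)) {
    pw <- rules$pathways[[i]]
    ppath <- sprintf("pathways[%d]", i)
    if (!is.character(pw$pathway_id) || length(pw$pathway_id) != 1L)
      fail_at(paste0(ppath, ".pathway_id"), "must be a single string")
    if (pw$pathway_id %in% seen_ids)
      fail_at(paste0(ppath, ".pathway_id"),
              paste0("duplicate pathway_id '", pw$pathway_id, "'"))
    seen_ids <- c(seen_ids, pw$pathway_id)
    if (!is.character(pw$display_name) || length(pw$display_name) != 1L)
      fail_at(paste0(ppath, ".display_name"), "must be a single string")
    if (!is.list(pw$variants) || length(pw$variants) < 1L)
      fail_at(paste0(ppath, ".variants"), "must be a non-empty list")
    for (j in seq_along(pw$variants)) {
      v <- pw$variants[[j]]
      vpath <- sprintf("%s.variants[%d]", ppath, j)
      if (!is.character(v$variant_id) || length(v$variant_id) != 1L)
        fail_at(paste0(vpath, ".variant_id"), "must be a single string")
      if (!is.list(v$clauses) || length(v$clauses) < 1L)
        fail_at(paste0(vpath, ".clauses"), "must be a non-empty list")
      for (k in seq_along(v$clauses)) {
        cl <- v$clauses[[k]]
        cpath <- sprintf("%s.clauses[%d]", vpath, k)
        if (!is.character(cl$quantifier) || length(cl$quantifier) != 1L ||
            !cl$quantifier %in% QUANTIFIERS)
          fail_at(paste0(cpath, ".quantifier"),
                  paste0("must be one of ", paste(QUANTIFIERS, collapse = ", ")))
        if (!is.character(cl$kos) || length(cl$kos) < 1L)
          fail_at(paste0(cpath, ".kos"), "must be a non-empty list of KO ids")
        bad <- cl$kos[!is_ko_id(cl$kos)]
        if (length(bad))
          fail_at(paste0(cpath, ".kos"),
                  paste0("malformed KO id(s): ", paste(bad, collapse = ", ")))
        if (anyDuplicated(cl$kos))
          fail_at(paste0(cpath, ".kos"), "duplicate KO ids within a clause")
        if (identical(cl$quantifier, "at_least")) {
          mc <- cl$min_count
          if (is.null(mc) || length(mc) != 1L || is.na(mc) ||
              !is.numeric(mc) || mc != as.integer(mc))
            fail_at(paste0(cpath, ".min_count"),
                    "at_least clauses require an integer min_count")
          if (mc < 1L || mc > length(cl$kos))
            fail_at(paste0(cpath, ".min_count"),
                    sprintf("min_count %d out of range [1, %d]",
                            as.integer(mc), length(cl$kos)))
        } else if (!is.null(cl$min_count)) {
          fail_at(paste0(cpath, ".min_count"),
                  paste0("min_count is only valid for at_least, not ",
                         cl$quantifier))
        }
      }
    }
  }
  census <- setNames(
    vapply(seen_ids, function(p) length(marker_ko_union(rules, p)), integer(1)),
    seen_ids)
  ko_by_pathway <- lapply(seen_ids, function(p) marker_ko_union(rules, p))
  names(ko_by_pathway) <- seen_ids
  all_kos <- unlist(ko_by_pathway)
  shared <- names(which(table(all_kos) > 1L))
  shared_kos <- lapply(shared, function(ko)
    seen_ids[vapply(ko_by_pathway, function(x) ko %in% x, logical(1))])
  names(shared_kos) <- shared
  if (!quiet && length(shared_kos)) {
    for (ko in names(shared_kos)) {
      message("note: KO ", ko, " is shared by pathways ",
              paste(shared_kos[[ko]], collapse = ", "))
    }
  }
  invisible(list(n_pathways = length(seen_ids), ko_census = census,
                 shared_kos = shared_kos))
}

ruleset_to_plain <- function(rules) {
  list(
    version = jsonlite::unbox(rules$version),
    pathways = lapply(rules$pathways, function(pw) {
      list(
        pathway_id = jsonlite::unbox(pw$pathway_id),
        display_name = jsonlite::unbox(pw$display_name),
        variants = lapply(pw$variants, function(v) {
          list(
            variant_id = jsonlite::unbox(v$variant_id),
            clauses = lapply(v$clauses, function(cl) {
              out <- list(quantifier = jsonlite::unbox(cl$quantifier),
                          kos = cl$kos)
              if (identical(cl$quantifier, "at_least"))
                out$min_count <- jsonlite::unbox(cl$min_count)
              out
            }))
        }))
    }))
}

#' Serialize a rule set to canonical JSON
#'
#' Emits the canonical rule JSON dialect: a top-level object with `version`
#' and `pathways`, each pathway carrying `pathway_id`, `display_name` and
#' `variants`, each variant `variant_id` and `clauses`, each clause
#' `quantifier`, `kos` and (for `at_least` only) `min_count`. Key order and
#' list order are stable, so serializing the same rule set twice yields
#' byte-identical output.
#'
#' @param rules A valid `co2fix_ruleset`.
#' @param path Optional file path; when given the JSON is written there
#'   (UTF-8, newline-terminated) and returned invisibly.
#' @return The JSON text as a single string.
#' @export
serialize_ruleset <- function(rules, path = NULL) {
  validate_ruleset(rules, quiet = TRUE)
  txt <- jsonlite::toJSON(ruleset_to_plain(rules), pretty = TRUE)
  txt <- as.character(txt)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

#' Load a rule set from JSON
#'
#' Reads and validates a rule-definition JSON document (see
#' [serialize_ruleset()] for the dialect). Schema violations -- missing
#' fields, unknown quantifiers, `min_count` out of range, malformed KO ids,
#' duplicate pathway ids -- are rejected with an error naming the offending
#' path in the document.
#'
#' @param source A file path, or a single string containing JSON text.
#' @return A validated `co2fix_ruleset`.
#' @examples
#' rules <- load_ruleset(serialize_ruleset(builtin_ruleset()))
#' @export
load_ruleset <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  txt <- if (file.exists(source)) {
    paste(readLines(source, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  } else {
    source
  }
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e)
                    stop("invalid JSON: ", conditionMessage(e), call. = FALSE))
  if (!is.list(doc)) fail_at("$", "top level must be an object")
  rs <- structure(
    list(
      version = if (is.null(doc$version)) NULL else as.character(doc$version),
      pathways = lapply(seq_along(doc$pathways), function(i) {
        pw <- doc$pathways[[i]]
        if (!is.list(pw)) fail_at(sprintf("pathways[%d]", i), "must be an object")
        list(
          pathway_id = if (is.null(pw$pathway_id)) NULL else
            as.character(pw$pathway_id),
          display_name = if (is.null(pw$display_name)) NULL else
            as.character(pw$display_name),
          variants = lapply(seq_along(pw$variants), function(j) {
            v <- pw$variants[[j]]
            if (!is.list(v))
              fail_at(sprintf("pathways[%d].variants[%d]", i, j),
                      "must be an object")
            list(
              variant_id = if (is.null(v$variant_id)) NULL else
                as.character(v$variant_id),
              clauses = lapply(seq_along(v$clauses), function(k) {
                cl <- v$clauses[[k]]
                if (!is.list(cl))
                  fail_at(sprintf("pathways[%d].variants[%d].clauses[%d]",
                                  i, j, k), "must be an object")
                out <- list(
                  quantifier = if (is.null(cl$quantifier)) NULL else
                    as.character(cl$quantifier),
                  kos = as.character(unlist(cl$kos)))
                if (!is.null(cl$min_count))
                  out$min_count <- as.integer(cl$min_count)
                out
              }))
          }))
      })),
    class = "co2fix_ruleset")
  validate_ruleset(rs, quiet = TRUE)
  rs
}

#' @export
print.co2fix_ruleset <- function(x, ...) {
  info <- validate_ruleset(x, quiet = TRUE)
  cat("CO2 fixation pathway rule set (version ", x$version, ")\n", sep = "")
  for (pw in x$pathways) {
    nvar <- length(pw$variants)
    cat(sprintf("  %-8s %-8s %d variant%s, %d marker KOs\n",
                pw$pathway_id, pw$display_name, nvar,
                if (nvar == 1) "" else "s",
                info$ko_census[[pw$pathway_id]]))
  }
  if (length(info$shared_kos)) {
    cat("  shared KOs:",
        paste(sprintf("%s (%s)", names(info$shared_kos),
                      vapply(info$shared_kos, paste, "", collapse = "+")),
              collapse = ", "), "\n")
  }
  invisible(x)
}
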