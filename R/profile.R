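#' Construct a KO profile
#'
#' A KO profile is the set of KEGG Orthology identifiers assigned to one
#' genome's protein complement. Profiles carry presence/absence only:
#' duplicates collapse and copy number is discarded, since the pathway rules
#' never use multiplicity.
#'
#' @param genome_id Genome identifier (single string).
#' @param kos Character vector of KO ids (`K` + five digits).
#' @return An object of class `ko_profile` with fields `genome_id` and
#'   `kos` (sorted, unique).
#' @export
ko_profile <- function(genome_id, kos = character(0)) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  kos <- as.character(kos)
  bad <- kos[!is_ko_id(kos)]
  if (length(bad)) {
    stop("malformed KO id(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  structure(list(genome_id = genome_id, kos = sort(unique(kos))),
            class = "ko_profile")
}

#' @export
print.ko_profile <- function(x, ...) {
  cat("KO profile for genome '", x$genome_id, "': ", length(x$kos),
      " KOs\n", sep = "")
  if (length(x$kos)) {
    shown <- utils::head(x$kos, 10L)
    cat("  ", paste(shown, collapse = " "),
        if (length(x$kos) > 10L) " ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Read a plain-text KO list
#'
#' Reads a KO list file: one KO identifier per line, `#` lines ignored,
#' blank lines skipped. Tokens that do not match the `K#####` pattern are
#' skipped with a warning naming the line number; duplicates collapse.
#'
#' @param path File path, or a character vector of lines (for in-memory use).
#' @param genome_id Genome id for the resulting profile; defaults to the file
#'   stem when `path` is a file.
#' @return A [ko_profile()].
#' @export
read_ko_list <- function(path, genome_id = NULL) {
  if (length(path) == 1L && file.exists(path)) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    if (is.null(genome_id))
      genome_id <- sub("\\.[^.]*$", "", basename(path))
  } else {
    lines <- as.character(path)
    if (is.null(genome_id)) genome_id <- "genome"
  }
  tokens <- trimws(lines)
  keep <- !startsWith(tokens, "#") & nzchar(tokens)
  idx <- which(keep)
  toks <- tokens[idx]
  ok <- is_ko_id(toks)
  if (any(!ok)) {
    for (i in which(!ok)) {
      warning("line ", idx[i], ": token '", toks[i],
              "' is not a KO id; skipped", call. = FALSE)
    }
  }
  ko_profile(genome_id, toks[ok])
}

#' Write a KO profile as a plain-text KO list
#'
#' One KO per line, sorted lexicographically, newline-terminated UTF-8.
#'
#' @param profile A [ko_profile()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ko_list <- function(profile, path) {
  stopifnot(inherits(profile, "ko_profile"))
  writeLines(profile$kos, path, useBytes = TRUE)
  invisible(path)
}
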