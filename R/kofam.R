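#' Parse KofamScan detail-TSV output
#'
#' Parses the tab-separated "detail" output of KofamScan, in which each data
#' row describes one hit of one protein query against one KOfam HMM profile:
#' a significance mark (`*` when the bit score exceeds the profile's adaptive
#' threshold), the gene (query) id, the KO id, the adaptive threshold (`-`
#' when the profile has none), the bit score, the E-value and the KO
#' definition text. Lines starting with `#` are headers or comments.
#'
#' @param path File path, or a character vector of lines.
#' @return A data frame with one row per hit, in file order, and columns
#'   `significant` (logical), `gene_id`, `ko`, `threshold` (`NA` when the
#'   profile has no adaptive threshold), `score`, `evalue`, `definition`.
#' @examples
#' hits <- parse_kofam_tsv(c(
#'   "# gene name\tKO\tthrshld\tscore\tE-value\tKO definition",
#'   "*\tg1\tK00855\t120.3\t250.1\t1e-50\tphosphoribulokinase"))
#' hits$significant
#' @export
parse_kofam_tsv <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, warn = FALSE, encoding = "UTF-8")
  } else {
    as.character(path)
  }
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  idx <- which(keep)
  n <- length(idx)
  empty <- data.frame(significant = logical(0), gene_id = character(0),
                      ko = character(0), threshold = numeric(0),
                      score = numeric(0), evalue = numeric(0),
                      definition = character(0), stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  parse_num <- function(x, line, what) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) {
      stop("line ", line, ": cannot parse ", what, " '", x, "'",
           call. = FALSE)
    }
    v
  }
  rows <- vector("list", n)
  for (r in seq_len(n)) {
    ln <- idx[r]
    fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 6L) {
      stop("line ", ln, ": expected at least 6 tab-separated fields, got ",
           length(fields), call. = FALSE)
    }
    thr <- trimws(fields[4])
    rows[[r]] <- list(
      significant = identical(trimws(fields[1]), "*"),
      gene_id = fields[2],
      ko = fields[3],
      threshold = if (identical(thr, "-")) NA_real_ else
        parse_num(thr, ln, "threshold"),
      score = parse_num(fields[5], ln, "score"),
      evalue = parse_num(fields[6], ln, "E-value"),
      definition = if (length(fields) >= 7L)
        paste(fields[7:length(fields)], collapse = "\t") else "")
  }
  out <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Assign KOs to a genome from KofamScan hits
#'
#' Implements the adaptive-threshold assignment rule with top-hit fallback.
#' Per gene: every significant hit (bit score above the KOfam profile's
#' adaptive threshold) contributes its KO to the genome's profile. When a
#' gene has hits but none is significant, the KO of its single top-scoring
#' hit is assigned instead (ties broken by lowest E-value, then
#' lexicographically smallest KO id, so the result is deterministic and
#' independent of input row order). The profile is the union over genes.
#'
#' When the input lacks significance marks entirely (no `*` in any row),
#' significance is recomputed as `score > threshold`; hits whose profile has
#' no adaptive threshold are treated as never-significant and so remain
#' fallback-eligible.
#'
#' @param hits Data frame from [parse_kofam_tsv()].
#' @param genome_id Genome id for the resulting profile.
#' @param exclude Optional character vector of KO ids to drop from the final
#'   profile (a mechanical stand-in for manual curation of KOs known to be
#'   unrelated to the pathways of interest).
#' @return A [ko_profile()].
#' @export
assign_kos <- function(hits, genome_id, exclude = NULL) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) return(ko_profile(genome_id))
  sig <- hits$significant
  if (!any(sig)) {
    sig <- !is.na(hits$threshold) & hits$score > hits$threshold
  }
  assigned <- character(0)
  for (g in unique(hits$gene_id)) {
    gi <- hits$gene_id == g
    if (any(sig[gi])) {
      assigned <- c(assigned, hits$ko[gi & sig])
    } else {
      cand <- hits[gi, , drop = FALSE]
      ord <- order(-cand$score, cand$evalue, cand$ko)
      assigned <- c(assigned, cand$ko[ord[1]])
    }
  }
  if (!is.null(exclude)) assigned <- setdiff(assigned, exclude)
  ko_profile(genome_id, assigned)
}

#' Convert a KofamScan detail-TSV to a KO profile in one step
#'
#' @param path KofamScan detail-TSV file path.
#' @param genome_id Genome id; defaults to the file stem.
#' @param exclude Passed to [assign_kos()].
#' @return A [ko_profile()].
#' @export
read_kofam_profile <- function(path, genome_id = NULL, exclude = NULL) {
  if (is.null(genome_id)) genome_id <- sub("\\.[^.]*$", "", basename(path))
  assign_kos(parse_kofam_tsv(path), genome_id, exclude = exclude)
}
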