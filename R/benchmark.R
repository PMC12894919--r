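#' Read a binary genome x pathway matrix from TSV
#'
#' The dialect is the one written by [write_matrix()]: a header row starting
#' with `genome_id` followed by pathway columns, then one row per genome
#' with 0/1 entries. Unknown pathway columns are preserved. Non-binary or
#' missing cells and duplicate genome rows are rejected with the offending
#' coordinates.
#'
#' @param path File path, or a character vector of lines.
#' @return Integer matrix with genome ids as rownames and pathway ids as
#'   colnames (possibly 0 rows for a header-only file).
#' @export
read_matrix <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) {
    readLines(path, warn = FALSE, encoding = "UTF-8")
  } else {
    as.character(path)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file: no header row", call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 1L || header[1] != "genome_id") {
    stop("matrix header must start with 'genome_id'", call. = FALSE)
  }
  pids <- header[-1]
  if (anyDuplicated(pids)) {
    stop("duplicate pathway column(s): ",
         paste(unique(pids[duplicated(pids)]), collapse = ", "),
         call. = FALSE)
  }
  n <- length(lines) - 1L
  mat <- matrix(0L, nrow = n, ncol = length(pids),
                dimnames = list(NULL, pids))
  ids <- character(n)
  for (r in seq_len(n)) {
    fields <- strsplit(lines[r + 1L], "\t", fixed = TRUE)[[1]]
    if (length(fields) != length(header)) {
      stop("row ", r, ": expected ", length(header), " fields, got ",
           length(fields), call. = FALSE)
    }
    ids[r] <- fields[1]
    for (cc in seq_along(pids)) {
      v <- fields[cc + 1L]
      if (!v %in% c("0", "1")) {
        stop("non-binary cell '", v, "' at genome '", ids[r],
             "', pathway '", pids[cc], "'", call. = FALSE)
      }
      mat[r, cc] <- as.integer(v)
    }
  }
  if (anyDuplicated(ids)) {
    stop("duplicate genome row(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  rownames(mat) <- ids
  mat
}

#' Confusion counts for one pathway
#'
#' Compares predicted vs curated presence calls for one pathway over the
#' genomes common to both matrices, matched by genome id (not by row
#' position). Genomes present in only one matrix are dropped.
#'
#' @param pred,truth Binary matrices as returned by [read_matrix()] or
#'   [predict_batch()].
#' @param pathway_id Pathway column present in both matrices.
#' @return Named integer vector `c(tp, fp, fn, tn)`.
#' @export
confusion_counts <- function(pred, truth, pathway_id) {
  if (!pathway_id %in% colnames(pred)) {
    stop("pathway '", pathway_id, "' absent from the prediction matrix",
         call. = FALSE)
  }
  if (!pathway_id %in% colnames(truth)) {
    stop("pathway '", pathway_id, "' absent from the truth matrix",
         call. = FALSE)
  }
  common <- intersect(rownames(pred), rownames(truth))
  if (!length(common)) {
    stop("no genomes in common between prediction and truth matrices",
         call. = FALSE)
  }
  p <- pred[common, pathway_id] == 1L
  t_ <- truth[common, pathway_id] == 1L
  c(tp = sum(p & t_), fp = sum(p & !t_), fn = sum(!p & t_),
    tn = sum(!p & !t_))
}

#' Precision, recall and F1 from confusion counts
#'
#' Standard per-pathway definitions: precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F1 their harmonic mean. A zero denominator yields 0 rather
#' than NaN, so pathways with no positives and no positive predictions score
#' (0, 0, 0).
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(precision = precision, recall = recall, f1 = f1)
}

#' Benchmark one or more tools against a curated truth matrix
#'
#' For each tool's prediction matrix, computes per-pathway confusion counts
#' and precision/recall/F1 over the genomes shared with the truth matrix.
#' Pathways of the truth matrix that a tool's matrix lacks are outside that
#' tool's prediction scope: they are marked `supported = FALSE` and scored 0
#' on all three metrics, with zero counts.
#'
#' @param predictions Named list of binary matrices, one per tool.
#' @param truth Curated binary truth matrix.
#' @return A `co2fix_benchmark` data frame with columns `tool`, `pathway`,
#'   `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `f1`, `supported`, plus
#'   an attribute `dropped` (named integer: genomes of the truth matrix not
#'   found in each tool's matrix).
#' @export
benchmark_tools <- function(predictions, truth) {
  stopifnot(is.list(predictions), length(predictions) >= 1L)
  if (is.null(names(predictions)) || any(!nzchar(names(predictions)))) {
    stop("'predictions' must be a named list (tool name -> matrix)",
         call. = FALSE)
  }
  pids <- colnames(truth)
  rows <- list()
  dropped <- integer(0)
  for (tool in names(predictions)) {
    pm <- predictions[[tool]]
    dropped[tool] <- length(setdiff(rownames(truth), rownames(pm)))
    for (p in pids) {
      if (p %in% colnames(pm)) {
        cc <- confusion_counts(pm, truth, p)
        m <- precision_recall_f1(cc[["tp"]], cc[["fp"]], cc[["fn"]])
        supported <- TRUE
      } else {
        cc <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
        m <- c(precision = 0, recall = 0, f1 = 0)
        supported <- FALSE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        tool = tool, pathway = p,
        tp = cc[["tp"]], fp = cc[["fp"]], fn = cc[["fn"]], tn = cc[["tn"]],
        precision = m[["precision"]], recall = m[["recall"]],
        f1 = m[["f1"]], supported = supported, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  class(out) <- c("co2fix_benchmark", class(out))
  out
}

#' Write a benchmark table as long-format TSV
#'
#' Columns `tool`, `pathway`, `tp`, `fp`, `fn`, `tn`, `precision`, `recall`,
#' `f1`, `supported`; metrics printed to 4 decimal places.
#'
#' @param bench A `co2fix_benchmark` from [benchmark_tools()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_benchmark <- function(bench, path) {
  df <- as.data.frame(bench)
  for (cc in c("precision", "recall", "f1")) {
    df[[cc]] <- sprintf("%.4f", df[[cc]])
  }
  df$supported <- ifelse(df$supported, "true", "false")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.co2fix_benchmark <- function(x, ...) {
  cat("Per-pathway benchmark (", length(unique(x$tool)), " tool(s), ",
      length(unique(x$pathway)), " pathways)\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  dropped <- attr(x, "dropped")
  if (!is.null(dropped) && any(dropped > 0)) {
    for (tool in names(dropped)[dropped > 0]) {
      cat("note: ", dropped[[tool]],
          " truth genomes absent from '", tool, "' and dropped\n", sep = "")
    }
  }
  invisible(x)
}
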