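# TSV adapters. All tables are plain tab-separated text; matrices carry
# gene IDs in the first column and either stage hours or sample IDs as the
# header. write(read(f)) round-trips values at full precision.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  n_fields <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(n_fields != n_fields[1])
  if (length(bad) > 0)
    stop(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                 path, bad[1], n_fields[bad[1]], n_fields[1]), call. = FALSE)
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a time-series expression matrix from TSV
#'
#' Expected layout: first column gene IDs, remaining column names the
#' stage hours (optionally prefixed "h"), cells the log-scale values.
#'
#' @param path TSV file.
#' @return A [ts_matrix()].
#' @export
read_timeseries_tsv <- function(path) {
  df <- read_tsv_checked(path)
  ids <- as.character(df[[1]])
  dup <- which(duplicated(ids))
  if (length(dup) > 0)
    stop(sprintf("%s: duplicated gene ID '%s' at line %d", path,
                 ids[dup[1]], dup[1] + 1L), call. = FALSE)
  hours <- suppressWarnings(as.numeric(sub("^h", "", names(df)[-1])))
  if (anyNA(hours))
    stop(sprintf("%s: header must carry numeric stage hours", path), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop(sprintf("%s: non-numeric cells in column '%s'", path,
                 names(df)[-1][bad]), call. = FALSE)
  }
  rownames(m) <- ids
  ts_matrix(m, hours)
}

#' Write a time-series expression matrix to TSV
#' @param x a [ts_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_timeseries_tsv <- function(x, path) {
  df <- data.frame(gene = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort expression matrix from TSV (genes x samples)
#' @param path TSV file: first column gene IDs, header sample IDs.
#' @return Numeric matrix with gene rownames.
#' @export
read_cohort_tsv <- function(path) {
  df <- read_tsv_checked(path)
  ids <- as.character(df[[1]])
  dup <- which(duplicated(ids))
  if (length(dup) > 0)
    stop(sprintf("%s: duplicated gene ID '%s' at line %d", path,
                 ids[dup[1]], dup[1] + 1L), call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop(sprintf("%s: non-numeric expression values", path), call. = FALSE)
  rownames(m) <- ids
  m
}

#' Write a cohort expression matrix to TSV
#' @param x gene x sample matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene list (one ID per line, or single-set GMT)
#'
#' Lines starting with `#` and blank lines are skipped. A GMT file (name,
#' description, members, tab-separated) must contain exactly one set.
#'
#' @param path text or `.gmt` file.
#' @return Character vector of gene IDs.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (grepl("\\.gmt$", path, ignore.case = TRUE)) {
    if (length(lines) != 1L)
      stop(sprintf("%s: expected a single-set GMT, found %d sets", path,
                   length(lines)), call. = FALSE)
    fields <- strsplit(lines, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop(sprintf("%s: GMT line needs name, description and members", path),
           call. = FALSE)
    return(unique(fields[-(1:2)]))
  }
  unique(trimws(lines))
}

#' Read a TF-target edge list (two-column TSV, TF first)
#' @param path TSV file with header.
#' @return data.frame with columns `tf`, `target`.
#' @export
read_edge_list <- function(path) {
  df <- read_tsv_checked(path)
  if (ncol(df) < 2L)
    stop(sprintf("%s: edge list needs two columns (TF, target)", path),
         call. = FALSE)
  out <- data.frame(tf = as.character(df[[1]]), target = as.character(df[[2]]),
                    stringsAsFactors = FALSE)
  out[!duplicated(out), ]
}

#' Write a TF-target edge list
#' @param edges data.frame with `tf`, `target`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges[, c("tf", "target")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read survival records (sample, time_months, event)
#' @param path TSV file.
#' @return data.frame with `sample`, `time_months`, `event`.
#' @export
read_survival_tsv <- function(path) {
  df <- read_tsv_checked(path)
  need <- c("sample", "time_months", "event")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: survival TSV needs columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  df[need]
}

#' Write survival records
#' @param surv data.frame with `sample`, `time_months`, `event`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_survival_tsv <- function(surv, path) {
  utils::write.table(surv[, c("sample", "time_months", "event")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a TF-TF network as Graphviz DOT
#' @param network a `tf_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_dot <- function(network, path) {
  stopifnot(inherits(network, "tf_network"))
  col <- c(positive = "orange", negative = "lightblue", unclassified = "grey")
  lines <- c("digraph tf_network {",
             sprintf("  \"%s\" [fillcolor=%s, style=filled];",
                     network$nodes$tf, col[network$nodes$class]),
             sprintf("  \"%s\" -> \"%s\";", network$edges$from, network$edges$to),
             "}")
  writeLines(lines, path)
  invisible(path)
}
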