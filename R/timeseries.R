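#' Construct a time-series expression matrix
#'
#' A `ts_matrix` is a numeric gene x stage matrix on log scale with an
#' ordered vector of stage times in hours. It is the container consumed by
#' the co-expression, signature and staging steps.
#'
#' @param values numeric matrix, genes in rows (rownames = gene IDs),
#'   stages in columns.
#' @param stages numeric vector of stage times in hours, strictly
#'   increasing, one per column.
#' @return An object of class `ts_matrix`: the matrix with a `stages`
#'   attribute.
#' @examples
#' x <- ts_matrix(matrix(rnorm(12), 3, 4,
#'                       dimnames = list(paste0("g", 1:3), NULL)),
#'                stages = c(0, 8, 24, 72))
#' stages(x)
#' @export
ts_matrix <- function(values, stages) {
  if (!is.matrix(values) || !is.numeric(values))
    abort_field("values", "must be a numeric matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    abort_field("values", "rows must carry unique gene IDs")
  if (anyNA(values))
    abort_field("values", "missing values are not allowed")
  stages <- check_stage_grid(stages, "stages")
  if (length(stages) != ncol(values))
    abort_field("stages", "length must equal the number of columns")
  colnames(values) <- format_hours(stages)
  structure(values, stages = stages, class = c("ts_matrix", "matrix", "array"))
}

#' Stage times of a time-series matrix
#' @param x a `ts_matrix`.
#' @return Numeric vector of hours.
#' @export
stages <- function(x) attr(x, "stages")

format_hours <- function(h) {
  s <- vapply(h, function(x) format(x, trim = TRUE, scientific = FALSE),
              character(1))
  # strip decimal trailing zeros only ("4.50" -> "4.5", "4.00" -> "4")
  s <- ifelse(grepl("\\.", s), sub("\\.$", "", sub("0+$", "", s)), s)
  paste0("h", s)
}

#' @export
print.ts_matrix <- function(x, ...) {
  cat(sprintf("ts_matrix: %d genes x %d stages (%s h)\n",
              nrow(x), ncol(x), paste(stages(x), collapse = ", ")))
  invisible(x)
}

# subsetting keeps the class and stage attribute when columns are intact
#' @export
`[.ts_matrix` <- function(x, i, j, ..., drop = FALSE) {
  st <- stages(x)
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    st_out <- if (missing(j)) st else st[j]
    attr(out, "stages") <- st_out
    class(out) <- c("ts_matrix", "matrix", "array")
  }
  out
}

# drop zero-variance genes (Pearson undefined); returns the filtered matrix
#' Filter genes without expression variance
#'
#' Pearson correlation is undefined for flat profiles; this removes them
#' before network construction.
#'
#' @param x a `ts_matrix`.
#' @param tol variance tolerance below which a gene counts as flat.
#' @return Filtered `ts_matrix`; attribute `dropped` lists removed genes.
#' @export
filter_invariant_genes <- function(x, tol = 1e-12) {
  v <- apply(unclass(x), 1L, stats::var)
  keep <- v > tol
  out <- ts_matrix(unclass(x)[keep, , drop = FALSE], stages(x))
  attr(out, "dropped") <- rownames(x)[!keep]
  out
}
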