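#' Build an association matrix
#'
#' The association matrix `Y` has lncRNAs on the rows and diseases on the
#' columns. On input it is binary (1 = curated association); after WKNKN
#' preprocessing its zero cells hold interaction probabilities in \[0, 1\].
#'
#' @param values numeric matrix, all entries finite and in \[0, 1\].
#' @param lnc_labels,dis_labels unique row / column labels. Taken from
#'   `dimnames(values)` when omitted.
#' @return the matrix with validated dimnames.
#' @examples
#' Y <- association_matrix(diag(2), c("l1", "l2"), c("dA", "dB"))
#' @export
association_matrix <- function(values, lnc_labels = rownames(values),
                               dis_labels = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(lnc_labels) || is.null(dis_labels)) {
    stop("association matrix needs both lncRNA (row) and disease (column) labels",
         call. = FALSE)
  }
  check_labels(lnc_labels, nrow(values), "lncRNA")
  check_labels(dis_labels, ncol(values), "disease")
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("association matrix values must all be finite numbers", call. = FALSE)
  }
  if (any(values < 0) || any(values > 1)) {
    bad <- which(values < 0 | values > 1, arr.ind = TRUE)[1, ]
    stop(sprintf("association value out of [0, 1] at row %d ('%s'), column %d ('%s')",
                 bad[1], lnc_labels[bad[1]], bad[2], dis_labels[bad[2]]),
         call. = FALSE)
  }
  dimnames(values) <- list(lnc_labels, dis_labels)
  values
}

#' Build a similarity matrix
#'
#' Square nonnegative matrix over one entity set (lncRNAs or diseases).
#' Symmetry is required for the semantic, functional, GIP, logistic and
#' fused kinds; LNS reconstruction-weight matrices are row-wise and may be
#' asymmetric.
#'
#' @param values square numeric matrix, finite and >= 0.
#' @param labels unique entity labels; default from `dimnames`.
#' @param kind one of `"semantic"`, `"functional"`, `"gip"`, `"logistic"`,
#'   `"fused"`, `"lns"`; attached as the `"kind"` attribute.
#' @return validated matrix with a `"kind"` attribute.
#' @export
similarity_matrix <- function(values, labels = rownames(values),
                              kind = c("semantic", "functional", "gip",
                                       "logistic", "fused", "lns")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("similarity matrix must be square", call. = FALSE)
  }
  if (is.null(labels)) {
    stop("similarity matrix needs entity labels", call. = FALSE)
  }
  check_labels(labels, nrow(values), "entity")
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop("similarity values must all be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("similarity values must be nonnegative", call. = FALSE)
  }
  if (kind != "lns" && !isTRUE(all.equal(values, t(values), tolerance = 1e-8,
                                         check.attributes = FALSE))) {
    stop(sprintf("'%s' similarity matrix must be symmetric", kind),
         call. = FALSE)
  }
  dimnames(values) <- list(labels, labels)
  attr(values, "kind") <- kind
  values
}

#' Read a labeled association matrix from TSV/CSV
#'
#' First row holds the disease labels, first column the lncRNA labels;
#' label order in the file is preserved.
#'
#' @param path file path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return association matrix (see [association_matrix()]).
#' @export
read_association_matrix <- function(path, format = c("tsv", "csv")) {
  m <- read_labeled_matrix(path, match.arg(format))
  association_matrix(m)
}

#' Read a labeled similarity matrix from TSV/CSV
#'
#' @inheritParams read_association_matrix
#' @param kind similarity kind tag, see [similarity_matrix()].
#' @return similarity matrix.
#' @export
read_similarity_matrix <- function(path, format = c("tsv", "csv"),
                                   kind = "fused") {
  m <- read_labeled_matrix(path, match.arg(format))
  similarity_matrix(m, kind = kind)
}

read_labeled_matrix <- function(path, format) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path), call. = FALSE)
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- read.table(path, sep = sep, header = TRUE, row.names = NULL,
                   check.names = FALSE, colClasses = "character",
                   quote = "", comment.char = "")
  if (ncol(df) < 2 || nrow(df) < 1) {
    stop(sprintf("'%s' does not contain a labeled matrix", path), call. = FALSE)
  }
  row_labels <- df[[1]]
  col_labels <- colnames(df)[-1]
  check_labels(row_labels, length(row_labels), "row", path)
  check_labels(col_labels, length(col_labels), "column", path)
  cells <- as.matrix(df[, -1, drop = FALSE])
  values <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (any(is.na(values))) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell '%s' at row %d ('%s'), column %d ('%s') of '%s'",
                 cells[bad[1], bad[2]], bad[1], row_labels[bad[1]],
                 bad[2], col_labels[bad[2]], path),
         call. = FALSE)
  }
  dimnames(values) <- list(row_labels, col_labels)
  values
}

#' Write a labeled matrix as TSV
#'
#' Writes with full double precision (17 significant digits) so that a
#' write/read round trip reproduces the matrix to well under 1e-12.
#' Labels containing tab, newline or the field separator are rejected.
#'
#' @param m labeled numeric matrix (association or similarity).
#' @param path output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  m <- as.matrix(m)
  if (nrow(m) == 0 || ncol(m) == 0) {
    stop("refusing to write an empty matrix", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("matrix must carry row and column labels", call. = FALSE)
  }
  sep <- if (format == "tsv") "\t" else ","
  labels <- c(rownames(m), colnames(m))
  if (any(grepl("[\t\n\r]", labels)) || any(grepl(sep, labels, fixed = TRUE))) {
    stop("labels may not contain tabs, newlines or the field separator",
         call. = FALSE)
  }
  cells <- format(m, digits = 17, scientific = FALSE, trim = TRUE)
  lines <- c(
    paste(c("", colnames(m)), collapse = sep),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], cells[i, ]), collapse = sep)
    }, character(1))
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

check_labels <- function(labels, n, what, path = NULL) {
  where <- if (is.null(path)) "" else sprintf(" in '%s'", path)
  if (length(labels) != n) {
    stop(sprintf("expected %d %s labels, got %d%s", n, what, length(labels), where),
         call. = FALSE)
  }
  if (anyNA(labels) || any(!nzchar(labels))) {
    stop(sprintf("empty or missing %s label%s", what, where), call. = FALSE)
  }
  dup <- unique(labels[duplicated(labels)])
  if (length(dup) > 0) {
    stop(sprintf("duplicated %s label%s: '%s'", what, where, dup[1]),
         call. = FALSE)
  }
  invisible(TRUE)
}

# shared guard: two labeled matrices must agree on the given margin labels
check_labels_agree <- function(a, b, what) {
  if (!identical(a, b)) {
    stop(sprintf("%s labels disagree between operands", what), call. = FALSE)
  }
  invisible(TRUE)
}
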