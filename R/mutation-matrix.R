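#' Binary somatic mutation matrix
#'
#' Construct a validated patients x genes binary incidence matrix.  Rows are
#' patients (tumor samples), columns are genes; an entry of 1 records a
#' somatic mutation of that gene in that patient.
#'
#' @param x a numeric or integer matrix with unique rownames (patient IDs)
#'   and unique colnames (gene symbols); every entry must be 0 or 1.
#' @return an object of class `mutation_matrix`: an integer 0/1 matrix with
#'   dimnames, as supplied.
#' @examples
#' m <- matrix(c(1L, 0L, 0L, 1L), 2, 2,
#'             dimnames = list(c("p1", "p2"), c("g1", "g2")))
#' mm <- mutation_matrix(m)
#' n_patients(mm)
#' @export
mutation_matrix <- function(x) {
  if (!is.matrix(x)) stop("`x` must be a matrix", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("mutation matrix needs at least one patient and one gene",
         call. = FALSE)
  pats <- rownames(x)
  genes <- colnames(x)
  if (is.null(pats) || is.null(genes))
    stop("mutation matrix requires patient rownames and gene colnames",
         call. = FALSE)
  if (anyDuplicated(pats))
    stop("duplicate patient identifiers: ",
         paste(unique(pats[duplicated(pats)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicate gene symbols: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  storage.mode(x) <- "integer"
  if (anyNA(x) || !all(x == 0L | x == 1L))
    stop("mutation matrix entries must all be 0 or 1", call. = FALSE)
  structure(x, class = c("mutation_matrix", "matrix", "array"))
}

#' @rdname mutation_matrix
#' @param mm a `mutation_matrix`.
#' @export
n_patients <- function(mm) nrow(mm)

#' @rdname mutation_matrix
#' @export
n_genes <- function(mm) ncol(mm)

#' @rdname mutation_matrix
#' @export
patients <- function(mm) rownames(mm)

#' @rdname mutation_matrix
#' @export
genes <- function(mm) colnames(mm)

#' @export
print.mutation_matrix <- function(x, ...) {
  cat(sprintf("mutation_matrix: %d patients x %d genes, %d mutation events\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

# Keep the class when users subset with drop = FALSE.
#' @export
`[.mutation_matrix` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out) && !is.null(rownames(out)) && !is.null(colnames(out)))
    class(out) <- c("mutation_matrix", "matrix", "array")
  out
}

#' Read a mutation matrix from a headered TSV file
#'
#' Expects a tab-delimited UTF-8 file whose first row is a header of gene
#' symbols and whose first column holds patient identifiers; every body cell
#' must be 0 or 1.  Row and column order of the file is preserved.
#'
#' @param path path to the TSV file.
#' @return a [mutation_matrix].
#' @seealso [read_pair_list()] for the two-column event-list format,
#'   [write_matrix_tsv()] for the inverse operation.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          row.names = NULL, comment.char = "")
  if (ncol(df) < 2L)
    stop("matrix TSV needs a patient-ID column and at least one gene column",
         call. = FALSE)
  pats <- df[[1L]]
  gene_names <- colnames(df)[-1L]
  body <- as.matrix(df[, -1L, drop = FALSE])
  bad <- !(body %in% c("0", "1"))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(body)), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "cell (%s, %s) is '%s'; mutation matrix cells must be 0 or 1",
      pats[idx[1L]], gene_names[idx[2L]], body[idx[1L], idx[2L]]),
      call. = FALSE)
  }
  storage.mode(body) <- "integer"
  dimnames(body) <- list(pats, gene_names)
  mutation_matrix(body)
}

#' Read a mutation matrix from a patient-gene pair list
#'
#' Each non-comment line records one mutation event as
#' `<patient_id><TAB><gene_symbol>`.  Lines starting with `#` are ignored,
#' duplicate pairs collapse to a single 1, and the resulting matrix is over
#' the union of observed patients and genes, both sorted lexicographically.
#'
#' @param path path to the pair-list file.
#' @return a [mutation_matrix].
#' @export
read_pair_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L)
    stop("pair list contains no mutation events", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 2L)) {
    i <- which(nf != 2L)[1L]
    stop(sprintf("line %d has %d tab-separated fields; expected 2 (patient, gene)",
                 lineno[i], nf[i]), call. = FALSE)
  }
  pat <- vapply(parts, `[[`, "", 1L)
  gene <- vapply(parts, `[[`, "", 2L)
  # lexicographic order, independent of locale
  upat <- sort(unique(pat), method = "radix")
  ugene <- sort(unique(gene), method = "radix")
  mat <- matrix(0L, length(upat), length(ugene),
                dimnames = list(upat, ugene))
  mat[cbind(match(pat, upat), match(gene, ugene))] <- 1L
  mutation_matrix(mat)
}

#' Write a mutation matrix as headered TSV
#'
#' Inverse of [read_matrix_tsv()]: re-reading the written file reproduces
#' the matrix exactly, including row and column order.
#'
#' @param mm a [mutation_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mm, path) {
  stopifnot(inherits(mm, "mutation_matrix"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("patient", colnames(mm)), collapse = "\t"), con)
  body <- apply(mm, 1L, paste, collapse = "\t")
  writeLines(paste(rownames(mm), body, sep = "\t"), con)
  invisible(path)
}

#' Remove infrequently mutated genes
#'
#' Drops genes mutated in fewer than `min_fraction` of all patients, the
#' standard pre-filter for driver-pathway discovery: genes altered in only
#' one or a few patients are likely passengers.  A gene is *kept* when its
#' mutation count is greater than or equal to `min_fraction * m` (strict-less
#' removal), patients are untouched, and gene order is preserved, so the
#' operation is idempotent.
#'
#' @param mm a [mutation_matrix].
#' @param min_fraction minimum mutated fraction of patients, in \[0, 1\];
#'   default 0.05.
#' @return the filtered [mutation_matrix].
#' @export
filter_by_frequency <- function(mm, min_fraction = 0.05) {
  stopifnot(inherits(mm, "mutation_matrix"))
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      is.na(min_fraction) || min_fraction < 0 || min_fraction > 1)
    stop("`min_fraction` must be a single number in [0, 1]", call. = FALSE)
  counts <- colSums(mm)
  m <- nrow(mm)
  # compare on the fraction scale so e.g. 15/300 equals 0.05 exactly
  keep <- (counts / m) >= min_fraction
  if (!any(keep))
    stop("frequency filter removed every gene; lower `min_fraction` ",
         "(largest observed mutated fraction is ",
         format(max(counts) / m), ")", call. = FALSE)
  mm[, keep, drop = FALSE]
}
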