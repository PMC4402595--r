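#' Exclusivity and coverage metrics for gene sets
#'
#' For a gene set M in a binary mutation matrix with m patients, with
#' per-gene coverage Gamma(g) = patients mutated in g and set coverage
#' Gamma(M) = union of the Gamma(g):
#'
#' * exclusive degree `ED(M) = |Gamma(M)| / sum_g |Gamma(g)|` — equals 1
#'   exactly when the per-gene coverages are pairwise disjoint (mutual
#'   exclusivity), and decreases as patients accumulate multiple mutated
#'   genes from M;
#' * coverage degree `CD(M) = |Gamma(M)| / m` — the fraction of patients
#'   carrying at least one mutation in M;
#' * exclusivity-coverage degree
#'   `ECD(M) = ED(M) * CD(M) = |Gamma(M)|^2 / (m * sum_g |Gamma(g)|)` —
#'   the trade-off objective maximized by the greedy pathway search; it is
#'   1 iff M is mutually exclusive and covers every patient.
#'
#' All three are ratios of integer counts; they are computed on integers
#' and divided only at the end, so results are exact up to one floating
#' division.
#'
#' @param mm a [mutation_matrix].
#' @param gene_set character vector of gene symbols, all present in `mm`.
#' @return `coverage_set()`: the patient IDs covered by the set, in matrix
#'   row order.  `exclusive_degree()`, `coverage_degree()`, `ecd()`: a
#'   single number.  `pair_metrics()`: a named numeric vector with
#'   elements `ed`, `cd`, `ecd`.
#' @examples
#' m <- matrix(c(1,1,1,0, 0,0,1,1), 4, 2,
#'             dimnames = list(paste0("p", 1:4), c("g1", "g2")))
#' mm <- mutation_matrix(m)
#' exclusive_degree(mm, c("g1", "g2"))  # 4/5
#' coverage_degree(mm, c("g1", "g2"))   # 1
#' ecd(mm, c("g1", "g2"))               # 0.8
#' @name metrics
NULL

check_genes <- function(mm, gene_set) {
  missing <- setdiff(gene_set, colnames(mm))
  if (length(missing))
    stop("gene(s) not present in matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
}

# integer numerator/denominator of ED and the covered-patient count,
# shared by all metric front-ends
set_counts <- function(mm, gene_set) {
  check_genes(mm, gene_set)
  if (length(gene_set) == 0L)
    return(list(union = 0L, total = 0L))
  sub <- mm[, gene_set, drop = FALSE]
  list(union = sum(rowSums(sub) > 0L), total = sum(sub))
}

#' @rdname metrics
#' @export
coverage_set <- function(mm, gene_set) {
  check_genes(mm, gene_set)
  if (length(gene_set) == 0L) return(character(0))
  sub <- mm[, gene_set, drop = FALSE]
  rownames(mm)[rowSums(sub) > 0L]
}

#' @rdname metrics
#' @export
exclusive_degree <- function(mm, gene_set) {
  cnt <- set_counts(mm, gene_set)
  if (length(gene_set) == 0L)
    stop("exclusive degree is undefined for an empty gene set", call. = FALSE)
  if (cnt$total == 0L)
    stop("exclusive degree is undefined: no mutations in the gene set",
         call. = FALSE)
  cnt$union / cnt$total
}

#' @rdname metrics
#' @export
coverage_degree <- function(mm, gene_set) {
  cnt <- set_counts(mm, gene_set)
  cnt$union / nrow(mm)
}

#' @rdname metrics
#' @export
ecd <- function(mm, gene_set) {
  cnt <- set_counts(mm, gene_set)
  if (length(gene_set) == 0L || cnt$total == 0L)
    stop("exclusivity-coverage degree is undefined: no mutations in the gene set",
         call. = FALSE)
  cnt$union^2 / (nrow(mm) * cnt$total)
}

#' @rdname metrics
#' @param g1,g2 single gene symbols.
#' @export
pair_metrics <- function(mm, g1, g2) {
  cnt <- set_counts(mm, c(g1, g2))
  if (cnt$total == 0L)
    stop("pair metrics undefined: neither gene has a mutation", call. = FALSE)
  c(ed = cnt$union / cnt$total,
    cd = cnt$union / nrow(mm),
    ecd = cnt$union^2 / (nrow(mm) * cnt$total))
}
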