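#' Build the gene exclusivity network
#'
#' Computes the pairwise exclusive degree
#' `ED(gj, gk) = |Gamma(gj) U Gamma(gk)| / (|Gamma(gj)| + |Gamma(gk)|)`
#' for every unordered gene pair and creates an undirected edge whenever
#' `ED >= lambda` (inclusive threshold), weighted by that ED.  Genes whose
#' exclusive degree with every other gene falls below `lambda` do not
#' appear in the network.  The result is independent of gene order.
#'
#' Pairwise EDs come from one integer cross-product of the matrix, so the
#' construction is a single O(m n^2) pass.
#'
#' @param mm a [mutation_matrix]; every gene should carry at least one
#'   mutation (run [filter_by_frequency()] first).
#' @param lambda edge-creation exclusivity threshold, in (0, 1];
#'   default 0.95.
#' @return an [igraph][igraph::graph_from_data_frame] undirected graph of
#'   class `gene_network` with vertex attribute `name` (gene symbol) and
#'   edge attributes `weight` (the ED, a double) plus the exact integer
#'   counts `num` (union size) and `den` (coverage-size sum) it is the
#'   ratio of.
#' @export
build_network <- function(mm, lambda = 0.95) {
  stopifnot(inherits(mm, "mutation_matrix"))
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda <= 0 || lambda > 1)
    stop("`lambda` must be a single number in (0, 1]", call. = FALSE)
  counts <- colSums(mm)
  if (any(counts == 0L))
    stop("gene(s) without any mutation: ",
         paste(utils::head(colnames(mm)[counts == 0L], 5L), collapse = ", "),
         "; run filter_by_frequency() first", call. = FALSE)
  ov <- crossprod(mm)              # pairwise intersection sizes
  den <- outer(counts, counts, "+")
  num <- den - ov                  # |union| = |A| + |B| - |A & B|
  keep <- upper.tri(num) & (num / den >= lambda)
  idx <- which(keep, arr.ind = TRUE)
  g <- colnames(mm)
  edges <- data.frame(
    from = g[idx[, 1L]],
    to = g[idx[, 2L]],
    weight = num[keep] / den[keep],
    num = as.integer(num[keep]),
    den = as.integer(den[keep]),
    stringsAsFactors = FALSE
  )
  net <- igraph::graph_from_data_frame(edges, directed = FALSE)
  class(net) <- c("gene_network", class(net))
  net
}

#' Read and write gene networks as edge-list TSV
#'
#' The file format is three tab-separated columns
#' `geneA<TAB>geneB<TAB>weight` with `geneA < geneB` lexicographically and
#' rows sorted; weights are written with 12 decimal digits, so a round trip
#' preserves them to that precision.
#'
#' @param net a `gene_network` from [build_network()].
#' @param path file path.
#' @return `write_edge_list()`: `path`, invisibly.  `read_edge_list()`: a
#'   `gene_network`.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "gene_network"))
  el <- igraph::as_data_frame(net, what = "edges")
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(el)) {
    a <- pmin(el$from, el$to)
    b <- pmax(el$from, el$to)
    ord <- order(a, b, method = "radix")
    writeLines(sprintf("%s\t%s\t%.12f", a[ord], b[ord], el$weight[ord]), con)
  }
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    net <- igraph::make_empty_graph(0, directed = FALSE)
    class(net) <- c("gene_network", class(net))
    return(net)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 3L))
    stop(sprintf("edge-list line %d has %d fields; expected 3",
                 which(nf != 3L)[1L], nf[nf != 3L][1L]), call. = FALSE)
  w <- as.numeric(vapply(parts, `[[`, "", 3L))
  if (anyNA(w) || any(w < 0) || any(w > 1))
    stop("edge weights must be numbers in [0, 1]", call. = FALSE)
  edges <- data.frame(
    from = vapply(parts, `[[`, "", 1L),
    to = vapply(parts, `[[`, "", 2L),
    weight = w,
    stringsAsFactors = FALSE
  )
  net <- igraph::graph_from_data_frame(edges, directed = FALSE)
  class(net) <- c("gene_network", class(net))
  net
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d genes, %d exclusivity edges\n",
              igraph::vcount(x), igraph::ecount(x)))
  invisible(x)
}
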