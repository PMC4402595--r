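#' Simulate a mutation matrix with implanted driver pathways
#'
#' Generates the implanted-pathway benchmark: `m` patients by `n` genes,
#' with `length(pathway_sizes)` mutually exclusive gene sets planted at
#' randomly chosen gene positions.  For pathway i, `round(coverage_degrees[i] * m)`
#' distinct patients are drawn uniformly and each receives a driver
#' mutation in exactly one uniformly chosen gene of that pathway, so within
#' each pathway the driver mutations are mutually exclusive and (at
#' `q = 0`) its coverage degree equals its configured value exactly up to
#' that rounding.  Passenger noise then sets each cell to 1 independently
#' with probability `q` (OR-semantics: a driver cell stays 1).
#'
#' Patient draws for different pathways are independent, so one patient
#' may carry drivers of several pathways; exclusivity holds only within a
#' pathway.  With the defaults this reproduces the standard benchmark:
#' 300 patients, 500 genes, five 5-gene pathways with coverage degrees
#' 0.95, 0.85, 0.75, 0.65, 0.55 (285, 255, 225, 195, 165 covered
#' patients).
#'
#' @param m number of patients (default 300).
#' @param n number of genes (default 500).
#' @param pathway_sizes integer vector of implanted pathway sizes
#'   (default five pathways of five genes).
#' @param coverage_degrees per-pathway coverage degrees in \[0, 1\], same
#'   length as `pathway_sizes` (default 0.95, 0.85, 0.75, 0.65, 0.55).
#' @param q passenger mutation probability in \[0, 1\] (default 0).
#' @param seed integer seed; fixing it makes the output fully
#'   reproducible.  `NULL` uses the current RNG state.
#' @param noise_scope `"all"` (default) applies passenger noise to every
#'   cell, including implanted driver genes — at high `q` implanted
#'   exclusivity therefore degrades, which is exactly the stressor the
#'   benchmark varies; `"nondriver_genes_only"` spares the implanted
#'   genes' columns.
#' @return a list with elements `matrix` (a [mutation_matrix]) and `truth`
#'   (class `nbm_ground_truth`): `pathways` — list of implanted gene-symbol
#'   sets; `driver_cells` — data.frame of (patient, gene) positions that
#'   carry implanted driver mutations.
#' @examples
#' sim <- simulate_mutations(q = 0, seed = 1)
#' sim$matrix
#' coverage_degree(sim$matrix, sim$truth$pathways[[1]])  # 0.95
#' @export
simulate_mutations <- function(m = 300L, n = 500L,
                               pathway_sizes = rep(5L, 5L),
                               coverage_degrees = c(0.95, 0.85, 0.75, 0.65, 0.55),
                               q = 0,
                               seed = NULL,
                               noise_scope = c("all", "nondriver_genes_only")) {
  noise_scope <- match.arg(noise_scope)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("`m` must be a single integer >= 1", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("`n` must be a single integer >= 1", call. = FALSE)
  if (length(pathway_sizes) != length(coverage_degrees))
    stop("`pathway_sizes` and `coverage_degrees` must have the same length",
         call. = FALSE)
  if (any(pathway_sizes < 1) || any(pathway_sizes != round(pathway_sizes)))
    stop("`pathway_sizes` must be positive integers", call. = FALSE)
  if (sum(pathway_sizes) > n)
    stop("implanted pathways need ", sum(pathway_sizes),
         " genes but the matrix has only ", n, call. = FALSE)
  if (any(coverage_degrees < 0) || any(coverage_degrees > 1))
    stop("`coverage_degrees` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1)
    stop("`q` must be a single probability in [0, 1]", call. = FALSE)
  m <- as.integer(m); n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)

  width <- max(4L, nchar(as.character(n)))
  gene_names <- sprintf(paste0("G%0", width, "d"), seq_len(n))
  pat_width <- max(4L, nchar(as.character(m)))
  pat_names <- sprintf(paste0("S%0", pat_width, "d"), seq_len(m))

  mat <- matrix(0L, m, n, dimnames = list(pat_names, gene_names))

  # plant pathways at randomly chosen gene positions
  k <- length(pathway_sizes)
  all_idx <- sample.int(n, sum(pathway_sizes))
  splits <- rep(seq_len(k), times = pathway_sizes)
  pathway_idx <- split(all_idx, splits)
  driver_pat <- character(0)
  driver_gene <- character(0)
  for (i in seq_len(k)) {
    cov_size <- as.integer(round(coverage_degrees[i] * m))
    if (cov_size == 0L) next
    pats <- sample.int(m, cov_size)
    which_gene <- pathway_idx[[i]][sample.int(pathway_sizes[i], cov_size,
                                              replace = TRUE)]
    mat[cbind(pats, which_gene)] <- 1L
    driver_pat <- c(driver_pat, pat_names[pats])
    driver_gene <- c(driver_gene, gene_names[which_gene])
  }

  if (q > 0) {
    noise <- matrix(stats::runif(m * n) < q, m, n)
    if (noise_scope == "nondriver_genes_only")
      noise[, unlist(pathway_idx)] <- FALSE
    mat <- mat | noise
    storage.mode(mat) <- "integer"
    dimnames(mat) <- list(pat_names, gene_names)
  }

  truth <- structure(list(
    pathways = lapply(pathway_idx,
                      function(ix) sort(gene_names[ix], method = "radix")),
    driver_cells = data.frame(patient = driver_pat, gene = driver_gene,
                              stringsAsFactors = FALSE)
  ), class = "nbm_ground_truth")
  names(truth$pathways) <- paste0("P", seq_len(k))

  list(matrix = mutation_matrix(mat), truth = truth)
}

#' @export
print.nbm_ground_truth <- function(x, ...) {
  cat(sprintf("nbm_ground_truth: %d implanted pathway(s), %d driver mutations\n",
              length(x$pathways), nrow(x$driver_cells)))
  invisible(x)
}

#' Write simulation ground truth as JSON
#'
#' @param truth an `nbm_ground_truth` from [simulate_mutations()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "nbm_ground_truth"))
  jsonlite::write_json(
    list(pathways = truth$pathways,
         driver_cells = truth$driver_cells),
    path, pretty = TRUE)
  invisible(path)
}
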