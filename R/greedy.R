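#' Parameters of the driver-pathway search
#'
#' Bundles the four tunable parameters of the pipeline.  The defaults
#' (`lambda = 0.95`, `delta = 0.3`, minimum reported set size 3, 5%
#' gene-frequency pre-filter) are the settings found to give good results
#' across simulated and tumor datasets.
#'
#' @param lambda exclusivity threshold in (0, 1]: gene pairs with pairwise
#'   exclusive degree `>= lambda` become network edges, and a growth move
#'   must keep the set's exclusive degree strictly above `lambda`.
#' @param delta minimum coverage degree in \[0, 1\] for a candidate to be
#'   reported as a driver pathway.
#' @param min_set_size minimum number of genes in a reported pathway.
#' @param min_gene_fraction minimum mutated-patient fraction a gene needs
#'   to survive the pre-filter (see [filter_by_frequency()]).
#' @return an object of class `nbm_params`.
#' @export
nbm_params <- function(lambda = 0.95, delta = 0.3, min_set_size = 3L,
                       min_gene_fraction = 0.05) {
  num1 <- function(x, nm, lo, hi, lo_open = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (if (lo_open) x <= lo else x < lo) || x > hi)
      stop(sprintf("`%s` must be a single number in %s%g, %g]",
                   nm, if (lo_open) "(" else "[", lo, hi), call. = FALSE)
    as.numeric(x)
  }
  lambda <- num1(lambda, "lambda", 0, 1, lo_open = TRUE)
  delta <- num1(delta, "delta", 0, 1)
  min_gene_fraction <- num1(min_gene_fraction, "min_gene_fraction", 0, 1)
  if (!is.numeric(min_set_size) || length(min_set_size) != 1L ||
      is.na(min_set_size) || min_set_size < 1 ||
      min_set_size != round(min_set_size))
    stop("`min_set_size` must be a single integer >= 1", call. = FALSE)
  structure(list(lambda = lambda, delta = delta,
                 min_set_size = as.integer(min_set_size),
                 min_gene_fraction = min_gene_fraction),
            class = "nbm_params")
}

#' @export
print.nbm_params <- function(x, ...) {
  cat(sprintf(paste0("nbm_params: lambda = %g, delta = %g, ",
                     "min_set_size = %d, min_gene_fraction = %g\n"),
              x$lambda, x$delta, x$min_set_size, x$min_gene_fraction))
  invisible(x)
}

# ---- exact fraction comparisons on integer counts ---------------------
# ECD(V) = u^2 / (m * t) with u = |Gamma(V)|, t = sum of per-gene coverages.
# m cancels in comparisons, and u^2 * t stays well below 2^53, so the
# cross-multiplied comparison is exact.
ecd_gt <- function(u1, t1, u2, t2) {
  as.numeric(u1)^2 * as.numeric(t2) > as.numeric(u2)^2 * as.numeric(t1)
}
ed_gt <- function(u1, t1, u2, t2) {
  as.numeric(u1) * as.numeric(t2) > as.numeric(u2) * as.numeric(t1)
}

# centralized threshold predicates (inclusive for edge creation, strict
# for growth admissibility)
ed_meets_edge_threshold <- function(u, t, lambda) (u / t) >= lambda
ed_above_lambda <- function(u, t, lambda) (u / t) > lambda

#' Construct a scored pathway candidate
#'
#' @param mm a [mutation_matrix].
#' @param gene_set character vector of genes in `mm`.
#' @return a `pathway_candidate`: the lexicographically sorted gene set
#'   together with its covered patients, ED, CD and ECD.
#' @export
pathway_candidate <- function(mm, gene_set) {
  cnt <- set_counts(mm, gene_set)
  if (cnt$total == 0L)
    stop("candidate has no mutations", call. = FALSE)
  m <- nrow(mm)
  structure(list(
    genes = sort(unique(gene_set), method = "radix"),
    covered_patients = coverage_set(mm, gene_set),
    size = length(unique(gene_set)),
    n_covered = cnt$union,
    ed = cnt$union / cnt$total,
    cd = cnt$union / m,
    ecd = cnt$union^2 / (m * cnt$total)
  ), class = "pathway_candidate")
}

#' @export
print.pathway_candidate <- function(x, ...) {
  cat(sprintf("pathway_candidate: {%s}\n  ED = %.4f, CD = %.4f, ECD = %.4f (%d/%s patients covered)\n",
              paste(x$genes, collapse = ", "), x$ed, x$cd, x$ecd,
              x$n_covered, x$size))
  invisible(x)
}

#' Select the next seed pair
#'
#' Among network edges whose two endpoints are both outside `consumed`,
#' returns the gene pair with the highest pairwise exclusivity-coverage
#' degree.  Ties are broken by higher pairwise ED, then by the
#' lexicographically smallest pair, so selection is deterministic.
#'
#' @param net a `gene_network` from [build_network()].
#' @param mm the [mutation_matrix] the network was built from.
#' @param consumed character vector of genes already absorbed into grown
#'   sets (or used as seeds).
#' @return a sorted character vector of two genes, or `NULL` when no
#'   eligible edge remains (the search termination condition).
#' @export
select_seed_pair <- function(net, mm, consumed = character()) {
  el <- igraph::as_data_frame(net, what = "edges")
  if (nrow(el) == 0L) return(NULL)
  free <- !(el$from %in% consumed) & !(el$to %in% consumed)
  el <- el[free, , drop = FALSE]
  if (nrow(el) == 0L) return(NULL)
  counts <- colSums(mm)
  # exact integer ingredients of the pair ECD
  u <- mapply(function(a, b) sum(mm[, a] | mm[, b]), el$from, el$to)
  t <- counts[el$from] + counts[el$to]
  a <- pmin(el$from, el$to)
  b <- pmax(el$from, el$to)
  best <- 1L
  for (i in seq_len(nrow(el))[-1L]) {
    if (ecd_gt(u[i], t[i], u[best], t[best])) { best <- i; next }
    if (ecd_gt(u[best], t[best], u[i], t[i])) next
    if (ed_gt(u[i], t[i], u[best], t[best])) { best <- i; next }
    if (ed_gt(u[best], t[best], u[i], t[i])) next
    if (a[i] < a[best] || (a[i] == a[best] && b[i] < b[best])) best <- i
  }
  c(a[best], b[best])
}

#' Grow a pathway candidate from a seed pair
#'
#' Greedy local search maximizing the exclusivity-coverage degree.  From
#' the current set V it evaluates every external network neighbor as an
#' addition and every member (seeds included) as a removal; a move is
#' admissible iff it strictly increases ECD and leaves the set's exclusive
#' degree strictly above `lambda`.  The best admissible move (highest ECD,
#' ties by higher ED then smallest gene symbol) is applied, and the search
#' stops at local optimality.  Each accepted move strictly increases ECD,
#' which is bounded by 1 over a finite state space, so the search halts.
#'
#' Addition candidates may include genes already absorbed by earlier grown
#' sets — this is what lets reported pathways overlap; only seeding is
#' restricted to unconsumed genes.
#'
#' All ECD/ED comparisons are done by exact integer cross-multiplication of
#' the underlying count fractions, so there is no floating-point livelock.
#'
#' @param net a `gene_network`.
#' @param mm the [mutation_matrix] the network was built from.
#' @param seeds character vector of two genes joined by a network edge.
#' @param params an [nbm_params] object (only `lambda` is used here).
#' @return a [pathway_candidate], locally optimal under single add/remove
#'   moves.
#' @export
grow_from_seeds <- function(net, mm, seeds, params = nbm_params()) {
  stopifnot(length(seeds) == 2L)
  vn <- igraph::V(net)$name
  if (!all(seeds %in% vn))
    stop("seed gene(s) not in network: ",
         paste(setdiff(seeds, vn), collapse = ", "), call. = FALSE)
  if (!igraph::are_adjacent(net, seeds[1L], seeds[2L]))
    stop("seed genes ", seeds[1L], " and ", seeds[2L],
         " are not connected in the network", call. = FALSE)
  check_genes(mm, vn)
  counts <- colSums(mm)
  lambda <- params$lambda

  V <- seeds
  cover <- rowSums(mm[, V, drop = FALSE])  # per-patient multiplicity over V
  u <- sum(cover > 0L)
  t <- sum(counts[V])

  repeat {
    nbr <- unique(unlist(lapply(V, function(v) igraph::neighbors(net, v)$name)))
    additions <- setdiff(nbr, V)
    removals <- if (length(V) > 1L) V else character(0)

    cand_gene <- c(additions, removals)
    if (length(cand_gene) == 0L) break
    is_add <- c(rep(TRUE, length(additions)), rep(FALSE, length(removals)))
    cu <- integer(length(cand_gene))
    ct <- numeric(length(cand_gene))
    for (i in seq_along(cand_gene)) {
      g <- cand_gene[i]
      col <- mm[, g]
      if (is_add[i]) {
        cu[i] <- u + sum(col == 1L & cover == 0L)
        ct[i] <- t + counts[[g]]
      } else {
        cu[i] <- u - sum(col == 1L & cover == 1L)
        ct[i] <- t - counts[[g]]
      }
    }
    ok <- ct > 0 & cu > 0 &
      ed_above_lambda(cu, ct, lambda) &
      mapply(ecd_gt, cu, ct, MoreArgs = list(u2 = u, t2 = t))
    if (!any(ok)) break
    idx <- which(ok)
    best <- idx[1L]
    for (i in idx[-1L]) {
      if (ecd_gt(cu[i], ct[i], cu[best], ct[best])) { best <- i; next }
      if (ecd_gt(cu[best], ct[best], cu[i], ct[i])) next
      if (ed_gt(cu[i], ct[i], cu[best], ct[best])) { best <- i; next }
      if (ed_gt(cu[best], ct[best], cu[i], ct[i])) next
      if (cand_gene[i] < cand_gene[best]) best <- i
    }
    g <- cand_gene[best]
    if (is_add[best]) {
      V <- c(V, g)
      cover <- cover + mm[, g]
    } else {
      V <- setdiff(V, g)
      cover <- cover - mm[, g]
    }
    u <- cu[best]
    t <- ct[best]
  }
  pathway_candidate(mm, V)
}

#' Run the full driver-pathway detection pipeline
#'
#' Applies the gene-frequency pre-filter, builds the exclusivity network
#' at `lambda`, then repeatedly seeds on the free gene pair with the
#' highest pairwise ECD and grows each seed pair to local optimality with
#' [grow_from_seeds()].  Genes of every grown set and its seeds are marked
#' consumed (whether or not the set survives filtering) so the seed loop
#' terminates.  Finally, candidates with fewer than `min_set_size` genes
#' or coverage degree below `delta` are discarded, duplicates are merged,
#' and surviving pathways are ordered by decreasing ECD.
#'
#' Reported pathways may share genes: growth absorbs any network neighbor,
#' consumed or not.
#'
#' @param mm a raw [mutation_matrix].
#' @param params an [nbm_params] object.
#' @return an `nbm_result`: list with elements `pathways` (list of
#'   [pathway_candidate], decreasing ECD), `discarded` (list of candidates
#'   with a `discard_reason` of `"too-small"` or `"low-coverage"`),
#'   `seeds_used` (list of seed pairs in selection order), `params`, and
#'   `n_patients`.
#' @export
run_nbm <- function(mm, params = nbm_params()) {
  stopifnot(inherits(mm, "mutation_matrix"), inherits(params, "nbm_params"))
  empty <- structure(list(pathways = list(), discarded = list(),
                          seeds_used = list(), params = params,
                          n_patients = nrow(mm)),
                     class = "nbm_result")
  filtered <- tryCatch(
    filter_by_frequency(mm, params$min_gene_fraction),
    error = function(e) NULL)
  if (is.null(filtered)) {
    warning("no gene passes the frequency filter; returning empty result",
            call. = FALSE)
    return(empty)
  }
  net <- build_network(filtered, params$lambda)
  if (igraph::ecount(net) == 0L) {
    warning("gene network has no edges at lambda = ", params$lambda,
            "; returning empty result", call. = FALSE)
    return(empty)
  }

  consumed <- character(0)
  candidates <- list()
  seeds_used <- list()
  repeat {
    seeds <- select_seed_pair(net, filtered, consumed)
    if (is.null(seeds)) break
    cand <- grow_from_seeds(net, filtered, seeds, params)
    candidates[[length(candidates) + 1L]] <- cand
    seeds_used[[length(seeds_used) + 1L]] <- seeds
    consumed <- union(consumed, union(cand$genes, seeds))
  }

  kept <- list()
  discarded <- list()
  seen <- character(0)
  for (cand in candidates) {
    if (cand$size < params$min_set_size) {
      cand$discard_reason <- "too-small"
      discarded[[length(discarded) + 1L]] <- cand
    } else if (cand$cd < params$delta) {
      cand$discard_reason <- "low-coverage"
      discarded[[length(discarded) + 1L]] <- cand
    } else {
      key <- paste(cand$genes, collapse = ";")
      if (!(key %in% seen)) {   # identical sets reported once
        seen <- c(seen, key)
        kept[[length(kept) + 1L]] <- cand
      }
    }
  }
  if (length(kept) > 1L) {
    ecds <- vapply(kept, `[[`, 0, "ecd")
    keys <- vapply(kept, function(p) paste(p$genes, collapse = ";"), "")
    kept <- kept[order(-ecds, keys, method = "radix")]
  }
  structure(list(pathways = kept, discarded = discarded,
                 seeds_used = seeds_used, params = params,
                 n_patients = nrow(mm)),
            class = "nbm_result")
}

#' @export
print.nbm_result <- function(x, ...) {
  cat(sprintf("nbm_result: %d driver pathway(s), %d candidate(s) discarded\n",
              length(x$pathways), length(x$discarded)))
  for (i in seq_along(x$pathways)) {
    p <- x$pathways[[i]]
    cat(sprintf("  %d. {%s}  ED = %.4f  CD = %.4f  ECD = %.4f\n",
                i, paste(p$genes, collapse = ", "), p$ed, p$cd, p$ecd))
  }
  invisible(x)
}

#' Tabulate an nbm_result
#'
#' @param x an `nbm_result`.
#' @param row.names,optional,... passed for S3 compatibility; unused.
#' @return a data.frame with one row per reported pathway: rank, genes
#'   (semicolon-joined), size, ed, cd, ecd, covered patients.
#' @export
as.data.frame.nbm_result <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  if (length(x$pathways) == 0L)
    return(data.frame(rank = integer(0), genes = character(0),
                      size = integer(0), ed = numeric(0), cd = numeric(0),
                      ecd = numeric(0), covered_patients = integer(0),
                      stringsAsFactors = FALSE))
  data.frame(
    rank = seq_along(x$pathways),
    genes = vapply(x$pathways, function(p) paste(p$genes, collapse = ";"), ""),
    size = vapply(x$pathways, `[[`, 0L, "size"),
    ed = vapply(x$pathways, `[[`, 0, "ed"),
    cd = vapply(x$pathways, `[[`, 0, "cd"),
    ecd = vapply(x$pathways, `[[`, 0, "ecd"),
    covered_patients = vapply(x$pathways, `[[`, 0L, "n_covered"),
    stringsAsFactors = FALSE
  )
}

#' Permutation-based empirical significance of a candidate
#'
#' A plumbing-level significance estimate (no external annotation service):
#' each permutation independently shuffles every candidate gene's column,
#' preserving per-gene mutation counts, and recomputes the ECD of the same
#' gene set.  The add-one estimator
#' `p = (1 + #\{ECD* >= ECD_obs\}) / (1 + n_permutations)` is returned, so
#' p is never exactly 0.
#'
#' @param mm a [mutation_matrix].
#' @param candidate a [pathway_candidate] or a character vector of genes.
#' @param n_permutations number of permutations (>= 1); default 1000.
#' @param seed integer seed for reproducibility; `NULL` leaves the RNG
#'   state alone.
#' @return the empirical p-value, a single number in (0, 1].
#' @export
permutation_pvalue <- function(mm, candidate, n_permutations = 1000L,
                               seed = NULL) {
  genes <- if (inherits(candidate, "pathway_candidate")) candidate$genes
           else as.character(candidate)
  stopifnot(n_permutations >= 1L)
  cnt <- set_counts(mm, genes)
  if (cnt$total == 0L) stop("candidate has no mutations", call. = FALSE)
  m <- nrow(mm)
  obs <- cnt$union^2 / (m * cnt$total)
  counts <- colSums(mm)[genes]
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  hits <- 0L
  for (i in seq_len(n_permutations)) {
    tab <- integer(m)
    for (cg in counts) {
      idx <- sample.int(m, cg)
      tab[idx] <- tab[idx] + 1L
    }
    u_star <- sum(tab > 0L)
    ecd_star <- u_star^2 / (m * cnt$total)
    if (ecd_star >= obs) hits <- hits + 1L
  }
  (1 + hits) / (1 + n_permutations)
}
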