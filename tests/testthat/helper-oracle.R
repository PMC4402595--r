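# Independent brute-force metric oracle built directly from patient-ID set
# arithmetic (union of per-gene coverage sets), used to cross-check the
# count-based implementation.  Kept deliberately naive.

oracle_gamma <- function(mm, g) rownames(mm)[mm[, g] == 1L]

oracle_metrics <- function(mm, gene_set) {
  sets <- lapply(gene_set, oracle_gamma, mm = mm)
  un <- unique(unlist(sets))
  total <- sum(lengths(sets))
  m <- nrow(mm)
  list(union = length(un), total = total,
       ed = length(un) / total,
       cd = length(un) / m,
       ecd = length(un)^2 / (m * total))
}

# random binary mutation matrix with guaranteed valid dimnames
random_mm <- function(m, n, p = 0.3) {
  mat <- matrix(rbinom(m * n, 1L, p), m, n,
                dimnames = list(sprintf("p%03d", seq_len(m)),
                                sprintf("g%03d", seq_len(n))))
  mutation_matrix(mat)
}

# small fixed matrix used across several files:
# Gamma(a)={p1,p6,p8}, Gamma(b)={p5}, Gamma(c)={p3,p7,p8}, Gamma(d)={p1,p5,p7}
toy4 <- function() {
  mat <- matrix(0L, 8, 4,
                dimnames = list(paste0("p", 1:8), c("a", "b", "c", "d")))
  mat[cbind(c(1, 6, 8), 1)] <- 1L
  mat[5, 2] <- 1L
  mat[cbind(c(3, 7, 8), 3)] <- 1L
  mat[cbind(c(1, 5, 7), 4)] <- 1L
  mutation_matrix(mat)
}

# canonical string form of a network's edge set, for subset comparisons
edge_keys <- function(net) {
  el <- igraph::as_data_frame(net, what = "edges")
  if (nrow(el) == 0L) return(character(0))
  sort(paste(pmin(el$from, el$to), pmax(el$from, el$to), sep = "|"))
}

# exhaustive audit that a gene set is locally optimal under single
# add/remove moves with the strict admissibility rule (ECD must increase,
# ED must stay strictly above lambda); uses the public metric functions,
# not the incremental bookkeeping of the growth loop
admissible_improving_moves <- function(net, mm, gene_set, lambda) {
  base_ecd <- ecd(mm, gene_set)
  nbrs <- setdiff(
    unique(unlist(lapply(intersect(gene_set, igraph::V(net)$name),
                         function(v) igraph::neighbors(net, v)$name))),
    gene_set)
  moves <- character(0)
  for (g in nbrs) {
    v2 <- c(gene_set, g)
    if (ecd(mm, v2) > base_ecd && exclusive_degree(mm, v2) > lambda)
      moves <- c(moves, paste0("+", g))
  }
  if (length(gene_set) > 1L) {
    for (g in gene_set) {
      v2 <- setdiff(gene_set, g)
      if (sum(mm[, v2, drop = FALSE]) == 0L) next
      if (ecd(mm, v2) > base_ecd && exclusive_degree(mm, v2) > lambda)
        moves <- c(moves, paste0("-", g))
    }
  }
  moves
}

# set-of-sets equality between reported pathways and ground truth
recovers_exactly <- function(result, truth) {
  found <- lapply(result$pathways, `[[`, "genes")
  want <- lapply(truth$pathways, sort)
  length(found) == length(want) &&
    all(vapply(want, function(p)
      any(vapply(found, identical, TRUE, p)), TRUE))
}
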