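test_that("seed selection maximizes pairwise ECD among unconsumed genes", {
  # toy4: Gamma(a)={p1,p6,p8}, Gamma(b)={p5}, Gamma(c)={p3,p7,p8},
  # Gamma(d)={p1,p5,p7}; m = 8
  mm <- toy4()
  net <- build_network(mm, 0.5)
  # pair ECDs: (a,b) 16/32, (a,c) 25/48, (a,d) 25/48, (b,c) 16/32,
  # (b,d) 9/32, (c,d) 25/48; the 25/48 tie also ties on ED = 5/6 and is
  # broken to the lexicographically smallest pair
  expect_identical(select_seed_pair(net, mm), c("a", "c"))
  # consuming 'a' removes its edges from consideration
  expect_identical(select_seed_pair(net, mm, consumed = "a"), c("c", "d"))
  # single-edge network returns its only pair
  mat <- matrix(c(1, 0, 0, 1), 2, 2,
                dimnames = list(c("p1", "p2"), c("g1", "g2")))
  net1 <- build_network(mutation_matrix(mat), 0.95)
  expect_identical(select_seed_pair(net1, mutation_matrix(mat)), c("g1", "g2"))
  # all nodes consumed -> termination condition
  expect_null(select_seed_pair(net1, mutation_matrix(mat),
                               consumed = c("g1", "g2")))
})

test_that("seed selection prefers the higher pairwise ECD", {
  # two disjoint edges with different pair ECDs
  mat <- matrix(0L, 10, 4,
                dimnames = list(sprintf("p%02d", 1:10), c("w", "x", "y", "z")))
  mat[1:4, "w"] <- 1L; mat[5:9, "x"] <- 1L   # ECD(w,x) = 81/90
  mat[1:2, "y"] <- 1L; mat[3:4, "z"] <- 1L   # ECD(y,z) = 16/40
  mm <- mutation_matrix(mat)
  net <- build_network(mm, 0.9)
  expect_identical(select_seed_pair(net, mm), c("w", "x"))
})

test_that("growth stops at the seed pair when every extension breaks exclusivity", {
  # g3 duplicates g1's coverage, so any extension drives ED to 2/3
  mat <- matrix(c(1, 1, 0, 0,
                  0, 0, 1, 1,
                  1, 1, 0, 0), 4, 3,
                dimnames = list(paste0("p", 1:4), c("g1", "g2", "g3")))
  mm <- mutation_matrix(mat)
  net <- build_network(mm, 0.6)
  pc <- grow_from_seeds(net, mm, c("g1", "g2"), nbm_params(lambda = 0.95))
  expect_identical(pc$genes, c("g1", "g2"))
  expect_identical(pc$ed, 1)
  expect_identical(pc$cd, 1)
})

test_that("growth can eject a seed gene when removal improves ECD", {
  # hand-verified trace on toy4 with lambda = 0.5, seeds {b, d}:
  #   {b,d}: u=3, t=4, ECD = 9/32
  #   best admissible move adds a (ECD 25/56, ties with c broken to a)
  #   {a,b,d}: removing b gives {a,d} with ECD 25/48 > 36/80 of adding c
  #   {a,d}: u=5, t=6; no admissible move remains
  mm <- toy4()
  net <- build_network(mm, 0.5)
  pc <- grow_from_seeds(net, mm, c("b", "d"), nbm_params(lambda = 0.5))
  expect_identical(pc$genes, c("a", "d"))
  expect_identical(pc$ed, 5 / 6)
  expect_identical(pc$ecd, 25 / 48)
  expect_false("b" %in% pc$genes)
})

test_that("growth from two implanted-pathway seeds recovers the whole pathway", {
  sim <- simulate_mutations(q = 0, seed = 4)
  filtered <- filter_by_frequency(sim$matrix, 0.05)
  net <- build_network(filtered, 0.95)
  p1 <- sim$truth$pathways[[1]]
  pc <- grow_from_seeds(net, filtered, p1[1:2], nbm_params())
  expect_identical(pc$genes, sort(p1))
  expect_identical(pc$ed, 1)
  expect_identical(pc$cd, 0.95)
  # each intermediate state had an admissible move; final state has none
  expect_length(admissible_improving_moves(net, filtered, pc$genes, 0.95), 0L)
})

test_that("growth rejects disconnected or unknown seeds", {
  mm <- toy4()
  net <- build_network(mm, 0.5)
  expect_error(grow_from_seeds(net, mm, c("b", "nope"), nbm_params()),
               "not in network")
  # b and c are not adjacent at lambda = 0.9 (ED(b,c) = 1 though: check at 0.5)
  mat <- matrix(0L, 6, 3, dimnames = list(paste0("p", 1:6), c("x", "y", "z")))
  mat[1:2, "x"] <- 1L; mat[3:4, "y"] <- 1L; mat[cbind(c(1, 3), 3)] <- 1L
  mm2 <- mutation_matrix(mat)
  net2 <- build_network(mm2, 0.9)   # only (x,y) edge survives
  expect_error(grow_from_seeds(net2, mm2, c("x", "z"), nbm_params()),
               "not in network|not connected")
})

test_that("full pipeline recovers implanted pathways with correct coverage", {
  sim <- simulate_mutations(q = 0, seed = 8)
  res <- run_nbm(sim$matrix)
  expect_true(recovers_exactly(res, sim$truth))
  expect_identical(vapply(res$pathways, `[[`, 0, "ed"), rep(1, 5))
  expect_identical(vapply(res$pathways, `[[`, 0, "cd"),
                   c(0.95, 0.85, 0.75, 0.65, 0.55))
  # ordered by decreasing ECD
  ecds <- vapply(res$pathways, `[[`, 0, "ecd")
  expect_identical(ecds, sort(ecds, decreasing = TRUE))
  # result table mirrors the pathway list
  tab <- as.data.frame(res)
  expect_identical(nrow(tab), 5L)
  expect_identical(tab$covered_patients, c(285L, 255L, 225L, 195L, 165L))
})

test_that("co-occurring matrices yield an empty result with a warning", {
  dense <- mutation_matrix(matrix(1L, 6, 4,
    dimnames = list(paste0("p", 1:6), paste0("g", 1:4))))
  expect_warning(res <- run_nbm(dense), "no edges")
  expect_length(res$pathways, 0L)
  # nothing passes the frequency filter
  sparse <- mutation_matrix(matrix(0L, 50, 3,
    dimnames = list(sprintf("p%02d", 1:50), paste0("g", 1:3))) )
  sparse[1, 1] <- 1L
  class(sparse) <- c("mutation_matrix", "matrix", "array")
  expect_warning(res2 <- run_nbm(sparse), "frequency filter")
  expect_length(res2$pathways, 0L)
})

test_that("second-step filter discards small and low-coverage candidates", {
  sim <- simulate_mutations(q = 0, seed = 12)
  # delta above 0.55 discards the shallowest implanted pathway
  res <- run_nbm(sim$matrix, nbm_params(delta = 0.6))
  expect_length(res$pathways, 4L)
  reasons <- vapply(res$discarded, `[[`, "", "discard_reason")
  expect_true("low-coverage" %in% reasons)
  # min_set_size above 5 discards everything
  res6 <- run_nbm(sim$matrix, nbm_params(min_set_size = 6L))
  expect_length(res6$pathways, 0L)
  expect_true(all(vapply(res6$discarded, `[[`, "", "discard_reason") ==
                    "too-small"))
})

test_that("pipeline results are deterministic and locally optimal", {
  sim <- simulate_mutations(q = 0.001, seed = 21)
  res1 <- run_nbm(sim$matrix)
  res2 <- run_nbm(sim$matrix)
  expect_identical(as.data.frame(res1), as.data.frame(res2))
  filtered <- filter_by_frequency(sim$matrix, 0.05)
  net <- build_network(filtered, 0.95)
  for (p in res1$pathways)
    expect_length(
      admissible_improving_moves(net, filtered, p$genes, 0.95), 0L)
  # every reported pathway satisfies the second-step thresholds
  for (p in res1$pathways) {
    expect_gte(p$size, 3L)
    expect_gte(p$cd, 0.3)
  }
})

test_that("growth halts on random networks and always returns a locally optimal set", {
  withr::local_seed(53)
  for (rep in 1:8) {
    mm <- random_mm(15, 8, p = 0.2)
    keep <- colSums(mm) > 0
    mm <- mm[, keep, drop = FALSE]
    if (is.null(dim(mm)) || ncol(mm) < 2) next
    lam <- 0.7
    net <- build_network(mm, lam)
    if (igraph::ecount(net) == 0) next
    seeds <- select_seed_pair(net, mm)
    pc <- grow_from_seeds(net, mm, seeds, nbm_params(lambda = lam, delta = 0))
    expect_length(admissible_improving_moves(net, mm, pc$genes, lam), 0L)
    expect_true(pc$ed > lam || identical(sort(seeds), pc$genes))
  }
})

test_that("permutation p-values are deterministic and calibrated", {
  # a perfectly exclusive, complete-coverage candidate is essentially
  # unbeatable: p stays near 1/(1+N)
  mat <- matrix(0L, 12, 3,
                dimnames = list(sprintf("p%02d", 1:12), c("g1", "g2", "g3")))
  mat[1:4, 1] <- 1L; mat[5:8, 2] <- 1L; mat[9:12, 3] <- 1L
  mm <- mutation_matrix(mat)
  p <- permutation_pvalue(mm, c("g1", "g2", "g3"), n_permutations = 200,
                          seed = 7)
  expect_identical(
    p, permutation_pvalue(mm, c("g1", "g2", "g3"), n_permutations = 200,
                          seed = 7))
  expect_lt(p, 0.05)

  # implanted pathway in noisy data is significant
  sim <- simulate_mutations(q = 0.01, seed = 33)
  filtered <- filter_by_frequency(sim$matrix, 0.05)
  p1 <- intersect(sim$truth$pathways[[1]], genes(filtered))
  pv <- permutation_pvalue(filtered, p1, n_permutations = 1000, seed = 5)
  expect_lt(pv, 0.05)
})
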