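test_that("dcg evaluates 1/log2(rank + 1) and rejects bad ranks", {
  expect_equal(dcg(1), 1)
  expect_equal(dcg(3), 0.5)
  expect_equal(dcg(7), 1 / 3)
  expect_equal(dcg(c(1, 3, 7)), c(1, 0.5, 1 / 3))
  expect_error(dcg(0), ">= 1")
  expect_error(dcg(NA), ">= 1")
})

test_that("original_ia counts lists with an associated drug inside the cutoff", {
  scores <- rbind(a = c(0, 0, 0), b = c(0, 0, 0),      # identical pair
                  far = c(1, 1, 1), lone = c(0.5, 0.5, 0.5))
  lists <- build_similarity_lists(interaction_matrix(scores))
  expect_equal(original_ia(c("a", "b"), lists, 10), 100)
  expect_equal(original_ia(c("a", "far"), lists, 1), 0)  # mutually ranked last
  expect_error(original_ia("a", lists, 10), "at least 2")
})

test_that("original_ia partial-hit case matches a hand count", {
  # d1 and d2 identical; d3 isolated: its list has no associated drug in top-1
  scores <- rbind(d1 = c(0.1, 0.1), d2 = c(0.1, 0.1), d3 = c(0.9, 0.9),
                  near3 = c(0.85, 0.85))
  lists <- build_similarity_lists(interaction_matrix(scores))
  expect_equal(original_ia(c("d1", "d2", "d3"), lists, 1), 100 * 2 / 3)
})

test_that("loo_rank equals its definition and the brute-force oracle", {
  # zero-noise cluster: withheld drug identical to the seeds -> rank 1
  scores <- rbind(a = c(0.2, 0.8), b = c(0.2, 0.8), c = c(0.2, 0.8),
                  u = c(0.9, 0.1), v = c(0.6, 0.4))
  lists <- build_similarity_lists(interaction_matrix(scores))
  expect_equal(loo_rank(c("a", "b", "c"), "a", lists, 10), 1L)
  expect_error(loo_rank(c("a", "b"), "c", lists, 10), "not associated")

  for (seed in 1:8) {
    m <- random_matrix(6, 4, 200 + seed)
    lists <- build_similarity_lists(m)
    drugs <- sample(rownames(m), 3)
    co <- sample(1:4, 1)
    expect_equal(loo_rank(drugs, drugs[1], lists, co),
                 oracle_loo_rank(drugs, drugs[1], m, co))
  }
})

test_that("benchmark_mapping recovers a zero-noise pair perfectly", {
  scores <- rbind(a = c(0, 1), b = c(0, 1), x = c(1, 0), y = c(0.4, 0.6))
  m <- interaction_matrix(scores)
  mapping <- indication_mapping(
    data.frame(drug_id = c("a", "b"), indication_id = "i1"),
    drug_library = rownames(m))
  bm <- benchmark_mapping(mapping, build_similarity_lists(m), 10)
  expect_equal(bm$summary$naia_top10, 100)
  expect_equal(bm$summary$nndcg_overall, 1)
})

test_that("rank cutoff equal to the library size yields nAIA 100", {
  m <- random_matrix(10, 4, 77)
  mapping <- indication_mapping(
    data.frame(drug_id = c("c01", "c02", "c03", "c05", "c08"),
               indication_id = rep(c("i1", "i2"), c(3, 2))),
    drug_library = rownames(m))
  bm <- benchmark_mapping(mapping, build_similarity_lists(m), 3,
                          rank_cutoffs = c(2, 10))
  expect_equal(bm$summary$naia_top10, 100)
})

test_that("nIA/nNDCG are monotone in k and nNDCG(k) <= overall", {
  w <- generate_synthetic(synthetic_config(n_compounds = 30, n_proteins = 40,
                                           n_indications = 4,
                                           drugs_per_indication = 3,
                                           noise_sd = 0.3, seed = 12))
  bm <- benchmark_mapping(w$mapping, build_similarity_lists(w$matrix), 5,
                          rank_cutoffs = c(3, 10, 25))
  pi <- bm$per_indication
  expect_true(all(pi$nia_top3 <= pi$nia_top10 & pi$nia_top10 <= pi$nia_top25))
  for (k in c("nndcg_top3", "nndcg_top10", "nndcg_top25"))
    expect_true(all(pi[[k]] <= pi$nndcg_overall + 1e-12))
  # aggregate = unweighted mean over indications
  expect_equal(bm$summary$naia_top10, mean(pi$nia_top10))
  # equality with overall iff every rank is inside k
  ranks <- bm$per_association$final_rank
  expect_equal(bm$summary$nndcg_top25 == bm$summary$nndcg_overall,
               all(ranks <= 25))
})

test_that("benchmark results are invariant to association row order", {
  w <- generate_synthetic(synthetic_config(n_compounds = 24, n_proteins = 30,
                                           n_indications = 3,
                                           drugs_per_indication = 4,
                                           noise_sd = 0.2, seed = 5))
  lists <- build_similarity_lists(w$matrix)
  assoc <- w$mapping$associations
  set.seed(1); shuf <- assoc[sample(nrow(assoc)), ]
  m2 <- indication_mapping(shuf, w$mapping$drug_library)
  b1 <- benchmark_mapping(w$mapping, lists, 6)
  b2 <- benchmark_mapping(m2, lists, 6)
  expect_equal(b1$summary, b2$summary)
})

test_that("indications with fewer than two drugs are skipped, not scored", {
  m <- random_matrix(8, 4, 9)
  mapping <- indication_mapping(
    data.frame(drug_id = c("c01", "c02", "c03"),
               indication_id = c("big", "big", "solo")),
    drug_library = rownames(m))
  lists <- build_similarity_lists(m)
  bm <- benchmark_mapping(mapping, lists, 3)
  expect_equal(bm$skipped, "solo")
  expect_equal(bm$per_indication$indication_id, "big")
  solo_only <- indication_mapping(
    data.frame(drug_id = "c01", indication_id = "solo"),
    drug_library = rownames(m))
  expect_error(benchmark_mapping(solo_only, lists, 3), "no benchmarkable")
})

test_that("hypergeometric control nAIA is 100 k / N", {
  expect_equal(hypergeom_control_naia(100, 10), 10)
  expect_equal(hypergeom_control_naia(50, 50), 100)
  expect_equal(hypergeom_control_naia(2449, 10), 100 * 10 / 2449)
  expect_error(hypergeom_control_naia(10, 11), "rank_cutoff")
})

test_that("randomized control is deterministic given its seed", {
  w <- generate_synthetic(synthetic_config(n_compounds = 20, n_proteins = 15,
                                           n_indications = 3,
                                           drugs_per_indication = 3,
                                           noise_sd = 0.1, seed = 3))
  r1 <- randomized_control_nndcg(w$matrix, w$mapping, 5, n_reps = 2, seed = 9)
  r2 <- randomized_control_nndcg(w$matrix, w$mapping, 5, n_reps = 2, seed = 9)
  expect_identical(r1, r2)
  r3 <- randomized_control_nndcg(w$matrix, w$mapping, 5, n_reps = 2, seed = 10)
  expect_false(identical(r1$mean, r3$mean))
  expect_equal(nrow(r1$replicates), 2L)
})
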