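test_that("spearman handles monotone, reversed and tied inputs", {
  x <- c(2, 5, 9, 14, 20)
  expect_equal(spearman(x, exp(x)), 1)
  expect_equal(spearman(x, rev(x)), -1)
  # tie case: ranks (1,2,3,4) vs (1.5,1.5,3,4)
  expect_equal(spearman(c(1, 2, 3, 4), c(1, 1, 3, 4)), 4.5 / sqrt(22.5))
  expect_error(spearman(c(1, 2, 3), c(2, 2, 2)), "constant")
  expect_error(spearman(1:2, 1:2), "length >= 3")
})

test_that("spearman agrees with stats::cor(method = 'spearman') to 1e-12", {
  set.seed(17)
  for (i in 1:20) {
    x <- sample(1:6, 15, replace = TRUE) + runif(15) * (i %% 2)  # ties half the time
    y <- sample(1:6, 15, replace = TRUE) + runif(15) * (i %% 2)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman(x, y), cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("chemical similarity features match hand enumeration", {
  # pairwise Tanimotos: AB = 0.5, AC = 0.2, BC = 0.1 by construction
  A <- fingerprint(c(1, 2, 4, 10, 20), 64)
  B <- fingerprint(c(1, 2, 3, 4), 64)
  C <- fingerprint(c(4, 10, 11, 12, 13, 14, 15), 64)
  expect_equal(tanimoto(A, B), 0.5)
  expect_equal(tanimoto(A, C), 0.2)
  expect_equal(tanimoto(B, C), 0.1)
  f <- chem_similarity_features(list(A, B, C))
  expect_equal(f$chem_max_pair, 0.5)
  expect_equal(f$chem_avg_avg, mean(c(0.35, 0.3, 0.15)))
  expect_equal(f$chem_avg_max, mean(c(0.5, 0.5, 0.2)))

  # degenerate pair: all three features equal the single Tanimoto
  f2 <- chem_similarity_features(list(A, B))
  expect_equal(unlist(f2, use.names = FALSE), rep(0.5, 3))
  # identical fingerprints
  f3 <- chem_similarity_features(list(A, A, A))
  expect_equal(unlist(f3, use.names = FALSE), rep(1, 3))
  expect_error(chem_similarity_features(list(A)), "at least 2")
})

test_that("chem features are invariant to drug order", {
  set.seed(23)
  fps <- lapply(1:5, function(i) fingerprint(sample(0:127, 12), 128))
  f1 <- chem_similarity_features(fps)
  f2 <- chem_similarity_features(rev(fps))
  expect_equal(f1, f2)
})

test_that("correlate_performance wires metrics to features and filters", {
  results <- data.frame(indication_id = sprintf("i%d", 1:6),
                        n_drugs = c(2, 3, 5, 6, 8, 2),
                        nia_top10 = c(0, 10, 30, 35, 60, 5))
  features <- data.frame(indication_id = sprintf("i%d", 1:6),
                         n_drugs = c(2, 3, 5, 6, 8, 2),
                         ia_top10 = c(1, 12, 28, 36, 58, 4),  # same order as nIA
                         chem_avg_max = c(0.9, 0.3, 0.5, 0.2, 0.8, 0.1))
  tab <- correlate_performance(results, features)
  expect_setequal(unique(tab$feature), c("n_drugs", "ia_top10", "chem_avg_max"))
  expect_equal(tab$rho[tab$feature == "ia_top10"], 1)  # same rank order
  expect_equal(unique(tab$n), 6L)
  tab5 <- correlate_performance(results, features, min_drugs = 5)
  expect_equal(unique(tab5$n), 3L)
  expect_error(correlate_performance(results, features, min_drugs = 8),
               "fewer than 3")
})

test_that("recovery correlates positively with cluster tightness", {
  # indications with tighter chemical clusters get tighter signature clusters
  # too, so the withheld drug is easier to recover
  set.seed(41)
  n_ind <- 8
  noise <- seq(0.02, 0.45, length.out = n_ind)
  nP <- 40
  rows <- list(); fps <- list(); assoc <- list()
  shared_frac <- seq(0.9, 0.05, length.out = n_ind)
  for (i in seq_len(n_ind)) {
    arch <- runif(nP)
    pool <- sample(0:511, 24)
    for (d in 1:3) {
      id <- sprintf("i%d_d%d", i, d)
      rows[[id]] <- pmin(1, pmax(0, arch + rnorm(nP, 0, noise[i])))
      nsh <- round(24 * shared_frac[i])
      fps[[id]] <- fingerprint(c(pool[seq_len(nsh)],
                                 sample(0:511, 24 - nsh)), 512)
    }
    assoc[[i]] <- data.frame(drug_id = sprintf("i%d_d%d", i, 1:3),
                             indication_id = sprintf("ind%d", i))
  }
  m <- interaction_matrix(do.call(rbind, rows))
  mapping <- indication_mapping(do.call(rbind, assoc),
                                drug_library = rownames(m))
  lists <- build_similarity_lists(m)
  bm <- benchmark_mapping(mapping, lists, 5, rank_cutoffs = c(3, 10))
  feats <- indication_features(mapping, lists, fps, rank_cutoffs = c(3, 10))
  tab <- correlate_performance(bm$per_indication, feats)
  rho <- tab$rho[tab$metric == "nia_top3" & tab$feature == "chem_avg_max"]
  expect_gt(rho, 0)
})

test_that("compare_mappings classifies shared associations and is antisymmetric", {
  mk_result <- function(ranks, inds, n_ind_rows) {
    structure(list(
      per_indication = data.frame(indication_id = names(n_ind_rows),
                                  n_drugs = 2L, nia_top10 = unname(n_ind_rows)),
      per_association = data.frame(indication_id = inds,
                                   withheld = names(ranks),
                                   final_rank = unname(ranks))),
      class = "benchmark_result")
  }
  ra <- mk_result(c(enz = 44L, d2 = 3L, d3 = 9L),
                  c("pc_a", "x_a", "x_a"), c(pc_a = 10, x_a = 50))
  rb <- mk_result(c(enz = 7L, d2 = 8L, d3 = 9L),
                  c("pc_b", "x_b", "x_b"), c(pc_b = 30, x_b = 50))
  match_tab <- data.frame(indication_a = c("pc_a", "x_a"),
                          indication_b = c("pc_b", "x_b"))
  cmp <- compare_mappings(ra, rb, match_tab, top_cutoffs = c(10, 100))
  expect_equal(unname(cmp$counts), c(1L, 1L, 1L))
  enz <- cmp$associations[cmp$associations$withheld == "enz", ]
  expect_equal(enz$class, "better_B")
  expect_equal(enz$final_rank_a - enz$final_rank_b, 37L)
  expect_equal(sum(cmp$counts), nrow(cmp$associations))
  expect_equal(cmp$indication_deltas$delta_nia_top10, c(-20, 0))

  # identity comparison: everything equal
  match_self <- data.frame(indication_a = c("pc_a", "x_a"),
                           indication_b = c("pc_a", "x_a"))
  cmp_id <- compare_mappings(ra, ra, match_self)
  expect_equal(unname(cmp_id$counts), c(0L, 0L, 3L))
  expect_equal(cmp_id$mean_rank_delta, 0)

  # antisymmetry under swapping A and B
  rev_match <- data.frame(indication_a = match_tab$indication_b,
                          indication_b = match_tab$indication_a)
  cmp_rev <- compare_mappings(rb, ra, rev_match, top_cutoffs = c(10, 100))
  expect_equal(unname(cmp_rev$counts[c("better_A", "better_B")]),
               unname(cmp$counts[c("better_B", "better_A")]))
  expect_equal(cmp_rev$mean_rank_delta, -cmp$mean_rank_delta)

  bad <- data.frame(indication_a = c("pc_a", "pc_a"),
                    indication_b = c("pc_b", "x_b"))
  expect_error(compare_mappings(ra, rb, bad), "one-to-one")
})
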