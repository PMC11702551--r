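# Independent brute-force oracles: plain loops, no shared code with the
# package beyond the public constructors they validate against.

oracle_dist <- function(a, b) sqrt(mean((a - b)^2))

# per-compound list as data.frame(compound_id, distance, rank), sorted by
# ascending distance then ascending id (radix order)
oracle_lists <- function(mat) {
  ids <- rownames(mat)
  out <- list()
  for (i in ids) {
    others <- setdiff(ids, i)
    d <- vapply(others, function(j) oracle_dist(mat[i, ], mat[j, ]), 0)
    o <- order(d, others, method = "radix")
    out[[i]] <- data.frame(compound_id = others[o], distance = unname(d[o]),
                           rank = seq_along(others),
                           stringsAsFactors = FALSE)
  }
  out
}

# first-principles consensus ordering over `candidates`
oracle_consensus <- function(seeds, mat, cutoff, candidates = rownames(mat)) {
  ol <- oracle_lists(mat)
  rows <- list()
  for (cand in candidates) {
    ranks <- c(); dists <- c()
    for (s in seeds) {
      hit <- ol[[s]][ol[[s]]$compound_id == cand, ]
      if (nrow(hit) == 1L) {
        ranks <- c(ranks, hit$rank); dists <- c(dists, hit$distance)
      }
    }
    within <- ranks[ranks <= cutoff]
    rows[[cand]] <- data.frame(
      compound_id = cand,
      count = length(within),
      mcr = if (length(within)) mean(within) else Inf,
      mfr = if (length(ranks)) mean(ranks) else Inf,
      mdist = if (length(dists)) mean(dists) else Inf,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$count, tab$mcr, tab$mfr, tab$mdist, tab$compound_id,
                   method = "radix"), ]
  tab$final_rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

oracle_loo_rank <- function(drugs, withheld, mat, cutoff,
                            candidates = rownames(mat)) {
  tab <- oracle_consensus(setdiff(drugs, withheld), mat, cutoff, candidates)
  tab$final_rank[tab$compound_id == withheld]
}

# random interaction matrix with distinct-enough scores
random_matrix <- function(n, p, seed) {
  set.seed(seed)
  interaction_matrix(matrix(runif(n * p), n, p,
                            dimnames = list(sprintf("c%02d", 1:n),
                                            sprintf("p%02d", 1:p))))
}

# structureless matrix: independently permute each protein column
permute_columns <- function(mat, seed) {
  set.seed(seed)
  perm <- apply(unclass(mat), 2L, function(col) col[sample.int(length(col))])
  rownames(perm) <- rownames(mat)
  interaction_matrix(perm)
}
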