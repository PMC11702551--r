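#' Discounted cumulative gain of a single rank
#'
#' `DCG = 1 / log2(rank + 1)`. Normalization divides by the ideal DCG, which
#' for a single withheld item recovered at rank 1 equals one, so NDCG and DCG
#' coincide here.
#'
#' @param rank positive integer rank(s), 1-based.
#' @return value(s) in (0, 1].
#' @export
dcg <- function(rank) {
  if (any(is.na(rank)) || any(rank < 1)) stop("rank must be >= 1")
  1 / log2(rank + 1)
}

#' Original similarity-list indication accuracy (IA)
#'
#' The earlier benchmarking protocol assessed the similarity lists directly:
#' for each associated drug, test whether at least one *other* associated
#' drug appears in its list at rank `<=` rank_cutoff. IA is the percentage of
#' associated drugs whose list passes.
#'
#' @param drugs character vector of associated drugs (at least 2).
#' @param lists a [build_similarity_lists()] result.
#' @param rank_cutoff positive integer rank threshold.
#' @return percentage in \[0, 100\].
#' @export
original_ia <- function(drugs, lists, rank_cutoff) {
  drugs <- unique(as.character(drugs))
  if (length(drugs) < 2L)
    stop("indication accuracy requires at least 2 associated drugs")
  rk <- lists$rank[drugs, drugs, drop = FALSE]
  hits <- apply(rk, 1L, function(r) any(r <= rank_cutoff, na.rm = TRUE))
  100 * mean(hits)
}

#' Leave-one-out rank of a withheld drug
#'
#' Withholds one drug from an indication, builds the consensus list from the
#' remaining associated drugs, and returns the withheld drug's final rank.
#'
#' @param drugs the indication's associated drugs (at least 2).
#' @param withheld one of `drugs`.
#' @param lists a [build_similarity_lists()] result.
#' @param cutoff similarity-list cutoff, see [rank_candidates()].
#' @param candidates candidate universe (default: all compounds in `lists`).
#' @return the withheld drug's 1-based final rank.
#' @export
loo_rank <- function(drugs, withheld, lists, cutoff, candidates = NULL) {
  drugs <- unique(as.character(drugs))
  if (!withheld %in% drugs) stop("withheld drug is not associated")
  if (length(drugs) < 2L) stop("leave-one-out requires at least 2 drugs")
  cl <- rank_candidates(setdiff(drugs, withheld), lists, cutoff,
                        candidates = candidates)
  cl$final_rank[match(withheld, cl$compound_id)]
}

#' Leave-one-out consensus benchmark over a drug-indication mapping
#'
#' For every indication with at least two associated drugs, each drug is
#' withheld in turn and re-predicted from the remaining drugs via
#' [rank_candidates()]. Per indication and rank cutoff k:
#' \describe{
#'   \item{nIA(k)}{percentage of withheld drugs with final rank `<=` k.}
#'   \item{nNDCG(k)}{mean over withheld drugs of `1/log2(rank+1)`, with the
#'     gain set to 0 when the rank exceeds k; the overall nNDCG applies no
#'     cutoff.}
#' }
#' Aggregates (nAIA, aggregate nNDCG) are unweighted means over assessed
#' indications. Indications with fewer than two drugs in the library are
#' skipped and reported.
#'
#' @param mapping an [indication_mapping()].
#' @param lists similarity lists over (at least) the mapping's drug library.
#' @param cutoff similarity-list cutoff for the consensus protocol.
#' @param rank_cutoffs integer vector of rank cutoffs k (default 10, 25, 100).
#' @param candidates candidate universe; defaults to the mapping's drug
#'   library.
#' @param with_ia also compute the original similarity-list IA/AIA at the
#'   same rank cutoffs.
#' @return list of class `benchmark_result` with elements
#'   `summary` (nAIA/nNDCG per cutoff + overall, AIA if requested),
#'   `per_indication` (data.frame of nIA/nNDCG/IA rows),
#'   `per_association` (indication, withheld drug, final rank),
#'   `skipped` (unbenchmarkable indication ids), and the parameters used.
#' @export
benchmark_mapping <- function(mapping, lists, cutoff,
                              rank_cutoffs = c(10L, 25L, 100L),
                              candidates = NULL, with_ia = FALSE) {
  stopifnot(inherits(mapping, "indication_mapping"))
  rank_cutoffs <- sort(unique(as.integer(rank_cutoffs)))
  if (any(rank_cutoffs < 1L)) stop("rank cutoffs must be positive")
  if (is.null(candidates)) candidates <- mapping$drug_library
  by_ind <- indication_drugs(mapping)
  present <- lapply(by_ind, intersect, lists$compound_ids)
  sizes <- lengths(present)
  skipped <- names(by_ind)[sizes < 2L]
  assess <- names(by_ind)[sizes >= 2L]
  if (length(assess) == 0L) stop("no benchmarkable indication (>= 2 drugs)")

  kcols <- paste0("top", rank_cutoffs)
  per_assoc <- vector("list", length(assess))
  per_ind <- vector("list", length(assess))
  for (ii in seq_along(assess)) {
    ind <- assess[ii]
    drugs <- present[[ind]]
    ranks <- vapply(drugs, function(w)
      loo_rank(drugs, w, lists, cutoff, candidates = candidates), 0)
    per_assoc[[ii]] <- data.frame(indication_id = ind, withheld = drugs,
                                  final_rank = as.integer(ranks),
                                  stringsAsFactors = FALSE, row.names = NULL)
    row <- data.frame(indication_id = ind, n_drugs = length(drugs),
                      stringsAsFactors = FALSE)
    for (j in seq_along(rank_cutoffs)) {
      k <- rank_cutoffs[j]
      row[[paste0("nia_", kcols[j])]] <- 100 * mean(ranks <= k)
      row[[paste0("nndcg_", kcols[j])]] <- mean(ifelse(ranks <= k, dcg(ranks), 0))
    }
    row$nndcg_overall <- mean(dcg(ranks))
    if (with_ia)
      for (j in seq_along(rank_cutoffs))
        row[[paste0("ia_", kcols[j])]] <- original_ia(drugs, lists, rank_cutoffs[j])
    per_ind[[ii]] <- row
  }
  per_ind <- do.call(rbind, per_ind)
  per_assoc <- do.call(rbind, per_assoc)

  metric_cols <- setdiff(names(per_ind), c("indication_id", "n_drugs"))
  summary <- as.list(colMeans(per_ind[metric_cols]))
  names(summary) <- sub("^nia_", "naia_", names(summary))
  names(summary) <- sub("^ia_", "aia_", names(summary))

  structure(list(summary = summary, per_indication = per_ind,
                 per_association = per_assoc, skipped = skipped,
                 cutoff = cutoff, rank_cutoffs = rank_cutoffs,
                 n_candidates = length(candidates)),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result: %d indications (cutoff %d, %d candidates)\n",
              nrow(x$per_indication), x$cutoff, x$n_candidates))
  for (nm in names(x$summary))
    cat(sprintf("  %-16s %.4f\n", nm, x$summary[[nm]]))
  if (length(x$skipped))
    cat(sprintf("  skipped %d indication(s) with < 2 drugs\n",
                length(x$skipped)))
  invisible(x)
}

#' Hypergeometric control for nAIA
#'
#' Under a random total order of `n_candidates` compounds, the probability
#' that a single withheld drug lands in the top k is `k / n_candidates`
#' (hypergeometric with one success state), so the expected nAIA is
#' `100 * k / n_candidates`.
#'
#' @param n_candidates size of the candidate universe.
#' @param rank_cutoff k, with `1 <= k <= n_candidates`.
#' @return expected control nAIA as a percentage.
#' @export
hypergeom_control_naia <- function(n_candidates, rank_cutoff) {
  if (rank_cutoff < 1 || rank_cutoff > n_candidates)
    stop("rank_cutoff must lie in [1, n_candidates]")
  100 * rank_cutoff / n_candidates
}

#' Randomized-matrix control for nNDCG
#'
#' Generates structureless interaction matrices by independently permuting
#' each protein column's scores across compounds (preserving every protein's
#' score distribution), rebuilds the similarity lists, re-runs the benchmark,
#' and averages the nNDCG metrics over replicates.
#'
#' @param matrix an [interaction_matrix()].
#' @param mapping an [indication_mapping()].
#' @param cutoff similarity-list cutoff.
#' @param rank_cutoffs rank cutoffs k.
#' @param n_reps number of randomized replicates (default 10).
#' @param seed integer seed driving the permutations.
#' @return list with `mean` (named mean nNDCG per cutoff and overall) and
#'   `replicates` (one row per replicate).
#' @export
randomized_control_nndcg <- function(matrix, mapping, cutoff,
                                     rank_cutoffs = c(10L, 25L, 100L),
                                     n_reps = 10L, seed = 1L) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  rng <- make_rng(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    perm <- apply(unclass(matrix), 2L, function(col) col[rng$sample(length(col))])
    rownames(perm) <- rownames(matrix)
    pm <- interaction_matrix(perm)
    bm <- benchmark_mapping(mapping, build_similarity_lists(pm), cutoff,
                            rank_cutoffs = rank_cutoffs)
    vals <- unlist(bm$summary[grep("^nndcg_", names(bm$summary))])
    reps[[r]] <- vals
  }
  reps <- do.call(rbind, reps)
  list(mean = colMeans(reps), replicates = as.data.frame(reps))
}

# Seed-local RNG helper: keeps package randomness insulated from the caller's
# RNG state and reproducible from one integer seed.
make_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    f()
  }
  list(sample = function(n, size = n, replace = FALSE)
         with_state(function() sample.int(n, size, replace)),
       runif = function(n, min = 0, max = 1)
         with_state(function() stats::runif(n, min, max)),
       rnorm = function(n, mean = 0, sd = 1)
         with_state(function() stats::rnorm(n, mean, sd)))
}
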