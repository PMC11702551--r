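#' Grouped random split of a mapping into optimization and evaluation sets
#'
#' Indications with at least two associated drugs are shuffled with the given
#' seed and the first `round(optimization_fraction * n)` (round half up) go to
#' the optimization mapping, the rest to evaluation. All associations of an
#' indication travel together, so parameters tuned on one side are assessed on
#' indications never seen during tuning. Unbenchmarkable indications (one
#' drug) are dropped from both sides.
#'
#' @param mapping an [indication_mapping()].
#' @param optimization_fraction fraction of indications for optimization
#'   (default 0.3).
#' @param seed integer seed; the split is deterministic given the seed.
#' @return list with `optimization` and `evaluation` mappings (both share the
#'   input's drug library) and the seed used.
#' @export
split_mapping <- function(mapping, optimization_fraction = 0.3, seed = 1L) {
  if (optimization_fraction <= 0 || optimization_fraction >= 1)
    stop("optimization_fraction must be in (0, 1)")
  sizes <- table(mapping$associations$indication_id)
  inds <- names(sizes)[sizes >= 2L]
  if (length(inds) < 2L)
    stop("need at least 2 benchmarkable indications to split")
  inds <- sort(inds, method = "radix")
  rng <- make_rng(seed)
  shuffled <- inds[rng$sample(length(inds))]
  n_opt <- floor(optimization_fraction * length(inds) + 0.5)
  n_opt <- max(1L, min(length(inds) - 1L, n_opt))
  list(optimization = subset_mapping(mapping, shuffled[seq_len(n_opt)]),
       evaluation = subset_mapping(mapping, shuffled[-seq_len(n_opt)]),
       seed = as.integer(seed))
}

#' Sweep the similarity-list cutoff
#'
#' Runs [benchmark_mapping()] once per cutoff value and tabulates nAIA and
#' nNDCG per rank cutoff plus overall nNDCG.
#'
#' @param mapping an [indication_mapping()].
#' @param lists similarity lists.
#' @param cutoffs integer vector of similarity-list cutoffs (each `>= 1`).
#' @param rank_cutoffs rank cutoffs k.
#' @param candidates candidate universe passed through.
#' @return data.frame, one row per cutoff, columns `cutoff`, `naia_top<k>`,
#'   `nndcg_top<k>`, `nndcg_overall`.
#' @export
sweep_cutoffs <- function(mapping, lists, cutoffs,
                          rank_cutoffs = c(10L, 25L, 100L),
                          candidates = NULL) {
  cutoffs <- sort(unique(as.integer(cutoffs)))
  if (length(cutoffs) == 0L || any(cutoffs < 1L))
    stop("cutoffs must be positive integers")
  rows <- lapply(cutoffs, function(co) {
    bm <- benchmark_mapping(mapping, lists, co, rank_cutoffs = rank_cutoffs,
                            candidates = candidates)
    cbind(data.frame(cutoff = co), as.data.frame(bm$summary))
  })
  do.call(rbind, rows)
}

#' Optimal cutoff for one metric in a sweep table
#'
#' The optimum is the cutoff at which the metric column attains its maximum;
#' exact ties resolve to the smallest cutoff.
#'
#' @param table a [sweep_cutoffs()] result.
#' @param metric column name, e.g. `"naia_top10"` or `"nndcg_overall"`.
#' @return list with `cutoff` and `value`.
#' @export
find_optimum <- function(table, metric) {
  if (nrow(table) == 0L) stop("empty sweep table")
  if (!metric %in% names(table)) stop("unknown metric: ", metric)
  tab <- table[order(table$cutoff), , drop = FALSE]
  i <- which.max(tab[[metric]])  # first max = smallest cutoff on ties
  list(cutoff = tab$cutoff[i], value = tab[[metric]][i])
}

#' Compare the three interaction scoring types
#'
#' Builds one interaction matrix per scoring type (C, CxP, dCxP) from the
#' same fingerprints and site library, sweeps the similarity-list cutoff for
#' each, and reports the best (type, cutoff, value) per metric.
#'
#' @param fingerprints named list of [fingerprint()] objects.
#' @param site_library list of [binding_site()] records.
#' @param mapping an [indication_mapping()].
#' @param cutoffs similarity-list cutoffs to sweep (default 1..100, capped at
#'   one less than the library size).
#' @param rank_cutoffs rank cutoffs k.
#' @param protein_ids optional protein universe for [build_matrix()].
#' @return list with `best` (data.frame: metric, scoring_type, cutoff, value)
#'   and `tables` (named list of per-type sweep tables).
#' @export
compare_scoring_types <- function(fingerprints, site_library, mapping,
                                  cutoffs = 1:100,
                                  rank_cutoffs = c(10L, 25L, 100L),
                                  protein_ids = NULL) {
  types <- c("C", "CxP", "dCxP")
  cutoffs <- cutoffs[cutoffs <= length(fingerprints) - 1L]
  if (length(cutoffs) == 0L) stop("no feasible cutoff below the library size")
  tables <- lapply(types, function(ty) {
    m <- build_matrix(fingerprints, site_library, protein_ids = protein_ids,
                      type = ty)
    sweep_cutoffs(mapping, build_similarity_lists(m), cutoffs,
                  rank_cutoffs = rank_cutoffs)
  })
  names(tables) <- types
  metrics <- setdiff(names(tables[[1L]]), "cutoff")
  best <- do.call(rbind, lapply(metrics, function(me) {
    per_type <- vapply(types, function(ty) {
      opt <- find_optimum(tables[[ty]], me)
      c(opt$cutoff, opt$value)
    }, c(0, 0))
    w <- which.max(per_type[2L, ])
    data.frame(metric = me, scoring_type = types[w],
               cutoff = per_type[1L, w], value = per_type[2L, w],
               stringsAsFactors = FALSE)
  }))
  list(best = best, tables = tables)
}
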