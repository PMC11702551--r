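#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values; ties receive average ranks.
#' Benchmark metrics are far from normal, so rank correlation is the
#' appropriate association measure here.
#'
#' @param x,y numeric vectors of equal length `>= 3`, neither constant.
#' @return correlation in \[-1, 1\].
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("spearman requires equal-length vectors of length >= 3")
  if (anyNA(x) || anyNA(y)) stop("spearman inputs must not contain NA")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("correlation undefined for constant input")
  stats::cor(rx, ry, method = "pearson")
}

#' Intra-indication chemical similarity features
#'
#' Three Tanimoto summaries over an indication's associated drugs:
#' \describe{
#'   \item{chem_max_pair}{best similarity between any pair of drugs.}
#'   \item{chem_avg_avg}{per drug, the mean similarity to the other drugs,
#'     averaged over drugs (equals the mean over all unordered pairs).}
#'   \item{chem_avg_max}{per drug, the best similarity to any other drug,
#'     averaged over drugs.}
#' }
#' A high chem_avg_max with a modest chem_avg_avg marks an indication where
#' every drug has at least one close chemical partner without the whole set
#' being homogeneous.
#'
#' @param fps list of [fingerprint()] objects for one indication's drugs
#'   (at least 2).
#' @return named list with the three features, each in \[0, 1\].
#' @export
chem_similarity_features <- function(fps) {
  n <- length(fps)
  if (n < 2L) stop("chemical features require at least 2 drugs")
  sim <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      sim[i, j] <- sim[j, i] <- tanimoto(fps[[i]], fps[[j]])
  diag(sim) <- NA
  per_drug_mean <- rowMeans(sim, na.rm = TRUE)
  per_drug_max <- apply(sim, 1L, max, na.rm = TRUE)
  list(chem_max_pair = max(sim, na.rm = TRUE),
       chem_avg_avg = mean(per_drug_mean),
       chem_avg_max = mean(per_drug_max))
}

#' Feature table for every benchmarkable indication
#'
#' Assembles, per indication with at least two drugs, the indication size,
#' the original similarity-list IA at each rank cutoff, and the three
#' chemical-similarity features.
#'
#' @param mapping an [indication_mapping()].
#' @param lists similarity lists (for IA).
#' @param fingerprints named list of [fingerprint()] objects covering the
#'   mapping's drugs.
#' @param rank_cutoffs rank cutoffs k for IA.
#' @return data.frame, one row per benchmarkable indication.
#' @export
indication_features <- function(mapping, lists, fingerprints,
                                rank_cutoffs = c(10L, 25L, 100L)) {
  by_ind <- indication_drugs(mapping)
  by_ind <- by_ind[lengths(by_ind) >= 2L]
  rows <- lapply(names(by_ind), function(ind) {
    drugs <- by_ind[[ind]]
    row <- data.frame(indication_id = ind, n_drugs = length(drugs),
                      stringsAsFactors = FALSE)
    for (k in rank_cutoffs)
      row[[paste0("ia_top", k)]] <- original_ia(drugs, lists, k)
    row <- cbind(row, as.data.frame(chem_similarity_features(fingerprints[drugs])))
    row
  })
  do.call(rbind, rows)
}

#' Correlate leave-one-out performance with indication features
#'
#' Spearman correlation of per-indication nIA (each rank cutoff) against the
#' candidate explanatory features: indication size, similarity-list IA, and
#' the chemical-similarity summaries. Indications with fewer than
#' `min_drugs` drugs are removed before ranking (re-running with
#' `min_drugs = 5` isolates the effect of the many small, zero-recall
#' indications).
#'
#' @param results per-indication benchmark table
#'   (`benchmark_result$per_indication`) with `nia_top<k>` columns.
#' @param features an [indication_features()] table.
#' @param min_drugs minimum indication size retained (default 2).
#' @return data.frame with columns `metric`, `feature`, `rho`, `n`; `rho` is
#'   `NA` when either column is constant after filtering (e.g. a saturated
#'   metric).
#' @export
correlate_performance <- function(results, features, min_drugs = 2L) {
  merged <- merge(results, features, by = "indication_id",
                  suffixes = c("", ".feat"))
  if ("n_drugs.feat" %in% names(merged)) merged$n_drugs.feat <- NULL
  merged <- merged[merged$n_drugs >= min_drugs, , drop = FALSE]
  if (nrow(merged) < 3L)
    stop("fewer than 3 indications after filtering; correlation unreliable")
  metric_cols <- grep("^nia_top", names(merged), value = TRUE)
  feat_cols <- c("n_drugs", grep("^ia_top|^chem_", names(merged), value = TRUE))
  out <- expand.grid(metric = metric_cols, feature = feat_cols,
                     stringsAsFactors = FALSE)
  # a saturated metric (every indication at 100%) has no rank variation;
  # report NA rather than fail the whole table
  out$rho <- mapply(function(m, f) {
    if (stats::sd(merged[[m]]) == 0 || stats::sd(merged[[f]]) == 0)
      return(NA_real_)
    spearman(merged[[m]], merged[[f]])
  }, out$metric, out$feature)
  out$n <- nrow(merged)
  out
}

#' Compare benchmark results between two drug-indication mappings
#'
#' Two comparisons, mirroring a head-to-head assessment of two association
#' sources over a combined drug library:
#' \enumerate{
#'   \item matched indications: per-cutoff nIA difference (A minus B) for
#'     each pair in the user-supplied match table;
#'   \item shared associations: for drugs associated with matched indications
#'     in both mappings, the two final ranks are classified `better_A`
#'     (strictly smaller rank in A), `better_B`, or `equal`.
#' }
#'
#' @param results_A,results_B [benchmark_mapping()] results.
#' @param indication_match data.frame with columns `indication_a`,
#'   `indication_b`; must be one-to-one.
#' @param top_cutoffs rank cutoffs for the within-top-k counts.
#' @return list with `indication_deltas` (matched indications, nIA deltas per
#'   cutoff), `associations` (drug, both ranks, class), `counts`
#'   (better_A/better_B/equal), `mean_rank_delta` (mean of rank_A - rank_B;
#'   positive means B ranks shared drugs higher), and `top_counts` per
#'   mapping.
#' @export
compare_mappings <- function(results_A, results_B, indication_match,
                             top_cutoffs = c(10L, 25L, 100L)) {
  req <- c("indication_a", "indication_b")
  if (!all(req %in% names(indication_match)))
    stop("match table needs columns indication_a and indication_b")
  if (anyDuplicated(indication_match$indication_a) ||
      anyDuplicated(indication_match$indication_b))
    stop("indication match table must be one-to-one")

  pa <- results_A$per_indication
  pb <- results_B$per_indication
  m <- indication_match
  m <- m[m$indication_a %in% pa$indication_id &
           m$indication_b %in% pb$indication_id, , drop = FALSE]
  ia <- pa[match(m$indication_a, pa$indication_id), , drop = FALSE]
  ib <- pb[match(m$indication_b, pb$indication_id), , drop = FALSE]
  deltas <- m
  for (col in grep("^nia_top", names(ia), value = TRUE))
    deltas[[paste0("delta_", col)]] <- ia[[col]] - ib[[col]]

  aa <- results_A$per_association
  ab <- results_B$per_association
  aa <- aa[aa$indication_id %in% m$indication_a, , drop = FALSE]
  aa$indication_b <- m$indication_b[match(aa$indication_id, m$indication_a)]
  shared <- merge(aa, ab,
                  by.x = c("indication_b", "withheld"),
                  by.y = c("indication_id", "withheld"),
                  suffixes = c("_a", "_b"))
  shared$class <- ifelse(shared$final_rank_a < shared$final_rank_b, "better_A",
                         ifelse(shared$final_rank_a > shared$final_rank_b,
                                "better_B", "equal"))
  counts <- c(better_A = sum(shared$class == "better_A"),
              better_B = sum(shared$class == "better_B"),
              equal = sum(shared$class == "equal"))
  top_counts <- sapply(top_cutoffs, function(k)
    c(A = sum(shared$final_rank_a <= k), B = sum(shared$final_rank_b <= k)))
  colnames(top_counts) <- paste0("top", top_cutoffs)
  list(indication_deltas = deltas,
       associations = shared[, c("indication_id", "indication_b", "withheld",
                                 "final_rank_a", "final_rank_b", "class")],
       counts = counts,
       mean_rank_delta = if (nrow(shared)) mean(shared$final_rank_a - shared$final_rank_b) else NA_real_,
       top_counts = top_counts)
}
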