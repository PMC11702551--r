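#' Consensus ranking of candidate compounds for an indication
#'
#' Combines the similarity lists of an indication's associated drugs (the
#' seeds) into one totally ordered prediction list. Each candidate receives:
#' \describe{
#'   \item{count}{the consensus score: the number of seed lists in which the
#'     candidate appears at rank `<=` cutoff.}
#'   \item{mean_cutoff_rank}{mean rank over those within-cutoff appearances
#'     (undefined when count is 0).}
#'   \item{mean_full_rank}{mean rank over all seed full lists in which the
#'     candidate appears.}
#'   \item{mean_distance}{mean signature distance to the seeds.}
#' }
#' Candidates are ordered by count (descending), then mean_cutoff_rank,
#' mean_full_rank and mean_distance (each ascending, undefined sorting last),
#' with ascending compound id as the final deterministic key. The two
#' ascending-mean keys order the compounds that never enter any cutoff
#' window; a single global key keeps the whole list totally ordered.
#'
#' @param assoc_drugs character vector of seed drug ids (non-empty, all
#'   present in `lists`).
#' @param lists a [build_similarity_lists()] result.
#' @param cutoff similarity-list cutoff: how many top entries of each seed
#'   list contribute to the consensus count (rank `<=` cutoff, inclusive).
#' @param candidates candidate universe; defaults to all compounds in
#'   `lists` except the seeds when `exclude_known = TRUE` (default keeps the
#'   full universe, matching ranks reported "out of" the whole library).
#' @param exclude_known drop the seed drugs themselves from the candidates.
#' @return data.frame (class `consensus_list`) with one row per candidate,
#'   columns `final_rank`, `compound_id`, `count`, `mean_cutoff_rank`,
#'   `mean_full_rank`, `mean_distance`, sorted by `final_rank`.
#' @export
rank_candidates <- function(assoc_drugs, lists, cutoff,
                            candidates = NULL, exclude_known = FALSE) {
  if (length(assoc_drugs) == 0L) stop("no seed drugs supplied")
  cutoff <- as.integer(cutoff)
  if (is.na(cutoff) || cutoff < 1L) stop("cutoff must be a positive integer")
  assoc_drugs <- unique(as.character(assoc_drugs))
  unknown <- setdiff(assoc_drugs, lists$compound_ids)
  if (length(unknown))
    stop("seed drug(s) not in similarity lists: ",
         paste(unknown, collapse = ", "))
  if (is.null(candidates)) candidates <- lists$compound_ids
  candidates <- unique(as.character(candidates))
  if (exclude_known) candidates <- setdiff(candidates, assoc_drugs)
  if (length(candidates) == 0L) stop("empty candidate set")

  rk <- lists$rank[assoc_drugs, candidates, drop = FALSE]
  dd <- lists$distance[assoc_drugs, candidates, drop = FALSE]
  dd[is.na(rk)] <- NA  # a seed does not appear in its own list

  within <- !is.na(rk) & rk <= cutoff
  count <- as.integer(colSums(within))
  names(count) <- candidates
  mcr <- ifelse(count > 0, colSums(rk * within, na.rm = TRUE) / count, Inf)
  n_app <- colSums(!is.na(rk))
  mfr <- ifelse(n_app > 0, colMeans(rk, na.rm = TRUE), Inf)
  mdist <- ifelse(n_app > 0, colMeans(dd, na.rm = TRUE), Inf)

  o <- order(-count, mcr, mfr, mdist, candidates, method = "radix")
  out <- data.frame(final_rank = seq_along(candidates),
                    compound_id = candidates[o],
                    count = unname(count[o]),
                    mean_cutoff_rank = unname(ifelse(count[o] > 0, mcr[o], NA_real_)),
                    mean_full_rank = unname(ifelse(is.finite(mfr[o]), mfr[o], NA_real_)),
                    mean_distance = unname(ifelse(is.finite(mdist[o]), mdist[o], NA_real_)),
                    stringsAsFactors = FALSE)
  class(out) <- c("consensus_list", class(out))
  out
}
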