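#' Binding-site library records
#'
#' A binding-site library holds, per protein, the predicted binding sites
#' produced by an upstream site-prediction pipeline: a site identifier, the
#' fingerprint of the site's most likely bound ligand, and a site
#' similarity/confidence score in \[0, 1\]. Site prediction itself is out of
#' scope; the library is consumed as input.
#'
#' @param protein_id,site_id identifiers.
#' @param ligand_fp a [fingerprint()] for the site's predicted ligand.
#' @param site_score binding-site similarity/confidence in \[0, 1\].
#' @return a `binding_site` record.
#' @export
binding_site <- function(protein_id, site_id, ligand_fp, site_score) {
  stopifnot(inherits(ligand_fp, "fingerprint"))
  site_score <- as.numeric(site_score)
  if (!is.finite(site_score) || site_score < 0 || site_score > 1)
    stop("site_score must lie in [0, 1]")
  structure(list(protein_id = as.character(protein_id),
                 site_id = as.character(site_id),
                 ligand_fp = ligand_fp, site_score = site_score),
            class = "binding_site")
}

#' Best predicted-ligand similarity for one protein
#'
#' The chemical component of an interaction score: the compound's highest
#' Tanimoto similarity to any of the protein's predicted ligands. Ties on the
#' similarity are broken by higher `site_score`, then ascending `site_id`, so
#' the chosen site never depends on record order.
#'
#' @param compound_fp the compound's [fingerprint()].
#' @param sites list of [binding_site()] records, all for one protein.
#' @return list with `chem_score` (max Tanimoto, in \[0, 1\]) and
#'   `chosen_site` (the maximizing record).
#' @export
best_ligand_similarity <- function(compound_fp, sites) {
  if (length(sites) == 0L) stop("protein has no predicted binding sites")
  pid <- unique(vapply(sites, `[[`, "", "protein_id"))
  if (length(pid) != 1L) stop("sites span multiple proteins")
  sims <- vapply(sites, function(s) tanimoto(compound_fp, s$ligand_fp), 0)
  sscore <- vapply(sites, `[[`, 0, "site_score")
  sid <- vapply(sites, `[[`, "", "site_id")
  best <- order(-sims, -sscore, sid, method = "radix")[1L]
  list(chem_score = sims[best], chosen_site = sites[[best]])
}

#' Compound-protein interaction score under one scoring type
#'
#' Three scoring types are supported:
#' \describe{
#'   \item{C}{compound-only: the chemical similarity score alone.}
#'   \item{CxP}{compound-and-protein: chemical score times the site score of
#'     the site contributing the best ligand.}
#'   \item{dCxP}{percentile compound-and-protein: the chemical score's
#'     percentile within `percentile_context` (fraction of context values
#'     `<=` the score, so the maximum maps to 1) times the site score.}
#' }
#'
#' @param compound_fp the compound's [fingerprint()].
#' @param sites list of [binding_site()] records for one protein.
#' @param type `"C"`, `"CxP"` or `"dCxP"`.
#' @param percentile_context numeric vector of all compounds' chem scores for
#'   this protein; required for `"dCxP"`.
#' @return score in \[0, 1\].
#' @export
interaction_score <- function(compound_fp, sites,
                              type = c("CxP", "C", "dCxP"),
                              percentile_context = NULL) {
  type <- match.arg(type)
  b <- best_ligand_similarity(compound_fp, sites)
  switch(type,
    C = b$chem_score,
    CxP = b$chem_score * b$chosen_site$site_score,
    dCxP = {
      if (is.null(percentile_context))
        stop("dCxP scoring requires a percentile context")
      mean(percentile_context <= b$chem_score) * b$chosen_site$site_score
    })
}

#' Assemble an interaction matrix from fingerprints and a site library
#'
#' One score per (compound, protein) pair. Proteins with no predicted sites
#' contribute a column of zeros (not missing values), so every signature has
#' full length. For `dCxP` the percentile context of a protein is the vector
#' of all compounds' chemical scores against that protein.
#'
#' @param fingerprints named list of [fingerprint()] objects (names are
#'   compound ids).
#' @param site_library list of [binding_site()] records.
#' @param protein_ids proteins to include as columns; defaults to the
#'   proteins present in the site library.
#' @param type scoring type, see [interaction_score()].
#' @return an [interaction_matrix()].
#' @export
build_matrix <- function(fingerprints, site_library,
                         protein_ids = NULL,
                         type = c("CxP", "C", "dCxP")) {
  type <- match.arg(type)
  if (length(fingerprints) == 0L) stop("no compounds supplied")
  if (is.null(names(fingerprints)) || anyDuplicated(names(fingerprints)))
    stop("fingerprints must be uniquely named by compound id")
  site_pids <- vapply(site_library, `[[`, "", "protein_id")
  if (is.null(protein_ids)) protein_ids <- unique(site_pids)
  if (length(protein_ids) == 0L) stop("no proteins supplied")
  cids <- names(fingerprints)
  scores <- matrix(0, length(cids), length(protein_ids),
                   dimnames = list(cids, protein_ids))
  for (p in protein_ids) {
    sites <- site_library[site_pids == p]
    if (length(sites) == 0L) next  # no sites: column stays 0
    res <- lapply(fingerprints, best_ligand_similarity, sites = sites)
    chem <- vapply(res, `[[`, 0, "chem_score")
    sitesc <- vapply(res, function(r) r$chosen_site$site_score, 0)
    scores[, p] <- switch(type,
      C = chem,
      CxP = chem * sitesc,
      dCxP = vapply(chem, function(x) mean(chem <= x), 0) * sitesc)
  }
  interaction_matrix(scores)
}
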