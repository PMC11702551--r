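#' Drug-indication mapping
#'
#' Associates drugs with indications over a drug library (the candidate
#' universe). Duplicate associations are dropped; every associated drug must
#' be in the library.
#'
#' @param associations data.frame with columns `drug_id`, `indication_id`.
#' @param drug_library character vector of candidate compound ids; defaults
#'   to the associated drugs.
#' @return an `indication_mapping` object.
#' @export
indication_mapping <- function(associations, drug_library = NULL) {
  if (!all(c("drug_id", "indication_id") %in% names(associations)))
    stop("associations need columns drug_id and indication_id")
  assoc <- unique(data.frame(drug_id = as.character(associations$drug_id),
                             indication_id = as.character(associations$indication_id),
                             stringsAsFactors = FALSE))
  rownames(assoc) <- NULL
  if (is.null(drug_library)) drug_library <- unique(assoc$drug_id)
  drug_library <- as.character(drug_library)
  if (anyDuplicated(drug_library)) stop("duplicate drug id in library")
  missing <- setdiff(assoc$drug_id, drug_library)
  if (length(missing))
    stop("associated drug(s) absent from library: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  structure(list(associations = assoc, drug_library = drug_library),
            class = "indication_mapping")
}

#' @export
print.indication_mapping <- function(x, ...) {
  s <- mapping_summary(x)
  cat(sprintf(paste0("indication_mapping: %d drugs, %d indications, ",
                     "%d associations (%d indications with >= 2 drugs)\n"),
              s$n_drugs, s$n_indications, s$n_associations,
              s$n_benchmarkable))
  invisible(x)
}

#' Summary statistics of a mapping
#'
#' @param mapping an [indication_mapping()].
#' @return list with `n_drugs` (library size), `n_indications`,
#'   `n_associations`, and `n_benchmarkable` (indications with at least two
#'   associated drugs, the only ones a leave-one-out benchmark can assess).
#' @export
mapping_summary <- function(mapping) {
  sizes <- table(mapping$associations$indication_id)
  list(n_drugs = length(mapping$drug_library),
       n_indications = length(sizes),
       n_associations = nrow(mapping$associations),
       n_benchmarkable = sum(sizes >= 2L))
}

# Named list of drug-id vectors, one per indication.
indication_drugs <- function(mapping) {
  split(mapping$associations$drug_id, mapping$associations$indication_id)
}

# Restrict a mapping to a subset of indications (library unchanged).
subset_mapping <- function(mapping, indication_ids) {
  keep <- mapping$associations$indication_id %in% indication_ids
  indication_mapping(mapping$associations[keep, , drop = FALSE],
                     mapping$drug_library)
}
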