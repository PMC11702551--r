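#' Read / write an interaction matrix as TSV
#'
#' Format: header row `compound_id<TAB>protein ids...`, then one row per
#' compound. Duplicate ids, ragged rows and non-numeric cells are rejected
#' with the offending line or id named.
#'
#' @param path file path.
#' @return an [interaction_matrix()].
#' @export
read_interaction_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("matrix file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  p_ids <- header[-1L]
  width <- length(header)
  cids <- character(length(fields) - 1L)
  scores <- matrix(NA_real_, length(fields) - 1L, length(p_ids))
  for (i in seq_along(fields)[-1L]) {
    row <- fields[[i]]
    if (length(row) != width)
      stop(sprintf("ragged row at line %d of %s (%d fields, expected %d)",
                   i, path, length(row), width))
    cids[i - 1L] <- row[1L]
    vals <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(vals))
      stop(sprintf("non-numeric score at line %d of %s", i, path))
    scores[i - 1L, ] <- vals
  }
  interaction_matrix(scores, compound_ids = cids, protein_ids = p_ids)
}

#' @rdname read_interaction_matrix
#' @param matrix an [interaction_matrix()] to write.
#' @export
write_interaction_matrix <- function(matrix, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("compound_id", colnames(matrix)), collapse = "\t"), con)
  # %.17g guarantees an exact double round-trip
  body <- apply(unclass(matrix), 1L, function(r)
    paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(paste(rownames(matrix), body, sep = "\t"), con)
  invisible(path)
}

#' Read / write a drug-indication mapping as TSV
#'
#' Expects a header with at least `drug_id` and `indication_id` columns.
#' Duplicate associations are counted once. When `drug_library` is supplied,
#' associations whose drug has no interaction signature are dropped and
#' counted; the mapping's candidate universe becomes that library.
#'
#' @param path file path.
#' @param drug_library optional character vector restricting (and defining)
#'   the candidate universe.
#' @return an [indication_mapping()] with attribute `"summary"` (see
#'   [mapping_summary()], plus `n_dropped`).
#' @export
read_mapping <- function(path, drug_library = NULL) {
  tab <- utils::read.delim(path, colClasses = "character",
                           check.names = FALSE)
  if (nrow(tab) == 0L) stop("empty mapping file: ", path)
  if (!all(c("drug_id", "indication_id") %in% names(tab)))
    stop("mapping file needs drug_id and indication_id columns: ", path)
  n_dropped <- 0L
  if (!is.null(drug_library)) {
    keep <- tab$drug_id %in% drug_library
    n_dropped <- sum(!keep)
    tab <- tab[keep, , drop = FALSE]
    if (nrow(tab) == 0L) stop("no association survives the drug-library filter")
  }
  mapping <- indication_mapping(tab[, c("drug_id", "indication_id")],
                                drug_library = drug_library)
  s <- mapping_summary(mapping)
  s$n_dropped <- n_dropped
  attr(mapping, "summary") <- s
  mapping
}

#' @rdname read_mapping
#' @param mapping an [indication_mapping()] to write.
#' @export
write_mapping <- function(mapping, path) {
  utils::write.table(mapping$associations, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write fingerprints as TSV
#'
#' Columns: `compound_id`, `bits` (comma-separated 0-based on-bit positions;
#' empty string for an empty fingerprint), `bit_space`.
#'
#' @param path file path.
#' @return named list of [fingerprint()] objects.
#' @export
read_fingerprints <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  req <- c("compound_id", "bits", "bit_space")
  if (!all(req %in% names(tab)))
    stop("fingerprint file needs columns ", paste(req, collapse = ", "))
  if (anyDuplicated(tab$compound_id))
    stop("duplicate compound id in fingerprint file")
  fps <- lapply(seq_len(nrow(tab)), function(i) {
    bits <- if (nzchar(tab$bits[i]))
      as.integer(strsplit(tab$bits[i], ",", fixed = TRUE)[[1L]]) else integer()
    fingerprint(bits, as.integer(tab$bit_space[i]))
  })
  names(fps) <- tab$compound_id
  fps
}

#' @rdname read_fingerprints
#' @param fps named list of [fingerprint()] objects to write.
#' @export
write_fingerprints <- function(fps, path) {
  tab <- data.frame(
    compound_id = names(fps),
    bits = vapply(fps, function(f) paste(f$bits, collapse = ","), ""),
    bit_space = vapply(fps, `[[`, 0L, "bit_space"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a binding-site library as TSV
#'
#' Columns: `protein_id`, `site_id`, `site_score`, `ligand_fp`
#' (comma-separated bit positions), `bit_space`.
#'
#' @param path file path.
#' @return list of [binding_site()] records.
#' @export
read_site_library <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  req <- c("protein_id", "site_id", "site_score", "ligand_fp", "bit_space")
  if (!all(req %in% names(tab)))
    stop("site library needs columns ", paste(req, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    bits <- if (nzchar(tab$ligand_fp[i]))
      as.integer(strsplit(tab$ligand_fp[i], ",", fixed = TRUE)[[1L]]) else integer()
    binding_site(tab$protein_id[i], tab$site_id[i],
                 fingerprint(bits, as.integer(tab$bit_space[i])),
                 as.numeric(tab$site_score[i]))
  })
}

#' @rdname read_site_library
#' @param sites list of [binding_site()] records to write.
#' @export
write_site_library <- function(sites, path) {
  tab <- data.frame(
    protein_id = vapply(sites, `[[`, "", "protein_id"),
    site_id = vapply(sites, `[[`, "", "site_id"),
    site_score = vapply(sites, `[[`, 0, "site_score"),
    ligand_fp = vapply(sites, function(s) paste(s$ligand_fp$bits, collapse = ","), ""),
    bit_space = vapply(sites, function(s) s$ligand_fp$bit_space, 0L))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write benchmark results to TSV + JSON
#'
#' Per-indication rows go to `<stem>_indications.tsv`, per-association ranks
#' to `<stem>_associations.tsv`, and the aggregate summary (with parameters)
#' to `<stem>_summary.json`.
#'
#' @param result a [benchmark_mapping()] result.
#' @param stem output path stem.
#' @return the three paths, invisibly.
#' @export
write_benchmark_result <- function(result, stem) {
  paths <- c(indications = paste0(stem, "_indications.tsv"),
             associations = paste0(stem, "_associations.tsv"),
             summary = paste0(stem, "_summary.json"))
  utils::write.table(result$per_indication, paths[["indications"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result$per_association, paths[["associations"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    c(result$summary,
      list(cutoff = result$cutoff, rank_cutoffs = result$rank_cutoffs,
           n_candidates = result$n_candidates,
           n_indications = nrow(result$per_indication),
           skipped = result$skipped)),
    paths[["summary"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
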