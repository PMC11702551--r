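#' Construct a compound x protein interaction matrix
#'
#' The interaction matrix is the platform's core signature store: one row per
#' compound, one column per protein, each cell the predicted interaction score
#' in \[0, 1\]. A compound's row is its proteomic interaction signature.
#'
#' @param scores numeric matrix with compound rownames and protein colnames,
#'   or an object coercible to one.
#' @param compound_ids,protein_ids optional character vectors overriding the
#'   dimnames of `scores`.
#' @return an `interaction_matrix`: a numeric matrix with class attribute and
#'   validated dimnames.
#' @details Scores outside \[0, 1\] trigger a warning, not an error, so that
#'   alternative scoring schemes can still be loaded. Non-finite scores and
#'   duplicate compound or protein identifiers are errors.
#' @export
interaction_matrix <- function(scores, compound_ids = NULL, protein_ids = NULL) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (!is.null(compound_ids)) rownames(scores) <- compound_ids
  if (!is.null(protein_ids)) colnames(scores) <- protein_ids
  if (is.null(rownames(scores)))
    stop("interaction matrix requires compound rownames")
  if (is.null(colnames(scores)))  # protein ids are rarely interesting per se
    colnames(scores) <- paste0("p", seq_len(ncol(scores)))
  if (anyDuplicated(rownames(scores)))
    stop("duplicate compound id: ",
         rownames(scores)[duplicated(rownames(scores))][1L])
  if (anyDuplicated(colnames(scores)))
    stop("duplicate protein id: ",
         colnames(scores)[duplicated(colnames(scores))][1L])
  if (!all(is.finite(scores)))
    stop("interaction matrix contains non-finite scores")
  if (any(scores < 0 | scores > 1))
    warning("interaction scores outside [0, 1]; downstream code assumes unit scale")
  class(scores) <- c("interaction_matrix", class(scores))
  scores
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("interaction_matrix: %d compounds x %d proteins\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Root-mean-squared distance between two interaction signatures
#'
#' Signature dissimilarity is the root mean squared elementwise difference:
#' `sqrt(mean((a - b)^2))`. It is symmetric, nonnegative, and zero exactly
#' when the two signatures are identical.
#'
#' @param sig_a,sig_b numeric vectors of equal positive length.
#' @return a single nonnegative number.
#' @export
rmsd_distance <- function(sig_a, sig_b) {
  if (length(sig_a) == 0L || length(sig_a) != length(sig_b))
    stop("signatures must be non-empty and of equal length")
  if (!all(is.finite(sig_a)) || !all(is.finite(sig_b)))
    stop("signatures must be finite")
  sqrt(mean((sig_a - sig_b)^2))
}

# Full RMSD distance matrix for an interaction matrix (euclidean / sqrt(P)).
rmsd_matrix <- function(matrix) {
  d <- as.matrix(stats::dist(matrix, method = "euclidean")) / sqrt(ncol(matrix))
  dimnames(d) <- list(rownames(matrix), rownames(matrix))
  d
}

#' Build per-compound similarity lists from an interaction matrix
#'
#' For every compound, all other compounds are sorted by ascending RMSD
#' signature distance; exact distance ties are broken by ascending compound id
#' (radix/C-locale order) so the ranking is a deterministic total order. Ranks
#' are 1-based with no gaps and the compound itself is excluded from its list.
#'
#' @param matrix an [interaction_matrix()] with at least 2 compounds.
#' @return a `similarity_lists` object holding the compound ids, the full
#'   pairwise distance matrix, and a rank matrix `rank[i, j]` giving compound
#'   j's 1-based rank in compound i's list (`NA` on the diagonal).
#' @seealso [similarity_list()] to extract one compound's ordered list.
#' @export
build_similarity_lists <- function(matrix) {
  if (nrow(matrix) < 2L)
    stop("similarity lists require at least 2 compounds")
  ids <- rownames(matrix)
  d <- rmsd_matrix(matrix)
  n <- length(ids)
  rk <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    o <- order(d[i, -i], ids[-i], method = "radix")
    rk[i, -i][o] <- seq_len(n - 1L)
  }
  structure(list(compound_ids = ids, distance = d, rank = rk),
            class = "similarity_lists")
}

#' @export
print.similarity_lists <- function(x, ...) {
  cat(sprintf("similarity_lists over %d compounds\n", length(x$compound_ids)))
  invisible(x)
}

#' Extract one compound's ordered similarity list
#'
#' @param lists a `similarity_lists` object.
#' @param compound_id the list owner.
#' @return data.frame with columns `compound_id`, `distance`, `rank`, sorted
#'   by rank.
#' @export
similarity_list <- function(lists, compound_id) {
  if (!compound_id %in% lists$compound_ids)
    stop("unknown compound id: ", compound_id)
  others <- setdiff(lists$compound_ids, compound_id)
  rk <- lists$rank[compound_id, others]
  o <- order(rk)
  data.frame(compound_id = others[o],
             distance = unname(lists$distance[compound_id, others][o]),
             rank = unname(rk[o]),
             stringsAsFactors = FALSE)
}

#' Construct a chemical fingerprint
#'
#' A fingerprint is the set of on-bit positions of a fixed-width circular
#' substructure bit vector (ECFP4-style, default width 2048).
#'
#' @param bits integer vector of 0-based on-bit positions (duplicates removed).
#' @param bit_space total width of the bit vector.
#' @return a `fingerprint` object.
#' @export
fingerprint <- function(bits = integer(), bit_space = 2048L) {
  bit_space <- as.integer(bit_space)
  if (is.na(bit_space) || bit_space <= 0L) stop("bit_space must be positive")
  bits <- sort(unique(as.integer(bits)))
  if (length(bits) && (min(bits) < 0L || max(bits) >= bit_space))
    stop("bit positions must lie in [0, bit_space)")
  structure(list(bits = bits, bit_space = bit_space), class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("fingerprint: %d/%d bits set\n", length(x$bits), x$bit_space))
  invisible(x)
}

#' Tanimoto coefficient of two fingerprints
#'
#' Intersection-over-union of the on-bit sets. Defined as 0 when both
#' fingerprints are empty (the 0/0 case).
#'
#' @param fp_a,fp_b [fingerprint()] objects sharing the same `bit_space`.
#' @return similarity in \[0, 1\].
#' @export
tanimoto <- function(fp_a, fp_b) {
  stopifnot(inherits(fp_a, "fingerprint"), inherits(fp_b, "fingerprint"))
  if (fp_a$bit_space != fp_b$bit_space)
    stop("fingerprints have different bit spaces (",
         fp_a$bit_space, " vs ", fp_b$bit_space, ")")
  n_int <- length(intersect(fp_a$bits, fp_b$bits))
  n_union <- length(fp_a$bits) + length(fp_b$bits) - n_int
  if (n_union == 0L) return(0)
  n_int / n_union
}
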