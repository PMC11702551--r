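#' Configuration for the synthetic data generator
#'
#' Describes a world in which the signature-similarity hypothesis holds by
#' construction: each indication's drugs share an archetype interaction
#' signature plus independent Gaussian noise, while unindicated background
#' compounds are drawn from the background distribution. Fingerprints are
#' likewise clustered: drugs of one indication share a configurable fraction
#' of on-bits.
#'
#' @param n_compounds,n_proteins,n_indications positive integers.
#' @param drugs_per_indication integer `>= 2`, or length-2 range sampled
#'   uniformly per indication.
#' @param noise_sd standard deviation of the per-drug signature noise around
#'   the indication archetype (interaction-score units; 0 gives identical
#'   within-cluster signatures).
#' @param background lower/upper bounds of the uniform background score
#'   distribution.
#' @param bit_space fingerprint width (default 2048, ECFP4-style).
#' @param n_bits on-bits per fingerprint (default 48, a typical small-
#'   molecule ECFP4 density).
#' @param shared_bit_fraction fraction of a cluster drug's bits drawn from
#'   its indication's shared bit pool.
#' @param n_sites_per_protein range of predicted binding sites per protein.
#' @param seed integer seed; generation is deterministic given the config.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_compounds = 50L, n_proteins = 100L,
                             n_indications = 5L, drugs_per_indication = 4L,
                             noise_sd = 0.05, background = c(0, 1),
                             bit_space = 2048L, n_bits = 48L,
                             shared_bit_fraction = 0.5,
                             n_sites_per_protein = c(1L, 3L), seed = 1L) {
  cfg <- list(n_compounds = as.integer(n_compounds),
              n_proteins = as.integer(n_proteins),
              n_indications = as.integer(n_indications),
              drugs_per_indication = as.integer(drugs_per_indication),
              noise_sd = as.numeric(noise_sd),
              background = as.numeric(background),
              bit_space = as.integer(bit_space),
              n_bits = as.integer(n_bits),
              shared_bit_fraction = as.numeric(shared_bit_fraction),
              n_sites_per_protein = as.integer(n_sites_per_protein),
              seed = as.integer(seed))
  if (any(c(cfg$n_compounds, cfg$n_proteins, cfg$n_indications) < 1L))
    stop("counts must be positive")
  if (any(cfg$drugs_per_indication < 2L))
    stop("drugs_per_indication must be >= 2 (indications must be benchmarkable)")
  if (cfg$noise_sd < 0) stop("noise_sd must be nonnegative")
  if (length(cfg$background) != 2L || cfg$background[1L] < 0 ||
      cfg$background[2L] > 1 || cfg$background[1L] >= cfg$background[2L])
    stop("background must be increasing bounds within [0, 1]")
  if (cfg$shared_bit_fraction < 0 || cfg$shared_bit_fraction > 1)
    stop("shared_bit_fraction must be in [0, 1]")
  if (cfg$n_indications * max(cfg$drugs_per_indication) > cfg$n_compounds)
    stop("infeasible config: indications x drugs_per_indication exceeds n_compounds")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic interaction matrix, mapping, fingerprints and sites
#'
#' Planted-cluster generator: per indication an archetype signature is drawn
#' from the uniform background; each of its drugs gets the archetype plus
#' independent N(0, noise_sd) noise, clipped to \[0, 1\]. Remaining compounds
#' are background draws. Clusters are disjoint. Fingerprints mix a per-
#' indication shared bit pool with private random bits; background compounds
#' get fully random bits. The binding-site library samples each site's
#' predicted ligand from the generated fingerprints (so chemistry and the
#' matrix are consistent worlds, not identical ones) with uniform site
#' scores.
#'
#' @param config a [synthetic_config()].
#' @return list with `matrix` ([interaction_matrix()]), `mapping`
#'   ([indication_mapping()]), `fingerprints` (named list), `site_library`
#'   (list of [binding_site()]), and `config`.
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  rng <- make_rng(config$seed)
  nC <- config$n_compounds; nP <- config$n_proteins
  cids <- sprintf("cmpd%03d", seq_len(nC))
  pids <- sprintf("prot%03d", seq_len(nP))
  inds <- sprintf("ind%02d", seq_len(config$n_indications))

  dpi <- config$drugs_per_indication
  sizes <- if (length(dpi) == 1L) rep(dpi, length(inds)) else
    dpi[1L] + rng$sample(dpi[2L] - dpi[1L] + 1L, length(inds), replace = TRUE) - 1L
  if (sum(sizes) > nC) stop("infeasible config: clusters exceed compound count")

  # disjoint clusters occupy the first sum(sizes) compounds
  member_of <- rep(NA_character_, nC)
  cursor <- 0L
  assoc <- list()
  for (i in seq_along(inds)) {
    idx <- cursor + seq_len(sizes[i]); cursor <- cursor + sizes[i]
    member_of[idx] <- inds[i]
    assoc[[i]] <- data.frame(drug_id = cids[idx], indication_id = inds[i],
                             stringsAsFactors = FALSE)
  }
  mapping <- indication_mapping(do.call(rbind, assoc), drug_library = cids)

  bg <- function(n) rng$runif(n, config$background[1L], config$background[2L])
  scores <- matrix(NA_real_, nC, nP, dimnames = list(cids, pids))
  archetypes <- lapply(inds, function(i) bg(nP))
  names(archetypes) <- inds
  for (c in seq_len(nC)) {
    scores[c, ] <- if (is.na(member_of[c])) bg(nP) else
      pmin(1, pmax(0, archetypes[[member_of[c]]] + rng$rnorm(nP, 0, config$noise_sd)))
  }

  pick_bits <- function(pool, k) pool[rng$sample(length(pool), min(k, length(pool)))]
  all_bits <- seq_len(config$bit_space) - 1L
  shared_pools <- lapply(inds, function(i) pick_bits(all_bits, config$n_bits))
  names(shared_pools) <- inds
  fps <- vector("list", nC); names(fps) <- cids
  n_shared <- round(config$shared_bit_fraction * config$n_bits)
  for (c in seq_len(nC)) {
    bits <- if (is.na(member_of[c])) pick_bits(all_bits, config$n_bits) else
      c(pick_bits(shared_pools[[member_of[c]]], n_shared),
        pick_bits(all_bits, config$n_bits - n_shared))
    fps[[c]] <- fingerprint(bits, config$bit_space)
  }

  nsr <- config$n_sites_per_protein
  site_library <- list()
  for (p in pids) {
    ns <- if (length(nsr) == 1L) nsr else
      nsr[1L] + rng$sample(nsr[2L] - nsr[1L] + 1L, 1L) - 1L
    for (s in seq_len(ns)) {
      donor <- fps[[rng$sample(nC, 1L)]]
      # perturb the donor ligand: drop/add a few bits
      keep <- pick_bits(donor$bits, max(1L, length(donor$bits) - 8L))
      lig <- fingerprint(c(keep, pick_bits(all_bits, 8L)), config$bit_space)
      site_library[[length(site_library) + 1L]] <-
        binding_site(p, sprintf("%s_site%d", p, s), lig, rng$runif(1L))
    }
  }

  list(matrix = interaction_matrix(scores), mapping = mapping,
       fingerprints = fps, site_library = site_library, config = config)
}
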