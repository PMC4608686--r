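# Synthetic raw-intensity datasets with known ground truth.
#
# The generator emulates the statistical structure of a single-channel
# comparability experiment: a media-only control group, a reference product,
# a test product inducing the identical expression response, and a
# "nonequivalent" product sharing only part of the reference effect profile.
# On the raw scale each spot measurement is a normal background plus an
# exponential-tailed signal, so the normexp background-correction model is
# exercised in-model.

#' Configuration for the synthetic-data generator
#'
#' Defaults mirror the study design the package was built around: a
#' whole-genome mouse array of 39,429 unique probes hybridized with
#' media (n = 7), reference product (n = 17), test product (n = 16) and a
#' nonequivalent control (n = 8); roughly a tenth of probes respond to
#' treatment with planted log2 effects of magnitude 1.
#'
#' @param n_unique_probes Number of unique probes.
#' @param spots_per_probe Replicate spots printed per probe (>= 1).
#' @param group_sizes Named integer vector of samples per group. Recognized
#'   roles (by name): `media` (no effects), `reference` and `test` (identical
#'   planted effects) and `nonequivalent` (partially shared effects).
#' @param bg_mean,bg_sd Normal background parameters, raw intensity units.
#' @param signal_mean Target mean of the true signal on the raw scale.
#' @param baseline_log2_mean,baseline_log2_sd Per-probe baseline log2 level
#'   distribution.
#' @param n_responsive Number of treatment-responsive probes.
#' @param effect_log2 Magnitude of the planted log2 effects (random sign).
#' @param share_fraction Fraction of the reference effect profile copied by
#'   the nonequivalent group (rounded down); the remainder receives
#'   independently drawn effects of the same magnitude.
#' @param n_factors Number of latent coexpression factors.
#' @param factor_sd Scale of the factor loadings (log2 units).
#' @param noise_sd Residual per-observation log2 noise.
#' @param seed Integer RNG seed; the generator is deterministic given it.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_unique_probes = 39429L,
                             spots_per_probe = 1L,
                             group_sizes = c(media = 7L, reference = 17L,
                                             test = 16L, nonequivalent = 8L),
                             bg_mean = 50, bg_sd = 10,
                             signal_mean = 2000,
                             baseline_log2_mean = 10, baseline_log2_sd = 0.8,
                             n_responsive = 4000L,
                             effect_log2 = 1,
                             share_fraction = 0.9,
                             n_factors = 5L, factor_sd = 0.1,
                             noise_sd = 0.25,
                             seed = 1L) {
  cfg <- list(n_unique_probes = as.integer(n_unique_probes),
              spots_per_probe = as.integer(spots_per_probe),
              group_sizes = group_sizes,
              bg_mean = bg_mean, bg_sd = bg_sd,
              signal_mean = signal_mean,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              n_responsive = as.integer(n_responsive),
              effect_log2 = effect_log2,
              share_fraction = share_fraction,
              n_factors = as.integer(n_factors),
              factor_sd = factor_sd,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    if (n_unique_probes < 1L || spots_per_probe < 1L) {
      stop("probe and spot counts must be positive")
    }
    if (length(group_sizes) < 1L || is.null(names(group_sizes)) ||
        any(!nzchar(names(group_sizes)))) {
      stop("group_sizes must be a named vector")
    }
    if (any(group_sizes < 1L)) stop("all group sizes must be positive")
    if (n_responsive < 0L || n_responsive > n_unique_probes) {
      stop("n_responsive must lie in [0, n_unique_probes]")
    }
    if (share_fraction < 0 || share_fraction > 1) {
      stop("share_fraction must lie in [0, 1]")
    }
    if (bg_sd <= 0 || noise_sd < 0 || factor_sd < 0 || signal_mean <= 0) {
      stop("scale parameters must be positive")
    }
    if (n_responsive > 0L && effect_log2 != 0 &&
        !("media" %in% names(group_sizes))) {
      stop("group_sizes must contain a 'media' control group when effects are requested")
    }
  })
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic raw-intensity dataset with known truth
#'
#' Per sample `s` in group `g` and probe `p`, the true log2 level is
#' `L = baseline_p + effect_{p,g} + sum_k loading_{p,k} * factor_{k,s} + eps`
#' with `eps ~ N(0, noise_sd)`. Signals `S = c * 2^L` are scaled so the
#' all-probe mean signal equals `signal_mean`. Each physical spot carries a
#' multiplicative print-batch effect `E ~ Exp(1)` drawn once per spot and
#' shared across arrays, giving the within-array signal the exponential
#' marginal assumed by normexp background correction while cancelling from
#' group contrasts. Foreground is `B + S * E` with spot background
#' `B ~ N(bg_mean, bg_sd)` truncated at zero; the recorded background is an
#' independent draw from the same background law.
#'
#' Groups named `reference` and `test` share the identical effect vector on
#' the responsive probes; `nonequivalent` copies `floor(share_fraction *
#' n_responsive)` of those effects and receives independently drawn effects
#' of the same magnitude on the remainder; `media` (and any unrecognized
#' group) has zero effects.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `raw` (a `raw_intensity_set`), `sheet`
#'   (a `sample_sheet`) and `truth` (class `"synthetic_truth"`: the
#'   responsive probe ids, the probe-by-group effect table and the config).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  config <- validate_synthetic_config(config)
  with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  np <- cfg$n_unique_probes
  groups <- names(cfg$group_sizes)
  n_samples <- sum(cfg$group_sizes)
  probe_ids <- sprintf("P%06d", seq_len(np))
  gene_symbols <- sprintf("GENE%06d", seq_len(np))

  # planted effects
  effect <- matrix(0, np, length(groups), dimnames = list(probe_ids, groups))
  responsive <- integer(0)
  if (cfg$n_responsive > 0L && cfg$effect_log2 != 0) {
    responsive <- sort(sample.int(np, cfg$n_responsive))
    ref_eff <- cfg$effect_log2 * sample(c(-1, 1), cfg$n_responsive, replace = TRUE)
    for (g in intersect(c("reference", "test"), groups)) {
      effect[responsive, g] <- ref_eff
    }
    if ("nonequivalent" %in% groups) {
      n_shared <- floor(cfg$share_fraction * cfg$n_responsive)
      shared <- sample.int(cfg$n_responsive, n_shared)
      ne_eff <- cfg$effect_log2 * sample(c(-1, 1), cfg$n_responsive, replace = TRUE)
      ne_eff[shared] <- ref_eff[shared]
      effect[responsive, "nonequivalent"] <- ne_eff
    }
  }

  group_of <- rep(groups, cfg$group_sizes)
  sample_id <- unlist(lapply(seq_along(groups), function(i) {
    sprintf("%s_%02d", groups[i], seq_len(cfg$group_sizes[i]))
  }), use.names = FALSE)
  sheet <- data.frame(sample_id = sample_id,
                      group = group_of,
                      lot = paste0(group_of, "_lot1"),
                      replicate = unlist(lapply(cfg$group_sizes, seq_len), use.names = FALSE),
                      include = TRUE, stringsAsFactors = FALSE)
  sheet <- validate_sample_sheet(sheet)

  baseline <- stats::rnorm(np, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  L <- matrix(baseline, np, n_samples) + effect[, group_of, drop = FALSE]
  if (cfg$n_factors > 0L) {
    loadings <- matrix(stats::rnorm(np * cfg$n_factors, 0, cfg$factor_sd), np)
    factors <- matrix(stats::rnorm(cfg$n_factors * n_samples), cfg$n_factors)
    L <- L + loadings %*% factors
  }
  L <- L + matrix(stats::rnorm(np * n_samples, 0, cfg$noise_sd), np)

  S <- 2^L
  S <- S * (cfg$signal_mean / mean(S))

  # replicate spots: exponential print-batch effect per physical spot,
  # shared across arrays
  spot_probe <- rep(seq_len(np), each = cfg$spots_per_probe)
  n_spots <- length(spot_probe)
  spot_effect <- stats::rexp(n_spots, rate = 1)
  fg <- S[spot_probe, , drop = FALSE] * spot_effect +
    trunc_norm(n_spots * n_samples, cfg$bg_mean, cfg$bg_sd)
  bg <- matrix(trunc_norm(n_spots * n_samples, cfg$bg_mean, cfg$bg_sd), n_spots)
  dim(fg) <- c(n_spots, n_samples)

  spot_ids <- if (cfg$spots_per_probe > 1L) {
    paste0(probe_ids[spot_probe], "_spot",
           rep(seq_len(cfg$spots_per_probe), times = np))
  } else probe_ids
  colnames(fg) <- colnames(bg) <- sheet$sample_id
  rownames(fg) <- rownames(bg) <- spot_ids
  spots <- data.frame(spot_id = spot_ids,
                      unique_probe_id = probe_ids[spot_probe],
                      gene_symbol = gene_symbols[spot_probe],
                      stringsAsFactors = FALSE)
  raw <- new_raw_intensity_set(fg, bg, spots, included_samples(sheet))

  truth <- structure(list(responsive_probe_ids = probe_ids[responsive],
                          effect_table = effect,
                          config = cfg),
                     class = "synthetic_truth")
  list(raw = raw, sheet = sheet, truth = truth)
}

# Normal draw truncated at zero (background intensities are nonnegative).
trunc_norm <- function(n, mean, sd) {
  pmax(stats::rnorm(n, mean, sd), 0)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", length(x$responsive_probe_ids), "responsive probes among",
      x$config$n_unique_probes, "\n")
  invisible(x)
}

#' Block dissimilarity fixture for two groups
#'
#' Builds the idealized dissimilarity matrix in which every within-group
#' pair is at dissimilarity `within` and every between-group pair at
#' `between`; useful for verifying the mvt statistic against hand
#' evaluations of its formula.
#'
#' @param n_G,n_H Group sizes (>= 1).
#' @param within,between Dissimilarities in `[0, 2]`.
#' @return A `dissimilarity_matrix` with samples `G1..`, `H1..`.
#' @export
generate_dissimilarity_fixture <- function(n_G, n_H, within, between) {
  if (n_G < 1L || n_H < 1L) stop("group sizes must be >= 1")
  if (within < 0 || within > 2 || between < 0 || between > 2) {
    stop("within and between must lie in [0, 2]")
  }
  n <- n_G + n_H
  ids <- c(paste0("G", seq_len(n_G)), paste0("H", seq_len(n_H)))
  grp <- rep(c(1L, 2L), c(n_G, n_H))
  d <- ifelse(outer(grp, grp, "=="), within, between)
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  new_dissimilarity_matrix(d)
}
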