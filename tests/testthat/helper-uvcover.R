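## Shared fixtures, built in code. Expensive bundles are memoised per
## test run.

.fixture_cache <- new.env(parent = emptyenv())

## standard small participant bundle (128x128, 15% missed everywhere)
cached_bundle <- function(f = 0.15, seed = 7L, dims = c(128L, 128L),
                          noise_sd = 2, channel_mode = "gray") {
  key <- paste("bundle", f, seed, paste(dims, collapse = "x"), noise_sd,
               channel_mode, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  spec <- participant_spec(
    true_missed_fraction = list(eyelid = f, non_eyelid = f, canthus = f),
    image_dims = dims, noise_sd = noise_sd, channel_mode = channel_mode)
  .fixture_cache[[key]] <- generate_participant(spec, seed = seed)
  .fixture_cache[[key]]
}

## brute-force per-pixel oracles (deliberately naive double loops)
oracle_percent_missed <- function(covered, region) {
  n_region <- 0L; n_unc <- 0L
  for (i in seq_len(nrow(region))) {
    for (j in seq_len(ncol(region))) {
      if (region[i, j]) {
        n_region <- n_region + 1L
        if (!covered[i, j]) n_unc <- n_unc + 1L
      }
    }
  }
  100 * n_unc / n_region
}

oracle_mean_intensity <- function(pixels, region) {
  total <- 0; n <- 0L
  for (i in seq_len(nrow(region))) {
    for (j in seq_len(ncol(region))) {
      if (region[i, j]) { total <- total + pixels[i, j]; n <- n + 1L }
    }
  }
  total / n
}

oracle_half_counts <- function(face, mid_x) {
  left <- 0L; right <- 0L
  for (i in seq_len(nrow(face))) {
    for (j in seq_len(ncol(face))) {
      if (face[i, j]) {
        if ((j - 1) < mid_x) left <- left + 1L else right <- right + 1L
      }
    }
  }
  c(left = left, right = right)
}

## small default population for statistics tests
cached_population <- function(seed = 11L, n = 84L, ...) {
  key <- paste("pop", seed, n, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  .fixture_cache[[key]] <- generate_population(
    population_spec(n_participants = n, seed = seed, ...))
  .fixture_cache[[key]]
}
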