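# Shared fixture builders (all generated in code at test time).

make_ball_volume <- function(radius = 3, grid = NULL, levels = 0,
                             noise_sd = 0, seed = 1, n_plateaus = length(levels)) {
  if (is.null(grid)) grid <- rep(2 * ceiling(radius) + 7, 3)
  spec <- phantom_spec(grid_shape = grid, nodule_radius_mm = radius,
                       n_plateaus = n_plateaus, plateau_levels = levels,
                       noise_sd = noise_sd)
  generate_phantom(spec, seed = seed)
}

# Random small volume with a random (nonempty) mask, for oracle tests.
random_small_volume <- function(seed, d = c(5, 5, 5), p_mask = 0.7,
                                lo = -100, hi = 100) {
  set.seed(seed)
  arr <- array(runif(prod(d), lo, hi), dim = d)
  mask <- array(runif(prod(d)) < p_mask, dim = d)
  if (!any(mask)) mask[sample(prod(d), 3)] <- TRUE
  list(arr = arr, mask = mask,
       vol = annotated_volume(arr, c(1, 1, 1), mask))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
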