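#' Specification of a synthetic nodule phantom
#'
#' Describes a 3D lung-nodule phantom: a sphere of given radius embedded in a
#' uniform background, partitioned internally into intensity plateaus that
#' play the role of tumor habitats. Plateaus are radial shells (core / mid /
#' rim) by default, which makes the planted partition unambiguous; a random
#' "blob" mode (nearest-seed Voronoi cells inside the nodule) is available.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param spacing_mm Numeric length-3, voxel size in mm (may be anisotropic).
#' @param nodule_radius_mm Sphere radius in mm; the nodule must fit strictly
#'   inside the grid.
#' @param n_plateaus Number of internal intensity plateaus (>= 1).
#' @param plateau_levels Numeric vector of HU levels, one per plateau;
#'   pairwise distinct when `n_plateaus > 1`.
#' @param noise_sd Additive Gaussian noise SD (HU) inside the nodule.
#' @param background_hu Background (lung parenchyma) level in HU.
#' @param plateau_mode `"slabs"` (default: axial bands of whole voxel
#'   layers with near-equal voxel counts; their planar interfaces make the
#'   planted partition unambiguous under 3x3x3 windowed statistics),
#'   `"shells"` (radial core/mid/rim) or `"blobs"` (nearest-seed Voronoi
#'   cells). Curved interfaces (shells, blobs) carry a one-voxel layer of
#'   formally ambiguous interface voxels; see the package vignette.
#' @param center_vox Optional integer length-3 voxel index of the nodule
#'   centre; defaults to the grid centre voxel.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(40L, 40L, 40L),
                         spacing_mm = c(1, 1, 1),
                         nodule_radius_mm = 8,
                         n_plateaus = 3L,
                         plateau_levels = c(-400, -150, 100),
                         noise_sd = 20,
                         background_hu = -800,
                         plateau_mode = c("slabs", "shells", "blobs"),
                         center_vox = NULL) {
  plateau_mode <- match.arg(plateau_mode)
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stopf("grid_shape must be 3 positive integers")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stopf("spacing_mm must be 3 positive values")
  if (nodule_radius_mm <= 0) stopf("nodule_radius_mm must be positive")
  n_plateaus <- as.integer(n_plateaus)
  if (n_plateaus < 1L) stopf("n_plateaus must be >= 1")
  if (length(plateau_levels) != n_plateaus)
    stopf("plateau_levels must have length n_plateaus (%d)", n_plateaus)
  if (n_plateaus > 1L && anyDuplicated(plateau_levels))
    stopf("plateau_levels must be pairwise distinct")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  if (is.null(center_vox)) center_vox <- ceiling(grid_shape / 2)
  center_vox <- as.integer(center_vox)
  center_mm <- (center_vox - 1) * spacing_mm
  extent_mm <- (grid_shape - 1) * spacing_mm
  if (any(center_mm - nodule_radius_mm < 0) ||
      any(center_mm + nodule_radius_mm > extent_mm))
    stopf("nodule of radius %.1f mm at voxel (%s) exceeds the %s grid",
          nodule_radius_mm, paste(center_vox, collapse = ","),
          paste(grid_shape, collapse = "x"))
  structure(list(grid_shape = grid_shape, spacing_mm = spacing_mm,
                 nodule_radius_mm = nodule_radius_mm,
                 n_plateaus = n_plateaus, plateau_levels = plateau_levels,
                 noise_sd = noise_sd, background_hu = background_hu,
                 plateau_mode = plateau_mode, center_vox = center_vox),
            class = "phantom_spec")
}

# Squared physical distance of every voxel centre to the nodule centre.
phantom_dist2 <- function(spec) {
  d <- spec$grid_shape; sp <- spec$spacing_mm; cv <- spec$center_vox
  ax <- lapply(1:3, function(a) (((seq_len(d[a]) - cv[a]) * sp[a]))^2)
  outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+")
}

# Regularize a planted partition to be median-stable: iteratively relabel
# each voxel to the plateau whose level equals the lower median of the
# plateau levels over its in-mask 3x3x3 neighbourhood. At the fixpoint the
# window lower-median of the painted (noiseless) phantom equals every
# voxel's own plateau level, so the partition is recoverable from windowed
# local statistics; without this step, single-voxel interface effects make
# a geometric partition formally unrecoverable.
median_stabilize_labels <- function(lab, mask, levels, max_iter = 50L) {
  d <- dim(mask)
  idx <- which(mask)
  ijk <- arrayInd(idx, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nbl <- matrix(NA_integer_, length(idx), nrow(offs))
  nbpos <- matrix(NA_integer_, length(idx), nrow(offs))
  for (r in seq_len(nrow(offs))) {
    ti <- ijk[, 1] + offs[r, 1]; tj <- ijk[, 2] + offs[r, 2]
    tk <- ijk[, 3] + offs[r, 3]
    ok <- ti >= 1 & ti <= d[1] & tj >= 1 & tj <= d[2] & tk >= 1 & tk <= d[3]
    lin <- (tk[ok] - 1) * d[1] * d[2] + (tj[ok] - 1) * d[1] + ti[ok]
    valid <- mask[lin]
    pos <- rep(NA_integer_, length(idx))
    pos[ok][valid] <- lin[valid]
    nbpos[, r] <- pos
  }
  lev_of <- function(l) levels[l]
  cur <- lab
  for (it in seq_len(max_iter)) {
    curvals <- array(NA_real_, d)
    curvals[idx] <- lev_of(cur[idx])
    new <- cur
    changed <- FALSE
    for (i in seq_along(idx)) {
      vs <- curvals[nbpos[i, ]]
      vs <- vs[!is.na(vs)]
      med <- sort(vs)[ceiling(length(vs) / 2)]
      nl <- which(levels == med)[1]
      if (nl != cur[idx[i]]) { new[idx[i]] <- nl; changed <- TRUE }
    }
    cur <- new
    if (!changed) break
  }
  cur
}

#' Generate a synthetic nodule phantom
#'
#' The mask is the set of voxels whose centres lie within
#' `nodule_radius_mm` of the nodule centre (physical distance, anisotropy
#' aware). In-mask intensities equal the plateau level of the voxel's planted
#' subregion plus Gaussian noise; out-of-mask voxels equal `background_hu`
#' exactly. The planted subregion labels are returned in the `truth` element
#' so habitat recovery can be scored.
#'
#' @param spec A [phantom_spec()].
#' @param seed RNG seed for the noise (and blob seeds, if used).
#' @return An [annotated_volume()] with an extra integer array element
#'   `truth` (0 outside the nodule, 1..n_plateaus inside).
#' @export
generate_phantom <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  dist2 <- phantom_dist2(spec)
  r <- spec$nodule_radius_mm
  mask <- dist2 <= r^2
  n <- spec$n_plateaus
  truth <- array(0L, dim = spec$grid_shape)
  with_seed(seed, {
    if (n == 1L) {
      lab <- rep(1L, sum(mask))
    } else if (spec$plateau_mode == "slabs") {
      # whole voxel layers grouped into n contiguous bands of near-equal
      # voxel count
      zc <- arrayInd(which(mask), spec$grid_shape)[, 3]
      layers <- sort(unique(zc))
      cnt <- as.vector(table(factor(zc, levels = layers)))
      cum <- cumsum(cnt)
      band_of_layer <- pmin(n, floor((cum - cnt / 2) / sum(cnt) * n) + 1L)
      band_of_layer <- cummax(band_of_layer)
      lab <- band_of_layer[match(zc, layers)]
    } else if (spec$plateau_mode == "shells") {
      lab <- pmin(n, floor(sqrt(dist2[mask]) / r * n) + 1L)
    } else {
      idx <- which(mask)
      seeds <- sample(idx, n)
      pos <- arrayInd(idx, spec$grid_shape) %*% diag(spec$spacing_mm)
      spos <- arrayInd(seeds, spec$grid_shape) %*% diag(spec$spacing_mm)
      dd <- sapply(seq_len(n), function(j)
        rowSums(sweep(pos, 2, spos[j, ], "-")^2))
      lab <- max.col(-dd, ties.method = "first")
    }
    truth[mask] <- as.integer(lab)
    if (n > 1L)
      truth <- median_stabilize_labels(truth, mask, spec$plateau_levels)
    if (length(unique(truth[mask])) < n)
      warnf("plateau(s) eliminated by partition regularization; %d of %d remain",
            length(unique(truth[mask])), n)
    # acquisition noise applies to the whole field of view; with
    # noise_sd = 0 the background is exactly background_hu
    img <- array(spec$background_hu +
                   if (spec$noise_sd > 0)
                     stats::rnorm(prod(spec$grid_shape), 0, spec$noise_sd)
                   else 0,
                 dim = spec$grid_shape)
    img[mask] <- spec$plateau_levels[truth[mask]] +
      if (spec$noise_sd > 0) stats::rnorm(sum(mask), 0, spec$noise_sd) else 0
    vol <- annotated_volume(img, spec$spacing_mm, mask)
    vol$truth <- truth
    vol
  })
}

#' Specification of a synthetic cohort
#'
#' Describes a cohort of phantom samples with a known, controllable label
#' signal. Each sample carries a binary molecular label (mutant vs
#' wild-type). One designated texture-bearing generative parameter — the
#' plateau contrast (HU spread between core and rim) — is shifted by
#' `effect_size_d` within-class standard deviations for mutants, so the Bayes
#' AUC of the cohort is the closed form `pnorm(d / sqrt(2))`. Smoking and
#' gender are sampled class-conditionally; the remaining clinical covariates
#' (stage, CT pattern, histology, lobe) are label-independent.
#'
#' Default class balance and class-conditional smoking/gender probabilities
#' follow the baseline profile of the multicenter early-stage NSCLC training
#' cohort the simulator emulates (63.8% mutant; smoking 22.8% in mutants vs
#' 47.4% in wild-type; female 65.5% vs 44.3%).
#'
#' @param n_samples Number of samples (>= 2).
#' @param mutant_fraction Probability a sample is mutant, in (0,1) normally.
#' @param effect_size_d Standardized mean shift of the designated
#'   texture-bearing parameter for mutants.
#' @param smoking_prob_by_class Length-2 probabilities `c(mutant, wildtype)`
#'   of positive smoking history.
#' @param female_prob_by_class Length-2 probabilities `c(mutant, wildtype)`
#'   of female gender.
#' @param seed Root RNG seed; per-sample child streams are derived from it.
#' @param phantom Base [phantom_spec()] template for the image phantoms.
#' @param contrast_mean,contrast_sd Mean and within-class SD (HU) of the
#'   designated plateau-contrast parameter.
#' @param resample_degenerate If `TRUE` (default), a draw in which one class
#'   is absent while `0 < mutant_fraction < 1` is redrawn (up to 100 times);
#'   if `FALSE`, such a draw is an error.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples,
                        mutant_fraction = 0.638,
                        effect_size_d = 1.5,
                        smoking_prob_by_class = c(0.228, 0.474),
                        female_prob_by_class = c(0.655, 0.443),
                        seed = 1L,
                        phantom = phantom_spec(),
                        contrast_mean = 250,
                        contrast_sd = 50,
                        resample_degenerate = TRUE) {
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L) stopf("n_samples must be >= 2")
  probs <- c(mutant_fraction, smoking_prob_by_class, female_prob_by_class)
  if (any(probs < 0) || any(probs > 1))
    stopf("all probabilities must lie in [0, 1]")
  stopifnot(inherits(phantom, "phantom_spec"),
            length(smoking_prob_by_class) == 2L,
            length(female_prob_by_class) == 2L)
  structure(list(n_samples = n_samples, mutant_fraction = mutant_fraction,
                 effect_size_d = effect_size_d,
                 smoking_prob_by_class = smoking_prob_by_class,
                 female_prob_by_class = female_prob_by_class,
                 seed = seed, phantom = phantom,
                 contrast_mean = contrast_mean, contrast_sd = contrast_sd,
                 resample_degenerate = resample_degenerate),
            class = "cohort_spec")
}

# Label-independent marginals for the remaining clinical covariates.
.clinical_marginals <- list(
  stage     = c(AIS = 0.067, IA = 0.828, IB = 0.105),
  ct_pattern = c(`ground-glass` = 0.52, mixed = 0.25, solid = 0.23),
  histology = c(adenocarcinoma = 0.87, other = 0.05, unknown = 0.08),
  location  = c(`left upper lobe` = 0.24, `left lower lobe` = 0.12,
                `right upper lobe` = 0.38, `right middle lobe` = 0.045,
                `right lower lobe` = 0.215)
)

#' Generate a phantom cohort
#'
#' Draws labels, clinical records and per-sample phantom volumes from a
#' [cohort_spec()]. RNG streams: the root seed first draws the label vector
#' and one child seed per sample; sample `i` is then generated entirely from
#' child seed `i` (clinical covariates, then latent image parameters, then
#' the phantom noise), so the cohort is bit-reproducible and individual
#' samples can be regenerated in isolation.
#'
#' @param spec A [cohort_spec()].
#' @param volumes If `FALSE`, skip phantom image generation and return only
#'   clinical records, labels and the latent parameter table (fast path for
#'   tabular downstream testing).
#' @return A list of class `phantom_cohort` with elements `samples` (list of
#'   `list(volume, record)`; volumes `NULL` when `volumes = FALSE`),
#'   `clinical` (data frame of clinical records), `labels` (factor
#'   wild-type/mutant), and `latent` (data frame of the generative per-sample
#'   parameters, including the designated `contrast` feature).
#' @export
generate_cohort <- function(spec, volumes = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_samples
  f <- spec$mutant_fraction
  with_seed(spec$seed, {
    lab <- stats::rbinom(n, 1L, f)
    if (f > 0 && f < 1) {
      tries <- 0L
      while (length(unique(lab)) < 2L) {
        if (!spec$resample_degenerate)
          stopf("degenerate single-class cohort draw (n = %d)", n)
        tries <- tries + 1L
        if (tries > 100L) stopf("failed to draw a two-class cohort")
        lab <- stats::rbinom(n, 1L, f)
      }
    }
    seeds <- child_seed(spec$seed, seq_len(n))
  })
  base <- spec$phantom
  grid_r_max <- min((base$center_vox - 1) * base$spacing_mm,
                    (base$grid_shape - base$center_vox) * base$spacing_mm)
  samples <- vector("list", n)
  clin <- vector("list", n)
  latent <- vector("list", n)
  for (i in seq_len(n)) {
    mutant <- lab[i] == 1L
    cls <- if (mutant) 1L else 2L
    res <- with_seed(seeds[i], {
      record <- data.frame(
        sample_id = sprintf("S%04d", i),
        age = max(30L, round(stats::rnorm(1, 60, 9))),
        gender = ifelse(stats::runif(1) < spec$female_prob_by_class[cls],
                        "female", "male"),
        stage = sample(names(.clinical_marginals$stage), 1,
                       prob = .clinical_marginals$stage),
        smoking = ifelse(stats::runif(1) < spec$smoking_prob_by_class[cls],
                         "yes", "no"),
        ct_pattern = sample(names(.clinical_marginals$ct_pattern), 1,
                            prob = .clinical_marginals$ct_pattern),
        histology = sample(names(.clinical_marginals$histology), 1,
                           prob = .clinical_marginals$histology),
        location = sample(names(.clinical_marginals$location), 1,
                          prob = .clinical_marginals$location),
        egfr = ifelse(mutant, "mutant", "wild-type"),
        stringsAsFactors = FALSE)
      contrast <- stats::rnorm(1, spec$contrast_mean +
                                 (if (mutant) spec$effect_size_d * spec$contrast_sd else 0),
                               spec$contrast_sd)
      contrast <- max(contrast, 10)
      mid <- stats::rnorm(1, -150, 30)
      radius <- stats::runif(1, 0.55, 0.9) *
        min(grid_r_max - max(base$spacing_mm), base$nodule_radius_mm * 1.2)
      noise_sd <- max(5, stats::rnorm(1, base$noise_sd, base$noise_sd / 5))
      lat <- data.frame(sample_id = record$sample_id,
                        contrast = contrast, mid_hu = mid,
                        radius_mm = radius, noise_sd = noise_sd,
                        egfr = record$egfr, stringsAsFactors = FALSE)
      vol <- NULL
      if (volumes) {
        pspec <- phantom_spec(
          grid_shape = base$grid_shape, spacing_mm = base$spacing_mm,
          nodule_radius_mm = radius, n_plateaus = base$n_plateaus,
          plateau_levels = mid + contrast *
            seq(-0.5, 0.5, length.out = base$n_plateaus),
          noise_sd = noise_sd, background_hu = base$background_hu,
          plateau_mode = base$plateau_mode, center_vox = base$center_vox)
        vol <- generate_phantom(pspec, seed = child_seed(seeds[i], 7919))
      }
      list(record = record, latent = lat, vol = vol)
    })
    clin[[i]] <- res$record
    latent[[i]] <- res$latent
    samples[[i]] <- list(volume = res$vol, record = res$record)
  }
  structure(list(samples = samples,
                 clinical = do.call(rbind, clin),
                 labels = factor(ifelse(lab == 1L, "mutant", "wild-type"),
                                 levels = c("wild-type", "mutant")),
                 latent = do.call(rbind, latent),
                 spec = spec),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat("<phantom_cohort> ", length(x$samples), " samples (",
      sum(x$labels == "mutant"), " mutant), volumes ",
      ifelse(is.null(x$samples[[1]]$volume), "absent", "present"),
      "\n", sep = "")
  invisible(x)
}

#' Simulate a tabular feature cohort
#'
#' A tabular phantom for exercising the selection cascade and model stages
#' at scale without image extraction: one designated informative Gaussian
#' feature whose class means differ by `d` within-class SDs, plus
#' independent standard-normal noise features. With a single such feature
#' the Bayes AUC is `pnorm(d / sqrt(2))`.
#'
#' @param n Number of samples.
#' @param d Standardized effect size of the informative feature.
#' @param n_noise Number of pure-noise features.
#' @param mutant_fraction Class balance.
#' @param seed RNG seed.
#' @return List with `features` (data frame; informative column named
#'   `signal`, noise columns `noise01`...) and `labels` (factor).
#' @export
simulate_feature_table <- function(n, d, n_noise = 20,
                                   mutant_fraction = 0.638, seed = 1L) {
  with_seed(seed, {
    lab <- stats::rbinom(n, 1L, mutant_fraction)
    while (length(unique(lab)) < 2L) lab <- stats::rbinom(n, 1L, mutant_fraction)
    x <- stats::rnorm(n, d * lab, 1)
    noise <- matrix(stats::rnorm(n * n_noise), n, n_noise,
                    dimnames = list(NULL, sprintf("noise%02d", seq_len(n_noise))))
    list(features = data.frame(signal = x, noise, check.names = FALSE),
         labels = factor(ifelse(lab == 1L, "mutant", "wild-type"),
                         levels = c("wild-type", "mutant")))
  })
}

#' Write a phantom cohort to disk
#'
#' Emits one NIfTI image/mask pair per sample, the clinical table as CSV,
#' and a manifest CSV mapping sample id to file paths and label.
#'
#' @param cohort A `phantom_cohort` generated with `volumes = TRUE`.
#' @param dir Output directory (created if needed).
#' @param compress Use `.nii.gz` (default) or plain `.nii`.
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir, compress = TRUE) {
  stopifnot(inherits(cohort, "phantom_cohort"))
  if (is.null(cohort$samples[[1]]$volume))
    stopf("cohort was generated without volumes")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (compress) ".nii.gz" else ".nii"
  rows <- lapply(cohort$samples, function(s) {
    id <- s$record$sample_id
    img <- file.path(dir, paste0(id, "_image", ext))
    msk <- file.path(dir, paste0(id, "_mask", ext))
    write_annotated_volume(s$volume, img, msk)
    data.frame(sample_id = id, image = img, mask = msk,
               egfr = s$record$egfr, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
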