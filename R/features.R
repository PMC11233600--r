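#' Extract the feature bank for one sample
#'
#' Runs the full handcrafted feature bank over the sample's analysis
#' regions: shape features once per region (original geometry only), and
#' first-order plus texture features per region per transform. Every value
#' carries provenance tags (region, transform, family, name).
#'
#' @param vol A preprocessed [annotated_volume()].
#' @param rs A [region_set()] for the same grid; if `NULL`, one is built
#'   with the defaults.
#' @param transforms A named list of transformed volumes from
#'   [transform_bank()], or `NULL` to compute it; pass
#'   `list(original = vol)` to restrict to the untransformed image.
#' @param disc A [discretization()].
#' @param sample_id Sample identifier recorded in the table.
#' @param families Feature families to compute, subset of
#'   `c("shape", "firstorder", "texture")`.
#' @param seed Seed for habitat clustering when `rs` is `NULL`.
#' @return A tidy data frame with columns `sample_id`, `region`,
#'   `transform`, `family`, `name`, `value`; one row per feature.
#' @export
extract_feature_table <- function(vol, rs = NULL, transforms = NULL,
                                  disc = discretization(),
                                  sample_id = "sample",
                                  families = c("shape", "firstorder",
                                               "texture"),
                                  seed = 1L) {
  stopifnot(is_annotated_volume(vol))
  families <- match.arg(families, several.ok = TRUE)
  if (is.null(rs)) rs <- region_set(vol, seed = seed)
  if (is.null(transforms)) transforms <- transform_bank(vol)
  regions <- c(list(intra = rs$tumor_mask), rs$shells)
  for (h in seq_len(rs$k)) {
    hm <- rs$habitat_labels == h
    if (any(hm)) regions[[paste0("habitat", h)]] <- hm
  }
  rows <- list()
  add <- function(region, transform, family, vals) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sample_id, region = region, transform = transform,
      family = family, name = names(vals), value = unname(vals),
      stringsAsFactors = FALSE)
  }
  for (rg in names(regions)) {
    msk <- regions[[rg]]
    if ("shape" %in% families) {
      sf <- shape_features(msk, vol$spacing)
      names(sf) <- paste0("shape_", names(sf))
      add(rg, "original", "shape", sf)
    }
    for (tf in names(transforms)) {
      tvol <- transforms[[tf]]
      if ("firstorder" %in% families) {
        fo <- first_order_features(tvol, mask = msk, disc = disc)
        names(fo) <- paste0("firstorder_", names(fo))
        add(rg, tf, "firstorder", fo)
      }
      if ("texture" %in% families) {
        tx <- texture_features(tvol, mask = msk, disc = disc)
        fam <- attr(tx, "family")
        add(rg, tf, NA, tx)
        rows[[length(rows)]]$family <- fam
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pivot a tidy feature table to one row per sample
#'
#' Column names follow the stable convention
#' `region__transform__name` (the name already carries its family prefix).
#'
#' @param tidy A tidy feature table from [extract_feature_table()] (possibly
#'   several samples row-bound).
#' @return A data frame, one row per sample, first column `sample_id`.
#' @export
widen_feature_table <- function(tidy) {
  key <- paste(tidy$region, tidy$transform, tidy$name, sep = "__")
  ids <- unique(tidy$sample_id)
  cols <- unique(key)
  wide <- matrix(NA_real_, length(ids), length(cols),
                 dimnames = list(ids, cols))
  wide[cbind(match(tidy$sample_id, ids), match(key, cols))] <- tidy$value
  data.frame(sample_id = ids, wide, check.names = FALSE,
             row.names = NULL, stringsAsFactors = FALSE)
}

# One-voxel segmentation perturbation used to synthesize a test-retest
# feature table: 6-connected erosion when it leaves the mask nonempty,
# otherwise a 1 mm dilation.
perturb_mask <- function(mask, spacing) {
  d <- dim(mask)
  P <- array(FALSE, d + 2L)
  P[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- mask
  er <- mask
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    er <- er & P[1L + o[1] + seq_len(d[1]), 1L + o[2] + seq_len(d[2]),
                 1L + o[3] + seq_len(d[3])]
  }
  if (any(er)) er else dilate_roi(mask, spacing, min(spacing))
}

#' Extract features for a whole cohort
#'
#' Preprocesses each sample (clip + isotropic resampling), constructs its
#' region set and transform bank, and extracts the feature table. With
#' `perturb = TRUE` a second table is extracted from one-voxel-perturbed
#' tumor masks, providing the segmentation test-retest pair consumed by
#' [icc_filter()].
#'
#' @param cohort A `phantom_cohort` (with volumes), or a list of
#'   [annotated_volume()] objects.
#' @param transforms Character: `"all"` (LoG + wavelet) or `"original"`.
#' @param disc A [discretization()].
#' @param shell_radii_mm,k,seed Region-construction parameters.
#' @param families Feature families to compute.
#' @param perturb Also extract the perturbed-mask table (default `FALSE`).
#' @param preprocess Apply [preprocess_volume()] first (default `TRUE`).
#' @param log_sigmas_mm LoG sigmas when `transforms = "all"`.
#' @return List with `wide` (samples x features data frame), `tidy`, and —
#'   when `perturb` — `wide_perturbed`.
#' @export
extract_cohort_features <- function(cohort, transforms = c("all", "original"),
                                    disc = discretization(),
                                    shell_radii_mm = c(1, 3, 5), k = 3L,
                                    seed = 1L,
                                    families = c("shape", "firstorder",
                                                 "texture"),
                                    perturb = FALSE, preprocess = TRUE,
                                    log_sigmas_mm = c(1, 2)) {
  transforms <- match.arg(transforms)
  vols <- if (inherits(cohort, "phantom_cohort"))
    lapply(cohort$samples, `[[`, "volume") else cohort
  ids <- if (inherits(cohort, "phantom_cohort"))
    vapply(cohort$samples, function(s) s$record$sample_id, "")
  else sprintf("S%04d", seq_along(vols))
  tidy <- list(); tidy_b <- list()
  for (i in seq_along(vols)) {
    vol <- vols[[i]]
    if (preprocess) vol <- preprocess_volume(vol, sample_id = ids[i])
    tb <- if (transforms == "all")
      transform_bank(vol, log_sigmas_mm = log_sigmas_mm)
    else list(original = vol)
    rs <- region_set(vol, shell_radii_mm = shell_radii_mm, k = k,
                     seed = child_seed(seed, i))
    tidy[[i]] <- extract_feature_table(vol, rs = rs, transforms = tb,
                                       disc = disc, sample_id = ids[i],
                                       families = families)
    if (perturb) {
      volb <- vol
      volb$mask <- perturb_mask(vol$mask, vol$spacing)
      tbb <- lapply(tb, function(v) { v$mask <- volb$mask; v })
      rsb <- region_set(volb, shell_radii_mm = shell_radii_mm, k = k,
                        seed = child_seed(seed, i))
      tidy_b[[i]] <- extract_feature_table(volb, rs = rsb, transforms = tbb,
                                           disc = disc, sample_id = ids[i],
                                           families = families)
    }
  }
  tidy_all <- do.call(rbind, tidy)
  out <- list(tidy = tidy_all, wide = widen_feature_table(tidy_all))
  if (perturb) {
    tb_all <- do.call(rbind, tidy_b)
    wb <- widen_feature_table(tb_all)
    common <- intersect(names(out$wide), names(wb))
    out$wide_perturbed <- wb[, common, drop = FALSE]
    out$wide <- out$wide[, common, drop = FALSE]
  }
  out
}

#' Write feature tables to CSV
#'
#' @param feats Result of [extract_cohort_features()].
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_feature_tables <- function(feats, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "features_tidy.csv")
  p2 <- file.path(dir, "features_wide.csv")
  utils::write.csv(feats$tidy, p1, row.names = FALSE)
  utils::write.csv(feats$wide, p2, row.names = FALSE)
  invisible(c(p1, p2))
}
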