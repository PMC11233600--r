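#' Default run configuration
#'
#' The full parameter set of a pipeline run, serializable to YAML with an
#' exact load/save round trip. Every random operation in the run traces to
#' the single `seed` recorded here.
#'
#' @param out_dir Run directory.
#' @param seed Root seed.
#' @param n_samples Cohort size.
#' @param effect_size_d Planted effect size.
#' @param transforms `"all"` or `"original"`.
#' @return A `run_config` list.
#' @export
default_run_config <- function(out_dir = "habitomics_run", seed = 1L,
                               n_samples = 40L, effect_size_d = 1.5,
                               transforms = "original") {
  structure(list(
    out_dir = out_dir,
    seed = seed,
    simulate = list(n_samples = n_samples, mutant_fraction = 0.638,
                    effect_size_d = effect_size_d,
                    smoking_prob_by_class = c(0.228, 0.474),
                    female_prob_by_class = c(0.655, 0.443),
                    grid_shape = c(28L, 28L, 28L), spacing_mm = c(1, 1, 1),
                    nodule_radius_mm = 8, n_plateaus = 3L, noise_sd = 20,
                    background_hu = -800),
    preprocess = list(clip_lo = -800, clip_hi = 800, target_spacing = 1),
    regions = list(shell_radii_mm = c(1, 3, 5), k = 3L, bin_width_hu = 25),
    features = list(transforms = transforms, bin_width_hu = 25,
                    log_sigmas_mm = c(1, 2), perturb = TRUE),
    select = list(icc_threshold = 0.85, alpha = 0.05, r_threshold = 0.9,
                  mrmr_k = 30L, cv_folds = 5L, lambda = "1se"),
    train = list(split_prop = 0.7, cv_folds = 5L,
                 algorithms = list(intra = "lr", peri1 = "lr", peri3 = "lr",
                                   peri5 = "lr", habitat = "lr"),
                 dtl_placeholder = TRUE),
    evaluate = list(hl_groups = 10L, dca_step = 0.01)),
    class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return A `run_config` (for `read_run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @return Invisibly, `path` (for `write_run_config`).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

manifest_path <- function(out_dir) file.path(out_dir, "manifest.json")

read_manifest <- function(out_dir) {
  p <- manifest_path(out_dir)
  if (file.exists(p)) jsonlite::read_json(p) else list(stages = list())
}

write_manifest <- function(out_dir, manifest) {
  jsonlite::write_json(manifest, manifest_path(out_dir), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
}

stage_done <- function(manifest, stage, out_dir) {
  st <- manifest$stages[[stage]]
  if (is.null(st) || !isTRUE(st$complete)) return(FALSE)
  all(file.exists(file.path(out_dir, unlist(st$outputs))))
}

record_stage <- function(out_dir, stage, outputs, t0) {
  manifest <- read_manifest(out_dir)
  rel <- outputs
  hashes <- as.list(tools::md5sum(file.path(out_dir, rel)))
  names(hashes) <- rel
  manifest$stages[[stage]] <- list(
    complete = TRUE, outputs = as.list(rel), md5 = hashes,
    seconds = round(as.numeric(Sys.time()) - t0, 2))
  write_manifest(out_dir, manifest)
}

pipeline_stages <- c("simulate", "preprocess", "regions", "extract",
                     "select", "train", "evaluate")

#' Run the full pipeline
#'
#' Executes simulate, preprocess, regions, extract, select, train and
#' evaluate in order inside `config$out_dir`, writing a manifest with
#' per-stage outputs, MD5 hashes and timing. A stage whose manifest entry
#' is complete and whose outputs still exist is skipped, so a run is
#' resumable per stage (delete a stage's outputs to re-run from there).
#' Stage failure leaves earlier results on disk and raises an error naming
#' the stage.
#'
#' @param config A `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @return Invisibly, the run directory.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  manifest <- read_manifest(out_dir)
  for (stage in pipeline_stages) {
    if (stage_done(manifest, stage, out_dir)) next
    t0 <- as.numeric(Sys.time())
    message(sprintf("[habitomics] stage %s ...", stage))
    outputs <- tryCatch(
      do.call(paste0("stage_", stage), list(config)),
      error = function(e) stopf("stage '%s' failed: %s", stage,
                                conditionMessage(e)))
    record_stage(out_dir, stage, outputs, t0)
    manifest <- read_manifest(out_dir)
  }
  invisible(out_dir)
}

stage_simulate <- function(config) {
  s <- config$simulate
  ph <- phantom_spec(grid_shape = unlist(s$grid_shape),
                     spacing_mm = unlist(s$spacing_mm),
                     nodule_radius_mm = s$nodule_radius_mm,
                     n_plateaus = s$n_plateaus,
                     plateau_levels = seq(-400, 100,
                                          length.out = s$n_plateaus),
                     noise_sd = s$noise_sd, background_hu = s$background_hu)
  cs <- cohort_spec(n_samples = s$n_samples,
                    mutant_fraction = s$mutant_fraction,
                    effect_size_d = s$effect_size_d,
                    smoking_prob_by_class = unlist(s$smoking_prob_by_class),
                    female_prob_by_class = unlist(s$female_prob_by_class),
                    seed = config$seed, phantom = ph)
  cohort <- generate_cohort(cs)
  dir <- file.path(config$out_dir, "cohort")
  write_cohort(cohort, dir)
  utils::write.csv(cohort$latent, file.path(dir, "latent.csv"),
                   row.names = FALSE)
  file.path("cohort", c("manifest.csv", "clinical.csv", "latent.csv"))
}

read_cohort_manifest <- function(config) {
  utils::read.csv(file.path(config$out_dir, "cohort", "manifest.csv"),
                  stringsAsFactors = FALSE)
}

stage_preprocess <- function(config) {
  mf <- read_cohort_manifest(config)
  p <- config$preprocess
  dir <- file.path(config$out_dir, "prep")
  dir.create(dir, showWarnings = FALSE)
  outs <- character(0)
  for (i in seq_len(nrow(mf))) {
    vol <- read_annotated_volume(mf$image[i], mf$mask[i])
    vol <- clip_intensities(vol, p$clip_lo, p$clip_hi)
    vol <- resample_isotropic(vol, p$target_spacing,
                              sample_id = mf$sample_id[i])
    ip <- file.path(dir, paste0(mf$sample_id[i], "_image.nii.gz"))
    mp <- file.path(dir, paste0(mf$sample_id[i], "_mask.nii.gz"))
    write_annotated_volume(vol, ip, mp)
    jsonlite::write_json(list(clip = c(p$clip_lo, p$clip_hi),
                              target_spacing = p$target_spacing,
                              order = c("clip", "resample")),
                         file.path(dir, paste0(mf$sample_id[i], ".json")),
                         auto_unbox = TRUE)
    outs <- c(outs, file.path("prep", basename(c(ip, mp))))
  }
  outs
}

read_prep_volume <- function(config, sample_id) {
  dir <- file.path(config$out_dir, "prep")
  read_annotated_volume(file.path(dir, paste0(sample_id, "_image.nii.gz")),
                        file.path(dir, paste0(sample_id, "_mask.nii.gz")))
}

stage_regions <- function(config) {
  mf <- read_cohort_manifest(config)
  r <- config$regions
  dir <- file.path(config$out_dir, "regions")
  outs <- character(0)
  for (i in seq_len(nrow(mf))) {
    vol <- read_prep_volume(config, mf$sample_id[i])
    rs <- region_set(vol, shell_radii_mm = unlist(r$shell_radii_mm),
                     k = r$k, seed = child_seed(config$seed, i),
                     bin_width_hu = r$bin_width_hu)
    paths <- write_region_set(rs, dir, prefix = mf$sample_id[i])
    outs <- c(outs, file.path("regions", basename(paths)))
  }
  outs
}

read_region_set <- function(config, sample_id) {
  dir <- file.path(config$out_dir, "regions")
  rd <- function(name) {
    arr <- RNifti::readNifti(file.path(dir, paste0(sample_id, "_", name,
                                                   ".nii.gz")))
    array(as.integer(arr), dim = dim(arr)[1:3])
  }
  radii <- unlist(config$regions$shell_radii_mm)
  shells <- lapply(radii, function(rr) rd(paste0("peri", rr)) > 0L)
  names(shells) <- paste0("peri", radii)
  structure(list(tumor_mask = rd("tumor") > 0L, shells = shells,
                 habitat_labels = rd("habitats"),
                 shell_radii_mm = radii, k = config$regions$k),
            class = "region_set")
}

stage_extract <- function(config) {
  mf <- read_cohort_manifest(config)
  f <- config$features
  disc <- discretization(bin_width_hu = f$bin_width_hu)
  tidy <- list(); tidy_b <- list()
  for (i in seq_len(nrow(mf))) {
    id <- mf$sample_id[i]
    vol <- read_prep_volume(config, id)
    rs <- read_region_set(config, id)
    rs$spacing <- vol$spacing
    tb <- if (identical(f$transforms, "all"))
      transform_bank(vol, log_sigmas_mm = unlist(f$log_sigmas_mm))
    else list(original = vol)
    tidy[[i]] <- extract_feature_table(vol, rs = rs, transforms = tb,
                                       disc = disc, sample_id = id)
    if (isTRUE(f$perturb)) {
      volb <- vol
      volb$mask <- perturb_mask(vol$mask, vol$spacing)
      tbb <- lapply(tb, function(v) { v$mask <- volb$mask; v })
      rsb <- region_set(volb, shell_radii_mm = unlist(config$regions$shell_radii_mm),
                        k = config$regions$k,
                        seed = child_seed(config$seed, i),
                        bin_width_hu = config$regions$bin_width_hu)
      tidy_b[[i]] <- extract_feature_table(volb, rs = rsb, transforms = tbb,
                                           disc = disc, sample_id = id)
    }
  }
  dir <- file.path(config$out_dir, "features")
  dir.create(dir, showWarnings = FALSE)
  wide <- widen_feature_table(do.call(rbind, tidy))
  utils::write.csv(wide, file.path(dir, "features_wide.csv"),
                   row.names = FALSE)
  outs <- file.path("features", "features_wide.csv")
  if (isTRUE(f$perturb)) {
    wb <- widen_feature_table(do.call(rbind, tidy_b))
    common <- intersect(names(wide), names(wb))
    utils::write.csv(wb[, common, drop = FALSE],
                     file.path(dir, "features_perturbed.csv"),
                     row.names = FALSE)
    outs <- c(outs, file.path("features", "features_perturbed.csv"))
  }
  outs
}

# Region groups used for per-region signatures; habitat pools the
# per-habitat sub-banks.
region_group_of <- function(colnames) {
  region <- sub("__.*$", "", colnames)
  ifelse(grepl("^habitat", region), "habitat", region)
}

stage_select <- function(config) {
  dir <- file.path(config$out_dir, "features")
  wide <- utils::read.csv(file.path(dir, "features_wide.csv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  clin <- utils::read.csv(file.path(config$out_dir, "cohort", "clinical.csv"),
                          stringsAsFactors = FALSE)
  labels <- factor(clin$egfr[match(wide$sample_id, clin$sample_id)],
                   levels = c("wild-type", "mutant"))
  pert_path <- file.path(dir, "features_perturbed.csv")
  widep <- if (file.exists(pert_path))
    utils::read.csv(pert_path, check.names = FALSE,
                    stringsAsFactors = FALSE) else NULL
  split <- split_cohort(labels, prop = config$train$split_prop,
                        seed = config$seed)
  sdir <- file.path(config$out_dir, "select")
  dir.create(sdir, showWarnings = FALSE)
  s <- config$select
  groups <- unique(region_group_of(feature_columns(wide)))
  outs <- character(0)
  for (g in groups) {
    cols <- feature_columns(wide)[region_group_of(feature_columns(wide)) == g]
    tab <- wide[split$train, c("sample_id", cols), drop = FALSE]
    tabp <- if (is.null(widep)) NULL else
      widep[split$train, intersect(c("sample_id", cols), names(widep)),
            drop = FALSE]
    rep_g <- tryCatch(
      run_selection_cascade(tab, labels[split$train], table_retest = tabp,
                            icc_threshold = s$icc_threshold,
                            alpha = s$alpha, r_threshold = s$r_threshold,
                            mrmr_k = s$mrmr_k, cv_folds = s$cv_folds,
                            lambda = s$lambda, seed = config$seed),
      error = function(e) e)
    p <- file.path(sdir, paste0("selection_", g, ".json"))
    if (inherits(rep_g, "error")) {
      jsonlite::write_json(list(error = conditionMessage(rep_g)), p,
                           auto_unbox = TRUE)
    } else {
      write_selection_report(rep_g, p)
    }
    outs <- c(outs, file.path("select", basename(p)))
  }
  # persist split
  jsonlite::write_json(split, file.path(sdir, "split.json"))
  c(outs, file.path("select", "split.json"))
}

stage_train <- function(config) {
  wide <- utils::read.csv(file.path(config$out_dir, "features",
                                    "features_wide.csv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  clin <- utils::read.csv(file.path(config$out_dir, "cohort", "clinical.csv"),
                          stringsAsFactors = FALSE)
  labels <- factor(clin$egfr[match(wide$sample_id, clin$sample_id)],
                   levels = c("wild-type", "mutant"))
  split <- jsonlite::read_json(file.path(config$out_dir, "select",
                                         "split.json"),
                               simplifyVector = TRUE)
  tdir <- file.path(config$out_dir, "train")
  dir.create(tdir, showWarnings = FALSE)
  scores <- data.frame(sample_id = wide$sample_id,
                       partition = ifelse(seq_len(nrow(wide)) %in% split$train,
                                          "train", "validation"),
                       egfr = as.character(labels),
                       stringsAsFactors = FALSE)
  groups <- names(config$train$algorithms)
  for (g in groups) {
    sel_path <- file.path(config$out_dir, "select",
                          paste0("selection_", g, ".json"))
    if (!file.exists(sel_path)) next
    sel <- jsonlite::read_json(sel_path, simplifyVector = TRUE)
    feats <- sel$stages$lasso
    if (is.null(feats) || length(feats) == 0) feats <- sel$stages$mrmr
    if (is.null(feats) || length(feats) == 0) next
    ztab <- wide[, c("sample_id", feats), drop = FALSE]
    # standardize with training statistics
    tr <- split$train
    ctr <- colMeans(ztab[tr, feats, drop = FALSE])
    scl <- apply(ztab[tr, feats, drop = FALSE], 2, stats::sd)
    scl[scl == 0] <- 1
    ztab[, feats] <- sweep(sweep(ztab[, feats, drop = FALSE], 2, ctr, "-"),
                           2, scl, "/")
    alg <- config$train$algorithms[[g]]
    model <- train_signature(ztab[tr, , drop = FALSE], labels[tr],
                             algorithm = alg, seed = config$seed,
                             cv_folds = config$train$cv_folds,
                             region_tag = g)
    scores[[paste0(g, "_sig")]] <- predict(model, ztab)
  }
  # deep-learning-placeholder signature: logistic score on 2D-slice
  # summary statistics of the max-area tumor slice
  if (isTRUE(config$train$dtl_placeholder)) {
    mf <- read_cohort_manifest(config)
    dtl_feats <- t(vapply(mf$sample_id, function(id)
      dtl_slice_features(read_prep_volume(config, id)), numeric(6)))
    dtab <- data.frame(sample_id = mf$sample_id, dtl_feats,
                       stringsAsFactors = FALSE)
    dtab <- dtab[match(wide$sample_id, dtab$sample_id), ]
    tr <- split$train
    model <- train_signature(dtab[tr, , drop = FALSE], labels[tr],
                             algorithm = "lr", seed = config$seed,
                             cv_folds = config$train$cv_folds,
                             region_tag = "dtl")
    scores$dtl_sig <- predict(model, dtab)
  }
  # clinical analysis and fusion nomogram on the training partition;
  # the clinical analysis needs a minimum cohort size and is reported as
  # unavailable (not fatal) below it
  tr <- split$train
  ca <- tryCatch(
    clinical_analysis(clin[match(wide$sample_id, clin$sample_id), ][tr, ],
                      labels[tr]),
    error = function(e) structure(
      list(univariable = NULL, multivariable = NULL,
           error = conditionMessage(e)), class = "clinical_analysis"))
  sig_cols <- intersect(c("peri3_sig", "habitat_sig", "dtl_sig"),
                        names(scores))
  smoking <- as.integer(clin$smoking[match(wide$sample_id,
                                           clin$sample_id)] == "yes")
  nomo <- build_nomogram(scores[tr, sig_cols, drop = FALSE],
                         smoking = smoking[tr], labels = labels[tr])
  full <- scores[, sig_cols, drop = FALSE]
  full$smoking <- smoking
  scores$nomogram <- predict(nomo, full)
  utils::write.csv(scores, file.path(tdir, "scores.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(univariable = ca$univariable, multivariable = ca$multivariable,
         nomogram = list(predictors = nomo$predictors,
                         coefficients = as.list(nomo$coefficients),
                         intercept = nomo$intercept)),
    file.path(tdir, "clinical_nomogram.json"), auto_unbox = TRUE,
    digits = NA, pretty = TRUE)
  file.path("train", c("scores.csv", "clinical_nomogram.json"))
}

stage_evaluate <- function(config) {
  scores <- utils::read.csv(file.path(config$out_dir, "train", "scores.csv"),
                            check.names = FALSE, stringsAsFactors = FALSE)
  edir <- file.path(config$out_dir, "evaluate")
  dir.create(edir, showWarnings = FALSE)
  score_cols <- setdiff(names(scores), c("sample_id", "partition", "egfr"))
  labels <- factor(scores$egfr, levels = c("wild-type", "mutant"))
  tr <- scores$partition == "train"
  thr <- vapply(score_cols, function(m)
    youden_threshold(scores[[m]][tr], labels[tr]), 0)
  outs <- character(0)
  for (part in c("train", "validation")) {
    sel <- scores$partition == part
    if (length(unique(labels[sel])) < 2L) next
    sbm <- lapply(score_cols, function(m) scores[[m]][sel])
    names(sbm) <- score_cols
    rep_p <- evaluation_report(sbm, labels[sel], thresholds = thr,
                               hl_groups = config$evaluate$hl_groups)
    p <- file.path(edir, paste0("evaluation_", part, ".json"))
    write_evaluation_report(rep_p, p)
    outs <- c(outs, file.path("evaluate", basename(p)))
  }
  outs
}

# Summary statistics of the maximum-area axial tumor slice; the pluggable
# stand-in score column for a deep-transfer-learning signature.
dtl_slice_features <- function(vol) {
  areas <- apply(vol$mask, 3, sum)
  z <- which.max(areas)
  v <- vol$intensities[, , z][vol$mask[, , z]]
  m <- mean(v)
  c(slice_mean = m, slice_sd = stats::sd(v),
    slice_p10 = stats::quantile(v, 0.1, names = FALSE),
    slice_p90 = stats::quantile(v, 0.9, names = FALSE),
    slice_area = areas[z],
    slice_range = max(v) - min(v))
}
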