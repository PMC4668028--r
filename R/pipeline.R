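#' Write phantom artifacts to a directory
#'
#' Emits the image (PGM), point and cluster annotation CSVs, and the true
#' breast mask (PNG), the on-disk form consumed by the command-line
#' pipeline.
#'
#' @param phantom A phantom from [generate_phantom()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_phantom <- function(phantom, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  id <- phantom$image_id
  paths <- c(
    image = file.path(out_dir, paste0(id, ".pgm")),
    points = file.path(out_dir, paste0(id, "_points.csv")),
    clusters = file.path(out_dir, paste0(id, "_clusters.csv")),
    mask = file.path(out_dir, paste0(id, "_mask.png"))
  )
  write_mammogram(phantom$image, paths["image"])
  write_mc_points(phantom$mc_points, paths["points"])
  write_mc_clusters(phantom$clusters, paths["clusters"])
  write_mask(phantom$breast_mask, paths["mask"])
  paths
}

#' Write detection-stage artifacts
#'
#' Detections CSV, breast mask PNG and the stage-1 posterior map as a
#' 16-bit PNG (probability scaled by 65535 and rounded).
#'
#' @param result An `mc_detection` from [detect_mc()].
#' @param out_dir Output directory.
#' @return Named character vector of the written paths.
#' @export
write_detection_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  id <- result$image_id
  paths <- c(
    detections = file.path(out_dir, paste0(id, "_detections.csv")),
    mask = file.path(out_dir, paste0(id, "_mask.png")),
    rf_prob = file.path(out_dir, paste0(id, "_rfprob.png"))
  )
  write_detections(result$detections, paths["detections"])
  write_mask(result$mask, paths["mask"])
  png::writePNG(round(result$rf_prob * 65535) / 65535, paths["rf_prob"])
  paths
}

#' Run the synthetic end-to-end pipeline and write a run manifest
#'
#' Generates training and test phantoms, trains the cascade, detects and
#' groups clusters on the test images, evaluates, and writes every artifact
#' plus a `manifest.json` (config snapshot, seeds, package version, per-file
#' MD5 hashes and per-stage counts) from which the run can be reproduced
#' bit-exactly.
#'
#' @param out_dir Output directory.
#' @param config A `pipeline_config`.
#' @param train_seeds,test_seeds Phantom seeds.
#' @param seed Model-training seed.
#' @param spec_template Phantom spec template.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(out_dir, config = preset_config("phantom"),
                         train_seeds = 100:103, test_seeds = 0:3,
                         seed = 1L, spec_template = phantom_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- run_phantom_experiment(train_seeds, test_seeds, config,
                                spec_template, seed = seed)
  paths <- character(0)
  write_forest(res$models$forest, file.path(out_dir, "forest.json"))
  write_drbm(res$models$drbm, file.path(out_dir, "drbm.json"))
  write_detections(res$detections, file.path(out_dir, "detections.csv"))
  cl <- res$clusters
  cl$members <- NULL
  write.csv(cl, file.path(out_dir, "clusters.csv"), row.names = FALSE)
  write.csv(res$per_image, file.path(out_dir, "per_image.csv"),
            row.names = FALSE)
  write.csv(res$metrics, file.path(out_dir, "metrics.csv"),
            row.names = FALSE)
  paths <- file.path(out_dir, c("forest.json", "drbm.json",
                                "detections.csv", "clusters.csv",
                                "per_image.csv", "metrics.csv"))
  manifest <- list(
    package = "mammocalc",
    version = as.character(utils::packageVersion("mammocalc")),
    seed = seed, train_seeds = train_seeds, test_seeds = test_seeds,
    config = config[setdiff(names(config), "cluster")],
    cluster_config = unclass(config$cluster),
    phantom_spec = unclass(spec_template)[setdiff(names(spec_template),
                                                  "breast_mask_shape")],
    breast_mask_shape = spec_template$breast_mask_shape,
    metrics = as.list(res$metrics),
    artifacts = as.list(setNames(unname(tools::md5sum(paths)),
                                 basename(paths)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
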