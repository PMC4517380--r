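#' Convert a parcellation to an integer label volume
#'
#' @param part a [parcellation()].
#' @param dims grid dimensions.
#' @return integer 3D array, 0 outside the parcellated voxels.
#' @export
parcellation_to_volume <- function(part, dims) {
  vol <- array(0L, dims)
  vol[part$voxels] <- part$labels
  vol
}

#' Read a label volume back into a parcellation
#'
#' @param vol integer 3D array (or NIfTI-backed array), positive labels on
#'   the parcellated voxels.
#' @param grid the matching [volume_grid()].
#' @param provenance provenance tag for the result.
#' @return A [parcellation()].
#' @export
volume_to_parcellation <- function(vol, grid, provenance = "iROI") {
  stopifnot(inherits(grid, "volume_grid"))
  vol <- array(as.integer(as.array(vol)), dim = dim(as.array(vol)))
  if (!identical(dim(vol), grid$dims)) stop("label volume dimensions mismatch")
  vox <- which(grid$mask)
  lab <- vol[vox]
  if (any(lab <= 0L)) stop("label volume leaves in-mask voxels unlabeled")
  parcellation(lab, vox, provenance = provenance)
}

#' Write a phantom dataset to disk
#'
#' Writes the two 4D series, mask, atlas and both ground-truth label maps
#' as NIfTI volumes, plus a JSON sidecar recording the generating spec.
#'
#' @param phantom a [generate_phantom()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dims <- phantom$spec$grid_dims
  paths <- c(
    bold_t1 = file.path(dir, "bold_t1.nii.gz"),
    bold_t2 = file.path(dir, "bold_t2.nii.gz"),
    mask = file.path(dir, "mask.nii.gz"),
    atlas = file.path(dir, "atlas.nii.gz"),
    truth_t1 = file.path(dir, "truth_t1.nii.gz"),
    truth_t2 = file.path(dir, "truth_t2.nii.gz"),
    spec = file.path(dir, "phantom_spec.json")
  )
  RNifti::writeNifti(phantom$bold_t1, paths["bold_t1"])
  RNifti::writeNifti(phantom$bold_t2, paths["bold_t2"])
  RNifti::writeNifti(array(as.integer(phantom$mask), dims), paths["mask"],
                     datatype = "int16")
  RNifti::writeNifti(phantom$atlas, paths["atlas"], datatype = "int32")
  RNifti::writeNifti(parcellation_to_volume(phantom$truth_t1, dims),
                     paths["truth_t1"], datatype = "int32")
  RNifti::writeNifti(parcellation_to_volume(phantom$truth_t2, dims),
                     paths["truth_t2"], datatype = "int32")
  jsonlite::write_json(unclass(phantom$spec), paths["spec"],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Pipeline configuration
#'
#' Collects and validates every tunable of the end-to-end run. Input
#' volumes are NIfTI paths; seeds for the Louvain and label-propagation
#' stages are independent entries so each stage's stochasticity can be
#' probed separately.
#'
#' @param bold_t1,bold_t2 paths to the two 4D BOLD NIfTI volumes.
#' @param mask path to a binary or probability mask volume.
#' @param atlas path to the integer meta-region atlas volume.
#' @param output_dir directory for all outputs.
#' @param mask_threshold strict threshold for [binarize_mask()].
#' @param band coherence band in Hz.
#' @param sampling_interval_s repetition time in seconds.
#' @param multitaper list with `half_bandwidth_product` and `n_tapers`.
#' @param louvain list with `seed` and `resolution` (time point 2 uses
#'   `seed + 1`).
#' @param lp list with `seed` and `max_sweeps`.
#' @param network list with `alpha` and `positive_only`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(bold_t1, bold_t2, mask, atlas, output_dir,
                            mask_threshold = 0.5,
                            band = c(0.005, 0.12),
                            sampling_interval_s = 2.0,
                            multitaper = list(half_bandwidth_product = 4,
                                              n_tapers = 7L),
                            louvain = list(seed = 1L, resolution = 1.0),
                            lp = list(seed = 1L, max_sweeps = 100L),
                            network = list(alpha = 0.05,
                                           positive_only = FALSE)) {
  cfg <- list(bold_t1 = bold_t1, bold_t2 = bold_t2, mask = mask,
              atlas = atlas, output_dir = output_dir,
              mask_threshold = mask_threshold, band = band,
              sampling_interval_s = sampling_interval_s,
              multitaper = multitaper, louvain = louvain, lp = lp,
              network = network)
  for (f in c("bold_t1", "bold_t2", "mask", "atlas"))
    if (!file.exists(cfg[[f]]))
      stop("input file for '", f, "' not found: ", cfg[[f]])
  if (!(band[1L] > 0 && band[1L] < band[2L]))
    stop("'band' must satisfy 0 < lo < hi")
  if (!is.numeric(mask_threshold) || length(mask_threshold) != 1L)
    stop("'mask_threshold' must be a scalar")
  stopifnot(is.numeric(multitaper$half_bandwidth_product),
            multitaper$n_tapers >= 1,
            lp$max_sweeps >= 1, network$alpha > 0, network$alpha < 1)
  structure(cfg, class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

edge_list_frame <- function(lattice) {
  data.frame(voxel_i = lattice$voxels[lattice$edges[, 1L]],
             voxel_j = lattice$voxels[lattice$edges[, 2L]],
             weight = if (is.null(lattice$weights)) 1 else lattice$weights)
}

adjacency_frame <- function(net) {
  df <- as.data.frame(net$weights)
  cbind(roi = net$roi_ids, df)
}

frag_frame <- function(rep_, stage) {
  data.frame(stage = stage, n_rois = rep_$n_rois, size_mean = rep_$size_mean,
             size_sd = rep_$size_sd, size_median = rep_$size_median,
             frac_lt5 = rep_$frac_lt5, frac_lt10 = rep_$frac_lt10)
}

net_metrics <- function(net) {
  pl <- if (count_links(net) > 0) mean_path_length(net) else NA_real_
  list(n_links = count_links(net),
       total_strength = total_strength(net),
       mean_clustering = mean_clustering(net),
       mean_path_length = as.numeric(pl),
       disconnected = isTRUE(attr(pl, "disconnected")))
}

#' Run the full AILP pipeline
#'
#' Executes mask binarization, lattice construction, coherence weighting,
#' per-timepoint Louvain parcellation, aggregation, label propagation, and
#' per-timepoint ROI-network metrics; writes every intermediate (label maps
#' as integer NIfTI, edge lists and adjacency matrices as TSV, reports as
#' JSON) plus a manifest with MD5 content hashes, and a resolved copy of
#' the configuration. With a fixed configuration the run is deterministic
#' end to end.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage progress messages.
#' @return invisibly, a list with the in-memory results (`grid`, `lattice`,
#'   weighted lattices, parcellations, networks, reports) and the manifest
#'   data frame.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say(sprintf("[%s] done in %.1fs", name,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  grid <- stage("inputs", {
    mask_vol <- as.array(RNifti::readNifti(config$mask))
    mask <- if (is.logical(mask_vol)) mask_vol
            else binarize_mask(mask_vol, config$mask_threshold)
    atlas <- as.array(RNifti::readNifti(config$atlas))
    volume_grid(mask, array(as.integer(atlas), dim = dim(atlas)))
  })
  bold1 <- as.array(RNifti::readNifti(config$bold_t1))
  bold2 <- as.array(RNifti::readNifti(config$bold_t2))
  for (b in list(bold1, bold2))
    if (length(dim(b)) != 4L || !identical(dim(b)[1:3], grid$dims))
      stop("BOLD volume dimensions do not match the mask/atlas grid")

  lattice <- stage("lattice", build_lattice(grid))
  wlat1 <- stage("coherence weights (t1)",
    weight_lattice(lattice, bold1, config$sampling_interval_s,
                   config$band[1L], config$band[2L],
                   config$multitaper$half_bandwidth_product,
                   config$multitaper$n_tapers))
  wlat2 <- stage("coherence weights (t2)",
    weight_lattice(lattice, bold2, config$sampling_interval_s,
                   config$band[1L], config$band[2L],
                   config$multitaper$half_bandwidth_product,
                   config$multitaper$n_tapers))
  iroi1 <- stage("louvain (t1)",
    louvain_partition(wlat1, seed = config$louvain$seed,
                      resolution = config$louvain$resolution))
  iroi2 <- stage("louvain (t2)",
    louvain_partition(wlat2, seed = config$louvain$seed + 1L,
                      resolution = config$louvain$resolution))
  aroi <- stage("aggregate", aggregate_parcellations(iroi1, iroi2))
  lproi <- stage("label propagation",
    ailp(lattice, iroi1, iroi2, seed = config$lp$seed,
         max_sweeps = config$lp$max_sweeps))
  say(sprintf("  modules: iROI t1 %d, iROI t2 %d, aROI %d, lpROI %d; sweeps %s",
              length(unique(iroi1$labels)), length(unique(iroi2$labels)),
              length(unique(aroi$labels)), length(unique(lproi$labels)),
              paste(attr(lproi, "sweep_changes"), collapse = ",")))

  nets <- stage("roi networks", {
    lapply(list(t1 = bold1, t2 = bold2), function(b)
      correlation_network(roi_mean_series(b, lproi),
                          alpha = config$network$alpha,
                          positive_only = config$network$positive_only))
  })

  dims <- grid$dims
  files <- c(
    config = file.path(out, "config.json"),
    iroi_t1 = file.path(out, "iroi_t1.nii.gz"),
    iroi_t2 = file.path(out, "iroi_t2.nii.gz"),
    aroi = file.path(out, "aroi.nii.gz"),
    lproi = file.path(out, "lproi.nii.gz"),
    edges_t1 = file.path(out, "edges_t1.tsv"),
    edges_t2 = file.path(out, "edges_t2.tsv"),
    adjacency_t1 = file.path(out, "adjacency_t1.tsv"),
    adjacency_t2 = file.path(out, "adjacency_t2.tsv"),
    fragmentation = file.path(out, "fragmentation.tsv"),
    metrics = file.path(out, "metrics.json")
  )
  jsonlite::write_json(unclass(config), files["config"], auto_unbox = TRUE,
                       digits = NA)
  RNifti::writeNifti(parcellation_to_volume(iroi1, dims), files["iroi_t1"],
                     datatype = "int32")
  RNifti::writeNifti(parcellation_to_volume(iroi2, dims), files["iroi_t2"],
                     datatype = "int32")
  RNifti::writeNifti(parcellation_to_volume(aroi, dims), files["aroi"],
                     datatype = "int32")
  RNifti::writeNifti(parcellation_to_volume(lproi, dims), files["lproi"],
                     datatype = "int32")
  write_tsv(edge_list_frame(wlat1), files["edges_t1"])
  write_tsv(edge_list_frame(wlat2), files["edges_t2"])
  write_tsv(adjacency_frame(nets$t1), files["adjacency_t1"])
  write_tsv(adjacency_frame(nets$t2), files["adjacency_t2"])
  write_tsv(rbind(frag_frame(fragmentation_report(iroi1), "iROI_t1"),
                  frag_frame(fragmentation_report(iroi2), "iROI_t2"),
                  frag_frame(fragmentation_report(aroi), "aROI"),
                  frag_frame(fragmentation_report(lproi), "lpROI")),
            files["fragmentation"])
  jsonlite::write_json(lapply(nets, net_metrics), files["metrics"],
                       auto_unbox = TRUE, digits = NA, na = "null")
  manifest <- data.frame(artifact = names(files),
                         file = basename(unname(files)),
                         md5 = unname(tools::md5sum(unname(files))))
  write_tsv(manifest, file.path(out, "manifest.tsv"))

  invisible(list(grid = grid, lattice = lattice, wlat_t1 = wlat1,
                 wlat_t2 = wlat2, iroi_t1 = iroi1, iroi_t2 = iroi2,
                 aroi = aroi, lproi = lproi, networks = nets,
                 manifest = manifest, files = files))
}
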