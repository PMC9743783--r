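#' Read and write volumes
#'
#' Volumes (phantom maps, sensitivity functions, reconstructions) are stored
#' as NIfTI images with the voxel size in the header, plus an optional JSON
#' sidecar (`<path>.json`) holding grid origin and arbitrary metadata.
#'
#' @param values 3-D numeric array.
#' @param grid A [voxel_grid()].
#' @param path Destination path (`.nii`).
#' @param meta Optional named list written to the JSON sidecar.
#' @return `write_volume`: `path`, invisibly. `read_volume`: list with
#'   `values`, `grid`, `meta`.
#' @export
write_volume <- function(values, grid, path, meta = NULL) {
  stopifnot(is.array(values), inherits(grid, "voxel_grid"),
            all(dim(values) == grid$shape))
  img <- RNifti::asNifti(values,
                         pixdim = rep(grid$voxel_size, 3L))
  RNifti::writeNifti(img, path)
  side <- list(origin = grid$origin, voxel_size = grid$voxel_size,
               shape = grid$shape)
  if (!is.null(meta)) side$meta <- meta
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  values <- array(as.numeric(img), dim = dim(img))
  sidecar <- paste0(path, ".json")
  meta <- NULL
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    grid <- voxel_grid(side$shape, side$voxel_size, side$origin)
    meta <- side$meta
  } else {
    pd <- RNifti::pixdim(img)
    grid <- voxel_grid(dim(img), pd[1], c(0, 0, 0))
  }
  list(values = values, grid = grid, meta = meta)
}

#' Read an experiment configuration
#'
#' Parses a JSON configuration describing phantom geometry, optical and
#' fluorescence parameters, probe, scan pattern, strategy and simulation
#' budgets into the package's domain objects. Missing sections fall back to
#' the defaults of the respective constructors.
#'
#' @param path JSON file path, or a list already parsed.
#' @return List with `phantom`, `probe`, `pattern`, `strategy`, `mc`
#'   (histories/seed/bin width/max time), `ftr_params`, `recon_params`,
#'   `separation_params`.
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path))
    jsonlite::read_json(path, simplifyVector = TRUE) else path
  take <- function(x, default = list()) if (is.null(x)) default else x
  grid <- do.call(voxel_grid, take(cfg$grid))
  medium <- do.call(optical_medium, take(cfg$medium))
  fluor <- do.call(fluorophore_props, take(cfg$fluor))
  shape <- if (is.null(cfg$shape)) NULL else {
    s <- cfg$shape
    switch(s$type,
           cylinder = cylinder_shape(s$center, s$radius,
                                     take(s$axis, 1L), take(s$length, Inf)),
           sphere = sphere_shape(s$center, s$radius),
           box = box_shape(s$center, s$half_size))
  }
  phantom <- make_phantom(grid, medium, fluor, shape)
  probe <- do.call(probe_geometry, take(cfg$probe))
  pattern <- do.call(scan_pattern, take(cfg$pattern))
  strat <- take(cfg$strategy, list(kind = "strategy2"))
  strategy <- if (identical(strat$kind, "strategy1"))
    build_strategy1(probe$sr_offsets, take(strat$gate, 200))
  else build_strategy2(probe$sr_offsets, take(strat$base_gate, 200))
  list(phantom = phantom, probe = probe, pattern = pattern,
       strategy = strategy,
       mc = take(cfg$mc, list(n_histories = 1e6, seed = 1L, bin_width = 2,
                              max_time = 400)),
       ftr_params = do.call(synthetic_ftr_params, take(cfg$ftr_params)),
       recon_params = do.call(recon_params, take(cfg$recon_params)),
       separation_params = do.call(separation_params,
                                   take(cfg$separation_params)))
}

#' Write a run manifest
#'
#' Records parameters, seeds and package version of a run as JSON.
#'
#' @param path Output path.
#' @param ... Named entries to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, ...) {
  entries <- list(...)
  entries$package <- "earlyflt"
  entries$version <- as.character(utils::packageVersion("earlyflt"))
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
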