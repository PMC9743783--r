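#' Uniform voxel grid
#'
#' Axis-aligned uniform grid of cubic voxels. Indexing is 0-based in the
#' compiled code and 1-based in R arrays; voxel `k` along an axis spans the
#' half-open interval `[origin + k h, origin + (k+1) h)`. The coordinate
#' frame is right-handed with z positive into the medium and the scanned
#' surface at z = 0.
#'
#' @param shape Integer vector of length 3, voxel counts along x, y, z.
#' @param voxel_size Voxel edge length h (mm), `> 0`.
#' @param origin Position of the corner of voxel (0,0,0) (mm).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape = c(200L, 200L, 150L), voxel_size = 0.1,
                       origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, length(origin) == 3L,
            is.numeric(voxel_size), length(voxel_size) == 1L)
  if (any(shape < 1L)) stop("voxel_grid: all voxel counts must be >= 1")
  if (voxel_size <= 0) stop("voxel_grid: voxel_size must be > 0")
  structure(list(shape = shape, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  ext <- x$shape * x$voxel_size
  cat(sprintf("<voxel_grid> %dx%dx%d voxels of %g mm (%g x %g x %g mm)\n",
              x$shape[1], x$shape[2], x$shape[3], x$voxel_size,
              ext[1], ext[2], ext[3]))
  invisible(x)
}

# Voxel-centre coordinates along one axis.
grid_centers <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 0.5) * grid$voxel_size
}

grid_extent <- function(grid) grid$shape * grid$voxel_size + grid$origin

#' Fluorophore inclusion shapes
#'
#' Geometric primitives for the fluorophore region of a digital phantom.
#' `cylinder_shape()` is an axis-aligned cylinder (default: axis along x,
#' mimicking a cylindrical hole filled with fluorescent solution running
#' along the phantom); `sphere_shape()` and `box_shape()` are the other
#' supported primitives. Coordinates in mm; `center` is the shape centre
#' (for the cylinder, the axis depth is `center[3]`).
#'
#' @param center Length-3 centre (mm). For `cylinder_shape` the coordinate
#'   along `axis` is ignored when `length = Inf`.
#' @param radius Radius (mm), `>= 0`.
#' @param axis Cylinder axis: 1 (x), 2 (y) or 3 (z).
#' @param length Cylinder length (mm); `Inf` spans the whole grid.
#' @param half_size Length-3 box half-widths (mm).
#' @return A shape description list.
#' @export
cylinder_shape <- function(center, radius = 1, axis = 1L, length = Inf) {
  stopifnot(length(center) == 3L, radius >= 0, axis %in% 1:3, length >= 0)
  list(type = "cylinder", center = as.numeric(center), radius = radius,
       axis = as.integer(axis), length = length)
}

#' @rdname cylinder_shape
#' @export
sphere_shape <- function(center, radius = 1) {
  stopifnot(length(center) == 3L, radius >= 0)
  list(type = "sphere", center = as.numeric(center), radius = radius)
}

#' @rdname cylinder_shape
#' @export
box_shape <- function(center, half_size) {
  stopifnot(length(center) == 3L, length(half_size) == 3L, all(half_size >= 0))
  list(type = "box", center = as.numeric(center),
       half_size = as.numeric(half_size))
}

shape_contains <- function(shape, x, y, z) {
  switch(shape$type,
    cylinder = {
      ax <- shape$axis
      co <- shape$center
      pd <- list(x, y, z)
      perp <- setdiff(1:3, ax)
      r2 <- (pd[[perp[1]]] - co[perp[1]])^2 + (pd[[perp[2]]] - co[perp[2]])^2
      inside <- r2 <= shape$radius^2
      if (is.finite(shape$length))
        inside <- inside & abs(pd[[ax]] - co[ax]) <= shape$length / 2
      inside
    },
    sphere = {
      (x - shape$center[1])^2 + (y - shape$center[2])^2 +
        (z - shape$center[3])^2 <= shape$radius^2
    },
    box = {
      abs(x - shape$center[1]) <= shape$half_size[1] &
        abs(y - shape$center[2]) <= shape$half_size[2] &
        abs(z - shape$center[3]) <= shape$half_size[3]
    },
    stop("unknown shape type: ", shape$type)
  )
}

#' Build a digital phantom
#'
#' Voxelizes a homogeneous turbid block containing a fluorophore inclusion.
#' Voxel membership is decided by the voxel *centre* lying inside the shape
#' (deterministic and orientation independent). The fluorophore absorption
#' map equals `fluor$muaf` inside the mask and 0 outside; the lifetime map
#' equals `fluor$tau` inside and `NA` outside.
#'
#' The default geometry is a 20 x 20 x 15 mm block at 0.1 mm voxels with a
#' 2-mm-diameter cylinder along x whose axis sits 4.4 mm below the scanned
#' surface (four times the shortest source-detector distance of the default
#' probe), so the top of the inclusion is at 3.4 mm depth.
#'
#' @param grid A [voxel_grid()].
#' @param medium An [optical_medium()].
#' @param fluor A [fluorophore_props()].
#' @param shape A shape from [cylinder_shape()] and friends. `NULL` gives the
#'   default centred cylinder at 4.4 mm axis depth.
#' @return An object of class `phantom` with elements `grid`, `medium`,
#'   `fluor`, `shape`, `mask` (logical array), `muaf_map`, `tau_map`.
#' @export
make_phantom <- function(grid = voxel_grid(), medium = optical_medium(),
                         fluor = fluorophore_props(), shape = NULL) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(medium, "optical_medium"),
            inherits(fluor, "fluorophore_props"))
  if (is.null(shape)) {
    ext <- grid_extent(grid)
    shape <- cylinder_shape(center = c(0, (grid$origin[2] + ext[2]) / 2, 4.4),
                            radius = 1, axis = 1L, length = Inf)
  }
  # Geometry sanity: shape centre must fall inside the grid box (along the
  # finite axes).
  lo <- grid$origin
  hi <- grid_extent(grid)
  chk <- if (shape$type == "cylinder" && !is.finite(shape$length))
    setdiff(1:3, shape$axis) else 1:3
  if (any(shape$center[chk] < lo[chk]) || any(shape$center[chk] > hi[chk]))
    stop("make_phantom: fluorophore shape centre lies outside the grid")

  cx <- grid_centers(grid, 1)
  cy <- grid_centers(grid, 2)
  cz <- grid_centers(grid, 3)
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  X <- rep(cx, times = ny * nz)
  Y <- rep(rep(cy, each = nx), times = nz)
  Z <- rep(cz, each = nx * ny)
  mask <- array(shape_contains(shape, X, Y, Z), dim = grid$shape)

  muaf_map <- array(0, dim = grid$shape)
  muaf_map[mask] <- fluor$muaf
  tau_map <- array(NA_real_, dim = grid$shape)
  tau_map[mask] <- fluor$tau

  structure(list(grid = grid, medium = medium, fluor = fluor, shape = shape,
                 mask = mask, muaf_map = muaf_map, tau_map = tau_map),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s inclusion, %d fluorophore voxels\n",
              x$shape$type, sum(x$mask)))
  print(x$grid)
  print(x$medium)
  print(x$fluor)
  invisible(x)
}

#' Fiber probe geometry
#'
#' Source and detector fibers modelled as coaxial circles on the surface.
#' The critical angle is the in-medium acceptance half-angle corresponding to
#' the fiber numerical aperture; launch polar angles follow a Gaussian
#' truncated at the critical angle and detection accepts exit angles within
#' the same cone.
#'
#' @param fiber_diameter Fiber core diameter (mm), `> 0`.
#' @param numerical_aperture Fiber NA, in `(0, 1)`.
#' @param critical_angle In-medium acceptance half-angle (degrees).
#' @param sr_offsets Source-detector centre distances (mm), positive and
#'   distinct.
#' @return An object of class `probe_geometry`.
#' @export
probe_geometry <- function(fiber_diameter = 0.4, numerical_aperture = 0.2,
                           critical_angle = 8.2,
                           sr_offsets = c(3.3, 2.2, 1.1)) {
  stopifnot(fiber_diameter > 0, numerical_aperture > 0,
            numerical_aperture < 1, critical_angle > 0)
  if (any(sr_offsets <= 0) || anyDuplicated(sr_offsets))
    stop("probe_geometry: sr_offsets must be positive and distinct")
  structure(list(fiber_diameter = fiber_diameter,
                 numerical_aperture = numerical_aperture,
                 critical_angle = critical_angle,
                 sr_offsets = as.numeric(sr_offsets)),
            class = "probe_geometry")
}

#' Raster scan pattern on the phantom surface
#'
#' A rectangular raster of probe positions on the z = 0 surface, traversed in
#' zigzag order: row 1 left to right, row 2 right to left, and so on. The
#' default reproduces a 19 x 19 scan at 0.5 mm step (9 x 9 mm area).
#'
#' @param n_rows,n_cols Position counts, `>= 1`.
#' @param step Step between adjacent positions (mm), `> 0`.
#' @param origin Length-2 (x, y) position of row 1, column 1 (mm).
#' @param scan_axis Axis along which a row advances: 1 (x) or 2 (y).
#' @return An object of class `scan_pattern`.
#' @export
scan_pattern <- function(n_rows = 19L, n_cols = 19L, step = 0.5,
                         origin = c(4, 5.5), scan_axis = 1L) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1L, n_cols >= 1L, step > 0, length(origin) == 2L,
            scan_axis %in% 1:2)
  structure(list(n_rows = n_rows, n_cols = n_cols, step = step,
                 origin = as.numeric(origin), scan_axis = as.integer(scan_axis)),
            class = "scan_pattern")
}

#' Enumerate source-detector links of a scan
#'
#' Expands a scan pattern and probe into the full list of gated measurement
#' links: every probe position times every source-detector offset, in zigzag
#' scan order with the offsets cycled fastest. The source centre sits at the
#' probe position; the detector centre is displaced along the scan axis by
#' the offset. All centres lie on the z = 0 surface.
#'
#' @param pattern A [scan_pattern()].
#' @param probe A [probe_geometry()].
#' @return A data.frame of class `sr_links` with columns `row`, `col`,
#'   `sr_distance`, `sx`, `sy`, `dx`, `dy` (one row per link,
#'   `n_rows * n_cols * length(sr_offsets)` rows in total).
#' @export
scan_links <- function(pattern, probe) {
  stopifnot(inherits(pattern, "scan_pattern"), inherits(probe, "probe_geometry"))
  rows <- integer(0); cols <- integer(0)
  for (r in seq_len(pattern$n_rows)) {
    cs <- seq_len(pattern$n_cols)
    if (r %% 2L == 0L) cs <- rev(cs)  # zigzag
    rows <- c(rows, rep(r, pattern$n_cols))
    cols <- c(cols, cs)
  }
  noff <- length(probe$sr_offsets)
  rows <- rep(rows, each = noff)
  cols <- rep(cols, each = noff)
  off <- rep(probe$sr_offsets, times = pattern$n_rows * pattern$n_cols)

  if (pattern$scan_axis == 1L) {
    sx <- pattern$origin[1] + (cols - 1L) * pattern$step
    sy <- pattern$origin[2] + (rows - 1L) * pattern$step
    dx <- sx + off; dy <- sy
  } else {
    sy <- pattern$origin[2] + (cols - 1L) * pattern$step
    sx <- pattern$origin[1] + (rows - 1L) * pattern$step
    dy <- sy + off; dx <- sx
  }
  out <- data.frame(row = rows, col = cols, sr_distance = off,
                    sx = sx, sy = sy, dx = dx, dy = dy)
  class(out) <- c("sr_links", "data.frame")
  out
}

# One link as a plain list (row of an sr_links frame or hand-made).
as_link <- function(x) {
  if (is.data.frame(x)) x <- as.list(x[1, , drop = FALSE])
  stopifnot(!is.null(x$sx), !is.null(x$sy), !is.null(x$dx), !is.null(x$dy))
  if (is.null(x$sr_distance))
    x$sr_distance <- sqrt((x$dx - x$sx)^2 + (x$dy - x$sy)^2)
  d <- sqrt((x$dx - x$sx)^2 + (x$dy - x$sy)^2)
  if (abs(d - x$sr_distance) > 1e-9)
    stop("link: centre distance does not match sr_distance")
  x
}
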