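#' Voxel grid geometry
#'
#' A minimal description of a regular 3-D voxel grid: array shape, physical
#' voxel size in millimetres per axis, and the millimetre offset of the grid
#' origin. All geometric operations in the package (morphology, blurring,
#' distance checks) work in millimetres so anisotropic grids are handled
#' consistently.
#'
#' @param shape integer vector of length 3, array dimensions (each >= 1).
#' @param voxel_size numeric vector of length 3, mm per axis (each > 0).
#' @param origin numeric vector of length 3, mm offset of the grid corner.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, voxel_size, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(shape) == 3, length(voxel_size) == 3, length(origin) == 3)
  if (any(shape < 1L)) stop("voxel_grid: all shape components must be >= 1")
  if (any(voxel_size <= 0)) stop("voxel_grid: all voxel_size components must be > 0")
  structure(list(shape = shape, voxel_size = voxel_size,
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels at %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  invisible(x)
}

#' Voxel-centre coordinates of a grid
#'
#' @param grid a [voxel_grid()].
#' @return A list with numeric vectors `x`, `y`, `z` of voxel-centre
#'   coordinates in mm.
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  lapply(stats::setNames(1:3, c("x", "y", "z")), function(i) {
    grid$origin[i] + (seq_len(grid$shape[i]) - 0.5) * grid$voxel_size[i]
  })
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Integer-labelled volume with a region table
#'
#' The container for digital phantoms and ROI label maps: one integer label
#' per voxel (0 = background) plus a table mapping labels to region names.
#'
#' @param labels 3-D integer array of region labels.
#' @param grid the [voxel_grid()] the labels live on.
#' @param region_table data.frame with columns `label` and `name`; every
#'   nonzero label present in `labels` must appear.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, grid, region_table) {
  stopifnot(inherits(grid, "voxel_grid"))
  labels <- array(as.integer(labels), dim = dim(labels))
  if (!identical(dim(labels), grid$shape))
    stop("label_volume: labels dimensions do not match grid shape")
  stopifnot(all(c("label", "name") %in% names(region_table)))
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  missing <- setdiff(present, region_table$label)
  if (length(missing))
    stop("label_volume: labels without region_table entry: ",
         paste(missing, collapse = ", "))
  structure(list(labels = labels, grid = grid,
                 region_table = region_table),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, %d regions\n",
              paste(x$grid$shape, collapse = "x"), nrow(x$region_table)))
  invisible(x)
}

#' Extract a binary mask for one or more named regions
#'
#' @param volume a [label_volume()].
#' @param regions character vector of region names (or integer labels).
#' @return Logical 3-D array.
#' @export
region_mask <- function(volume, regions) {
  stopifnot(inherits(volume, "label_volume"))
  if (is.character(regions)) {
    unknown <- setdiff(regions, volume$region_table$name)
    if (length(unknown))
      stop("region_mask: unknown region(s): ", paste(unknown, collapse = ", "))
    labs <- volume$region_table$label[volume$region_table$name %in% regions]
  } else {
    labs <- as.integer(regions)
  }
  array(volume$labels %in% labs, dim = dim(volume$labels))
}

#' Floating-point PET image
#'
#' @param values 3-D numeric array.
#' @param grid the [voxel_grid()].
#' @param unit one of `"kBq/mL"`, `"SUV"`, `"SUVR"`.
#' @param provenance named list recording how the image was produced
#'   (seed, frame schedule, scanner, reference region, ...).
#' @return An object of class `pet_image`.
#' @export
pet_image <- function(values, grid, unit = c("kBq/mL", "SUV", "SUVR"),
                      provenance = list()) {
  unit <- match.arg(unit)
  stopifnot(inherits(grid, "voxel_grid"))
  if (!identical(dim(values), grid$shape))
    stop("pet_image: values dimensions do not match grid shape")
  if (unit == "SUVR" && is.null(provenance$reference_region))
    stop("pet_image: SUVR images must record their reference region in provenance")
  structure(list(values = values, grid = grid, unit = unit,
                 provenance = provenance),
            class = "pet_image")
}

#' @export
print.pet_image <- function(x, ...) {
  cat(sprintf("<pet_image> %s voxels [%s], range %.3g..%.3g\n",
              paste(x$grid$shape, collapse = "x"), x$unit,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Resample a volume onto another grid
#'
#' Continuous volumes are interpolated trilinearly at the target voxel
#' centres; label or mask volumes use nearest-neighbour lookup so labels are
#' never mixed. Points falling outside the source grid get 0.
#'
#' @param values 3-D array on `from` grid.
#' @param from,to [voxel_grid()] objects.
#' @param method `"trilinear"` or `"nearest"`.
#' @return 3-D array on the `to` grid.
#' @export
resample_volume <- function(values, from, to, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (same_grid(from, to)) return(values)
  tc <- grid_coords(to)
  # continuous source index (1-based voxel coordinates)
  ix <- (tc$x - from$origin[1]) / from$voxel_size[1] + 0.5
  iy <- (tc$y - from$origin[2]) / from$voxel_size[2] + 0.5
  iz <- (tc$z - from$origin[3]) / from$voxel_size[3] + 0.5
  d <- from$shape
  if (method == "nearest") {
    rx <- pmin(pmax(round(ix), 1L), d[1])
    ry <- pmin(pmax(round(iy), 1L), d[2])
    rz <- pmin(pmax(round(iz), 1L), d[3])
    out <- values[as.matrix(expand.grid(rx, ry, rz))]
    oob <- expand.grid(ix < 0.5 | ix > d[1] + 0.5,
                       iy < 0.5 | iy > d[2] + 0.5,
                       iz < 0.5 | iz > d[3] + 0.5)
    out[oob[[1]] | oob[[2]] | oob[[3]]] <- 0
    return(array(out, dim = to$shape))
  }
  # trilinear with zero padding outside
  f <- function(v, n) pmin(pmax(v, 1), n)
  x0 <- floor(ix); y0 <- floor(iy); z0 <- floor(iz)
  wx <- ix - x0; wy <- iy - y0; wz <- iz - z0
  acc <- array(0, to$shape)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    gx <- x0 + dx; gy <- y0 + dy; gz <- z0 + dz
    vin_x <- gx >= 1 & gx <= d[1]
    vin_y <- gy >= 1 & gy <= d[2]
    vin_z <- gz >= 1 & gz <= d[3]
    src <- values[as.matrix(expand.grid(f(gx, d[1]), f(gy, d[2]), f(gz, d[3])))]
    valid <- outer(outer(vin_x, vin_y, "&"), vin_z, "&")
    src[!valid] <- 0
    w <- outer(outer(if (dx) wx else 1 - wx, if (dy) wy else 1 - wy),
               if (dz) wz else 1 - wz)
    acc <- acc + array(src, to$shape) * w
  }
  acc
}
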