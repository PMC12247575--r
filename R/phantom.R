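#' Parametric digital brain phantom specification
#'
#' The phantom is a geometric surrogate for an atlas-based emission map. It
#' preserves the adjacencies that drive extra-cerebral spill-in: a sinus
#' cavity in face contact with an entorhinal-cortex (ERC) region at the
#' antero-inferior brain surface, a meningeal shell wrapping the cerebrum
#' and cerebellum (hence touching the inferior cerebellar reference region),
#' and an interior insula-like control region kept clear of all ECB sources.
#' All positions and radii are millimetres in grid coordinates.
#'
#' @param shape,voxel_size grid geometry; the default is a 96^3 grid at 2 mm
#'   (a 192 mm field of view).
#' @param cerebrum_center,cerebrum_radii cerebrum ellipsoid (mm).
#' @param cerebellum_center,cerebellum_radii cerebellum ellipsoid (mm).
#' @param ribbon_thickness_mm cortical grey-matter ribbon thickness; the
#'   interior of the cerebrum beyond it is white matter.
#' @param sinus_center,sinus_radii sinus-cavity ellipsoid; it must penetrate
#'   the cerebrum surface so that the extracranial part is face adjacent to
#'   the brain.
#' @param erc_thickness_mm depth of the ERC band inside the brain measured
#'   from the sinus wall.
#' @param hippocampus_thickness_mm depth of the hippocampus-like band just
#'   interior to the ERC.
#' @param insula_center,insula_radii interior control region.
#' @param pons_center,pons_radii pons-like region (alternative reference).
#' @param shell_thickness_mm meningeal shell width (classically 5 mm).
#' @param insula_clearance_mm minimum Euclidean distance required between
#'   the insula-like region and any ECB voxel.
#' @param seed integer seed recorded with the phantom (the geometry itself
#'   is deterministic; the seed governs downstream ECB field draws).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 96),
                         voxel_size = c(2, 2, 2),
                         cerebrum_center = c(96, 96, 116),
                         cerebrum_radii = c(60, 68, 50),
                         cerebellum_center = c(96, 60, 58),
                         cerebellum_radii = c(32, 28, 26),
                         ribbon_thickness_mm = 6,
                         sinus_center = c(96, 142, 72),
                         sinus_radii = c(18, 16, 14),
                         erc_thickness_mm = 8,
                         hippocampus_thickness_mm = 8,
                         insula_center = c(96, 100, 116),
                         insula_radii = c(10, 12, 10),
                         pons_center = c(96, 84, 84),
                         pons_radii = c(12, 12, 10),
                         shell_thickness_mm = 5,
                         insula_clearance_mm = 15,
                         seed = 1L) {
  spec <- as.list(environment())
  spec$grid <- voxel_grid(shape, voxel_size)
  structure(spec, class = "phantom_spec")
}

# region labels used by build_phantom
phantom_labels <- function() {
  data.frame(
    label = 1:10,
    name = c("white_matter", "cortical_gm", "erc", "hippocampus", "insula",
             "superior_cerebellum", "inferior_cerebellum", "pons",
             "sinus", "meninges_shell"),
    stringsAsFactors = FALSE
  )
}

ellipsoid_mask <- function(grid, center, radii) {
  co <- grid_coords(grid)
  q <- outer(outer(((co$x - center[1]) / radii[1])^2,
                   ((co$y - center[2]) / radii[2])^2, "+"),
             ((co$z - center[3]) / radii[3])^2, "+")
  q <= 1
}

#' Build the digital brain phantom
#'
#' Constructs the labelled phantom from a [phantom_spec()] and verifies its
#' structural invariants: the ERC is in face contact with the sinus cavity,
#' the inferior cerebellum touches the meningeal shell, and the insula-like
#' region is at least `insula_clearance_mm` from every ECB voxel. Violated
#' adjacencies raise a configuration error naming the adjacency.
#'
#' @param spec a [phantom_spec()].
#' @return A [label_volume()] with regions white matter, cortical grey, ERC,
#'   hippocampus, insula, superior/inferior cerebellum, pons, sinus and
#'   meningeal shell.
#' @export
build_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- spec$grid
  vs <- grid$voxel_size

  cerebrum <- ellipsoid_mask(grid, spec$cerebrum_center, spec$cerebrum_radii)
  cerebellum <- ellipsoid_mask(grid, spec$cerebellum_center, spec$cerebellum_radii)
  brain <- cerebrum | cerebellum
  sinus_ell <- ellipsoid_mask(grid, spec$sinus_center, spec$sinus_radii)
  sinus <- sinus_ell & !brain
  if (!any(sinus))
    stop("phantom configuration error: sinus cavity lies entirely inside the brain")
  if (!any(sinus_ell & brain))
    stop("phantom configuration error: ERC-sinus adjacency impossible ",
         "(sinus cavity does not touch the brain surface)")

  labels <- array(0L, grid$shape)
  wm_core <- erode_mm(cerebrum, spec$ribbon_thickness_mm, vs)
  labels[cerebrum] <- 2L
  labels[wm_core] <- 1L

  hip_band <- dilate_mm(sinus, spec$erc_thickness_mm + spec$hippocampus_thickness_mm, vs)
  erc_band <- dilate_mm(sinus, spec$erc_thickness_mm, vs)
  labels[hip_band & cerebrum] <- 4L
  labels[erc_band & cerebrum] <- 3L

  insula <- ellipsoid_mask(grid, spec$insula_center, spec$insula_radii)
  labels[insula & cerebrum] <- 5L

  labels[cerebellum] <- 6L
  co <- grid_coords(grid)
  zmat <- array(rep(co$z, each = prod(grid$shape[1:2])), grid$shape)
  labels[cerebellum & zmat < spec$cerebellum_center[3]] <- 7L

  pons <- ellipsoid_mask(grid, spec$pons_center, spec$pons_radii)
  labels[pons & brain] <- 8L

  labels[sinus] <- 9L
  shell <- make_meninges_shell(brain, spec$shell_thickness_mm, vs) & !sinus
  labels[shell] <- 10L

  phantom <- label_volume(labels, grid, phantom_labels())

  # structural invariants
  erc <- labels == 3L
  if (!any(erc))
    stop("phantom configuration error: ERC region is empty ",
         "(sinus too far from the cerebrum for erc_thickness_mm)")
  if (any(erc & sinus))
    stop("phantom configuration error: ERC overlaps the sinus cavity")
  if (!any(dilate_mm(erc, max(vs), vs) & sinus))
    stop("phantom configuration error: ERC-sinus adjacency violated")
  infc <- labels == 7L
  if (!any(dilate_mm(infc, max(vs), vs) & shell))
    stop("phantom configuration error: inferior cerebellum-meningeal shell ",
         "adjacency violated")
  ecb <- shell | sinus
  insula_vox <- labels == 5L
  if (!any(insula_vox))
    stop("phantom configuration error: insula region is empty")
  if (any(dilate_mm(ecb, spec$insula_clearance_mm, vs) & insula_vox))
    stop("phantom configuration error: insula clearance violated ",
         "(insula voxel within ", spec$insula_clearance_mm, " mm of ECB)")

  attr(phantom, "spec") <- spec
  phantom
}

#' Derived masks for a phantom
#'
#' Returns the analysis masks used throughout the pipeline, including the
#' eroded reference-region variants (inferior cerebellum eroded by 3 mm,
#' white matter eroded by 4 mm).
#'
#' @param phantom a phantom [label_volume()].
#' @param cerebellum_erosion_mm,white_matter_erosion_mm erosion radii for
#'   the alternative reference regions.
#' @return Named list of logical arrays.
#' @export
phantom_masks <- function(phantom, cerebellum_erosion_mm = 3,
                          white_matter_erosion_mm = 4) {
  vs <- phantom$grid$voxel_size
  m <- list(
    white_matter = region_mask(phantom, "white_matter"),
    cortical_gm = region_mask(phantom, "cortical_gm"),
    erc = region_mask(phantom, "erc"),
    hippocampus = region_mask(phantom, "hippocampus"),
    insula = region_mask(phantom, "insula"),
    cerebellum = region_mask(phantom, c("superior_cerebellum", "inferior_cerebellum")),
    inferior_cerebellum = region_mask(phantom, "inferior_cerebellum"),
    pons = region_mask(phantom, "pons"),
    sinus = region_mask(phantom, "sinus"),
    meninges_shell = region_mask(phantom, "meninges_shell")
  )
  m$brain <- m$white_matter | m$cortical_gm | m$erc | m$hippocampus |
    m$insula | m$cerebellum | m$pons
  m$ecb <- m$sinus | m$meninges_shell
  m$eroded_inferior_cerebellum <-
    suppressWarnings(erode_mm(m$inferior_cerebellum, cerebellum_erosion_mm, vs))
  m$eroded_white_matter <-
    suppressWarnings(erode_mm(m$white_matter, white_matter_erosion_mm, vs))
  m
}

#' Reference region specification
#'
#' Names one of the candidate SUVR reference regions together with its
#' conventional erosion: the inferior cerebellar grey matter (no erosion or
#' eroded by 3 mm), the pons, or the cerebral white matter eroded by 4 mm.
#'
#' @param name reference region name.
#' @param erosion_mm erosion radius; defaults to the convention for `name`.
#' @return An object of class `reference_region_spec`.
#' @export
reference_region <- function(name = c("inferior_cerebellum",
                                      "eroded_inferior_cerebellum",
                                      "pons", "eroded_white_matter"),
                             erosion_mm = NULL) {
  name <- match.arg(name)
  default <- c(inferior_cerebellum = 0, eroded_inferior_cerebellum = 3,
               pons = 0, eroded_white_matter = 4)[[name]]
  if (is.null(erosion_mm)) erosion_mm <- default
  if (erosion_mm != default)
    stop("reference_region: erosion_mm (", erosion_mm,
         ") does not match the convention for ", name, " (", default, " mm)")
  structure(list(name = name, erosion_mm = erosion_mm),
            class = "reference_region_spec")
}

#' Mask for a reference region specification
#'
#' @param phantom a phantom [label_volume()].
#' @param spec a [reference_region()].
#' @return Logical mask.
#' @export
reference_mask <- function(phantom, spec = reference_region()) {
  stopifnot(inherits(spec, "reference_region_spec"))
  m <- phantom_masks(phantom)
  switch(spec$name,
         inferior_cerebellum = m$inferior_cerebellum,
         eroded_inferior_cerebellum = m$eroded_inferior_cerebellum,
         pons = m$pons,
         eroded_white_matter = m$eroded_white_matter)
}
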