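#' Read and write label volumes as NIfTI plus a region TSV
#'
#' Volumes are stored as NIfTI (`.nii` / `.nii.gz`) with the voxel size in
#' the header (mm, RAS convention) and the region table as a two-column
#' TSV (`label`, `name`).
#'
#' @param volume a [label_volume()].
#' @param nii_path path of the NIfTI file.
#' @param tsv_path path of the region TSV; defaults to the NIfTI path with
#'   a `.tsv` extension.
#' @return `write_label_volume` returns the paths invisibly;
#'   `read_label_volume` returns a [label_volume()].
#' @export
write_label_volume <- function(volume, nii_path, tsv_path = NULL) {
  stopifnot(inherits(volume, "label_volume"))
  if (is.null(tsv_path))
    tsv_path <- sub("\\.nii(\\.gz)?$", ".tsv", nii_path)
  img <- RNifti::asNifti(volume$labels)
  RNifti::pixdim(img) <- volume$grid$voxel_size
  RNifti::writeNifti(img, nii_path)
  utils::write.table(volume$region_table, tsv_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(list(nii = nii_path, tsv = tsv_path))
}

#' @rdname write_label_volume
#' @export
read_label_volume <- function(nii_path, tsv_path = NULL) {
  if (is.null(tsv_path))
    tsv_path <- sub("\\.nii(\\.gz)?$", ".tsv", nii_path)
  img <- RNifti::readNifti(nii_path)
  vs <- RNifti::pixdim(img)[1:3]
  rt <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  labels <- array(as.integer(round(as.vector(img))), dim = dim(img)[1:3])
  label_volume(labels, voxel_grid(dim(img)[1:3], vs), rt)
}

#' Read and write PET images as NIfTI with a JSON sidecar
#'
#' The sidecar records the unit and provenance (seed, frame schedule,
#' scanner settings) so images remain self-describing.
#'
#' @param image a [pet_image()].
#' @param nii_path path of the NIfTI file.
#' @param json_path sidecar path; defaults to the NIfTI path with `.json`.
#' @return `write_pet_image` returns the paths invisibly;
#'   `read_pet_image` returns a [pet_image()].
#' @export
write_pet_image <- function(image, nii_path, json_path = NULL) {
  stopifnot(inherits(image, "pet_image"))
  if (is.null(json_path))
    json_path <- sub("\\.nii(\\.gz)?$", ".json", nii_path)
  img <- RNifti::asNifti(image$values)
  RNifti::pixdim(img) <- image$grid$voxel_size
  RNifti::writeNifti(img, nii_path)
  jsonlite::write_json(list(unit = image$unit,
                            provenance = image$provenance),
                       json_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list(nii = nii_path, json = json_path))
}

#' @rdname write_pet_image
#' @export
read_pet_image <- function(nii_path, json_path = NULL) {
  if (is.null(json_path))
    json_path <- sub("\\.nii(\\.gz)?$", ".json", nii_path)
  img <- RNifti::readNifti(nii_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  vs <- RNifti::pixdim(img)[1:3]
  pet_image(array(as.vector(img), dim = dim(img)[1:3]),
            voxel_grid(dim(img)[1:3], vs),
            unit = meta$unit, provenance = as.list(meta$provenance))
}
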