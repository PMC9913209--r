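# Readers and writers for the field's interchange formats: NIfTI volumes
# (HU after any scl slope/intercept, handled by RNifti), pre-windowed PNG
# patches, and PNG/CSV export of patch sets.

#' Read a CT volume from NIfTI
#'
#' Returns the voxel array in Hounsfield units (RNifti applies the NIfTI
#' scaling slope/intercept) plus the axial slice through a nodule centroid,
#' ready for [makePatch()].
#'
#' @param path NIfTI file (`.nii` / `.nii.gz`).
#' @param centroid optional `(x, y, z)` 0-based voxel coordinates of the
#'   nodule centroid; when given, the returned `slice` is the axial plane
#'   `z` (single-slice model).
#' @return `list(volume = 3-D HU array, slice = matrix | NULL)`.
#' @export
readNiftiVolume <- function(path, centroid = NULL) {
  vol <- as.array(RNifti::readNifti(path))
  if (length(dim(vol)) != 3L) stopData("expected a 3-D NIfTI volume")
  slice <- NULL
  if (!is.null(centroid)) {
    z <- as.integer(round(centroid[3L])) + 1L
    if (z < 1L || z > dim(vol)[3L]) stopParam("centroid z outside the volume")
    slice <- vol[, , z]
  }
  list(volume = vol, slice = slice)
}

#' Read pre-windowed PNG patches
#'
#' PNG patches are assumed already display-windowed to `[0, 1]` (8- or
#' 16-bit grey; colour images are averaged to one channel) and are resized
#' to the target patch size.
#'
#' @param paths PNG files, one patch per file.
#' @param labels optional 0/1 labels aligned with `paths`.
#' @param cohort cohort tag.
#' @param size output patch side.
#' @return a [CtPatchSet-class].
#' @export
readPatchPng <- function(paths, labels = NA_integer_, cohort = "png",
                         size = 224L) {
  px <- lapply(paths, function(p) {
    im <- png::readPNG(p)
    if (length(dim(im)) == 3L) im <- rowMeans(im, dims = 2L)
    pmin(pmax(bilinearResize(im, as.integer(size)), 0), 1)
  })
  newCtPatchSet(px, data.frame(
    patient_id = tools::file_path_sans_ext(basename(paths)),
    cohort = cohort, label = rep_len(labels, length(paths)),
    provenance = "png", stringsAsFactors = FALSE))
}

#' Write a patch set as 8-bit PNG files plus a CSV manifest
#'
#' @param patches a [CtPatchSet-class].
#' @param dir output directory (created if needed).
#' @return invisible character vector of written PNG paths.
#' @export
writePatchesPng <- function(patches, dir) {
  stopifnot(is(patches, "CtPatchSet"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ph <- patchPheno(patches)
  paths <- file.path(dir, paste0(ph$patient_id, ".png"))
  for (i in seq_along(paths))
    png::writePNG(patches@pixels[[i]], paths[i])   # 8-bit grey
  write.csv(cbind(ph, file = basename(paths)),
            file.path(dir, "patches.csv"), row.names = FALSE)
  invisible(paths)
}
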