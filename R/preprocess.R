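#' Construct a display window
#'
#' @param level window centre in HU.
#' @param width window width in HU (> 0).
#' @return a [WindowSpec-class].
#' @export
windowSpec <- function(level, width) {
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0)
    stopParam("window width must be a positive finite scalar")
  new("WindowSpec", level = as.numeric(level), width = as.numeric(width))
}

#' @describeIn windowSpec the standard lung window (level -600 HU, width 1500 HU).
#' @export
lungWindow <- function() windowSpec(-600, 1500)

#' @describeIn windowSpec the standard mediastinal window (level 40 HU, width 300 HU).
#' @export
mediastinalWindow <- function() windowSpec(40, 300)

#' Apply a display window to a Hounsfield-unit image
#'
#' Linearly maps `[level - width/2, level + width/2]` onto `[0, 1]`, clamping
#' outside; monotone non-decreasing in HU.
#'
#' @param grid numeric vector/matrix of HU values (finite).
#' @param w a [WindowSpec-class].
#' @return object of the same shape with values in `[0, 1]`.
#' @export
applyWindow <- function(grid, w) {
  stopifnot(is(w, "WindowSpec"))
  if (!all(is.finite(grid))) stopData("HU grid contains non-finite values")
  lo <- w@level - w@width / 2
  pmin(pmax((grid - lo) / w@width, 0), 1)
}

bilinearResize <- function(m, size) {
  if (identical(dim(m), c(size, size))) return(m)
  r <- EBImage::resize(m, w = size, h = size)
  as.matrix(r)
}

#' Cut, window and resize a nodule-centred patch
#'
#' Crops a half-open `cropSize`-pixel square centred (0-based, pixel-centred
#' coordinates) on `center` from an HU image, pads out-of-bounds pixels with
#' the window floor (`level - width/2`), applies the display window and
#' bilinearly resizes to `size` x `size`. The windowed channel is replicated
#' to three channels in the returned [CtPatchSet-class].
#'
#' @param grid numeric HU matrix (rows = y, cols = x).
#' @param center length-2 numeric `(row, col)` 0-based centre.
#' @param cropSize side of the square crop in pixels.
#' @param window a [WindowSpec-class]; default lung window.
#' @param size output spatial size (default 224).
#' @param patientId,cohort,label,provenance metadata for the patch.
#' @return a length-1 [CtPatchSet-class].
#' @export
makePatch <- function(grid, center, cropSize, window = lungWindow(), size = 224L,
                      patientId = "p1", cohort = "adhoc", label = NA_integer_,
                      provenance = "makePatch") {
  stopifnot(is.matrix(grid))
  cropSize <- as.integer(cropSize)
  if (cropSize < 1L) stopParam("cropSize must be >= 1")
  r0 <- as.integer(round(center[1L] - cropSize / 2))
  c0 <- as.integer(round(center[2L] - cropSize / 2))
  rows <- r0 + seq_len(cropSize)        # 1-based row indices into grid
  cols <- c0 + seq_len(cropSize)
  if (all(rows < 1L | rows > nrow(grid)) || all(cols < 1L | cols > ncol(grid)))
    stop(errorCondition("crop window does not intersect the image",
                        class = c("tlrGeometryError", "error")))
  floorHu <- window@level - window@width / 2
  crop <- matrix(floorHu, cropSize, cropSize)
  rOk <- rows >= 1L & rows <= nrow(grid)
  cOk <- cols >= 1L & cols <= ncol(grid)
  crop[rOk, cOk] <- grid[rows[rOk], cols[cOk], drop = FALSE]
  win <- applyWindow(crop, window)
  out <- bilinearResize(win, as.integer(size))
  out <- pmin(pmax(out, 0), 1)
  newCtPatchSet(list(out), data.frame(patient_id = patientId, cohort = cohort,
                                      label = label, provenance = provenance,
                                      stringsAsFactors = FALSE),
                window = window)
}

newCtPatchSet <- function(pixels, pheno, window = lungWindow(), channels = 3L) {
  new("CtPatchSet", pixels = pixels, pheno = pheno, window = window,
      channels = as.integer(channels))
}

#' @export
setMethod("length", "CtPatchSet", function(x) length(x@pixels))

#' @export
setMethod("show", "CtPatchSet", function(object) {
  d <- if (length(object)) dim(object@pixels[[1L]]) else c(NA, NA)
  cat(sprintf("CtPatchSet with %d patch(es) of %s x %s (x%d channels)\n",
              length(object), d[1L], d[2L], object@channels))
  tab <- table(object@pheno$label, useNA = "ifany")
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat("  cohorts:", paste(unique(object@pheno$cohort), collapse = ", "), "\n")
})

#' @export
setMethod("[", "CtPatchSet", function(x, i, j, ..., drop = FALSE) {
  newCtPatchSet(x@pixels[i], x@pheno[i, , drop = FALSE], x@window, x@channels)
})

#' Patch metadata
#' @param x a [CtPatchSet-class].
#' @return data.frame of per-patch metadata.
#' @export
patchPheno <- function(x) x@pheno

#' Patch labels as 0/1 integers
#' @param x a [CtPatchSet-class].
#' @export
patchLabels <- function(x) asLabel01(x@pheno$label)

#' Dense input array of a patch set
#'
#' Materialises patches as an `H x W x channels x n` array with the windowed
#' channel replicated, the network's input representation.
#'
#' @param x a [CtPatchSet-class].
#' @param i optional patch indices.
#' @export
patchArray <- function(x, i = seq_len(length(x))) {
  stopifnot(is(x, "CtPatchSet"))
  px <- x@pixels[i]
  d <- dim(px[[1L]])
  out <- array(0, c(d[1L], d[2L], x@channels, length(px)))
  for (k in seq_along(px)) out[, , , k] <- px[[k]]   # recycled across channels
  out
}
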