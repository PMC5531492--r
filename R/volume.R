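#' 3D scalar volume with grid geometry
#'
#' Container for a 3D image in Hounsfield units (or any scalar field) on a
#' regular axis-aligned grid. The world position of the centre of voxel
#' `(i, j, k)` (0-based) is `origin + c(i, j, k) * spacing`, all in mm.
#'
#' @param data 3D numeric array. All values must be finite.
#' @param spacing Numeric length-3, per-axis voxel edge length in mm
#'   (strictly positive).
#' @param origin Numeric length-3, world position (mm) of the centre of
#'   voxel (0,0,0).
#' @return An object of class `scalar_volume` with fields `data`,
#'   `spacing`, `origin`.
#' @examples
#' v <- scalar_volume(array(-1000, c(4, 4, 4)), spacing = c(1, 1, 1))
#' voxel_volume(v)
#' @export
scalar_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  if (any(!is.finite(data)))
    stop("scalar_volume: non-finite voxel values")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<scalar_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, intensity range [%.1f, %.1f]\n",
              paste(signif(x$origin, 4), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.scalar_volume <- function(x) dim(x$data)

#' Geometric volume of one voxel
#'
#' @param vol A [scalar_volume()].
#' @return Voxel volume in mm^3 (product of the spacings; constant over the
#'   grid).
#' @export
voxel_volume <- function(vol) prod(vol$spacing)

#' World coordinates of a set of voxel indices
#'
#' @param vol A [scalar_volume()] (only its geometry is used).
#' @param ijk Integer matrix (n x 3) of 0-based voxel indices; if missing,
#'   all voxels of the grid in array order.
#' @return n x 3 matrix of world positions in mm.
#' @export
voxel_coords <- function(vol, ijk = NULL) {
  if (is.null(ijk)) {
    d <- dim(vol$data)
    ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                                 k = 0:(d[3] - 1)))
  }
  sweep(ijk %*% diag(vol$spacing), 2, vol$origin, "+")
}

#' Segmentation masks attached to a volume
#'
#' Bundles the lung mask with optional lobe, airway and vessel masks. All
#' masks must share the grid of the image they describe; a geometry mismatch
#' between mask and image is an error, never a resample.
#'
#' @param lung Binary (0/1 or logical) 3D array, non-empty.
#' @param lobes Optional labelled integer 3D array.
#' @param airways,vessels Optional binary 3D arrays.
#' @return An object of class `mask_set`.
#' @export
mask_set <- function(lung, lobes = NULL, airways = NULL, vessels = NULL) {
  lung <- as_binary_mask(lung, "lung")
  if (sum(lung) == 0L) stop("lung mask is empty")
  d <- dim(lung)
  for (nm in c("lobes", "airways", "vessels")) {
    m <- get(nm)
    if (!is.null(m) && !identical(dim(m), d))
      stop(sprintf("mask '%s' shape differs from lung mask", nm))
  }
  if (!is.null(airways)) airways <- as_binary_mask(airways, "airways")
  if (!is.null(vessels)) vessels <- as_binary_mask(vessels, "vessels")
  structure(list(lung = lung, lobes = lobes, airways = airways,
                 vessels = vessels), class = "mask_set")
}

as_binary_mask <- function(m, name) {
  if (!is.array(m) || length(dim(m)) != 3L)
    stop(sprintf("mask '%s' must be a 3D array", name))
  v <- unique(as.vector(m))
  if (!all(v %in% c(0, 1, TRUE, FALSE)))
    stop(sprintf("mask '%s' must be binary 0/1", name))
  storage.mode(m) <- "integer"
  m
}

check_same_geometry <- function(vol, mask, what = "mask") {
  if (!identical(dim(vol$data), dim(mask$lung)))
    stop(sprintf("%s shape %s does not match image shape %s",
                 what, paste(dim(mask$lung), collapse = "x"),
                 paste(dim(vol$data), collapse = "x")))
  invisible(TRUE)
}

## ---- file I/O ------------------------------------------------------------

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path)
is_meta_path <- function(path) grepl("\\.(mha|mhd)$", path)

#' Read a 3D volume from NIfTI or MetaImage
#'
#' Spacing is taken from the sform/qform (NIfTI) or `ElementSpacing`
#' (MetaImage); the origin from the translation column / `Offset`. Intensity
#' values are returned unmodified.
#'
#' @param path Path to a `.nii`, `.nii.gz`, `.mha` or `.mhd` file.
#' @return A [scalar_volume()].
#' @export
read_volume <- function(path) {
  if (!is_nifti_path(path) && !is_meta_path(path))
    stop(sprintf("unsupported volume format: %s", path))
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is_nifti_path(path)) {
    img <- RNifti::readNifti(path)
    geo <- nifti_geometry(img)
    arr <- array(as.numeric(img), dim = dim(img)[1:3])
    scalar_volume(arr, spacing = geo$spacing, origin = geo$origin)
  } else if (is_meta_path(path)) {
    m <- read_metaimage(path)
    scalar_volume(m$data, spacing = m$spacing, origin = m$origin)
  } else {
    stop(sprintf("unsupported volume format: %s", path))
  }
}

nifti_geometry <- function(img) {
  xf <- RNifti::xform(img)
  spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("volume header carries no usable spacing")
  list(spacing = as.numeric(spacing), origin = as.numeric(xf[1:3, 4]))
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' Data are stored as float32, so values representable in single precision
#' round-trip exactly through [read_volume()]. Integer masks survive a
#' round trip unchanged.
#'
#' @param vol A [scalar_volume()].
#' @param path Output path; format chosen from the extension.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "scalar_volume"))
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory does not exist: %s", dirname(path)))
  if (is_nifti_path(path)) {
    img <- RNifti::asNifti(vol$data, datatype = "float")
    sf <- diag(c(vol$spacing, 1))
    sf[1:3, 4] <- vol$origin
    img <- RNifti::`sform<-`(img, structure(sf, code = 2L))
    ok <- tryCatch({RNifti::writeNifti(img, path); TRUE},
                   error = function(e) FALSE)
    if (!ok || !file.exists(path)) stop(sprintf("failed to write %s", path))
  } else if (is_meta_path(path)) {
    write_metaimage(vol$data, vol$spacing, vol$origin, path)
  } else {
    stop(sprintf("unsupported volume format: %s", path))
  }
  invisible(path)
}

#' Read / write a displacement field
#'
#' Fields are stored as 4D NIfTI volumes (nx, ny, nz, 3) holding the
#' per-reference-voxel displacement in mm, with the reference grid geometry
#' in the header.
#'
#' @param path NIfTI file path.
#' @return For `read_field`, a `deformation_field` (see
#'   [deformation_field()]).
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop("deformation field must be a 4D (x,y,z,3) volume")
  geo <- nifti_geometry(img)
  deformation_field(array(as.numeric(img), dim = d),
                    spacing = geo$spacing, origin = geo$origin)
}

#' @param field A `deformation_field`.
#' @rdname read_field
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "deformation_field"))
  img <- RNifti::asNifti(field$disp, datatype = "float")
  sf <- diag(c(field$spacing, 1))
  sf[1:3, 4] <- field$origin
  img <- RNifti::`sform<-`(img, structure(sf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

## MetaImage (.mha/.mhd): plain key = value header, little-endian raw
## payload; no installed package covers it, so read/write it directly.
read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- character()
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0L) stop("MetaImage header missing ElementDataFile")
    hdr <- c(hdr, ln)
    if (grepl("^ElementDataFile", ln)) break
  }
  kv <- parse_meta_header(hdr)
  dims <- kv$DimSize
  n <- prod(dims)
  if (identical(kv$ElementDataFile, "LOCAL")) {
    data <- read_meta_payload(con, kv$ElementType, n)
  } else {
    raw_path <- file.path(dirname(path), kv$ElementDataFile)
    if (!file.exists(raw_path))
      stop(sprintf("MetaImage payload not found: %s", raw_path))
    rcon <- file(raw_path, "rb")
    on.exit(close(rcon), add = TRUE)
    data <- read_meta_payload(rcon, kv$ElementType, n)
  }
  list(data = array(data, dim = dims), spacing = kv$ElementSpacing,
       origin = kv$Offset)
}

parse_meta_header <- function(lines) {
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) next
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    kv[[key]] <- val
  }
  if (is.null(kv$DimSize)) stop("MetaImage header missing DimSize")
  if (is.null(kv$ElementSpacing)) stop("MetaImage header missing spacing")
  num <- function(s) as.numeric(strsplit(s, "\\s+")[[1]])
  kv$DimSize <- as.integer(num(kv$DimSize))
  kv$ElementSpacing <- num(kv$ElementSpacing)
  kv$Offset <- if (is.null(kv$Offset)) rep(0, 3) else num(kv$Offset)
  if (identical(kv$BinaryDataByteOrderMSB, "True") ||
      identical(kv$ElementByteOrderMSB, "True"))
    stop("big-endian MetaImage not supported")
  kv$ElementType <- if (is.null(kv$ElementType)) "MET_FLOAT" else kv$ElementType
  kv
}

read_meta_payload <- function(con, type, n) {
  switch(type,
    MET_FLOAT = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    MET_DOUBLE = readBin(con, "numeric", n = n, size = 8, endian = "little"),
    MET_SHORT = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                        endian = "little"),
    MET_USHORT = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                         endian = "little"),
    MET_UCHAR = as.integer(readBin(con, "raw", n = n)),
    MET_INT = readBin(con, "integer", n = n, size = 4, endian = "little"),
    stop(sprintf("unsupported MetaImage ElementType: %s", type)))
}

write_metaimage <- function(data, spacing, origin, path) {
  dims <- dim(data)
  ## .mha embeds the payload; .mhd points at a sibling .raw file
  local <- grepl("\\.mha$", path)
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %s", paste(dims, collapse = " ")),
           sprintf("ElementSpacing = %s",
                   paste(format(spacing, digits = 17), collapse = " ")),
           sprintf("Offset = %s",
                   paste(format(origin, digits = 17), collapse = " ")),
           "ElementType = MET_FLOAT",
           sprintf("ElementDataFile = %s", if (local) "LOCAL" else raw_name))
  con <- tryCatch(file(path, "wb"), error = function(e)
    stop(sprintf("cannot open %s for writing", path)))
  on.exit(close(con), add = TRUE)
  writeLines(hdr, con)
  if (local) {
    writeBin(as.numeric(data), con, size = 4, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(as.numeric(data), rcon, size = 4, endian = "little")
  }
  invisible(path)
}

## ---- HU calibration ------------------------------------------------------

#' Calibration regions for HU adjustment
#'
#' Voxel index sets over the tracheal air column and the aorta, used to
#' anchor the intensity scale at -1000 HU (air) and +55 HU (soft tissue).
#'
#' @param trachea,aorta Either logical 3D arrays or integer vectors of
#'   1-based linear voxel indices; both non-empty and disjoint.
#' @return An object of class `calibration_rois`.
#' @export
calibration_rois <- function(trachea, aorta) {
  as_idx <- function(x, name) {
    if (is.array(x)) x <- which(x != 0)
    x <- as.integer(x)
    if (length(x) == 0L) stop(sprintf("%s ROI is empty", name))
    x
  }
  trachea <- as_idx(trachea, "trachea")
  aorta <- as_idx(aorta, "aorta")
  if (length(intersect(trachea, aorta)) > 0L)
    stop("trachea and aorta ROIs overlap")
  structure(list(trachea = trachea, aorta = aorta),
            class = "calibration_rois")
}

#' Two-point HU calibration against trachea and aorta
#'
#' Fits the affine intensity map `a * I + b` that sends the mean intensity
#' of the tracheal ROI to -1000 HU and the mean of the aortic ROI to
#' +55 HU, and applies it to the whole volume. The map is strictly
#' increasing whenever the aorta ROI is brighter than the trachea ROI, so
#' intensity ordering is preserved; applying the calibration twice is a
#' no-op.
#'
#' @param vol A [scalar_volume()].
#' @param rois A [calibration_rois()].
#' @return The calibrated [scalar_volume()], with the fitted `a` and `b`
#'   attached as attribute `"calibration"`.
#' @export
calibrate_hu <- function(vol, rois) {
  stopifnot(inherits(vol, "scalar_volume"), inherits(rois, "calibration_rois"))
  mt <- mean(vol$data[rois$trachea])
  ma <- mean(vol$data[rois$aorta])
  if (isTRUE(all.equal(mt, ma)) || mt == ma)
    stop("degenerate calibration ROIs: trachea and aorta means are equal")
  a <- (55 - (-1000)) / (ma - mt)
  b <- -1000 - a * mt
  out <- scalar_volume(a * vol$data + b, spacing = vol$spacing,
                       origin = vol$origin)
  attr(out, "calibration") <- c(a = a, b = b)
  out
}
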