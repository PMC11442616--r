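#' DWI volumes and scalar maps
#'
#' A `dwi_volume` is a 4D intensity array (x, y, z, measurement) with a
#' voxel size in mm; the 4th dimension is matched one-to-one against a
#' [gradient_table()]. A `scalar_map` is one derived 3D map (FA, ADC, S0 or
#' a tensor diagonal element) carrying its kind and units. Axes follow the
#' fixed patient-frame convention x = right-left, y = anterior-posterior,
#' z = feet-head.
#'
#' @param data 4D non-negative array
#' @param voxel_size length-3 positive numeric, mm
#' @param gradients optional `gradient_table` checked against dim 4
#' @return a `dwi_volume` (list with `data`, `voxel_size`)
#' @export
dwi_volume <- function(data, voxel_size, gradients = NULL) {
  data <- unclass(data)
  if (length(dim(data)) != 4) {
    abort(sprintf("expected 4D volume, got %dD.", length(dim(data)) %||% 1L))
  }
  if (any(data < 0, na.rm = TRUE)) abort("DWI intensities must be >= 0.")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0)) {
    abort("`voxel_size` must be 3 strictly positive numbers (mm).")
  }
  if (!is.null(gradients) && dim(data)[4] != nrow(gradients)) {
    abort(sprintf(
      "count mismatch: %d measurement volumes but %d gradient-table entries.",
      dim(data)[4], nrow(gradients)
    ))
  }
  structure(list(data = data, voxel_size = voxel_size), class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<dwi_volume> %d x %d x %d voxels, %d measurements, voxel %s mm\n",
    d[1], d[2], d[3], d[4], paste(x$voxel_size, collapse = " x ")
  ))
  invisible(x)
}

SCALAR_KINDS <- c("FA", "ADC", "S0", "Dxx", "Dyy", "Dzz", "MD")

#' @rdname dwi_volume
#' @param kind one of FA, ADC, S0, Dxx, Dyy, Dzz, MD
#' @param units `"mm^2/s"` for diffusivities/ADC, `"1"` for FA, `"a.u."`
#'   for S0; filled in from `kind` when omitted
#' @export
scalar_map <- function(data, voxel_size, kind, units = NULL) {
  data <- unclass(data)
  if (length(dim(data)) != 3) abort("scalar map must be a 3D array.")
  kind <- match.arg(kind, SCALAR_KINDS)
  if (kind == "FA" && any(data < -1e-9 | data > 1 + 1e-9, na.rm = TRUE)) {
    abort("FA values must lie in [0, 1]; clip before constructing the map.")
  }
  units <- units %||% switch(kind, FA = "1", S0 = "a.u.", "mm^2/s")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(voxel_size <= 0)) {
    abort("`voxel_size` must be 3 strictly positive numbers (mm).")
  }
  structure(list(data = data, voxel_size = voxel_size, kind = kind,
                 units = units), class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  cat(sprintf(
    "<scalar_map:%s> %s voxels [%s], range %.4g..%.4g\n", x$kind,
    paste(dim(x$data), collapse = " x "), x$units,
    min(x$data, na.rm = TRUE), max(x$data, na.rm = TRUE)
  ))
  invisible(x)
}

#' Read a 4D DWI NIfTI against a gradient table
#'
#' Voxel size is taken from the NIfTI header; the number of measurement
#' volumes must equal the gradient-table length.
#'
#' @param file NIfTI-1 path (.nii or .nii.gz)
#' @param gradients a `gradient_table`
#' @return a `dwi_volume`
#' @export
read_dwi <- function(file, gradients) {
  stopifnot(inherits(gradients, "gradient_table"))
  img <- RNifti::readNifti(file)
  if (length(dim(img)) != 4) {
    abort(sprintf("expected 4D NIfTI, got %dD.", length(dim(img))))
  }
  vs <- RNifti::pixdim(img)[1:3]
  dwi_volume(strip_nifti(img), vs, gradients)
}

#' Write a DWI volume as NIfTI-1
#'
#' @param vol a `dwi_volume`
#' @param file destination path
#' @return `file`, invisibly
#' @export
write_dwi <- function(vol, file) {
  stopifnot(inherits(vol, "dwi_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- c(vol$voxel_size, 1)  # 4D: temporal unit is a dummy
  RNifti::writeNifti(img, file, datatype = "double")
  invisible(file)
}

#' Write / read scalar maps with a JSON metadata sidecar
#'
#' The map is stored as a 3D NIfTI; `kind` and `units` go to a JSON sidecar
#' next to it (same path with `.json` appended after stripping `.nii`/
#' `.nii.gz`), from which [read_scalar_map()] restores them.
#'
#' @param map a `scalar_map`
#' @param file destination NIfTI path
#' @param datatype NIfTI storage type (default `"float"`, i.e. float32)
#' @return `file`, invisibly
#' @export
write_scalar_map <- function(map, file, datatype = "float") {
  stopifnot(inherits(map, "scalar_map"))
  img <- RNifti::asNifti(map$data)
  RNifti::pixdim(img) <- map$voxel_size
  RNifti::writeNifti(img, file, datatype = datatype)
  jsonlite::write_json(
    list(kind = map$kind, units = map$units),
    sidecar_path(file), auto_unbox = TRUE
  )
  invisible(file)
}

#' @rdname write_scalar_map
#' @export
read_scalar_map <- function(file) {
  img <- RNifti::readNifti(file)
  if (length(dim(img)) != 3) {
    abort(sprintf("expected 3D NIfTI, got %dD.", length(dim(img))))
  }
  sc <- sidecar_path(file)
  meta <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE)
          else list(kind = "S0", units = NULL)
  scalar_map(strip_nifti(img), RNifti::pixdim(img)[1:3],
             kind = meta$kind, units = meta$units)
}

# plain array without the NIfTI header attributes
strip_nifti <- function(img) {
  array(as.vector(as.array(img)), dim(img))
}

sidecar_path <- function(file) {
  paste0(sub("\\.nii(\\.gz)?$", "", file), ".json")
}
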