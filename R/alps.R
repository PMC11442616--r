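#' ALPS region-of-interest specification
#'
#' Projection/association ROIs follow the method's fixed footprint: 2 x 2
#' voxels on one slice (4 x 4 mm^2 at 2 mm voxels). `start_voxel` is the
#' 0-based minimum corner; the extent is half-open
#' `[start, start + size)`. Deviating sizes for these kinds require
#' `allow_resize = TRUE`; tumor ROIs are unconstrained.
#'
#' @param kind `"projection"`, `"association"` or `"tumor"`
#' @param start_voxel integer 3-vector, 0-based
#' @param size_voxels integer 3-vector (default `c(2, 2, 1)`)
#' @param hemisphere `"ipsilateral"`, `"contralateral"`, `"left"`,
#'   `"right"` or NA
#' @param allow_resize permit non-2x2x1 projection/association ROIs
#' @return a `roi_spec`
#' @export
roi_spec <- function(kind, start_voxel, size_voxels = c(2L, 2L, 1L),
                     hemisphere = NA_character_, allow_resize = FALSE) {
  kind <- match.arg(kind, c("projection", "association", "tumor"))
  start_voxel <- as.integer(start_voxel)
  size_voxels <- as.integer(size_voxels)
  stopifnot(length(start_voxel) == 3, length(size_voxels) == 3)
  if (any(start_voxel < 0) || any(size_voxels < 1)) {
    abort("ROI start must be >= 0 and sizes >= 1 (0-based, half-open).")
  }
  if (kind != "tumor" && !allow_resize &&
      !identical(size_voxels, c(2L, 2L, 1L))) {
    abort(paste0(
      "projection/association ROIs are fixed at 2 x 2 x 1 voxels; ",
      "pass allow_resize = TRUE to override."
    ))
  }
  if (!is.na(hemisphere)) {
    hemisphere <- match.arg(hemisphere,
                            c("ipsilateral", "contralateral", "left", "right"))
  }
  structure(
    list(kind = kind, start_voxel = start_voxel, size_voxels = size_voxels,
         hemisphere = hemisphere),
    class = "roi_spec"
  )
}

roi_indices <- function(roi, grid_shape) {
  lo <- roi$start_voxel
  hi <- roi$start_voxel + roi$size_voxels
  if (any(lo < 0) || any(hi > grid_shape)) {
    abort(sprintf(
      "ROI [%s)..[%s) lies outside the %s grid.",
      paste(lo, collapse = ","), paste(hi, collapse = ","),
      paste(grid_shape, collapse = "x")
    ))
  }
  list(x = (lo[1] + 1):hi[1], y = (lo[2] + 1):hi[2], z = (lo[3] + 1):hi[3])
}

#' Read/write an ROI sidecar (JSON list of ROI specs)
#'
#' Format: JSON array of objects with fields `kind`, `hemisphere`,
#' `start_voxel`, `size_voxels` (0-based starts, half-open extents).
#'
#' @param file JSON path
#' @return list of `roi_spec`s (named by `kind_hemisphere` when available)
#' @export
read_roi_sidecar <- function(file) {
  raw <- jsonlite::read_json(file, simplifyVector = FALSE)
  rois <- lapply(raw, function(r) {
    roi_spec(r$kind, unlist(r$start_voxel),
             unlist(r$size_voxels) %||% c(2L, 2L, 1L),
             r$hemisphere %||% NA_character_)
  })
  nm <- vapply(rois, function(r) {
    if (is.na(r$hemisphere)) r$kind else paste(r$kind, r$hemisphere, sep = "_")
  }, character(1))
  setNames(rois, nm)
}

#' @rdname read_roi_sidecar
#' @param rois list of `roi_spec`s
#' @export
write_roi_sidecar <- function(rois, file) {
  jsonlite::write_json(
    lapply(unname(rois), function(r) {
      list(kind = r$kind, hemisphere = r$hemisphere,
           start_voxel = r$start_voxel, size_voxels = r$size_voxels)
    }),
    file, auto_unbox = TRUE, null = "null", na = "null"
  )
  invisible(file)
}

#' ROI-mean tensor diffusivities
#'
#' Arithmetic mean of each tensor element over the ROI voxels. Errors if
#' the ROI leaves the grid or touches voxels outside the fitted mask.
#'
#' @param fit a `dti_fit`
#' @param roi a [roi_spec()]
#' @return one-row tibble: `kind, hemisphere, n_voxels, dxx, dyy, dzz,
#'   dxy, dxz, dyz` (mm^2/s)
#' @export
roi_mean_diffusivities <- function(fit, roi) {
  stopifnot(inherits(fit, "dti_fit"), inherits(roi, "roi_spec"))
  gs <- dim(fit$s0)
  ix <- roi_indices(roi, gs)
  if (!all(fit$mask[ix$x, ix$y, ix$z])) {
    abort("ROI intersects voxels outside the fitted mask.")
  }
  m <- vapply(seq_len(6), function(i) {
    mean(fit$tensors[ix$x, ix$y, ix$z, i])
  }, numeric(1))
  tibble(
    kind = roi$kind, hemisphere = roi$hemisphere,
    n_voxels = prod(roi$size_voxels),
    dxx = m[1], dyy = m[2], dzz = m[3], dxy = m[4], dxz = m[5], dyz = m[6]
  )
}

#' DTI-ALPS index
#'
#' `ALPS = mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)`: the
#' ratio of the two diffusivities along the perivascular (right-left, x)
#' direction to the two diffusivities perpendicular to both the fibers and
#' the perivascular space. Values near 1 mean no preferential x-axis
#' diffusivity; impaired perivascular flow lowers the index.
#'
#' @param proj,assoc one-row tibbles from [roi_mean_diffusivities()] (or
#'   anything with `dxx`/`dyy` resp. `dxx`/`dzz` fields)
#' @return an `alps_measurement`: one-row tibble
#'   `dxx_proj, dxx_assoc, dyy_proj, dzz_assoc, index`
#' @export
#' @examples
#' compute_alps_index(list(dxx = 1.2e-3, dyy = 0.8e-3),
#'                    list(dxx = 1.0e-3, dzz = 0.7e-3))
compute_alps_index <- function(proj, assoc) {
  vals <- c(dxx_proj = as.numeric(proj$dxx), dxx_assoc = as.numeric(assoc$dxx),
            dyy_proj = as.numeric(proj$dyy), dzz_assoc = as.numeric(assoc$dzz))
  if (length(vals) != 4 || any(!is.finite(vals))) {
    abort("all four diffusivities (Dxx_proj, Dxx_assoc, Dyy_proj, Dzz_assoc) must be present and finite.")
  }
  den <- mean(vals[c("dyy_proj", "dzz_assoc")])
  if (den <= 0) abort("non-positive denominator: mean(Dyy_proj, Dzz_assoc) <= 0.")
  out <- tibble(
    dxx_proj = vals[["dxx_proj"]], dxx_assoc = vals[["dxx_assoc"]],
    dyy_proj = vals[["dyy_proj"]], dzz_assoc = vals[["dzz_assoc"]],
    index = mean(vals[c("dxx_proj", "dxx_assoc")]) / den
  )
  class(out) <- c("alps_measurement", class(out))
  out
}

#' @rdname compute_alps_index
#' @param fit a `dti_fit`
#' @param proj_roi,assoc_roi projection/association [roi_spec()]s
#' @export
alps_from_fit <- function(fit, proj_roi, assoc_roi) {
  compute_alps_index(
    roi_mean_diffusivities(fit, proj_roi),
    roi_mean_diffusivities(fit, assoc_roi)
  )
}

#' Tumor ROI mean ADC
#'
#' In-plane circular ROI of the given area (default 5.3 mm^2, sub-voxel at
#' 2 x 2 mm in-plane resolution), centered at a point in mm, rasterized to
#' voxel centers on the nearest slice. A voxel belongs to the ROI when its
#' center lies within the circle radius; the voxel containing the center is
#' always included, so the ROI is never empty.
#'
#' @param adc a `scalar_map` (kind ADC)
#' @param center_mm length-3 position in mm (image frame, origin at the
#'   corner of voxel (0,0,0))
#' @param area_mm2 circle area, mm^2
#' @return mean ADC over the rasterized voxels, in the map's units
#' @export
tumor_roi_adc <- function(adc, center_mm, area_mm2 = 5.3) {
  stopifnot(inherits(adc, "scalar_map"))
  gs <- dim(adc$data)
  vs <- adc$voxel_size
  if (any(center_mm < 0) || any(center_mm > gs * vs)) {
    abort("tumor ROI center lies outside the grid.")
  }
  ctr_vox <- pmin(pmax(floor(center_mm / vs), 0), gs - 1)  # 0-based
  k <- ctr_vox[3] + 1
  r <- sqrt(area_mm2 / pi)
  cx <- (seq_len(gs[1]) - 0.5) * vs[1]
  cy <- (seq_len(gs[2]) - 0.5) * vs[2]
  inside <- outer(cx, cy, function(a, b) {
    (a - center_mm[1])^2 + (b - center_mm[2])^2 <= r^2
  })
  inside[ctr_vox[1] + 1, ctr_vox[2] + 1] <- TRUE
  mean(adc$data[, , k][inside])
}

#' Advisory ALPS ROI placement
#'
#' Heuristic stand-in for expert consensus placement: scans every 2 x 2
#' window of the given slice and scores the mean absolute alignment of the
#' principal tensor eigenvector with the feet-head axis (projection
#' candidate) and the anterior-posterior axis (association candidate),
#' gated on every window voxel having FA >= `fa_threshold`. Advisory only:
#' callers supplying explicit ROIs must not route them through here.
#'
#' @param fa a `scalar_map` of kind FA
#' @param fit the matching `dti_fit`
#' @param slice_index 0-based z slice
#' @param hemisphere restrict the search to the left/right half of the
#'   x-range, or `"both"`
#' @param fa_threshold FA gate (default 0.2)
#' @return list of two [roi_spec()]s (`projection`, `association`)
#' @export
suggest_roi <- function(fa, fit, slice_index, hemisphere = "both",
                        fa_threshold = 0.2) {
  stopifnot(inherits(fa, "scalar_map"), inherits(fit, "dti_fit"))
  hemisphere <- match.arg(hemisphere, c("both", "left", "right"))
  gs <- dim(fa$data)
  k <- slice_index + 1
  if (k < 1 || k > gs[3]) abort("slice_index outside the grid.")
  xr <- switch(hemisphere,
    both = 1:(gs[1] - 1),
    left = 1:max(1, floor(gs[1] / 2) - 1),
    right = (floor(gs[1] / 2) + 1):(gs[1] - 1)
  )
  # principal eigenvector alignment per voxel of the slice
  align_z <- array(NA_real_, gs[1:2])
  align_y <- array(NA_real_, gs[1:2])
  for (i in seq_len(gs[1])) {
    for (j in seq_len(gs[2])) {
      if (!fit$mask[i, j, k]) next
      v <- fit$tensors[i, j, k, ]
      if (any(!is.finite(v))) next
      e <- eigen(tensor6_to_mat(v), symmetric = TRUE)
      pe <- e$vectors[, which.max(e$values)]
      align_z[i, j] <- abs(pe[3])
      align_y[i, j] <- abs(pe[2])
    }
  }
  best <- list(projection = NULL, association = NULL)
  score <- c(projection = -Inf, association = -Inf)
  for (i in xr) {
    for (j in 1:(gs[2] - 1)) {
      w_fa <- fa$data[i:(i + 1), j:(j + 1), k]
      if (any(is.na(w_fa)) || min(w_fa) < fa_threshold) next
      sz <- mean(align_z[i:(i + 1), j:(j + 1)])
      sy <- mean(align_y[i:(i + 1), j:(j + 1)])
      if (is.finite(sz) && sz > score[["projection"]]) {
        score[["projection"]] <- sz
        best$projection <- roi_spec("projection", c(i - 1, j - 1, slice_index))
      }
      if (is.finite(sy) && sy > score[["association"]]) {
        score[["association"]] <- sy
        best$association <- roi_spec("association", c(i - 1, j - 1, slice_index))
      }
    }
  }
  if (is.null(best$projection) || is.null(best$association)) {
    abort(sprintf(
      "no candidate window: no 2x2 region on slice %d passes the FA >= %g gate.",
      slice_index, fa_threshold
    ))
  }
  best
}
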