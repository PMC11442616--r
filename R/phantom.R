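#' Digital DWI phantom specification
#'
#' The phantom emulates the periventricular geometry at the level of the
#' lateral-ventricle body: a projection-fiber compartment whose dominant
#' axons run feet-head (z), an association-fiber compartment with axons
#' running anterior-posterior (y), a CSF-filled ventricle, an isotropic
#' tumor, and low-diffusivity background. Perivascular water appears as
#' elevated right-left (x) diffusivity in the two fiber compartments —
#' exactly the contrast the ALPS index measures.
#'
#' Region boxes use 0-based voxel starts and half-open extents
#' `[start, start + size)`, and must be disjoint and inside the grid.
#' Compartment tensors are symmetric with non-negative eigenvalues, given
#' as length-6 vectors `(xx, yy, zz, xy, xz, yz)` in mm^2/s.
#'
#' @param grid_shape integer 3-vector, voxels
#' @param voxel_size mm, length 3
#' @param regions named list of `list(start = , size = )` boxes; names from
#'   projection_area, association_area, ventricle_CSF, tumor
#' @param tensors named list of length-6 compartment tensors (same names as
#'   `regions`, plus `background`)
#' @param s0 baseline b = 0 signal (arbitrary units)
#' @param noise_sigma Gaussian channel standard deviation (same units)
#' @param seed integer seed for the noise stream
#' @return a `phantom_spec`
#' @export
phantom_spec <- function(grid_shape, voxel_size, regions, tensors,
                         s0 = 1000, noise_sigma = 0, seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape > 0))
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  if (!"background" %in% names(tensors)) {
    abort("`tensors` must include a 'background' compartment.")
  }
  for (nm in names(regions)) {
    box <- regions[[nm]]
    if (is.null(tensors[[nm]])) {
      abort(sprintf("no compartment tensor for region '%s'.", nm))
    }
    if (any(box$start < 0) || any(box$start + box$size > grid_shape)) {
      abort(sprintf("region '%s' lies outside the grid.", nm))
    }
  }
  for (nm in names(tensors)) {
    ev <- eigen(tensor6_to_mat(tensors[[nm]]), symmetric = TRUE,
                only.values = TRUE)$values
    if (any(ev < -1e-15)) {
      abort(sprintf("compartment tensor '%s' has a negative eigenvalue.", nm))
    }
  }
  structure(
    list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
         regions = regions, tensors = tensors, s0 = s0,
         noise_sigma = noise_sigma, seed = seed),
    class = "phantom_spec"
  )
}

#' Default periventricular phantom
#'
#' A 20 x 20 x 5 grid of 2 mm isotropic voxels with a central CSF
#' "ventricle", flanking projection- and association-fiber boxes, an
#' isotropic tumor and background. Three variants set the compartment
#' diffusivities:
#'
#' * `"contralateral"` — designed ALPS index 1.40 (healthy-like hemisphere)
#' * `"ipsilateral"` — designed ALPS index 1.25 (tumor-side-like, reduced
#'   perivascular x-diffusivity)
#' * `"isotropic"` — all fiber compartments isotropic, designed index 1
#'
#' The two fiber designs keep principal diffusivity ~1.7e-3 mm^2/s along
#' the fiber axis, ~0.75-0.85e-3 across it, and elevate the x (perivascular)
#' diffusivity to ~1.0-1.15e-3, typical deep-white-matter values; CSF is
#' 3.0e-3 isotropic, tumor 1.6e-3 isotropic, background 0.8e-3 isotropic.
#'
#' @param variant compartment set, see Details
#' @param s0,noise_sigma,seed passed to [phantom_spec()]
#' @return a `phantom_spec`
#' @export
default_phantom_spec <- function(variant = c("contralateral", "ipsilateral",
                                             "isotropic"),
                                 s0 = 1000, noise_sigma = 0, seed = NULL) {
  variant <- match.arg(variant)
  dtens <- function(xx, yy, zz) c(xx, yy, zz, 0, 0, 0) * 1e-3
  tensors <- switch(variant,
    contralateral = list(
      projection_area  = dtens(1.10, 0.75, 1.70),
      association_area = dtens(1.14, 1.70, 0.85)
    ),
    ipsilateral = list(
      projection_area  = dtens(1.00, 0.78, 1.70),
      association_area = dtens(1.00, 1.70, 0.82)
    ),
    isotropic = list(
      projection_area  = dtens(0.80, 0.80, 0.80),
      association_area = dtens(0.80, 0.80, 0.80)
    )
  )
  tensors$ventricle_CSF <- dtens(3.0, 3.0, 3.0)
  tensors$tumor <- dtens(1.6, 1.6, 1.6)
  tensors$background <- dtens(0.8, 0.8, 0.8)
  phantom_spec(
    grid_shape = c(20L, 20L, 5L), voxel_size = c(2, 2, 2),
    regions = list(
      ventricle_CSF    = list(start = c(8L, 8L, 0L),  size = c(4L, 4L, 5L)),
      projection_area  = list(start = c(3L, 6L, 1L),  size = c(4L, 6L, 3L)),
      association_area = list(start = c(13L, 6L, 1L), size = c(4L, 6L, 3L)),
      tumor            = list(start = c(14L, 14L, 1L), size = c(4L, 4L, 3L))
    ),
    tensors = tensors, s0 = s0, noise_sigma = noise_sigma, seed = seed
  )
}

#' 2x2x1 ALPS ROIs inside the default phantom's fiber boxes
#' @return list of two [roi_spec()]s (`projection`, `association`)
#' @export
default_phantom_rois <- function() {
  list(
    projection  = roi_spec("projection",  c(4L, 8L, 2L)),
    association = roi_spec("association", c(14L, 8L, 2L))
  )
}

#' Materialize ground-truth tensors for a phantom
#'
#' Paints every voxel with its compartment tensor and evaluates the
#' designed ALPS index implied by the projection/association compartments:
#' `mean(Dxx_proj, Dxx_assoc) / mean(Dyy_proj, Dzz_assoc)`.
#'
#' @param spec a [phantom_spec()]
#' @return a `phantom_truth`: list with `tensors` (x, y, z, 6 array),
#'   `labels` (3D character array), `designed_alps`, and the `spec`
#' @export
build_phantom_tensors <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape
  labels <- array("background", gs)
  tensors <- array(0, c(gs, 6L))
  flat <- matrix(tensors, prod(gs), 6)
  flat[] <- matrix(spec$tensors$background, prod(gs), 6, byrow = TRUE)
  for (nm in names(spec$regions)) {
    box <- spec$regions[[nm]]
    ix <- (box$start[1] + 1):(box$start[1] + box$size[1])
    iy <- (box$start[2] + 1):(box$start[2] + box$size[2])
    iz <- (box$start[3] + 1):(box$start[3] + box$size[3])
    sub <- labels[ix, iy, iz]
    if (any(sub != "background")) {
      abort(sprintf("overlapping region labels: '%s' intersects '%s'.",
                    nm, setdiff(unique(c(sub)), "background")[1]))
    }
    labels[ix, iy, iz] <- nm
    lin <- which(labels == nm)
    flat[lin, ] <- matrix(spec$tensors[[nm]], length(lin), 6, byrow = TRUE)
  }
  tensors <- array(flat, c(gs, 6L))
  p <- spec$tensors$projection_area
  a <- spec$tensors$association_area
  designed <- if (is.null(p) || is.null(a)) NA_real_
              else mean(c(p[1], a[1])) / mean(c(p[2], a[3]))
  structure(
    list(tensors = tensors, labels = labels, designed_alps = designed,
         spec = spec),
    class = "phantom_truth"
  )
}

#' Simulate the DWI signal of a phantom
#'
#' Mono-exponential single-tensor model per voxel,
#' `S = s0 * exp(-b g' D g)`, with optional Rician corruption
#' `|S + n1 + i n2|`, `n1, n2 ~ N(0, noise_sigma^2)` — the magnitude-MRI
#' noise model. The noise stream is fully determined by `seed`.
#'
#' @param truth a `phantom_truth` from [build_phantom_tensors()]
#' @param gradients a `gradient_table` (default: the packaged 64-direction
#'   scheme)
#' @param s0,noise_sigma,seed override the spec's values
#' @return a `dwi_volume`
#' @export
simulate_signal <- function(truth, gradients = default_gradient_table(),
                            s0 = NULL, noise_sigma = NULL, seed = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  spec <- truth$spec
  s0 <- s0 %||% spec$s0
  noise_sigma <- noise_sigma %||% spec$noise_sigma
  seed <- seed %||% spec$seed
  if (noise_sigma < 0) abort("`noise_sigma` must be >= 0.")
  if (noise_sigma > 0 && is.null(seed)) {
    abort("a `seed` is required when noise_sigma > 0.")
  }
  gs <- spec$grid_shape
  nvox <- prod(gs)
  V <- matrix(truth$tensors, nvox, 6)             # voxels x elements
  Q <- gradients$bval * quad_form_matrix(gradients)  # meas x elements
  S <- s0 * exp(-tcrossprod(V, Q))                # voxels x measurements
  if (noise_sigma > 0) {
    S <- withr::with_seed(seed, {
      n1 <- matrix(rnorm(length(S), 0, noise_sigma), nrow(S))
      n2 <- matrix(rnorm(length(S), 0, noise_sigma), nrow(S))
      sqrt((S + n1)^2 + n2^2)
    })
  }
  dwi_volume(array(S, c(gs, nrow(gradients))), spec$voxel_size, gradients)
}

#' Write a phantom to disk (NIfTI + bval/bvec + JSON truth file)
#'
#' @param truth a `phantom_truth`
#' @param dir destination directory (created if needed)
#' @param gradients,s0,noise_sigma,seed passed to [simulate_signal()]
#' @return the directory, invisibly
#' @export
write_phantom <- function(truth, dir, gradients = default_gradient_table(),
                          s0 = NULL, noise_sigma = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vol <- simulate_signal(truth, gradients, s0 = s0,
                         noise_sigma = noise_sigma, seed = seed)
  write_dwi(vol, file.path(dir, "phantom.nii.gz"))
  write_gradient_table(gradients, file.path(dir, "phantom.bval"),
                       file.path(dir, "phantom.bvec"))
  jsonlite::write_json(
    list(
      designed_alps = truth$designed_alps,
      compartment_tensors = truth$spec$tensors,
      grid_shape = truth$spec$grid_shape,
      voxel_size = truth$spec$voxel_size,
      s0 = s0 %||% truth$spec$s0,
      noise_sigma = noise_sigma %||% truth$spec$noise_sigma,
      seed = seed %||% truth$spec$seed
    ),
    file.path(dir, "phantom_truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(dir)
}
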