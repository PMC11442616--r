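#' Log-linear diffusion tensor fit
#'
#' Per masked voxel, solves the linearized mono-exponential model
#' `ln S_i = ln S0 - b_i g_i' D g_i` for `(ln S0, Dxx, Dyy, Dzz, Dxy, Dxz,
#' Dyz)` by ordinary (unweighted) least squares — deterministic and exact
#' on noiseless data. No positivity constraint is imposed on the fitted
#' tensor: the ALPS index uses the raw diagonal elements, and constraining
#' them would silently alter the statistic. Signals at or below zero are
#' clamped to `1e-6 * max(S)` before the log.
#'
#' @param dwi a [dwi_volume()]
#' @param gradients a `gradient_table`; must pass the rank-6 design check
#' @param mask optional 3D logical array of voxels to fit (default: all)
#' @return a `dti_fit`: list with `tensors` (x, y, z, 6 array ordered
#'   xx, yy, zz, xy, xz, yz; mm^2/s), `s0` (3D), `mask`, `voxel_size`
#' @export
fit_dti <- function(dwi, gradients, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"), inherits(gradients, "gradient_table"))
  d <- dim(dwi$data)
  if (d[4] != nrow(gradients)) {
    abort(sprintf("count mismatch: %d volumes vs %d gradient entries.",
                  d[4], nrow(gradients)))
  }
  gs <- d[1:3]
  if (is.null(mask)) mask <- array(TRUE, gs)
  if (!identical(dim(mask), as.integer(gs)) && !identical(dim(mask), gs)) {
    abort("mask dimensions do not match the volume grid.")
  }
  if (!any(mask)) abort("empty mask: no voxels to fit.")
  X <- dti_design_matrix(gradients)
  if (qr(X)$rank < 7) abort("rank-deficient design matrix.")
  S <- matrix(dwi$data, prod(gs), d[4])[which(mask), , drop = FALSE]
  floor_val <- 1e-6 * max(S)
  S[S < floor_val] <- floor_val
  beta <- solve(crossprod(X), crossprod(X, t(log(S))))  # 7 x nmasked
  tensors <- array(NA_real_, c(gs, 6L))
  flat <- matrix(tensors, prod(gs), 6)
  flat[which(mask), ] <- t(beta[-1, , drop = FALSE])
  s0 <- array(NA_real_, gs)
  s0[which(mask)] <- exp(beta[1, ])
  structure(
    list(tensors = array(flat, c(gs, 6L)), s0 = s0, mask = mask,
         voxel_size = dwi$voxel_size),
    class = "dti_fit"
  )
}

#' @export
print.dti_fit <- function(x, ...) {
  cat(sprintf("<dti_fit> %s voxels, %d fitted\n",
              paste(dim(x$s0), collapse = " x "), sum(x$mask)))
  invisible(x)
}

# pull one element map (xx, yy, zz, xy, xz, yz) from a fit
tensor_element <- function(fit, element) {
  i <- match(element, TENSOR_ELEMENTS)
  if (is.na(i)) abort(sprintf("unknown tensor element '%s'.", element))
  gs <- dim(fit$s0)
  array(fit$tensors[, , , i], gs)
}

#' Fractional anisotropy map
#'
#' `FA = sqrt(3/2) * sqrt(sum((lambda_i - mean)^2)) / sqrt(sum(lambda_i^2))`
#' computed from tensor invariants (equivalent to the eigenvalue form),
#' clipped to \[0, 1\]; voxels with non-positive trace or degenerate norm
#' map to 0.
#'
#' @param fit a `dti_fit`
#' @return a `scalar_map` of kind FA
#' @export
fa_map <- function(fit) {
  stopifnot(inherits(fit, "dti_fit"))
  gs <- dim(fit$s0)
  V <- matrix(fit$tensors, prod(gs), 6)
  md <- rowMeans(V[, 1:3, drop = FALSE])
  off2 <- 2 * rowSums(V[, 4:6, drop = FALSE]^2)
  num <- rowSums((V[, 1:3, drop = FALSE] - md)^2) + off2
  den <- rowSums(V[, 1:3, drop = FALSE]^2) + off2
  fa <- sqrt(1.5 * num / den)
  fa[!is.finite(fa) | den <= 0 | 3 * md <= 0] <- 0
  fa <- pmin(pmax(fa, 0), 1)
  scalar_map(array(fa, gs), fit$voxel_size, kind = "FA")
}

#' Mean diffusivity from a fitted tensor field
#' @param fit a `dti_fit`
#' @return a `scalar_map` of kind MD, mm^2/s
#' @export
md_map <- function(fit) {
  gs <- dim(fit$s0)
  V <- matrix(fit$tensors, prod(gs), 6)
  scalar_map(array(rowMeans(V[, 1:3, drop = FALSE]), gs), fit$voxel_size,
             kind = "MD")
}

#' @rdname md_map
#' @export
s0_map <- function(fit) {
  scalar_map(fit$s0, fit$voxel_size, kind = "S0")
}

#' Trace-image ADC map
#'
#' The trace image is the geometric mean of all b > 0 measurements per
#' voxel; the ADC is `ln(S_b0 / S_trace) / b`. With the geometric mean,
#' this equals the mean diffusivity of the mono-exponential tensor model
#' exactly on noiseless data. Non-positive signals are clamped as in
#' [fit_dti()].
#'
#' @param dwi a [dwi_volume()]
#' @param gradients a `gradient_table` with one positive shell
#' @return a `scalar_map` of kind ADC (mm^2/s); multiply by 1e6 for the
#'   1e-6 mm^2/s convention of the cohort tables
#' @export
trace_adc_map <- function(dwi, gradients) {
  stopifnot(inherits(dwi, "dwi_volume"), inherits(gradients, "gradient_table"))
  d <- dim(dwi$data)
  if (d[4] != nrow(gradients)) {
    abort(sprintf("count mismatch: %d volumes vs %d gradient entries.",
                  d[4], nrow(gradients)))
  }
  b0 <- which(gradients$bval == 0)
  b1 <- which(gradients$bval > 0)
  if (length(b0) == 0) abort("missing b = 0 volume.")
  if (length(b1) == 0) abort("missing diffusion-weighted (b > 0) volumes.")
  b <- mean(gradients$bval[b1])
  S <- matrix(dwi$data, prod(d[1:3]), d[4])
  floor_val <- 1e-6 * max(S)
  S[S < floor_val] <- floor_val
  s_b0 <- rowMeans(S[, b0, drop = FALSE])
  s_trace <- exp(rowMeans(log(S[, b1, drop = FALSE])))
  adc <- log(s_b0 / s_trace) / b
  scalar_map(array(adc, d[1:3]), dwi$voxel_size, kind = "ADC")
}
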