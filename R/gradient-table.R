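#' Diffusion gradient tables
#'
#' A gradient table pairs each DWI measurement with its b-value (s/mm^2) and
#' unit diffusion-encoding direction (direction cosines in the image frame:
#' x = right-left, y = anterior-posterior, z = feet-head). Directions are
#' never reoriented by an affine; the phantom generator and the tensor
#' fitter share this one fixed frame.
#'
#' A table is fit-capable only if it holds at least one b = 0 measurement
#' and at least six b > 0 directions whose quadratic forms span the space of
#' symmetric tensors (rank-6 design, which excludes collinear sets).
#'
#' @param bvals numeric vector of b-values (s/mm^2), non-negative
#' @param bvecs n x 3 numeric matrix of direction cosines; rows with
#'   bval > 0 must have Euclidean norm within `tol` of 1, rows with
#'   bval == 0 may be zero
#' @param tol unit-norm tolerance (default 1e-3)
#' @return a `gradient_table`: tibble with columns `bval, gx, gy, gz`
#' @export
#' @examples
#' dirs <- rbind(diag(3), cbind(diag(3)[-3, ] + diag(3)[-1, ]) / sqrt(2))
#' gt <- gradient_table(c(0, rep(1000, 6)), rbind(c(0, 0, 0), dirs))
gradient_table <- function(bvals, bvecs, tol = 1e-3) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3 && nrow(bvecs) == 3) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3) {
    abort("`bvecs` must be an n x 3 matrix of direction cosines.")
  }
  if (length(bvals) != nrow(bvecs)) {
    abort(sprintf(
      "count mismatch: %d b-values but %d directions.",
      length(bvals), nrow(bvecs)
    ))
  }
  if (anyNA(bvals) || anyNA(bvecs)) abort("non-numeric token in gradient table.")
  if (any(bvals < 0)) abort("b-values must be non-negative.")
  norms <- sqrt(rowSums(bvecs^2))
  bad <- bvals > 0 & abs(norms - 1) > tol
  if (any(bad)) {
    abort(sprintf(
      "norm violation: %d direction(s) with b > 0 deviate from unit norm by more than %g (max deviation %.3g).",
      sum(bad), tol, max(abs(norms - 1)[bvals > 0])
    ))
  }
  gt <- tibble(
    bval = bvals,
    gx = bvecs[, 1], gy = bvecs[, 2], gz = bvecs[, 3]
  )
  class(gt) <- c("gradient_table", class(gt))
  validate_gradient_table(gt)
  gt
}

validate_gradient_table <- function(gt) {
  if (!any(gt$bval == 0)) {
    abort("gradient table needs at least one b = 0 measurement.")
  }
  dwi <- gt[gt$bval > 0, ]
  if (nrow(dwi) < 6 || qr(quad_form_matrix(dwi))$rank < 6) {
    abort(paste0(
      "rank-deficient gradient scheme: need >= 6 non-collinear b > 0 ",
      "directions spanning the symmetric-tensor space."
    ))
  }
  invisible(gt)
}

# rows of g_i' D g_i as linear functionals of (xx, yy, zz, xy, xz, yz)
quad_form_matrix <- function(gt) {
  cbind(
    gt$gx^2, gt$gy^2, gt$gz^2,
    2 * gt$gx * gt$gy, 2 * gt$gx * gt$gz, 2 * gt$gy * gt$gz
  )
}

# full log-linear design: columns (ln S0, xx, yy, zz, xy, xz, yz)
dti_design_matrix <- function(gt) {
  cbind(1, -gt$bval * quad_form_matrix(gt))
}

#' Read an FSL-dialect bval/bvec pair
#'
#' The bval file is one whitespace-separated row of N b-values; the bvec
#' file is three rows of N direction cosines (x, y, z). Directions already
#' within tolerance of unit norm are kept verbatim, not re-normalized.
#'
#' @param bval_file,bvec_file paths (or connections) to the two text files
#' @param tol unit-norm tolerance passed to [gradient_table()]
#' @return a `gradient_table`
#' @export
read_gradient_table <- function(bval_file, bvec_file, tol = 1e-3) {
  bvals <- scan_numeric_rows(bval_file, "bval")
  if (length(bvals) != 1) abort("bval source must be a single row of numbers.")
  bvecs <- scan_numeric_rows(bvec_file, "bvec")
  if (length(bvecs) != 3) abort("bvec source must have exactly three rows.")
  n <- lengths(c(bvals, bvecs))
  if (length(unique(n)) != 1) {
    abort(sprintf(
      "count mismatch between bval and bvec columns: %s.",
      paste(n, collapse = " vs ")
    ))
  }
  gradient_table(bvals[[1]], do.call(rbind, bvecs), tol = tol)
}

scan_numeric_rows <- function(file, what) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    toks <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      abort(sprintf("non-numeric token in %s source, row %d.", what, i))
    }
    vals
  })
}

#' Write a gradient table as FSL bval/bvec text files
#'
#' @param gt a `gradient_table`
#' @param bval_file,bvec_file destination paths
#' @return `gt`, invisibly
#' @export
write_gradient_table <- function(gt, bval_file, bvec_file) {
  stopifnot(inherits(gt, "gradient_table"))
  writeLines(paste(format(gt$bval, trim = TRUE, scientific = FALSE),
                   collapse = " "), bval_file)
  writeLines(
    vapply(
      list(gt$gx, gt$gy, gt$gz),
      function(v) paste(sprintf("%.10g", v), collapse = " "),
      character(1)
    ),
    bvec_file
  )
  invisible(gt)
}

#' Default 64-direction acquisition scheme
#'
#' One b = 0 measurement plus 64 directions at b = 1000 s/mm^2, laid out by
#' a deterministic electrostatic-repulsion optimization (antipodally
#' symmetric energy) and shipped as a text fixture. This emulates a
#' two-shell (b = 0/1000) clinical tumor-protocol DTI acquisition.
#'
#' @return a `gradient_table` with 65 rows
#' @export
default_gradient_table <- function() {
  read_gradient_table(
    system.file("extdata", "scheme64.bval", package = "alpsdti", mustWork = TRUE),
    system.file("extdata", "scheme64.bvec", package = "alpsdti", mustWork = TRUE)
  )
}
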