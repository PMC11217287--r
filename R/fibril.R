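#' @include AllClasses.R AllGenerics.R
NULL

#' Nematic-tensor quantification of fibril orientation
#'
#' The image-gradient nematic tensor computation for quantifying the mean
#' orientation and degree of organization of a fibrillar texture (the
#' FibrilTool algorithm family): the image is Gaussian-smoothed
#' (\code{sigma} px), per-pixel intensity gradients are taken by central
#' differences with Scharr cross-smoothing (which minimizes the orientation
#' anisotropy of discrete gradients), the local fibril axis is the gradient
#' rotated by 90°, and
#' the nematic tensor is the weighted mean over the ROI of
#' \eqn{u u^T - I/2} with weight the squared gradient norm (unit weights
#' behind \code{weighting = "unit"} for sensitivity analysis). The mean
#' orientation is the angle of the principal eigenvector (degrees in
#' [0, 180), measured from the image x axis); the organization score is the
#' eigenvalue difference of the weight-normalized tensor, in [0, 1].
#'
#' A constant ROI yields score 0 with the orientation flagged undefined
#' (NA). Scores are projection- and preprocessing-dependent, so the
#' smoothing and weighting settings are recorded in the output row.
#'
#' @param image a \linkS4class{FibrilImage} or a numeric matrix
#' @param roiMask optional logical matrix selecting the ROI (default: all)
#' @param sigma Gaussian pre-smoothing in px (0 disables)
#' @param weighting "gradient" (squared gradient norm) or "unit"
#' @param roiId identifier copied to the output row
#' @return one-row data.frame: roi_id, orientation_deg, score, n_pixels,
#'   sigma, weighting, undefined_orientation
#' @export
fibrilTensor <- function(image, roiMask = NULL, sigma = 1,
                         weighting = c("gradient", "unit"), roiId = 1L) {
  weighting <- match.arg(weighting)
  img <- if (is(image, "FibrilImage")) image@pixels else as.matrix(image)
  if (is.null(roiMask)) roiMask <- matrix(TRUE, nrow(img), ncol(img))
  stopifnot(identical(dim(roiMask), dim(img)))
  nPix <- sum(roiMask)
  if (nPix < 64L) stop("precondition error: ROI smaller than 64 pixels")
  if (sigma > 0) img <- EBImage::gblur(img, sigma = sigma)
  nx <- nrow(img); ny <- ncol(img)
  ## Scharr stencil: a central difference with the cross-smoothing weights
  ## that minimize orientation anisotropy of the gradient direction
  Dx <- matrix(c(-3, -10, -3, 0, 0, 0, 3, 10, 3), 3L, 3L, byrow = TRUE) / 32
  gx <- as.matrix(EBImage::filter2(img, Dx))
  gy <- as.matrix(EBImage::filter2(img, t(Dx)))
  inner <- matrix(FALSE, nx, ny)
  inner[3:(nx - 2), 3:(ny - 2)] <- TRUE
  sel <- roiMask & inner
  gxs <- gx[sel]; gys <- gy[sel]
  g2 <- gxs^2 + gys^2
  ok <- g2 > 0
  if (!any(ok))
    return(data.frame(roi_id = roiId, orientation_deg = NA_real_, score = 0,
                      n_pixels = nPix, sigma = sigma, weighting = weighting,
                      undefined_orientation = TRUE))
  ## fibril axis u = gradient rotated 90 deg: u = (-gy, gx)/|g|
  w <- if (weighting == "gradient") g2[ok] else rep(1, sum(ok))
  uxux <- gys[ok]^2 / g2[ok]
  uyuy <- gxs[ok]^2 / g2[ok]
  uxuy <- -gxs[ok] * gys[ok] / g2[ok]
  wsum <- sum(w)
  qxx <- sum(w * uxux) / wsum - 0.5
  qyy <- sum(w * uyuy) / wsum - 0.5
  qxy <- sum(w * uxuy) / wsum
  orientation <- (0.5 * atan2(2 * qxy, qxx - qyy) * 180 / pi) %% 180
  score <- min(1, 2 * sqrt(((qxx - qyy) / 2)^2 + qxy^2))
  data.frame(roi_id = roiId, orientation_deg = orientation, score = score,
             n_pixels = nPix, sigma = sigma, weighting = weighting,
             undefined_orientation = FALSE)
}

#' Per-cell fibril measurements from a label mask
#'
#' Runs \code{\link{fibrilTensor}} on every labelled region of a mask (one
#' measurement per cell), optionally reporting each orientation relative to
#' a supplied organ-axis angle (the axial difference in [0, 90], so fibrils
#' perpendicular to the organ axis report 90° — the "hoops around a barrel"
#' configuration).
#'
#' @param image a \linkS4class{FibrilImage} or numeric matrix
#' @param labelMask integer matrix; positive labels, background 0
#' @param organAxisDeg optional organ axis angle in degrees
#' @param ... passed to \code{\link{fibrilTensor}}
#' @return data.frame with one row per label; empty labels get
#'   \code{n_pixels = 0} and flags
#' @export
roiBatchMeasure <- function(image, labelMask, organAxisDeg = NULL, ...) {
  img <- if (is(image, "FibrilImage")) image@pixels else as.matrix(image)
  stopifnot(identical(dim(labelMask), dim(img)))
  labs <- seq_len(max(0L, max(labelMask)))
  rows <- lapply(labs, function(lb) {
    m <- labelMask == lb
    if (sum(m) < 64L)
      data.frame(roi_id = lb, orientation_deg = NA_real_, score = NA_real_,
                 n_pixels = sum(m), sigma = NA_real_, weighting = NA_character_,
                 undefined_orientation = TRUE)
    else fibrilTensor(img, roiMask = m, roiId = lb, ...)
  })
  out <- do.call(rbind, rows)
  if (!is.null(organAxisDeg))
    out$relative_orientation_deg <- axialDiffDeg(out$orientation_deg,
                                                 organAxisDeg)
  out
}

#' @rdname accessors
#' @export
setMethod("pixelValues", "FibrilImage", function(x) x@pixels)

setMethod("show", "FibrilImage", function(object) {
  cat(sprintf("FibrilImage: %d x %d px (%.3g um/px)", nrow(object@pixels),
              ncol(object@pixels), object@pixelSize))
  if (!is.na(object@trueOrientation))
    cat(sprintf(", ground truth %.1f deg at anisotropy %.2f",
                object@trueOrientation, object@trueAnisotropy))
  cat("\n")
})
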