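#' @include tessellation.R
NULL

#' Huang minimum-fuzziness threshold
#'
#' Gray-level threshold minimizing the Shannon fuzziness measure of the
#' two-class membership function (Huang & Wang), computed on a 256-bin
#' histogram. The segmentation entry point of seed silhouette images.
#'
#' @param img numeric matrix of intensities
#' @return threshold on the intensity scale of \code{img}
#' @export
huangThreshold <- function(img) {
  x <- as.numeric(img)
  lo <- min(x); hi <- max(x)
  if (hi == lo) stop("image is constant; no threshold exists")
  nb <- 256L
  bin <- pmin(nb, floor((x - lo) / (hi - lo) * nb) + 1L)
  h <- tabulate(bin, nb)
  mids <- lo + (seq_len(nb) - 0.5) * (hi - lo) / nb
  W0 <- cumsum(h); S0 <- cumsum(h * mids)
  Wt <- W0[nb]; St <- S0[nb]
  C <- hi - lo
  best <- Inf; bestT <- 1L
  for (t in seq_len(nb - 1L)) {
    if (W0[t] == 0L || W0[t] == Wt) next
    mu0 <- S0[t] / W0[t]
    mu1 <- (St - S0[t]) / (Wt - W0[t])
    mu <- c(rep(mu0, t), rep(mu1, nb - t))
    u <- 1 / (1 + abs(mids - mu) / C)        # membership in [0.5, 1]
    Hf <- -u * log(u) - (1 - u) * log(1 - u)
    Hf[!is.finite(Hf)] <- 0
    S <- sum(h * Hf)
    if (S < best) { best <- S; bestT <- t }
  }
  lo + bestT * (hi - lo) / nb
}

#' Segment seed silhouettes
#'
#' Binarizes an image with the Huang minimum-fuzziness threshold and
#' separates touching seeds with a distance-transform watershed: the binary
#' mask's distance map is flooded from its maxima, so tangent objects split
#' at their waist. Objects below \code{minArea} px² are discarded; objects
#' with solidity below \code{minSolidity} (incorrect segmentations were
#' removed manually in interactive practice) are kept but flagged.
#'
#' @param image numeric intensity matrix
#' @param minArea minimum object area in px² (default 100)
#' @param tolerance watershed merging tolerance on the distance map
#' @param minSolidity solidity flagging cutoff
#' @param minSeparation minimum between-class mean separation, in units of
#'   the pooled within-class SD; below it the image is treated as having no
#'   foreground (background noise alone would otherwise be thresholded into
#'   speckle)
#' @return integer label matrix (0 = background) with attributes
#'   \code{flagged} (label ids with low solidity) and \code{noForeground}
#' @export
segmentSeeds <- function(image, minArea = 100, tolerance = 1,
                         minSolidity = 0.8, minSeparation = 3) {
  img <- as.matrix(image)
  if (max(img) == min(img)) stop("image is constant; nothing to segment")
  thr <- huangThreshold(img)
  binary <- img > thr
  separated <- any(binary) && any(!binary) &&
    (mean(img[binary]) - mean(img[!binary])) >
      minSeparation * (stats::sd(img[binary]) + stats::sd(img[!binary])) / 2
  if (!separated) {
    out <- matrix(0L, nrow(img), ncol(img))
    attr(out, "noForeground") <- TRUE
    attr(out, "flagged") <- integer(0)
    warning("no foreground after thresholding")
    return(out)
  }
  dm <- EBImage::distmap(EBImage::Image(binary * 1))
  lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = tolerance))
  ## drop small objects, then relabel 1..n
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minArea)
  lab[!(lab %in% keep)] <- 0L
  lab <- matrix(match(lab, c(0L, keep)) - 1L, nrow(img), ncol(img))
  flagged <- integer(0)
  for (k in seq_len(max(lab))) {
    sol <- objectSolidity(lab == k)
    if (!is.na(sol) && sol < minSolidity) flagged <- c(flagged, k)
  }
  storage.mode(lab) <- "integer"
  attr(lab, "noForeground") <- FALSE
  attr(lab, "flagged") <- flagged
  attr(lab, "threshold") <- thr
  lab
}

## area / convex-hull-area of a binary object
objectSolidity <- function(mask) {
  pix <- which(mask, arr.ind = TRUE)
  if (nrow(pix) < 3L) return(NA_real_)
  hull <- grDevices::chull(pix)
  hp <- pix[hull, , drop = FALSE]
  n <- nrow(hp)
  hullArea <- abs(sum(hp[, 1L] * hp[c(2:n, 1L), 2L] -
                        hp[c(2:n, 1L), 1L] * hp[, 2L])) / 2
  if (hullArea == 0) return(NA_real_)
  nrow(pix) / hullArea
}

#' Measure the shape of a segmented seed
#'
#' Shape descriptors of a single connected object. Mode \code{"ellipse"}
#' (mature-seed convention) takes L and W as the major and minor axes of
#' the second-moment-matched ellipse ("Fit Ellipse"); mode \code{"axes"}
#' (developing-seed convention) takes L as the longest chord along the
#' principal axis through the centroid and W as the perpendicular extent
#' through its midpoint — the automated proxy for the manually drawn
#' pedicel-to-tip line. The aspect ratio is L/W.
#'
#' @param mask logical or 0/1 or single-label matrix
#' @param mode "ellipse" or "axes"
#' @return data.frame with area, length, width, aspect_ratio, mode
#' @export
measureSeed <- function(mask, mode = c("ellipse", "axes")) {
  mode <- match.arg(mode)
  m <- as.matrix(mask) > 0
  ncomp <- max(EBImage::bwlabel(EBImage::Image(m * 1)))
  if (ncomp != 1L)
    stop("ambiguity error: mask must contain exactly one connected object")
  pix <- which(m, arr.ind = TRUE)
  area <- nrow(pix)
  ctr <- colMeans(pix)
  cov <- crossprod(sweep(pix, 2L, ctr)) / area
  eg <- eigen(cov, symmetric = TRUE)
  if (mode == "ellipse") {
    L <- 4 * sqrt(eg$values[1L])     # full axes of the moment-matched ellipse
    W <- 4 * sqrt(eg$values[2L])
  } else {
    ax <- eg$vectors[, 1L]
    perp <- eg$vectors[, 2L]
    s <- sweep(pix, 2L, ctr) %*% ax
    q <- sweep(pix, 2L, ctr) %*% perp
    onAxis <- abs(q) <= 0.75          # pixels within the central chord band
    L <- diff(range(s[onAxis])) + 1
    mid <- (max(s[onAxis]) + min(s[onAxis])) / 2
    onPerp <- abs(s - mid) <= 0.75
    W <- diff(range(q[onPerp])) + 1
  }
  data.frame(area = area, length = L, width = W, aspect_ratio = L / W,
             mode = mode)
}

#' Per-cell growth map from matched tessellations
#'
#' Quantifies cell growth between two timepoints of a tessellation with
#' shared mesh topology (e.g. a pair from
#' \code{\link{makePairedTessellation}}). Per parent cell: areal growth is
#' the summed offspring area over the parent area minus 1; growth
#' anisotropy and the main growth axis come from the best-fit linear map
#' between the cell's boundary points at the two timepoints after
#' projecting both to the cell's tangent plane (singular values
#' \eqn{\lambda_1 \ge \lambda_2}; anisotropy \eqn{\lambda_1/\lambda_2},
#' isotropic = 1; the main axis is the \eqn{\lambda_1} stretch direction,
#' reported as an axial angle in degrees from the in-plane x direction);
#' the division count comes from the lineage.
#'
#' @param t0,t1 \linkS4class{CellTessellation}s with identical face topology
#' @param lineage parent-to-offspring map; defaults to the lineage stored
#'   on \code{t1}
#' @return data.frame with cell_id, areal_growth, anisotropy,
#'   main_axis_deg, n_offspring, flagged
#' @export
cellGrowthMap <- function(t0, t1, lineage = NULL) {
  stopifnot(is(t0, "CellTessellation"), is(t1, "CellTessellation"))
  if (!identical(t0@mesh@faces, t1@mesh@faces))
    stop("tessellations must share mesh topology")
  lineage <- lineage %||% t1@lineage
  ids0 <- seq_len(nCells(t0))
  if (!all(as.character(ids0) %in% names(lineage)))
    stop("lineage error: some parent cells have no offspring entry")
  n0 <- cellNormals(t0)
  n1 <- cellNormals(t1)
  v0 <- t0@mesh@vertices; v1 <- t1@mesh@vertices
  f <- t0@mesh@faces
  rows <- lapply(ids0, function(ci) {
    off <- lineage[[as.character(ci)]]
    fset <- which(t0@faceCell == ci)
    vids <- unique(as.integer(f[fset, ]))
    areal <- sum(t1@areas[off]) / t0@areas[ci] - 1
    flagged <- t0@areas[ci] < 1e-9
    fr0 <- tangentFrame(n0[ci, ])
    nOff <- normalizeRows(matrix(colSums(matrix(n1[off, ], ncol = 3L)), 1L, 3L))
    fr1 <- tangentFrame(nOff[1L, ])
    p0 <- sweep(v0[vids, , drop = FALSE], 2L,
                colMeans(v0[vids, , drop = FALSE]))
    p1 <- sweep(v1[vids, , drop = FALSE], 2L,
                colMeans(v1[vids, , drop = FALSE]))
    Q0 <- cbind(p0 %*% fr0$e1, p0 %*% fr0$e2)
    Q1 <- cbind(p1 %*% fr1$e1, p1 %*% fr1$e2)
    M <- t(qr.coef(qr(Q0), Q1))          # best-fit 2x2 map Q0 -> Q1
    sv <- svd(M)
    anis <- sv$d[1L] / sv$d[2L]
    axis <- (atan2(sv$v[2L, 1L], sv$v[1L, 1L]) * 180 / pi) %% 180
    data.frame(cell_id = ci, areal_growth = areal, anisotropy = anis,
               main_axis_deg = axis, n_offspring = length(off),
               flagged = flagged)
  })
  do.call(rbind, rows)
}
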