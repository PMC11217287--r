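#' @include utils.R
NULL

#' Synthetic per-seed daily growth observations
#'
#' Scatters per-seed daily measurements of seed area and aspect ratio
#' lognormally about given daily means with a fixed coefficient of
#' variation (the lognormal is parameterized so the arithmetic mean equals
#' the input mean exactly). \code{cv = 0} reproduces the means exactly.
#' Ground truth for recovering growth-rate and growth-anisotropy series.
#'
#' @param dailyMeanArea per-day mean seed area (µm² or px²), length >= 2
#' @param dailyMeanAR per-day mean aspect ratio, same length
#' @param cv coefficient of variation across seeds, >= 0
#' @param nSeeds number of seeds per day, >= 1
#' @param rngSeed integer RNG seed
#' @return data.frame with columns seed, day, area, aspect_ratio
#' @export
makeGrowthObservations <- function(dailyMeanArea, dailyMeanAR, cv, nSeeds,
                                   rngSeed = 1L) {
  if (length(dailyMeanArea) != length(dailyMeanAR))
    stop("invalid spec: daily mean series differ in length")
  if (length(dailyMeanArea) < 2L) stop("invalid spec: need at least 2 days")
  if (cv < 0) stop("invalid spec: cv must be >= 0")
  if (nSeeds < 1L) stop("empty table: nSeeds must be >= 1")
  nd <- length(dailyMeanArea)
  sdlog <- sqrt(log(1 + cv^2))
  withSeed(rngSeed, {
    mult <- function(n) if (cv == 0) rep(1, n) else
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    data.frame(
      seed = rep(seq_len(nSeeds), times = nd),
      day = rep(seq_len(nd) - 1L, each = nSeeds),
      area = rep(dailyMeanArea, each = nSeeds) * mult(nd * nSeeds),
      aspect_ratio = rep(dailyMeanAR, each = nSeeds) * mult(nd * nSeeds))
  })
}

#' Daily summary of growth observations
#'
#' Per-day mean and SD of area and aspect ratio from a per-seed table, in
#' the layout \code{\link{growthDerivativeSeries}} consumes.
#'
#' @param obs data.frame with columns day, area, aspect_ratio
#' @return data.frame with day, mean_area, sd_area, mean_ar, sd_ar
#' @export
dailyGrowthSummary <- function(obs) {
  stopifnot(all(c("day", "area", "aspect_ratio") %in% names(obs)))
  days <- sort(unique(obs$day))
  do.call(rbind, lapply(days, function(d) {
    s <- obs[obs$day == d, ]
    data.frame(day = d, mean_area = mean(s$area), sd_area = stats::sd(s$area),
               mean_ar = mean(s$aspect_ratio), sd_ar = stats::sd(s$aspect_ratio))
  }))
}

#' Growth-rate and growth-anisotropy series from daily means
#'
#' Derives the organ-scale growth series from daily measurements of seed
#' size and aspect ratio:
#' \deqn{\mathrm{rate}_{n \to n+1} = (\mathrm{mean}_{n+1} -
#'   \mathrm{mean}_n)/\mathrm{mean}_n}
#' with the propagated standard deviation
#' \deqn{\mathrm{sd}_{n \to n+1} = \sqrt{(\mathrm{sd}_{n+1}/
#'   \mathrm{mean}_{n+1})^2 + (\mathrm{sd}_n/\mathrm{mean}_n)^2}.}
#' Applied to area this is the seed growth rate; applied to aspect ratio it
#' is the organ-scale growth anisotropy. Interval \code{n -> n+1} is
#' reported on row \code{n}; the last row carries NA.
#'
#' @param daily data.frame with columns day, mean_area, sd_area, mean_ar,
#'   sd_ar (see \code{\link{dailyGrowthSummary}})
#' @return the input with growth_rate, sd_growth_rate, growth_anisotropy,
#'   sd_growth_anisotropy columns appended
#' @export
growthDerivativeSeries <- function(daily) {
  need <- c("day", "mean_area", "sd_area", "mean_ar", "sd_ar")
  stopifnot(all(need %in% names(daily)))
  if (nrow(daily) < 2L) stop("need at least 2 days")
  if (any(daily$mean_area <= 0) || any(daily$mean_ar <= 0))
    stop("domain error: daily means must be positive")
  daily <- daily[order(daily$day), ]
  n <- nrow(daily)
  rate <- function(m) c((m[-1L] - m[-n]) / m[-n], NA_real_)
  propSD <- function(m, s) {
    cv <- s / m
    c(sqrt(cv[-1L]^2 + cv[-n]^2), NA_real_)
  }
  daily$growth_rate <- rate(daily$mean_area)
  daily$sd_growth_rate <- propSD(daily$mean_area, daily$sd_area)
  daily$growth_anisotropy <- rate(daily$mean_ar)
  daily$sd_growth_anisotropy <- propSD(daily$mean_ar, daily$sd_ar)
  daily
}

#' Per-cell dimension changes between paired observations
#'
#' Percent change in cell length, width and thickness between two matched
#' per-cell tables (e.g. before and after pricking the endosperm), with
#' per-seed summaries taken as the median across cells — robust to the
#' occasional segmentation outlier — rather than the mean.
#'
#' @param before,after data.frames with columns seed_id, cell_id, length,
#'   width, thickness; rows are matched on (seed_id, cell_id)
#' @return list with \code{perCell} (percent changes per cell) and
#'   \code{perSeed} (median percent change per seed)
#' @export
dimensionChangeStats <- function(before, after) {
  need <- c("seed_id", "cell_id", "length", "width", "thickness")
  stopifnot(all(need %in% names(before)), all(need %in% names(after)))
  keyB <- paste(before$seed_id, before$cell_id)
  keyA <- paste(after$seed_id, after$cell_id)
  shared <- intersect(keyB, keyA)
  if (length(shared) == 0L) stop("join error: no shared (seed_id, cell_id) pairs")
  missing <- c(setdiff(keyB, keyA), setdiff(keyA, keyB))
  if (length(missing))
    stop("join error: unmatched cell ids: ",
         paste(utils::head(missing, 10L), collapse = ", "))
  b <- before[match(shared, keyB), ]
  a <- after[match(shared, keyA), ]
  pct <- function(x0, x1) 100 * (x1 - x0) / x0
  perCell <- data.frame(
    seed_id = b$seed_id, cell_id = b$cell_id,
    length_change_pct = pct(b$length, a$length),
    width_change_pct = pct(b$width, a$width),
    thickness_change_pct = pct(b$thickness, a$thickness))
  perSeed <- do.call(rbind, lapply(split(perCell, perCell$seed_id), function(s)
    data.frame(seed_id = s$seed_id[1L], n_cells = nrow(s),
               median_length_change_pct = stats::median(s$length_change_pct),
               median_width_change_pct = stats::median(s$width_change_pct),
               median_thickness_change_pct =
                 stats::median(s$thickness_change_pct))))
  rownames(perSeed) <- NULL
  list(perCell = perCell, perSeed = perSeed)
}
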