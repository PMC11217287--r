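#' @include regions.R curvature.R cmt-field.R growth.R morphometry.R synth-images.R fibril.R angles.R
NULL

#' Run configuration
#'
#' Parameters of an end-to-end run: seed shape, mesh refinement, shell
#' material, tessellation size, curvature neighborhood, CMT sampling and a
#' mandatory root RNG seed. Per-stage seeds are derived deterministically
#' from the root seed and the stage name, so adding a stage never perturbs
#' the draws of earlier stages.
#'
#' @param spec an \linkS4class{EllipsoidSpec} (default, the 2DPA seed)
#' @param refinement icosahedral mesh refinement level
#' @param material a \linkS4class{ShellMaterial}
#' @param nCells tessellation size
#' @param curvatureRadius curvature neighborhood radius (µm; 30 at 2DPA)
#' @param cmtKappa,cmtOffsetDeg CMT sampling concentration and offset
#' @param configuration "inflated" (stress and curvature on the finite
#'   inflation equilibrium, the model-prediction mode) or "reference"
#'   (small-strain solve on the given shape)
#' @param rngSeed root RNG seed (mandatory)
#' @param outputDir directory for CSV outputs, manifest and log
#' @return a list of class "runConfig"
#' @export
runConfig <- function(spec = spec2DPA(), refinement = 4L,
                      material = shellMaterial(), nCells = 300L,
                      curvatureRadius = 30, cmtKappa = 20, cmtOffsetDeg = 0,
                      configuration = c("inflated", "reference"),
                      rngSeed, outputDir = tempfile("seedmech_run_")) {
  if (missing(rngSeed)) stop("rngSeed is mandatory")
  configuration <- match.arg(configuration)
  validObject(spec); validObject(material)
  structure(list(spec = spec, refinement = as.integer(refinement),
                 material = material, nCells = as.integer(nCells),
                 curvatureRadius = curvatureRadius, cmtKappa = cmtKappa,
                 cmtOffsetDeg = cmtOffsetDeg, configuration = configuration,
                 rngSeed = as.integer(rngSeed), outputDir = outputDir),
            class = "runConfig")
}

#' @rdname runConfig
#' @param path a YAML file with keys matching the \code{runConfig} arguments
#'   (spec and material given as mappings of their fields)
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- if (!is.null(y$spec))
    ellipsoidSpec(y$spec$a, y$spec$b, y$spec$c) else spec2DPA()
  mat <- if (!is.null(y$material))
    shellMaterial(youngModulus = y$material$young_modulus %||% 100,
                  poissonRatio = y$material$poisson_ratio %||% 0.3,
                  thickness = y$material$thickness %||% 1,
                  pressure = y$material$pressure %||% 0.2)
  else shellMaterial()
  runConfig(spec = spec, refinement = y$refinement %||% 4L, material = mat,
            nCells = y$n_cells %||% 300L,
            curvatureRadius = y$curvature_radius %||% 30,
            cmtKappa = y$cmt_kappa %||% 20,
            cmtOffsetDeg = y$cmt_offset_deg %||% 0,
            configuration = y$configuration %||% "inflated",
            rngSeed = y$rng_seed %||% stop("rng_seed is mandatory"),
            outputDir = y$output_dir %||% tempfile("seedmech_run_"))
}

pipelineLog <- function(conn, fmt, ...) {
  line <- sprintf(fmt, ...)
  message("[seedmech] ", line)
  if (!is.null(conn)) writeLines(line, conn)
}

#' Predict shape-driven stress on a seed-shaped shell
#'
#' The model-prediction pipeline: generates the ellipsoid mesh, tessellates
#' it into cells, solves the pressurized-membrane stress field, estimates
#' the curvature field, classifies tip/flank/flat-face regions and writes
#' per-cell CSVs, a region-wise summary, a parameter manifest and a run
#' log under \code{config$outputDir}. Outputs are keyed by cell_id and
#' byte-identical across reruns of the same config.
#'
#' @param config a \code{\link{runConfig}}
#' @return (invisibly) list with mesh, tess, stress, curvature, cmt,
#'   labels, summaryStress, summaryCurvature, thetaDistribution
#' @export
predictSeedStress <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  logFile <- file(file.path(config$outputDir, "run.log"), "w")
  on.exit(close(logFile))
  stage <- function(name, expr) {
    pipelineLog(logFile, "stage %s", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  pipelineLog(logFile, "seedmech %s, root seed %d",
              as.character(utils::packageVersion("seedmech")), config$rngSeed)
  mesh <- stage("mesh", makeEllipsoidMesh(config$spec, config$refinement))
  tess <- stage("tessellation",
                tessellateSurface(mesh, config$nCells,
                                  deriveSeed(config$rngSeed, "tessellation")))
  stress <- stage("stress",
                  solveMembraneStress(mesh, config$material, tess,
                                      configuration = config$configuration))
  curvMesh <- attr(stress, "inflatedMesh") %||% mesh
  curvTess <- if (is.null(attr(stress, "inflatedMesh"))) tess else
    cellTessellation(curvMesh, faceCell(tess))
  curv <- stage("curvature",
                estimateCurvature(curvMesh, curvTess, config$curvatureRadius))
  cmt <- stage("cmt", sampleCMTField(curv, config$cmtKappa,
                                     config$cmtOffsetDeg,
                                     deriveSeed(config$rngSeed, "cmt")))
  labels <- stage("regions", classifyRegions(mesh, tess, config$spec))
  sumS <- stage("summary", fieldSummary(stress, labels))
  sumC <- fieldSummary(curv, labels)
  theta <- stage("correlate", correlateOrientationWithCurvature(cmt, curv))
  out <- function(df, name)
    utils::write.csv(df, file.path(config$outputDir, name), row.names = FALSE)
  out(asDataFrame(stress), "stress.csv")
  out(asDataFrame(curv), "curvature.csv")
  out(asDataFrame(cmt), "cmt.csv")
  out(data.frame(cell_id = cellIds(labels), region = regionLabel(labels)),
      "regions.csv")
  out(cbind(field = "stress", sumS), "summary_stress.csv")
  out(cbind(field = "curvature", sumC), "summary_curvature.csv")
  out(data.frame(cell_id = as.integer(names(thetaValues(theta))),
                 theta_deg = thetaValues(theta)), "theta.csv")
  manifest <- list(
    package = "seedmech",
    version = as.character(utils::packageVersion("seedmech")),
    spec = as.list(semiAxes(config$spec)),
    refinement = config$refinement,
    material = list(young_modulus = config$material@youngModulus,
                    poisson_ratio = config$material@poissonRatio,
                    thickness = config$material@thickness,
                    pressure = config$material@pressure),
    configuration = config$configuration,
    n_cells = config$nCells, curvature_radius = config$curvatureRadius,
    cmt_kappa = config$cmtKappa, cmt_offset_deg = config$cmtOffsetDeg,
    rng_seed = config$rngSeed,
    derived_seeds = list(tessellation = deriveSeed(config$rngSeed, "tessellation"),
                         cmt = deriveSeed(config$rngSeed, "cmt")))
  yaml::write_yaml(manifest, file.path(config$outputDir, "manifest.yaml"))
  pipelineLog(logFile, "done: %d cells", nCells(tess))
  invisible(list(mesh = mesh, tess = tess, stress = stress, curvature = curv,
                 cmt = cmt, labels = labels, summaryStress = sumS,
                 summaryCurvature = sumC, thetaDistribution = theta))
}

validationRow <- function(check, measured, expected, tol, pass)
  data.frame(check = check, measured = measured, expected = expected,
             tol = tol, pass = pass)

#' Synthetic end-to-end validation suite
#'
#' Runs every generator-to-analyzer loop-back and oracle comparison on
#' synthetic data and reports one row per check with the measured value,
#' the expectation and the tolerance. Failures are rows, not errors, so a
#' deliberately broken configuration leaves the other checks unaffected.
#'
#' @param config a \code{\link{runConfig}}; the shell and curvature checks
#'   run at its refinement and material, the loop-backs at fixed small sizes
#' @return data.frame with columns check, measured, expected, tol, pass
#' @export
validatePipeline <- function(config) {
  stopifnot(inherits(config, "runConfig"))
  rows <- list()
  add <- function(check, measured, expected, tol)
    rows[[length(rows) + 1L]] <<- validationRow(
      check, measured, expected, tol,
      is.finite(measured) && abs(measured - expected) <= tol)
  mat <- config$material
  safely <- function(expr) tryCatch(expr, error = function(e) NA_real_)

  ## sphere shell oracle: sigma = pR/(2t), anisotropy ~ 0
  R <- config$spec@b
  sphere <- makeEllipsoidMesh(ellipsoidSpec(R, R, R), config$refinement)
  sphereStress <- safely(solveMembraneStress(sphere, mat))
  sRef <- mat@pressure * R / (2 * mat@thickness)
  add("sphere_sigma1", safely(stats::median(sphereStress@value1)), sRef, 0.02 * sRef)
  add("sphere_sigma2", safely(stats::median(sphereStress@value2)), sRef, 0.02 * sRef)
  add("sphere_stress_anisotropy",
      safely(stats::median(sphereStress@anisotropy)), 0, 0.02)

  ## spheroid equator ratio vs closed form 2 - (b/a)^2
  a <- config$spec@a; b <- config$spec@b
  spheroid <- makeEllipsoidMesh(ellipsoidSpec(a, b, b), config$refinement)
  spS <- safely(solveMembraneStress(spheroid, mat))
  ratio <- safely({
    fc <- faceCentroidsRaw(spheroid@vertices, spheroid@faces)
    eq <- abs(fc[, 1L]) < 0.1 * a
    stats::median(spS@value1[eq] / spS@value2[eq])
  })
  oracle <- spheroidStressOracle(a, b, mat, 0)
  refRatio <- unname(oracle["sigma_hoop"] / oracle["sigma_meridional"])
  add("spheroid_equator_stress_ratio", ratio, refRatio, 0.05 * refRatio)

  ## curvature estimator vs analytic oracle (sphere and spheroid equator)
  tessS <- tessellateSurface(sphere, min(config$nCells, 200L),
                             deriveSeed(config$rngSeed, "validate_tess"))
  curvS <- safely(estimateCurvature(sphere, tessS, config$curvatureRadius))
  add("sphere_kappa", safely(stats::median(curvS@value1)), 1 / R, 0.03 / R)
  tessP <- tessellateSurface(spheroid, min(config$nCells, 200L),
                             deriveSeed(config$rngSeed, "validate_tess2"))
  curvP <- safely(estimateCurvature(spheroid, tessP, config$curvatureRadius))
  kEq <- safely({
    eq <- abs(tessP@centroids[, 1L]) < 0.1 * a
    stats::median(curvP@value1[eq])
  })
  add("spheroid_equator_kappa_hoop", kEq, 1 / b, 0.05 / b)

  ## fibril loop-back
  fib <- makeFibrilImage(c(128L, 128L), 30, 0.9,
                         deriveSeed(config$rngSeed, "fibril"))
  meas <- fibrilTensor(fib)
  add("fibril_orientation_recovery",
      axialDiffDeg(meas$orientation_deg, 30), 0, 1)
  isoScores <- vapply(1:5, function(k)
    fibrilTensor(makeFibrilImage(c(128L, 128L), 0, 0,
                                 deriveSeed(config$rngSeed + k, "iso")))$score,
    numeric(1))
  add("fibril_isotropic_score", mean(isoScores), 0, 0.05)

  ## uniform axial field: mean theta = 45 deg
  curvFlat <- new("CurvatureField", cellId = 1:1000,
                  value1 = rep(1, 1000), value2 = rep(0, 1000),
                  axis1 = matrix(rep(c(1, 0, 0), each = 1000), ncol = 3L),
                  axis2 = matrix(rep(c(0, 1, 0), each = 1000), ncol = 3L),
                  anisotropy = rep(1, 1000), neighborhoodRadius = 0)
  unif <- sampleCMTField(curvFlat, 0, 0, deriveSeed(config$rngSeed, "unif"))
  th <- correlateOrientationWithCurvature(unif, curvFlat)
  add("uniform_axial_mean_theta", th@summary$mean, 45, 3)

  ## growth formulas on a hand-computed case
  g <- growthDerivativeSeries(data.frame(day = 0:1, mean_area = c(100, 150),
                                         sd_area = c(10, 15),
                                         mean_ar = c(1, 1), sd_ar = c(0, 0)))
  add("growth_rate_formula", g$growth_rate[1L], 0.5, 1e-12)
  add("growth_sd_formula", g$sd_growth_rate[1L], sqrt(0.02), 1e-12)

  ## cell-growth recovery on a planar patch
  plan <- makePlanarMesh(100, 100, 16L, 16L)
  tess0 <- tessellateSurface(plan, 25L, deriveSeed(config$rngSeed, "growth"))
  tess1 <- makePairedTessellation(tess0, 1.2, 1.0, 0,
                                  deriveSeed(config$rngSeed, "growth2"))
  gm <- cellGrowthMap(tess0, tess1)
  add("cell_areal_growth_recovery", mean(gm$areal_growth), 0.2, 0.01)
  add("cell_growth_anisotropy_recovery", mean(gm$anisotropy), 1.2, 0.02)

  ## segmentation object counts
  s3 <- makeSilhouetteImage(
    silhouetteSpec(40, 25, rbind(c(60, 60), c(180, 60), c(120, 180)),
                   sizePx = c(240L, 240L), noiseAmp = 0.01),
    deriveSeed(config$rngSeed, "sil"))
  add("segmentation_three_objects", max(segmentSeeds(s3)), 3, 0)
  s2 <- makeSilhouetteImage(
    silhouetteSpec(40, 25, rbind(c(60, 80), c(140, 80)),
                   sizePx = c(220L, 160L), noiseAmp = 0),
    deriveSeed(config$rngSeed, "sil2"))
  add("segmentation_tangent_pair", max(segmentSeeds(s2)), 2, 0)

  do.call(rbind, rows)
}
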