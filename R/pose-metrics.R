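## Agonist-pose metrics: indole-core RMSD against a reference agonist core
## (the tetracyclic core of LSD) after receptor-frame superposition, the
## signed insertion depth of the ligand core along the receptor axis, and
## the time-series statistics used for reporting (fraction below threshold,
## moving average, kernel density estimate).

#' Construct a CoreMapping
#'
#' @param referenceCore K x 3 matrix of reference core coordinates in the
#'   reference receptor frame (K >= 3).
#' @param coreAtomNames ligand atom names matched row-by-row to
#'   `referenceCore`.
#' @param fitQuery atom-selection query (see [selectAtoms()]) for the
#'   receptor atoms used to superpose each frame; C-alpha atoms of the
#'   annotated TM bundle are the usual choice.
#' @param referenceFit M x 3 matrix of the fit atoms in the reference
#'   structure, in `fitQuery` selection order.
#' @return a [CoreMapping-class].
#' @export
coreMapping <- function(referenceCore, coreAtomNames, fitQuery,
                        referenceFit) {
  new("CoreMapping", referenceCore = as.matrix(referenceCore),
      coreAtomNames = coreAtomNames, fitQuery = fitQuery,
      referenceFit = as.matrix(referenceFit))
}

#' Per-frame indole-core RMSD (RMSD_i)
#'
#' For each frame, the receptor fit atoms are superposed onto their
#' reference coordinates (proper-rotation Kabsch) and the RMSD of the ligand
#' core against the reference core is evaluated under that same transform,
#' without refitting.  Poses with RMSD_i strictly below 2 Angstrom are
#' conventionally taken as agonist-compatible.
#'
#' @param traj a [Trajectory-class].
#' @param mapping a [CoreMapping-class].
#' @return numeric vector of per-frame RMSD_i, Angstrom.
#' @export
rmsdISeries <- function(traj, mapping) {
  top <- topology(traj)
  fitIdx <- selectAtoms(top, mapping@fitQuery)
  if (length(fitIdx) != nrow(mapping@referenceFit))
    .err(sprintf("fit selection matches %d atoms but the reference has %d",
                 length(fitIdx), nrow(mapping@referenceFit)),
         "topology_error")
  coreIdx <- vapply(mapping@coreAtomNames, function(nm) {
    hit <- which(top$name == nm &
                   !(toupper(top$resname) %in% .WATER_RESNAMES))
    if (length(hit) != 1L)
      .err(paste("ligand core atom not uniquely resolvable:", nm),
           "topology_error")
    hit
  }, integer(1))
  nf <- nFrames(traj)
  out <- numeric(nf)
  for (k in seq_len(nf)) {
    xyz <- traj@coords[, , k]
    out[k] <- tryCatch(
      rmsdAfterFitOnSubset(xyz[fitIdx, , drop = FALSE],
                           mapping@referenceFit,
                           xyz[coreIdx, , drop = FALSE],
                           mapping@referenceCore),
      error = function(e) .err(sprintf("RMSD_i at frame %d: %s", k,
                                       conditionMessage(e)), "pose_error"))
  }
  out
}

#' Percentage of values strictly below a threshold
#'
#' Strict inequality: boundary values count as not-below.
#'
#' @param series numeric vector (e.g. per-frame RMSD_i).
#' @param threshold Angstrom, default 2.0.
#' @return percentage in [0, 100].
#' @export
fractionBelow <- function(series, threshold = 2.0) {
  if (!length(series)) .err("empty series", "value_error")
  100 * sum(series < threshold) / length(series)
}

#' Receptor principal axis for the depth metric
#'
#' The direction is the principal axis of the TM-bundle C-alpha cloud (>= 20
#' atoms with role `tm`), with the sign fixed so that the extracellular
#' vestibule centroid projects negative, i.e. the axis points intracellular.
#' The origin is the C-gamma of the 3.32 anchor.
#'
#' @param xyz frame coordinate matrix.
#' @param topology matching topology data.frame.
#' @param map a [ResidueMap-class].
#' @return list `(origin, direction)` defining the depth axis.
#' @export
receptorAxis <- function(xyz, topology, map) {
  tmCA <- .roleAtomIdx(topology, map, "tm", "CA")
  if (length(tmCA) < 20L)
    .err("receptor axis needs at least 20 annotated TM C-alpha atoms",
         "axis_error")
  P <- xyz[tmCA, , drop = FALSE]
  C <- sweep(P, 2L, colMeans(P))
  eig <- eigen(crossprod(C) / nrow(C), symmetric = TRUE)
  if ((eig$values[1L] - eig$values[2L]) / max(eig$values[1L], 1e-12) < 1e-6)
    .err("degenerate TM C-alpha cloud: principal axis undefined",
         "axis_error")
  dirv <- eig$vectors[, 1L]
  vest <- .roleAtomIdx(topology, map, "vestibule", "CA")
  origin <- xyz[.roleAtomIdx(topology, map, "anchor", "CG"), ]
  vc <- colMeans(xyz[vest, , drop = FALSE])
  if (sum((vc - origin) * dirv) > 0) dirv <- -dirv
  list(origin = as.numeric(origin), direction = as.numeric(dirv))
}

#' Signed ligand insertion depth
#'
#' Projection of the ligand aromatic-core centroid onto the receptor axis,
#' relative to the C-gamma of the 3.32 anchor; positive values are deeper
#' (more intracellular) than the anchor.
#'
#' @param xyz frame coordinate matrix.
#' @param topology matching topology data.frame.
#' @param map a [ResidueMap-class].
#' @param axis list `(origin, direction)` from [receptorAxis()]; computed
#'   from the frame when omitted.
#' @return signed depth in Angstrom.
#' @export
insertionDepth <- function(xyz, topology, map, axis = NULL) {
  if (is.null(axis)) axis <- receptorAxis(xyz, topology, map)
  .assert(abs(sqrt(sum(axis$direction^2)) - 1) < 1e-9,
          "axis direction must be a unit vector")
  core <- .ligandRoleIdx(topology, map, "core")
  centroid <- colMeans(xyz[core, , drop = FALSE])
  sum((centroid - axis$origin) * axis$direction)
}

#' Trailing moving average
#'
#' Element i is the mean of the last `min(window, i)` values, so the output
#' has the same length as the input and early elements average over what is
#' available.
#'
#' @param series numeric vector.
#' @param window window size in frames, default 20.
#' @return numeric vector, same length as `series`.
#' @export
movingAverage <- function(series, window = 20L) {
  if (window < 1L) .err("window must be >= 1", "value_error")
  n <- length(series)
  if (!n) return(numeric(0))
  cs <- cumsum(series)
  i <- seq_len(n)
  lo <- pmax(i - window, 0L)
  (cs - c(0, cs)[lo + 1L]) / (i - lo)
}

#' One-dimensional Gaussian kernel density estimate
#'
#' Direct kernel sum on an explicit grid.  With `bandwidth = "scott"` the
#' bandwidth is `sd(x) * n^(-1/5)`; zero-variance samples fall back to a
#' fixed minimal bandwidth of 0.05 Angstrom with a warning.  The default
#' grid spans the sample range plus five bandwidths on each side, so the
#' density integrates to 1 (within 1e-3).
#'
#' @param samples numeric vector, >= 2 values (Angstrom in typical use).
#' @param grid evaluation grid; computed from the samples when NULL.
#' @param bandwidth positive numeric or "scott".
#' @param gridSize number of points of the automatic grid.
#' @return data.frame with columns `grid` and `density`.
#' @export
kde1d <- function(samples, grid = NULL, bandwidth = "scott",
                  gridSize = 512L) {
  .assert(length(samples) >= 2L, "kde1d needs at least 2 samples")
  if (identical(bandwidth, "scott")) {
    s <- stats::sd(samples)
    bandwidth <- s * length(samples)^(-1 / 5)
    if (!is.finite(bandwidth) || bandwidth <= 0) {
      warning("zero-variance samples: using minimal bandwidth 0.05 A")
      bandwidth <- 0.05
    }
  }
  .assert(is.numeric(bandwidth) && bandwidth > 0, "bandwidth must be > 0")
  if (is.null(grid))
    grid <- seq(min(samples) - 5 * bandwidth, max(samples) + 5 * bandwidth,
                length.out = gridSize)
  dens <- vapply(grid, function(g)
    mean(stats::dnorm(g, mean = samples, sd = bandwidth)), numeric(1))
  data.frame(grid = grid, density = dens)
}
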