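## Per-frame geometric interaction detectors and occupancy statistics.
##
## All detectors are pure functions of a single frame's coordinates, so every
## result is invariant under global rigid motion, and the trajectory-level
## series is the frame-by-frame composition of the single-shot calls.

#' Hydrogen-bond detector
#'
#' A donor-H / acceptor pair is hydrogen bonded when the donor-acceptor
#' distance is at most `distCutoff` and the D-H...A angle (measured at the
#' hydrogen; linear = 180 degrees) is at least `angleCutoff`.  The geometry
#' is returned whether or not the criterion holds.
#'
#' @param xyz nAtoms x 3 coordinate matrix of one frame.
#' @param donor,hydrogen,acceptor atom indices; the hydrogen must be
#'   covalently bound to the donor (within 1.2 Angstrom).
#' @param distCutoff,angleCutoff criteria (default 3.5 Angstrom, 120 degrees).
#' @return list `(present, dist, angle)`.
#' @export
detectHBond <- function(xyz, donor, hydrogen, acceptor,
                        distCutoff = 3.5, angleCutoff = 120) {
  D <- xyz[donor, ]; H <- xyz[hydrogen, ]; A <- xyz[acceptor, ]
  if (vecDistance(D, H) > 1.2)
    .err("hydrogen is not covalently bound to the donor (> 1.2 A)",
         "topology_error")
  d <- vecDistance(D, A)
  ang <- vecAngle(D, H, A)
  list(present = (d <= distCutoff) && (ang >= angleCutoff),
       dist = d, angle = ang)
}

#' Salt-bridge detector
#'
#' Present when the minimum distance over all basic-nitrogen / acidic-oxygen
#' pairs is at most `distCutoff`.
#'
#' @param xyz frame coordinate matrix.
#' @param basicIdx,acidicIdx non-empty index vectors (e.g. protonated amine
#'   N and carboxylate O atoms).
#' @param distCutoff Angstrom, default 4.0.
#' @return list `(present, dist)` with `dist` the minimum N-O distance.
#' @export
detectSaltBridge <- function(xyz, basicIdx, acidicIdx, distCutoff = 4.0) {
  if (!length(basicIdx) || !length(acidicIdx))
    .err("empty atom group in salt-bridge detection", "selection_error")
  d <- .minGroupDistance(xyz, basicIdx, acidicIdx)
  list(present = d <= distCutoff, dist = d)
}

.minGroupDistance <- function(xyz, ia, ib) {
  A <- xyz[ia, , drop = FALSE]
  B <- xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(max(0, min(d2)))
}

#' Hydrophobic-contact detector
#'
#' Present when any inter-group heavy-atom pair is within `distCutoff`.
#' Hydrogens in either selection are rejected.
#'
#' @param xyz frame coordinate matrix.
#' @param topology topology data.frame matching `xyz` (for the element check).
#' @param groupA,groupB heavy-atom index vectors.
#' @param distCutoff Angstrom, default 4.5.
#' @return list `(present, dist)`.
#' @export
detectHydrophobicContact <- function(xyz, topology, groupA, groupB,
                                     distCutoff = 4.5) {
  if (!length(groupA) || !length(groupB))
    .err("empty atom group in contact detection", "selection_error")
  if (any(toupper(topology$element[c(groupA, groupB)]) == "H"))
    .err("hydrogen atoms are not allowed in hydrophobic-contact selections",
         "selection_error")
  d <- .minGroupDistance(xyz, groupA, groupB)
  list(present = d <= distCutoff, dist = d)
}

## Ring centroid and unit plane normal via SVD; errors if the ring deviates
## from planarity by more than `planarityTol` (max point-to-plane residual).
.ringPlane <- function(xyz, ringIdx, planarityTol = 0.3) {
  if (length(ringIdx) < 5L)
    .err("ring selections need at least 5 atoms", "geometry_error")
  P <- xyz[ringIdx, , drop = FALSE]
  centroid <- colMeans(P)
  C <- sweep(P, 2L, centroid)
  sv <- svd(C)
  normal <- sv$v[, 3L]
  resid <- abs(C %*% normal)
  if (max(resid) > planarityTol)
    .err(sprintf("ring is not planar (max residual %.2f A)", max(resid)),
         "geometry_error")
  list(centroid = centroid, normal = normal)
}

#' Pi-pi stacking detector
#'
#' Present when the ring-centroid separation is at most `distCutoff` and the
#' interplanar angle is either parallel (<= `parallelAngle`) or T-shaped
#' (within `tShapeRange`).  Ring planes are fitted by SVD; non-planar rings
#' (residual > 0.3 Angstrom) raise a geometry error.
#'
#' @param xyz frame coordinate matrix.
#' @param ringA,ringB index vectors of >= 5 ring atoms each.
#' @param distCutoff centroid distance cutoff, Angstrom (default 5.5).
#' @param parallelAngle degrees (default 30).
#' @param tShapeRange length-2 numeric, degrees (default c(60, 90)).
#' @return list `(present, dist, angle)`; the angle is folded into [0, 90].
#' @export
detectPiStack <- function(xyz, ringA, ringB, distCutoff = 5.5,
                          parallelAngle = 30, tShapeRange = c(60, 90)) {
  a <- .ringPlane(xyz, ringA)
  b <- .ringPlane(xyz, ringB)
  d <- vecDistance(a$centroid, b$centroid)
  cosang <- abs(sum(a$normal * b$normal))
  ang <- .rad2deg(acos(max(-1, min(1, cosang))))
  geomOk <- (ang <= parallelAngle) ||
    (ang >= tShapeRange[1L] && ang <= tShapeRange[2L])
  list(present = (d <= distCutoff) && geomOk, dist = d, angle = ang)
}

#' Construct an InteractionSpec
#'
#' @param kind one of `"hbond"`, `"salt_bridge"`, `"hydrophobic"`,
#'   `"pi_stack"`.
#' @param label unique report label.
#' @param ... named selection query strings as required by `kind` (see
#'   [InteractionSpec-class]); an `hbond` may additionally carry `donor2`,
#'   `hydrogen2`, `acceptor2` describing the swapped-direction evaluation of
#'   an ambiguous donor (the bond counts as present if either direction
#'   holds).
#' @return an [InteractionSpec-class].
#' @export
interactionSpec <- function(kind, label, ...) {
  sel <- list(...)
  if (length(sel) == 1L && is.list(sel[[1L]]) && is.null(names(sel)))
    sel <- sel[[1L]]
  new("InteractionSpec", kind = kind, label = label, selections = sel)
}

.resolveSpec <- function(spec, topology) {
  idx <- lapply(spec@selections, function(q) selectAtoms(topology, q))
  need <- .SPEC_SELECTIONS[[spec@kind]]
  for (nm in need)
    if (!length(idx[[nm]]))
      .err(sprintf("selection '%s' of interaction '%s' matches no atoms",
                   nm, spec@label), "selection_error")
  idx
}

.evalSpecOnFrame <- function(spec, idx, xyz, topology, params) {
  switch(spec@kind,
    hbond = {
      r <- detectHBond(xyz, idx$donor[1L], idx$hydrogen[1L], idx$acceptor[1L],
                       params$hbond_dist, params$hbond_angle)
      if (!is.null(idx$donor2)) {
        r2 <- detectHBond(xyz, idx$donor2[1L], idx$hydrogen2[1L],
                          idx$acceptor2[1L],
                          params$hbond_dist, params$hbond_angle)
        r <- list(present = r$present || r2$present,
                  dist = min(r$dist, r2$dist))
      }
      r
    },
    salt_bridge = detectSaltBridge(xyz, idx$basic, idx$acidic,
                                   params$salt_bridge_dist),
    hydrophobic = detectHydrophobicContact(xyz, topology, idx$group_a,
                                           idx$group_b,
                                           params$hydrophobic_dist),
    pi_stack = detectPiStack(xyz, idx$ring_a, idx$ring_b,
                             params$pi_centroid_dist,
                             params$pi_parallel_angle, params$pi_tshape_range)
  )
}

#' Evaluate interaction specs on every frame of a trajectory
#'
#' @param traj a [Trajectory-class].
#' @param specs list of [InteractionSpec-class] objects with unique labels.
#' @param params geometric-cutoff preset, see [preset()].
#' @return list of [InteractionSeries-class], one per spec, in input order.
#' @export
interactionSeries <- function(traj, specs, params = preset()) {
  if (!length(specs)) return(list())
  labels <- vapply(specs, function(s) s@label, character(1))
  .assert(!anyDuplicated(labels), "interaction labels must be unique")
  top <- topology(traj)
  resolved <- lapply(specs, .resolveSpec, topology = top)
  nf <- nFrames(traj)
  lapply(seq_along(specs), function(si) {
    present <- logical(nf)
    geom <- numeric(nf)
    for (k in seq_len(nf)) {
      r <- tryCatch(
        .evalSpecOnFrame(specs[[si]], resolved[[si]], traj@coords[, , k],
                         top, params),
        error = function(e) .err(sprintf("interaction '%s', frame %d: %s",
                                         labels[si], k, conditionMessage(e)),
                                 "interaction_error"))
      present[k] <- r$present
      geom[k] <- r$dist
    }
    new("InteractionSeries", spec = specs[[si]], present = present,
        geometry = geom)
  })
}

#' Occupancy of an interaction series
#'
#' The occupancy is the exact percentage of frames in which the interaction
#' criterion holds; nothing is rounded until report rendering.
#'
#' @param x an [InteractionSeries-class] (or a logical vector).
#' @param ... unused.
#' @return one-row data.frame with columns label, occupancy_percent,
#'   n_frames, mean_dist, min_dist.
#' @export
setMethod("occupancy", "InteractionSeries", function(x, ...) {
  n <- length(x@present)
  if (n < 1L) .err("empty interaction series", "value_error")
  data.frame(label = x@spec@label,
             occupancy_percent = 100 * sum(x@present) / n,
             n_frames = n,
             mean_dist = mean(x@geometry),
             min_dist = min(x@geometry),
             stringsAsFactors = FALSE)
})

#' @rdname occupancy
#' @export
setMethod("occupancy", "logical", function(x, ...) {
  if (!length(x)) .err("empty interaction series", "value_error")
  100 * sum(x) / length(x)
})

#' Occupancy table for a list of interaction series
#'
#' @param seriesList list of [InteractionSeries-class].
#' @return data.frame, one row per series.
#' @export
occupancyTable <- function(seriesList) {
  if (!length(seriesList))
    return(data.frame(label = character(), occupancy_percent = numeric(),
                      n_frames = integer(), mean_dist = numeric(),
                      min_dist = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(seriesList, occupancy))
}
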