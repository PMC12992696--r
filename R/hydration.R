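## Sodium-pocket coordination and water-channel detection.
##
## The allosteric Na+ site at Asp 2.50 reports activation readiness: in the
## inactive state the ion sits in a dehydrated cage (Phe 6.44 lid above,
## Asn 7.49 hydrogen-bonded to Asp 2.50, ~2 first-shell waters); loss of that
## network opens a continuous water pathway from the extracellular vestibule
## and the shell grows to ~4 waters.

#' Count first-shell waters around the sodium ion
#'
#' @param xyz frame coordinate matrix.
#' @param topology matching topology data.frame (waters are residues named
#'   HOH/WAT/SOL/TIP3/OPC; the ion is element NA or residue NA+/SOD).
#' @param naIndex atom index of the Na+ ion; defaults to the single sodium
#'   found in the topology.
#' @param cutoff first-shell Na-O cutoff, Angstrom (default 3.2).
#' @return integer count of water oxygens within `cutoff`.
#' @export
naFirstShellCount <- function(xyz, topology, naIndex = NULL, cutoff = 3.2) {
  if (is.null(naIndex)) {
    naIndex <- .sodiumIdx(topology)
    if (!length(naIndex))
      .err("no sodium ion found in the topology", "selection_error")
    naIndex <- naIndex[1L]
  }
  wo <- .waterOxygenIdx(topology)
  if (!length(wo)) return(0L)
  d <- sqrt(colSums((t(xyz[wo, , drop = FALSE]) - xyz[naIndex, ])^2))
  sum(d <= cutoff)
}

#' Geometric state of the sodium pocket in one frame
#'
#' @param xyz frame coordinate matrix.
#' @param topology matching topology data.frame.
#' @param map a [ResidueMap-class].
#' @param params geometric preset, see [preset()].
#' @return list with `na_index`, `n_water_first_shell`, `asp_contact`
#'   (Na+ within 3.2 A of the Asp 2.50 carboxylate), `asn_asp_hbond`
#'   (Asn 7.49 ND2-H donating to the Asp 2.50 carboxylate),
#'   `ser_backup` (Ser 3.39 OG within 3.2 A of Na+) and `lid_closed`
#'   (Phe 6.44 ring centroid within 6 A of Na+).  With no sodium in the
#'   system all contact fields are FALSE and the shell count 0.
#' @export
naPocketState <- function(xyz, topology, map, params = preset()) {
  aspO <- .roleAtomIdx(topology, map, "na_site", c("OD1", "OD2"))
  asnIdx <- c(.roleAtomIdx(topology, map, "na_stabilizer", "ND2"),
              .roleAtomIdx(topology, map, "na_stabilizer", "HD21"))
  serOG <- .roleAtomIdx(topology, map, "na_backup", "OG")
  ring <- .roleAtomIdx(topology, map, "na_lid",
                       c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"))
  na <- .sodiumIdx(topology)
  hb <- FALSE
  for (o in aspO) {
    r <- detectHBond(xyz, asnIdx[1L], asnIdx[2L], o,
                     params$hbond_dist, params$hbond_angle)
    if (r$present) { hb <- TRUE; break }
  }
  if (!length(na)) {
    return(list(na_index = NA_integer_, n_water_first_shell = 0L,
                asp_contact = FALSE, asn_asp_hbond = hb, ser_backup = FALSE,
                lid_closed = FALSE))
  }
  na <- na[1L]
  shell <- naFirstShellCount(xyz, topology, na, params$na_shell_cutoff)
  aspContact <- .minGroupDistance(xyz, na, aspO) <= params$na_contact_dist
  serBackup <- vecDistance(xyz[na, ], xyz[serOG, ]) <= params$na_contact_dist
  lid <- vecDistance(colMeans(xyz[ring, , drop = FALSE]), xyz[na, ]) <=
    params$lid_centroid_dist
  list(na_index = na, n_water_first_shell = shell, asp_contact = aspContact,
       asn_asp_hbond = hb, ser_backup = serBackup, lid_closed = lid)
}

## Build the water hydrogen-bond graph of one frame: nodes are water oxygen
## indices, edges O-O pairs within `edgeDist`; sources are waters within
## `attachDist` of any vestibule C-alpha, sinks within `attachDist` of the
## Asp 2.50 carboxylate.
.waterGraph <- function(xyz, topology, map, params = preset()) {
  wo <- .waterOxygenIdx(topology)
  if (!length(wo))
    return(list(nodes = integer(0), edges = matrix(integer(0), 0, 2),
                sources = integer(0), sinks = integer(0)))
  W <- xyz[wo, , drop = FALSE]
  d2 <- outer(rowSums(W^2), rowSums(W^2), "+") - 2 * tcrossprod(W)
  adj <- which(d2 <= params$water_edge_dist^2 &
                 upper.tri(d2), arr.ind = TRUE)
  vest <- .roleAtomIdx(topology, map, "vestibule", "CA")
  aspO <- .roleAtomIdx(topology, map, "na_site", c("OD1", "OD2"))
  distTo <- function(idxSet) {
    A <- xyz[idxSet, , drop = FALSE]
    dd <- outer(rowSums(W^2), rowSums(A^2), "+") - 2 * tcrossprod(W, A)
    sqrt(pmax(0, apply(dd, 1L, min)))
  }
  list(nodes = wo, edges = adj,
       sources = which(distTo(vest) <= params$water_attach_dist),
       sinks = which(distTo(aspO) <= params$water_attach_dist))
}

#' Water-channel existence between vestibule and sodium pocket
#'
#' Builds the water oxygen hydrogen-bond graph (O-O edges within 3.5 A) and
#' asks whether any water near the extracellular vestibule reference atoms
#' (within 4 A of a vestibule C-alpha) is connected to any water near the
#' Asp 2.50 carboxylate (within 4 A).  The path length is the number of
#' waters on a shortest such path (1 when a single water touches both ends),
#' 0 when there is no path.
#'
#' @param xyz frame coordinate matrix.
#' @param topology matching topology data.frame.
#' @param map a [ResidueMap-class] (roles `vestibule` and `na_site`).
#' @param params geometric preset, see [preset()].
#' @return list `(exists, path_length)`.
#' @export
waterChannelExists <- function(xyz, topology, map, params = preset()) {
  g <- .waterGraph(xyz, topology, map, params)
  if (!length(g$nodes) || !length(g$sources) || !length(g$sinks))
    return(list(exists = FALSE, path_length = 0L))
  common <- intersect(g$sources, g$sinks)
  if (length(common)) return(list(exists = TRUE, path_length = 1L))
  n <- length(g$nodes)
  ig <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(g$edges))
    ig <- igraph::add_edges(ig, t(g$edges))
  dmat <- igraph::distances(ig, v = g$sources, to = g$sinks)
  best <- suppressWarnings(min(dmat))
  if (!is.finite(best)) return(list(exists = FALSE, path_length = 0L))
  list(exists = TRUE, path_length = as.integer(best) + 1L)
}

#' Per-frame hydration table for a whole trajectory
#'
#' @param traj a [Trajectory-class].
#' @param map a [ResidueMap-class].
#' @param params geometric preset.
#' @return data.frame with columns frame, time_ns, n_water_first_shell,
#'   asp_contact, asn_asp_hbond, ser_backup, lid_closed, channel, path_len.
#' @export
hydrationSeries <- function(traj, map, params = preset()) {
  top <- topology(traj)
  nf <- nFrames(traj)
  rows <- vector("list", nf)
  for (k in seq_len(nf)) {
    xyz <- traj@coords[, , k]
    st <- naPocketState(xyz, top, map, params)
    ch <- waterChannelExists(xyz, top, map, params)
    rows[[k]] <- data.frame(frame = k - 1L, time_ns = timeNs(traj)[k],
                            n_water_first_shell = st$n_water_first_shell,
                            asp_contact = st$asp_contact,
                            asn_asp_hbond = st$asn_asp_hbond,
                            ser_backup = st$ser_backup,
                            lid_closed = st$lid_closed,
                            channel = ch$exists, path_len = ch$path_length)
  }
  do.call(rbind, rows)
}
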