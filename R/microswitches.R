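## The four activation microswitch observables and the activation-state
## classifier.  Reference anchors from inactive vs active class A receptor
## structures: inactive d_TM ~ 9 A, d_IL ~ 4 A, chi1 ~ -80 deg (vertical
## toggle), Na+ coordinated; active d_TM ~ 12 A, d_IL ~ 16 A, chi1 ~ -160 deg
## (horizontal toggle), Na+ expelled.

#' Ionic-lock distance (d_IL)
#'
#' Minimum nitrogen-oxygen distance between the Arg 3.50 guanidinium
#' (NE/NH1/NH2) and the Glu 6.30 carboxylate (OE1/OE2).
#'
#' @param xyz frame coordinate matrix.
#' @param topology matching topology data.frame.
#' @param map a [ResidueMap-class].
#' @return distance in Angstrom.
#' @export
ionicLockDistance <- function(xyz, topology, map) {
  argN <- .roleAtomIdx(topology, map, "ionic_lock_arg", c("NE", "NH1", "NH2"))
  gluO <- .roleAtomIdx(topology, map, "ionic_lock_glu", c("OE1", "OE2"))
  .minGroupDistance(xyz, argN, gluO)
}

#' TM3-TM6 cytoplasmic gap (d_TM)
#'
#' C-alpha distance between roles 6.34 and 3.50, reporting the outward TM6
#' displacement on activation.
#'
#' @inheritParams ionicLockDistance
#' @return distance in Angstrom.
#' @export
tm6Gap <- function(xyz, topology, map) {
  ca1 <- .roleAtomIdx(topology, map, "tm6_ref", "CA")
  ca2 <- .roleAtomIdx(topology, map, "ionic_lock_arg", "CA")
  vecDistance(xyz[ca1, ], xyz[ca2, ])
}

#' Toggle-switch side-chain dihedrals of Trp 6.48
#'
#' chi1 = N-CA-CB-CG, chi2 = CA-CB-CG-CD1, degrees in (-180, 180].
#'
#' @inheritParams ionicLockDistance
#' @return named numeric `c(chi1 = , chi2 = )`.
#' @export
toggleDihedrals <- function(xyz, topology, map) {
  idx <- vapply(c("N", "CA", "CB", "CG", "CD1"), function(nm)
    .roleAtomIdx(topology, map, "toggle", nm), integer(1))
  c(chi1 = dihedralAngle(xyz[idx[1L], ], xyz[idx[2L], ], xyz[idx[3L], ],
                         xyz[idx[4L], ]),
    chi2 = dihedralAngle(xyz[idx[2L], ], xyz[idx[3L], ], xyz[idx[4L], ],
                         xyz[idx[5L], ]))
}

#' Classify the Trp 6.48 toggle rotamer
#'
#' Half-open chi1 bins with deterministic tie-breaks: vertical (inactive) for
#' chi1 in (-120, -40]; horizontal (active-like) for chi1 in (-180, -120];
#' downward for chi1 in (-40, 40] with chi2 < 0; otherwise "other".  The
#' -120 degree edge belongs to the horizontal bin.
#'
#' @param chi1,chi2 dihedrals in degrees.
#' @return one of "vertical", "horizontal", "downward", "other".
#' @export
classifyToggle <- function(chi1, chi2) {
  if (chi1 > -120 && chi1 <= -40) "vertical"
  else if (chi1 > -180 && chi1 <= -120) "horizontal"
  else if (chi1 > -40 && chi1 <= 40 && chi2 < 0) "downward"
  else "other"
}

#' Default microswitch reference table
#'
#' Anchor values for the inactive and active states and the midpoint
#' thresholds used for voting.
#'
#' @param params a [preset()] list (for the thresholds).
#' @return list with anchors and thresholds.
#' @export
microswitchReferences <- function(params = preset()) {
  list(
    inactive = list(d_tm = 9, d_il = 4, chi1 = -80, na_bound = TRUE),
    active = list(d_tm = 12, d_il = 16, chi1 = -160, na_bound = FALSE),
    dtm_threshold = params$dtm_threshold,
    dil_threshold = params$dil_threshold
  )
}

#' Classify the receptor activation state of one frame
#'
#' Each of the four microswitch metrics votes for the nearest reference
#' anchor: d_TM active when at or above the midpoint threshold (10.5 A
#' between the 9 and 12 A anchors), d_IL active at or above 10 A, toggle
#' active for the horizontal or downward rotamer, Na+ active when expelled.
#' The label is inactive when no metric votes active (no activation marker
#' engaged), active with at least 3 concordant active votes, and
#' intermediate otherwise; the score is the active-vote fraction.
#'
#' @param dTM,dIL Angstrom.
#' @param toggleClass rotamer class from [classifyToggle()].
#' @param naBound logical, Na+ coordinated at the 2.50 site.
#' @param refs reference table from [microswitchReferences()].
#' @return list `(label, score, votes)` with `votes` a named logical vector
#'   (TRUE = active vote).
#' @export
classifyState <- function(dTM, dIL, toggleClass, naBound,
                          refs = microswitchReferences()) {
  votes <- c(d_tm = dTM >= refs$dtm_threshold,
             d_il = dIL >= refs$dil_threshold,
             toggle = toggleClass %in% c("horizontal", "downward"),
             sodium = !naBound)
  nActive <- sum(votes)
  label <- if (nActive >= 3L) "active"
  else if (nActive == 0L) "inactive"
  else "intermediate"
  list(label = label, score = nActive / 4, votes = votes)
}

#' Per-frame microswitch table for a whole trajectory
#'
#' Computes d_TM, d_IL, chi1/chi2, sodium status and hydration, the toggle
#' rotamer class and the voted activation label for every frame.
#'
#' @param traj a [Trajectory-class].
#' @param map a [ResidueMap-class].
#' @param params geometric preset, see [preset()].
#' @param refs reference table, see [microswitchReferences()].
#' @return data.frame with one row per frame: frame, time_ns, d_tm, d_il,
#'   chi1, chi2, na_bound, na_hydration, toggle_class, label, score.
#' @export
microswitchSeries <- function(traj, map, params = preset(),
                              refs = microswitchReferences(params)) {
  top <- topology(traj)
  nf <- nFrames(traj)
  out <- data.frame(frame = seq_len(nf) - 1L, time_ns = timeNs(traj),
                    d_tm = NA_real_, d_il = NA_real_, chi1 = NA_real_,
                    chi2 = NA_real_, na_bound = NA, na_hydration = NA_integer_,
                    toggle_class = NA_character_, label = NA_character_,
                    score = NA_real_, stringsAsFactors = FALSE)
  for (k in seq_len(nf)) {
    xyz <- traj@coords[, , k]
    out$d_tm[k] <- tm6Gap(xyz, top, map)
    out$d_il[k] <- ionicLockDistance(xyz, top, map)
    chis <- toggleDihedrals(xyz, top, map)
    out$chi1[k] <- chis[["chi1"]]
    out$chi2[k] <- chis[["chi2"]]
    na <- naPocketState(xyz, top, map, params)
    out$na_bound[k] <- na$asp_contact
    out$na_hydration[k] <- na$n_water_first_shell
    out$toggle_class[k] <- classifyToggle(chis[["chi1"]], chis[["chi2"]])
    call <- classifyState(out$d_tm[k], out$d_il[k], out$toggle_class[k],
                          out$na_bound[k], refs)
    out$label[k] <- call$label
    out$score[k] <- call$score
  }
  out
}
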