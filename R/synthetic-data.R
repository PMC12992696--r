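## Deterministic synthetic-trajectory generator.
##
## Builds a minimal receptor scaffold (~30 residues) carrying every annotated
## role the analyses need, one ligand, one Na+ ion and a pool of waters, then
## drives selected atoms frame by frame so that ground-truth quantities are
## exact by construction: an occupancy target f over n frames places the
## interaction inside its geometric criterion in exactly round(f * n) frames
## (chosen as a seeded pseudo-random permutation of frame indices, so the
## occupancy is exact rather than binomial), rotamer schedules rebuild the
## toggle side chain at exact chi1/chi2, distance schedules translate marker
## residues, and pose targets displace the ligand rigidly by 0.5 A (below
## the 2 A criterion) or 3.0 A (above).  Fixtures are geometric
## constructions, not physical dynamics.

.N_SHELL_SLOTS <- 6L
.SHELL_DIRS <- rbind(c(0, 0, 1), c(0, -1, 0), c(0.71, 0.71, 0),
                     c(-0.71, 0.71, 0), c(0.71, -0.71, 0), c(0, 0.71, 0.71))

## NeRF-style placement: position D such that |c-D| = bond, angle(b,c,D) =
## angleDeg and dihedral(a,b,c,D) = dihedralDeg under the IUPAC convention.
.placeAtomNeRF <- function(a, b, c, bond, angleDeg, dihedralDeg) {
  u <- .unitv(c - b)
  r1 <- (a - b) - sum((a - b) * u) * u
  e1 <- .unitv(r1)
  e2 <- .cross3(u, e1)
  th <- .deg2rad(angleDeg)
  chi <- .deg2rad(dihedralDeg)
  d <- sin(th) * (cos(chi) * e1 + sin(chi) * e2) - cos(th) * u
  c + bond * d
}

## Base scaffold: topology + coordinates + the packaged residue map.  The
## template fixes the microswitch defaults (inactive: d_TM 9 A, d_IL 4 A,
## chi1 -80 deg, Na+ bound with 2 shell waters; active: 12 A, 16 A,
## -160 deg, Na+ expelled, no shell waters).
.templateDefaults <- function(template) {
  switch(template,
    inactive = list(d_tm = 9, d_il = 4, chi1 = -80, chi2 = 100,
                    na_in_pocket = TRUE, n_shell = 2L, channel = FALSE),
    active = list(d_tm = 12, d_il = 16, chi1 = -160, chi2 = 80,
                  na_in_pocket = FALSE, n_shell = 0L, channel = FALSE),
    .err(paste("unknown template:", template), "spec_error"))
}

.buildScaffold <- function(template = "inactive") {
  tp <- .templateDefaults(template)
  rows <- list()
  addAtom <- function(name, resname, resnum, element, x, y, z) {
    rows[[length(rows) + 1L]] <<- list(name = name, resname = resname,
                                       resnum = resnum, element = element,
                                       x = x, y = y, z = z)
  }
  addRing <- function(resname, resnum, center, radius = 1.39) {
    nms <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    for (i in seq_along(nms)) {
      ang <- (i - 1L) * pi / 3
      addAtom(nms[i], resname, resnum, "C",
              center[1L] + radius * cos(ang),
              center[2L] + radius * sin(ang), center[3L])
    }
  }

  ## --- orthosteric pocket side ------------------------------------------
  # Asp155 3.32 anchor (salt-bridge partner; CG is the depth origin)
  addAtom("CA", "ASP", 155L, "C", 4.0, 0.0, 6.0)
  addAtom("CB", "ASP", 155L, "C", 3.4, 0.0, 5.0)
  addAtom("CG", "ASP", 155L, "C", 2.6, 0.0, 4.0)
  addAtom("OD1", "ASP", 155L, "O", 1.4, 0.0, 4.0)
  addAtom("OD2", "ASP", 155L, "O", 3.1, 0.0, 2.9)
  # Val156 3.33 / Ser159 3.36 hydrophobic shell
  addAtom("CA", "VAL", 156L, "C", 4.5, -1.5, 3.5)
  addAtom("CB", "VAL", 156L, "C", 3.8, -1.2, 2.5)
  addAtom("CA", "SER", 159L, "C", 4.2, 1.0, 0.5)
  addAtom("CB", "SER", 159L, "C", 3.5, 1.0, -0.3)
  # Thr160 3.37 pocket base (indole N1-H acceptor / methoxy donor)
  addAtom("CA", "THR", 160L, "C", 4.0, 2.5, 2.0)
  addAtom("CB", "THR", 160L, "C", 3.2, 2.5, 1.2)
  og1 <- c(3.0, 2.3, 1.9)
  addAtom("OG1", "THR", 160L, "O", og1[1L], og1[2L], og1[3L])
  hg1 <- og1 + 0.96 * .unitv(c(-1.0, 0.5, 1.0))
  addAtom("HG1", "THR", 160L, "H", hg1[1L], hg1[2L], hg1[3L])
  # Ser162 3.39 sodium backup
  addAtom("CA", "SER", 162L, "C", 3.0, 1.5, -1.5)
  addAtom("OG", "SER", 162L, "O", 2.2, 1.2, -2.2)
  # Arg173 3.50 (ionic lock / TM gap reference)
  argCA <- c(3.0, 0.0, -15.0)
  addAtom("CA", "ARG", 173L, "C", argCA[1L], argCA[2L], argCA[3L])
  addAtom("NE", "ARG", 173L, "N", 2.2, 0.0, -13.6)
  nh1 <- c(3.6, 0.6, -13.0)
  addAtom("NH1", "ARG", 173L, "N", nh1[1L], nh1[2L], nh1[3L])
  addAtom("NH2", "ARG", 173L, "N", 2.5, -1.0, -12.8)
  # Glu318 6.30: carboxylate placed so the minimum N-O distance is exactly
  # the d_IL of the template (schedules re-place it per frame)
  oe1 <- nh1 + c(tp$d_il, 0, 0)
  addAtom("OE1", "GLU", 318L, "O", oe1[1L], oe1[2L], oe1[3L])
  addAtom("OE2", "GLU", 318L, "O", oe1[1L] + 0.8, oe1[2L] + 1.0,
          oe1[3L] + 0.3)
  addAtom("CA", "GLU", 318L, "C", oe1[1L] + 1.8, oe1[2L] + 0.5,
          oe1[3L] - 0.8)
  # Cys322 6.34: CA placed exactly d_TM from Arg173 CA
  addAtom("CA", "CYS", 322L, "C", argCA[1L], argCA[2L] + tp$d_tm, argCA[3L])
  # Leu230 / Val235 hydrophobic shell
  addAtom("CA", "LEU", 230L, "C", -3.0, -2.0, 5.0)
  addAtom("CB", "LEU", 230L, "C", -2.2, -1.8, 4.2)
  addAtom("CA", "VAL", 235L, "C", -3.5, 2.0, 5.5)
  addAtom("CB", "VAL", 235L, "C", -2.7, 2.0, 4.7)
  # Asp231 5.35: backbone amide donates to the ligand methoxy oxygen
  aspN <- c(-2.6, 2.8, 8.8)
  o1base <- c(-1.0, 2.2, 8.2)
  addAtom("N", "ASP", 231L, "N", aspN[1L], aspN[2L], aspN[3L])
  aspH <- aspN + 1.0 * .unitv(o1base - aspN)
  addAtom("H", "ASP", 231L, "H", aspH[1L], aspH[2L], aspH[3L])
  addAtom("CA", "ASP", 231L, "C", -3.5, 3.2, 9.5)
  addAtom("C", "ASP", 231L, "C", -4.2, 2.5, 10.3)
  addAtom("O", "ASP", 231L, "O", -4.0, 1.4, 10.7)
  # Polar triad: Ser239 5.44, Ser242 5.46, Asn343 6.55
  addAtom("CA", "SER", 239L, "C", -3.0, 4.0, 6.0)
  og239 <- c(-2.2, 3.8, 5.2)
  addAtom("OG", "SER", 239L, "O", og239[1L], og239[2L], og239[3L])
  hg239 <- og239 + 0.96 * .unitv(c(1.0, -0.5, -0.5))
  addAtom("HG", "SER", 239L, "H", hg239[1L], hg239[2L], hg239[3L])
  addAtom("CA", "SER", 242L, "C", -2.5, 4.0, 3.0)
  og242 <- c(-1.8, 3.7, 2.2)
  addAtom("OG", "SER", 242L, "O", og242[1L], og242[2L], og242[3L])
  hg242 <- og242 + 0.96 * .unitv(c(1.0, -0.5, 0.5))
  addAtom("HG", "SER", 242L, "H", hg242[1L], hg242[2L], hg242[3L])
  addAtom("CA", "ASN", 343L, "C", 1.0, 4.5, 7.0)
  addAtom("CG", "ASN", 343L, "C", 0.6, 3.9, 6.2)
  addAtom("OD1", "ASN", 343L, "O", -0.4, 3.6, 6.2)
  nd343 <- c(1.4, 3.6, 5.4)
  addAtom("ND2", "ASN", 343L, "N", nd343[1L], nd343[2L], nd343[3L])
  hd343 <- nd343 + 1.0 * .unitv(c(0.2, -0.8, -0.6))
  addAtom("HD21", "ASN", 343L, "H", hd343[1L], hd343[2L], hd343[3L])
  # Aromatic pair lining the pocket: Phe243 5.47 / Phe340 6.52 (parallel
  # rings 3.6 A apart -> pi-stacked in the base scaffold)
  addAtom("CA", "PHE", 243L, "C", -3.8, -1.8, 1.2)
  addRing("PHE", 243L, c(-2.5, -1.5, 1.0))
  addAtom("CA", "PHE", 340L, "C", -3.8, -1.2, 4.9)
  addRing("PHE", 340L, c(-2.5, -1.5, 4.6))

  ## --- sodium pocket -----------------------------------------------------
  aspOD1 <- c(-1.2, 0.4, -2.0)
  aspOD2 <- c(-1.6, -0.7, -2.8)
  addAtom("CA", "ASP", 120L, "C", -3.0, 0.0, -2.0)
  addAtom("CB", "ASP", 120L, "C", -2.2, 0.3, -2.6)
  addAtom("CG", "ASP", 120L, "C", -1.6, 0.3, -2.3)
  addAtom("OD1", "ASP", 120L, "O", aspOD1[1L], aspOD1[2L], aspOD1[3L])
  addAtom("OD2", "ASP", 120L, "O", aspOD2[1L], aspOD2[2L], aspOD2[3L])
  naPocket <- aspOD1 + c(2.3, 0, 0)
  naPos <- if (tp$na_in_pocket) naPocket else c(20.0, -20.0, 5.0)
  # Phe332 6.44 aromatic lid above the ion
  addAtom("CA", "PHE", 332L, "C", 2.4, 1.5, 1.2)
  addRing("PHE", 332L, naPocket + c(0, 0.3, 2.5))
  # Trp336 6.48 toggle: chi1/chi2 realized exactly via NeRF placement
  trpCA <- c(0.0, -3.0, 1.0)
  trpN <- trpCA + 1.46 * .unitv(c(-0.8, -1.0, -0.6))
  trpCB <- trpCA + 1.53 * .unitv(c(0.3, 0.9, 0.3))
  addAtom("N", "TRP", 336L, "N", trpN[1L], trpN[2L], trpN[3L])
  addAtom("CA", "TRP", 336L, "C", trpCA[1L], trpCA[2L], trpCA[3L])
  addAtom("CB", "TRP", 336L, "C", trpCB[1L], trpCB[2L], trpCB[3L])
  trpCG <- .placeAtomNeRF(trpN, trpCA, trpCB, 1.50, 113, tp$chi1)
  addAtom("CG", "TRP", 336L, "C", trpCG[1L], trpCG[2L], trpCG[3L])
  trpCD1 <- .placeAtomNeRF(trpCA, trpCB, trpCG, 1.37, 127, tp$chi2)
  addAtom("CD1", "TRP", 336L, "C", trpCD1[1L], trpCD1[2L], trpCD1[3L])
  # Asn380 7.49: side-chain amide donating to the Asp120 carboxylate
  uAsn <- .unitv(c(-1.6, -1.1, -1.2))
  nd380 <- aspOD2 + 2.9 * uAsn
  hd380 <- nd380 - 1.0 * uAsn
  addAtom("CG", "ASN", 380L, "C", nd380[1L] - 0.8, nd380[2L] - 0.4,
          nd380[3L] - 0.6)
  addAtom("OD1", "ASN", 380L, "O", nd380[1L] - 1.3, nd380[2L] + 0.5,
          nd380[3L] - 0.9)
  addAtom("ND2", "ASN", 380L, "N", nd380[1L], nd380[2L], nd380[3L])
  addAtom("HD21", "ASN", 380L, "H", hd380[1L], hd380[2L], hd380[3L])
  addAtom("CA", "ASN", 380L, "C", -4.0, -2.0, -4.5)

  ## --- vestibule + TM bundle --------------------------------------------
  addAtom("CA", "GLY", 501L, "C", 1.0, 0.5, 14.0)
  addAtom("CA", "GLY", 502L, "C", -1.0, -0.5, 14.0)
  resn <- 601L
  for (h in 0:6) {
    th <- 2 * pi * h / 7
    for (z in c(-12, -6, 0, 6)) {
      addAtom("CA", "GLY", resn, "C", 6 * cos(th), 6 * sin(th), z)
      resn <- resn + 1L
    }
  }

  ## --- ligand ------------------------------------------------------------
  # protonated amine N placed exactly 3.0 A from the Asp155 OD1 (salt bridge)
  uSB <- .unitv(c(-1.0, 0.3, 0.6))
  ligN <- c(1.4, 0.0, 4.0) + 3.0 * uSB   # Asp155 OD1 + 3 A
  addAtom("N", "LIG", 900L, "N", ligN[1L], ligN[2L], ligN[3L])
  # planar 9-atom indole core in the xz-plane at y = 1.5
  core2d <- rbind(N1 = c(3.45, -0.3), C2 = c(2.7, -1.2), C3 = c(2.6, 0.7),
                  C3A = c(1.4, 0.0), C4 = c(0.7, 1.21), C5 = c(-0.7, 1.21),
                  C6 = c(-1.4, 0.0), C7 = c(-0.7, -1.21),
                  C7A = c(0.7, -1.21))
  for (nm in rownames(core2d))
    addAtom(nm, "LIG", 900L, if (nm == "N1") "N" else "C",
            0.5 + core2d[nm, 1L], 1.5, 4.5 + core2d[nm, 2L])
  n1 <- c(0.5 + core2d["N1", 1L], 1.5, 4.5 + core2d["N1", 2L])
  hn1 <- n1 + 1.0 * .unitv(og1 - n1)
  addAtom("HN1", "LIG", 900L, "H", hn1[1L], hn1[2L], hn1[3L])
  addAtom("O1", "LIG", 900L, "O", o1base[1L], o1base[2L], o1base[3L])

  ## --- ion + water pool ---------------------------------------------------
  addAtom("NA", "NA", 920L, "NA", naPos[1L], naPos[2L], naPos[3L])
  for (i in seq_len(.N_SHELL_SLOTS)) {
    p <- if (i <= tp$n_shell) naPocket + 2.4 * .SHELL_DIRS[i, ]
    else c(40 + 5 * i, 40, 40)
    addAtom("O", "HOH", 700L + i, "O", p[1L], p[2L], p[3L])
  }
  chain <- .channelChain()
  for (i in seq_len(nrow(chain))) {
    p <- if (tp$channel) chain[i, ] else c(40 + 5 * i, -40, 40)
    addAtom("O", "HOH", 720L + i, "O", p[1L], p[2L], p[3L])
  }

  top <- do.call(rbind, lapply(rows, function(r)
    data.frame(name = r$name, resname = r$resname, resnum = r$resnum,
               chain = "A", element = r$element, stringsAsFactors = FALSE)))
  top <- cbind(serial = seq_len(nrow(top)), top)
  top <- top[, c("serial", "name", "resname", "resnum", "chain", "element")]
  xyz <- do.call(rbind, lapply(rows, function(r) c(r$x, r$y, r$z)))
  list(topology = top, xyz = xyz, naPocket = naPocket)
}

## Linear water chain joining the extracellular vestibule to the sodium
## pocket, spaced under the 3.5 A O-O edge cutoff.
.channelChain <- function() {
  s <- c(1.0, 0.5, 12.5)       # within 4 A of a vestibule C-alpha
  e <- c(-1.5, 0.4, 1.0)       # within 4 A of the Asp120 carboxylate,
                               # outside the Na+ first shell
  len <- sqrt(sum((e - s)^2))
  n <- ceiling(len / 2.7) + 1L
  t(vapply(seq_len(n), function(i) s + (e - s) * (i - 1) / (n - 1),
           numeric(3)))
}

#' Residue map matching the synthetic scaffold
#'
#' Loads the packaged annotation config for the synthetic receptor scaffold
#' (5-HT2A numbering: Asp155 3.32, Thr160 3.37, Arg173 3.50, Glu318 6.30,
#' Cys322 6.34, Trp336 6.48, Asp120 2.50, Asn380 7.49, Ser162 3.39,
#' Phe332 6.44, Ser239 5.44, Ser242 5.46, Asn343 6.55, Asp231 5.35).
#'
#' @return a [ResidueMap-class].
#' @export
scaffoldResidueMap <- function() {
  loadResidueMap(system.file("extdata", "residue_map_5ht2a_synthetic.yaml",
                             package = "GPCRswitch", mustWork = TRUE))
}

#' Construct a FixtureSpec
#'
#' @param name fixture name.
#' @param nFrames number of frames.
#' @param seed integer seed for the satisfaction pattern.
#' @param template "inactive" or "active".
#' @param targets named list of target declarations (see
#'   [generateFixture()]).
#' @return a [FixtureSpec-class].
#' @export
fixtureSpec <- function(name, nFrames, seed, template = "inactive",
                        targets = list()) {
  new("FixtureSpec", name = name, nFrames = as.integer(nFrames),
      seed = as.integer(seed), template = template, targets = targets)
}

#' Load the packaged paper-profile fixture specs
#'
#' The packaged config declares the named fixtures whose ground-truth
#' fractions drive the headline occupancy and pose statistics (e.g.
#' `trans1_thr160`, `trans1_asp155`, `trans1_asp231`, `cis1_rmsdi`,
#' `trans2_rmsdi`, `cis2_thr160_active`).
#'
#' @param name fixture name; with NULL, all specs are returned as a list.
#' @param path fixture config; defaults to the packaged paper-profile file.
#' @return a [FixtureSpec-class] (or named list of them).
#' @export
paperFixtureSpec <- function(name = NULL, path = NULL) {
  path <- path %||% system.file("extdata", "paper_profile_fixtures.yaml",
                                package = "GPCRswitch", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  specs <- lapply(names(cfg$fixtures), function(nm) {
    f <- cfg$fixtures[[nm]]
    fixtureSpec(nm, f$n_frames, f$seed, f$template %||% "inactive",
                f$targets)
  })
  names(specs) <- names(cfg$fixtures)
  if (is.null(name)) return(specs)
  if (!name %in% names(specs))
    .err(paste("unknown fixture spec:", name), "spec_error")
  specs[[name]]
}

## atoms a target drives, as "resnum|name" keys, for contradiction checks
.drivenAtomKeys <- function(tg, top) {
  key <- function(resnum, name) paste(resnum, name, sep = "|")
  lig <- function() key(top$resnum[top$resname == "LIG"],
                        top$name[top$resname == "LIG"])
  switch(tg$kind,
    hbond = {
      k <- key(tg$acceptor$resnum, tg$acceptor$name)
      for (r in tg$riders %||% list()) k <- c(k, key(r$resnum, r$name))
      k
    },
    salt_bridge = key(tg$basic$resnum, tg$basic$name),
    rmsd_below = lig(),
    dtm_dil = c(key(322L, "CA"), key(318L, c("OE1", "OE2", "CA"))),
    chi = key(336L, c("CG", "CD1")),
    shell_waters = key(701L:(700L + .N_SHELL_SLOTS), "O"),
    channel = key(721L:(720L + nrow(.channelChain())), "O"),
    asn_hbond = key(380L, c("ND2", "HD21")),
    .err(paste("unknown target kind:", tg$kind), "spec_error"))
}

.atomRow <- function(top, resnum, name) {
  i <- which(top$resnum == resnum & top$name == name)
  .assert(length(i) == 1L, sprintf("scaffold atom %d/%s not unique", resnum,
                                   name))
  i
}

## expand a scalar or length-n schedule to length n
.expandSchedule <- function(x, n, what) {
  x <- as.numeric(x)
  if (length(x) == 1L) return(rep(x, n))
  .assert(length(x) == n, paste("schedule", what,
                                "must have length 1 or nFrames"))
  x
}

#' Generate a synthetic fixture trajectory with exact ground truth
#'
#' Target kinds (entries of `spec@targets`, each a list with `kind`):
#' \describe{
#'   \item{hbond}{`donor`, `hydrogen`, `acceptor` as `list(resnum=, name=)`,
#'     optional `riders`; `fraction`.  In satisfying frames the acceptor is
#'     placed 2.8 A from the donor along the donor-hydrogen axis (angle 180
#'     degrees); otherwise 5.5 A.}
#'   \item{salt_bridge}{`basic`, `acidic` atom refs and `fraction`; the basic
#'     nitrogen is placed 3.0 A (satisfying) or 6.0 A from the acidic oxygen.}
#'   \item{rmsd_below}{`fraction`; the whole ligand is displaced rigidly by
#'     0.5 A (below the 2 A pose criterion) or 3.0 A (above).}
#'   \item{dtm_dil}{`d_tm`, `d_il` schedules (scalar or per frame, A).}
#'   \item{chi}{`chi1`, `chi2` schedules (degrees).}
#'   \item{shell_waters}{`counts` schedule of first-shell water counts.}
#'   \item{channel}{`open` logical schedule for the vestibule-to-pocket
#'     water chain.}
#'   \item{asn_hbond}{`intact` logical schedule for the Asn7.49-Asp2.50
#'     hydrogen bond.}
#' }
#' Frames satisfying a fraction target are a seeded pseudo-random
#' permutation prefix of the frame indices, so exactly `round(fraction *
#' nFrames)` frames satisfy the criterion and the realized occupancy is
#' exact.  Two targets driving the same atom are rejected.
#'
#' @param spec a [FixtureSpec-class].
#' @param dir output directory (created if needed).
#' @return a [FixtureManifest-class]; writes `<name>.pdb`,
#'   `<name>_manifest.json` and `<name>_map.yaml` under `dir`.
#' @export
generateFixture <- function(spec, dir = tempdir()) {
  ok <- validObject(spec, test = TRUE)
  if (!isTRUE(ok)) .err(paste(ok, collapse = "; "), "spec_error")
  sc <- .buildScaffold(spec@template)
  top <- sc$topology
  n <- spec@nFrames

  driven <- character()
  for (nm in names(spec@targets)) {
    k <- .drivenAtomKeys(spec@targets[[nm]], top)
    clash <- intersect(driven, k)
    if (length(clash))
      .err(paste0("contradictory targets: atoms driven twice (",
                  paste(clash, collapse = ", "), ")"), "spec_error")
    driven <- c(driven, k)
  }

  ## precompute per-target plans
  plans <- list()
  groundTruth <- list()
  for (nm in names(spec@targets)) {
    tg <- spec@targets[[nm]]
    plan <- list(kind = tg$kind)
    if (tg$kind %in% c("hbond", "salt_bridge", "rmsd_below")) {
      nSat <- round(tg$fraction * n)
      perm <- .withSeed(spec@seed, sample.int(n))
      sat <- logical(n)
      sat[perm[seq_len(nSat)]] <- TRUE
      plan$sat <- sat
      groundTruth[[nm]] <- list(kind = tg$kind, n_frames = n,
                                n_satisfied = nSat,
                                fraction_target = tg$fraction,
                                occupancy_percent = 100 * nSat / n)
    }
    if (tg$kind == "hbond") {
      plan$d <- .atomRow(top, tg$donor$resnum, tg$donor$name)
      plan$h <- .atomRow(top, tg$hydrogen$resnum, tg$hydrogen$name)
      plan$a <- .atomRow(top, tg$acceptor$resnum, tg$acceptor$name)
      plan$riders <- vapply(tg$riders %||% list(), function(r)
        .atomRow(top, r$resnum, r$name), integer(1))
    } else if (tg$kind == "salt_bridge") {
      plan$b <- .atomRow(top, tg$basic$resnum, tg$basic$name)
      plan$aO <- .atomRow(top, tg$acidic$resnum, tg$acidic$name)
      plan$u <- .unitv(sc$xyz[plan$b, ] - sc$xyz[plan$aO, ])
    } else if (tg$kind == "rmsd_below") {
      plan$lig <- which(top$resname == "LIG")
    } else if (tg$kind == "dtm_dil") {
      plan$d_tm <- .expandSchedule(tg$d_tm, n, "d_tm")
      plan$d_il <- .expandSchedule(tg$d_il, n, "d_il")
      plan$cys <- .atomRow(top, 322L, "CA")
      plan$arg <- .atomRow(top, 173L, "CA")
      plan$nh1 <- .atomRow(top, 173L, "NH1")
      plan$glu <- c(.atomRow(top, 318L, "OE1"), .atomRow(top, 318L, "OE2"),
                    .atomRow(top, 318L, "CA"))
      groundTruth[[nm]] <- list(kind = "dtm_dil", d_tm = plan$d_tm,
                                d_il = plan$d_il)
    } else if (tg$kind == "chi") {
      plan$chi1 <- .expandSchedule(tg$chi1, n, "chi1")
      plan$chi2 <- .expandSchedule(tg$chi2, n, "chi2")
      plan$trp <- vapply(c("N", "CA", "CB", "CG", "CD1"), function(a)
        .atomRow(top, 336L, a), integer(1))
      groundTruth[[nm]] <- list(kind = "chi", chi1 = plan$chi1,
                                chi2 = plan$chi2)
    } else if (tg$kind == "shell_waters") {
      plan$counts <- as.integer(.expandSchedule(tg$counts, n, "counts"))
      .assert(all(plan$counts <= .N_SHELL_SLOTS),
              paste("at most", .N_SHELL_SLOTS, "first-shell waters supported"))
      plan$wat <- vapply(seq_len(.N_SHELL_SLOTS), function(i)
        .atomRow(top, 700L + i, "O"), integer(1))
      groundTruth[[nm]] <- list(kind = "shell_waters", counts = plan$counts)
    } else if (tg$kind == "channel") {
      plan$open <- as.logical(.expandSchedule(tg$open, n, "open"))
      plan$chain <- .channelChain()
      plan$wat <- vapply(seq_len(nrow(plan$chain)), function(i)
        .atomRow(top, 720L + i, "O"), integer(1))
      groundTruth[[nm]] <- list(kind = "channel", open = plan$open)
    } else if (tg$kind == "asn_hbond") {
      plan$intact <- as.logical(.expandSchedule(tg$intact, n, "intact"))
      plan$nd <- .atomRow(top, 380L, "ND2")
      plan$hd <- .atomRow(top, 380L, "HD21")
      plan$od <- .atomRow(top, 120L, "OD2")
      groundTruth[[nm]] <- list(kind = "asn_hbond", intact = plan$intact)
    }
    plans[[nm]] <- plan
  }

  coords <- array(NA_real_, dim = c(nrow(top), 3L, n))
  for (k in seq_len(n)) {
    xyz <- sc$xyz
    for (nm in names(plans)) {
      p <- plans[[nm]]
      xyz <- switch(p$kind,
        hbond = {
          u <- .unitv(sc$xyz[p$h, ] - sc$xyz[p$d, ])
          tgt <- sc$xyz[p$d, ] + (if (p$sat[k]) 2.8 else 5.5) * u
          delta <- tgt - sc$xyz[p$a, ]
          for (i in c(p$a, p$riders)) xyz[i, ] <- sc$xyz[i, ] + delta
          xyz
        },
        salt_bridge = {
          xyz[p$b, ] <- sc$xyz[p$aO, ] + (if (p$sat[k]) 3.0 else 6.0) * p$u
          xyz
        },
        rmsd_below = {
          shift <- if (p$sat[k]) 0.5 else 3.0
          xyz[p$lig, 1L] <- sc$xyz[p$lig, 1L] + shift
          xyz
        },
        dtm_dil = {
          xyz[p$cys, ] <- sc$xyz[p$arg, ] + c(0, p$d_tm[k], 0)
          oe1 <- sc$xyz[p$nh1, ] + c(p$d_il[k], 0, 0)
          base <- sc$xyz[p$glu[1L], ]
          for (j in seq_along(p$glu))
            xyz[p$glu[j], ] <- oe1 + (sc$xyz[p$glu[j], ] - base)
          xyz
        },
        chi = {
          cg <- .placeAtomNeRF(xyz[p$trp[1L], ], xyz[p$trp[2L], ],
                               xyz[p$trp[3L], ], 1.50, 113, p$chi1[k])
          xyz[p$trp[4L], ] <- cg
          xyz[p$trp[5L], ] <- .placeAtomNeRF(xyz[p$trp[2L], ],
                                             xyz[p$trp[3L], ], cg,
                                             1.37, 127, p$chi2[k])
          xyz
        },
        shell_waters = {
          for (i in seq_len(.N_SHELL_SLOTS)) {
            xyz[p$wat[i], ] <- if (i <= p$counts[k])
              sc$naPocket + 2.4 * .SHELL_DIRS[i, ]
            else c(40 + 5 * i, 40, 40)
          }
          xyz
        },
        channel = {
          for (i in seq_along(p$wat)) {
            xyz[p$wat[i], ] <- if (p$open[k]) p$chain[i, ]
            else c(40 + 5 * i, -40, 40)
          }
          xyz
        },
        asn_hbond = {
          if (!p$intact[k]) {
            u <- .unitv(sc$xyz[p$nd, ] - sc$xyz[p$od, ])
            xyz[p$nd, ] <- sc$xyz[p$nd, ] + 3.5 * u
            xyz[p$hd, ] <- sc$xyz[p$hd, ] + 3.5 * u
          }
          xyz
        })
    }
    coords[, , k] <- xyz
  }

  traj <- new("Trajectory", topology = top, coords = coords,
              timeNs = (seq_len(n) - 1) * 1.0, strideNs = 1.0,
              topologyHash = .topologyHash(top))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pdbPath <- file.path(dir, paste0(spec@name, ".pdb"))
  writeMultimodelPDB(traj, pdbPath)
  mapPath <- file.path(dir, paste0(spec@name, "_map.yaml"))
  writeResidueMap(scaffoldResidueMap(), mapPath)
  manifestPath <- file.path(dir, paste0(spec@name, "_manifest.json"))
  manifest <- new("FixtureManifest", spec = spec,
                  files = c(trajectory = pdbPath, residue_map = mapPath,
                            manifest = manifestPath),
                  groundTruth = groundTruth)
  jsonlite::write_json(
    list(name = spec@name, n_frames = n, seed = spec@seed,
         template = spec@template,
         files = as.list(manifest@files), ground_truth = groundTruth),
    manifestPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Single-frame anchor fixtures for the two reference states
#'
#' Builds one frame realizing the inactive reference tuple exactly (d_TM
#' 9 A, d_IL 4 A, chi1 -80 deg, Na+ coordinated with two shell waters) and
#' one realizing the active tuple (12 A, 16 A, -160 deg, Na+ out of the
#' pocket).
#'
#' @return list with elements `inactive` and `active`, each a single-frame
#'   [Trajectory-class].
#' @export
anchorFrames <- function() {
  build <- function(template) {
    sc <- .buildScaffold(template)
    new("Trajectory", topology = sc$topology,
        coords = array(sc$xyz, dim = c(nrow(sc$xyz), 3L, 1L)),
        timeNs = 0, strideNs = 1.0, topologyHash = .topologyHash(sc$topology))
  }
  list(inactive = build("inactive"), active = build("active"))
}

#' Reference core mapping for the synthetic scaffold
#'
#' The ligand indole core of the scaffold's base pose serves as the
#' reference agonist core (a synthetic stand-in for the tetracyclic core of
#' LSD, packaged as a PDB fragment); frames are superposed on the TM-bundle
#' C-alpha atoms.
#'
#' @return a [CoreMapping-class].
#' @export
scaffoldCoreMapping <- function() {
  ref <- readMultimodelPDB(system.file("extdata",
                                       "reference_core_synthetic.pdb",
                                       package = "GPCRswitch",
                                       mustWork = TRUE))
  sc <- .buildScaffold("inactive")
  fitQuery <- "resname GLY and name CA"
  fitIdx <- selectAtoms(sc$topology, fitQuery)
  coreMapping(referenceCore = frameCoords(ref, 1L),
              coreAtomNames = topology(ref)$name,
              fitQuery = fitQuery,
              referenceFit = sc$xyz[fitIdx, , drop = FALSE])
}
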