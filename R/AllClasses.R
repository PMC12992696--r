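#' @import methods
NULL

## Central containers. Coordinates are Angstrom throughout; the membrane
## normal is +z pointing extracellular unless a receptor axis is computed
## explicitly (see receptorAxis()).

#' Trajectory: an ordered stack of frames over one topology
#'
#' A `Trajectory` holds a topology table (one row per atom: serial, name,
#' resname, resnum, chain, element) and an `nAtoms x 3 x nFrames` coordinate
#' array in Angstrom, plus the frame times in nanoseconds.  Atom ordering is
#' identical across frames; the topology hash is a digest of the atom
#' identity sequence used to detect mismatched topologies cheaply.
#'
#' @slot topology data.frame with columns serial, name, resname, resnum,
#'   chain, element.
#' @slot coords numeric array, `nAtoms x 3 x nFrames`, Angstrom.
#' @slot timeNs numeric vector of frame times, ns, strictly increasing.
#' @slot strideNs single positive numeric, ns between frames.
#' @slot topologyHash character(1), digest of the atom identity sequence.
#' @exportClass Trajectory
setClass("Trajectory",
  representation(
    topology = "data.frame",
    coords = "array",
    timeNs = "numeric",
    strideNs = "numeric",
    topologyHash = "character"
  )
)

setValidity("Trajectory", function(object) {
  msgs <- character()
  top <- object@topology
  need <- c("serial", "name", "resname", "resnum", "chain", "element")
  if (!all(need %in% names(top)))
    msgs <- c(msgs, paste("topology must have columns:",
                          paste(need, collapse = ", ")))
  d <- dim(object@coords)
  if (length(d) != 3L || d[2L] != 3L)
    msgs <- c(msgs, "coords must be an nAtoms x 3 x nFrames array")
  else {
    if (d[1L] != nrow(top))
      msgs <- c(msgs, "coords atom dimension does not match topology")
    if (d[3L] < 1L) msgs <- c(msgs, "trajectory must have at least one frame")
    if (length(object@timeNs) != d[3L])
      msgs <- c(msgs, "timeNs length must equal the number of frames")
  }
  if (!all(is.finite(object@coords)))
    msgs <- c(msgs, "coordinates must be finite")
  if (length(object@timeNs) > 1L && any(diff(object@timeNs) <= 0))
    msgs <- c(msgs, "frame times must be strictly increasing")
  if (length(object@strideNs) != 1L || !is.finite(object@strideNs) ||
      object@strideNs <= 0)
    msgs <- c(msgs, "strideNs must be a single positive number")
  if (all(need %in% names(top)) && nrow(top) > 0L) {
    key <- paste(top$chain, top$resnum, top$name)
    if (anyDuplicated(key))
      msgs <- c(msgs, "(chain, resnum, name) must be unique within a frame")
    if (any(!nzchar(top$element)))
      msgs <- c(msgs, "element must be non-empty for every atom")
  }
  if (length(msgs)) msgs else TRUE
})

#' ResidueMap: Ballesteros-Weinstein annotation bound to concrete atoms
#'
#' Binds the receptor roles the analyses need (toggle switch, ionic-lock
#' partners, sodium-site residues, polar triad, anchor, depth anchor, base of
#' the pocket, vestibule reference and TM-bundle membership) to residue
#' numbers, and names the functional ligand atoms (protonated amine nitrogen,
#' indole N1-H, methoxy oxygen, aromatic core atoms).
#'
#' @slot residues data.frame with columns resnum, chain, resname, bw, role.
#' @slot ligandResname character(1) ligand residue name.
#' @slot ligandChain character(1) ligand chain id.
#' @slot ligandAtomRoles named list, role -> character vector of atom names.
#' @exportClass ResidueMap
setClass("ResidueMap",
  representation(
    residues = "data.frame",
    ligandResname = "character",
    ligandChain = "character",
    ligandAtomRoles = "list"
  )
)

## Receptor roles that must appear exactly once; the BW index each one is
## expected to carry in a class A receptor is documented in loadResidueMap().
.REQUIRED_ROLES <- c(
  "toggle",         # 6.48 Trp toggle switch
  "ionic_lock_arg", # 3.50
  "ionic_lock_glu", # 6.30
  "tm6_ref",        # 6.34 (TM6 displacement partner of 3.50)
  "na_site",        # 2.50 Asp
  "na_stabilizer",  # 7.49 Asn
  "na_backup",      # 3.39 Ser
  "na_lid",         # 6.44 Phe
  "polar_ser1",     # 5.44
  "polar_ser2",     # 5.46
  "polar_asn",      # 6.55
  "anchor",         # 3.32 Asp
  "depth_anchor",   # 5.35
  "base"            # 3.37 Thr
)
.MULTI_ROLES <- c("vestibule", "tm", "hydrophobic")

.REQUIRED_LIGAND_ROLES <- c("amine_n", "indole_nh_n", "indole_nh_h",
                            "methoxy_o", "core")

setValidity("ResidueMap", function(object) {
  msgs <- character()
  res <- object@residues
  need <- c("resnum", "chain", "resname", "bw", "role")
  if (!all(need %in% names(res)))
    return(paste("residues must have columns:", paste(need, collapse = ", ")))
  bad <- setdiff(res$role, c(.REQUIRED_ROLES, .MULTI_ROLES))
  if (length(bad))
    msgs <- c(msgs, paste("unknown roles:", paste(unique(bad), collapse = ", ")))
  counts <- table(res$role)
  missing <- setdiff(.REQUIRED_ROLES, names(counts))
  if (length(missing))
    msgs <- c(msgs, paste("missing required roles:",
                          paste(missing, collapse = ", ")))
  dup <- intersect(.REQUIRED_ROLES, names(counts)[counts > 1L])
  if (length(dup))
    msgs <- c(msgs, paste("roles assigned more than once:",
                          paste(dup, collapse = ", ")))
  req <- res$role %in% .REQUIRED_ROLES
  if (any(req) && !all(grepl("^[0-9]+\\.[0-9]+$", res$bw[req])))
    msgs <- c(msgs, "bw index must match T.NN for required roles")
  missingLig <- setdiff(.REQUIRED_LIGAND_ROLES, names(object@ligandAtomRoles))
  if (length(missingLig))
    msgs <- c(msgs, paste("missing ligand atom roles:",
                          paste(missingLig, collapse = ", ")))
  if (length(object@ligandAtomRoles) &&
      length(object@ligandAtomRoles$core %||% character()) < 3L)
    msgs <- c(msgs, "ligand core must name at least 3 atoms")
  if (length(msgs)) msgs else TRUE
})

#' InteractionSpec: one named geometric interaction to monitor
#'
#' @slot kind one of "hbond", "salt_bridge", "hydrophobic", "pi_stack".
#' @slot label unique label for reports.
#' @slot selections named list of atom-selection query strings (see
#'   [selectAtoms()]); required names depend on `kind`.
#' @exportClass InteractionSpec
setClass("InteractionSpec",
  representation(kind = "character", label = "character",
                 selections = "list")
)

.SPEC_SELECTIONS <- list(
  hbond = c("donor", "hydrogen", "acceptor"),
  salt_bridge = c("basic", "acidic"),
  hydrophobic = c("group_a", "group_b"),
  pi_stack = c("ring_a", "ring_b")
)

setValidity("InteractionSpec", function(object) {
  msgs <- character()
  if (length(object@kind) != 1L || !object@kind %in% names(.SPEC_SELECTIONS))
    return(paste("kind must be one of:",
                 paste(names(.SPEC_SELECTIONS), collapse = ", ")))
  if (length(object@label) != 1L || !nzchar(object@label))
    msgs <- c(msgs, "label must be a non-empty string")
  need <- .SPEC_SELECTIONS[[object@kind]]
  missing <- setdiff(need, names(object@selections))
  if (length(missing))
    msgs <- c(msgs, paste0("kind '", object@kind, "' needs selections: ",
                           paste(missing, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' InteractionSeries: per-frame evaluation of one InteractionSpec
#'
#' @slot spec the [InteractionSpec-class] that was evaluated.
#' @slot present logical vector, one entry per frame.
#' @slot geometry numeric vector, the characteristic distance per frame
#'   (donor-acceptor, minimum inter-group, or centroid distance; Angstrom).
#' @exportClass InteractionSeries
setClass("InteractionSeries",
  representation(spec = "InteractionSpec", present = "logical",
                 geometry = "numeric")
)

setValidity("InteractionSeries", function(object) {
  if (length(object@present) != length(object@geometry))
    return("present and geometry must have equal length")
  TRUE
})

#' CoreMapping: how ligand core atoms map onto the reference agonist core
#'
#' Defines the indole-core RMSD comparison: which ligand atoms form the core,
#' the reference core coordinates they are compared to (the tetracyclic-core
#' substructure of the reference agonist, in the reference receptor frame),
#' and the receptor atoms used to superpose each trajectory frame onto that
#' reference frame.
#'
#' @slot referenceCore K x 3 matrix, Angstrom, reference core coordinates.
#' @slot coreAtomNames character(K), ligand atom names in reference order.
#' @slot fitQuery atom-selection query for the receptor superposition set.
#' @slot referenceFit M x 3 matrix, coordinates of the fit atoms in the
#'   reference structure (M >= 3).
#' @exportClass CoreMapping
setClass("CoreMapping",
  representation(referenceCore = "matrix", coreAtomNames = "character",
                 fitQuery = "character", referenceFit = "matrix")
)

setValidity("CoreMapping", function(object) {
  msgs <- character()
  if (nrow(object@referenceCore) != length(object@coreAtomNames))
    msgs <- c(msgs, "referenceCore rows must match coreAtomNames length")
  if (length(object@coreAtomNames) < 3L)
    msgs <- c(msgs, "core must have at least 3 atoms")
  if (nrow(object@referenceFit) < 3L)
    msgs <- c(msgs, "fit set must have at least 3 atoms")
  if (ncol(object@referenceCore) != 3L || ncol(object@referenceFit) != 3L)
    msgs <- c(msgs, "coordinate matrices must have 3 columns")
  if (length(msgs)) msgs else TRUE
})

#' FixtureSpec: declaration of a synthetic trajectory with exact ground truth
#'
#' @slot name fixture name (used for output file names).
#' @slot nFrames number of frames.
#' @slot seed integer seed controlling the satisfaction pattern.
#' @slot template "inactive" or "active" receptor template.
#' @slot targets named list of target declarations; see [generateFixture()].
#' @exportClass FixtureSpec
setClass("FixtureSpec",
  representation(name = "character", nFrames = "integer", seed = "integer",
                 template = "character", targets = "list")
)

setValidity("FixtureSpec", function(object) {
  msgs <- character()
  if (object@nFrames < 1L) msgs <- c(msgs, "nFrames must be >= 1")
  if (!object@template %in% c("inactive", "active"))
    msgs <- c(msgs, "template must be 'inactive' or 'active'")
  if (length(object@targets) &&
      (is.null(names(object@targets)) || any(!nzchar(names(object@targets)))))
    msgs <- c(msgs, "targets must be a named list")
  for (nm in names(object@targets)) {
    t <- object@targets[[nm]]
    if (!is.null(t$fraction) && (t$fraction < 0 || t$fraction > 1))
      msgs <- c(msgs, paste0("target '", nm, "': fraction must be in [0,1]"))
  }
  if (length(msgs)) msgs else TRUE
})

#' FixtureManifest: realized ground truth of a generated fixture
#'
#' @slot spec the [FixtureSpec-class] that was generated.
#' @slot files named character vector of output paths.
#' @slot groundTruth named list, per-target realized truth (exact counts).
#' @exportClass FixtureManifest
setClass("FixtureManifest",
  representation(spec = "FixtureSpec", files = "character",
                 groundTruth = "list")
)

#' RunReport: full per-system analysis output
#'
#' @slot occupancy data.frame of interaction occupancies.
#' @slot microswitches per-frame microswitch table.
#' @slot hydration per-frame sodium-pocket hydration table.
#' @slot poses per-frame pose-metric table (rmsd_i, depth).
#' @slot summary list of headline numbers (state fractions, pose fraction
#'   below threshold, mean depth, mean shell count, channel fraction).
#' @slot config list echoing the analysis configuration used.
#' @exportClass RunReport
setClass("RunReport",
  representation(occupancy = "data.frame", microswitches = "data.frame",
                 hydration = "data.frame", poses = "data.frame",
                 summary = "list", config = "list")
)
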