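#' @describeIn Trajectory-class number of frames
#' @param x,object a `Trajectory`
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @describeIn Trajectory-class number of atoms
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @describeIn Trajectory-class topology table (one row per atom)
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @describeIn Trajectory-class coordinates of frame `i` as an nAtoms x 3 matrix
#' @param i frame index (1-based)
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @describeIn Trajectory-class frame times in ns
#' @export
setGeneric("timeNs", function(x) standardGeneric("timeNs"))

#' @describeIn Trajectory-class frame stride in ns
#' @export
setGeneric("strideNs", function(x) standardGeneric("strideNs"))

#' @describeIn Trajectory-class digest of the atom identity sequence
#' @export
setGeneric("topologyHash", function(x) standardGeneric("topologyHash"))

#' @rdname occupancy
#' @export
setGeneric("occupancy", function(x, ...) standardGeneric("occupancy"))

setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[3L])
setMethod("nAtoms", "Trajectory", function(x) dim(x@coords)[1L])
setMethod("topology", "Trajectory", function(x) x@topology)
setMethod("frameCoords", "Trajectory", function(x, i) {
  .assert(i >= 1L && i <= nFrames(x), paste("frame index out of range:", i))
  x@coords[, , i, drop = TRUE]
})
setMethod("timeNs", "Trajectory", function(x) x@timeNs)
setMethod("strideNs", "Trajectory", function(x) x@strideNs)
setMethod("topologyHash", "Trajectory", function(x) x@topologyHash)

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nAtoms(object), "atoms x", nFrames(object), "frames\n")
  cat("  stride:", strideNs(object), "ns; time:",
      min(timeNs(object)), "-", max(timeNs(object)), "ns\n")
  res <- topology(object)
  cat("  residues:", length(unique(paste(res$chain, res$resnum))),
      " waters:", length(unique(res$resnum[.isWater(res)])),
      " ions:", length(.sodiumIdx(res)), "(Na+)\n")
  cat("  topology hash:", substr(topologyHash(object), 1, 12), "...\n")
})

setMethod("show", "ResidueMap", function(object) {
  res <- object@residues
  cat("ResidueMap:", nrow(res), "annotated residues; ligand",
      object@ligandResname, "chain", object@ligandChain, "\n")
  req <- res[res$role %in% .REQUIRED_ROLES, ]
  cat("  roles:", paste(sprintf("%s=%s%d(%s)", req$role, req$resname,
                                req$resnum, req$bw), collapse = ", "), "\n")
  cat("  ligand core atoms:",
      paste(object@ligandAtomRoles$core, collapse = " "), "\n")
})

setMethod("show", "InteractionSpec", function(object) {
  cat("InteractionSpec <", object@label, "> kind=", object@kind, "\n",
      sep = "")
  for (nm in names(object@selections))
    cat("  ", nm, ": ", object@selections[[nm]], "\n", sep = "")
})

setMethod("show", "InteractionSeries", function(object) {
  n <- length(object@present)
  occ <- if (n) 100 * sum(object@present) / n else NA_real_
  cat("InteractionSeries <", object@spec@label, ">: ", n, " frames, ",
      formatC(occ, format = "f", digits = 1), "% occupancy\n", sep = "")
})

setMethod("show", "FixtureSpec", function(object) {
  cat("FixtureSpec <", object@name, ">: ", object@nFrames, " frames, seed ",
      object@seed, ", template ", object@template, "\n", sep = "")
  for (nm in names(object@targets)) {
    t <- object@targets[[nm]]
    extra <- if (!is.null(t$fraction)) paste0(" fraction=", t$fraction) else ""
    cat("  target ", nm, ": kind=", t$kind, extra, "\n", sep = "")
  }
})

setMethod("show", "FixtureManifest", function(object) {
  cat("FixtureManifest <", object@spec@name, ">\n", sep = "")
  cat("  files:", paste(basename(object@files), collapse = ", "), "\n")
  for (nm in names(object@groundTruth)) {
    gt <- object@groundTruth[[nm]]
    if (!is.null(gt$occupancy_percent))
      cat(sprintf("  %s: %d/%d frames (%.1f%%)\n", nm, gt$n_satisfied,
                  gt$n_frames, gt$occupancy_percent))
    else cat("  ", nm, ": ", gt$kind %||% "schedule", "\n", sep = "")
  }
})

setMethod("show", "RunReport", function(object) {
  cat("RunReport:", nrow(object@microswitches), "frames analysed\n")
  if (nrow(object@occupancy)) {
    cat("  occupancies:\n")
    apply(object@occupancy, 1L, function(r)
      cat(sprintf("    %-32s %6.1f%%\n", r[["label"]],
                  as.numeric(r[["occupancy_percent"]]))))
  }
  s <- object@summary
  if (length(s)) {
    cat(sprintf("  activation: %.1f%% inactive / %.1f%% intermediate / %.1f%% active\n",
                s$state_fractions[["inactive"]],
                s$state_fractions[["intermediate"]],
                s$state_fractions[["active"]]))
    if (!is.null(s$rmsd_below_percent))
      cat(sprintf("  RMSD_i < %.1f A: %.1f%% of frames; mean depth %.2f A\n",
                  s$rmsd_threshold, s$rmsd_below_percent, s$mean_depth))
    cat(sprintf("  Na+ shell: %.2f waters (mean); channel open %.1f%% of frames\n",
                s$mean_shell_count, s$channel_percent))
  }
  invisible(NULL)
})
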