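## End-to-end orchestration: interaction occupancies, microswitch series,
## hydration series and pose metrics for one system, plus side-by-side
## comparison of systems.  Every number in a RunReport is reproducible by
## calling the underlying module operation directly; the pipeline adds no
## computation of its own.

#' Default interaction specs for the synthetic scaffold
#'
#' The monitored network mirrors the canonical 5-HT2A binding-pocket
#' fingerprint: the indole N1-H bond to the pocket base Thr 3.37, the
#' conserved protonated-amine salt bridge to Asp 3.32, the methoxy hydrogen
#' bonds to the Asp 5.35 backbone and to Thr 3.37, ligand-core hydrophobic
#' contacts, and the Phe 5.47 / Phe 6.52 aromatic stack.
#'
#' @return list of [InteractionSpec-class].
#' @export
scaffoldInteractionSpecs <- function() {
  ring <- "name CG,CD1,CE1,CZ,CE2,CD2"
  list(
    interactionSpec("hbond", "lig:N1H-Thr160^3.37",
                    donor = "resname LIG and name N1",
                    hydrogen = "resname LIG and name HN1",
                    acceptor = "resnum 160 and name OG1"),
    interactionSpec("salt_bridge", "lig:amine-Asp155^3.32",
                    basic = "resname LIG and name N",
                    acidic = "resnum 155 and name OD1,OD2"),
    interactionSpec("hbond", "lig:O1-Asp231^5.35",
                    donor = "resnum 231 and name N",
                    hydrogen = "resnum 231 and name H",
                    acceptor = "resname LIG and name O1"),
    interactionSpec("hbond", "lig:O1-Thr160^3.37",
                    donor = "resnum 160 and name OG1",
                    hydrogen = "resnum 160 and name HG1",
                    acceptor = "resname LIG and name O1"),
    interactionSpec("hydrophobic", "lig:core-hydrophobic",
                    group_a = "resname LIG and element C",
                    group_b = "resnum 156,159,230,235 and name CB"),
    interactionSpec("pi_stack", "Phe243^5.47-Phe340^6.52",
                    ring_a = paste("resnum 243 and", ring),
                    ring_b = paste("resnum 340 and", ring))
  )
}

#' Run the full analysis on one trajectory
#'
#' Computes the interaction occupancy table, the per-frame microswitch and
#' hydration tables, and (when a core mapping is supplied) the per-frame
#' pose metrics, then summarises activation-label fractions, the
#' agonist-compatible pose fraction and the hydration headline numbers.
#' With `outDir`, tables are written as CSV and the whole report as JSON;
#' identical inputs produce byte-identical outputs, and partial outputs are
#' removed if any stage fails.
#'
#' @param traj a [Trajectory-class] or path to a multi-model PDB file.
#' @param map a [ResidueMap-class] or path to a residue-map YAML.
#' @param specs list of [InteractionSpec-class] (may be empty).
#' @param coreMap a [CoreMapping-class] or NULL to skip pose metrics.
#' @param params geometric preset, see [preset()].
#' @param outDir output directory, or NULL for no files.
#' @param system label for this system in comparisons.
#' @param strideNs frame stride when `traj` is a path.
#' @return a [RunReport-class].
#' @export
runAnalysis <- function(traj, map, specs = scaffoldInteractionSpecs(),
                        coreMap = NULL, params = preset(), outDir = NULL,
                        system = "system", strideNs = 1.0) {
  if (is.character(traj)) traj <- readMultimodelPDB(traj, strideNs)
  if (is.character(map)) map <- loadResidueMap(map)
  top <- topology(traj)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .err(paste0("stage '", name, "': ", conditionMessage(e)),
           "pipeline_error"))
  }
  occ <- stage("interactions", occupancyTable(interactionSeries(traj, specs,
                                                                params)))
  ms <- stage("microswitches",
              microswitchSeries(traj, map, params,
                                microswitchReferences(params)))
  hyd <- stage("hydration", hydrationSeries(traj, map, params))
  poses <- data.frame(frame = ms$frame, time_ns = ms$time_ns)
  rmsdBelow <- NULL
  meanDepth <- NULL
  if (!is.null(coreMap)) {
    poses$rmsd_i <- stage("pose_rmsd", rmsdISeries(traj, coreMap))
    poses$depth <- stage("pose_depth", vapply(seq_len(nFrames(traj)),
      function(k) {
        xyz <- traj@coords[, , k]
        insertionDepth(xyz, top, map, receptorAxis(xyz, top, map))
      }, numeric(1)))
    rmsdBelow <- fractionBelow(poses$rmsd_i, params$rmsd_threshold)
    meanDepth <- mean(poses$depth)
  }
  stateFractions <- vapply(c("inactive", "intermediate", "active"),
                           function(l) 100 * sum(ms$label == l) / nrow(ms),
                           numeric(1))
  summary <- list(
    system = system,
    n_frames = nFrames(traj),
    state_fractions = as.list(stateFractions),
    mean_shell_count = mean(hyd$n_water_first_shell),
    channel_percent = 100 * sum(hyd$channel) / nrow(hyd),
    rmsd_threshold = params$rmsd_threshold,
    rmsd_below_percent = rmsdBelow,
    mean_depth = meanDepth,
    occupancy = stats::setNames(as.list(occ$occupancy_percent), occ$label)
  )
  report <- new("RunReport", occupancy = occ, microswitches = ms,
                hydration = hyd, poses = poses, summary = summary,
                config = list(preset = params$name, version = params$version,
                              overridden = params$overridden %||% character(),
                              system = system))
  if (!is.null(outDir)) .writeReport(report, outDir)
  report
}

.writeReport <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(outDir, c("occupancy.csv", "microswitches.csv",
                               "hydration.csv", "poses.csv", "report.json"))
  ok <- FALSE
  on.exit(if (!ok) unlink(paths), add = TRUE)
  utils::write.csv(report@occupancy, paths[1L], row.names = FALSE)
  utils::write.csv(report@microswitches, paths[2L], row.names = FALSE)
  utils::write.csv(report@hydration, paths[3L], row.names = FALSE)
  utils::write.csv(report@poses, paths[4L], row.names = FALSE)
  jsonlite::write_json(list(summary = report@summary,
                            config = report@config),
                       paths[5L], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  ok <- TRUE
  invisible(paths)
}

#' Summary list of a RunReport (raw, unrounded values)
#' @param report a [RunReport-class].
#' @return named list.
#' @export
reportSummary <- function(report) report@summary

#' Compare analysed systems side by side
#'
#' Builds a table of the occupancies shared by all reports together with the
#' activation-label fractions and pose metrics, ranked by mean insertion
#' depth (deepest first) and by active-state fraction.  Ties keep the input
#' order.
#'
#' @param reports named list of [RunReport-class] (>= 2).
#' @return data.frame, one row per system, with `rank_depth` and
#'   `rank_activation` columns.
#' @export
compareSystems <- function(reports) {
  .assert(length(reports) >= 2L, "need at least two reports to compare")
  if (is.null(names(reports)))
    names(reports) <- vapply(reports, function(r)
      r@summary$system %||% "system", character(1))
  labelSets <- lapply(reports, function(r) r@occupancy$label)
  shared <- Reduce(intersect, labelSets)
  if (length(unlist(labelSets)) && !length(shared))
    .err("reports share no interaction labels", "comparison_error")
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    s <- r@summary
    row <- data.frame(system = nm,
                      mean_depth = s$mean_depth %||% NA_real_,
                      rmsd_below_percent = s$rmsd_below_percent %||% NA_real_,
                      inactive_percent = s$state_fractions$inactive,
                      active_percent = s$state_fractions$active,
                      mean_shell_count = s$mean_shell_count,
                      channel_percent = s$channel_percent,
                      stringsAsFactors = FALSE)
    for (lab in shared)
      row[[paste0("occ:", lab)]] <-
        r@occupancy$occupancy_percent[r@occupancy$label == lab]
    row
  })
  out <- do.call(rbind, rows)
  depth <- ifelse(is.na(out$mean_depth), -Inf, out$mean_depth)
  out$rank_depth <- rank(-depth, ties.method = "first")
  out$rank_activation <- rank(-out$active_percent, ties.method = "first")
  out[order(out$rank_depth), , drop = FALSE]
}
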