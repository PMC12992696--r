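# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, msg, class = "gpcrswitch_error") {
  if (!isTRUE(cond)) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  invisible(TRUE)
}

.err <- function(msg, class) {
  stop(structure(class = c(class, "gpcrswitch_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.unitv <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) .err("cannot normalise a zero-length vector", "geometry_error")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' @noRd
#' md5 of the atom-identity sequence; used to detect topology drift between
#' frames and trajectories without keeping full topology copies around.
.topologyHash <- function(topology) {
  key <- paste(topology$chain, topology$resnum, topology$resname,
               topology$name, topology$element, sep = "|", collapse = "\n")
  tf <- tempfile(fileext = ".txt")
  on.exit(unlink(tf), add = TRUE)
  writeLines(key, tf)
  unname(tools::md5sum(tf))
}

# Run code with a fixed RNG state and restore the caller's stream afterwards.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Residue/ion vocabularies (OPC water and physiological NaCl are the
# simulation conditions these trajectories come from).
.WATER_RESNAMES <- c("HOH", "WAT", "SOL", "TIP3", "OPC")
.ION_ELEMENTS <- c("NA", "CL")
.ION_RESNAMES <- c("NA+", "SOD", "NA", "CL-", "CLA")

.isWater <- function(topology) toupper(topology$resname) %in% .WATER_RESNAMES

.waterOxygenIdx <- function(topology) {
  which(.isWater(topology) & toupper(topology$element) == "O")
}

.sodiumIdx <- function(topology) {
  which(toupper(topology$element) == "NA" |
          toupper(topology$resname) %in% c("NA+", "SOD", "NA"))
}
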