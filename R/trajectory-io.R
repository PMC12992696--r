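## Multi-model PDB and plain XYZ trajectory I/O plus atom selection.
##
## The PDB dialect is deliberately strict and deterministic: fixed-column
## parsing, HETATM treated like ATOM, altloc characters other than blank/'A'
## dropped with a warning.  No unit cell / PBC handling: frames are assumed
## pre-imaged.

.parsePdbAtomLines <- function(lines, lineNumbers) {
  n <- length(lines)
  wide <- nchar(lines) >= 54L
  if (any(!wide))
    .err(paste0("malformed ATOM record at line ", lineNumbers[which(!wide)[1L]],
                ": record shorter than coordinate columns"), "parse_error")
  serial <- suppressWarnings(as.integer(substr(lines, 7L, 11L)))
  name <- trimws(substr(lines, 13L, 16L))
  altloc <- substr(lines, 17L, 17L)
  resname <- trimws(substr(lines, 18L, 21L))
  chain <- substr(lines, 22L, 22L)
  resnum <- suppressWarnings(as.integer(substr(lines, 23L, 26L)))
  x <- suppressWarnings(as.numeric(substr(lines, 31L, 38L)))
  y <- suppressWarnings(as.numeric(substr(lines, 39L, 46L)))
  z <- suppressWarnings(as.numeric(substr(lines, 47L, 54L)))
  element <- trimws(substr(lines, 77L, 78L))
  bad <- which(is.na(serial) | is.na(resnum) | is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    .err(paste0("malformed ATOM record at line ", lineNumbers[bad[1L]],
                ": unparseable numeric field"), "parse_error")
  keep <- altloc %in% c(" ", "", "A")
  if (any(!keep)) {
    warning(sprintf("dropping %d atoms with altloc other than blank/'A'",
                    sum(!keep)))
    serial <- serial[keep]; name <- name[keep]; resname <- resname[keep]
    chain <- chain[keep]; resnum <- resnum[keep]
    x <- x[keep]; y <- y[keep]; z <- z[keep]; element <- element[keep]
  }
  # element fallback: first letter of the atom name (digits stripped)
  noel <- !nzchar(element)
  if (any(noel))
    element[noel] <- substr(gsub("[0-9']", "", name[noel]), 1L, 1L)
  list(topology = data.frame(serial = serial, name = name, resname = resname,
                             resnum = resnum, chain = chain,
                             element = element, stringsAsFactors = FALSE),
       xyz = cbind(x, y, z))
}

#' Read a multi-model PDB file as a Trajectory
#'
#' One frame per MODEL/ENDMDL block (a file without MODEL records yields a
#' single frame).  Coordinates come from the fixed PDB columns; HETATM is
#' treated like ATOM.  Frame times are `index * strideNs` with the default
#' stride of 1 ns per frame.
#'
#' @param path path to a PDB file.
#' @param strideNs frame stride in ns (default 1.0).
#' @return a [Trajectory-class].
#' @export
readMultimodelPDB <- function(path, strideNs = 1.0) {
  .assert(file.exists(path), paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  isAtom <- rec == "ATOM  " | rec == "HETATM"
  isModel <- startsWith(rec, "MODEL")
  isEnd <- startsWith(rec, "ENDMDL")
  if (!any(isAtom)) .err("no ATOM/HETATM records found", "parse_error")
  modelId <- cumsum(isModel)
  if (!any(isModel)) modelId[] <- 1L
  atomIdx <- which(isAtom)
  frames <- split(atomIdx, modelId[atomIdx])
  parsed <- lapply(frames, function(ix) .parsePdbAtomLines(lines[ix], ix))
  nAt <- vapply(parsed, function(p) nrow(p$topology), integer(1))
  if (length(unique(nAt)) != 1L)
    .err(paste0("inconsistent atom count between models: ",
                paste(unique(nAt), collapse = " vs ")), "topology_error")
  top <- parsed[[1L]]$topology
  hash <- .topologyHash(top)
  for (k in seq_along(parsed)) {
    tk <- parsed[[k]]$topology
    if (!identical(paste(tk$chain, tk$resnum, tk$name),
                   paste(top$chain, top$resnum, top$name)))
      .err(paste("model", k, "does not match the topology of model 1"),
           "topology_error")
  }
  coords <- array(NA_real_, dim = c(nrow(top), 3L, length(parsed)))
  for (k in seq_along(parsed)) coords[, , k] <- parsed[[k]]$xyz
  new("Trajectory", topology = top, coords = coords,
      timeNs = (seq_along(parsed) - 1) * strideNs,
      strideNs = strideNs, topologyHash = hash)
}

.formatPdbAtomName <- function(name, element) {
  # standard PDB: element right-justified in cols 13-14; short organic names
  # start in column 14
  ifelse(nchar(name) >= 4L, substr(sprintf("%-4s", name), 1L, 4L),
         ifelse(nchar(element) == 2L, sprintf("%-4s", name),
                sprintf(" %-3s", name)))
}

#' Write a Trajectory as a multi-model PDB file
#'
#' Inverse of [readMultimodelPDB()] at 3-decimal coordinate precision.
#'
#' @param traj a [Trajectory-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMultimodelPDB <- function(traj, path) {
  top <- topology(traj)
  nameField <- .formatPdbAtomName(top$name, top$element)
  rec <- ifelse(toupper(top$resname) %in%
                  c(.WATER_RESNAMES, .ION_RESNAMES, "LIG"), "HETATM", "ATOM  ")
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (k in seq_len(nFrames(traj))) {
    xyz <- traj@coords[, , k, drop = TRUE]
    body <- sprintf("%s%5d %s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    rec, top$serial, nameField, substr(top$resname, 1L, 4L),
                    top$chain, top$resnum, xyz[, 1L], xyz[, 2L], xyz[, 3L],
                    1.00, 0.00, sprintf("%2s", top$element))
    writeLines(c(sprintf("MODEL     %4d", k), body, "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a whitespace XYZ-per-frame trajectory
#'
#' Simple dialect: repeated blocks of `natoms` lines, each `x y z`, one block
#' per frame, blocks separated implicitly by atom count.  Labels are attached
#' positionally from `names`, formatted "RESNAME:RESNUM:NAME" or plain atom
#' names (residue UNK is then assumed).
#'
#' @param path file path.
#' @param names character vector of atom labels, one per atom.
#' @param strideNs frame stride in ns.
#' @return a [Trajectory-class].
#' @export
readXYZFrames <- function(path, names, strideNs = 1.0) {
  .assert(file.exists(path), paste("no such file:", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) .err("no frames in XYZ file", "parse_error")
  vals <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(vals) != 3L)
  if (length(bad))
    .err(paste("XYZ line", bad[1L], "does not have 3 fields"), "parse_error")
  m <- matrix(suppressWarnings(as.numeric(unlist(vals))), ncol = 3L,
              byrow = TRUE)
  if (anyNA(m)) .err("non-numeric coordinate in XYZ file", "parse_error")
  nat <- length(names)
  if (nrow(m) %% nat != 0L)
    .err(sprintf("coordinate count (%d lines) is not a multiple of the %d labels",
                 nrow(m), nat), "topology_error")
  nf <- nrow(m) %/% nat
  parts <- strsplit(names, ":", fixed = TRUE)
  top <- data.frame(
    serial = seq_len(nat),
    name = vapply(parts, function(p) p[[length(p)]], character(1)),
    resname = vapply(parts, function(p) if (length(p) == 3L) p[[1L]] else "UNK",
                     character(1)),
    resnum = vapply(parts, function(p) if (length(p) == 3L)
      as.integer(p[[2L]]) else 1L, integer(1)),
    chain = "A", stringsAsFactors = FALSE)
  top$element <- substr(gsub("[0-9']", "", top$name), 1L, 1L)
  coords <- array(NA_real_, dim = c(nat, 3L, nf))
  for (k in seq_len(nf)) coords[, , k] <- m[((k - 1L) * nat + 1L):(k * nat), ]
  new("Trajectory", topology = top, coords = coords,
      timeNs = (seq_len(nf) - 1) * strideNs, strideNs = strideNs,
      topologyHash = .topologyHash(top))
}

#' Write a Trajectory in the plain XYZ-per-frame dialect
#'
#' @param traj a [Trajectory-class].
#' @param path output path.
#' @return `path`, invisibly; labels are "RESNAME:RESNUM:NAME".
#' @export
writeXYZFrames <- function(traj, path) {
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (k in seq_len(nFrames(traj))) {
    xyz <- traj@coords[, , k, drop = TRUE]
    writeLines(sprintf("%12.6f %12.6f %12.6f",
                       xyz[, 1L], xyz[, 2L], xyz[, 3L]), con)
  }
  invisible(path)
}

#' XYZ labels for a trajectory, pairing with writeXYZFrames()
#'
#' @param traj a [Trajectory-class].
#' @return character vector "RESNAME:RESNUM:NAME", one per atom.
#' @export
xyzLabels <- function(traj) {
  top <- topology(traj)
  sprintf("%s:%d:%s", top$resname, top$resnum, top$name)
}

## ---- atom selection --------------------------------------------------------

.SELECT_FIELDS <- c("resnum", "residue_number", "resname", "residue_name",
                    "name", "chain", "element")

.evalSelectTerm <- function(top, field, value) {
  vals <- strsplit(value, ",", fixed = TRUE)[[1L]]  # "name CG,CD1" matches either
  switch(field,
    resnum = , residue_number = {
      v <- suppressWarnings(as.integer(vals))
      if (anyNA(v)) .err(paste("resnum value is not an integer:", value),
                         "selection_error")
      top$resnum %in% v
    },
    resname = , residue_name = toupper(top$resname) %in% toupper(vals),
    name = top$name %in% vals,
    chain = top$chain %in% vals,
    element = toupper(top$element) %in% toupper(vals),
    .err(paste("unknown selection field:", field), "selection_error")
  )
}

#' Select atoms by a simple boolean query
#'
#' Grammar: terms `field value` joined by `and` / `or`, with `and` binding
#' tighter.  Fields: `resnum` (`residue_number`), `resname` (`residue_name`),
#' `name`, `chain`, `element`.  The result is a deterministic, order-stable
#' atom index vector valid for every frame of the trajectory.
#'
#' @param x a [Trajectory-class] or a topology data.frame.
#' @param query query string, e.g. `"resnum 155 and name CG"`.
#' @return integer vector of atom indices (1-based, increasing).
#' @export
#' @examples
#' \dontrun{selectAtoms(traj, "resname LIG and element N")}
selectAtoms <- function(x, query) {
  top <- if (is(x, "Trajectory")) topology(x) else x
  .assert(is.character(query) && length(query) == 1L && nzchar(trimws(query)),
          "query must be a non-empty string")
  toks <- strsplit(trimws(query), "[[:space:]]+")[[1L]]
  low <- tolower(toks)
  orMask <- rep(FALSE, nrow(top))
  i <- 1L
  andMask <- NULL
  expectTerm <- TRUE
  while (i <= length(toks)) {
    if (expectTerm) {
      if (i + 1L > length(toks))
        .err(paste("dangling selection term:", toks[i]), "selection_error")
      term <- .evalSelectTerm(top, low[i], toks[i + 1L])
      andMask <- if (is.null(andMask)) term else andMask & term
      i <- i + 2L
      expectTerm <- FALSE
    } else {
      if (low[i] == "and") expectTerm <- TRUE
      else if (low[i] == "or") {
        orMask <- orMask | andMask
        andMask <- NULL
        expectTerm <- TRUE
      } else .err(paste("expected 'and' or 'or', got:", toks[i]),
                  "selection_error")
      i <- i + 1L
    }
  }
  if (expectTerm) .err("query ends with a dangling connector",
                       "selection_error")
  which(orMask | andMask)
}
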