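map <- scaffoldResidueMap()
coreMap <- scaffoldCoreMapping()

test_that("RMSD_i is zero for the reference pose and tracks rigid core shifts", {
  anchors <- anchorFrames()
  ri <- rmsdISeries(anchors$inactive, coreMap)
  expect_lt(ri, 2e-3)   # reference fragment is stored at 3-decimal precision
  # rigid ligand displacement after a perfect receptor fit
  spec <- fixtureSpec("pose", 6, 5,
                      targets = list(p = list(kind = "rmsd_below",
                                              fraction = 0.5)))
  m <- generateFixture(spec, tempfile())
  traj <- readMultimodelPDB(m@files[["trajectory"]])
  ri <- rmsdISeries(traj, coreMap)
  expect_equal(sort(unique(round(ri, 2))), c(0.5, 3.0), tolerance = 1e-6)
  # composition oracle: subset-fit primitive applied per frame
  top <- topology(traj)
  fitIdx <- selectAtoms(top, coreMap@fitQuery)
  coreIdx <- vapply(coreMap@coreAtomNames, function(nm)
    which(top$name == nm & top$resname == "LIG"), integer(1))
  for (k in seq_len(nFrames(traj))) {
    xyz <- frameCoords(traj, k)
    oracle <- rmsdAfterFitOnSubset(xyz[fitIdx, ], coreMap@referenceFit,
                                   xyz[coreIdx, ], coreMap@referenceCore)
    expect_equal(ri[k], oracle, tolerance = 1e-12)
  }
  # invariance under a global rigid motion of each frame
  R <- randomRotation(); tr <- c(4, -7, 2)
  coords2 <- traj@coords
  for (k in seq_len(nFrames(traj)))
    coords2[, , k] <- rigidMove(traj@coords[, , k], R, tr)
  traj2 <- new("Trajectory", topology = top, coords = coords2,
               timeNs = timeNs(traj), strideNs = strideNs(traj),
               topologyHash = topologyHash(traj))
  expect_equal(rmsdISeries(traj2, coreMap), ri, tolerance = 1e-6)
})

test_that("fractionBelow uses strict inequality and matches counting", {
  expect_equal(fractionBelow(c(1.0, 1.5, 3.0, 2.5), 2.0), 50.0)
  expect_equal(fractionBelow(c(0.1, 0.5), 2.0), 100.0)
  expect_equal(fractionBelow(c(2.0, 2.0), 2.0), 0.0)  # boundary not below
  expect_error(fractionBelow(numeric(0)), "empty")
  set.seed(43)
  for (i in 1:40) {
    v <- runif(sample(1:100, 1), 0, 4)
    thr <- runif(1, 0, 4)
    cnt <- 0L; for (x in v) if (x < thr) cnt <- cnt + 1L
    expect_equal(fractionBelow(v, thr), 100 * cnt / length(v))
    expect_gte(fractionBelow(v, thr + 0.5), fractionBelow(v, thr))
  }
})

test_that("receptor axis is the principal TM eigenvector pointing intracellular", {
  anchors <- anchorFrames()
  top <- topology(anchors$inactive)
  xyz <- frameCoords(anchors$inactive, 1)
  ax <- receptorAxis(xyz, top, map)
  expect_equal(abs(ax$direction[3]), 1, tolerance = 1e-9)
  expect_lt(ax$direction[3], 0)  # vestibule is extracellular (+z)
  # eigenvector oracle
  tmCA <- selectAtoms(top, "resname GLY and name CA")
  tmCA <- setdiff(tmCA, selectAtoms(top, "resnum 501,502"))
  P <- xyz[tmCA, ]
  ev <- eigen(cov(P))$vectors[, 1]
  expect_equal(abs(sum(ax$direction * ev)), 1, tolerance = 1e-6)
  # equivariance under rotation
  R <- randomRotation()
  moved <- rigidMove(xyz, R, c(0, 0, 0))
  ax2 <- receptorAxis(moved, top, map)
  expect_equal(ax2$direction, as.numeric(R %*% ax$direction),
               tolerance = 1e-6)
  # a planar cloud has no unique principal axis
  flat <- xyz; flat[tmCA, 3] <- 0
  flat[tmCA, 1:2] <- cbind(rep(c(-6, 6), length.out = length(tmCA)),
                           rep(c(-6, 6), each = 2,
                               length.out = length(tmCA)))
  expect_error(receptorAxis(flat, top, map), "degenerate|axis")
})

test_that("insertion depth is the signed axial projection of the core centroid", {
  anchors <- anchorFrames()
  top <- topology(anchors$inactive)
  xyz <- frameCoords(anchors$inactive, 1)
  ax <- receptorAxis(xyz, top, map)
  core <- selectAtoms(top, "resname LIG and name N1,C2,C3,C3A,C4,C5,C6,C7,C7A")
  # oracle: explicit dot product
  oracle <- sum((colMeans(xyz[core, ]) - ax$origin) * ax$direction)
  expect_equal(insertionDepth(xyz, top, map, ax), oracle, tolerance = 1e-12)
  # centroid placed at the origin -> depth 0
  xyz0 <- xyz
  shift <- ax$origin - colMeans(xyz[core, ])
  xyz0[core, ] <- xyz[core, ] + matrix(shift, length(core), 3, byrow = TRUE)
  expect_equal(insertionDepth(xyz0, top, map, ax), 0, tolerance = 1e-9)
  # +3 A along the axis direction -> exactly 3 deeper
  xyz3 <- xyz0
  xyz3[core, ] <- xyz0[core, ] + matrix(3 * ax$direction, length(core), 3,
                                        byrow = TRUE)
  expect_equal(insertionDepth(xyz3, top, map, ax), 3, tolerance = 1e-9)
  # translating the whole frame leaves depth unchanged (axis recomputed)
  moved <- xyz + matrix(c(10, -4, 6), nrow(xyz), 3, byrow = TRUE)
  expect_equal(insertionDepth(moved, top, map),
               insertionDepth(xyz, top, map), tolerance = 1e-9)
})

test_that("moving average is the trailing mean with warm-up", {
  expect_equal(movingAverage(rep(2.5, 30), 20), rep(2.5, 30))
  ramp <- as.numeric(1:100)
  ma <- movingAverage(ramp, 20)
  expect_equal(length(ma), 100)
  expect_equal(ma[20], mean(1:20))  # = 10.5
  expect_equal(ma[1], 1)
  expect_equal(ma[5], mean(1:5))
  expect_error(movingAverage(1:5, 0), "window")
  # naive loop oracle
  set.seed(47)
  for (i in 1:20) {
    v <- rnorm(sample(1:60, 1))
    w <- sample(1:25, 1)
    oracle <- vapply(seq_along(v), function(j)
      mean(v[max(1, j - w + 1):j]), numeric(1))
    expect_equal(movingAverage(v, w), oracle, tolerance = 1e-12)
  }
})

test_that("kde1d is a normalized Gaussian kernel sum", {
  set.seed(51)
  x <- c(rnorm(200, 3.0, 0.15))
  kd <- kde1d(x)
  expect_true(all(kd$density >= 0))
  # integrates to ~1 over the +-5 bandwidth grid
  expect_equal(sum(kd$density) * diff(kd$grid[1:2]), 1, tolerance = 1e-3)
  # unimodal peak near the cluster
  expect_lt(abs(kd$grid[which.max(kd$density)] - 3.0), 0.1)
  # two equal clusters -> symmetric bimodal density
  y <- c(rep(2, 50), rep(6, 50))
  kdy <- kde1d(y, grid = seq(0, 8, length.out = 401), bandwidth = 0.3)
  expect_equal(kdy$density, rev(kdy$density), tolerance = 1e-9)
  expect_equal(kdy$grid[which.max(kdy$density)] %in% c(2, 6), TRUE)
  # direct kernel-sum oracle at 100 grid points
  g <- seq(2, 4, length.out = 100)
  kd2 <- kde1d(x, grid = g, bandwidth = 0.2)
  oracle <- vapply(g, function(p)
    sum(exp(-(p - x)^2 / (2 * 0.2^2))) / (length(x) * 0.2 * sqrt(2 * pi)),
    numeric(1))
  expect_equal(kd2$density, oracle, tolerance = 1e-12)
  # zero-variance fallback
  expect_warning(kz <- kde1d(rep(1.5, 10)), "bandwidth")
  expect_equal(kz$grid[which.max(kz$density)], 1.5, tolerance = 0.01)
})
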