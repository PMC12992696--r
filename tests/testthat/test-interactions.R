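test_that("hydrogen-bond predicate matches an independent grid oracle", {
  for (d in c(2.4, 2.8, 3.2, 3.5, 3.6, 4.5, 5.0)) {
    for (ang in c(100, 119, 120, 135, 160, 180)) {
      g <- hbondGeometry(d, ang)
      r <- detectHBond(g, 1, 2, 3)
      expect_equal(r$dist, d, tolerance = 1e-9)
      expect_equal(r$angle, ang, tolerance = 1e-6)
      # independent predicate applied to the measured geometry (the exact
      # 120-degree boundary is not representable in the construction)
      expect_identical(r$present, r$dist <= 3.5 && r$angle >= 120,
                       label = sprintf("d=%.1f ang=%d", d, ang))
    }
  }
  expect_true(detectHBond(hbondGeometry(2.8, 170), 1, 2, 3)$present)
  expect_false(detectHBond(hbondGeometry(5.0, 170), 1, 2, 3)$present)
  # hydrogen not bound to the donor
  bad <- rbind(c(0, 0, 0), c(2.5, 0, 0), c(3, 0, 0))
  expect_error(detectHBond(bad, 1, 2, 3), "not covalently bound")
})

test_that("salt-bridge and hydrophobic detectors equal all-pairs minima", {
  set.seed(13)
  for (i in 1:30) {
    nA <- sample(1:4, 1); nB <- sample(1:5, 1)
    xyz <- matrix(rnorm((nA + nB) * 3, sd = 3), nA + nB, 3)
    ia <- seq_len(nA); ib <- nA + seq_len(nB)
    oracle <- min(apply(expand.grid(ia, ib), 1, function(p)
      vecDistance(xyz[p[1], ], xyz[p[2], ])))
    sb <- detectSaltBridge(xyz, ia, ib)
    expect_equal(sb$dist, oracle, tolerance = 1e-9)
    expect_identical(sb$present, oracle <= 4.0)
    top <- data.frame(element = rep("C", nA + nB))
    hc <- detectHydrophobicContact(xyz, top, ia, ib)
    expect_equal(hc$dist, oracle, tolerance = 1e-9)
    expect_identical(hc$present, oracle <= 4.5)
  }
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0))
  expect_error(detectSaltBridge(xyz, integer(0), 2), "empty")
  topH <- data.frame(element = c("H", "C"))
  expect_error(detectHydrophobicContact(xyz, topH, 1, 2), "hydrogen")
})

hexRing <- function(center, normalAxis = c(0, 0, 1), radius = 1.39) {
  u <- if (abs(normalAxis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- u - sum(u * normalAxis) * normalAxis
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normalAxis[2] * e1[3] - normalAxis[3] * e1[2],
          normalAxis[3] * e1[1] - normalAxis[1] * e1[3],
          normalAxis[1] * e1[2] - normalAxis[2] * e1[1])
  t(vapply(0:5, function(k)
    center + radius * (cos(k * pi / 3) * e1 + sin(k * pi / 3) * e2),
    numeric(3)))
}

test_that("pi-stacking geometry matches the SVD plane fit", {
  nrmA <- c(0, 0, 1)
  a <- hexRing(c(0, 0, 0), nrmA)
  # parallel offset 3.8 A -> stacked
  b <- hexRing(c(0.5, 0.5, 3.8), nrmA)
  r <- detectPiStack(rbind(a, b), 1:6, 7:12)
  expect_true(r$present)
  expect_equal(r$angle, 0, tolerance = 1e-6)
  # far apart -> absent
  far <- detectPiStack(rbind(a, hexRing(c(8, 0, 0), nrmA)), 1:6, 7:12)
  expect_false(far$present)
  expect_equal(far$dist, 8, tolerance = 1e-9)
  # T-shaped (90 degrees) within distance -> present
  tsh <- detectPiStack(rbind(a, hexRing(c(0, 0, 5.0), c(1, 0, 0))),
                       1:6, 7:12)
  expect_true(tsh$present)
  expect_equal(tsh$angle, 90, tolerance = 1e-6)
  # 45-degree tilt is neither parallel nor T-shaped
  mid <- detectPiStack(rbind(a, hexRing(c(0, 0, 4), c(1, 0, 1) / sqrt(2))),
                       1:6, 7:12)
  expect_false(mid$present)
  expect_equal(mid$angle, 45, tolerance = 1e-6)
  # interplanar angle equals the known normal angle for random orientations
  set.seed(17)
  for (i in 1:20) {
    n2 <- rnorm(3); n2 <- n2 / sqrt(sum(n2^2))
    b2 <- hexRing(c(0, 0, 4), n2)
    got <- detectPiStack(rbind(a, b2), 1:6, 7:12)$angle
    oracle <- acos(abs(n2[3])) * 180 / pi
    expect_equal(got, oracle, tolerance = 1e-6)
  }
  # non-planar ring errors
  bent <- a; bent[1, 3] <- 1.0
  expect_error(detectPiStack(rbind(bent, b), 1:6, 7:12), "not planar")
})

test_that("detectors are invariant under global rigid motion", {
  set.seed(19)
  g <- hbondGeometry(3.2, 150)
  ring2 <- hexRing(c(0, 1, 3.6))
  xyz <- rbind(g, hexRing(c(0, 0, 0)), ring2)
  for (i in 1:10) {
    R <- randomRotation(); tr <- rnorm(3, sd = 20)
    m <- rigidMove(xyz, R, tr)
    expect_equal(detectHBond(m, 1, 2, 3),
                 detectHBond(xyz, 1, 2, 3), tolerance = 1e-9)
    expect_equal(detectPiStack(m, 4:9, 10:15),
                 detectPiStack(xyz, 4:9, 10:15), tolerance = 1e-5)
    expect_equal(detectSaltBridge(m, 1, 3), detectSaltBridge(xyz, 1, 3),
                 tolerance = 1e-9)
  }
})

test_that("interaction series equals frame-by-frame detector composition", {
  spec <- paperFixtureSpec("trans1_thr160")
  spec@nFrames <- 40L
  m <- generateFixture(spec, tempfile())
  traj <- readMultimodelPDB(m@files[["trajectory"]])
  specs <- scaffoldInteractionSpecs()[1]
  ser <- interactionSeries(traj, specs)[[1]]
  top <- topology(traj)
  d <- selectAtoms(top, "resname LIG and name N1")
  h <- selectAtoms(top, "resname LIG and name HN1")
  a <- selectAtoms(top, "resnum 160 and name OG1")
  for (k in seq_len(nFrames(traj))) {
    r <- detectHBond(frameCoords(traj, k), d, h, a)
    expect_identical(ser@present[k], r$present)
    expect_equal(ser@geometry[k], r$dist, tolerance = 1e-9)
  }
  expect_identical(interactionSeries(traj, list()), list())
})

test_that("occupancy is the exact satisfied-frame percentage", {
  spec <- interactionSpec("hbond", "x", donor = "name A", hydrogen = "name B",
                          acceptor = "name C")
  mk <- function(present) new("InteractionSeries", spec = spec,
                              present = present,
                              geometry = seq_along(present) * 1.0)
  r <- occupancy(mk(c(rep(TRUE, 7), rep(FALSE, 3))))
  expect_equal(r$occupancy_percent, 70.0)
  expect_equal(r$n_frames, 10L)
  expect_equal(occupancy(mk(rep(FALSE, 5)))$occupancy_percent, 0.0)
  expect_error(occupancy(logical(0)), "empty")
  set.seed(23)
  for (i in 1:50) {
    v <- sample(c(TRUE, FALSE), sample(1:200, 1), replace = TRUE)
    cnt <- 0L; for (x in v) if (x) cnt <- cnt + 1L  # counting oracle
    expect_equal(occupancy(v), 100 * cnt / length(v))
  }
  # monotone when satisfying frames are appended
  v <- c(TRUE, FALSE, TRUE)
  expect_gte(occupancy(c(v, TRUE)), occupancy(v))
})
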