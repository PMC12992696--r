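test_that("distance matches the componentwise formula and its invariants", {
  expect_equal(vecDistance(c(0, 0, 0), c(0, 0, 4)), 4.0)
  expect_equal(vecDistance(c(1, 2, 3), c(1, 2, 3)), 0.0)
  expect_error(vecDistance(c(NA, 0, 0), c(0, 0, 0)), "non-finite")
  set.seed(11)
  for (i in 1:100) {
    a <- rnorm(3, sd = 10); b <- rnorm(3, sd = 10)
    oracle <- sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2 + (a[3] - b[3])^2)
    expect_equal(vecDistance(a, b), oracle, tolerance = 1e-12)
    expect_equal(vecDistance(b, a), vecDistance(a, b))
  }
})

test_that("dihedral follows the IUPAC convention with the trans branch at +180", {
  # planar cis: p1 and p4 eclipsed on the same side
  expect_equal(dihedralAngle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(1, 0, 0)),
               0, tolerance = 1e-9)
  # planar trans: opposite sides
  expect_equal(dihedralAngle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0), c(-1, 0, 0)),
               180, tolerance = 1e-9)
  expect_error(dihedralAngle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
  expect_error(dihedralAngle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "coincident|undefined")
})

test_that("dihedral agrees with an independent projection oracle on random quadruples", {
  # oracle: signed angle between the projections of (p1-p2) and (p4-p3)
  # onto the plane perpendicular to the central bond
  projOracle <- function(p1, p2, p3, p4) {
    u <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
    v1 <- (p1 - p2) - sum((p1 - p2) * u) * u
    v2 <- (p4 - p3) - sum((p4 - p3) * u) * u
    e1 <- v1 / sqrt(sum(v1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    ang <- atan2(sum(v2 * e2), sum(v2 * e1)) * 180 / pi
    if (ang <= -180 + 1e-12) ang + 360 else ang
  }
  set.seed(7)
  for (i in 1:200) {
    ps <- lapply(1:4, function(j) rnorm(3, sd = 3))
    got <- try(dihedralAngle(ps[[1]], ps[[2]], ps[[3]], ps[[4]]),
               silent = TRUE)
    if (inherits(got, "try-error")) next
    expect_equal(got, projOracle(ps[[1]], ps[[2]], ps[[3]], ps[[4]]),
                 tolerance = 1e-9)
  }
})

test_that("dihedral antisymmetry and rigid-motion invariance hold", {
  set.seed(21)
  for (i in 1:50) {
    ps <- lapply(1:4, function(j) rnorm(3, sd = 3))
    a <- dihedralAngle(ps[[1]], ps[[2]], ps[[3]], ps[[4]])
    # reversing the atom order preserves the torsion (IUPAC identity) ...
    b <- dihedralAngle(ps[[4]], ps[[3]], ps[[2]], ps[[1]])
    expect_equal(b, a, tolerance = 1e-8)
    # ... while a mirror reflection negates it (mod 360)
    refl <- lapply(ps, function(p) c(p[1], p[2], -p[3]))
    m <- dihedralAngle(refl[[1]], refl[[2]], refl[[3]], refl[[4]])
    expect_equal((a + m) %% 360, 0, tolerance = 1e-8)
    R <- randomRotation(); tr <- rnorm(3, sd = 5)
    moved <- lapply(ps, function(p) as.numeric(R %*% p + tr))
    expect_equal(dihedralAngle(moved[[1]], moved[[2]], moved[[3]],
                               moved[[4]]), a, tolerance = 1e-9)
    d0 <- vecDistance(ps[[1]], ps[[2]])
    expect_equal(vecDistance(moved[[1]], moved[[2]]), d0, tolerance = 1e-9)
  }
})

test_that("kabsch recovers exact superpositions and enforces proper rotations", {
  set.seed(3)
  ref <- matrix(rnorm(15, sd = 4), 5, 3)
  fit0 <- kabsch(ref, ref)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  fitT <- kabsch(ref + matrix(c(5, 0, 0), 5, 3, byrow = TRUE), ref)
  expect_equal(fitT$rmsd, 0, tolerance = 1e-9)
  # known rotation+translation is recovered
  R <- randomRotation(); tr <- c(1, -2, 3)
  fitR <- kabsch(rigidMove(ref, R, tr), ref)
  expect_equal(fitR$rmsd, 0, tolerance = 1e-9)
  expect_equal(fitR$rotation %*% t(fitR$rotation), diag(3),
               tolerance = 1e-9)
  expect_equal(det(fitR$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch(ref[1:2, ], ref[1:2, ]), "at least 3")
})

test_that("kabsch rmsd is invariant to pre-rotation and beats random rotations", {
  set.seed(5)
  nrot <- 300
  rots <- replicate(nrot, randomRotation(), simplify = FALSE)
  for (case in 1:10) {
    mob <- matrix(rnorm(15, sd = 3), 5, 3)
    ref <- mob + matrix(rnorm(15, sd = 0.6), 5, 3)
    best <- kabsch(mob, ref)$rmsd
    pre <- kabsch(rigidMove(mob, randomRotation(), rnorm(3)), ref)$rmsd
    expect_equal(pre, best, tolerance = 1e-9)
    # brute-force lower bound: optimally translated random rotations
    refC <- sweep(ref, 2, colMeans(ref))
    mobC <- sweep(mob, 2, colMeans(mob))
    bruteBest <- min(vapply(rots, function(R)
      sqrt(sum((mobC %*% t(R) - refC)^2) / 5), numeric(1)))
    expect_lte(best, bruteBest + 1e-12)
  }
})

test_that("subset-fit RMSD equals the explicit two-stage composition", {
  set.seed(9)
  fitRef <- matrix(rnorm(24, sd = 4), 8, 3)
  core <- matrix(rnorm(9, sd = 2), 3, 3)
  # identical clouds -> 0
  expect_equal(rmsdAfterFitOnSubset(fitRef, fitRef, core, core), 0,
               tolerance = 1e-9)
  # rigid displacement of the eval subset after a perfect fit -> its size
  expect_equal(rmsdAfterFitOnSubset(fitRef, fitRef,
                                    core + matrix(c(2, 0, 0), 3, 3,
                                                  byrow = TRUE), core),
               2.0, tolerance = 1e-9)
  for (i in 1:25) {
    R <- randomRotation(); tr <- rnorm(3, sd = 5)
    mobFit <- rigidMove(fitRef, R, tr)
    mobCore <- rigidMove(core + matrix(rnorm(9, sd = 0.5), 3, 3), R, tr)
    got <- rmsdAfterFitOnSubset(mobFit, fitRef, mobCore, core)
    # oracle: run kabsch, transform, then plain rmsd
    f <- kabsch(mobFit, fitRef)
    moved <- applyTransform(mobCore, f)
    expect_equal(got, sqrt(sum((moved - core)^2) / 3), tolerance = 1e-9)
  }
})
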