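# Shared helpers: random rigid motions, tiny random topologies and
# independent brute-force oracles used across the suite.

# uniform-ish random proper rotation via QR of a Gaussian matrix
randomRotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rigidMove <- function(xyz, R, t) {
  m <- as.matrix(xyz) %*% t(R)
  m + matrix(t, nrow(m), 3, byrow = TRUE)
}

# small random topology for selection tests
randomTopology <- function(n = 40) {
  data.frame(
    serial = seq_len(n),
    name = sample(c("CA", "CB", "CG", "N", "O", "OD1", "NE2"), n, TRUE),
    resname = sample(c("ALA", "ASP", "ARG", "HOH", "LIG"), n, TRUE),
    resnum = sample(1:12, n, TRUE),
    chain = sample(c("A", "B"), n, TRUE),
    element = sample(c("C", "N", "O"), n, TRUE),
    stringsAsFactors = FALSE)
}

# brute-force reachability oracle: boolean transitive closure
closureReachable <- function(n, edges, sources, sinks) {
  if (!n || !length(sources) || !length(sinks)) return(FALSE)
  A <- diag(TRUE, n)
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    A[edges[i, 1], edges[i, 2]] <- TRUE
    A[edges[i, 2], edges[i, 1]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  any(A[sources, sinks, drop = FALSE])
}

# place a donor-hydrogen-acceptor triple with prescribed D-A distance and
# D-H...A angle (vertex at H); independent of the detector internals
hbondGeometry <- function(dist, angleDeg) {
  D <- c(0, 0, 0)
  H <- c(1, 0, 0)
  # acceptor in the xy-plane at the requested angle from the H->D direction
  th <- angleDeg * pi / 180
  dirHA <- c(-cos(th), sin(th), 0)   # angle between H->D = (-1,0,0) and this
  # choose |H->A| so that |D->A| = dist
  # solve |H + s*dirHA - D| = dist
  b <- 2 * sum(H * dirHA)
  cc <- sum(H * H) - dist^2
  s <- (-b + sqrt(b^2 - 4 * cc)) / 2
  A <- H + s * dirHA
  rbind(D = D, H = H, A = A)
}
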