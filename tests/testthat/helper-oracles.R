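# Independent oracles used across the suite.

# Trilateration: realize a 4- or 5-point distance set by direct construction
# (P1 at origin, P2 on the x axis, P3 in the xy plane, later points solved
# from three references). Returns coordinates plus the squared out-of-plane
# component of each solved point; a negative z-squared means the distance set
# is not realizable in 3D.
trilaterate <- function(D) {
  n <- nrow(D)
  P <- matrix(0, n, 3)
  zsq <- rep(NA_real_, n)
  P[2, ] <- c(D[1, 2], 0, 0)
  if (n >= 3) {
    x <- (D[1, 2]^2 + D[1, 3]^2 - D[2, 3]^2) / (2 * D[1, 2])
    P[3, ] <- c(x, sqrt(max(D[1, 3]^2 - x^2, 0)), 0)
  }
  for (k in seq_len(n)[-(1:3)]) {
    x <- (D[1, 2]^2 + D[1, k]^2 - D[2, k]^2) / (2 * D[1, 2])
    y <- (D[1, k]^2 - D[3, k]^2 + P[3, 1]^2 + P[3, 2]^2 - 2 * x * P[3, 1]) /
      (2 * P[3, 2])
    zsq[k] <- D[1, k]^2 - x^2 - y^2
    P[k, ] <- c(x, y, sqrt(max(zsq[k], 0)))
  }
  list(coords = P, zsq = zsq)
}

# Exhaustive rotation-grid oracle for the minimal proper-rotation RMSD of
# two centered point sets (coarse but independent of the SVD route).
gridRmsdOracle <- function(A, B, step = pi / 36) {
  A0 <- sweep(A, 2, colMeans(A)); B0 <- sweep(B, 2, colMeans(B))
  best <- Inf
  angs <- seq(0, 2 * pi - step, by = step)
  Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3)
  Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3)
  for (a in angs) for (b in seq(0, pi, by = step)) for (c in angs) {
    R <- Rz(a) %*% Ry(b) %*% Rz(c)
    v <- sqrt(mean(rowSums((A0 %*% R - B0)^2)))
    if (v < best) best <- v
  }
  best
}

# Random matcher instance: a small pharmacophore model built from random 3D
# points (hence realizable) and a random feature cloud.
randomMatchInstance <- function(nFeat, nPts) {
  types <- featureTypes()
  repeat {
    X <- matrix(stats::runif(nPts * 3, -5, 5), nPts, 3)
    D <- as.matrix(stats::dist(X))
    if (min(D[upper.tri(D)]) > 1) break
  }
  pts <- lapply(seq_len(nPts), function(i)
    phPoint(sprintf("P%d", i), sample(types, sample(1:2, 1))))
  model <- pharmacophoreModel("random", pts, D, defaultTolerance = 1.5)
  feats <- data.frame(
    type = sample(types, nFeat, replace = TRUE),
    x = stats::runif(nFeat, -6, 6), y = stats::runif(nFeat, -6, 6),
    z = stats::runif(nFeat, -6, 6),
    label = sprintf("f%d", seq_len(nFeat))
  )
  feats$sourceAtoms <- as.list(seq_len(nFeat))
  list(model = model, features = feats)
}

# Canonical string form of a correspondence set, for set equality checks.
corKey <- function(cors)
  sort(vapply(cors, function(co)
    paste(names(co@mapping), co@mapping, sep = "=", collapse = ","),
    character(1)))

# Features placed exactly on the strict embedding of the consensus model,
# with types chosen so P1-P4 are each satisfiable.
consensusEmbeddedFeatures <- function() {
  co <- embedModel(builtinModel("bk_consensus"), "strict")@coordinates
  feats <- data.frame(
    type = c("POSITIVE", "DONOR", "AROMATIC", "ACCEPTOR"),
    x = co[, 1], y = co[, 2], z = co[, 3],
    label = rownames(co)
  )
  feats$sourceAtoms <- as.list(seq_len(4))
  feats
}
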