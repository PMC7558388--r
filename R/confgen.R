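# Seeded conformer-ensemble generation, a build-up in three stages:
#  1. base geometry by stochastic distance geometry (bounds from equilibrium
#     bond lengths, hybridization angles and exact aromatic-ring geometry,
#     triangle-smoothed; metric-matrix embedding) refined hard by MMFF94;
#  2. candidate conformers by seeded random torsion driving of the base
#     geometry around its rotatable bonds, with a cheap steric pre-screen;
#  3. deterministic force-field refinement of every candidate (obabel
#     MMFF94, UFF fallback), energy windowing, clash rejection and
#     heavy-atom RMSD deduplication.

.VDW_RADIUS <- c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                 Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75, Br = 1.85,
                 I = 1.98, Se = 1.90)

.vdwOf <- function(elem) {
  r <- .VDW_RADIUS[elem]
  r[is.na(r)] <- 1.7
  unname(r)
}

.adjList <- function(nAtoms, bonds) {
  adj <- vector("list", nAtoms)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$a1[k]; j <- bonds$a2[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

.graphDistances <- function(adj) {
  n <- length(adj)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[D[s, nxt] == Inf]
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# sp carbon/nitrogen -> 180 deg, sp2/aromatic -> 120, else tetrahedral;
# small-ring atoms get the polygon interior angle instead.
.idealAngle <- function(mol, center, adj) {
  a <- mol@atoms; b <- mol@bonds
  inc <- which(b$a1 == center | b$a2 == center)
  orders <- b$order[inc]
  rs <- a$ringSize[center]
  if (rs %in% 3:5) {
    ringBonds <- sum(b$ring[inc])
    if (ringBonds >= 2L) return((rs - 2) * pi / rs)
  }
  if (any(orders >= 3L) || sum(orders == 2L) >= 2L) return(pi)
  if (a$aromatic[center] || any(orders == 2L) || any(b$aromatic[inc]))
    return(2 * pi / 3)
  acos(-1 / 3)   # 109.47 deg
}

# Distance bounds matrix (list of L and U) on heavy atoms.
.distanceBounds <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  n <- nrow(a)
  adj <- .adjList(n, b)
  gd <- .graphDistances(adj)
  vdw <- .vdwOf(a$elem)
  L <- outer(vdw, vdw, "+") * 0.8
  U <- matrix(999, n, n)
  diag(L) <- diag(U) <- 0
  blen <- matrix(NA_real_, n, n)
  for (k in seq_len(nrow(b))) {
    i <- b$a1[k]; j <- b$a2[k]
    d <- b$eqLength[k]
    if (!is.finite(d) || d <= 0) d <- 1.5
    blen[i, j] <- blen[j, i] <- d
    L[i, j] <- L[j, i] <- d - 0.01
    U[i, j] <- U[j, i] <- d + 0.01
  }
  ang <- matrix(NA_real_, n, n)   # angle at the middle atom, per 1-3 pair
  for (m in seq_len(n)) {
    nb <- adj[[m]]
    if (length(nb) < 2L) next
    th <- .idealAngle(mol, m, adj)
    for (ii in seq_len(length(nb) - 1L)) for (jj in (ii + 1L):length(nb)) {
      i <- nb[ii]; j <- nb[jj]
      d13 <- sqrt(blen[i, m]^2 + blen[m, j]^2 -
                    2 * blen[i, m] * blen[m, j] * cos(th))
      L[i, j] <- L[j, i] <- min(L[i, j], d13 - 0.05)
      U[i, j] <- U[j, i] <- min(U[i, j], d13 + 0.05)
      ang[i, j] <- ang[j, i] <- th
    }
  }
  # 1-4 pairs: cis and trans extremes with the local angles
  for (k in seq_len(nrow(b))) {
    a2 <- b$a1[k]; a3 <- b$a2[k]
    for (a1 in setdiff(adj[[a2]], a3)) for (a4 in setdiff(adj[[a3]], a2)) {
      if (a1 == a4 || gd[a1, a4] < 3) next
      r12 <- blen[a1, a2]; r23 <- blen[a2, a3]; r34 <- blen[a3, a4]
      t123 <- if (is.na(ang[a1, a3])) 2 * pi / 3 else ang[a1, a3]
      t234 <- if (is.na(ang[a2, a4])) 2 * pi / 3 else ang[a2, a4]
      p1 <- c(r12 * cos(t123), r12 * sin(t123), 0)
      p4cis <- c(r23 - r34 * cos(t234), r34 * sin(t234), 0)
      p4trans <- c(r23 - r34 * cos(t234), -r34 * sin(t234), 0)
      dcis <- sqrt(sum((p1 - p4cis)^2))
      dtrans <- sqrt(sum((p1 - p4trans)^2))
      L[a1, a4] <- L[a4, a1] <- min(L[a1, a4], min(dcis, dtrans) - 0.1)
      U[a1, a4] <- U[a4, a1] <- min(U[a1, a4], max(dcis, dtrans) + 0.1)
    }
  }
  # aromatic rings are rigid regular polygons
  sdf <- .mol2sdf(mol)
  for (pat in c("a1aaaa1", "a1aaaaa1", "a1aaaaaa1")) {
    rings <- .obSmarts(sdf, pat)[[1]]
    for (ring in rings) {
      m <- length(ring)
      side <- mean(blen[cbind(ring, c(ring[-1], ring[1]))], na.rm = TRUE)
      if (!is.finite(side)) side <- 1.39
      for (ii in seq_len(m - 1L)) for (jj in (ii + 1L):m) {
        k <- min(jj - ii, m - (jj - ii))
        d <- side * sin(k * pi / m) / sin(pi / m)
        i <- ring[ii]; j <- ring[jj]
        L[i, j] <- L[j, i] <- d - 0.01
        U[i, j] <- U[j, i] <- d + 0.01
      }
    }
  }
  # triangle smoothing
  for (k in seq_len(n)) U <- pmin(U, outer(U[, k], U[k, ], "+"))
  for (k in seq_len(n)) {
    lk <- outer(L[, k], U[k, ], "-")
    L <- pmax(L, lk, t(lk))
  }
  L <- pmin(L, U)
  diag(L) <- diag(U) <- 0
  list(L = L, U = U)
}

# RMSD between two heavy-atom coordinate sets after optimal superposition;
# falls back to a distance-matrix RMSD for fewer than 3 atoms.
.heavyRMSD <- function(A, B) {
  if (nrow(A) >= 3L) return(kabschSuperpose(A, B)$rmsd)
  if (nrow(A) == 1L) return(0)
  abs(stats::dist(A)[1] - stats::dist(B)[1])
}

.minNonbondedDist <- function(coords, bonds) {
  n <- nrow(coords)
  if (n < 2L) return(Inf)
  dm <- as.matrix(stats::dist(coords))
  dm[cbind(bonds$a1, bonds$a2)] <- Inf
  dm[cbind(bonds$a2, bonds$a1)] <- Inf
  diag(dm) <- Inf
  min(dm)
}

# Rotatable bonds: acyclic single bonds between non-terminal atoms, skipping
# amide C-N and bonds at sp (triple-bonded) centers, whose torsions are
# degenerate or frozen.
.rotatableBonds <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  deg <- tabulate(c(b$a1, b$a2), nrow(a))
  spAtom <- rep(FALSE, nrow(a))
  tr <- which(b$order == 3L)
  spAtom[c(b$a1[tr], b$a2[tr])] <- TRUE
  hasCO <- function(i) {
    inc <- which((b$a1 == i | b$a2 == i) & b$order == 2L)
    any(a$elem[setdiff(c(b$a1[inc], b$a2[inc]), i)] == "O")
  }
  out <- integer(0)
  for (k in seq_len(nrow(b))) {
    if (b$order[k] != 1L || b$ring[k]) next
    i <- b$a1[k]; j <- b$a2[k]
    if (deg[i] < 2L || deg[j] < 2L) next
    if (spAtom[i] || spAtom[j]) next
    amide <- (a$elem[i] == "N" && hasCO(j)) || (a$elem[j] == "N" && hasCO(i))
    if (amide) next
    out <- c(out, k)
  }
  out
}

# Atoms on the a2 side of bond k (excluding a2's partner side).
.bondSide <- function(mol, k) {
  b <- mol@bonds
  adj <- .adjList(numAtoms(mol), b)
  from <- b$a1[k]; to <- b$a2[k]
  side <- to
  frontier <- to
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), c(side, from))
    side <- c(side, nxt)
    frontier <- nxt
  }
  side
}

# Signed dihedral angle a-b-c-d in radians.
.dihedral <- function(co, a, b, c, d) {
  b1 <- co[b, ] - co[a, ]; b2 <- co[c, ] - co[b, ]; b3 <- co[d, ] - co[c, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

.rotateAboutBond <- function(coords, axisFrom, axisTo, sideAtoms, angle) {
  u <- coords[axisTo, ] - coords[axisFrom, ]
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  p0 <- coords[axisFrom, ]
  coords[sideAtoms, ] <- sweep(sweep(coords[sideAtoms, , drop = FALSE],
                                     2L, p0) %*% t(R), 2L, p0, "+")
  coords
}

# Refine a set of candidate geometries with obabel (add hydrogens, minimize)
# and score them with obenergy; MMFF94 first, UFF fallback.
.refineCandidates <- function(mol, candidates, steps) {
  inPath <- tempfile(fileext = ".sdf"); outPath <- tempfile(fileext = ".sdf")
  on.exit(unlink(c(inPath, outPath)))
  cat(paste(vapply(candidates, function(co) .mol2sdf(mol, co), character(1)),
            collapse = ""), file = inPath)
  nA <- numAtoms(mol)
  for (ff in c("MMFF94", "UFF")) {
    .obMinimizeFile(inPath, outPath, ff = ff, steps = steps)
    parsed <- tryCatch(.obParse("SDF",
                                paste(readLines(outPath, warn = FALSE),
                                      collapse = "\n")),
                       error = function(e) list())
    if (length(parsed) != length(candidates)) next
    en <- .obEnergies(outPath, ff = ff)
    if (length(en) != length(candidates) || !all(is.finite(en))) next
    coords <- lapply(parsed, function(p) {
      if (!identical(p$atoms$elem[seq_len(nA)], mol@atoms$elem))
        stop("atom order changed during refinement of '", mol@name, "'")
      co <- as.matrix(p$atoms[seq_len(nA), c("x", "y", "z")])
      dimnames(co) <- NULL
      co
    })
    return(list(coords = coords, energies = en))
  }
  stop("conformer refinement failed for molecule '", mol@name, "'")
}

#' Generate a seeded conformer ensemble
#'
#' A build-up procedure in three deterministic stages. A base geometry is
#' constructed by stochastic distance geometry: inter-atomic distance bounds
#' derived from force-field equilibrium bond lengths, hybridization-ideal
#' angles, rigid aromatic-ring geometry and cis/trans torsion extremes,
#' triangle-smoothed, sampled, realized by metric-matrix embedding and
#' energy-minimized hard. Candidate conformers are then produced by seeded
#' random torsion driving of the base geometry around its rotatable bonds
#' (60-degree grid plus jitter) with a steric pre-screen, and every candidate
#' is refined by force-field minimization (MMFF94; UFF fallback when MMFF94
#' lacks parameters), pruned to an energy window above the ensemble minimum,
#' cleared of steric clashes, and deduplicated by heavy-atom RMSD.
#' Deterministic for fixed inputs and seed.
#'
#' @param mol a [Molecule-class].
#' @param n requested number of conformers (>= 1); default 200.
#' @param seed integer seed.
#' @param dedup RMSD deduplication threshold in \eqn{\AA} (default 0.5).
#' @param window energy window in kcal/mol above the minimum (default 20).
#' @param steps force-field minimization steps per candidate (default 500).
#' @return a [ConformerEnsemble-class], conformers ordered by energy.
#' @export
generateConformers <- function(mol, n = 200L, seed = 1L, dedup = 0.5,
                               window = 20, steps = 500L) {
  stopifnot(is(mol, "Molecule"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("requested conformer count must be >= 1")
  nA <- numAtoms(mol)
  bounds <- .distanceBounds(mol)
  iu <- which(upper.tri(matrix(0, nA, nA)))
  withSeed <- function(s, expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(s)
    force(expr)
  }
  # stage 1: distance-geometry base geometries, minimized hard; keep up to
  # three mutually distinct bases so ring puckers are not frozen to one form
  dgStarts <- withSeed(seed, lapply(1:4, function(t) {
    u <- stats::runif(length(iu))^c(1, 0.5, 0.25, 1)[t]
    Dm <- matrix(0, nA, nA)
    Dm[iu] <- bounds$L[iu] + (bounds$U[iu] - bounds$L[iu]) * u
    Dm <- Dm + t(Dm)
    .cmdsEmbed(Dm)$coords
  }))
  base <- .refineCandidates(mol, dgStarts, steps = 3000L)
  bOrd <- order(base$energies)
  bases <- list(base$coords[[bOrd[1]]])
  for (bi in bOrd[-1]) {
    if (length(bases) >= 3L) break
    if (all(vapply(bases, function(bc)
      .heavyRMSD(base$coords[[bi]], bc) >= 1.0, logical(1))))
      bases <- c(bases, base$coords[bi])
  }
  # stage 2: torsion-driven candidates round-robin over the bases, cycling
  # three sampling modes: 60-degree grid + jitter, extended-biased (anti
  # torsions favoured), and fully uniform angles
  rb <- .rotatableBonds(mol)
  sides <- lapply(rb, function(k) .bondSide(mol, k))
  adj <- .adjList(nA, mol@bonds)
  # reference atoms defining each rotor's dihedral, for absolute targets
  refAtoms <- lapply(seq_along(rb), function(ri) {
    i <- mol@bonds$a1[rb[ri]]; j <- mol@bonds$a2[rb[ri]]
    c(min(setdiff(adj[[i]], j)), i, j, min(setdiff(adj[[j]], i)))
  })
  nGen <- if (length(rb) == 0L) length(bases) else n   # rigid: no torsions
  candidates <- vector("list", nGen)
  candidates[seq_along(bases)] <- bases
  if (nGen > length(bases)) {
    # oversample torsion space cheaply, then keep a maximally diverse subset
    # (greedy max-min in the space of feature-pair distances, which is what
    # downstream pharmacophore matching consumes; query-agnostic)
    template <- .featureTemplate(mol)
    descriptor <- function(co) {
      P <- as.matrix(.featurePositions(template, co)[, c("x", "y", "z")])
      if (nrow(P) < 2L) return(stats::dist(co[1:min(3, nrow(co)), ]))
      as.numeric(stats::dist(P))
    }
    grid <- pi * seq(0, 300, by = 60) / 180
    nPool <- min(15L * nGen, 4000L)
    pool <- vector("list", nPool)
    for (t in seq_len(nPool)) pool[[t]] <- withSeed(seed + t, {
      baseCo <- bases[[(t - 1L) %% length(bases) + 1L]]
      mode <- t %% 3L
      best <- NULL; bestSep <- -Inf
      for (try in 1:10) {
        co <- baseCo
        for (ri in seq_along(rb)) {
          ra <- refAtoms[[ri]]
          delta <- if (mode == 0L) {
            sample(grid, 1L) + stats::runif(1, -pi / 12, pi / 12)
          } else if (mode == 1L) {
            # extended bias: drive the backbone dihedral toward anti
            if (stats::runif(1) < 0.6)
              pi + stats::runif(1, -pi / 9, pi / 9) -
                .dihedral(co, ra[1], ra[2], ra[3], ra[4])
            else sample(grid, 1L) + stats::runif(1, -pi / 12, pi / 12)
          } else {
            stats::runif(1, 0, 2 * pi)
          }
          co <- .rotateAboutBond(co, mol@bonds$a1[rb[ri]],
                                 mol@bonds$a2[rb[ri]], sides[[ri]], delta)
        }
        sep <- .minNonbondedDist(co, mol@bonds)
        if (sep >= 1.0) { best <- co; break }
        if (sep > bestSep) { bestSep <- sep; best <- co }
      }
      best
    })
    desc <- t(vapply(pool, descriptor, descriptor(bases[[1]])))
    chosen <- integer(0)
    minD <- rep(Inf, nPool)
    for (b in seq_along(bases))   # the bases anchor the selection
      minD <- pmin(minD, sqrt(rowSums(sweep(desc, 2L,
                                            descriptor(bases[[b]]))^2)))
    while (length(chosen) < nGen - length(bases)) {
      pick <- which.max(minD)
      chosen <- c(chosen, pick)
      minD <- pmin(minD, sqrt(rowSums(sweep(desc, 2L, desc[pick, ])^2)))
    }
    candidates[(length(bases) + 1L):nGen] <- pool[chosen]
  }
  refined <- .refineCandidates(mol, candidates, steps = steps)
  coordsList <- refined$coords
  en <- refined$energies
  # stage 3: energy window, clash rejection, RMSD deduplication
  ok <- vapply(coordsList, function(co)
    .minNonbondedDist(co, mol@bonds) >= 0.5, logical(1)) &
    en <= min(en) + window
  if (!any(ok)) ok[which.min(en)] <- TRUE
  ord <- order(en, seq_along(en))
  idx <- ord[ok[ord]]
  kept <- integer(0)
  for (i in idx) {
    if (all(vapply(kept, function(k)
      .heavyRMSD(coordsList[[i]], coordsList[[k]]) >= dedup, logical(1)))) {
      kept <- c(kept, i)
    }
    if (length(kept) >= n) break
  }
  new("ConformerEnsemble", molecule = mol,
      conformers = coordsList[kept], energies = en[kept],
      seed = as.integer(seed),
      params = list(n = n, dedup = dedup, window = window, steps = steps))
}

#' Write a conformer ensemble as a multi-record SDF
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeConformers <- function(ensemble, path) {
  stopifnot(is(ensemble, "ConformerEnsemble"))
  txt <- vapply(ensemble@conformers,
                function(co) .mol2sdf(ensemble@molecule, co), character(1))
  cat(paste(txt, collapse = ""), file = path)
  invisible(path)
}
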