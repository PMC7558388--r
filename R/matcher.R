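# Correspondence search between perceived ligand features and a pharmacophore
# model's distance matrix. Matching is defined on distance matrices only (the
# model is never embedded in the match path), which makes it invariant under
# rigid motion and reflection of the conformer and sidesteps the
# non-realizability of the five-point distance sets.

.featDistMatrix <- function(features)
  as.matrix(stats::dist(cbind(features$x, features$y, features$z)))

.newCorrespondence <- function(mapping, labs, D, FD, tolMat) {
  n <- length(mapping)
  devs <- numeric(0)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- abs(FD[mapping[i], mapping[j]] - D[i, j])
    devs[sprintf("%s-%s", labs[i], labs[j])] <- d
  }
  new("Correspondence", mapping = stats::setNames(as.integer(mapping), labs),
      deviations = devs, sumSq = sum(devs^2),
      maxDev = if (length(devs)) max(devs) else 0)
}

.sortCorrespondences <- function(cors) {
  if (length(cors) <= 1L) return(cors)
  key <- vapply(cors, function(co)
    paste(sprintf("%06d", co@mapping), collapse = ","), character(1))
  cors[order(vapply(cors, function(co) co@sumSq, numeric(1)), key)]
}

#' Match one conformer's features against a pharmacophore model
#'
#' Returns every injective, type-compatible assignment of model points to
#' features whose pairwise feature distances all deviate from the model's
#' target distances by at most the pair allowance (the sum of the two
#' points' tolerance radii, see [pairTolerances()]). The search backtracks over
#' model points ordered by fewest compatible features, pruning on each
#' partial pair; results are sorted by ascending sum of squared deviations,
#' ties broken by lexicographic mapping.
#'
#' @param features data.frame as returned by [perceiveFeatures()].
#' @param model a [PharmacophoreModel-class].
#' @param tolerance optional \eqn{\AA} override applied to every pair.
#' @return list of [Correspondence-class] objects (empty when no match).
#' @export
matchConformer <- function(features, model, tolerance = NULL) {
  stopifnot(is(model, "PharmacophoreModel"))
  labs <- pointLabels(model)
  D <- model@distances
  tolMat <- pairTolerances(model)
  if (!is.null(tolerance) && !is.na(tolerance)) {
    tolMat[] <- tolerance
    diag(tolMat) <- 0
  }
  nPts <- length(labs)
  if (nrow(features) < nPts) return(list())
  compat <- lapply(model@points, function(p)
    which(features$type %in% p@acceptedTypes))
  if (any(vapply(compat, length, integer(1)) == 0L)) return(list())
  FD <- .featDistMatrix(features)
  ord <- order(vapply(compat, length, integer(1)))   # scarcest point first
  found <- list()
  assign_ <- integer(nPts)   # indexed by model point position (original order)
  used <- logical(nrow(features))
  recurse <- function(depth) {
    if (depth > nPts) {
      found[[length(found) + 1L]] <<- .newCorrespondence(assign_, labs, D,
                                                         FD, tolMat)
      return(invisible())
    }
    p <- ord[depth]
    for (f in compat[[p]]) {
      if (used[f]) next
      ok <- TRUE
      if (depth > 1L) for (q in ord[seq_len(depth - 1L)]) {
        if (abs(FD[f, assign_[q]] - D[p, q]) > tolMat[p, q]) { ok <- FALSE; break }
      }
      if (!ok) next
      assign_[p] <<- f; used[f] <<- TRUE
      recurse(depth + 1L)
      used[f] <<- FALSE
    }
    invisible()
  }
  recurse(1L)
  .sortCorrespondences(found)
}

#' Brute-force matching oracle
#'
#' Exhaustively enumerates every injective type-compatible assignment and
#' filters by tolerance; by construction returns the same set as
#' [matchConformer()] and serves as its independent test oracle. Guarded to
#' at most 10 features.
#'
#' @inheritParams matchConformer
#' @return list of [Correspondence-class] objects.
#' @export
bruteForceMatch <- function(features, model, tolerance = NULL) {
  stopifnot(is(model, "PharmacophoreModel"))
  if (nrow(features) > 10L)
    stop("brute-force oracle is guarded to at most 10 features")
  labs <- pointLabels(model)
  D <- model@distances
  tolMat <- pairTolerances(model)
  if (!is.null(tolerance) && !is.na(tolerance)) {
    tolMat[] <- tolerance
    diag(tolMat) <- 0
  }
  nPts <- length(labs)
  if (nrow(features) < nPts) return(list())
  compat <- lapply(model@points, function(p)
    which(features$type %in% p@acceptedTypes))
  FD <- .featDistMatrix(features)
  grid <- expand.grid(rev(compat), KEEP.OUT.ATTRS = FALSE)[, nPts:1, drop = FALSE]
  found <- list()
  for (r in seq_len(nrow(grid))) {
    asg <- as.integer(grid[r, ])
    if (anyDuplicated(asg)) next
    ok <- TRUE
    for (i in seq_len(nPts - 1L)) {
      for (j in (i + 1L):nPts)
        if (abs(FD[asg[i], asg[j]] - D[i, j]) > tolMat[i, j]) { ok <- FALSE; break }
      if (!ok) break
    }
    if (ok) found[[length(found) + 1L]] <- .newCorrespondence(asg, labs, D,
                                                              FD, tolMat)
  }
  .sortCorrespondences(found)
}

#' Optimal proper rigid superposition (Kabsch)
#'
#' Least-RMSD proper rigid-body alignment of paired point sets: returns the
#' rotation (determinant +1), translation and RMSD such that
#' \code{A \%*\% rotation + translation} best fits \code{B}.
#'
#' @param A,B numeric matrices of identical dimension (n x 3, n >= 3).
#' @return list with \code{rotation} (3x3), \code{translation} (length 3),
#'   \code{rmsd} (\eqn{\AA}).
#' @export
kabschSuperpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("point sets must have identical dimensions")
  if (nrow(A) < 3L) stop("at least 3 points are required for a unique rotation")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2L, ca); B0 <- sweep(B, 2L, cb)
  H <- t(A0) %*% B0
  sv <- svd(H)
  s <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)
  fit <- A0 %*% R
  rmsd <- sqrt(mean(rowSums((fit - B0)^2)))
  list(rotation = R, translation = cb - as.vector(ca %*% R), rmsd = rmsd)
}

#' Match a conformer ensemble against a pharmacophore model
#'
#' Perceives features per conformer (the feature set itself is
#' conformation-independent; positions vary), runs [matchConformer()] on
#' each, and reports the best (conformer, correspondence) pair by minimal sum
#' of squared deviations, ties broken by lowest conformer index. The
#' superposition RMSD of the matched feature points onto the model's
#' least-squares embedding is reported as a diagnostic; it is never a match
#' criterion.
#'
#' @param ensemble a [ConformerEnsemble-class].
#' @param model a [PharmacophoreModel-class].
#' @param tolerance optional \eqn{\AA} override applied to every pair.
#' @return a [MatchResult-class].
#' @export
matchMolecule <- function(ensemble, model, tolerance = NULL) {
  stopifnot(is(ensemble, "ConformerEnsemble"), is(model, "PharmacophoreModel"))
  mol <- ensemble@molecule
  template <- .featureTemplate(mol)
  bestCor <- NULL
  bestConf <- NA_integer_
  for (ci in seq_along(ensemble@conformers)) {
    feats <- .featurePositions(template, ensemble@conformers[[ci]])
    cors <- matchConformer(feats, model, tolerance)
    if (length(cors) && (is.null(bestCor) || cors[[1]]@sumSq < bestCor@sumSq)) {
      bestCor <- cors[[1]]
      bestConf <- ci
    }
  }
  if (is.null(bestCor))
    return(new("MatchResult", matched = FALSE, molecule = mol@name,
               model = model@name, bestConformer = NA_integer_, best = NULL,
               maxDeviation = NA_real_, sumSqDeviation = NA_real_,
               superpositionRMSD = NA_real_))
  feats <- .featurePositions(template, ensemble@conformers[[bestConf]])
  P <- cbind(feats$x, feats$y, feats$z)[bestCor@mapping, , drop = FALSE]
  Q <- embedModel(model, "least_squares")@coordinates
  rmsd <- kabschSuperpose(P, Q)$rmsd
  new("MatchResult", matched = TRUE, molecule = mol@name, model = model@name,
      bestConformer = bestConf, best = bestCor,
      maxDeviation = bestCor@maxDev, sumSqDeviation = bestCor@sumSq,
      superpositionRMSD = rmsd)
}
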