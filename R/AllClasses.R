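#' @import methods
NULL

#' Molecule: a small-molecule structure
#'
#' The screening unit: a heavy-atom graph with formal charges, implicit
#' hydrogen counts, aromaticity flags, and optional 3D coordinates (\eqn{\AA}).
#' Create with [parseSmiles()] or [readMolecules()]; never fill slots by hand.
#'
#' @slot name character(1), the molecule identifier.
#' @slot atoms data.frame with one row per heavy atom: \code{elem} (element
#'   symbol), \code{charge} (formal charge), \code{implicitH} (implicit
#'   hydrogen count), \code{aromatic} (logical), \code{ringSize} (size of the
#'   smallest ring containing the atom, 0 if acyclic), \code{x}, \code{y},
#'   \code{z} (coordinates, NA when absent).
#' @slot bonds data.frame with one row per bond: \code{a1}, \code{a2} (atom
#'   indices), \code{order} (kekulized bond order), \code{aromatic},
#'   \code{ring} (logicals), \code{eqLength} (force-field equilibrium bond
#'   length, used by the conformer generator).
#' @slot source character(1), the SMILES string or SDF record the molecule
#'   was read from.
#' @export
setClass("Molecule", representation(
  name = "character", atoms = "data.frame", bonds = "data.frame",
  source = "character"
))

setValidity("Molecule", function(object) {
  a <- object@atoms; b <- object@bonds
  if (nrow(a) == 0L) return("molecule has no atoms")
  if (nrow(b) > 0L) {
    if (any(b$a1 < 1L | b$a1 > nrow(a) | b$a2 < 1L | b$a2 > nrow(a)))
      return("bond references an atom index out of range")
    if (any(b$a1 == b$a2)) return("self-bond present")
    key <- paste(pmin(b$a1, b$a2), pmax(b$a1, b$a2))
    if (anyDuplicated(key)) return("duplicate bond present")
    if (any(b$aromatic & !b$ring))
      return("aromatic-flagged bond outside any ring")
  }
  mw <- sum(.massOf(a$elem)) + sum(a$implicitH) * .ATOMIC_MASS[["H"]]
  if (!(mw > 0)) return("molecular weight must be strictly positive")
  TRUE
})

#' ConformerEnsemble: seeded 3D geometries of one molecule
#'
#' @slot molecule the [Molecule-class] the conformers belong to.
#' @slot conformers list of numeric matrices (heavy atoms x 3, \eqn{\AA}),
#'   ordered by increasing force-field energy.
#' @slot energies numeric, force-field energies (kcal/mol) parallel to
#'   \code{conformers}.
#' @slot seed integer(1), the seed that produced the ensemble.
#' @slot params list: requested count \code{n}, RMSD deduplication threshold
#'   \code{dedup} (\eqn{\AA}), energy window \code{window} (kcal/mol).
#' @export
setClass("ConformerEnsemble", representation(
  molecule = "Molecule", conformers = "list", energies = "numeric",
  seed = "integer", params = "list"
))

setValidity("ConformerEnsemble", function(object) {
  k <- length(object@conformers)
  if (k < 1L) return("ensemble must contain at least one conformer")
  if (k > object@params$n) return("more conformers than requested")
  n <- nrow(object@molecule@atoms)
  ok <- vapply(object@conformers, function(m)
    is.matrix(m) && nrow(m) == n && ncol(m) == 3L && !anyNA(m), logical(1))
  if (!all(ok)) return("conformer matrices must be heavy-atoms x 3, no NA")
  TRUE
})

#' PharmacophorePoint: one labeled model point
#'
#' @slot label character(1), unique within a model (e.g. "P1").
#' @slot acceptedTypes character, non-empty subset of [featureTypes()].
#' @slot tolerance numeric(1), \eqn{\AA}: the radius of this point's
#'   tolerance sphere. A pair of points can absorb a pairwise-distance
#'   deviation up to the sum of their radii (see [pairTolerances()]).
#' @export
setClass("PharmacophorePoint", representation(
  label = "character", acceptedTypes = "character", tolerance = "numeric"
))

setValidity("PharmacophorePoint", function(object) {
  if (length(object@label) != 1L || !nzchar(object@label))
    return("label must be a non-empty string")
  if (length(object@acceptedTypes) == 0L)
    return("acceptedTypes must be non-empty")
  bad <- setdiff(object@acceptedTypes, featureTypes())
  if (length(bad)) return(paste("unknown feature type:", bad[1]))
  if (length(object@tolerance) != 1L ||
      (!is.na(object@tolerance) && object@tolerance <= 0))
    return("tolerance must be a single positive number (or NA for default)")
  TRUE
})

#' PharmacophoreModel: labeled points plus a target distance matrix
#'
#' @slot name character(1).
#' @slot points list of [PharmacophorePoint-class] objects, ordered.
#' @slot distances symmetric numeric matrix of inter-point target distances
#'   (\eqn{\AA}), dimnames = point labels.
#' @slot defaultTolerance numeric(1), \eqn{\AA}; the tolerance used for points
#'   that do not carry their own.
#' @export
setClass("PharmacophoreModel", representation(
  name = "character", points = "list", distances = "matrix",
  defaultTolerance = "numeric"
))

setValidity("PharmacophoreModel", function(object) {
  pts <- object@points
  if (length(pts) < 1L) return("a model needs at least one point")
  labs <- vapply(pts, function(p) p@label, character(1))
  if (anyDuplicated(labs)) return("point labels must be unique")
  if (!(length(object@defaultTolerance) == 1L && object@defaultTolerance > 0))
    return("defaultTolerance must be a single positive number")
  D <- object@distances
  n <- length(pts)
  if (!is.matrix(D) || nrow(D) != n || ncol(D) != n)
    return("distance matrix dimension must equal the number of points")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-12)))
    return("distance matrix must be symmetric")
  if (any(diag(D) != 0)) return("distance matrix diagonal must be zero")
  off <- D[upper.tri(D)]
  if (any(off <= 0)) return("off-diagonal distances must be positive")
  tol2 <- 2 * object@defaultTolerance
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
    if (i != j && j != k && i != k && D[i, k] > D[i, j] + D[j, k] + tol2)
      return(sprintf("triangle inequality violated beyond 2x tolerance (%s,%s,%s)",
                     labs[i], labs[j], labs[k]))
  TRUE
})

#' EmbeddingResult: 3D realization diagnostics of a distance matrix
#'
#' @slot coordinates numeric matrix (points x 3, \eqn{\AA}), centered at the
#'   origin; dimnames = point labels.
#' @slot realizable logical(1): TRUE iff the doubly-centered Gram matrix is
#'   positive semidefinite of rank at most 3 (to numerical tolerance) and the
#'   realized distances reproduce the targets within 1e-6 \eqn{\AA}.
#' @slot maxResidual numeric(1), largest absolute deviation between realized
#'   and target distances (\eqn{\AA}).
#' @slot gramEigenvalues numeric, eigenvalues of the doubly-centered Gram
#'   matrix, decreasing.
#' @slot mode character(1), "strict" or "least_squares".
#' @export
setClass("EmbeddingResult", representation(
  coordinates = "matrix", realizable = "logical", maxResidual = "numeric",
  gramEigenvalues = "numeric", mode = "character"
))

setValidity("EmbeddingResult", function(object) {
  if (object@realizable && object@maxResidual > 1e-6)
    return("realizable embeddings must have maxResidual <= 1e-6")
  ctr <- colMeans(object@coordinates)
  if (any(abs(ctr) > 1e-6)) return("coordinates must be centered at origin")
  TRUE
})

#' Correspondence: one injective model-to-feature assignment
#'
#' @slot mapping named integer: model point label -> feature row index.
#' @slot deviations named numeric: per point pair ("Pi-Pj"),
#'   |ligand distance - target distance| in \eqn{\AA}.
#' @slot sumSq numeric(1), sum of squared deviations (\eqn{\AA^2}).
#' @slot maxDev numeric(1), largest deviation (\eqn{\AA}).
#' @export
setClass("Correspondence", representation(
  mapping = "integer", deviations = "numeric", sumSq = "numeric",
  maxDev = "numeric"
))

#' MatchResult: outcome of matching one molecule against one model
#'
#' @slot matched logical(1).
#' @slot molecule character(1), molecule name.
#' @slot model character(1), model name.
#' @slot bestConformer integer(1), index of the best conformer (NA when
#'   unmatched).
#' @slot best [Correspondence-class] of the best (conformer, assignment) pair,
#'   or NULL-like empty correspondence when unmatched.
#' @slot maxDeviation numeric(1), \eqn{\AA} (NA when unmatched).
#' @slot sumSqDeviation numeric(1), \eqn{\AA^2} (NA when unmatched).
#' @slot superpositionRMSD numeric(1), RMSD (\eqn{\AA}) of the matched feature
#'   points onto the model's least-squares embedding after optimal proper
#'   rigid superposition; diagnostic only, never a match criterion.
#' @export
setClass("MatchResult", representation(
  matched = "logical", molecule = "character", model = "character",
  bestConformer = "integer", best = "ANY", maxDeviation = "numeric",
  sumSqDeviation = "numeric", superpositionRMSD = "numeric"
))

setValidity("MatchResult", function(object) {
  if (object@matched && is.na(object@bestConformer))
    return("matched results must name a best conformer")
  if (!object@matched && !is.na(object@bestConformer))
    return("unmatched results cannot name a best conformer")
  TRUE
})

#' FixtureLibrary: the bundled screen-validation library
#'
#' Eight approved drugs that carry a protonatable basic center plus
#' constructed decoys guaranteed to lack any positive-ionizable group, so the
#' positive-charge pharmacophore point is unmatchable for every decoy.
#'
#' @slot hits list of 8 [Molecule-class] objects (the named drugs).
#' @slot decoys list of [Molecule-class] objects.
#' @slot seed integer(1), the seed used to draw the decoys.
#' @export
setClass("FixtureLibrary", representation(
  hits = "list", decoys = "list", seed = "integer"
))

setValidity("FixtureLibrary", function(object) {
  nm <- sort(tolower(vapply(object@hits, function(m) m@name, character(1))))
  if (!identical(nm, sort(.HIT_NAMES)))
    return("hits must be exactly the eight named drugs")
  TRUE
})

#' ScreenConfig: configuration of a virtual screen
#'
#' @slot mwLo,mwHi numeric(1), molecular-weight window in g/mol (closed
#'   interval, defaults 200 and 600).
#' @slot nConformers integer(1), requested conformers per molecule.
#' @slot seed integer(1).
#' @slot tolerance numeric(1), optional \eqn{\AA} override of every pair
#'   tolerance (NA = use model tolerances).
#' @slot models character, subset of \code{c("bk_consensus","bk_b1","bk_b2")};
#'   must contain "bk_consensus".
#' @export
setClass("ScreenConfig", representation(
  mwLo = "numeric", mwHi = "numeric", nConformers = "integer",
  seed = "integer", tolerance = "numeric", models = "character"
))

setValidity("ScreenConfig", function(object) {
  if (!(object@mwLo < object@mwHi))
    return("mwLo must be strictly less than mwHi")
  if (object@nConformers < 1L) return("nConformers must be >= 1")
  if (!"bk_consensus" %in% object@models)
    return("the consensus model must always be screened")
  bad <- setdiff(object@models, c("bk_consensus", "bk_b1", "bk_b2"))
  if (length(bad)) return(paste("unknown model:", bad[1]))
  TRUE
})

#' ScreenReport: per-molecule results of a virtual screen
#'
#' @slot results data.frame, one row per input molecule (see [runScreen()]).
#' @slot matches list (per molecule) of named lists of [MatchResult-class].
#' @slot config the [ScreenConfig-class] used.
#' @slot metadata list: seed, config hash, package version, timestamp.
#' @export
setClass("ScreenReport", representation(
  results = "data.frame", matches = "list", config = "ScreenConfig",
  metadata = "list"
))
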