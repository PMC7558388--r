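# Pharmacophore models: constructors, the three built-in bradykinin models,
# distance-geometry embedding with 3D-realizability diagnostics, and a
# versioned YAML serialization.

#' Construct a pharmacophore point
#'
#' @param label character(1), unique point label (e.g. "P1").
#' @param acceptedTypes character, subset of [featureTypes()] a ligand
#'   feature may have to occupy this point.
#' @param tolerance sphere radius in \eqn{\AA}; NA means "use the model
#'   default".
#' @return a [PharmacophorePoint-class].
#' @export
phPoint <- function(label, acceptedTypes, tolerance = NA_real_) {
  p <- new("PharmacophorePoint", label = label,
           acceptedTypes = acceptedTypes, tolerance = as.numeric(tolerance))
  if (!is.na(tolerance)) validObject(p)
  p
}

#' Construct a pharmacophore model
#'
#' @param name character(1).
#' @param points list of [PharmacophorePoint-class] objects.
#' @param distances symmetric matrix of target inter-point distances
#'   (\eqn{\AA}); dimnames are set to the point labels.
#' @param defaultTolerance \eqn{\AA}, default 1.5.
#' @return a [PharmacophoreModel-class].
#' @export
pharmacophoreModel <- function(name, points, distances,
                               defaultTolerance = 1.5) {
  distances <- as.matrix(distances)
  labs <- vapply(points, function(p) p@label, character(1))
  dimnames(distances) <- list(labs, labs)
  m <- new("PharmacophoreModel", name = name, points = points,
           distances = distances, defaultTolerance = defaultTolerance)
  validObject(m)
  m
}

# Consensus inter-point distances shared by the B1 and B2 five-point models,
# and the receptor-specific P5 rows.
.BK_CONSENSUS_D <- local({
  D <- matrix(0, 4, 4, dimnames = list(paste0("P", 1:4), paste0("P", 1:4)))
  D["P1", "P2"] <- D["P2", "P1"] <- 9.0
  D["P1", "P3"] <- D["P3", "P1"] <- 14.0
  D["P1", "P4"] <- D["P4", "P1"] <- 10.5
  D["P2", "P3"] <- D["P3", "P2"] <- 6.0
  D["P2", "P4"] <- D["P4", "P2"] <- 7.0
  D["P3", "P4"] <- D["P4", "P3"] <- 7.5
  D
})
.BK_P5 <- list(
  bk_b1 = c(P1 = 9.5, P2 = 9.3, P3 = 9.5, P4 = 5.7),
  bk_b2 = c(P1 = 11.0, P2 = 9.0, P3 = 8.8, P4 = 8.4)
)

.consensusPoints <- function() list(
  phPoint("P1", "POSITIVE"),
  phPoint("P2", c("DONOR", "ACCEPTOR")),
  phPoint("P3", "AROMATIC"),
  phPoint("P4", c("DONOR", "ACCEPTOR"))
)

#' The built-in bradykinin-receptor pharmacophore models
#'
#' \describe{
#'   \item{bk_consensus}{the four points common to the B1 and B2 receptor
#'     pharmacophores: P1 positive charge, P2 and P4 hydrogen-bond
#'     donor-or-acceptor, P3 aromatic ring, with the six consensus
#'     inter-point distances. Ligands fulfilling all four are candidate
#'     non-selective antagonists.}
#'   \item{bk_b1}{consensus plus the B1-discriminating P5 (hydrogen-bond
#'     acceptor).}
#'   \item{bk_b2}{consensus plus the B2-discriminating P5
#'     (hydrophobic/aromatic moiety).}
#' }
#' P5 carries a larger tolerance radius (2.0 \eqn{\AA} vs the 1.5 \eqn{\AA}
#' default) because the five-point distance sets are not exactly realizable
#' in 3D; matching compares distance matrices directly and never embeds the
#' model, so the inconsistency is absorbed by the pair allowances (sums of
#' the two point radii).
#'
#' @param name one of "bk_consensus", "bk_b1", "bk_b2".
#' @return a [PharmacophoreModel-class].
#' @examples
#' builtinModel("bk_consensus")
#' @export
builtinModel <- function(name) {
  valid <- c("bk_consensus", "bk_b1", "bk_b2")
  if (!is.character(name) || length(name) != 1L || !(name %in% valid))
    stop("unknown model '", paste(name, collapse = ","),
         "'; valid names: ", paste(valid, collapse = ", "))
  if (name == "bk_consensus")
    return(pharmacophoreModel(name, .consensusPoints(), .BK_CONSENSUS_D))
  p5 <- if (name == "bk_b1") phPoint("P5", "ACCEPTOR", 2.0)
        else phPoint("P5", c("HYDROPHOBIC", "AROMATIC"), 2.0)
  D <- rbind(cbind(.BK_CONSENSUS_D, P5 = .BK_P5[[name]]),
             P5 = c(.BK_P5[[name]], 0))
  pharmacophoreModel(name, c(.consensusPoints(), list(p5)), D)
}

# Classical multidimensional scaling of a squared-distance matrix, with sign
# conventions fixed so the result is reproducible.
.cmdsEmbed <- function(D) {
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  lam <- e$values
  V <- e$vectors
  for (k in seq_len(ncol(V))) {   # canonical eigenvector signs
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  take <- seq_len(min(3L, n))
  X <- V[, take, drop = FALSE] %*% diag(sqrt(pmax(lam[take], 0)), length(take))
  if (ncol(X) < 3L) X <- cbind(X, matrix(0, n, 3L - ncol(X)))
  list(coords = X, eigenvalues = lam)
}

.pairDist <- function(X) as.matrix(stats::dist(X))

#' Embed a pharmacophore model in 3D
#'
#' Strict mode performs classical multidimensional scaling on the
#' squared-distance matrix; the model is flagged realizable iff the
#' doubly-centered Gram matrix has at most 3 positive eigenvalues, no
#' eigenvalue below \code{-1e-8} times the largest magnitude (a
#' Cayley-Menger-type positive-semidefiniteness condition), and the realized
#' distances reproduce the targets within 1e-6 \eqn{\AA}. Least-squares mode
#' additionally refines the coordinates to minimize the sum of squared
#' distance residuals, reporting the residual honestly; the realizability
#' flag is the same as in strict mode. A non-realizable matrix yields
#' \code{realizable = FALSE} with diagnostics, not an error.
#'
#' @param model a [PharmacophoreModel-class] (or a symmetric distance matrix).
#' @param mode "strict" or "least_squares".
#' @return an [EmbeddingResult-class].
#' @examples
#' embedModel(builtinModel("bk_consensus"))
#' @export
embedModel <- function(model, mode = c("strict", "least_squares")) {
  mode <- match.arg(mode)
  D <- if (is(model, "PharmacophoreModel")) model@distances else as.matrix(model)
  n <- nrow(D)
  emb <- .cmdsEmbed(D)
  lam <- emb$eigenvalues
  eps <- 1e-8 * max(abs(lam), 1e-300)
  psdOK <- (sum(lam > eps) <= 3L) && (min(lam) >= -eps)
  X <- emb$coords
  if (mode == "least_squares" && n >= 2L) {
    iu <- which(upper.tri(D))
    obj <- function(v) {
      Y <- matrix(v, n, 3L)
      sum((as.matrix(stats::dist(Y))[iu] - D[iu])^2)
    }
    grad <- function(v) {
      Y <- matrix(v, n, 3L)
      dm <- as.matrix(stats::dist(Y))
      G <- matrix(0, n, 3L)
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j || dm[i, j] < 1e-12) next
        w <- 2 * (dm[i, j] - D[i, j]) / dm[i, j]
        G[i, ] <- G[i, ] + w * (Y[i, ] - Y[j, ])
      }
      as.vector(G)
    }
    opt <- stats::optim(as.vector(X), obj, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    X <- matrix(opt$par, n, 3L)
  }
  X <- sweep(X, 2L, colMeans(X))
  realized <- .pairDist(X)
  maxResid <- max(abs(realized - D))
  realizable <- psdOK && maxResid <= 1e-6
  rownames(X) <- rownames(D)
  new("EmbeddingResult", coordinates = X, realizable = realizable,
      maxResidual = maxResid, gramEigenvalues = lam, mode = mode)
}

#' Serialize / parse pharmacophore models
#'
#' Versioned structured-text (YAML) format preserving the model name, point
#' labels, accepted types, tolerances and every distance to full precision.
#' Reading validates the schema and reports the offending field on failure.
#'
#' @param model a [PharmacophoreModel-class].
#' @param path optional file; when omitted, text is returned/parsed directly.
#' @return \code{writePharmacophore}: the serialized text (invisibly when
#'   written to a file). \code{readPharmacophore}: a
#'   [PharmacophoreModel-class].
#' @export
writePharmacophore <- function(model, path = NULL) {
  stopifnot(is(model, "PharmacophoreModel"))
  labs <- pointLabels(model)
  obj <- list(
    format = "phorescreen-model", version = 1L, name = model@name,
    default_tolerance = model@defaultTolerance,
    points = lapply(model@points, function(p) list(
      label = p@label, accepted_types = as.list(p@acceptedTypes),
      tolerance = if (is.na(p@tolerance)) NULL else p@tolerance)),
    distances = stats::setNames(lapply(seq_along(labs), function(i)
      stats::setNames(as.list(model@distances[i, ]), labs)), labs)
  )
  txt <- yaml::as.yaml(obj, precision = 15L)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' @rdname writePharmacophore
#' @param text serialized model text (alternative to \code{path}).
#' @export
readPharmacophore <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  obj <- yaml::yaml.load(text)
  need <- function(field) {
    if (is.null(obj[[field]])) stop("model file invalid: missing field '",
                                    field, "'")
    obj[[field]]
  }
  if (!identical(need("format"), "phorescreen-model"))
    stop("model file invalid: field 'format' must be 'phorescreen-model'")
  if (need("version") != 1L) stop("model file invalid: unsupported 'version'")
  ptsIn <- need("points")
  pts <- lapply(ptsIn, function(p) {
    if (is.null(p$label)) stop("model file invalid: point without 'label'")
    if (is.null(p$accepted_types))
      stop("model file invalid: point '", p$label, "' without 'accepted_types'")
    bad <- setdiff(unlist(p$accepted_types), featureTypes())
    if (length(bad)) stop("model file invalid: unknown feature type '",
                          bad[1], "' in point '", p$label, "'")
    tol <- if (is.null(p$tolerance)) NA_real_ else as.numeric(p$tolerance)
    if (!is.na(tol) && tol <= 0)
      stop("model file invalid: tolerance of point '", p$label,
           "' must be positive")
    phPoint(p$label, unlist(p$accepted_types), tol)
  })
  labs <- vapply(pts, function(p) p@label, character(1))
  dIn <- need("distances")
  D <- matrix(NA_real_, length(labs), length(labs),
              dimnames = list(labs, labs))
  for (i in labs) for (j in labs) {
    v <- dIn[[i]][[j]]
    if (is.null(v)) stop("model file invalid: missing distance [", i, "][",
                         j, "]")
    D[i, j] <- as.numeric(v)
  }
  if (any(D != t(D)))
    stop("model file invalid: 'distances' is not symmetric")
  if (any(D[upper.tri(D)] <= 0))
    stop("model file invalid: negative or zero distance in 'distances'")
  pharmacophoreModel(obj$name, pts, D,
                     defaultTolerance = as.numeric(need("default_tolerance")))
}
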