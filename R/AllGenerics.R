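#' @rdname Molecule-class
#' @param object,x an object.
#' @export
setGeneric("molName", function(x) standardGeneric("molName"))

#' @rdname Molecule-class
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname Molecule-class
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' @rdname Molecule-class
#' @export
setGeneric("numAtoms", function(x) standardGeneric("numAtoms"))

#' @rdname Molecule-class
#' @export
setGeneric("hasCoords", function(x) standardGeneric("hasCoords"))

#' @rdname ConformerEnsemble-class
#' @export
setGeneric("conformers", function(x) standardGeneric("conformers"))

#' @rdname ConformerEnsemble-class
#' @export
setGeneric("numConformers", function(x) standardGeneric("numConformers"))

#' @rdname ConformerEnsemble-class
#' @export
setGeneric("energies", function(x) standardGeneric("energies"))

#' @rdname PharmacophoreModel-class
#' @export
setGeneric("modelName", function(x) standardGeneric("modelName"))

#' @rdname PharmacophoreModel-class
#' @export
setGeneric("points", function(x) standardGeneric("points"))

#' @rdname PharmacophoreModel-class
#' @export
setGeneric("pointLabels", function(x) standardGeneric("pointLabels"))

#' @rdname PharmacophoreModel-class
#' @export
setGeneric("targetDistances", function(x) standardGeneric("targetDistances"))

#' @rdname PharmacophoreModel-class
#' @export
setGeneric("pairTolerances", function(x) standardGeneric("pairTolerances"))

#' @rdname MatchResult-class
#' @export
setGeneric("isMatched", function(x) standardGeneric("isMatched"))

#' @rdname ScreenReport-class
#' @export
setGeneric("results", function(x) standardGeneric("results"))

setMethod("molName", "Molecule", function(x) x@name)
setMethod("atoms", "Molecule", function(x) x@atoms)
setMethod("bonds", "Molecule", function(x) x@bonds)
setMethod("numAtoms", "Molecule", function(x) nrow(x@atoms))
setMethod("hasCoords", "Molecule", function(x) !anyNA(x@atoms$x))

setMethod("conformers", "ConformerEnsemble", function(x) x@conformers)
setMethod("numConformers", "ConformerEnsemble", function(x) length(x@conformers))
setMethod("energies", "ConformerEnsemble", function(x) x@energies)
setMethod("molName", "ConformerEnsemble", function(x) x@molecule@name)

setMethod("modelName", "PharmacophoreModel", function(x) x@name)
setMethod("points", "PharmacophoreModel", function(x) x@points)
setMethod("pointLabels", "PharmacophoreModel", function(x)
  vapply(x@points, function(p) p@label, character(1)))
setMethod("targetDistances", "PharmacophoreModel", function(x) x@distances)

# Point tolerances are sphere radii: a ligand feature satisfies a model
# point when it lies within that point's tolerance sphere, so the pairwise
# distance deviation two points can absorb is the sum of their radii (a
# point with NA tolerance inherits the model default). Matching never embeds
# the model; these pair allowances are also where the non-realizability of
# the 5-point distance sets is absorbed.
setMethod("pairTolerances", "PharmacophoreModel", function(x) {
  tol <- vapply(x@points, function(p) p@tolerance, numeric(1))
  tol[is.na(tol)] <- x@defaultTolerance
  m <- outer(tol, tol, "+")
  dimnames(m) <- dimnames(x@distances)
  diag(m) <- 0
  m
})

setMethod("isMatched", "MatchResult", function(x) x@matched)
setMethod("results", "ScreenReport", function(x) x@results)

setMethod("show", "Molecule", function(object) {
  cat(sprintf("Molecule '%s': %d heavy atoms, %d bonds, net charge %+d, %s coordinates\n",
              object@name, nrow(object@atoms), nrow(object@bonds),
              sum(object@atoms$charge),
              if (hasCoords(object)) "with" else "no"))
})

setMethod("show", "ConformerEnsemble", function(object) {
  cat(sprintf("ConformerEnsemble of '%s': %d conformer(s) (requested %d, seed %d)\n",
              object@molecule@name, length(object@conformers),
              object@params$n, object@seed))
  if (length(object@energies))
    cat(sprintf("  energy range: %.2f .. %.2f kcal/mol\n",
                min(object@energies), max(object@energies)))
})

setMethod("show", "PharmacophoreModel", function(object) {
  cat(sprintf("PharmacophoreModel '%s' (%d points, default tolerance %.2f A)\n",
              object@name, length(object@points), object@defaultTolerance))
  for (p in object@points)
    cat(sprintf("  %s: {%s} tol %.2f A\n", p@label,
                paste(p@acceptedTypes, collapse = ","),
                if (is.na(p@tolerance)) object@defaultTolerance else p@tolerance))
  cat("Target distances (A):\n")
  print(round(object@distances, 2))
})

setMethod("show", "EmbeddingResult", function(object) {
  cat(sprintf("EmbeddingResult (%s): realizable = %s, max residual = %.3g A\n",
              object@mode, object@realizable, object@maxResidual))
  cat("Gram eigenvalues:", format(signif(object@gramEigenvalues, 4)), "\n")
})

setMethod("show", "MatchResult", function(object) {
  if (object@matched)
    cat(sprintf("MatchResult: '%s' MATCHES '%s' (conformer %d, max dev %.3f A, sum sq %.3f A^2, superposition RMSD %.3f A)\n",
                object@molecule, object@model, object@bestConformer,
                object@maxDeviation, object@sumSqDeviation,
                object@superpositionRMSD))
  else
    cat(sprintf("MatchResult: '%s' does not match '%s'\n",
                object@molecule, object@model))
})

setMethod("show", "FixtureLibrary", function(object) {
  cat(sprintf("FixtureLibrary: 8 hit drugs + %d decoys (seed %d)\n",
              length(object@decoys), object@seed))
})

setMethod("show", "ScreenReport", function(object) {
  r <- object@results
  cat(sprintf("ScreenReport: %d molecule(s), seed %d\n",
              nrow(r), object@metadata$seed))
  if (nrow(r)) print(table(label = r$label))
})
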