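# Rule-based protonation adjustment and pharmacophore feature perception.
#
# Feature vocabulary: POSITIVE (positive-charge center), DONOR / ACCEPTOR
# (hydrogen-bonding), AROMATIC (ring, positioned at the ring centroid),
# HYDROPHOBIC (aliphatic carbocycle or chain of >= 3 aliphatic carbons,
# positioned at the group centroid). The composite "donor/acceptor" model
# points are handled on the model side (a point accepting either type);
# ligand perception stays atomic.

#' The closed feature-type vocabulary
#' @return character vector of the five recognized feature types.
#' @export
featureTypes <- function()
  c("POSITIVE", "DONOR", "ACCEPTOR", "AROMATIC", "HYDROPHOBIC")

.rulesCache <- new.env(parent = emptyenv())

.readRuleTable <- function(file) {
  if (!is.null(.rulesCache[[file]])) return(.rulesCache[[file]])
  path <- system.file("extdata", file, package = "PhoreScreen")
  if (!nzchar(path))  # not installed: development tree
    path <- file.path("inst", "extdata", file)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "",
                           quote = "")
  .rulesCache[[file]] <- tab
  tab
}

#' Assign physiological-pH formal charges
#'
#' Applies a fixed rule table (pH around 7.4 convention): aliphatic primary,
#' secondary and tertiary amines and the sp2 nitrogen of amidines/guanidines
#' gain +1 (with one extra hydrogen); carboxylic acids and tetrazoles lose a
#' proton to -1. Pyridine-type ring nitrogens, anilines, amides and
#' sulfonamides are left neutral. Idempotent: the patterns only match the
#' un-ionized forms.
#'
#' @param mol a [Molecule-class].
#' @return the adjusted [Molecule-class].
#' @examples
#' atoms(assignProtonation(parseSmiles("CCN", "ethylamine")))$charge
#' @export
assignProtonation <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  rules <- .readRuleTable("protonation_smarts.tsv")
  sdf <- .mol2sdf(mol)
  a <- mol@atoms
  gd <- .graphDistances(.adjList(nrow(a), mol@bonds))
  # graph distance to the nearest aromatic atom: aryl substitution lowers
  # amine basicity, so the remoter nitrogen of a diamine is preferred
  aromD <- if (any(a$aromatic))
    apply(gd[, a$aromatic, drop = FALSE], 1L, min) else rep(99, nrow(a))
  for (r in seq_len(nrow(rules))) {
    hits <- .obSmarts(sdf, rules$smarts[r])[[1]]
    if (length(hits) == 0L) next
    targets <- unique(vapply(hits, `[`, integer(1), rules$atom[r]))
    if (rules$dCharge[r] > 0L) {
      # one cation per proximal basic cluster: two basic centers within 3
      # bonds (e.g. the two nitrogens of a piperazine) yield a mono-cation;
      # prefer more hydrogens, then distance from aromatic rings
      targets <- targets[order(-a$implicitH[targets], -aromD[targets],
                               targets)]
      for (t in targets) {
        pos <- which(a$charge > 0L)
        if (length(pos) == 0L || min(gd[t, pos]) > 3) {
          a$charge[t] <- a$charge[t] + rules$dCharge[r]
          a$implicitH[t] <- a$implicitH[t] + rules$dH[r]
        }
      }
    } else {
      a$charge[targets] <- a$charge[targets] + rules$dCharge[r]
      a$implicitH[targets] <- pmax(0L, a$implicitH[targets] + rules$dH[r])
    }
  }
  mol@atoms <- a
  validObject(mol)
  mol
}

# Conformation-independent feature template: which atoms carry which feature,
# computed once per molecule from its graph and formal charges. Positions are
# filled in per conformer by perceiveFeatures().
.featureTemplate <- function(mol) {
  a <- mol@atoms
  sdf <- .mol2sdf(mol)
  feats <- list()
  add <- function(type, sourceAtoms, label)
    feats[[length(feats) + 1L]] <<- list(type = type,
                                         sourceAtoms = as.integer(sourceAtoms),
                                         label = label)
  # POSITIVE: one feature per positively charged atom (= per ionizable group)
  for (i in which(a$charge > 0L))
    add("POSITIVE", i, sprintf("positive charge on %s%d", a$elem[i], i))

  rules <- .readRuleTable("feature_smarts.tsv")
  seen <- list(DONOR = integer(0), ACCEPTOR = integer(0))
  for (r in seq_len(nrow(rules))) {
    hits <- .obSmarts(sdf, rules$smarts[r])[[1]]
    if (length(hits) == 0L) next
    if (rules$mode[r] == "atom") {
      ty <- rules$type[r]
      for (i in setdiff(unique(vapply(hits, `[`, integer(1), 1L)), seen[[ty]])) {
        seen[[ty]] <- c(seen[[ty]], i)
        add(ty, i, sprintf("%s (%s%d)", rules$label[r], a$elem[i], i))
      }
    } else {
      for (h in hits) add(rules$type[r], sort(h), rules$label[r])
    }
  }
  # HYDROPHOBIC chains: maximal connected sets of >= 3 acyclic, non-aromatic
  # carbons bonded only to carbon or hydrogen.
  b <- mol@bonds
  nbrElems <- lapply(seq_len(nrow(a)), function(i) {
    j <- c(b$a2[b$a1 == i], b$a1[b$a2 == i])
    a$elem[j]
  })
  eligible <- which(a$elem == "C" & !a$aromatic & a$ringSize == 0L &
                      vapply(nbrElems, function(e) all(e == "C"), logical(1)))
  if (length(eligible) >= 3L) {
    adj <- b[b$a1 %in% eligible & b$a2 %in% eligible, , drop = FALSE]
    comp <- setNames(seq_along(eligible), eligible)
    repeat {
      changed <- FALSE
      for (k in seq_len(nrow(adj))) {
        c1 <- comp[[as.character(adj$a1[k])]]
        c2 <- comp[[as.character(adj$a2[k])]]
        if (c1 != c2) { comp[comp == c2] <- c1; changed <- TRUE }
      }
      if (!changed) break
    }
    for (cc in split(eligible, comp))
      if (length(cc) >= 3L)
        add("HYDROPHOBIC", sort(cc),
            sprintf("aliphatic chain of %d carbons", length(cc)))
  }
  # deterministic ordering: by first source atom, then type, then size
  if (length(feats)) {
    ord <- order(vapply(feats, function(f) min(f$sourceAtoms), integer(1)),
                 vapply(feats, `[[`, character(1), "type"),
                 vapply(feats, function(f) length(f$sourceAtoms), integer(1)))
    feats <- feats[ord]
  }
  feats
}

#' Perceive pharmacophore features on one conformer
#'
#' Emits POSITIVE for every positively charged atom, DONOR for every N/O
#' bearing at least one hydrogen, ACCEPTOR for every N/O with an available
#' lone pair (excluding pyrrole-type N-H, amide and sulfonamide N, and
#' positively charged N), AROMATIC for every aromatic ring at its centroid,
#' and HYDROPHOBIC for every non-aromatic carbocycle and every chain of at
#' least three aliphatic carbons at the group centroid. Single-atom features
#' sit exactly on their source atom. The feature set (types and source atoms)
#' is conformation-independent; only positions vary between conformers.
#'
#' @param mol a [Molecule-class] (protonation already assigned if desired).
#' @param coords optional numeric matrix (heavy atoms x 3, \eqn{\AA}); by
#'   default the coordinates stored on the molecule.
#' @return data.frame with columns \code{type}, \code{x}, \code{y}, \code{z},
#'   \code{label} and list column \code{sourceAtoms}.
#' @export
perceiveFeatures <- function(mol, coords = NULL) {
  stopifnot(is(mol, "Molecule"))
  if (is.null(coords)) {
    coords <- cbind(mol@atoms$x, mol@atoms$y, mol@atoms$z)
  }
  coords <- as.matrix(coords)
  if (nrow(coords) < numAtoms(mol) || ncol(coords) != 3L || anyNA(coords))
    stop("perceiveFeatures needs complete 3D coordinates for all heavy atoms")
  template <- .featureTemplate(mol)
  .featurePositions(template, coords)
}

.featurePositions <- function(template, coords) {
  n <- length(template)
  out <- data.frame(type = character(n), x = numeric(n), y = numeric(n),
                    z = numeric(n), label = character(n))
  src <- vector("list", n)
  for (i in seq_len(n)) {
    f <- template[[i]]
    p <- colMeans(coords[f$sourceAtoms, , drop = FALSE])
    out$type[i] <- f$type
    out$x[i] <- p[1]; out$y[i] <- p[2]; out$z[i] <- p[3]
    out$label[i] <- f$label
    src[[i]] <- f$sourceAtoms
  }
  out$sourceAtoms <- src
  out
}
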