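# Molecule input/output and the molecular-weight filter.

.newMolecule <- function(name, parsed, source) {
  new("Molecule", name = as.character(name), atoms = parsed$atoms,
      bonds = parsed$bonds, source = as.character(source))
}

# Light lexical sanity check run before handing a SMILES string to OpenBabel,
# whose reader silently truncates some malformed inputs instead of failing.
.smilesLexCheck <- function(text) {
  chars <- strsplit(text, "")[[1]]
  if (sum(chars == "(") != sum(chars == ")"))
    return("unbalanced parentheses")
  if (sum(chars == "[") != sum(chars == "]"))
    return("unbalanced brackets")
  stripped <- gsub("\\[[^]]*\\]", "A", text)   # ring digits never inside []
  stripped <- gsub("%[0-9]{2}", "R", stripped) # two-digit closures pair as R
  for (d in c(0:9, "R")) {
    k <- sum(strsplit(stripped, "")[[1]] == as.character(d))
    if (k %% 2 != 0) return(sprintf("unpaired ring closure '%s'", d))
  }
  NULL
}

#' Parse a SMILES string into a Molecule
#'
#' Sanitizes the input (valence and aromaticity perception are delegated to
#' OpenBabel), producing a [Molecule-class] without 3D coordinates.
#'
#' @param smiles character(1), a SMILES string.
#' @param name character(1), identifier for the molecule.
#' @return A [Molecule-class].
#' @examples
#' parseSmiles("c1ccccc1", "benzene")
#' @export
parseSmiles <- function(smiles, name = "molecule") {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(trimws(smiles)))
    stop("SMILES input must be a single non-empty string")
  smiles <- trimws(smiles)
  lex <- .smilesLexCheck(smiles)
  if (!is.null(lex))
    stop(sprintf("cannot parse SMILES '%s': %s", smiles, lex))
  parsed <- tryCatch(.obParse("SMI", smiles),
                     error = function(e) stop(sprintf(
                       "cannot parse SMILES '%s': %s", smiles,
                       conditionMessage(e)), call. = FALSE))
  if (length(parsed) == 0L)
    stop(sprintf("cannot parse SMILES '%s': no atoms produced", smiles))
  .newMolecule(name, parsed[[1]], smiles)
}

# Serialize one Molecule to an SDF (V2000) record; fixed formatting so that
# write -> read -> write is byte-stable. Missing coordinates are written as
# zeros (and read back as absent).
.mol2sdf <- function(mol, coords = NULL) {
  a <- mol@atoms
  b <- mol@bonds
  if (is.null(coords)) {
    coords <- cbind(a$x, a$y, a$z)
    if (anyNA(coords)) coords <- matrix(0, nrow(a), 3L)
  }
  stopifnot(nrow(coords) == nrow(a))
  lines <- c(
    mol@name, "  PhoreScreen", "",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            coords[, 1], coords[, 2], coords[, 3], a$elem)
  )
  if (nrow(b) > 0L)
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", b$a1, b$a2, b$order))
  chg <- which(a$charge != 0L)
  if (length(chg)) {
    for (grp in split(chg, ceiling(seq_along(chg) / 8))) {
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(grp)),
                               paste0(sprintf("%4d%4d", grp, a$charge[grp]),
                                      collapse = "")))
    }
  }
  paste(c(lines, "M  END", "$$$$", ""), collapse = "\n")
}

.splitSdfRecords <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  ends <- grep("^\\${4}", lines)
  if (length(ends) == 0L) return(character(0))
  starts <- c(1L, head(ends, -1L) + 1L)
  mapply(function(s, e) paste(c(lines[s:e], ""), collapse = "\n"),
         starts, ends)
}

#' Read molecules from a file
#'
#' @param path file to read.
#' @param format "sdf" (MDL V2000) or "smiles" (one record per line, optional
#'   whitespace-separated name).
#' @param lenient logical; when TRUE a corrupt record produces a warning
#'   carrying its index and the remaining records are still returned.
#' @return list of [Molecule-class] objects.
#' @export
readMolecules <- function(path, format = c("sdf", "smiles"), lenient = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (format == "sdf") {
    recs <- .splitSdfRecords(text)
    out <- vector("list", length(recs))
    keep <- logical(length(recs))
    for (i in seq_along(recs)) {
      m <- tryCatch({
        p <- .obParse("SDF", recs[[i]])
        if (length(p) == 0L) stop("record is empty")
        nm <- p[[1]]$title
        if (!nzchar(nm)) nm <- sprintf("record_%d", i)
        .newMolecule(nm, p[[1]], recs[[i]])
      }, error = function(e) {
        if (lenient) {
          warning(sprintf("skipping corrupt SDF record %d: %s", i,
                          conditionMessage(e)), call. = FALSE)
          NULL
        } else stop(sprintf("corrupt SDF record %d: %s", i,
                            conditionMessage(e)), call. = FALSE)
      })
      if (!is.null(m)) { out[[i]] <- m; keep[i] <- TRUE }
    }
    out[keep]
  } else {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    out <- vector("list", length(lines))
    keep <- logical(length(lines))
    for (i in seq_along(lines)) {
      tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      nm <- if (length(tok) > 1L) paste(tok[-1L], collapse = " ")
            else sprintf("record_%d", i)
      m <- tryCatch(parseSmiles(tok[1L], nm), error = function(e) {
        if (lenient) {
          warning(sprintf("skipping corrupt SMILES record %d: %s", i,
                          conditionMessage(e)), call. = FALSE)
          NULL
        } else stop(sprintf("corrupt SMILES record %d: %s", i,
                            conditionMessage(e)), call. = FALSE)
      })
      if (!is.null(m)) { out[[i]] <- m; keep[i] <- TRUE }
    }
    out[keep]
  }
}

#' Write molecules to a file
#'
#' The SDF writer preserves atom order, kekulized bond orders and formal
#' charges; a write/read round trip preserves atom count, bond count, formal
#' charges and names, and a second write is byte-identical.
#'
#' @param mols list of [Molecule-class] objects.
#' @param path output file.
#' @param format "sdf" or "smiles" (canonical SMILES plus name, tab-separated).
#' @return the path, invisibly.
#' @export
writeMolecules <- function(mols, path, format = c("sdf", "smiles")) {
  format <- match.arg(format)
  stopifnot(all(vapply(mols, is, logical(1), "Molecule")))
  if (format == "sdf") {
    txt <- paste(vapply(mols, .mol2sdf, character(1)), collapse = "")
    cat(txt, file = path)
  } else {
    lines <- vapply(mols, function(m) {
      smi <- .obCanonicalSmiles(.mol2sdf(m))
      paste(smi, m@name, sep = "\t")
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Molecular weight of a molecule
#'
#' Sum of standard atomic masses over all atoms including implicit hydrogens,
#' in g/mol.
#'
#' @param mol a [Molecule-class].
#' @return numeric(1), g/mol.
#' @examples
#' molecularWeight(parseSmiles("O", "water"))  # 18.02
#' @export
molecularWeight <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  a <- atoms(mol)
  if (nrow(a) == 0L) stop("molecule has no atoms")
  sum(.massOf(a$elem)) + sum(a$implicitH) * .ATOMIC_MASS[["H"]]
}

#' Filter molecules by molecular weight
#'
#' Retains molecules whose weight lies in the closed interval
#' \code{[lo, hi]}; the two returned lists partition the input preserving
#' order.
#'
#' @param mols list of [Molecule-class] objects.
#' @param lo,hi bounds in g/mol (defaults 200 and 600).
#' @return list with elements \code{retained} and \code{excluded}.
#' @export
weightFilter <- function(mols, lo = 200, hi = 600) {
  if (!(lo < hi)) stop("weight filter misconfigured: lo must be < hi")
  if (length(mols) == 0L) return(list(retained = list(), excluded = list()))
  mw <- vapply(mols, molecularWeight, numeric(1))
  inside <- mw >= lo & mw <= hi
  list(retained = mols[inside], excluded = mols[!inside])
}
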