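# Internal glue around OpenBabel: molecule parsing through the ChemmineOB
# SWIG bindings, SMARTS matching with atom-index map lists (not exposed by the
# high-level ChemmineOB API), and the obabel/obenergy command-line tools used
# for force-field refinement of conformers.

.cob <- function() getNamespace("ChemmineOB")

# Standard atomic weights (IUPAC 2021, conventional values) for the elements
# that occur in drug-like organic molecules and the decoy pool.
.ATOMIC_MASS <- c(
  H = 1.008, He = 4.0026, Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.95,
  K = 39.098, Ca = 40.078, Fe = 55.845, Cu = 63.546, Zn = 65.38,
  As = 74.922, Se = 78.971, Br = 79.904, I = 126.90
)

.ELEMENT_SYMBOL <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe"
)

.massOf <- function(elem) {
  m <- .ATOMIC_MASS[elem]
  if (anyNA(m))
    stop("no atomic mass tabulated for element(s): ",
         paste(unique(elem[is.na(m)]), collapse = ", "))
  unname(m)
}

# Apply f to every molecule record OpenBabel can read from `text`; reads
# until the stream is exhausted rather than trusting the record pre-count,
# which undercounts some multi-record SDF output.
.obForEach <- function(format, text, f) {
  cob <- .cob()
  inStr <- cob$istreamFromString(text)
  conv <- cob$OBConversion(inStr)
  if (!cob$OBConversion_SetInFormat(conv, format))
    stop("unknown OpenBabel input format: ", format)
  out <- list()
  repeat {
    mol <- cob$OBMol()
    if (!cob$OBConversion_Read(conv, mol)) break
    out[[length(out) + 1L]] <- f(mol)
  }
  out
}

# Parse one or more molecule records with OpenBabel and extract atom/bond
# tables. `format` is an OpenBabel format tag ("SMI", "SDF", ...). Returns a
# list with one entry per record: list(title, atoms, bonds) where atoms has
# columns elem/charge/implicitH/aromatic/ringSize/x/y/z and bonds has columns
# a1/a2/order/aromatic/ring/eqLength. Coordinates are NA when the record
# carries none (all-zero coordinate blocks are treated as absent).
.obParse <- function(format, text) {
  cob <- .cob()
  out <- .obForEach(format, text, function(mol) {
    n <- cob$OBMol_NumAtoms(mol)
    if (n == 0L) return(NULL)
    atoms <- data.frame(
      elem = character(n), charge = integer(n), implicitH = integer(n),
      aromatic = logical(n), ringSize = integer(n),
      x = numeric(n), y = numeric(n), z = numeric(n)
    )
    for (i in seq_len(n)) {
      a <- cob$OBMol_GetAtom(mol, i)
      atoms$elem[i] <- .ELEMENT_SYMBOL[cob$OBAtom_GetAtomicNum(a)]
      atoms$charge[i] <- as.integer(cob$OBAtom_GetFormalCharge(a))
      atoms$implicitH[i] <- as.integer(cob$OBAtom_GetImplicitHCount(a))
      atoms$aromatic[i] <- cob$OBAtom_IsAromatic(a)
      rs <- 0L
      for (s in 3:8) if (cob$OBAtom_IsInRingSize(a, s)) { rs <- s; break }
      atoms$ringSize[i] <- rs
      atoms$x[i] <- cob$OBAtom_GetX(a)
      atoms$y[i] <- cob$OBAtom_GetY(a)
      atoms$z[i] <- cob$OBAtom_GetZ(a)
    }
    if (all(atoms$x == 0 & atoms$y == 0 & atoms$z == 0))
      atoms$x <- atoms$y <- atoms$z <- NA_real_
    nb <- cob$OBMol_NumBonds(mol)
    bonds <- data.frame(
      a1 = integer(nb), a2 = integer(nb), order = integer(nb),
      aromatic = logical(nb), ring = logical(nb), eqLength = numeric(nb)
    )
    for (i in seq_len(nb)) {
      b <- cob$OBMol_GetBond(mol, i - 1L)
      bonds$a1[i] <- as.integer(cob$OBBond_GetBeginAtomIdx(b))
      bonds$a2[i] <- as.integer(cob$OBBond_GetEndAtomIdx(b))
      bonds$order[i] <- as.integer(cob$OBBond_GetBondOrder(b))
      bonds$aromatic[i] <- cob$OBBond_IsAromatic(b)
      bonds$ring[i] <- cob$OBBond_IsInRing(b)
      bonds$eqLength[i] <- cob$OBBond_GetEquibLength(b)
    }
    list(title = cob$OBMol_GetTitle(mol), atoms = atoms, bonds = bonds)
  })
  Filter(Negate(is.null), out)
}

# SMARTS matching against an SDF text block. Returns, per molecule record, a
# list of integer vectors of matched atom indices (1-based, unique match sets).
.obSmarts <- function(sdfText, smarts) {
  cob <- .cob()
  .obForEach("SDF", sdfText, function(mol) {
    sp <- cob$OBSmartsPattern()
    on.exit(cob$delete_OBSmartsPattern(sp))
    if (!cob$OBSmartsPattern_Init(sp, smarts))
      stop("failed to parse SMARTS pattern: ", smarts)
    if (!cob$OBSmartsPattern_Match(sp, mol)) return(list())
    maps <- cob$OBSmartsPattern_GetUMapList(sp)
    lapply(maps, as.integer)
  })
}

.obCanonicalSmiles <- function(sdfText) {
  out <- ChemmineOB::convertFormat("SDF", "CAN", sdfText)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  vapply(strsplit(lines, "\t|[ ]+"), `[`, character(1), 1L)
}

.obabelPath <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("the 'obabel' executable is required but not on PATH")
  p
}

.obenergyPath <- function() {
  p <- Sys.which("obenergy")
  if (!nzchar(p)) stop("the 'obenergy' executable is required but not on PATH")
  p
}

# Add hydrogens and energy-minimize every record of an SDF file with a
# molecular-mechanics force field; deterministic for a given input file.
.obMinimizeFile <- function(inPath, outPath, ff = "MMFF94", steps = 300L) {
  res <- suppressWarnings(system2(
    .obabelPath(),
    c(inPath, "-O", outPath, "-h",
      "--minimize", "--ff", ff, "--steps", as.integer(steps)),
    stdout = TRUE, stderr = TRUE
  ))
  if (!file.exists(outPath))
    stop("obabel minimization failed: ", paste(res, collapse = "\n"))
  invisible(outPath)
}

# Force-field energies (kcal/mol) for every record of an SDF file, in file
# order. UFF energies are reported by obenergy in kJ/mol and converted.
.obEnergies <- function(path, ff = "MMFF94") {
  out <- suppressWarnings(system2(
    .obenergyPath(), c("-ff", ff, path), stdout = TRUE, stderr = FALSE
  ))
  lines <- grep("^TOTAL ENERGY", out, value = TRUE)
  if (length(lines) == 0L) return(numeric(0))
  vals <- as.numeric(sub("^TOTAL ENERGY =\\s*([-0-9.eE+]+).*", "\\1", lines))
  if (any(grepl("kJ/mol", lines))) vals <- vals / 4.184
  vals
}
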