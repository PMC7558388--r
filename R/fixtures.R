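# Bundled fixture library: the eight approved drugs used to validate the
# screen, plus a hand-curated pool of neutral decoy scaffolds.

.HIT_NAMES <- c("raloxifene", "sildenafil", "cefepime", "cefpirome",
                "imatinib", "ponatinib", "abemaciclib", "entrectinib")

# Parent (free base / salt-stripped) structures encoded from standard public
# references; cefepime and cefpirome are native quaternary-ammonium
# zwitterions and are encoded as such.
.HIT_SMILES <- c(
  raloxifene  = "C1CCN(CC1)CCOc1ccc(cc1)C(=O)c1c(sc2cc(O)ccc12)-c1ccc(O)cc1",
  sildenafil  = "CCCc1nn(C)c2c1nc(-c1cc(ccc1OCC)S(=O)(=O)N1CCN(C)CC1)[nH]c2=O",
  cefepime    = "CON=C(C(=O)NC1C2SCC(=C(N2C1=O)C(=O)[O-])C[N+]1(C)CCCC1)c1csc(N)n1",
  cefpirome   = "CON=C(C(=O)NC1C2SCC(=C(N2C1=O)C(=O)[O-])C[n+]1ccc2c(c1)CCC2)c1csc(N)n1",
  imatinib    = "Cc1ccc(NC(=O)c2ccc(CN3CCN(C)CC3)cc2)cc1Nc1nccc(-c2cccnc2)n1",
  ponatinib   = "Cc1ccc(C(=O)Nc2ccc(CN3CCN(C)CC3)c(c2)C(F)(F)F)cc1C#Cc1cnc2cccnn12",
  abemaciclib = "CCN1CCN(Cc2ccc(Nc3ncc(F)c(-c4cc(F)c5nc(C)n(C(C)C)c5c4)n3)nc2)CC1",
  entrectinib = "CN1CCN(CC1)c1ccc(c(NC2CCOCC2)c1)C(=O)Nc1n[nH]c2ccc(Cc3cc(F)cc(F)c3)cc12"
)

# Published molecular weights (g/mol) of the parent structures; used as an
# encoding self-check when the library is built.
.HIT_MW <- c(
  raloxifene = 473.58, sildenafil = 474.58, cefepime = 480.56,
  cefpirome = 514.58, imatinib = 493.60, ponatinib = 532.56,
  abemaciclib = 506.59, entrectinib = 560.64
)

# Decoy pool: neutral, mostly rigid scaffolds with no basic amine, amidine or
# guanidine (no positive-ionizable group, so the positive-charge point is
# unmatchable by construction), molecular weights inside [200, 600].
.DECOY_SMILES <- c(
  pyrene                   = "c1cc2ccc3cccc4ccc(c1)c2c34",
  fluoranthene             = "c1ccc2c(c1)-c1cccc3cccc2c13",
  triphenylene             = "c1ccc2c(c1)c1ccccc1c1ccccc21",
  chrysene                 = "c1ccc2c(c1)ccc1c2ccc2ccccc21",
  p_terphenyl              = "c1ccc(-c2ccc(-c3ccccc3)cc2)cc1",
  o_terphenyl              = "c1ccc(-c2ccccc2-c2ccccc2)cc1",
  pentacene                = "c1ccc2cc3cc4cc5ccccc5cc4cc3cc2c1",
  coronene                 = "c1cc2ccc3ccc4ccc5ccc6ccc1c1c6c5c4c3c21",
  benzyl_benzoate          = "O=C(OCc1ccccc1)c1ccccc1",
  dibenzoylmethane         = "O=C(CC(=O)c1ccccc1)c1ccccc1",
  anthraquinone            = "O=C1c2ccccc2C(=O)c2ccccc21",
  phenanthrenequinone      = "O=C1c2ccccc2-c2ccccc2C1=O",
  thioxanthone             = "O=C1c2ccccc2Sc2ccccc21",
  binaphthyl               = "c1ccc2c(-c3ccc4ccccc4c3)cccc2c1",
  phenylanthracene         = "c1ccc(-c2c3ccccc3cc3ccccc23)cc1",
  triphenylbenzene         = "c1ccc(-c2cc(-c3ccccc3)cc(-c3ccccc3)c2)cc1",
  biphenyl_diester         = "COC(=O)c1ccc(-c2ccc(C(=O)OC)cc2)cc1",
  diphenyl_phthalate       = "O=C(Oc1ccccc1)c1ccccc1C(=O)Oc1ccccc1",
  dimethyl_naphthalate     = "COC(=O)c1ccc2cc(C(=O)OC)ccc2c1",
  benzil                   = "O=C(C(=O)c1ccccc1)c1ccccc1",
  benzoylbiphenyl          = "O=C(c1ccccc1)c1ccc(-c2ccccc2)cc1",
  diphenylanthracene       = "c1ccc(-c2c3ccccc3c(-c3ccccc3)c3ccccc23)cc1",
  decafluorobiphenyl       = "Fc1c(F)c(F)c(-c2c(F)c(F)c(F)c(F)c2F)c(F)c1F",
  octafluoronaphthalene    = "Fc1c(F)c(F)c2c(F)c(F)c(F)c(F)c2c1F",
  tetraphenylethylene      = "c1ccc(C(=C(c2ccccc2)c2ccccc2)c2ccccc2)cc1"
)

.makeHit <- function(name) {
  mol <- parseSmiles(.HIT_SMILES[[name]], name)
  mw <- molecularWeight(mol)
  if (abs(mw - .HIT_MW[[name]]) > 0.5)
    stop(sprintf("encoded structure of %s has MW %.2f, expected %.2f",
                 name, mw, .HIT_MW[[name]]))
  mol
}

#' The bundled fixture library
#'
#' Builds the screen-validation library: the eight approved drugs identified
#' as prospective non-selective bradykinin-receptor antagonists (raloxifene,
#' sildenafil, cefepime, cefpirome, imatinib, ponatinib, abemaciclib,
#' entrectinib; parent structures) plus \code{nDecoys} decoy molecules drawn
#' deterministically from a built-in pool of neutral scaffolds that contain
#' no basic amine, amidine or guanidine. Every decoy therefore yields zero
#' positive-ionizable features and is a guaranteed screen negative.
#'
#' @param nDecoys number of decoys to draw (>= 0); when it exceeds the pool
#'   size the pool is recycled with numbered names.
#' @param seed integer seed controlling the decoy draw.
#' @return a [FixtureLibrary-class].
#' @examples
#' fixtureLibrary(0, 1)
#' @export
fixtureLibrary <- function(nDecoys = 12L, seed = 1L) {
  nDecoys <- as.integer(nDecoys)
  if (is.na(nDecoys) || nDecoys < 0L) stop("nDecoys must be >= 0")
  hits <- lapply(.HIT_NAMES, .makeHit)
  decoys <- list()
  if (nDecoys > 0L) {
    picks <- withCallingHandlers(
      local({
        old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
                else suppressWarnings(rm(".Random.seed", envir = globalenv())))
        set.seed(seed)
        idx <- integer(0)
        while (length(idx) < nDecoys)
          idx <- c(idx, sample(seq_along(.DECOY_SMILES),
                               min(nDecoys - length(idx), length(.DECOY_SMILES))))
        idx
      }), warning = function(w) invokeRestart("muffleWarning"))
    nm <- names(.DECOY_SMILES)[picks]
    dup <- ave(seq_along(nm), nm, FUN = seq_along)
    nm <- ifelse(dup > 1L, paste(nm, dup, sep = "_"), nm)
    decoys <- mapply(function(s, n) parseSmiles(s, n),
                     .DECOY_SMILES[picks], nm, SIMPLIFY = FALSE)
    names(decoys) <- NULL
  }
  new("FixtureLibrary", hits = hits, decoys = decoys, seed = as.integer(seed))
}
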