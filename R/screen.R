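# End-to-end virtual screening pipeline: molecular-weight filter ->
# protonation -> conformer generation -> per-model matching -> selectivity
# label, with deterministic CSV/summary reporting.

#' Construct a screen configuration
#'
#' @param mwLo,mwHi molecular-weight window in g/mol (closed interval;
#'   defaults 200 and 600).
#' @param nConformers requested conformers per molecule (default 200).
#' @param seed integer seed for the whole screen.
#' @param tolerance optional \eqn{\AA} override of every pair tolerance
#'   (NA = model defaults).
#' @param models models to screen; must include "bk_consensus".
#' @return a [ScreenConfig-class].
#' @export
screenConfig <- function(mwLo = 200, mwHi = 600, nConformers = 200L,
                         seed = 1L, tolerance = NA_real_,
                         models = c("bk_consensus", "bk_b1", "bk_b2")) {
  cfg <- new("ScreenConfig", mwLo = as.numeric(mwLo), mwHi = as.numeric(mwHi),
             nConformers = as.integer(nConformers), seed = as.integer(seed),
             tolerance = as.numeric(tolerance), models = models)
  validObject(cfg)
  cfg
}

#' Selectivity label from per-model match results
#'
#' Fulfilling the four common points (the consensus model) is the paper-level
#' criterion for a non-selective candidate; the receptor-specific 5-point
#' models refine the call when they were screened:
#' consensus unmatched gives \code{no_match}; consensus matched and both (or
#' neither) 5-point model matched gives \code{non_selective_candidate};
#' exactly one 5-point model matched gives \code{b1_biased} or
#' \code{b2_biased}; when no 5-point model was screened at all the label is
#' \code{consensus_only}.
#'
#' @param consensus a [MatchResult-class] for the consensus model.
#' @param b1,b2 optional [MatchResult-class] for the 5-point models (NULL =
#'   not screened).
#' @return character(1) label.
#' @export
classifySelectivity <- function(consensus, b1 = NULL, b2 = NULL) {
  stopifnot(is(consensus, "MatchResult"))
  if (!isMatched(consensus)) return("no_match")
  if (is.null(b1) && is.null(b2)) return("consensus_only")
  m1 <- !is.null(b1) && isMatched(b1)
  m2 <- !is.null(b2) && isMatched(b2)
  if (m1 && !m2) return("b1_biased")
  if (m2 && !m1) return("b2_biased")
  "non_selective_candidate"
}

.fnv1a <- function(text) {
  xor32 <- function(a, b) {   # 32-bit xor on doubles (bitwXor is 31-bit)
    lo <- bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
    hi <- bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536))
    hi * 65536 + lo
  }
  h <- 2166136261
  for (b in utf8ToInt(text)) {
    h <- xor32(h, b)
    # h * 16777619 mod 2^32, kept exact in doubles via a 16-bit split
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.configHash <- function(config)
  .fnv1a(paste(config@mwLo, config@mwHi, config@nConformers, config@seed,
               config@tolerance, paste(config@models, collapse = ","),
               sep = "|"))

#' Run the virtual screen
#'
#' Stages, in order, per molecule: molecular-weight filter (closed interval),
#' protonation assignment, seeded conformer-ensemble generation, matching
#' against each configured pharmacophore model, selectivity labeling.
#' Deterministic for a fixed configuration and seed (each molecule receives
#' the sub-seed \code{seed + position - 1}). A conformer-generation failure
#' is recorded on the molecule's row (label \code{error}) and does not abort
#' the screen.
#'
#' @param library list of [Molecule-class] objects (possibly empty), or a
#'   [FixtureLibrary-class].
#' @param config a [ScreenConfig-class].
#' @param verbose logical, log stage decisions to stderr.
#' @return a [ScreenReport-class]. The \code{results} data.frame has one row
#'   per input molecule with columns name, mw, passed_filter, n_conformers,
#'   matched per model, best deviations, selectivity label and a
#'   flag_for_docking column marking consensus hits for downstream
#'   receptor-side checks (docking itself is out of scope here).
#' @export
runScreen <- function(library, config = screenConfig(), verbose = FALSE) {
  if (is(library, "FixtureLibrary")) library <- c(library@hits, library@decoys)
  stopifnot(is.list(library),
            all(vapply(library, is, logical(1), "Molecule")))
  validObject(config)
  say <- function(...) if (verbose) message(sprintf(...))
  models <- lapply(stats::setNames(config@models, config@models), builtinModel)
  tol <- if (is.na(config@tolerance)) NULL else config@tolerance
  nMol <- length(library)
  rows <- vector("list", nMol)
  matches <- vector("list", nMol)
  for (i in seq_len(nMol)) {
    mol <- library[[i]]
    mw <- molecularWeight(mol)
    row <- list(name = mol@name, mw = round(mw, 3), passed_filter = FALSE,
                n_conformers = 0L,
                matched_consensus = NA, matched_b1 = NA, matched_b2 = NA,
                best_sumsq_consensus = NA_real_, best_conformer = NA_integer_,
                label = "filtered_out", flag_for_docking = FALSE,
                note = "")
    if (mw < config@mwLo || mw > config@mwHi) {
      say("%s: MW %.1f outside [%g, %g], filtered out", mol@name, mw,
          config@mwLo, config@mwHi)
      rows[[i]] <- row
      next
    }
    row$passed_filter <- TRUE
    res <- tryCatch({
      prot <- assignProtonation(mol)
      ens <- generateConformers(prot, n = config@nConformers,
                                seed = config@seed + i - 1L)
      say("%s: %d conformer(s)", mol@name, numConformers(ens))
      mr <- lapply(models, function(mo) matchMolecule(ens, mo, tolerance = tol))
      list(ensemble = ens, results = mr)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      row$label <- "error"
      row$note <- conditionMessage(res)
      say("%s: ERROR %s", mol@name, row$note)
      rows[[i]] <- row
      next
    }
    matches[[i]] <- res$results
    cons <- res$results[["bk_consensus"]]
    row$n_conformers <- numConformers(res$ensemble)
    row$matched_consensus <- isMatched(cons)
    if ("bk_b1" %in% names(res$results))
      row$matched_b1 <- isMatched(res$results[["bk_b1"]])
    if ("bk_b2" %in% names(res$results))
      row$matched_b2 <- isMatched(res$results[["bk_b2"]])
    if (isMatched(cons)) {
      row$best_sumsq_consensus <- round(cons@sumSqDeviation, 4)
      row$best_conformer <- cons@bestConformer
      row$flag_for_docking <- TRUE
    }
    row$label <- classifySelectivity(
      cons,
      if ("bk_b1" %in% names(res$results)) res$results[["bk_b1"]],
      if ("bk_b2" %in% names(res$results)) res$results[["bk_b2"]])
    say("%s: label %s", mol@name, row$label)
    rows[[i]] <- row
  }
  results <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(results))
    results <- data.frame(name = character(0), mw = numeric(0),
                          passed_filter = logical(0),
                          n_conformers = integer(0),
                          matched_consensus = logical(0),
                          matched_b1 = logical(0), matched_b2 = logical(0),
                          best_sumsq_consensus = numeric(0),
                          best_conformer = integer(0), label = character(0),
                          flag_for_docking = logical(0), note = character(0))
  rownames(results) <- NULL
  new("ScreenReport", results = results, matches = matches, config = config,
      metadata = list(seed = config@seed, config_hash = .configHash(config),
                      package_version = as.character(utils::packageVersion("PhoreScreen")),
                      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
}

#' Write a screen report to disk
#'
#' Writes \code{<prefix>.csv} (frozen column order, no timestamp, so
#' identical configuration and seed give byte-identical files) and
#' \code{<prefix>_summary.txt} (run metadata including the timestamp and a
#' label tally). With \code{writeHits = TRUE} the best-matching conformer of
#' every consensus hit is also written to \code{<prefix>_hits.sdf}.
#'
#' @param report a [ScreenReport-class].
#' @param prefix output path prefix.
#' @param library the molecule list that was screened (only needed for
#'   \code{writeHits}).
#' @param writeHits logical.
#' @return invisible character vector of the files written.
#' @export
writeScreenReport <- function(report, prefix, library = NULL,
                              writeHits = FALSE) {
  stopifnot(is(report, "ScreenReport"))
  csvPath <- paste0(prefix, ".csv")
  utils::write.csv(results(report), csvPath, row.names = FALSE, quote = TRUE)
  sumPath <- paste0(prefix, "_summary.txt")
  r <- results(report)
  lines <- c("PhoreScreen run summary",
             sprintf("timestamp: %s", report@metadata$timestamp),
             sprintf("package version: %s", report@metadata$package_version),
             sprintf("seed: %d", report@metadata$seed),
             sprintf("config hash: %s", report@metadata$config_hash),
             sprintf("models: %s", paste(report@config@models, collapse = ", ")),
             sprintf("molecules screened: %d", nrow(r)),
             "label counts:")
  if (nrow(r)) {
    tab <- table(r$label)
    lines <- c(lines, sprintf("  %s: %d", names(tab), as.integer(tab)))
  }
  writeLines(lines, sumPath)
  out <- c(csvPath, sumPath)
  if (writeHits && !is.null(library) && nrow(r)) {
    hitIdx <- which(!is.na(r$matched_consensus) & r$matched_consensus)
    if (length(hitIdx)) {
      sdfPath <- paste0(prefix, "_hits.sdf")
      txt <- character(0)
      for (i in hitIdx) {
        cons <- report@matches[[i]][["bk_consensus"]]
        mol <- assignProtonation(library[[i]])
        ens <- generateConformers(mol, n = report@config@nConformers,
                                  seed = report@config@seed + i - 1L)
        txt <- c(txt, .mol2sdf(mol, ens@conformers[[cons@bestConformer]]))
      }
      cat(paste(txt, collapse = ""), file = sdfPath)
      out <- c(out, sdfPath)
    }
  }
  invisible(out)
}
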