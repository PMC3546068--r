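## End-to-end orchestration: runs -> raw areas -> internal-standard
## normalization -> control-relative ratios -> per-site statistics.

#' Quantify a paired experiment end-to-end
#'
#' For every run, integrates the raw peak area of each panel peptide
#' (fragment XICs for phosphopeptides, precursor XICs for internal
#' standards), normalizes each phosphopeptide area by the mean
#' internal-standard area of the same run, and summarizes each site with
#' control-relative ratios, fold change +/- SEM and a two-sided paired
#' t-test.
#'
#' @param runs either a named list of \linkS4class{SpectrumRun} (each
#'   carrying \code{condition} and \code{replicate} metadata) or the path
#'   of an experiment manifest (see \code{\link{readExperiment}}).
#' @param panel a \linkS4class{PeptidePanel}.
#' @param ppmTol precursor XIC tolerance, ppm (default 10).
#' @param daTol fragment XIC tolerance, Da (default 0.5).
#' @param exclude integer vector of pair indices to exclude, an explicit
#'   and logged choice (default none; there is no automatic outlier
#'   removal).
#' @param ... passed to \code{\link{quantifyPeptide}} (integration
#'   parameters).
#' @return list: \code{quant} (site x experiment x condition normalized
#'   areas), \code{results} (per-site fold change, SEM, t, p; see
#'   \code{\link{reanalyzeTable}}), \code{ratios}, \code{peptides} (raw
#'   per-run areas), \code{ions} (per-ion audit table), \code{log}
#'   (parameters and exclusions applied).
#' @export
runQuantify <- function(runs, panel = ppp1r12bPanel(), ppmTol = 10,
                        daTol = 0.5, exclude = integer(), ...) {
  if (is.character(runs)) runs <- readExperiment(runs)
  if (is(runs, "SpectrumRun")) runs <- list(runs)
  stopifnot(is(panel, "PeptidePanel"))

  cond <- vapply(runs, slot, character(1), name = "condition")
  repl <- vapply(runs, slot, integer(1), name = "replicate")
  ids <- vapply(runs, slot, character(1), name = "runId")
  if (any(is.na(cond)) || any(is.na(repl)))
    stop("every run needs condition and replicate metadata")
  pairs <- sort(unique(repl))
  orphan <- character()
  for (p in pairs) for (cc in c("control", "treated"))
    if (sum(repl == p & cond == cc) != 1L)
      orphan <- c(orphan, sprintf("pair %d: %s", p, cc))
  if (length(orphan))
    stop("unpaired runs: ", paste(orphan, collapse = "; "))
  keepPairs <- setdiff(pairs, exclude)
  if (length(keepPairs) < 2L) stop("fewer than 2 pairs remain after exclusion")

  pepRows <- list()
  ionRows <- list()
  quantRows <- list()
  for (i in seq_along(runs)) {
    if (!(repl[i] %in% keepPairs)) next
    qr <- quantifyRun(runs[[i]], panel, ppmTol = ppmTol, daTol = daTol, ...)
    pepRows[[i]] <- qr$peptides
    ionRows[[i]] <- qr$ions
    stds <- qr$peptides$area[qr$peptides$internalStandard]
    if (all(stds == 0))
      stop("sample failed loading control: run ", ids[i],
           " has no internal-standard signal")
    phos <- qr$peptides[!qr$peptides$internalStandard, , drop = FALSE]
    quantRows[[i]] <- data.frame(
      site = phos$site, experiment = repl[i], condition = cond[i],
      normalizedArea = vapply(phos$area, normalizeArea, numeric(1),
                              standardAreas = stds),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  quant <- do.call(rbind, quantRows)
  rownames(quant) <- NULL
  siteOrder <- vapply(Filter(function(e) !e$internalStandard, panel@entries),
                      `[[`, character(1), "site")
  fit <- reanalyzeTable(quant, siteOrder = siteOrder)
  log <- list(ppmTol = ppmTol, daTol = daTol, excludedPairs = exclude,
              pairsUsed = keepPairs, nRuns = sum(repl %in% keepPairs),
              test = "paired t, two-sided",
              multipleTesting = "none (per-site p-values reported as such)")
  list(quant = quant, results = fit$results, ratios = fit$ratios,
       peptides = do.call(rbind, pepRows), ions = do.call(rbind, ionRows),
       log = log)
}
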