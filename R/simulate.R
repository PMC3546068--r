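## Seeded simulator of paired control/treated DDA LC-MS/MS runs with known
## ground-truth fold changes. The generator writes the same spectrum model
## the reader produces, so every downstream stage is testable end-to-end
## without external data.

.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

.rnorm_trunc <- function(n, sd, maxAbs) {
  x <- rnorm(n, 0, sd)
  pmin(pmax(x, -maxAbs), maxAbs)
}

#' Simulation configuration
#'
#' Assembles and validates the configuration of
#' \code{\link{simulateExperiment}}. The defaults emulate the paired
#' insulin-stimulation design the package was built around: 4 paired
#' control/treated biological replicates, Gaussian chromatographic
#' elution, accurate-mass MS1 with ion-trap-accuracy MS2, condition fold
#' changes of ~3x / ~11.7x / ~2.3x at three phosphosites and 1x at the
#' other three, internal standards held condition-independent, and
#' multiplicative lognormal between-replicate noise.
#'
#' @param panel a \linkS4class{PeptidePanel} (default the shipped
#'   PPP1R12B panel).
#' @param foldMap named vector: site label -> true treated/control fold
#'   (> 0). Sites absent from the map get fold 1.
#' @param nPairs number of paired control/treated replicates (default 4).
#' @param rtCenters named vector of elution apex RTs in minutes (default:
#'   panel entries spaced 1 min apart starting at 3 min).
#' @param elutionSigma Gaussian elution width sigma, minutes (default 0.1).
#' @param baseAbundance named vector of per-peptide base abundances
#'   (arbitrary intensity units; defaults 5e4 for phosphopeptides, 1e7
#'   for internal standards).
#' @param sigmaRun lognormal sigma of the per-run loading factor shared by
#'   all peptides of a run (default 0.15); cancelled by internal-standard
#'   normalization.
#' @param sigmaPep lognormal sigma of per-run, per-peptide abundance noise
#'   (default 0.2) -- the biological/technical replicate scatter.
#' @param noiseFloor additive intensity added to every generated peak
#'   (default 0).
#' @param ms1Interval MS1 duty-cycle interval, minutes (default 0.05).
#' @param topN DDA precursors selected per cycle (default 3).
#' @param ddaThreshold minimum MS1 peak intensity to trigger MS2
#'   (default 200).
#' @param dynamicExclusion exclusion time in minutes after selecting a
#'   precursor (default 0: re-sampled every cycle so fragment XICs track
#'   the whole elution peak; set 0.5 for classic 30 s exclusion).
#' @param ppmJitterSd MS1 m/z measurement jitter sigma in ppm (default 2,
#'   truncated at +/- 9 ppm, within the 10 ppm extraction tolerance).
#' @param fragJitterSd MS2 fragment m/z jitter sigma in Da (default 0.1,
#'   truncated at +/- 0.3 Da, within the 0.5 Da tolerance).
#' @param rtJitterSd per-run retention-time shift sigma, minutes
#'   (default 0.02).
#' @param isolationHalfWidth MS2 isolation half-width, Da (default 1.5).
#' @param quantWeight fragment intensity of each quantifier ion relative
#'   to the precursor's instantaneous intensity (default 0.2).
#' @param otherWeight relative intensity of non-quantifier b/y ions
#'   (default 0.03).
#' @param nlWeight relative intensity of the precursor - H3PO4 neutral
#'   loss peak of phosphopeptides (default 0.3; an - H2O peak is emitted
#'   at a sixth of this).
#' @param runLength total run length in minutes (default: last RT center
#'   + 1.5 min).
#' @param seed integer random seed.
#' @return A validated list of class \code{"SimConfig"}.
#' @export
simConfig <- function(panel = ppp1r12bPanel(),
                      foldMap = c("Ser29" = 3.0, "Ser504" = 11.7,
                                  "Ser645/T646" = 2.3),
                      nPairs = 4L,
                      rtCenters = NULL,
                      elutionSigma = 0.1,
                      baseAbundance = NULL,
                      sigmaRun = 0.15,
                      sigmaPep = 0.2,
                      noiseFloor = 0,
                      ms1Interval = 0.05,
                      topN = 3L,
                      ddaThreshold = 200,
                      dynamicExclusion = 0,
                      ppmJitterSd = 2,
                      fragJitterSd = 0.1,
                      rtJitterSd = 0.02,
                      isolationHalfWidth = 1.5,
                      quantWeight = 0.2,
                      otherWeight = 0.03,
                      nlWeight = 0.3,
                      runLength = NULL,
                      seed = 1L) {
  stopifnot(is(panel, "PeptidePanel"))
  labels <- vapply(panel@entries, `[[`, character(1), "label")
  isStd <- vapply(panel@entries, `[[`, logical(1), "internalStandard")
  if (is.null(rtCenters))
    rtCenters <- setNames(3 + seq_along(labels) - 1, labels)
  if (is.null(baseAbundance))
    baseAbundance <- setNames(ifelse(isStd, 1e7, 5e4), labels)
  if (!all(labels %in% names(rtCenters)))
    stop("rtCenters must name every panel entry")
  if (!all(labels %in% names(baseAbundance)))
    stop("baseAbundance must name every panel entry")
  fold <- setNames(rep(1, length(labels)), labels)
  sites <- vapply(panel@entries, `[[`, character(1), "site")
  for (s in names(foldMap)) fold[sites == s] <- foldMap[[s]]
  if (any(fold <= 0)) stop("folds must be > 0")
  if (any(c(elutionSigma, sigmaRun, sigmaPep, ppmJitterSd, fragJitterSd,
            rtJitterSd) < 0)) stop("all sigmas must be >= 0")
  if (is.null(runLength)) runLength <- max(rtCenters[labels]) + 1.5
  if (any(rtCenters[labels] < 4 * elutionSigma) ||
      any(rtCenters[labels] > runLength - 4 * elutionSigma))
    stop("RT centers must lie inside the run window")
  structure(list(
    panel = panel, labels = labels, internalStandard = isStd,
    fold = fold, nPairs = as.integer(nPairs),
    rtCenters = rtCenters[labels], elutionSigma = elutionSigma,
    baseAbundance = baseAbundance[labels], sigmaRun = sigmaRun,
    sigmaPep = sigmaPep, noiseFloor = noiseFloor,
    ms1Interval = ms1Interval, topN = as.integer(topN),
    ddaThreshold = ddaThreshold, dynamicExclusion = dynamicExclusion,
    ppmJitterSd = ppmJitterSd, fragJitterSd = fragJitterSd,
    rtJitterSd = rtJitterSd, isolationHalfWidth = isolationHalfWidth,
    quantWeight = quantWeight, otherWeight = otherWeight,
    nlWeight = nlWeight, runLength = runLength, seed = as.integer(seed)
  ), class = "SimConfig")
}

## theoretical fragment table for one panel entry: mz + relative weight.
## Site-dependent fragments of ambiguous peptides are omitted (the
## instrument "did not detect" them, mirroring the peptide's ambiguity).
.sim_ion_table <- function(entry, quantWeight, otherWeight, nlWeight) {
  pep <- entry$peptide
  n <- nchar(pep@sequence)
  rows <- list()
  for (series in c("b", "y")) for (idx in seq_len(n - 1L)) {
    mz <- tryCatch(fragmentMz(pep, series, idx, 1L), error = function(e) NA)
    if (!is.na(mz))
      rows[[length(rows) + 1L]] <- data.frame(series = series, index = idx,
                                              mz = mz, weight = otherWeight)
  }
  tab <- do.call(rbind, rows)
  q <- entry$quantifiers
  q <- q[q$type == "frag", , drop = FALSE]
  for (i in seq_len(nrow(q))) {
    hit <- tab$series == q$series[i] & tab$index == q$index[i]
    tab$weight[hit] <- quantWeight
  }
  phospho <- length(pep@ambiguityGroup) > 0L ||
    any(pep@modifications$label == "phospho")
  if (phospho) {
    z <- entry$precursorCharge
    nm <- neutralMass(pep)
    nl <- data.frame(
      series = "nl", index = NA_integer_,
      mz = c((nm - .MASS_CONST[["H3PO4"]] + z * .MASS_CONST[["proton"]]) / z,
             (nm - .MASS_CONST[["H2O"]] + z * .MASS_CONST[["proton"]]) / z),
      weight = c(nlWeight, nlWeight / 6))
    tab <- rbind(tab, nl)
  }
  tab
}

#' Simulate a paired control/treated LC-MS/MS experiment
#'
#' Generates \code{2 * nPairs} DDA runs over the configured peptide panel:
#' MS1 scans on a fixed duty-cycle grid carrying each peptide's
#' monoisotopic precursor with Gaussian elution and ppm-scale m/z jitter,
#' and MS2 scans triggered on the most intense precursors, carrying b/y
#' fragment ions (quantifier ions heavier-weighted) plus phosphate
#' neutral-loss peaks, with Dalton-scale m/z jitter. Internal standards
#' are condition-independent; phosphopeptide abundance is multiplied by
#' the configured fold in treated runs. All draws come from the seeded
#' generator, so a fixed config reproduces identical runs.
#'
#' @param config a \code{\link{simConfig}}.
#' @return list with \code{runs} (list of \linkS4class{SpectrumRun},
#'   \code{pair<k>_control} / \code{pair<k>_treated}) and \code{truth}
#'   (data.frame: run, pair, condition, label, site, abundance, fold).
#' @export
simulateExperiment <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  .with_seed(config$seed, {
    ionTables <- lapply(config$panel@entries, .sim_ion_table,
                        quantWeight = config$quantWeight,
                        otherWeight = config$otherWeight,
                        nlWeight = config$nlWeight)
    runs <- list()
    truth <- list()
    for (pair in seq_len(config$nPairs)) {
      for (cond in c("control", "treated")) {
        id <- sprintf("pair%d_%s", pair, cond)
        sim <- .simulate_run(config, ionTables, cond)
        runs[[id]] <- spectrumRun(id, sim$spectra, sampleLabel = id,
                                  condition = cond, replicate = pair)
        truth[[id]] <- data.frame(
          run = id, pair = pair, condition = cond, label = config$labels,
          site = vapply(config$panel@entries, `[[`, character(1), "site"),
          abundance = sim$abundance, fold = config$fold,
          stringsAsFactors = FALSE)
      }
    }
    list(runs = runs, truth = do.call(rbind, truth))
  })
}

## one run: abundances -> MS1 grid -> DDA-triggered MS2
.simulate_run <- function(config, ionTables, cond) {
  labels <- config$labels
  nPep <- length(labels)
  runEffect <- rlnorm(1, 0, config$sigmaRun)
  rtShift <- rnorm(1, 0, config$rtJitterSd)
  pepNoise <- rlnorm(nPep, 0, config$sigmaPep)
  fold <- ifelse(!config$internalStandard & cond == "treated", config$fold, 1)
  abundance <- config$baseAbundance * runEffect * pepNoise * fold
  rtc <- config$rtCenters + rtShift
  sg <- config$elutionSigma

  ## precursor charge states: phosphopeptides at their precursorCharge,
  ## internal standards split equally over their quantified charges
  pcs <- list()
  for (i in seq_len(nPep)) {
    e <- config$panel@entries[[i]]
    if (e$internalStandard) {
      zs <- e$quantifiers$charge[e$quantifiers$type == "prec"]
      for (z in zs)
        pcs[[length(pcs) + 1L]] <- list(pep = i, z = z,
                                        amp = abundance[i] / length(zs),
                                        mz = protonatedMz(e$peptide, z))
    } else {
      z <- e$precursorCharge
      pcs[[length(pcs) + 1L]] <- list(pep = i, z = z, amp = abundance[i],
                                      mz = protonatedMz(e$peptide, z))
    }
  }

  grid <- seq(0, config$runLength, by = config$ms1Interval)
  nCyc <- length(grid)
  ## per-cycle MS1 peak lists: row index = cycle
  cycPeaks <- vector("list", nCyc)
  for (j in seq_along(pcs)) {
    pc <- pcs[[j]]
    i <- pc$pep
    idx <- which(abs(grid - rtc[i]) <= 4 * sg)
    if (!length(idx)) next
    int <- pc$amp * exp(-((grid[idx] - rtc[i])^2) / (2 * sg^2)) +
      config$noiseFloor
    jit <- .rnorm_trunc(length(idx), config$ppmJitterSd, 9)
    mzm <- pc$mz * (1 + jit * 1e-6)
    for (k in seq_along(idx)) {
      cycPeaks[[idx[k]]] <- rbind(cycPeaks[[idx[k]]],
                                  c(j, mzm[k], int[k]))
    }
  }

  spectra <- list()
  scan <- 0L
  lastSel <- rep(-Inf, length(pcs))
  for (k in seq_len(nCyc)) {
    scan <- scan + 1L
    pk <- cycPeaks[[k]]
    if (is.null(pk)) {
      spectra[[length(spectra) + 1L]] <-
        spectrum(scan, 1L, grid[k])
      next
    }
    spectra[[length(spectra) + 1L]] <-
      spectrum(scan, 1L, grid[k], mz = pk[, 2], intensity = pk[, 3])
    ## DDA selection: intensity-ordered, above threshold, not excluded
    ord <- order(-pk[, 3])
    sel <- integer()
    for (o in ord) {
      if (pk[o, 3] < config$ddaThreshold) break
      j <- as.integer(pk[o, 1])
      if (grid[k] - lastSel[j] < config$dynamicExclusion) next
      sel <- c(sel, o)
      if (length(sel) >= config$topN) break
    }
    for (s in seq_along(sel)) {
      o <- sel[s]
      j <- as.integer(pk[o, 1])
      lastSel[j] <- grid[k]
      pc <- pcs[[j]]
      rt2 <- grid[k] + s * config$ms1Interval / (config$topN + 1)
      parent <- pc$amp * exp(-((rt2 - rtc[pc$pep])^2) / (2 * sg^2))
      ions <- ionTables[[pc$pep]]
      fj <- .rnorm_trunc(nrow(ions), config$fragJitterSd, 0.3)
      scan <- scan + 1L
      spectra[[length(spectra) + 1L]] <- spectrum(
        scan, 2L, rt2,
        mz = ions$mz + fj,
        intensity = ions$weight * parent + config$noiseFloor,
        precursorMz = pk[o, 2], precursorCharge = pc$z,
        isolationWidth = config$isolationHalfWidth)
    }
  }
  list(spectra = spectra, abundance = abundance)
}
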