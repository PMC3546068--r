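## Reading and writing LC-MS/MS runs. mzML is the primary on-disk format
## (through mzR/proteowizard); a delimited fallback format keeps fixtures
## human-readable. Retention time is normalized to minutes on read.

#' Construct a Spectrum
#'
#' @param scanId integer scan number.
#' @param msLevel 1 or 2.
#' @param rt retention time in minutes.
#' @param mz,intensity parallel peak arrays; peaks are sorted ascending by
#'   m/z if needed.
#' @param precursorMz,precursorCharge MS2 precursor annotation.
#' @param isolationWidth isolation half-width in Da (\code{NA} = unknown).
#' @return A \linkS4class{Spectrum}.
#' @export
spectrum <- function(scanId, msLevel, rt, mz = numeric(),
                     intensity = numeric(), precursorMz = NA_real_,
                     precursorCharge = NA_integer_,
                     isolationWidth = NA_real_) {
  if (length(mz) && is.unsorted(mz, strictly = TRUE)) {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
    ## coincident m/z values are merged (their intensities summed)
    if (any(duplicated(mz))) {
      intensity <- as.numeric(tapply(intensity, match(mz, unique(mz)), sum))
      mz <- unique(mz)
    }
  }
  new("Spectrum", scanId = as.integer(scanId), msLevel = as.integer(msLevel),
      rt = as.numeric(rt), mz = as.numeric(mz),
      intensity = as.numeric(intensity),
      precursorMz = as.numeric(precursorMz),
      precursorCharge = as.integer(precursorCharge),
      isolationWidth = as.numeric(isolationWidth))
}

#' Construct a SpectrumRun
#'
#' @param runId unique run identifier.
#' @param spectra list of \linkS4class{Spectrum}; sorted by RT if needed.
#' @param sampleLabel free-text label.
#' @param condition \code{"control"}, \code{"treated"} or \code{NA}.
#' @param replicate pair/replicate index.
#' @return A \linkS4class{SpectrumRun}.
#' @export
spectrumRun <- function(runId, spectra = list(), sampleLabel = runId,
                        condition = NA_character_, replicate = NA_integer_) {
  if (length(spectra)) {
    rt <- vapply(spectra, slot, numeric(1), name = "rt")
    if (is.unsorted(rt)) spectra <- spectra[order(rt)]
  }
  new("SpectrumRun", runId = as.character(runId),
      sampleLabel = as.character(sampleLabel),
      condition = as.character(condition),
      replicate = as.integer(replicate), spectra = spectra)
}

#' Read an LC-MS/MS run from mzML
#'
#' Reads all spectra (scan id, MS level, retention time, peaks, precursor
#' annotation) into a \linkS4class{SpectrumRun}. Retention times are
#' converted to minutes. MS2 spectra lacking a precursor annotation are
#' dropped with a warning (they cannot contribute to fragment XICs).
#'
#' @param path mzML file.
#' @param runId run identifier (defaults to the file base name).
#' @param condition,replicate,sampleLabel design metadata to attach.
#' @return A \linkS4class{SpectrumRun}.
#' @seealso \code{\link{writeRun}}
#' @export
readRun <- function(path, runId = NULL, condition = NA_character_,
                    replicate = NA_integer_, sampleLabel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(runId)) runId <- sub("\\.[^.]*$", "", basename(path))
  if (is.null(sampleLabel)) sampleLabel <- runId
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::header(ms)
  if (nrow(hdr) == 0L)
    return(spectrumRun(runId, list(), sampleLabel, condition, replicate))
  pks <- mzR::peaks(ms)
  if (is.matrix(pks)) pks <- list(pks)
  ## mzR reports seconds
  rt_min <- hdr$retentionTime / 60
  iso <- rep(NA_real_, nrow(hdr))
  if (all(c("isolationWindowLowerOffset", "isolationWindowUpperOffset") %in%
          names(hdr))) {
    iso <- (hdr$isolationWindowLowerOffset + hdr$isolationWindowUpperOffset) / 2
  }
  drop <- hdr$msLevel == 2L & (is.na(hdr$precursorMZ) | hdr$precursorMZ <= 0)
  if (any(drop))
    warning(sum(drop), " MS2 spectra without precursor annotation were dropped")
  sp <- vector("list", nrow(hdr))
  for (i in seq_len(nrow(hdr))) {
    if (drop[i]) next
    p <- pks[[i]]
    prec_z <- hdr$precursorCharge[i]
    sp[[i]] <- spectrum(
      scanId = hdr$acquisitionNum[i], msLevel = hdr$msLevel[i],
      rt = rt_min[i], mz = p[, 1], intensity = p[, 2],
      precursorMz = if (hdr$msLevel[i] == 2L) hdr$precursorMZ[i] else NA_real_,
      precursorCharge = if (!is.na(prec_z) && prec_z > 0L) as.integer(prec_z)
                        else NA_integer_,
      isolationWidth = if (!is.na(iso[i]) && iso[i] > 0) iso[i] else NA_real_)
  }
  spectrumRun(runId, sp[!vapply(sp, is.null, logical(1))], sampleLabel,
              condition, replicate)
}

#' Write an LC-MS/MS run to mzML
#'
#' Writes a standard-conformant mzML file (retention times in seconds, as
#' the format requires). Together with \code{\link{readRun}} this
#' round-trips scan count, MS level, RT, precursor annotation and peak
#' arrays.
#'
#' @param run a \linkS4class{SpectrumRun}.
#' @param path output file path (.mzML).
#' @return \code{path}, invisibly.
#' @export
writeRun <- function(run, path) {
  stopifnot(is(run, "SpectrumRun"))
  sp <- run@spectra
  n <- length(sp)
  if (n == 0L)
    stop("mzR cannot write a run with zero spectra; use writeRunTable() for empty fixtures")
  pk <- lapply(sp, function(s) cbind(mz = s@mz, intensity = s@intensity))
  lvl <- vapply(sp, slot, integer(1), name = "msLevel")
  rt_s <- vapply(sp, slot, numeric(1), name = "rt") * 60
  pmz <- vapply(sp, slot, numeric(1), name = "precursorMz")
  pz <- vapply(sp, slot, integer(1), name = "precursorCharge")
  iso <- vapply(sp, slot, numeric(1), name = "isolationWidth")
  npk <- lengths(lapply(sp, slot, name = "mz"))
  bp <- vapply(seq_len(n), function(i) {
    if (npk[i] == 0L) return(c(NA_real_, NA_real_, 0, NA_real_, NA_real_))
    j <- which.max(sp[[i]]@intensity)
    c(sp[[i]]@mz[j], sp[[i]]@intensity[j], sum(sp[[i]]@intensity),
      min(sp[[i]]@mz), max(sp[[i]]@mz))
  }, numeric(5))
  hdr <- data.frame(
    seqNum = seq_len(n),
    acquisitionNum = vapply(sp, slot, integer(1), name = "scanId"),
    msLevel = lvl,
    polarity = rep(1L, n),
    peaksCount = as.integer(npk),
    totIonCurrent = bp[3, ],
    retentionTime = rt_s,
    basePeakMZ = bp[1, ],
    basePeakIntensity = bp[2, ],
    collisionEnergy = ifelse(lvl == 2L, 35, 0),
    ionisationEnergy = rep(0, n),
    lowMZ = bp[4, ],
    highMZ = bp[5, ],
    precursorScanNum = rep(0L, n),
    precursorMZ = ifelse(lvl == 2L, pmz, 0),
    precursorCharge = ifelse(lvl == 2L & !is.na(pz), pz, 0L),
    precursorIntensity = rep(0, n),
    mergedScan = rep(0L, n),
    mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n),
    mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n),
    filterString = rep(NA_character_, n),
    spectrumId = sprintf("scan=%d", vapply(sp, slot, integer(1), name = "scanId")),
    centroided = rep(TRUE, n),
    ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = ifelse(lvl == 2L, pmz, NA_real_),
    isolationWindowLowerOffset = ifelse(lvl == 2L, iso, NA_real_),
    isolationWindowUpperOffset = ifelse(lvl == 2L, iso, NA_real_),
    scanWindowLowerLimit = rep(NA_real_, n),
    scanWindowUpperLimit = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(pk, path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Delimited fallback run format
#'
#' A plain-text spectrum table for small fixtures: one row per scan with
#' columns \code{scan}, \code{level}, \code{rt} (minutes),
#' \code{precursor_mz}, \code{precursor_charge}, \code{isolation_width}
#' and \code{peaks} (space-separated \code{mz:intensity} pairs).
#'
#' @param run a \linkS4class{SpectrumRun}.
#' @param path file path.
#' @return \code{writeRunTable}: \code{path} invisibly;
#'   \code{readRunTable}: a \linkS4class{SpectrumRun}.
#' @export
writeRunTable <- function(run, path) {
  stopifnot(is(run, "SpectrumRun"))
  rows <- vapply(run@spectra, function(s) {
    paste(s@scanId, s@msLevel, format(s@rt, digits = 10),
          format(s@precursorMz, digits = 10), s@precursorCharge,
          format(s@isolationWidth, digits = 10),
          paste(sprintf("%.6f:%.6g", s@mz, s@intensity), collapse = " "),
          sep = "\t")
  }, character(1))
  writeLines(c(paste("scan", "level", "rt", "precursor_mz", "precursor_charge",
                     "isolation_width", "peaks", sep = "\t"), rows), path)
  invisible(path)
}

#' @rdname writeRunTable
#' @param runId,condition,replicate metadata for the returned run.
#' @export
readRunTable <- function(path, runId = NULL, condition = NA_character_,
                         replicate = NA_integer_) {
  if (is.null(runId)) runId <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  if (length(lines) <= 1L)
    return(spectrumRun(runId, list(), runId, condition, replicate))
  sp <- lapply(lines[-1], function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    pk <- if (length(f) >= 7L && nzchar(f[7])) {
      do.call(rbind, lapply(strsplit(f[7], " ", fixed = TRUE)[[1]], function(p)
        as.numeric(strsplit(p, ":", fixed = TRUE)[[1]])))
    } else matrix(numeric(), ncol = 2)
    num <- function(x) if (x == "NA") NA_real_ else as.numeric(x)
    spectrum(as.integer(f[1]), as.integer(f[2]), as.numeric(f[3]),
             mz = pk[, 1], intensity = pk[, 2],
             precursorMz = num(f[4]),
             precursorCharge = as.integer(num(f[5])),
             isolationWidth = num(f[6]))
  })
  spectrumRun(runId, sp, runId, condition, replicate)
}

#' Write or read an experiment of runs with a manifest
#'
#' \code{writeExperiment} writes each run to \code{<dir>/<runId>.mzML} and
#' a tab-delimited \code{manifest.tsv} recording path, condition, replicate
#' and sample label. \code{readExperiment} reads the manifest back into a
#' list of \linkS4class{SpectrumRun}.
#'
#' @param runs list of \linkS4class{SpectrumRun}.
#' @param dir output directory (created if needed).
#' @return \code{writeExperiment}: the manifest path, invisibly;
#'   \code{readExperiment}: a named list of runs.
#' @export
writeExperiment <- function(runs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- data.frame(
    path = vapply(runs, function(r) paste0(r@runId, ".mzML"), character(1)),
    run_id = vapply(runs, slot, character(1), name = "runId"),
    sample_label = vapply(runs, slot, character(1), name = "sampleLabel"),
    condition = vapply(runs, slot, character(1), name = "condition"),
    replicate = vapply(runs, slot, integer(1), name = "replicate"),
    stringsAsFactors = FALSE
  )
  for (r in runs) writeRun(r, file.path(dir, paste0(r@runId, ".mzML")))
  mpath <- file.path(dir, "manifest.tsv")
  write.table(man, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mpath)
}

#' @rdname writeExperiment
#' @param manifest path to a manifest.tsv (paths are resolved relative to
#'   its directory).
#' @export
readExperiment <- function(manifest) {
  man <- read.delim(manifest, stringsAsFactors = FALSE)
  base <- dirname(manifest)
  runs <- lapply(seq_len(nrow(man)), function(i) {
    readRun(file.path(base, man$path[i]), runId = man$run_id[i],
            condition = man$condition[i], replicate = man$replicate[i],
            sampleLabel = man$sample_label[i])
  })
  names(runs) <- man$run_id
  runs
}
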