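## Reconstructed ion chromatograms and peak-area integration -- the core
## quantification step. Precursor XICs use a ppm tolerance (accurate-mass
## MS1), fragment XICs a Dalton tolerance (ion-trap MS2). Missing signal is
## an observed zero, never a missing value.

## flatten a run's peaks into long tables once; every XIC is then a
## windowed lookup instead of a per-spectrum loop
.flatten_run <- function(run) {
  sp <- run@spectra
  lvl <- vapply(sp, slot, integer(1), name = "msLevel")
  rt <- vapply(sp, slot, numeric(1), name = "rt")
  id <- vapply(sp, slot, integer(1), name = "scanId")
  npk <- lengths(lapply(sp, slot, name = "mz"))
  mk <- function(idx) {
    if (!length(idx))
      return(list(scan = data.frame(scanId = integer(), rt = numeric(),
                                    precursorMz = numeric(), iso = numeric()),
                  peak = data.frame(row = integer(), mz = numeric(),
                                    intensity = numeric())))
    scan <- data.frame(
      scanId = id[idx], rt = rt[idx],
      precursorMz = vapply(sp[idx], slot, numeric(1), name = "precursorMz"),
      iso = vapply(sp[idx], slot, numeric(1), name = "isolationWidth"))
    peak <- data.frame(
      row = rep(seq_along(idx), npk[idx]),
      mz = unlist(lapply(sp[idx], slot, name = "mz"), use.names = FALSE),
      intensity = unlist(lapply(sp[idx], slot, name = "intensity"),
                         use.names = FALSE))
    o <- order(peak$mz)
    peak <- peak[o, , drop = FALSE]
    list(scan = scan, peak = peak)
  }
  list(ms1 = mk(which(lvl == 1L)), ms2 = mk(which(lvl == 2L)))
}

## sum, per scan row, the intensities of peaks with mz in [lo, hi];
## peaks must be sorted by mz
.sum_in_window <- function(flat, lo, hi, rows = NULL) {
  nscan <- nrow(flat$scan)
  out <- numeric(nscan)
  pk <- flat$peak
  if (nrow(pk)) {
    ## inclusive window [lo, hi]
    i0 <- findInterval(lo, pk$mz, left.open = TRUE) + 1L
    i1 <- findInterval(hi, pk$mz)
    if (i1 >= i0) {
      sel <- i0:i1
      agg <- tapply(pk$intensity[sel], pk$row[sel], sum)
      out[as.integer(names(agg))] <- agg
    }
  }
  if (is.null(rows)) out else out[rows]
}

#' Precursor-level extracted ion chromatogram
#'
#' One point per MS1 scan in the RT window; each point is the sum of peak
#' intensities within \code{+/- mz * ppmTol * 1e-6} of the target. Scans
#' with no qualifying peak contribute zero intensity.
#'
#' @param run a \linkS4class{SpectrumRun}.
#' @param mz target m/z (> 0).
#' @param ppmTol tolerance in parts per million (default 10).
#' @param rtWindow optional \code{c(min, max)} RT window in minutes.
#' @return A \linkS4class{Chromatogram}.
#' @export
precursorXIC <- function(run, mz, ppmTol = 10, rtWindow = NULL) {
  stopifnot(is(run, "SpectrumRun"), mz > 0, ppmTol > 0)
  flat <- .flatten_run(run)$ms1
  .xic_from_flat(flat, mz, mz * ppmTol * 1e-6, rtWindow,
                 target = list(mz = mz, ppmTol = ppmTol, level = 1L))
}

.xic_from_flat <- function(flat, mz, tolDa, rtWindow, target, rows = NULL) {
  keep <- if (is.null(rows)) seq_len(nrow(flat$scan)) else rows
  if (!is.null(rtWindow))
    keep <- keep[flat$scan$rt[keep] >= rtWindow[1] &
                 flat$scan$rt[keep] <= rtWindow[2]]
  int <- .sum_in_window(flat, mz - tolDa, mz + tolDa, rows = keep)
  rt <- flat$scan$rt[keep]
  ids <- flat$scan$scanId[keep]
  o <- order(rt)
  ## one point per scan; coincident RTs (should not occur) are dropped
  rt <- rt[o]; int <- int[o]; ids <- ids[o]
  dup <- duplicated(rt)
  new("Chromatogram", target = target, rt = rt[!dup],
      intensity = int[!dup], scanIds = as.integer(ids[!dup]))
}

#' Fragment-level extracted ion chromatogram
#'
#' One point per MS2 scan whose isolation window covers the target
#' precursor; each point is the sum of fragment-peak intensities within
#' \code{+/- daTol} of the fragment m/z. When a spectrum carries no
#' isolation width, \code{defaultIsolation} (half-width, Da) is used; a
#' fixed Dalton precursor tolerance can be forced with
#' \code{precursorTol}.
#'
#' @param run a \linkS4class{SpectrumRun}.
#' @param precursorMz precursor m/z selecting the MS2 scans.
#' @param fragmentMz target fragment m/z.
#' @param daTol fragment tolerance in Da (default 0.5).
#' @param rtWindow optional \code{c(min, max)} RT window, minutes.
#' @param precursorTol optional fixed precursor tolerance in Da
#'   (overrides isolation widths).
#' @param defaultIsolation half-width used when a spectrum has none
#'   (default 1.5 Da, typical ion-trap DDA).
#' @return A \linkS4class{Chromatogram}.
#' @export
fragmentXIC <- function(run, precursorMz, fragmentMz, daTol = 0.5,
                        rtWindow = NULL, precursorTol = NULL,
                        defaultIsolation = 1.5) {
  stopifnot(is(run, "SpectrumRun"), precursorMz > 0, fragmentMz > 0, daTol > 0)
  flat <- .flatten_run(run)$ms2
  .fragment_xic_flat(flat, precursorMz, fragmentMz, daTol, rtWindow,
                     precursorTol, defaultIsolation)
}

.fragment_xic_flat <- function(flat, precursorMz, fragmentMz, daTol = 0.5,
                               rtWindow = NULL, precursorTol = NULL,
                               defaultIsolation = 1.5) {
  tol <- if (!is.null(precursorTol)) rep(precursorTol, nrow(flat$scan))
         else ifelse(is.na(flat$scan$iso), defaultIsolation, flat$scan$iso)
  rows <- which(abs(flat$scan$precursorMz - precursorMz) <= tol)
  .xic_from_flat(flat, fragmentMz, daTol, rtWindow,
                 target = list(mz = fragmentMz, daTol = daTol, level = 2L,
                               precursorMz = precursorMz),
                 rows = rows)
}

#' Integrate a chromatographic peak
#'
#' Deterministic trapezoidal integration around the apex. The apex is the
#' most intense point (or, given \code{expectedRt}, the local maximum
#' nearest to it); the integration region extends from the apex in both
#' directions until intensity falls below \code{edgeFrac} of the apex, a
#' local minimum drops below \code{valleyFrac} of the apex, or the region
#' reaches \code{maxWidth} minutes.
#'
#' @param chrom a \linkS4class{Chromatogram}.
#' @param expectedRt optional expected apex RT, minutes.
#' @param edgeFrac stop extending below this fraction of apex intensity
#'   (default 0.01).
#' @param valleyFrac a local minimum below this fraction of apex intensity
#'   ends the peak (default 0.05).
#' @param maxWidth maximum total peak width in minutes (default 2).
#' @return A \linkS4class{PeakArea}; all-zero (or empty) traces yield area
#'   0 with \code{zeroFlag = TRUE}.
#' @export
integratePeak <- function(chrom, expectedRt = NULL, edgeFrac = 0.01,
                          valleyFrac = 0.05, maxWidth = 2) {
  stopifnot(is(chrom, "Chromatogram"))
  rt <- chrom@rt
  y <- chrom@intensity
  n <- length(rt)
  if (n == 0L || all(y == 0))
    return(new("PeakArea", area = 0, rtApex = NA_real_,
               rtBounds = c(NA_real_, NA_real_), nScans = 0L,
               zeroFlag = TRUE))
  apex <- .find_apex(rt, y, expectedRt)
  apexInt <- y[apex]
  lo <- hi <- apex
  halfw <- maxWidth / 2
  while (lo > 1L) {
    i <- lo - 1L
    if (rt[apex] - rt[i] > halfw) break
    if (y[i] < edgeFrac * apexInt) break
    isMin <- y[i] < valleyFrac * apexInt &&
      (i == 1L || y[i - 1L] >= y[i])
    lo <- i
    if (isMin) break
  }
  while (hi < n) {
    i <- hi + 1L
    if (rt[i] - rt[apex] > halfw) break
    if (y[i] < edgeFrac * apexInt) break
    isMin <- y[i] < valleyFrac * apexInt &&
      (i == n || y[i + 1L] >= y[i])
    hi <- i
    if (isMin) break
  }
  idx <- lo:hi
  a <- if (length(idx) > 1L)
    sum(diff(rt[idx]) * (head(y[idx], -1L) + tail(y[idx], -1L)) / 2)
  else 0
  new("PeakArea", area = a, rtApex = rt[apex],
      rtBounds = c(rt[lo], rt[hi]), nScans = length(idx),
      zeroFlag = FALSE)
}

.find_apex <- function(rt, y, expectedRt) {
  if (is.null(expectedRt)) return(which.max(y))
  n <- length(y)
  isMax <- vapply(seq_len(n), function(i) {
    y[i] > 0 &&
      (i == 1L || y[i] >= y[i - 1L]) &&
      (i == n || y[i] >= y[i + 1L])
  }, logical(1))
  cand <- which(isMax)
  if (!length(cand)) return(which.max(y))
  cand[which.min(abs(rt[cand] - expectedRt))]
}

#' Quantify one panel peptide in one run
#'
#' Computes the raw peak area of a panel entry: for phosphopeptides, the
#' sum of the integrated fragment-XIC areas over the listed quantifier
#' ions (extracted from MS2 scans matching the peptide's precursor); for
#' internal standards, the sum of the integrated precursor-XIC areas over
#' the listed charge states. Per-ion areas are retained for audit.
#'
#' @param run a \linkS4class{SpectrumRun}.
#' @param entry one panel entry (see \code{\link{panelEntries}}).
#' @param ppmTol precursor tolerance, ppm (default 10).
#' @param daTol fragment tolerance, Da (default 0.5).
#' @param rtWindow optional RT window, minutes.
#' @param expectedRt optional expected apex RT.
#' @param ... passed to \code{\link{integratePeak}}.
#' @return list with \code{area} (raw summed area), \code{zeroFlag}
#'   (TRUE when no ion carried signal) and \code{ions} (per-ion
#'   data.frame: ion, mz, area, rtApex, rtLo, rtHi, nScans, zeroFlag).
#' @export
quantifyPeptide <- function(run, entry, ppmTol = 10, daTol = 0.5,
                            rtWindow = NULL, expectedRt = NULL, ...) {
  flat <- .flatten_run(run)
  .quantify_entry(flat, entry, ppmTol = ppmTol, daTol = daTol,
                  rtWindow = rtWindow, expectedRt = expectedRt, ...)
}

.quantify_entry <- function(flat, entry, ppmTol = 10, daTol = 0.5,
                            rtWindow = NULL, expectedRt = NULL, ...) {
  q <- entry$quantifiers
  if (!nrow(q)) stop("panel entry '", entry$label, "' has no quantifier ions")
  rows <- vector("list", nrow(q))
  for (i in seq_len(nrow(q))) {
    if (q$type[i] == "prec") {
      mzt <- protonatedMz(entry$peptide, q$charge[i])
      ch <- .xic_from_flat(flat$ms1, mzt, mzt * ppmTol * 1e-6, rtWindow,
                           target = list(mz = mzt, ppmTol = ppmTol, level = 1L))
      ion <- sprintf("prec/+%d", q$charge[i])
    } else {
      mzt <- fragmentMz(entry$peptide, q$series[i], q$index[i], q$charge[i])
      pmz <- protonatedMz(entry$peptide, entry$precursorCharge)
      ch <- .fragment_xic_flat(flat$ms2, pmz, mzt, daTol, rtWindow)
      ion <- sprintf("%s%d/+%d", q$series[i], q$index[i], q$charge[i])
    }
    pa <- integratePeak(ch, expectedRt = expectedRt, ...)
    rows[[i]] <- data.frame(ion = ion, mz = mzt, area = pa@area,
                            rtApex = pa@rtApex, rtLo = pa@rtBounds[1],
                            rtHi = pa@rtBounds[2], nScans = pa@nScans,
                            zeroFlag = pa@zeroFlag)
  }
  ions <- do.call(rbind, rows)
  list(area = sum(ions$area), zeroFlag = all(ions$zeroFlag), ions = ions)
}

#' Quantify a whole panel in one run
#'
#' @param run a \linkS4class{SpectrumRun}.
#' @param panel a \linkS4class{PeptidePanel}.
#' @param ... passed to \code{\link{quantifyPeptide}}.
#' @return list with \code{peptides} (data.frame: run, label, site,
#'   internalStandard, area, zeroFlag) and \code{ions} (per-ion audit
#'   table across all peptides).
#' @export
quantifyRun <- function(run, panel, ...) {
  stopifnot(is(panel, "PeptidePanel"))
  flat <- .flatten_run(run)
  res <- lapply(panel@entries, function(e) .quantify_entry(flat, e, ...))
  pep <- data.frame(
    run = run@runId,
    label = vapply(panel@entries, `[[`, character(1), "label"),
    site = vapply(panel@entries, `[[`, character(1), "site"),
    internalStandard = vapply(panel@entries, `[[`, logical(1),
                              "internalStandard"),
    area = vapply(res, `[[`, numeric(1), "area"),
    zeroFlag = vapply(res, `[[`, logical(1), "zeroFlag"),
    stringsAsFactors = FALSE
  )
  ions <- do.call(rbind, lapply(seq_along(res), function(i)
    cbind(run = run@runId, label = pep$label[i], res[[i]]$ions)))
  rownames(pep) <- rownames(ions) <- NULL
  list(peptides = pep, ions = ions)
}
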