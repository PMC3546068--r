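## Central S4 classes. Validity is kept cheap: these objects are created in
## bulk by the simulator and the mzML reader.

#' ModifiedPeptide: a peptide with positioned mass modifications
#'
#' Represents one (possibly phosphorylated) tryptic peptide: an uppercase
#' residue sequence, a table of fixed modifications (1-based position, mass
#' delta in Da, label), an optional ambiguity group over which exactly one
#' phosphate floats (used for peptides whose spectra cannot discriminate
#' adjacent acceptor residues), and 1-based inclusive protein coordinates.
#'
#' @slot sequence uppercase residue letters.
#' @slot modifications \code{data.frame} with columns \code{position}
#'   (integer, 1-based), \code{delta} (Da), \code{label} (e.g.
#'   \code{"phospho"}, \code{"ox"}).
#' @slot ambiguityGroup integer positions over which one phosphate floats;
#'   empty for unambiguous peptides. The floating phosphate is in addition
#'   to \code{modifications} and always contributes to the neutral mass.
#' @slot proteinStart,proteinStop 1-based inclusive protein coordinates
#'   (\code{NA} when unknown).
#' @seealso \code{\link{modifiedPeptide}}
#' @exportClass ModifiedPeptide
setClass("ModifiedPeptide",
  slots = c(
    sequence = "character",
    modifications = "data.frame",
    ambiguityGroup = "integer",
    proteinStart = "integer",
    proteinStop = "integer"
  )
)

setValidity("ModifiedPeptide", function(object) {
  s <- object@sequence
  if (length(s) != 1L || is.na(s) || nchar(s) == 0L)
    return("'sequence' must be a single non-empty string")
  letters <- strsplit(s, "")[[1]]
  bad <- setdiff(letters, names(residueMasses()))
  if (length(bad))
    return(sprintf("unknown residue letter(s): %s", paste(bad, collapse = ", ")))
  m <- object@modifications
  if (!all(c("position", "delta", "label") %in% names(m)))
    return("'modifications' needs columns position, delta, label")
  n <- nchar(s)
  if (nrow(m)) {
    if (any(m$position < 1L | m$position > n))
      return("modification position out of [1, peptide length]")
    if (anyDuplicated(m$position))
      return("at most one modification per position")
  }
  ag <- object@ambiguityGroup
  if (length(ag)) {
    if (any(ag < 1L | ag > n))
      return("ambiguity positions out of range")
    if (!all(letters[ag] %in% c("S", "T", "Y")))
      return("ambiguity positions must carry S/T/Y residues")
    if (any(ag %in% m$position))
      return("ambiguity positions cannot also carry a fixed modification")
  }
  TRUE
})

#' Spectrum: one centroided mass spectrum
#'
#' A single MS1 or MS2 scan: parallel m/z (strictly ascending) and
#' intensity (non-negative) vectors plus acquisition metadata. Retention
#' time is always in minutes. MS2 spectra carry the annotated precursor m/z
#' and the isolation half-width in Da.
#'
#' @slot scanId integer scan number.
#' @slot msLevel 1 or 2.
#' @slot rt retention time, minutes.
#' @slot mz,intensity parallel peak arrays.
#' @slot precursorMz,precursorCharge MS2 precursor annotation (\code{NA}
#'   for MS1; charge may be \code{NA} on MS2).
#' @slot isolationWidth isolation half-width in Da (\code{NA} when the
#'   file does not state one).
#' @seealso \code{\link{spectrum}}
#' @exportClass Spectrum
setClass("Spectrum",
  slots = c(
    scanId = "integer",
    msLevel = "integer",
    rt = "numeric",
    mz = "numeric",
    intensity = "numeric",
    precursorMz = "numeric",
    precursorCharge = "integer",
    isolationWidth = "numeric"
  )
)

setValidity("Spectrum", function(object) {
  if (length(object@mz) != length(object@intensity))
    return("mz and intensity must be parallel")
  if (is.unsorted(object@mz, strictly = TRUE))
    return("m/z must be strictly ascending")
  if (length(object@intensity) && any(object@intensity < 0))
    return("intensities must be non-negative")
  if (!object@msLevel %in% c(1L, 2L))
    return("msLevel must be 1 or 2")
  if (object@msLevel == 2L && is.na(object@precursorMz))
    return("MS2 spectra must carry a precursorMz")
  TRUE
})

#' SpectrumRun: one RT-ordered LC-MS/MS run
#'
#' An ordered collection of \linkS4class{Spectrum} objects from a single
#' injection, with the sample metadata needed by a paired design: condition
#' (\code{"control"} or \code{"treated"}) and replicate (pair) index.
#'
#' @slot runId unique run identifier.
#' @slot sampleLabel free-text sample label.
#' @slot condition \code{"control"}, \code{"treated"}, or \code{NA}.
#' @slot replicate pair index (\code{NA} when not part of a design).
#' @slot spectra list of \linkS4class{Spectrum}, non-decreasing in RT.
#' @seealso \code{\link{spectrumRun}}, \code{\link{readRun}}
#' @exportClass SpectrumRun
setClass("SpectrumRun",
  slots = c(
    runId = "character",
    sampleLabel = "character",
    condition = "character",
    replicate = "integer",
    spectra = "list"
  )
)

setValidity("SpectrumRun", function(object) {
  if (length(object@runId) != 1L || is.na(object@runId) || !nzchar(object@runId))
    return("'runId' must be a single non-empty string")
  if (!is.na(object@condition) &&
      !object@condition %in% c("control", "treated"))
    return("condition must be 'control', 'treated' or NA")
  sp <- object@spectra
  if (length(sp)) {
    if (!all(vapply(sp, is, logical(1), class2 = "Spectrum")))
      return("'spectra' must be a list of Spectrum objects")
    rt <- vapply(sp, slot, numeric(1), name = "rt")
    if (is.unsorted(rt))
      return("spectra must be ordered by non-decreasing retention time")
  }
  TRUE
})

#' Chromatogram: an extracted ion chromatogram
#'
#' RT -> intensity trace for one target m/z: one point per contributing
#' scan (zero intensity when no peak fell inside the tolerance window).
#'
#' @slot target named list describing the extraction (target m/z,
#'   tolerance, precursor filter, ...).
#' @slot rt retention times, minutes, strictly increasing.
#' @slot intensity summed intensity within tolerance per scan.
#' @slot scanIds source scan ids.
#' @seealso \code{\link{precursorXIC}}, \code{\link{fragmentXIC}}
#' @exportClass Chromatogram
setClass("Chromatogram",
  slots = c(
    target = "list",
    rt = "numeric",
    intensity = "numeric",
    scanIds = "integer"
  )
)

setValidity("Chromatogram", function(object) {
  if (length(object@rt) != length(object@intensity))
    return("rt and intensity must be parallel")
  if (is.unsorted(object@rt, strictly = TRUE))
    return("rt must be strictly increasing")
  TRUE
})

#' PeakArea: the integral of one chromatographic peak
#'
#' @slot area integrated intensity x minutes (>= 0).
#' @slot rtApex apex retention time (NA when zeroFlag).
#' @slot rtBounds integration bounds, minutes.
#' @slot nScans number of points integrated.
#' @slot zeroFlag TRUE when the trace carried no qualifying signal; the
#'   area is then an observed zero, not a missing value.
#' @seealso \code{\link{integratePeak}}
#' @exportClass PeakArea
setClass("PeakArea",
  slots = c(
    area = "numeric",
    rtApex = "numeric",
    rtBounds = "numeric",
    nScans = "integer",
    zeroFlag = "logical"
  )
)

setValidity("PeakArea", function(object) {
  if (object@area < 0) return("area must be >= 0")
  if (object@zeroFlag && object@area != 0)
    return("zeroFlag implies area == 0")
  TRUE
})

#' LocalizationResult: Ascore-style phosphosite localization
#'
#' @slot peptide peptide sequence.
#' @slot candidates candidate acceptor positions considered.
#' @slot bestSite,runnerUpSite best and second-best single-site isoforms.
#' @slot ascore -10 log10 probability-difference score between the two
#'   best isoforms, computed on site-determining ions; \code{Inf} when only
#'   one candidate exists.
#' @slot peakDepth spectral peak depth (peaks kept per 100 m/z window) at
#'   which the score separation is maximal.
#' @slot confident \code{TRUE} when ascore >= the confidence threshold
#'   (default 13, ~ P <= 0.05) and the top isoforms are not tied.
#' @slot onlyCandidate \code{TRUE} when a single acceptor position made
#'   localization trivial.
#' @slot scores per-depth, per-isoform full-ion scores (audit trail).
#' @seealso \code{\link{localize}}
#' @exportClass LocalizationResult
setClass("LocalizationResult",
  slots = c(
    peptide = "character",
    candidates = "integer",
    bestSite = "integer",
    runnerUpSite = "integer",
    ascore = "numeric",
    peakDepth = "integer",
    confident = "logical",
    onlyCandidate = "logical",
    scores = "data.frame"
  )
)

setValidity("LocalizationResult", function(object) {
  if (length(object@ascore) != 1L || (!is.na(object@ascore) && object@ascore < 0))
    return("ascore must be a single non-negative number")
  TRUE
})

#' PeptidePanel: the quantification panel
#'
#' The set of peptides driving an analysis: phosphopeptides with their
#' quantifier fragment ions, and unphosphorylated internal-standard
#' peptides with the precursor charge states at which they are quantified.
#'
#' @slot entries list; each element is a list with components
#'   \code{label}, \code{site}, \code{peptide} (\linkS4class{ModifiedPeptide}),
#'   \code{internalStandard} (logical), \code{quantifiers} (data.frame with
#'   columns \code{type} ("frag"/"prec"), \code{series}, \code{index},
#'   \code{charge}) and \code{precursorCharge} (charge assumed for MS2
#'   precursor matching and simulation).
#' @seealso \code{\link{readPanel}}, \code{\link{ppp1r12bPanel}}
#' @exportClass PeptidePanel
setClass("PeptidePanel", slots = c(entries = "list"))

setValidity("PeptidePanel", function(object) {
  need <- c("label", "site", "peptide", "internalStandard", "quantifiers",
            "precursorCharge")
  for (e in object@entries) {
    if (!all(need %in% names(e)))
      return(sprintf("panel entry missing component(s): %s",
                     paste(setdiff(need, names(e)), collapse = ", ")))
    if (!is(e$peptide, "ModifiedPeptide"))
      return("panel entry 'peptide' must be a ModifiedPeptide")
  }
  if (anyDuplicated(vapply(object@entries, `[[`, character(1), "label")))
    return("panel labels must be unique")
  TRUE
})
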