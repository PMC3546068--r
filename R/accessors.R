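## Accessors and show() methods. Slots are never reached into from user
## code; these are the supported surface.

#' @rdname accessors
#' @export
setGeneric("scanId", function(x) standardGeneric("scanId"))
#' @rdname accessors
#' @export
setGeneric("msLevel", function(x) standardGeneric("msLevel"))
#' @rdname accessors
#' @export
setGeneric("rtime", function(x) standardGeneric("rtime"))
#' @rdname accessors
#' @export
setGeneric("peaksMatrix", function(x) standardGeneric("peaksMatrix"))
#' @rdname accessors
#' @export
setGeneric("precursorMz", function(x) standardGeneric("precursorMz"))
#' @rdname accessors
#' @export
setGeneric("precursorCharge", function(x) standardGeneric("precursorCharge"))
#' @rdname accessors
#' @export
setGeneric("runId", function(x) standardGeneric("runId"))
#' @rdname accessors
#' @export
setGeneric("condition", function(x) standardGeneric("condition"))
#' @rdname accessors
#' @export
setGeneric("replicate", function(x) standardGeneric("replicate"))
#' @rdname accessors
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))
#' @rdname accessors
#' @export
setGeneric("peptideSequence", function(x) standardGeneric("peptideSequence"))
#' @rdname accessors
#' @export
setGeneric("modifications", function(x) standardGeneric("modifications"))
#' @rdname accessors
#' @export
setGeneric("ambiguityGroup", function(x) standardGeneric("ambiguityGroup"))
#' @rdname accessors
#' @export
setGeneric("proteinCoords", function(x) standardGeneric("proteinCoords"))
#' @rdname accessors
#' @export
setGeneric("area", function(x) standardGeneric("area"))
#' @rdname accessors
#' @export
setGeneric("rtApex", function(x) standardGeneric("rtApex"))
#' @rdname accessors
#' @export
setGeneric("zeroFlag", function(x) standardGeneric("zeroFlag"))
#' @rdname accessors
#' @export
setGeneric("ascore", function(x) standardGeneric("ascore"))
#' @rdname accessors
#' @export
setGeneric("bestSite", function(x) standardGeneric("bestSite"))
#' @rdname accessors
#' @export
setGeneric("isConfident", function(x) standardGeneric("isConfident"))
#' @rdname accessors
#' @export
setGeneric("panelEntries", function(x) standardGeneric("panelEntries"))

#' Accessors for phosquant classes
#'
#' Read-only accessors for the slots of \linkS4class{Spectrum},
#' \linkS4class{SpectrumRun}, \linkS4class{ModifiedPeptide},
#' \linkS4class{Chromatogram}, \linkS4class{PeakArea},
#' \linkS4class{LocalizationResult} and \linkS4class{PeptidePanel}.
#'
#' @param x the object.
#' @return The corresponding slot value; \code{peaksMatrix} returns a
#'   two-column \code{mz}/\code{intensity} matrix; \code{rtime} on a
#'   \code{SpectrumRun} returns the vector of spectrum retention times.
#' @name accessors
#' @aliases scanId msLevel rtime peaksMatrix precursorMz precursorCharge
#'   runId condition replicate spectra peptideSequence modifications
#'   ambiguityGroup proteinCoords area rtApex zeroFlag ascore bestSite
#'   isConfident panelEntries
NULL

#' @rdname accessors
#' @export
setMethod("scanId", "Spectrum", function(x) x@scanId)
#' @rdname accessors
#' @export
setMethod("msLevel", "Spectrum", function(x) x@msLevel)
#' @rdname accessors
#' @export
setMethod("rtime", "Spectrum", function(x) x@rt)
#' @rdname accessors
#' @export
setMethod("peaksMatrix", "Spectrum", function(x)
  cbind(mz = x@mz, intensity = x@intensity))
#' @rdname accessors
#' @export
setMethod("precursorMz", "Spectrum", function(x) x@precursorMz)
#' @rdname accessors
#' @export
setMethod("precursorCharge", "Spectrum", function(x) x@precursorCharge)

#' @rdname accessors
#' @export
setMethod("runId", "SpectrumRun", function(x) x@runId)
#' @rdname accessors
#' @export
setMethod("condition", "SpectrumRun", function(x) x@condition)
#' @rdname accessors
#' @export
setMethod("replicate", "SpectrumRun", function(x) x@replicate)
#' @rdname accessors
#' @export
setMethod("spectra", "SpectrumRun", function(x) x@spectra)
#' @rdname accessors
#' @export
setMethod("rtime", "SpectrumRun", function(x)
  vapply(x@spectra, slot, numeric(1), name = "rt"))

#' @rdname accessors
#' @export
setMethod("peptideSequence", "ModifiedPeptide", function(x) x@sequence)
#' @rdname accessors
#' @export
setMethod("modifications", "ModifiedPeptide", function(x) x@modifications)
#' @rdname accessors
#' @export
setMethod("ambiguityGroup", "ModifiedPeptide", function(x) x@ambiguityGroup)
#' @rdname accessors
#' @export
setMethod("proteinCoords", "ModifiedPeptide", function(x)
  c(start = x@proteinStart, stop = x@proteinStop))

#' @rdname accessors
#' @export
setMethod("rtime", "Chromatogram", function(x) x@rt)
#' @rdname accessors
#' @export
setMethod("area", "PeakArea", function(x) x@area)
#' @rdname accessors
#' @export
setMethod("rtApex", "PeakArea", function(x) x@rtApex)
#' @rdname accessors
#' @export
setMethod("zeroFlag", "PeakArea", function(x) x@zeroFlag)

#' @rdname accessors
#' @export
setMethod("ascore", "LocalizationResult", function(x) x@ascore)
#' @rdname accessors
#' @export
setMethod("bestSite", "LocalizationResult", function(x) x@bestSite)
#' @rdname accessors
#' @export
setMethod("isConfident", "LocalizationResult", function(x) x@confident)

#' @rdname accessors
#' @export
setMethod("panelEntries", "PeptidePanel", function(x) x@entries)
#' @rdname accessors
#' @export
setMethod("length", "PeptidePanel", function(x) length(x@entries))
#' @rdname accessors
#' @export
setMethod("length", "SpectrumRun", function(x) length(x@spectra))

setMethod("show", "ModifiedPeptide", function(object) {
  m <- object@modifications
  mods <- if (nrow(m)) paste(sprintf("%s@%d", m$label, m$position),
                             collapse = ", ") else "none"
  amb <- if (length(object@ambiguityGroup))
    paste0("; 1 phospho floating over positions ",
           paste(object@ambiguityGroup, collapse = "/")) else ""
  cat(sprintf("ModifiedPeptide %s (protein %s-%s)\n  mods: %s%s\n  neutral mass: %.4f Da\n",
              object@sequence, object@proteinStart, object@proteinStop,
              mods, amb, neutralMass(object)))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum scan %d, MS%d, RT %.3f min, %d peaks",
              object@scanId, object@msLevel, object@rt, length(object@mz)))
  if (object@msLevel == 2L)
    cat(sprintf(", precursor %.4f", object@precursorMz))
  cat("\n")
})

setMethod("show", "SpectrumRun", function(object) {
  lv <- vapply(object@spectra, slot, integer(1), name = "msLevel")
  cat(sprintf("SpectrumRun '%s' (%s, replicate %s): %d MS1 + %d MS2 spectra\n",
              object@runId, object@condition, object@replicate,
              sum(lv == 1L), sum(lv == 2L)))
})

setMethod("show", "Chromatogram", function(object) {
  cat(sprintf("Chromatogram (%d points, RT %.2f-%.2f min) target m/z %.4f\n",
              length(object@rt),
              if (length(object@rt)) min(object@rt) else NA,
              if (length(object@rt)) max(object@rt) else NA,
              object@target$mz))
})

setMethod("show", "PeakArea", function(object) {
  if (object@zeroFlag) {
    cat("PeakArea: 0 (no qualifying signal)\n")
  } else {
    cat(sprintf("PeakArea %.4g over RT %.3f-%.3f min (apex %.3f, %d scans)\n",
                object@area, object@rtBounds[1], object@rtBounds[2],
                object@rtApex, object@nScans))
  }
})

setMethod("show", "LocalizationResult", function(object) {
  cat(sprintf("LocalizationResult %s: best site %s (runner-up %s), Ascore %.2f at depth %s -> %s\n",
              object@peptide, object@bestSite, object@runnerUpSite,
              object@ascore, object@peakDepth,
              if (object@confident) "confident" else "ambiguous"))
})

setMethod("show", "PeptidePanel", function(object) {
  is_std <- vapply(object@entries, `[[`, logical(1), "internalStandard")
  cat(sprintf("PeptidePanel: %d phosphopeptides + %d internal standards\n",
              sum(!is_std), sum(is_std)))
})
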