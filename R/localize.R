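## Ascore-style phosphosite localization: cumulative binomial scoring of
## matched fragment ions at spectral peak depths 1..10 per 100 m/z window,
## with the final score computed on site-determining ions only.

#' Cumulative binomial tail probability
#'
#' \eqn{P(X \ge n)} for \eqn{X \sim Binomial(k, p)} -- the probability of
#' matching at least \code{nMatched} of \code{nTrials} theoretical ions by
#' chance when each trial succeeds with probability \code{p}. Exact
#' (computed via \code{\link[stats]{pbinom}}).
#'
#' @param nMatched observed number of matches, 0..nTrials.
#' @param nTrials number of theoretical ions considered.
#' @param p per-trial match probability, in (0, 1).
#' @return The tail probability; 1 when \code{nMatched == 0}.
#' @examples binomialTail(3, 3, 0.5)  # 0.125
#' @export
binomialTail <- function(nMatched, nTrials, p) {
  if (nMatched < 0 || nTrials < 0 || nMatched > nTrials)
    stop("need 0 <= nMatched <= nTrials")
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  if (nMatched == 0) return(1)
  pbinom(nMatched - 1, nTrials, p, lower.tail = FALSE)
}

.ascore_points <- function(nMatched, nTrials, p) {
  -10 * log10(binomialTail(nMatched, nTrials, p))
}

## peaks retained at depth d: the d most intense per contiguous 100 m/z
## window starting at the spectrum's minimum m/z. Ties broken toward the
## lower m/z peak (deterministic).
.depth_filter <- function(mz, intensity, depth, windowSize = 100) {
  if (!length(mz)) return(numeric())
  win <- floor((mz - mz[1]) / windowSize)
  keep <- unlist(lapply(split(seq_along(mz), win), function(idx) {
    o <- idx[order(-intensity[idx], mz[idx])]
    o[seq_len(min(depth, length(o)))]
  }), use.names = FALSE)
  sort(mz[keep])
}

.count_matched <- function(theoretical, peaks, tol) {
  if (!length(peaks)) return(0L)
  i <- findInterval(theoretical, peaks)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(peaks))
  near <- pmin(abs(theoretical - peaks[lo]), abs(theoretical - peaks[hi]))
  sum(near <= tol)
}

#' Ascore-style phosphosite localization
#'
#' Scores each single-site phospho isoform of a peptide against an MS2
#' spectrum. For every peak depth \code{d} in \code{1..maxDepth} the
#' spectrum is reduced to its \code{d} most intense peaks per
#' \code{windowSize} m/z window and each isoform receives
#' \eqn{-10 \log_{10}} of the cumulative binomial probability of its
#' matched b/y ion count (match tolerance \code{tol} Da, trial success
#' probability \code{d / windowSize}). The depth maximizing the separation
#' between the two best isoforms is selected, and the reported Ascore is
#' the score difference computed on the site-determining ions of that pair
#' at that depth. Neutral-loss peaks are not counted as evidence.
#'
#' With a single candidate position the site is fixed by construction:
#' the Ascore is \code{Inf} and the result is flagged
#' \code{onlyCandidate}. Exactly tied isoforms give Ascore 0 and an
#' ambiguous (not confident) call.
#'
#' @param spec an MS2 \linkS4class{Spectrum}.
#' @param sequence peptide sequence.
#' @param candidates candidate phosphosite positions (S/T/Y).
#' @param fixed optional fixed-modification data.frame
#'   (\code{position}, \code{delta}) applied to every isoform.
#' @param tol fragment match tolerance in Da (default 0.5).
#' @param maxDepth maximum peak depth (default 10).
#' @param windowSize m/z window width for the depth filter (default 100).
#' @param charges fragment charges considered (default 1).
#' @param threshold confidence threshold on the Ascore (default 13,
#'   corresponding to roughly P <= 0.05).
#' @return A \linkS4class{LocalizationResult}.
#' @export
localize <- function(spec, sequence, candidates, fixed = NULL, tol = 0.5,
                     maxDepth = 10L, windowSize = 100, charges = 1L,
                     threshold = 13) {
  stopifnot(is(spec, "Spectrum"))
  if (spec@msLevel != 2L) stop("localization needs an MS2 spectrum")
  letters <- strsplit(sequence, "")[[1]]
  candidates <- as.integer(candidates)
  if (!all(letters[candidates] %in% c("S", "T", "Y")))
    stop("candidate positions must be S/T/Y residues")

  if (length(candidates) < 2L) {
    return(new("LocalizationResult", peptide = sequence,
               candidates = candidates,
               bestSite = candidates[1], runnerUpSite = NA_integer_,
               ascore = Inf, peakDepth = NA_integer_, confident = TRUE,
               onlyCandidate = TRUE,
               scores = data.frame(depth = integer(), site = integer(),
                                   score = numeric())))
  }

  ions <- lapply(candidates, function(s)
    isoformIons(sequence, site = s, fixed = fixed, charges = charges)$mz)
  nTrials <- length(ions[[1]])

  depths <- seq_len(maxDepth)
  score <- matrix(0, nrow = length(depths), ncol = length(candidates))
  retained <- vector("list", length(depths))
  for (d in depths) {
    peaks <- .depth_filter(spec@mz, spec@intensity, d, windowSize)
    retained[[d]] <- peaks
    p <- d / windowSize
    for (j in seq_along(candidates))
      score[d, j] <- .ascore_points(.count_matched(ions[[j]], peaks, tol),
                                    nTrials, p)
  }

  ## separation between best and runner-up at each depth; the best depth is
  ## the smallest one attaining the maximal separation
  sep <- apply(score, 1, function(s) {
    o <- sort(s, decreasing = TRUE)
    o[1] - o[2]
  })
  dStar <- which.max(sep)
  sAtD <- score[dStar, ]
  ord <- order(-sAtD, candidates)  # ties -> lower position first
  best <- candidates[ord[1]]
  runner <- candidates[ord[2]]

  ## site-determining ions of the best pair, scored at the chosen depth
  if (!is.null(fixed) && nrow(fixed) && is.null(fixed$label))
    fixed$label <- "other"
  pep <- modifiedPeptide(sequence, fixed)
  sdi <- siteDeterminingIons(pep, best, runner, charges = charges)
  peaks <- retained[[dStar]]
  p <- dStar / windowSize
  scoreSD <- function(mzs) {
    if (!length(mzs)) return(0)
    .ascore_points(.count_matched(mzs, peaks, tol), length(mzs), p)
  }
  aBest <- scoreSD(sdi$a$mz)
  aRunner <- scoreSD(sdi$b$mz)
  asc <- aBest - aRunner
  if (asc < 0) {  # site-determining evidence overrules the full-ion order
    tmp <- best; best <- runner; runner <- tmp
    asc <- -asc
  }

  scoresDf <- data.frame(depth = rep(depths, times = length(candidates)),
                         site = rep(candidates, each = length(depths)),
                         score = as.vector(score))
  new("LocalizationResult", peptide = sequence, candidates = candidates,
      bestSite = best, runnerUpSite = runner, ascore = asc,
      peakDepth = as.integer(dStar),
      confident = is.finite(asc) && asc >= threshold,
      onlyCandidate = FALSE, scores = scoresDf)
}

#' Localize phosphosites across runs
#'
#' Applies \code{\link{localize}} to every MS2 scan whose precursor
#' matches a phosphopeptide of the panel (within the spectrum's isolation
#' half-width, default 1.5 Da when unspecified). Candidate positions are
#' the peptide's ambiguity group when present, otherwise all S/T/Y
#' positions of the sequence.
#'
#' @param runs list of \linkS4class{SpectrumRun}.
#' @param panel a \linkS4class{PeptidePanel}.
#' @param ... passed to \code{\link{localize}}.
#' @return \code{data.frame}: run, scan, label, peptide, bestSite,
#'   runnerUpSite, ascore, peakDepth, confident.
#' @export
runLocalize <- function(runs, panel, ...) {
  if (is(runs, "SpectrumRun")) runs <- list(runs)
  stopifnot(is(panel, "PeptidePanel"))
  phos <- Filter(function(e) !e$internalStandard, panel@entries)
  out <- list()
  for (run in runs) {
    for (sp in run@spectra) {
      if (sp@msLevel != 2L) next
      iso <- if (is.na(sp@isolationWidth)) 1.5 else sp@isolationWidth
      for (e in phos) {
        pmz <- protonatedMz(e$peptide, e$precursorCharge)
        if (abs(sp@precursorMz - pmz) > iso) next
        seqs <- peptideSequence(e$peptide)
        ag <- ambiguityGroup(e$peptide)
        cand <- if (length(ag)) ag
                else which(strsplit(seqs, "")[[1]] %in% c("S", "T", "Y"))
        fixed <- modifications(e$peptide)
        fixed <- fixed[!fixed$label %in% "phospho", , drop = FALSE]
        loc <- localize(sp, seqs, cand, fixed = fixed, ...)
        out[[length(out) + 1L]] <- data.frame(
          run = run@runId, scan = sp@scanId, label = e$label,
          peptide = seqs, bestSite = loc@bestSite,
          runnerUpSite = loc@runnerUpSite, ascore = loc@ascore,
          peakDepth = loc@peakDepth, confident = loc@confident,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(run = character(), scan = integer(),
                      label = character(), peptide = character(),
                      bestSite = integer(), runnerUpSite = integer(),
                      ascore = numeric(), peakDepth = integer(),
                      confident = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
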