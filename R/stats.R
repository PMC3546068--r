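## Internal-standard normalization, control-relative ratios, fold change
## +/- SEM, and paired t-tests. Zeros are observed measurements and
## propagate into means and tests; no multiple-testing correction is
## applied across sites (the per-site results are reported as such).

#' Normalize a raw peak area to internal standards
#'
#' Divides a phosphopeptide raw area by the mean raw area of the
#' internal-standard peptides measured in the same sample, correcting for
#' per-sample protein loading.
#'
#' @param rawArea raw phosphopeptide peak area (a zero is a measurement).
#' @param standardAreas numeric vector of internal-standard areas (>= 1
#'   value, not all zero).
#' @return Normalized area.
#' @examples normalizeArea(10, c(5, 15))  # 1
#' @export
normalizeArea <- function(rawArea, standardAreas) {
  if (!length(standardAreas)) stop("need at least one internal-standard area")
  if (all(standardAreas == 0)) stop("sample failed loading control: all internal-standard areas are zero")
  rawArea / mean(standardAreas)
}

#' Control-relative ratios for one site
#'
#' Divides every normalized area of a site (both conditions) by the mean
#' of its control normalized areas, so the control ratios average to 1 by
#' construction.
#'
#' @param quant quantification table: \code{data.frame} with columns
#'   \code{site}, \code{experiment}, \code{condition}
#'   (\code{"control"}/\code{"treated"}), \code{normalizedArea}.
#' @param site site label to extract.
#' @return \code{data.frame} with columns \code{experiment},
#'   \code{condition}, \code{normalizedArea}, \code{ratio}; carries the
#'   attribute \code{quantifiable = FALSE} (ratios \code{NA}) when the
#'   control mean is zero.
#' @export
controlRelativeRatios <- function(quant, site) {
  rows <- quant[quant$site == site, , drop = FALSE]
  if (!nrow(rows)) stop("site not present: ", site)
  ctrl <- rows$normalizedArea[rows$condition == "control"]
  if (!length(ctrl)) stop("site has no control values: ", site)
  cm <- mean(ctrl)
  out <- rows[order(rows$condition, rows$experiment),
              c("experiment", "condition", "normalizedArea")]
  if (cm > 0) {
    out$ratio <- out$normalizedArea / cm
    attr(out, "quantifiable") <- TRUE
  } else {
    out$ratio <- NA_real_
    attr(out, "quantifiable") <- FALSE
  }
  rownames(out) <- NULL
  out
}

#' Fold change and SEM from control-relative ratios
#'
#' The fold change is the mean treated ratio; its SEM uses the sample
#' (n-1) standard deviation divided by sqrt(n).
#'
#' @param ratios output of \code{\link{controlRelativeRatios}}, or a list
#'   with components \code{control} and \code{treated} (ratio vectors).
#' @return list: \code{n}, \code{foldChange}, \code{sem},
#'   \code{controlMean} (1 by construction), \code{controlSem}.
#' @export
foldChangeSummary <- function(ratios) {
  if (is.data.frame(ratios)) {
    ratios <- list(control = ratios$ratio[ratios$condition == "control"],
                   treated = ratios$ratio[ratios$condition == "treated"])
  }
  tr <- ratios$treated
  ct <- ratios$control
  n <- length(tr)
  if (n < 2L)
    return(list(n = n, foldChange = if (n) mean(tr) else NA_real_,
                sem = NA_real_, controlMean = mean(ct), controlSem = NA_real_))
  list(n = n, foldChange = mean(tr), sem = sd(tr) / sqrt(n),
       controlMean = mean(ct), controlSem = sd(ct) / sqrt(length(ct)))
}

#' Two-sided paired t-test on normalized areas
#'
#' Invariant to a common positive rescaling of both vectors, so testing
#' normalized areas and testing control-relative ratios give the same
#' p-value. All-zero differences (treated identical to control) give
#' t = 0, p = 1; non-zero constant differences have no sampling variance
#' and the p-value is undefined (\code{NA}, flagged).
#'
#' @param control,treated equal-length paired vectors (n >= 2).
#' @return list: \code{t}, \code{df}, \code{p}, \code{flag}
#'   (\code{NA_character_} when the test is regular).
#' @export
pairedTTest <- function(control, treated) {
  if (length(control) != length(treated))
    stop("paired vectors must have equal length")
  n <- length(control)
  if (n < 2L) stop("need n >= 2 pairs")
  d <- treated - control
  if (sd(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, df = n - 1L, p = 1, flag = "zero-difference"))
    return(list(t = NaN, df = n - 1L, p = NA_real_, flag = "zero-variance"))
  }
  ht <- t.test(treated, control, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, flag = NA_character_)
}

#' Per-site differential summary from a normalized-area table
#'
#' The re-analysis entry point: takes a quantification table (site,
#' experiment, condition, normalizedArea), forms control-relative ratios,
#' fold change +/- SEM and a two-sided paired t-test per site. The t-test
#' is computed on the normalized areas; by scale invariance the same
#' p-value results from the ratios.
#'
#' @param quant quantification table (see
#'   \code{\link{controlRelativeRatios}}); \code{\link{table4Fixture}}
#'   returns one.
#' @param siteOrder optional site ordering for the output.
#' @return list with \code{results} (one row per site: site, n,
#'   foldChange, sem, controlMean, controlSem, t, df, p, flag) and
#'   \code{ratios} (per-experiment ratio table across sites).
#' @examples
#' fit <- reanalyzeTable(table4Fixture())
#' fit$results[, c("site", "foldChange", "sem", "p")]
#' @export
reanalyzeTable <- function(quant, siteOrder = unique(quant$site)) {
  need <- c("site", "experiment", "condition", "normalizedArea")
  if (!all(need %in% names(quant)))
    stop("quant table needs columns: ", paste(need, collapse = ", "))
  if (!all(quant$condition %in% c("control", "treated")))
    stop("condition must be 'control' or 'treated'")
  resRows <- list()
  ratioRows <- list()
  for (s in siteOrder) {
    rr <- controlRelativeRatios(quant, s)
    quantifiable <- isTRUE(attr(rr, "quantifiable"))
    ctrl <- rr[rr$condition == "control", ]
    trt <- rr[rr$condition == "treated", ]
    if (!all(ctrl$experiment %in% trt$experiment) ||
        !all(trt$experiment %in% ctrl$experiment))
      stop("site ", s, " is not fully paired across experiments")
    trt <- trt[match(ctrl$experiment, trt$experiment), ]
    fc <- foldChangeSummary(rr)
    tt <- if (quantifiable && nrow(ctrl) >= 2L)
      pairedTTest(ctrl$normalizedArea, trt$normalizedArea)
    else list(t = NA_real_, df = NA_real_, p = NA_real_,
              flag = if (!quantifiable) "unquantifiable" else "n<2")
    resRows[[s]] <- data.frame(
      site = s, n = fc$n,
      foldChange = if (quantifiable) fc$foldChange else NA_real_,
      sem = if (quantifiable) fc$sem else NA_real_,
      controlMean = if (quantifiable) fc$controlMean else NA_real_,
      controlSem = if (quantifiable) fc$controlSem else NA_real_,
      t = tt$t, df = tt$df, p = tt$p, flag = tt$flag,
      stringsAsFactors = FALSE)
    ratioRows[[s]] <- cbind(site = s, rr)
  }
  results <- do.call(rbind, resRows)
  ratios <- do.call(rbind, ratioRows)
  rownames(results) <- rownames(ratios) <- NULL
  list(results = results, ratios = ratios)
}

#' Protein sequence coverage from detected peptide intervals
#'
#' Percentage of protein residues covered by the union of 1-based
#' inclusive intervals.
#'
#' @param protein either the protein sequence (string) or its length.
#' @param intervals \code{data.frame}/matrix with columns \code{start},
#'   \code{stop} (1-based inclusive).
#' @return Percent coverage in [0, 100].
#' @examples
#' sequenceCoverage(100, data.frame(start = c(1, 5), stop = c(10, 14)))
#' @export
sequenceCoverage <- function(protein, intervals) {
  len <- if (is.character(protein)) nchar(protein) else as.integer(protein)
  if (is.matrix(intervals)) intervals <- as.data.frame(intervals)
  if (!nrow(intervals)) return(0)
  st <- as.integer(intervals$start)
  en <- as.integer(intervals$stop)
  if (any(st < 1L | en > len | st > en))
    stop("interval out of range [1, ", len, "]")
  covered <- sum(IRanges::width(IRanges::reduce(IRanges::IRanges(st, en))))
  100 * covered / len
}
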