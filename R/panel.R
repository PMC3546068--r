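## The peptide panel: which peptides are quantified, by which ions, and
## which peptides serve as endogenous internal standards.

.parse_quantifiers <- function(spec) {
  parts <- strsplit(trimws(spec), ";", fixed = TRUE)[[1]]
  rows <- lapply(parts, function(p) {
    kv <- strsplit(trimws(p), "/", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop(sprintf("cannot parse quantifier '%s' (expected e.g. y8/+1 or prec/+2)", p))
    z <- as.integer(sub("^\\+", "", kv[2]))
    if (identical(kv[1], "prec"))
      return(data.frame(type = "prec", series = NA_character_,
                        index = NA_integer_, charge = z))
    data.frame(type = "frag", series = substr(kv[1], 1, 1),
               index = as.integer(substring(kv[1], 2)), charge = z)
  })
  out <- do.call(rbind, rows)
  if (!all(out$type == "prec" | out$series %in% c("b", "y")))
    stop("quantifier series must be b or y")
  out
}

#' Read a peptide panel file
#'
#' Tab-delimited panel with columns \code{label}, \code{site},
#' \code{start}, \code{stop}, \code{sequence}, \code{mods} (e.g.
#' \code{"phospho@2"}), \code{ambiguity} (comma-separated positions over
#' which one phosphate floats), \code{internal_standard} (0/1),
#' \code{quantifiers} (\code{"y8/+1;y9/+1"} for fragment ions,
#' \code{"prec/+2;prec/+1"} for precursor charge states) and
#' \code{precursor_charge} (charge assumed when matching MS2 precursors).
#'
#' @param path panel file.
#' @return A \linkS4class{PeptidePanel}.
#' @seealso \code{\link{ppp1r12bPanel}} for the shipped panel.
#' @export
readPanel <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = list(mods = "character",
                                      ambiguity = "character",
                                      site = "character"))
  tab$mods[is.na(tab$mods)] <- ""
  tab$ambiguity[is.na(tab$ambiguity)] <- ""
  tab$site[is.na(tab$site)] <- ""
  entries <- lapply(seq_len(nrow(tab)), function(i) {
    amb <- if (nzchar(tab$ambiguity[i]))
      as.integer(strsplit(tab$ambiguity[i], ",", fixed = TRUE)[[1]])
    else integer()
    pep <- modifiedPeptide(tab$sequence[i], tab$mods[i], ambiguityGroup = amb,
                           proteinStart = tab$start[i],
                           proteinStop = tab$stop[i])
    list(label = tab$label[i],
         site = tab$site[i],
         peptide = pep,
         internalStandard = as.logical(tab$internal_standard[i]),
         quantifiers = .parse_quantifiers(tab$quantifiers[i]),
         precursorCharge = as.integer(tab$precursor_charge[i]))
  })
  new("PeptidePanel", entries = entries)
}

#' The PPP1R12B quantification panel
#'
#' The shipped panel of six quantified PPP1R12B phosphopeptides (with
#' their quantifier b/y fragment ions) and eight unphosphorylated
#' PPP1R12B peptides used as endogenous internal standards (with the
#' precursor charge states at which they are quantified). The peptide
#' carrying the adjacent Ser645/Thr646 acceptors is modeled with a single
#' phosphate floating over its first two residues, because its spectra do
#' not discriminate the two sites.
#'
#' @return A \linkS4class{PeptidePanel}.
#' @export
ppp1r12bPanel <- function() {
  readPanel(system.file("extdata", "ppp1r12b_panel.tsv",
                        package = "phosquant", mustWork = TRUE))
}

#' Published normalized peak areas (re-analysis fixture)
#'
#' The published 6-site x 4-experiment x 2-condition table of normalized
#' peak areas (phosphopeptide raw area divided by the mean
#' internal-standard area of the same sample), transcribed as printed;
#' zeros are observed zeros. Feed it to \code{\link{reanalyzeTable}} to
#' reproduce the published fold changes, SEMs and paired t-tests.
#'
#' @return \code{data.frame} with columns \code{site}, \code{experiment},
#'   \code{condition} (\code{"control"}/\code{"treated"}),
#'   \code{normalizedArea}.
#' @export
table4Fixture <- function() {
  tab <- read.delim(system.file("extdata", "table4_normalized_areas.tsv",
                                package = "phosquant", mustWork = TRUE),
                    stringsAsFactors = FALSE)
  data.frame(site = tab$site, experiment = as.integer(tab$experiment),
             condition = tab$condition,
             normalizedArea = as.numeric(tab$normalized_area),
             stringsAsFactors = FALSE)
}

#' Theoretical m/z table for a panel
#'
#' Computes, for every panel entry, the neutral mass, \eqn{[M+H]^+}, and
#' the m/z of each quantifier ion -- the package's rendering of a
#' "quantified m/z" / "product ion m/z" reference table.
#'
#' @param panel a \linkS4class{PeptidePanel}.
#' @return \code{data.frame}: label, site, start, stop, sequence,
#'   neutralMass, mhPlus, ion, charge, mz.
#' @export
panelMzTable <- function(panel = ppp1r12bPanel()) {
  stopifnot(is(panel, "PeptidePanel"))
  rows <- lapply(panel@entries, function(e) {
    q <- e$quantifiers
    co <- proteinCoords(e$peptide)
    mz <- numeric(nrow(q))
    ion <- character(nrow(q))
    for (i in seq_len(nrow(q))) {
      if (q$type[i] == "prec") {
        mz[i] <- protonatedMz(e$peptide, q$charge[i])
        ion[i] <- sprintf("prec/+%d", q$charge[i])
      } else {
        mz[i] <- fragmentMz(e$peptide, q$series[i], q$index[i], q$charge[i])
        ion[i] <- sprintf("%s%d/+%d", q$series[i], q$index[i], q$charge[i])
      }
    }
    data.frame(label = e$label, site = e$site, start = co[["start"]],
               stop = co[["stop"]], sequence = peptideSequence(e$peptide),
               neutralMass = neutralMass(e$peptide),
               mhPlus = protonatedMz(e$peptide, 1L),
               ion = ion, charge = q$charge, mz = mz,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
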