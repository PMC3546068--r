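## Monoisotopic mass engine for modified tryptic peptides and their b/y
## fragment ions. Conventions: proton 1.00728 Da (back-calculated from the
## published precursor m/z table), I/L mass-identical, cysteine unmodified
## unless a fixed modification is supplied.

.RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.MASS_CONST <- c(
  proton = 1.00728,
  water = 18.01056,
  phospho = 79.96633,
  oxidation = 15.99491,
  H3PO4 = 97.97690,
  H2O = 18.01056
)

#' Monoisotopic residue masses
#'
#' @return Named numeric vector of the 20 standard residue monoisotopic
#'   masses in Da (I and L share one mass).
#' @examples residueMasses()[["G"]]
#' @export
residueMasses <- function() .RESIDUE_MASSES

#' Mass constants
#'
#' Proton, water, phosphorylation and methionine-oxidation deltas, and the
#' H3PO4 / H2O neutral-loss masses, all monoisotopic Da.
#'
#' @return Named numeric vector.
#' @export
massConstants <- function() .MASS_CONST

.residue_vec <- function(sequence) {
  letters <- strsplit(sequence, "")[[1]]
  bad <- setdiff(letters, names(.RESIDUE_MASSES))
  if (length(bad))
    stop(sprintf("unknown residue letter(s): %s", paste(bad, collapse = ", ")))
  unname(.RESIDUE_MASSES[letters])
}

#' Construct a ModifiedPeptide
#'
#' @param sequence uppercase residue letters.
#' @param modifications either \code{NULL}, a \code{data.frame} with
#'   columns \code{position}, \code{delta}, \code{label}, or a compact
#'   character spec such as \code{"phospho@2"} or
#'   \code{"phospho@4;ox@7"} (labels \code{phospho} and \code{ox} map to
#'   the standard deltas; any other label needs \code{delta@pos=...} form
#'   is not supported -- pass a data.frame).
#' @param ambiguityGroup integer positions (S/T/Y) over which exactly one
#'   phosphate floats; the floating phosphate is additional to
#'   \code{modifications}.
#' @param proteinStart,proteinStop 1-based inclusive protein coordinates.
#' @return A \linkS4class{ModifiedPeptide}.
#' @examples
#' modifiedPeptide("GSLTEQEPAER", "phospho@2", proteinStart = 28,
#'                 proteinStop = 38)
#' @export
modifiedPeptide <- function(sequence, modifications = NULL,
                            ambiguityGroup = integer(),
                            proteinStart = NA_integer_,
                            proteinStop = NA_integer_) {
  if (is.character(modifications)) {
    modifications <- .parse_mod_spec(modifications)
  } else if (is.null(modifications)) {
    modifications <- data.frame(position = integer(), delta = numeric(),
                                label = character())
  }
  modifications$position <- as.integer(modifications$position)
  new("ModifiedPeptide", sequence = sequence,
      modifications = modifications,
      ambiguityGroup = as.integer(ambiguityGroup),
      proteinStart = as.integer(proteinStart),
      proteinStop = as.integer(proteinStop))
}

.parse_mod_spec <- function(spec) {
  spec <- trimws(spec)
  if (!nzchar(spec))
    return(data.frame(position = integer(), delta = numeric(),
                      label = character()))
  parts <- strsplit(spec, ";", fixed = TRUE)[[1]]
  deltas <- c(phospho = .MASS_CONST[["phospho"]], ox = .MASS_CONST[["oxidation"]])
  out <- lapply(parts, function(p) {
    kv <- strsplit(trimws(p), "@", fixed = TRUE)[[1]]
    if (length(kv) != 2L || !kv[1] %in% names(deltas))
      stop(sprintf("cannot parse modification spec '%s'", p))
    data.frame(position = as.integer(kv[2]), delta = unname(deltas[kv[1]]),
               label = kv[1])
  })
  do.call(rbind, out)
}

## mass deltas per position, phospho placed at `site` when the peptide has
## an ambiguity group and a site assignment is supplied (or taken literally
## when no group exists)
.delta_by_pos <- function(peptide, site = NULL) {
  n <- nchar(peptide@sequence)
  d <- numeric(n)
  m <- peptide@modifications
  if (nrow(m)) d[m$position] <- m$delta
  if (!is.null(site)) {
    site <- as.integer(site)
    if (site < 1L || site > n) stop("site out of range")
    d[site] <- d[site] + .MASS_CONST[["phospho"]]
  }
  d
}

#' @rdname neutralMass
#' @export
setGeneric("neutralMass", function(peptide, ...) standardGeneric("neutralMass"))

#' Monoisotopic neutral peptide mass
#'
#' Sum of residue masses plus water plus all modification deltas. A
#' floating phosphate (ambiguity group) contributes regardless of which
#' acceptor residue carries it.
#'
#' @param peptide a \linkS4class{ModifiedPeptide} or a plain sequence
#'   string (no modifications).
#' @param ... unused.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' neutralMass("IQSGFFK")  # 825.4385
#' @export
setMethod("neutralMass", "ModifiedPeptide", function(peptide, ...) {
  m <- sum(.residue_vec(peptide@sequence)) + .MASS_CONST[["water"]] +
    sum(peptide@modifications$delta)
  if (length(peptide@ambiguityGroup)) m <- m + .MASS_CONST[["phospho"]]
  m
})

#' @rdname neutralMass
#' @export
setMethod("neutralMass", "character", function(peptide, ...) {
  neutralMass(modifiedPeptide(peptide))
})

#' @rdname protonatedMz
#' @export
setGeneric("protonatedMz", function(peptide, charge = 1L, ...)
  standardGeneric("protonatedMz"))

#' Protonated m/z at a given charge
#'
#' \code{(neutralMass + charge * 1.00728) / charge}.
#'
#' @param peptide a \linkS4class{ModifiedPeptide} or sequence string.
#' @param charge positive integer charge state.
#' @param ... unused.
#' @return m/z in Da per charge.
#' @examples
#' protonatedMz("IQSGFFK", 2)  # 413.7265
#' @export
setMethod("protonatedMz", "ModifiedPeptide", function(peptide, charge = 1L, ...) {
  charge <- as.integer(charge)
  if (any(charge <= 0L)) stop("charge must be a positive integer")
  (neutralMass(peptide) + charge * .MASS_CONST[["proton"]]) / charge
})

#' @rdname protonatedMz
#' @export
setMethod("protonatedMz", "character", function(peptide, charge = 1L, ...) {
  protonatedMz(modifiedPeptide(peptide), charge)
})

#' b/y fragment-ion m/z
#'
#' Monoisotopic m/z of a b or y backbone fragment: \code{b_i} sums residues
#' 1..i (plus their modification deltas and charge protons), \code{y_j}
#' sums the last j residues plus water. Neutral losses (\code{"H3PO4"},
#' \code{"H2O"}; repeat an element for multiple losses) are subtracted from
#' the fragment's neutral mass before dividing by charge.
#'
#' For peptides with an ambiguity group, a fragment covering some but not
#' all candidate positions has a site-dependent mass and is an error unless
#' an explicit \code{site} is supplied; fragments covering all or none of
#' the group are ambiguity-safe.
#'
#' @param peptide a \linkS4class{ModifiedPeptide}.
#' @param series \code{"b"} or \code{"y"}.
#' @param index fragment index, 1 .. length-1.
#' @param charge positive integer.
#' @param losses character vector of neutral losses.
#' @param site optional explicit phosphosite resolving an ambiguity group.
#' @return Fragment m/z.
#' @examples
#' p <- modifiedPeptide("GSLTEQEPAER", "phospho@2")
#' fragmentMz(p, "y", 8)   # 959.44
#' @export
fragmentMz <- function(peptide, series = c("b", "y"), index, charge = 1L,
                       losses = character(), site = NULL) {
  series <- match.arg(series)
  stopifnot(is(peptide, "ModifiedPeptide"))
  n <- nchar(peptide@sequence)
  index <- as.integer(index)
  charge <- as.integer(charge)
  if (index < 1L || index >= n) stop("fragment index must be in 1 .. length-1")
  if (charge <= 0L) stop("charge must be a positive integer")
  pos <- if (series == "b") seq_len(index) else (n - index + 1L):n

  ag <- peptide@ambiguityGroup
  deltas <- .delta_by_pos(peptide, site = if (length(ag)) site else NULL)
  if (length(ag) && is.null(site)) {
    inside <- sum(ag %in% pos)
    if (inside == length(ag)) {
      deltas[ag[1]] <- deltas[ag[1]] + .MASS_CONST[["phospho"]]
    } else if (inside != 0L) {
      stop("site-dependent fragment: ", series, index,
           " straddles the ambiguity group; supply an explicit site")
    }
  } else if (length(ag) && !is.null(site) && !(site %in% ag)) {
    stop("explicit site must be one of the ambiguity-group positions")
  }

  res <- .residue_vec(peptide@sequence)
  neutral <- sum(res[pos]) + sum(deltas[pos])
  if (series == "y") neutral <- neutral + .MASS_CONST[["water"]]
  if (length(losses)) {
    known <- c("H3PO4", "H2O")
    if (!all(losses %in% known))
      stop("unknown neutral loss; use H3PO4 and/or H2O")
    neutral <- neutral - sum(.MASS_CONST[losses])
  }
  (neutral + charge * .MASS_CONST[["proton"]]) / charge
}

## all b/y ions of a single-site isoform (internal; used by localization
## and the simulator)
.all_by_ions <- function(sequence, deltaByPos, charges = 1L) {
  res <- .residue_vec(sequence)
  n <- length(res)
  cumb <- cumsum(res + deltaByPos)[-n]
  cumy <- rev(cumsum(rev(res + deltaByPos))[-n]) + .MASS_CONST[["water"]]
  out <- lapply(charges, function(z) {
    data.frame(
      series = rep(c("b", "y"), each = n - 1L),
      index = c(seq_len(n - 1L), rev(seq_len(n - 1L))),
      charge = z,
      mz = (c(cumb, cumy) + z * .MASS_CONST[["proton"]]) / z
    )
  })
  do.call(rbind, out)
}

#' Fragment ions of a single-site phospho isoform
#'
#' All b/y ions (at the requested charges) of \code{sequence} carrying one
#' phosphate at \code{site} plus any fixed modifications.
#'
#' @param sequence peptide sequence.
#' @param site phosphosite position (\code{NULL} for none).
#' @param fixed optional fixed-modification \code{data.frame}
#'   (\code{position}, \code{delta}).
#' @param charges integer vector of fragment charges.
#' @return \code{data.frame} with columns series, index, charge, mz.
#' @export
isoformIons <- function(sequence, site = NULL, fixed = NULL, charges = 1L) {
  n <- nchar(sequence)
  d <- numeric(n)
  if (!is.null(fixed) && nrow(fixed)) d[fixed$position] <- fixed$delta
  if (!is.null(site)) d[site] <- d[site] + .MASS_CONST[["phospho"]]
  .all_by_ions(sequence, d, charges = charges)
}

#' Site-determining ions between two phosphosite isoforms
#'
#' Enumerates all b/y ions of the two single-site isoforms of a peptide
#' (one phosphate at \code{siteA} vs at \code{siteB}) and returns those
#' whose m/z differs between isoforms. Symmetric in its arguments;
#' identical sites give empty sets.
#'
#' @param peptide a \linkS4class{ModifiedPeptide} (its ambiguity group, if
#'   any, is ignored in favor of the explicit sites; fixed modifications
#'   are retained).
#' @param siteA,siteB candidate phosphosite positions (S/T/Y).
#' @param charges integer vector of fragment charges to consider.
#' @return list with components \code{a} and \code{b}: data.frames of the
#'   discriminating ions (series, index, charge, mz) under each isoform.
#' @examples
#' p <- modifiedPeptide("GSLTEQEPAER", "phospho@2")
#' siteDeterminingIons(p, 2, 4)$a$mz
#' @export
siteDeterminingIons <- function(peptide, siteA, siteB, charges = 1L) {
  stopifnot(is(peptide, "ModifiedPeptide"))
  seqs <- peptide@sequence
  letters <- strsplit(seqs, "")[[1]]
  for (s in c(siteA, siteB))
    if (!letters[s] %in% c("S", "T", "Y"))
      stop("candidate sites must be S/T/Y residues")
  fixed <- peptide@modifications[!peptide@modifications$label %in% "phospho", ,
                                 drop = FALSE]
  a <- isoformIons(seqs, site = siteA, fixed = fixed, charges = charges)
  b <- isoformIons(seqs, site = siteB, fixed = fixed, charges = charges)
  diff <- abs(a$mz - b$mz) > 1e-9
  list(a = a[diff, , drop = FALSE], b = b[diff, , drop = FALSE])
}
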