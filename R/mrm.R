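NOMINAL_MASS <- c(C = 12L, H = 1L, N = 14L, O = 16L)
MONO_MASS <- c(C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221)

#' Molecular formula and mass of an N-acyl homoserine lactone
#'
#' An unsubstituted Cn-HSL (acyl chain of n carbons amide-linked to the
#' homoserine lactone ring) has formula C(n+4) H(2(n+4)-3) N O3; the 3-oxo
#' variant carries one more oxygen and two fewer hydrogens:
#' C(n+4) H(2(n+4)-5) N O4.
#'
#' @param n acyl chain length in carbons (>= 4); vectorized.
#' @param is3oxo logical, 3-oxo substitution; vectorized.
#' @return data.frame with \code{n}, \code{is3oxo}, \code{formula},
#'   element counts \code{C}, \code{H}, \code{N}, \code{O},
#'   \code{nominalMass} (integer Da) and \code{monoisotopicMass} (Da, 4 dp).
#' @examples
#' ahlFormula(6, FALSE)   # C10H17NO3, nominal 199 ([M+H]+ 200)
#' ahlFormula(6, TRUE)    # C10H15NO4, nominal 213 ([M+H]+ 214)
#' @export
ahlFormula <- function(n, is3oxo = FALSE) {
  if (any(n < 4)) stop("acyl chain length must be >= 4")
  k <- length(n)
  is3oxo <- rep_len(is3oxo, k)
  C <- n + 4L
  H <- 2L * (n + 4L) - ifelse(is3oxo, 5L, 3L)
  O <- ifelse(is3oxo, 4L, 3L)
  nominal <- C * NOMINAL_MASS["C"] + H * NOMINAL_MASS["H"] +
    NOMINAL_MASS["N"] + O * NOMINAL_MASS["O"]
  mono <- C * MONO_MASS["C"] + H * MONO_MASS["H"] + MONO_MASS["N"] +
    O * MONO_MASS["O"]
  data.frame(n = n, is3oxo = is3oxo,
             formula = sprintf("C%dH%dNO%d", C, H, O),
             C = as.integer(C), H = as.integer(H), N = 1L,
             O = as.integer(O),
             nominalMass = as.integer(nominal),
             monoisotopicMass = round(unname(mono), 4))
}

#' Nominal [M+H]+ m/z of an AHL
#'
#' Protonated molecular ion at unit resolution: nominal mass + 1.
#'
#' @inheritParams ahlFormula
#' @return integer m/z values.
#' @examples
#' precursorMz(12, TRUE)   # 298 (3-oxo-C12-HSL)
#' precursorMz(12, FALSE)  # 284 (C12-HSL)
#' @export
precursorMz <- function(n, is3oxo = FALSE) {
  ahlFormula(n, is3oxo)$nominalMass + 1L
}

#' Diagnostic homoserine-lactone fragment ion m/z
#'
#' All AHL MRM transitions share the product ion of the protonated
#' homoserine lactone ring (C4H7NO2 + H), computed here from its formula:
#' m/z 102 at unit resolution.
#'
#' @return integer, 102.
#' @export
hslFragmentMz <- function() {
  as.integer(4L * NOMINAL_MASS["C"] + 7L * NOMINAL_MASS["H"] +
             NOMINAL_MASS["N"] + 2L * NOMINAL_MASS["O"] + 1L)
}

#' AHL standards table
#'
#' The ten-analyte standards panel used for MRM screening: name, chain
#' length, 3-oxo flag, nominal [M+H]+ and reference retention time
#' (minutes). Note C7-HSL and 3-oxo-C6-HSL share nominal [M+H]+ 214 and are
#' distinguished only by retention time.
#'
#' @return data.frame with columns \code{name}, \code{n}, \code{is3oxo},
#'   \code{mz}, \code{rt}.
#' @export
ahlStandards <- function() {
  path <- system.file("extdata", "ahl_standards.csv", package = "ahlqs")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$is3oxo <- as.logical(df$is3oxo)
  df
}

#' Match MRM peaks against the AHL standards
#'
#' Verdicts: a peak is \code{matched} to a standard iff its product ion is
#' within \code{mzTol} of 102, its precursor within \code{mzTol} of the
#' standard's [M+H]+, and (when the standard has a reference retention time)
#' its retention time within \code{rtTol}; a peak with product near 102 but
#' no precursor (or rt) match is a \code{putative unknown AHL}, reported with
#' its retention time; peaks with product ion away from 102 are
#' \code{ignored}. Every peak receives exactly one verdict. When several
#' standards are compatible (e.g. C7 vs 3-oxo-C6 at m/z 214), the one with
#' the closest retention time (then closest precursor m/z) is chosen and the
#' peak is flagged \code{ambiguous} with the full candidate list.
#'
#' @param peaks data.frame with columns \code{sample}, \code{precursor_mz},
#'   \code{product_mz}, \code{rt}, \code{area}.
#' @param standards standards data.frame (default \code{\link{ahlStandards}}).
#' @param mzTol m/z tolerance in Da (default 0.5, unit-resolution practice).
#' @param rtTol retention-time tolerance in minutes (default 0.2).
#' @return the peaks data.frame with added columns \code{verdict}
#'   (matched/unknown/ignored), \code{analyte}, \code{ambiguous},
#'   \code{candidates}.
#' @export
matchTransitions <- function(peaks, standards = ahlStandards(),
                             mzTol = 0.5, rtTol = 0.2) {
  if (mzTol < 0 || rtTol < 0) stop("tolerances must be non-negative")
  need <- c("sample", "precursor_mz", "product_mz", "rt", "area")
  if (!all(need %in% names(peaks)))
    stop("peaks need columns: ", paste(need, collapse = ", "))
  if (any(peaks$area < 0)) stop("peak areas must be non-negative")
  n <- nrow(peaks)
  verdict <- character(n); analyte <- rep(NA_character_, n)
  ambiguous <- logical(n); candidates <- rep("", n)
  frag <- hslFragmentMz()
  for (i in seq_len(n)) {
    if (abs(peaks$product_mz[i] - frag) > mzTol) {
      verdict[i] <- "ignored"; next
    }
    okMz <- abs(peaks$precursor_mz[i] - standards$mz) <= mzTol
    okRt <- is.na(standards$rt) | abs(peaks$rt[i] - standards$rt) <= rtTol
    cand <- which(okMz & okRt)
    if (!length(cand)) {
      verdict[i] <- "unknown"
      analyte[i] <- sprintf("putative unknown AHL (t_R %.1f)", peaks$rt[i])
      next
    }
    verdict[i] <- "matched"
    if (length(cand) > 1L) {
      ambiguous[i] <- TRUE
      candidates[i] <- paste(standards$name[cand], collapse = ";")
      dRt <- ifelse(is.na(standards$rt[cand]), Inf,
                    abs(peaks$rt[i] - standards$rt[cand]))
      dMz <- abs(peaks$precursor_mz[i] - standards$mz[cand])
      cand <- cand[order(dRt, dMz)]
    }
    analyte[i] <- standards$name[cand[1]]
  }
  cbind(peaks, data.frame(verdict = verdict, analyte = analyte,
                          ambiguous = ambiguous, candidates = candidates,
                          stringsAsFactors = FALSE))
}

#' Presence/absence matrix of matched analytes
#'
#' One row per analyte (all standards, plus any putative unknown AHLs), one
#' column per sample; cells are \code{"Detected"} or \code{"-"}. A companion
#' matrix of summed peak areas supports relative comparison only — the
#' underlying data carry no absolute quantification.
#'
#' @param matches output of \code{\link{matchTransitions}}.
#' @param standards standards table (defines the row order).
#' @return list with character matrix \code{presence} and numeric matrix
#'   \code{areas}.
#' @export
presenceMatrix <- function(matches, standards = ahlStandards()) {
  samples <- sort(unique(as.character(matches$sample)))
  if (!length(samples)) samples <- character(0)
  unknowns <- sort(unique(matches$analyte[matches$verdict == "unknown"]))
  rows <- c(standards$name, unknowns)
  presence <- matrix("-", nrow = length(rows), ncol = length(samples),
                     dimnames = list(rows, samples))
  areas <- matrix(0, nrow = length(rows), ncol = length(samples),
                  dimnames = list(rows, samples))
  hit <- matches[matches$verdict %in% c("matched", "unknown"), , drop = FALSE]
  for (i in seq_len(nrow(hit))) {
    r <- hit$analyte[i]; s <- as.character(hit$sample[i])
    presence[r, s] <- "Detected"
    areas[r, s] <- areas[r, s] + hit$area[i]
  }
  list(presence = presence, areas = areas)
}
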