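# Monoisotopic atomic masses (u) of the elements encountered in plant
# secondary metabolites measured by negative-mode ESI.
MONOISOTOPIC_MASS <- c(
  C = 12, H = 1.00782503, N = 14.00307401, O = 15.99491462, S = 31.97207117,
  P = 30.97376200, Na = 22.98976928, Cl = 34.96885268, K = 38.96370649
)

HYDROGEN_ATOM_MASS <- 1.00782503
PROTON_MASS <- 1.00727646

# Diagnostic neutral losses (Da) flagged during fragment interpretation.
NEUTRAL_LOSSES <- c(
  hexosyl = 162.0528, deoxyhexosyl = 146.0579, galloyl = 152.0110,
  sulfate = 79.9568, co2 = 43.9898, h2o = 18.0106
)

#' Parse an elemental formula string
#'
#' Accepts plain Hill-style formulas such as `"C15H10O5"`; underscores and
#' Unicode subscript digits around the counts (common in typeset tables)
#' are tolerated and stripped.
#'
#' @param text A single formula string.
#' @return Named integer vector of element counts, class
#'   `elemental_formula`.
#' @examples
#' parse_formula("C15H10O5")
#' parse_formula("C_21_H_20_O_14_S")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  clean <- gsub("_", "", text)
  clean <- chartr("₀₁₂₃₄₅₆₇₈₉",
                  "0123456789", clean)
  clean <- gsub("[[:space:]]", "", clean)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", clean)) {
    stop(sprintf("cannot parse formula '%s'", text), call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", clean)[[1]]
  tokens <- regmatches(clean, list(m))[[1]]
  elements <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(elements, names(MONOISOTOPIC_MASS))
  if (length(unknown)) {
    stop(sprintf("unknown element symbol(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  tab <- tapply(counts, factor(elements, levels = unique(elements)), sum)
  structure(as.integer(tab), names = names(tab), class = "elemental_formula")
}

#' Format an elemental formula in Hill order
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically;
#' unit counts are omitted. `format_formula(parse_formula(x)) == x` for
#' Hill-ordered input.
#'
#' @param formula An [parse_formula()] result or named count vector.
#' @return A single string.
#' @export
format_formula <- function(formula) {
  counts <- unclass(formula)
  els <- names(counts)
  others <- sort(setdiff(els, c("C", "H")))
  ord <- c(intersect(c("C", "H"), els), others)
  paste0(vapply(ord, function(e) {
    if (counts[[e]] == 1L) e else paste0(e, counts[[e]])
  }, character(1)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula>", format_formula(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a neutral formula
#'
#' @param formula A formula string or [parse_formula()] result.
#' @return Mass in u.
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  sum(MONOISOTOPIC_MASS[names(formula)] * as.numeric(formula))
}

#' Calculated m/z of the deprotonated \[M-H\]- adduct
#'
#' The default `h_atom` convention subtracts the hydrogen-atom mass from
#' the neutral monoisotopic mass, neglecting the electron; the stricter
#' `proton` convention subtracts the proton mass (leaving the electron with
#' the anion).
#'
#' @param formula A formula string or [parse_formula()] result; must
#'   contain hydrogen.
#' @param convention `"h_atom"` (default) or `"proton"`.
#' @return m/z in Th.
#' @examples
#' deprotonated_mz("C15H10O5")  # apigenin, 269.045
#' @export
deprotonated_mz <- function(formula, convention = c("h_atom", "proton")) {
  convention <- match.arg(convention)
  if (is.character(formula)) formula <- parse_formula(formula)
  if (!("H" %in% names(formula)) || formula[["H"]] < 1L) {
    stop("formula has no hydrogen to lose; [M-H]- is undefined",
         call. = FALSE)
  }
  monoisotopic_mass(formula) -
    switch(convention, h_atom = HYDROGEN_ATOM_MASS, proton = PROTON_MASS)
}

#' Relative mass error in parts per million
#'
#' @param observed,calculated m/z values in Th; `calculated > 0`.
#' @return `1e6 * (observed - calculated) / calculated`.
#' @export
ppm_error <- function(observed, calculated) {
  stopifnot(all(calculated > 0))
  1e6 * (observed - calculated) / calculated
}

#' Match a peak list against a compound library by ppm error
#'
#' Every library entry whose calculated \[M-H\]- m/z lies within
#' `tolerance_ppm` of a query peak is returned for that peak, ranked by
#' absolute ppm error. Peaks with no match are listed in the `unmatched`
#' attribute.
#'
#' @param peaks Numeric vector of query m/z values.
#' @param library A compound-library data frame (see
#'   [read_compound_library()]) with at least `name` and `formula` columns;
#'   a `calculated_mz` column is used if present, otherwise computed.
#' @param tolerance_ppm Match tolerance (> 0), default 5 ppm.
#' @param convention Adduct convention passed to [deprotonated_mz()].
#' @return Data frame of class `annotation_matches` with columns `peak_mz`,
#'   `name`, `formula`, `calculated_mz`, `ppm`; attribute `unmatched` holds
#'   the unmatched query m/z values.
#' @export
annotate_peaks <- function(peaks, library, tolerance_ppm = 5,
                           convention = "h_atom") {
  stopifnot(tolerance_ppm > 0)
  if (nrow(library) == 0L) stop("compound library is empty", call. = FALSE)
  calc <- if ("calculated_mz" %in% names(library)) {
    library$calculated_mz
  } else {
    vapply(library$formula, function(f) deprotonated_mz(f, convention),
           numeric(1))
  }
  rows <- lapply(peaks, function(mz) {
    ppm <- ppm_error(mz, calc)
    hit <- which(abs(ppm) <= tolerance_ppm)
    if (!length(hit)) return(NULL)
    hit <- hit[order(abs(ppm[hit]))]
    data.frame(peak_mz = mz, name = library$name[hit],
               formula = library$formula[hit],
               calculated_mz = calc[hit], ppm = ppm[hit])
  })
  matched <- !vapply(rows, is.null, logical(1))
  out <- if (any(matched)) do.call(rbind, rows[matched]) else {
    data.frame(peak_mz = numeric(), name = character(),
               formula = character(), calculated_mz = numeric(),
               ppm = numeric())
  }
  rownames(out) <- NULL
  structure(out, unmatched = peaks[!matched],
            class = c("annotation_matches", "data.frame"))
}

#' Flag diagnostic neutral losses among a precursor and its fragments
#'
#' Examines the pairwise mass differences between the precursor and every
#' fragment (and among fragments) and flags differences matching a built-in
#' table of common losses: hexosyl 162.0528, deoxyhexosyl 146.0579,
#' galloyl 152.0110, sulfate 79.9568, CO2 43.9898 and H2O 18.0106 Da. The
#' default window of +/-0.02 Da accommodates fragment lists printed at two
#' decimals.
#'
#' @param precursor_mz Precursor ion m/z.
#' @param fragments Numeric vector of fragment m/z values.
#' @param tolerance_da Absolute match window in Da.
#' @return Data frame with columns `from_mz`, `to_mz`, `delta_da`, `loss`.
#' @examples
#' neutral_loss_flags(567.2084, c(405.15, 387.14))
#' @export
neutral_loss_flags <- function(precursor_mz, fragments, tolerance_da = 0.02) {
  ions <- sort(unique(c(precursor_mz, fragments)), decreasing = TRUE)
  out <- data.frame(from_mz = numeric(), to_mz = numeric(),
                    delta_da = numeric(), loss = character())
  if (length(ions) < 2L) return(out)
  pairs <- utils::combn(ions, 2L)
  for (j in seq_len(ncol(pairs))) {
    delta <- pairs[1L, j] - pairs[2L, j]
    hit <- which(abs(NEUTRAL_LOSSES - delta) <= tolerance_da)
    for (h in hit) {
      out <- rbind(out, data.frame(
        from_mz = pairs[1L, j], to_mz = pairs[2L, j],
        delta_da = delta, loss = names(NEUTRAL_LOSSES)[h]))
    }
  }
  out
}

#' Recompute calculated m/z and self-consistency of a compound library
#'
#' Adds (or replaces) the `calculated_mz` column from each row's formula,
#' together with the ppm error of the observed m/z against it and any
#' neutral-loss flags between the observed precursor and its fragments.
#'
#' @param library Compound-library data frame.
#' @param convention Adduct convention for [deprotonated_mz()].
#' @return The library with columns `calculated_mz`, `ppm`, `loss_flags`
#'   (semicolon-joined loss names) appended.
#' @export
annotate_library <- function(library, convention = "h_atom") {
  calc <- vapply(library$formula, function(f) deprotonated_mz(f, convention),
                 numeric(1))
  library$calculated_mz <- unname(calc)
  library$ppm <- ppm_error(library$observed_mz, calc)
  library$loss_flags <- vapply(seq_len(nrow(library)), function(i) {
    fr <- parse_fragments(library$fragments[i])
    if (!length(fr)) return("")
    paste(unique(neutral_loss_flags(library$observed_mz[i], fr)$loss),
          collapse = ";")
  }, character(1))
  library
}

parse_fragments <- function(text) {
  if (is.na(text) || !nzchar(text)) return(numeric())
  as.numeric(strsplit(text, ";", fixed = TRUE)[[1]])
}
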