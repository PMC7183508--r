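# Elemental mass arithmetic, biotransformation delta table, ppm matching.

# Monoisotopic masses of the most abundant isotope (IUPAC 2021), Da.
.ELEMENT_MASS <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  S  = 31.9720711744,
  P  = 30.9737615120,
  Na = 22.9897692820,
  K  = 38.9637064864,
  Cl = 34.9688526800,
  F  = 18.9984031627,
  Br = 78.9183376000,
  I  = 126.9044719000,
  Si = 27.9769265347,
  B  = 11.0093053600,
  Li = 7.0160034366,
  Mg = 23.9850417000,
  Ca = 39.9625908600,
  Fe = 55.9349363300,
  Zn = 63.9291420100,
  Cu = 62.9295977200,
  Mn = 54.9380439100,
  Se = 79.9165218000,
  Co = 58.9331943000,
  Mo = 97.9054048200
)

# Mass of a proton (Da); used to deionize [M+H]+/[M-H]- observations.
PROTON_MASS <- 1.007276467
# Electron mass (Da); enters metal-adduct shifts.
ELECTRON_MASS <- 0.000548579909

# Mass offset of the 34S isotopologue relative to 32S (Da) and its
# natural relative abundance per sulfur atom.
MASS_OFFSET_34S <- 1.99580
ABUNDANCE_34S <- 0.0425

#' Parse a molecular formula in Hill notation
#'
#' Converts a formula string such as \code{"C6H8O6"} into a named integer
#' vector of element counts. Only IUPAC element symbols known to the
#' package's embedded monoisotopic mass table are accepted. The empty
#' string is a valid formula (the empty composition, mass 0).
#'
#' @param formula A single formula string, or an already-parsed named
#'   numeric vector of element counts (returned unchanged after
#'   validation).
#' @return Named integer vector of element counts.
#' @examples
#' parse_formula("C6H8O6")
#' parse_formula("SO3")
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    if (is.null(names(formula)) && length(formula) > 0L)
      stop("numeric formula must be a named vector of element counts")
    bad <- setdiff(names(formula), names(.ELEMENT_MASS))
    if (length(bad))
      stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
    if (any(formula < 0))
      stop("element counts must be non-negative")
    return(formula)
  }
  if (!is.character(formula) || length(formula) != 1L || is.na(formula))
    stop("formula must be a single character string")
  s <- gsub("[[:space:]]", "", formula)
  if (!nzchar(s)) return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  tokens <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (sum(nchar(tokens)) != nchar(s))
    stop("cannot parse formula: '", formula, "'")
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
  bad <- setdiff(sym, names(.ELEMENT_MASS))
  if (length(bad))
    stop("unknown element symbol(s): ", paste(unique(bad), collapse = ", "))
  out <- tapply(cnt, sym, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of count times most-abundant-isotope mass per element, using
#' IUPAC monoisotopic masses embedded in the package.
#'
#' @param formula Formula string in Hill notation or a named count vector
#'   (see [parse_formula()]).
#' @return Monoisotopic mass in Da. The empty formula has mass 0.
#' @examples
#' monoisotopic_mass("C6H8O6")   # glucuronic acid - H2O, 176.03209
#' monoisotopic_mass("SO3")      # sulfation delta, 79.95682
#' @export
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  if (length(counts) == 0L) return(0)
  sum(.ELEMENT_MASS[names(counts)] * counts)
}

#' Construct a biotransformation reaction delta
#'
#' A reaction delta names a biotransformation (e.g. glucuronidation),
#' the elemental formula gained (or lost), the monoisotopic mass shift
#' derived from that formula, and the retention-time-shift window
#' (minutes, computed as conjugate RT minus source RT) inside which an
#' edge is considered chromatographically plausible.
#'
#' @param name Reaction name.
#' @param formula Gained/lost elemental formula (Hill notation).
#' @param rt_window Numeric length-2, `c(min_shift, max_shift)` minutes.
#' @param direction `"gain"` (product is heavier) or `"loss"` (product is
#'   lighter, e.g. microbial deglycosylation).
#' @param reference_shift Optional expected RT shift (minutes) from a
#'   calibrant compound, used by [score_source_by_reference_shift()].
#' @param group Free-text grouping label (`"conjugation"` or `"other"`).
#' @return One-row data frame with class `reaction_table`.
#' @export
reaction_delta <- function(name, formula, rt_window, direction = "gain",
                           reference_shift = NA_real_, group = "conjugation") {
  stopifnot(is.character(name), length(name) == 1L,
            length(rt_window) == 2L, rt_window[1] <= rt_window[2],
            direction %in% c("gain", "loss"))
  dm <- monoisotopic_mass(formula)
  if (!(dm > 0)) stop("reaction '", name, "': delta mass must be positive")
  out <- data.frame(
    name = name,
    formula = if (is.character(formula)) formula else format_formula(formula),
    direction = direction,
    delta_mass = dm,
    rt_min = as.numeric(rt_window[1]),
    rt_max = as.numeric(rt_window[2]),
    reference_shift = as.numeric(reference_shift),
    group = group,
    stringsAsFactors = FALSE
  )
  class(out) <- c("reaction_table", "data.frame")
  out
}

# Hill-notation string from a named count vector.
format_formula <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) return("")
  ord <- if ("C" %in% names(counts)) {
    c("C", "H", sort(setdiff(names(counts), c("C", "H"))))
  } else sort(names(counts))
  ord <- intersect(ord, names(counts))
  paste0(ord, ifelse(counts[ord] > 1, counts[ord], ""), collapse = "")
}

#' Default biotransformation reaction table
#'
#' The five major phase-II conjugation reactions (glucuronic acid,
#' sulfate, glycine, glutamine, glutathione) plus a small "other known
#' reactions" group for deglycosylation edges: hexose gain/loss
#' (\eqn{\pm}C6H10O5) and glucuronide loss (\eqn{-}C6H8O6).
#'
#' RT windows follow reversed-phase behaviour: glucuronidation and
#' sulfation shorten retention, window \eqn{[-3, +0.2]} min; other
#' conjugations use \eqn{[-5, +5]} min. Reference shifts for
#' glucuronidation (\eqn{-1.9} min) and sulfation (\eqn{-1.4} min) come
#' from the 7-hydroxycoumarin calibrant pair and can be overridden.
#'
#' @param glutathione `"dehydro"` (default, +C10H15N3O6S, 305.06816 Da,
#'   the common net GSH-conjugation delta) or `"reduced"`
#'   (+C10H17N3O6S, 307.08381 Da).
#' @param reference_shifts Named numeric vector overriding per-reaction
#'   expected RT shifts, e.g. `c(sulfation = -1.4)`.
#' @return A `reaction_table` data frame (one row per reaction) with
#'   columns name, formula, direction, delta_mass, rt_min, rt_max,
#'   reference_shift, group.
#' @examples
#' default_reaction_table()
#' @export
default_reaction_table <- function(glutathione = c("dehydro", "reduced"),
                                   reference_shifts = NULL) {
  glutathione <- match.arg(glutathione)
  gsh <- if (glutathione == "dehydro") "C10H15N3O6S" else "C10H17N3O6S"
  tab <- rbind(
    reaction_delta("glucuronidation", "C6H8O6", c(-3, 0.2),
                   reference_shift = -1.9),
    reaction_delta("sulfation", "SO3", c(-3, 0.2), reference_shift = -1.4),
    reaction_delta("glycine_conjugation", "C2H3NO", c(-5, 5)),
    reaction_delta("glutamine_conjugation", "C5H8N2O2", c(-5, 5)),
    reaction_delta("glutathione_conjugation", gsh, c(-5, 5)),
    reaction_delta("hexose_gain", "C6H10O5", c(-5, 5), group = "other"),
    reaction_delta("hexose_loss", "C6H10O5", c(-5, 5), direction = "loss",
                   group = "other"),
    reaction_delta("glucuronide_loss", "C6H8O6", c(-5, 5), direction = "loss",
                   group = "other")
  )
  if (!is.null(reference_shifts)) {
    i <- match(names(reference_shifts), tab$name)
    if (anyNA(i)) stop("reference_shifts names unknown reaction(s): ",
                       paste(names(reference_shifts)[is.na(i)], collapse = ", "))
    tab$reference_shift[i] <- as.numeric(reference_shifts)
  }
  class(tab) <- c("reaction_table", "data.frame")
  tab
}

#' Read a reaction table from a plain-text config
#'
#' Accepts either a TSV/CSV with columns `name`, `formula`, and
#' optionally `direction`, `rt_min`, `rt_max`, `reference_shift`,
#' `group`; or a YAML file holding a list of records with the same
#' fields. `delta_mass` is always recomputed from the formula.
#'
#' @param path File path (`.yml`/`.yaml` selects the YAML reader).
#' @return A `reaction_table` data frame.
#' @export
read_reaction_table <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    recs <- yaml::read_yaml(path)
    df <- do.call(rbind, lapply(recs, function(r) {
      data.frame(name = r$name, formula = r$formula,
                 direction = r$direction %||% "gain",
                 rt_min = as.numeric(r$rt_min %||% -5),
                 rt_max = as.numeric(r$rt_max %||% 5),
                 reference_shift = as.numeric(r$reference_shift %||% NA),
                 group = r$group %||% "conjugation",
                 stringsAsFactors = FALSE)
    }))
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    for (col in c("name", "formula"))
      if (!col %in% names(df))
        stop("reaction table missing required column '", col, "'")
    if (!"direction" %in% names(df)) df$direction <- "gain"
    if (!"rt_min" %in% names(df)) df$rt_min <- -5
    if (!"rt_max" %in% names(df)) df$rt_max <- 5
    if (!"reference_shift" %in% names(df)) df$reference_shift <- NA_real_
    if (!"group" %in% names(df)) df$group <- "conjugation"
  }
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    reaction_delta(df$name[i], df$formula[i], c(df$rt_min[i], df$rt_max[i]),
                   direction = df$direction[i],
                   reference_shift = df$reference_shift[i],
                   group = df$group[i])
  }))
  class(out) <- c("reaction_table", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Match a neutral-mass difference against a reaction delta
#'
#' Tests whether the difference between two neutral monoisotopic masses
#' equals a biotransformation delta within a ppm tolerance. The residual
#' of the difference is normalized by the heavier mass (matching how MS
#' accuracy scales), so the test is symmetric in argument order.
#'
#' @param mass_a,mass_b Neutral monoisotopic masses (Da), both positive.
#'   May be vectors of equal length.
#' @param delta A `reaction_table` row, or a numeric delta mass (Da).
#' @param ppm Tolerance in parts per million (default 5).
#' @return Logical vector: TRUE where the pair matches the delta.
#' @examples
#' match_mass_difference(256.07356, 432.10565, 176.03209)  # glucuronidation
#' @export
match_mass_difference <- function(mass_a, mass_b, delta, ppm = 5) {
  if (is.data.frame(delta)) delta <- delta$delta_mass
  stopifnot(is.numeric(delta), length(delta) == 1L, ppm > 0)
  if (any(mass_a <= 0) || any(mass_b <= 0))
    stop("masses must be positive")
  hi <- pmax(mass_a, mass_b)
  lo <- pmin(mass_a, mass_b)
  abs((hi - lo) - delta) / hi * 1e6 <= ppm
}

# Signed ppm residual of an observed difference against a delta,
# normalized by the heavier mass.
ppm_residual <- function(lo_mass, hi_mass, delta) {
  ((hi_mass - lo_mass) - delta) / hi_mass * 1e6
}
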