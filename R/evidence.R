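# Orthogonal spectral evidence: 34S isotopologue detection, diagnostic
# neutral losses in MS/MS, and the MSI-level rubric combining evidence.

#' Default diagnostic neutral-loss table
#'
#' Losses diagnostic of phase-II conjugates: SO3 (79.95682 Da, the
#' classic "NL-80" of sulfates), dehydrated glucuronic acid (C6H8O6,
#' 176.03209 Da, "NL-176") and anhydrohexose (C6H10O5, 162.05282 Da).
#'
#' @return Data frame with columns `name`, `loss` (Da).
#' @export
default_neutral_losses <- function() {
  data.frame(name = c("NL-80", "NL-176", "NL-162"),
             loss = c(monoisotopic_mass("SO3"),
                      monoisotopic_mass("C6H8O6"),
                      monoisotopic_mass("C6H10O5")),
             stringsAsFactors = FALSE)
}

#' Detect the 34S isotopologue in an isotope pattern
#'
#' Sulfur-containing metabolites (e.g. sulfate conjugates) show a
#' natural-abundance isotopologue +1.99580 Da above the monoisotopic
#' peak at about 4.25\% relative intensity per sulfur atom. The narrow
#' offset tolerance (default 0.01 Da) separates 34S from the 13C2
#' isotopologue at +2.00671 Da. A hit requires the per-sulfur relative
#' intensity (observed ratio divided by the implied sulfur count) to
#' fall inside `ratio_band`.
#'
#' An empty pattern yields `has_34S = FALSE` with `note = "no pattern"`:
#' absence of data is not counter-evidence.
#'
#' @param pattern Data frame with columns `offset_mz`,
#'   `relative_intensity`, or NULL.
#' @param offset_tol Offset tolerance, Da (default 0.01).
#' @param ratio_band Accepted per-sulfur relative-intensity range
#'   (default `c(0.02, 0.08)` around the natural 4.25\%).
#' @return List: `has_34S`, `observed_offset`, `observed_ratio`,
#'   `estimated_sulfur_count`, `note`.
#' @examples
#' detect_34S(data.frame(offset_mz = 1.9957, relative_intensity = 0.043))
#' @export
detect_34S <- function(pattern, offset_tol = 0.01,
                       ratio_band = c(0.02, 0.08)) {
  none <- list(has_34S = FALSE, observed_offset = NA_real_,
               observed_ratio = NA_real_, estimated_sulfur_count = 0L,
               note = "")
  if (is.null(pattern) || nrow(pattern) == 0L) {
    none$note <- "no pattern"
    return(none)
  }
  d <- abs(pattern$offset_mz - MASS_OFFSET_34S)
  cand <- which(d <= offset_tol)
  if (!length(cand)) return(none)
  k <- cand[which.min(d[cand])]
  ratio <- pattern$relative_intensity[k]
  n_s <- max(1L, as.integer(round(ratio / ABUNDANCE_34S)))
  per_s <- ratio / n_s
  if (per_s < ratio_band[1] || per_s > ratio_band[2]) {
    none$observed_offset <- pattern$offset_mz[k]
    none$observed_ratio <- ratio
    none$note <- "offset matched but intensity outside band"
    return(none)
  }
  list(has_34S = TRUE, observed_offset = pattern$offset_mz[k],
       observed_ratio = ratio, estimated_sulfur_count = n_s, note = "")
}

#' Detect diagnostic neutral losses in an MS/MS spectrum
#'
#' A loss is matched when some fragment satisfies
#' `|precursor_mz - fragment_mz - loss| <= frag_tol`. The default
#' tolerance (0.5 Da) suits ion-trap fragment spectra; use 0.01 Da for
#' high-resolution MS/MS.
#'
#' @param spectrum List with `precursor_mz` and `fragments`
#'   (data frame `mz`, `intensity`), e.g. one element of [read_mgf()].
#' @param losses Loss table (default [default_neutral_losses()]).
#' @param frag_tol Fragment tolerance, Da (default 0.5).
#' @return Data frame of matched losses: `name`, `expected`, `observed`,
#'   `fragment_mz` (0 rows when nothing matches or the spectrum is
#'   empty).
#' @examples
#' sp <- list(precursor_mz = 335.02310,
#'            fragments = data.frame(mz = 255.06628, intensity = 100))
#' detect_neutral_loss(sp, frag_tol = 0.01)
#' @export
detect_neutral_loss <- function(spectrum, losses = default_neutral_losses(),
                                frag_tol = 0.5) {
  empty <- data.frame(name = character(), expected = numeric(),
                      observed = numeric(), fragment_mz = numeric(),
                      stringsAsFactors = FALSE)
  if (is.null(spectrum) || is.null(spectrum$fragments) ||
      nrow(spectrum$fragments) == 0L)
    return(empty)
  frag <- spectrum$fragments
  if (any(frag$mz >= spectrum$precursor_mz + 0.5))
    stop("fragment m/z above precursor m/z + 0.5")
  out <- lapply(seq_len(nrow(losses)), function(r) {
    obs <- spectrum$precursor_mz - frag$mz
    hit <- which(abs(obs - losses$loss[r]) <= frag_tol)
    if (!length(hit)) return(NULL)
    k <- hit[which.min(abs(obs[hit] - losses$loss[r]))]
    data.frame(name = losses$name[r], expected = losses$loss[r],
               observed = obs[k], fragment_mz = frag$mz[k],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) empty else out
}

MSI_LEVELS <- c("1", "2", "3", "4", "unknown")

#' Assign an MSI identification-confidence level
#'
#' Explicit rubric over the Metabolomics Standards Initiative levels:
#' \itemize{
#'   \item level 1 - matched to an authentic standard by accurate mass
#'     and RT;
#'   \item level 2 - a conjugate in the network with a preferred source
#'     and at least one orthogonal line of evidence (34S isotopologue,
#'     diagnostic neutral loss, or RT-shift agreement with the
#'     calibrant);
#'   \item level 3 - a database/literature annotation exists;
#'   \item level 4 - an elemental formula is assigned;
#'   \item unknown otherwise.
#' }
#' Adding evidence can only improve (never worsen) the level, and
#' missing spectra or isotope data never downgrade a node below what
#' the network alone supports.
#'
#' @param has_standard_match Standard matched on mass (<= ppm tol) and
#'   RT (<= rt tol).
#' @param has_preferred_edge Node is the target of a within-window edge
#'   whose source is marked preferred.
#' @param has_34S,has_neutral_loss Orthogonal spectral evidence flags.
#' @param shift_agreement Observed RT shift agrees with the calibrant
#'   reference within the configured tolerance.
#' @param has_annotation A user database/literature annotation exists.
#' @param has_formula An elemental formula is assigned.
#' @return List: `level` (one of "1","2","3","4","unknown") and
#'   `rationale` (character vector of the evidence that fired).
#' @export
assign_msi_level <- function(has_standard_match = FALSE,
                             has_preferred_edge = FALSE,
                             has_34S = FALSE,
                             has_neutral_loss = FALSE,
                             shift_agreement = FALSE,
                             has_annotation = FALSE,
                             has_formula = FALSE) {
  rationale <- character()
  if (has_standard_match)
    return(list(level = "1",
                rationale = "authentic standard: accurate mass + RT"))
  orth <- c(if (has_34S) "34S isotopologue",
            if (has_neutral_loss) "diagnostic neutral loss",
            if (shift_agreement) "calibrant RT-shift agreement")
  if (has_preferred_edge && length(orth))
    return(list(level = "2",
                rationale = c("network edge with preferred source", orth)))
  if (has_annotation)
    return(list(level = "3", rationale = "database/literature annotation"))
  if (has_formula)
    return(list(level = "4", rationale = "elemental formula only"))
  list(level = "unknown", rationale = character())
}

#' Annotate a network with spectral evidence and MSI levels
#'
#' Attaches per-node 34S and neutral-loss evidence (looked up by member
#' peak id in the MGF spectra and isotope patterns), matches nodes to
#' authentic standards (mass and RT) and to database annotations (mass
#' only), and assigns MSI levels with [assign_msi_level()]. Edge
#' `evidence` strings collect the flags supporting each conjugation
#' edge.
#'
#' @param network A `conjugation_network` with scored edges.
#' @param standards Optional [annotation_table()] of authentic standards
#'   (rows with a reference `rt`).
#' @param annotations Optional [annotation_table()] of database or
#'   literature annotations (RT not required).
#' @param msms Optional named list of spectra from [read_mgf()], keyed
#'   by peak id.
#' @param isotopes Optional named list from [read_isotope_patterns()].
#' @param ppm Mass tolerance for standard/annotation matching
#'   (default 5).
#' @param rt_tol RT tolerance for standard matching, minutes
#'   (default 0.2).
#' @param shift_tol RT-shift agreement tolerance vs the calibrant
#'   reference, minutes (default 0.5).
#' @param frag_tol Fragment tolerance for neutral losses, Da
#'   (default 0.5).
#' @return The network with node columns `label`, `has_34S`,
#'   `neutral_losses`, `msi_level`, `msi_rationale` and updated edge
#'   `evidence`.
#' @export
annotate_network <- function(network, standards = NULL, annotations = NULL,
                             msms = NULL, isotopes = NULL, ppm = 5,
                             rt_tol = 0.2, shift_tol = 0.5, frag_tol = 0.5) {
  nd <- network$nodes
  ed <- network$edges
  member_list <- strsplit(if ("members" %in% names(nd)) nd$members else
    nd$node_id, "/", fixed = TRUE)

  iso_ev <- lapply(member_list, function(m) {
    pats <- isotopes[intersect(m, names(isotopes))]
    hits <- lapply(pats, detect_34S)
    hit <- Filter(function(h) h$has_34S, hits)
    if (length(hit)) hit[[1]] else detect_34S(NULL)
  })
  nd$has_34S <- vapply(iso_ev, `[[`, logical(1), "has_34S")
  nd$sulfur_count <- vapply(iso_ev, `[[`, integer(1),
                            "estimated_sulfur_count")

  nl_ev <- lapply(member_list, function(m) {
    sps <- msms[intersect(m, names(msms))]
    hits <- do.call(rbind, lapply(sps, detect_neutral_loss,
                                  frag_tol = frag_tol))
    if (is.null(hits)) character() else unique(hits$name)
  })
  nd$neutral_losses <- vapply(nl_ev, paste, "", collapse = ",")

  match_by_mass <- function(tab, mass, rt = NULL) {
    if (is.null(tab) || nrow(tab) == 0L) return(NA_integer_)
    ok <- abs(tab$neutral_mass - mass) / mass * 1e6 <= ppm
    if (!is.null(rt)) ok <- ok & !is.na(tab$rt) & abs(tab$rt - rt) <= rt_tol
    if (!any(ok)) return(NA_integer_)
    idx <- which(ok)
    # nearest mass; isobaric ties (e.g. ephedrine/pseudoephedrine) break
    # by RT proximity when a reference RT is in play
    ord <- order(abs(tab$neutral_mass[idx] - mass),
                 if (is.null(rt)) rep(0, length(idx)) else
                   abs(tab$rt[idx] - rt))
    idx[ord[1]]
  }

  has_pref <- nd$node_id %in% ed$target[nrow(ed) > 0 & ed$preferred &
                                          !is.na(ed$within_window) &
                                          ed$within_window]
  shift_ok <- nd$node_id %in% ed$target[nrow(ed) > 0 & ed$preferred &
                                          !is.na(ed$shift_score) &
                                          ed$shift_score <= shift_tol]

  nd$label <- if ("label" %in% names(nd)) nd$label else NA_character_
  nd$msi_level <- NA_character_
  nd$msi_rationale <- NA_character_
  for (i in seq_len(nrow(nd))) {
    std <- match_by_mass(standards, nd$neutral_mass[i], nd$rt[i])
    ann <- match_by_mass(annotations, nd$neutral_mass[i])
    res <- assign_msi_level(
      has_standard_match = !is.na(std),
      has_preferred_edge = has_pref[i],
      has_34S = nd$has_34S[i],
      has_neutral_loss = nzchar(nd$neutral_losses[i]),
      shift_agreement = shift_ok[i],
      has_annotation = !is.na(ann),
      has_formula = !is.na(ann) ||
        ("formula" %in% names(nd) && !is.na(nd$formula[i]))
    )
    nd$msi_level[i] <- res$level
    nd$msi_rationale[i] <- paste(res$rationale, collapse = "; ")
    if (!is.na(std) && is.na(nd$label[i])) nd$label[i] <- standards$name[std]
    if (is.na(nd$label[i]) && !is.na(ann)) nd$label[i] <- annotations$name[ann]
  }

  if (nrow(ed)) {
    tgt <- match(ed$target, nd$node_id)
    ed$evidence <- vapply(seq_len(nrow(ed)), function(k) {
      i <- tgt[k]
      paste(c(if (nd$has_34S[i]) "iso34S",
              if (nzchar(nd$neutral_losses[i]))
                strsplit(nd$neutral_losses[i], ",")[[1]],
              if (!is.na(ed$shift_score[k]) && ed$shift_score[k] <= shift_tol)
                "shift_agreement",
              if (!is.na(nd$msi_level[i]) && nd$msi_level[i] == "1")
                "standard_confirmed"),
            collapse = ",")
    }, "")
  }
  network$nodes <- nd
  network$edges <- ed
  network
}
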