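# Deterministic synthetic-experiment generator: a complete maoto-like
# study (multi-subject pre/post time series, mock blanks, extract and
# per-herb rat plasma) with a planted ground-truth conjugation network,
# MS/MS spectra and isotopologue patterns.

#' Specification for a synthetic experiment
#'
#' All randomness flows from `seed` through one generator stream, so a
#' fixed seed yields byte-identical output files. Mass jitter is
#' Gaussian in ppm, clipped at two standard deviations (mass error of a
#' calibrated high-resolution instrument is bounded, and errors within
#' one run are strongly correlated, so a conjugate's jitter is applied
#' relative to its observed source mass). RT jitter is applied to the
#' planted conjugate shifts, likewise clipped.
#'
#' @param seed Integer RNG seed.
#' @param n_subjects Number of subjects (default 4, as in a small
#'   crossover-style PK study).
#' @param timepoints Post-dose sampling times in hours
#'   (default 0.25, 0.5, 1, 2, 4, 8; a pre-dose sample is always
#'   included per subject).
#' @param compounds Compound table (see [default_compound_table()]):
#'   source metabolites and conjugates with planted RT shifts and
#'   kinetic profiles.
#' @param extra_edges Additional planted relations between existing
#'   compounds (data frame `source`, `target`, `reaction`), e.g.
#'   microbial deglycosylation of a glycoside to an aglycone that is
#'   itself listed as a source.
#' @param mass_noise_ppm Mass jitter sd in ppm (default 2, clipped at
#'   2 sd).
#' @param rt_jitter_sd RT-shift jitter sd in minutes (default 0.1,
#'   clipped at 2 sd).
#' @param decoys Named integer vector: `background` (present in
#'   pre/post/mock), `pre_only`, `singleton` (one sample only),
#'   `candidate` (pass all filters; masses rejection-sampled away from
#'   all reaction deltas), `low_intensity` (pass all but the ion-count
#'   rule).
#' @param n_mock Number of solvent-blank samples (default 2).
#' @param include_extract,include_herbs Include the extract sample and
#'   the four per-herb rat plasma samples.
#' @param detection_limit Intensities below this are recorded as not
#'   detected (default 500 counts).
#' @param subject_sd Log-scale between-subject amplitude sd
#'   (default 0.3, clipped at 2 sd).
#' @param measurement_sd Log-scale per-cell intensity jitter
#'   (default 0.05, clipped at 2 sd).
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1,
                         n_subjects = 4,
                         timepoints = c(0.25, 0.5, 1, 2, 4, 8),
                         compounds = default_compound_table(),
                         extra_edges = default_extra_edges(),
                         mass_noise_ppm = 2,
                         rt_jitter_sd = 0.1,
                         decoys = c(background = 12, pre_only = 5,
                                    singleton = 3, candidate = 10,
                                    low_intensity = 2),
                         n_mock = 2,
                         include_extract = TRUE,
                         include_herbs = TRUE,
                         detection_limit = 500,
                         subject_sd = 0.3,
                         measurement_sd = 0.05) {
  stopifnot(n_subjects >= 1, length(timepoints) >= 1, all(timepoints > 0))
  compounds <- validate_compound_table(compounds)
  if (nrow(extra_edges)) {
    bad <- setdiff(c(extra_edges$source, extra_edges$target), compounds$name)
    if (length(bad))
      stop("extra_edges reference unknown compound(s): ",
           paste(bad, collapse = ", "))
  }
  dk <- c(background = 0, pre_only = 0, singleton = 0, candidate = 0,
          low_intensity = 0)
  dk[names(decoys)] <- decoys
  structure(list(seed = as.integer(seed), n_subjects = n_subjects,
                 timepoints = sort(timepoints), compounds = compounds,
                 extra_edges = extra_edges,
                 mass_noise_ppm = mass_noise_ppm,
                 rt_jitter_sd = rt_jitter_sd, decoys = dk, n_mock = n_mock,
                 include_extract = include_extract,
                 include_herbs = include_herbs,
                 detection_limit = detection_limit,
                 subject_sd = subject_sd, measurement_sd = measurement_sd),
            class = "fixture_spec")
}

#' Default synthetic compound table
#'
#' Ten source metabolites of the four maoto herbs (ephedra alkaloids,
#' apricot prunasin, cinnamon phenylpropanoids, licorice flavonoids and
#' glycyrrhetinic acid) and ten phase-II conjugates with
#' reversed-phase-plausible planted RT shifts (glucuronides about
#' -1.7/-1.9 min, sulfates about -1.3/-1.4 min, glycine conjugation
#' -0.5 min). Kinetic peak times emulate the study's phenomenology:
#' ephedrine analogues absorb early (~0.5 h); licorice aglycones and
#' their conjugates, formed after microbial deglycosylation, peak late
#' (4-8 h). Ephedrine and pseudoephedrine are isobaric near co-eluters
#' and form the canonical never-merge exception pair.
#'
#' @return Data frame with columns `name`, `formula`, `herb`, `rt`,
#'   `parent`, `reaction`, `shift`, `tmax`, `width`, `amplitude`,
#'   `in_extract`, `dual_mode`.
#' @export
default_compound_table <- function() {
  src <- function(name, formula, herb, rt, tmax, amp, in_extract = TRUE)
    data.frame(name = name, formula = formula, herb = herb, rt = rt,
               parent = NA_character_, reaction = NA_character_,
               shift = NA_real_, tmax = tmax, width = 1.2, amplitude = amp,
               in_extract = in_extract, dual_mode = FALSE,
               stringsAsFactors = FALSE)
  cj <- function(name, parent, reaction, shift, tmax, amp,
                 dual_mode = FALSE)
    data.frame(name = name, formula = NA_character_, herb = NA_character_,
               rt = NA_real_, parent = parent, reaction = reaction,
               shift = shift, tmax = tmax, width = 1.2, amplitude = amp,
               in_extract = FALSE, dual_mode = dual_mode,
               stringsAsFactors = FALSE)
  rbind(
    src("ephedrine", "C10H15NO", "ephedra", 2.10, 0.5, 2e5),
    src("pseudoephedrine", "C10H15NO", "ephedra", 2.25, 0.5, 1.5e5),
    src("prunasin", "C14H17NO6", "apricot", 4.60, 1, 8e4),
    src("7-hydroxycoumarin", "C9H6O3", "cinnamon", 6.80, 1, 6e4),
    src("cinnamic_acid", "C9H8O2", "cinnamon", 7.60, 0.5, 9e4),
    src("liquiritin", "C21H22O9", "licorice", 8.20, 1, 7e4),
    src("liquiritigenin", "C15H12O4", "licorice", 9.00, 6, 6e4,
        in_extract = FALSE),
    src("isoliquiritigenin", "C15H12O4", "licorice", 10.50, 6, 5e4,
        in_extract = FALSE),
    src("eugenol", "C10H12O2", "cinnamon", 11.20, 1, 5e4),
    src("glycyrrhetinic_acid", "C30H46O4", "licorice", 13.50, 8, 1.2e5),
    cj("liquiritigenin_sulfate", "liquiritigenin", "sulfation", -1.3, 6, 9e4),
    cj("liquiritigenin_glucuronide", "liquiritigenin", "glucuronidation",
       -1.7, 6, 1.1e5, dual_mode = TRUE),
    cj("isoliquiritigenin_glucuronide", "isoliquiritigenin",
       "glucuronidation", -1.7, 6, 8e4),
    cj("liquiritigenin_glucuronide_sulfate", "liquiritigenin_glucuronide",
       "sulfation", -1.3, 8, 5e4),
    cj("glycyrrhetinic_acid_sulfate", "glycyrrhetinic_acid", "sulfation",
       -1.4, 8, 7e4),
    cj("7-hydroxycoumarin_sulfate", "7-hydroxycoumarin", "sulfation",
       -1.4, 1, 8e4),
    cj("7-hydroxycoumarin_glucuronide", "7-hydroxycoumarin",
       "glucuronidation", -1.9, 1, 7e4),
    cj("eugenol_sulfate", "eugenol", "sulfation", -1.4, 1, 9e4),
    cj("eugenol_glucuronide", "eugenol", "glucuronidation", -1.9, 1, 8e4),
    cj("hippuric_acid", "cinnamic_acid", "glycine_conjugation", -0.5, 1, 2e5)
  )
}

#' @rdname fixture_spec
#' @export
default_extra_edges <- function() {
  data.frame(source = "liquiritin", target = "liquiritigenin",
             reaction = "hexose_loss", stringsAsFactors = FALSE)
}

#' Licorice subnetwork preset
#'
#' Eight licorice metabolites reproducing the canonical glycoside /
#' aglycone / conjugate subnetwork: liquiritin and isoliquiritin
#' (418.12638 Da), their aglycones liquiritigenin (LG) and
#' isoliquiritigenin (ILG, both 256.07356 Da), LG sulfate
#' (336.03038 Da), LG and ILG glucuronides (432.10565 Da) and the
#' doubly conjugated LG glucuronide sulfate (512.06247 Da). Planted RTs
#' put ILG 1.5 min after LG, so the conjugate shifts measured from LG
#' are -1.3 (sulfate) and -1.7 (glucuronide) min while the same
#' conjugates sit -2.8 and -3.2 min from ILG - only the LG assignment
#' survives the glucuronidation/sulfation RT window and the calibrant
#' scoring. Noise-free (`mass_noise_ppm = 0`, `rt_jitter_sd = 0`),
#' decoy-free.
#'
#' @param seed RNG seed (affects only intensity jitter).
#' @return A [fixture_spec()].
#' @export
subnetwork_a_spec <- function(seed = 1) {
  src <- function(name, formula, rt, tmax, amp, in_extract = TRUE)
    data.frame(name = name, formula = formula, herb = "licorice", rt = rt,
               parent = NA_character_, reaction = NA_character_,
               shift = NA_real_, tmax = tmax, width = 1.2, amplitude = amp,
               in_extract = in_extract, dual_mode = FALSE,
               stringsAsFactors = FALSE)
  cj <- function(name, parent, reaction, shift, tmax, amp, dual = FALSE)
    data.frame(name = name, formula = NA_character_, herb = NA_character_,
               rt = NA_real_, parent = parent, reaction = reaction,
               shift = shift, tmax = tmax, width = 1.2, amplitude = amp,
               in_extract = FALSE, dual_mode = dual,
               stringsAsFactors = FALSE)
  compounds <- rbind(
    src("liquiritin", "C21H22O9", 8.20, 1, 7e4),
    src("isoliquiritin", "C21H22O9", 9.60, 1, 6e4),
    src("liquiritigenin", "C15H12O4", 9.00, 6, 6e4, in_extract = FALSE),
    src("isoliquiritigenin", "C15H12O4", 10.50, 6, 5e4, in_extract = FALSE),
    cj("liquiritigenin_sulfate", "liquiritigenin", "sulfation", -1.3, 6, 9e4),
    cj("liquiritigenin_glucuronide", "liquiritigenin", "glucuronidation",
       -1.7, 6, 1.1e5, dual = TRUE),
    cj("isoliquiritigenin_glucuronide", "isoliquiritigenin",
       "glucuronidation", -1.7, 6, 8e4),
    cj("liquiritigenin_glucuronide_sulfate", "liquiritigenin_glucuronide",
       "sulfation", -1.3, 8, 5e4)
  )
  extra <- data.frame(
    source = c("liquiritin", "isoliquiritin"),
    target = c("liquiritigenin", "isoliquiritigenin"),
    reaction = "hexose_loss", stringsAsFactors = FALSE)
  fixture_spec(seed = seed, compounds = compounds, extra_edges = extra,
               mass_noise_ppm = 0, rt_jitter_sd = 0,
               decoys = c(background = 0, pre_only = 0, singleton = 0,
                          candidate = 0, low_intensity = 0))
}

# Resolve conjugate formulas/masses/RTs from their parents; validate.
validate_compound_table <- function(cmp) {
  req <- c("name", "formula", "herb", "rt", "parent", "reaction", "shift",
           "tmax", "width", "amplitude", "in_extract", "dual_mode")
  miss <- setdiff(req, names(cmp))
  if (length(miss))
    stop("compound table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cmp$name)) stop("duplicated compound name")
  is_conj <- !is.na(cmp$parent)
  bad <- is_conj & !(cmp$parent %in% cmp$name)
  if (any(bad))
    stop("conjugate without source: ",
         paste(cmp$name[bad], collapse = ", "))
  cmp
}

clipped_norm <- function(n, sd) {
  if (sd == 0) return(rep(0, n))
  pmin(pmax(stats::rnorm(n), -2), 2) * sd
}

#' Generate a complete synthetic experiment
#'
#' Emits an aligned feature table, sample design, MS/MS spectra
#' (sulfates carry an NL-80 fragment, glucuronides NL-176),
#' isotopologue patterns (sulfates get a 34S isotopologue at ~4.25\%,
#' everything gets a 13C peak), an authentic-standards table for the
#' source compounds, and the planted ground truth (compounds, edges,
#' maoto-derived peak ids). All outputs are reproducible from the seed.
#'
#' @param spec A [fixture_spec()].
#' @return List of class `dacmet_fixture` with elements `table`,
#'   `design`, `msms`, `isotopes`, `standards`, `truth`, `exceptions`
#'   (recommended never-merge pairs), `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)

  cmp <- spec$compounds
  reactions <- default_reaction_table()
  n_c <- nrow(cmp)

  # resolve formulas / true masses / RTs parent-first
  cmp$true_mass <- NA_real_
  for (pass in 1:5) {
    for (i in seq_len(n_c)) {
      if (!is.na(cmp$true_mass[i])) next
      if (is.na(cmp$parent[i])) {
        cmp$true_mass[i] <- monoisotopic_mass(cmp$formula[i])
      } else {
        p <- match(cmp$parent[i], cmp$name)
        if (is.na(cmp$true_mass[p])) next
        r <- match(cmp$reaction[i], reactions$name)
        if (is.na(r)) stop("unknown reaction '", cmp$reaction[i], "'")
        sgn <- if (reactions$direction[r] == "gain") 1 else -1
        cmp$true_mass[i] <- cmp$true_mass[p] + sgn * reactions$delta_mass[r]
        pf <- parse_formula(cmp$formula[p])
        gf <- parse_formula(reactions$formula[r])
        all_el <- union(names(pf), names(gf))
        counts <- stats::setNames(rep(0L, length(all_el)), all_el)
        counts[names(pf)] <- counts[names(pf)] + pf
        counts[names(gf)] <- counts[names(gf)] + sgn * gf
        if (any(counts < 0)) stop("loss reaction removes absent atoms for ",
                                  cmp$name[i])
        cmp$formula[i] <- format_formula(counts)
        cmp$herb[i] <- cmp$herb[p]
        cmp$rt[i] <- cmp$rt[p] + cmp$shift[i]
      }
    }
  }
  if (anyNA(cmp$true_mass)) stop("unresolvable parent chain in compounds")

  # observed masses: sources jittered vs truth, conjugates vs observed parent
  cmp$obs_mass <- NA_real_
  noise <- clipped_norm(n_c, spec$mass_noise_ppm)
  for (pass in 1:5) {
    for (i in seq_len(n_c)) {
      if (!is.na(cmp$obs_mass[i])) next
      if (is.na(cmp$parent[i])) {
        cmp$obs_mass[i] <- cmp$true_mass[i] * (1 + noise[i] * 1e-6)
      } else {
        p <- match(cmp$parent[i], cmp$name)
        if (is.na(cmp$obs_mass[p])) next
        r <- match(cmp$reaction[i], reactions$name)
        sgn <- if (reactions$direction[r] == "gain") 1 else -1
        base <- cmp$obs_mass[p] + sgn * reactions$delta_mass[r]
        cmp$obs_mass[i] <- base + cmp$true_mass[i] * noise[i] * 1e-6
      }
    }
  }
  # observed RT: jitter the planted shift
  rtj <- clipped_norm(n_c, spec$rt_jitter_sd)
  cmp$obs_rt <- cmp$rt + ifelse(is.na(cmp$parent), 0, rtj)

  # decoy masses: rejection-sampled so no pairwise difference with any
  # planted or accepted mass matches a reaction delta (25 ppm guard),
  # and no direct mass coincidence (would merge).
  n_d <- sum(spec$decoys)
  taken <- cmp$true_mass
  decoy_mass <- numeric(0)
  guard_ok <- function(m, pool) {
    if (!length(pool)) return(TRUE)
    if (any(abs(m - pool) / m * 1e6 <= 25)) return(FALSE)
    d <- abs(pool - m)
    hi <- pmax(pool, m)
    for (delta in reactions$delta_mass)
      if (any(abs(d - delta) / hi * 1e6 <= 25)) return(FALSE)
    TRUE
  }
  while (length(decoy_mass) < n_d) {
    m <- stats::runif(1, 150, 600)
    if (guard_ok(m, taken)) {
      decoy_mass <- c(decoy_mass, m)
      taken <- c(taken, m)
    }
  }
  decoy_kind <- rep(names(spec$decoys), spec$decoys)
  decoy_rt <- stats::runif(n_d, 1, 14)

  # ---- samples -----------------------------------------------------------
  subjects <- sprintf("S%d", seq_len(spec$n_subjects))
  des <- do.call(rbind, lapply(subjects, function(s) {
    rbind(data.frame(sample_id = paste0(s, "_pre"), subject = s,
                     class = "pre", timepoint = NA_real_,
                     herb = NA_character_, stringsAsFactors = FALSE),
          data.frame(sample_id = paste0(s, "_t", spec$timepoints),
                     subject = s, class = "post",
                     timepoint = spec$timepoints, herb = NA_character_,
                     stringsAsFactors = FALSE))
  }))
  if (spec$n_mock > 0)
    des <- rbind(des, data.frame(
      sample_id = sprintf("MOCK%d", seq_len(spec$n_mock)), subject = "mock",
      class = "mock", timepoint = NA_real_, herb = NA_character_,
      stringsAsFactors = FALSE))
  if (spec$include_extract)
    des <- rbind(des, data.frame(sample_id = "EXTRACT1", subject = "extract",
                                 class = "extract", timepoint = NA_real_,
                                 herb = NA_character_,
                                 stringsAsFactors = FALSE))
  if (spec$include_herbs)
    des <- rbind(des, data.frame(sample_id = paste0("RAT_", HERBS),
                                 subject = paste0("rat_", HERBS),
                                 class = "herb_plasma",
                                 timepoint = NA_real_, herb = HERBS,
                                 stringsAsFactors = FALSE))
  design <- sample_design(des)

  # ---- peaks -------------------------------------------------------------
  # primary ion mode: nitrogenous compounds positive, others negative
  has_N <- vapply(cmp$formula, function(f) "N" %in% names(parse_formula(f)),
                  logical(1))
  primary_mode <- ifelse(has_N, "positive", "negative")
  counter <- 1000L
  new_id <- function(mode) {
    counter <<- counter + 1L
    paste0(if (mode == "positive") "P" else "N", counter)
  }
  peak_rows <- list()
  peak_owner <- character()   # compound (or decoy) name per peak
  add_peak <- function(owner, mode, mass, rt) {
    id <- new_id(mode)
    shift <- if (mode == "positive") PROTON_MASS else -PROTON_MASS
    peak_rows[[length(peak_rows) + 1L]] <<- data.frame(
      peak_id = id, ion_mode = mode, mz = mass + shift,
      adduct = if (mode == "positive") "[M+H]+" else "[M-H]-",
      neutral_mass = mass, rt = rt, stringsAsFactors = FALSE)
    peak_owner[length(peak_owner) + 1L] <<- owner
    id
  }
  cmp$peak_id <- vapply(seq_len(n_c), function(i)
    add_peak(cmp$name[i], primary_mode[i], cmp$obs_mass[i], cmp$obs_rt[i]),
    "")
  cmp$peak_id2 <- NA_character_
  for (i in which(cmp$dual_mode)) {
    other <- if (primary_mode[i] == "positive") "negative" else "positive"
    cmp$peak_id2[i] <- add_peak(cmp$name[i], other, cmp$obs_mass[i],
                                cmp$obs_rt[i] + 0.03)
  }
  decoy_id <- if (n_d) vapply(seq_len(n_d), function(k)
    add_peak(paste0("decoy_", decoy_kind[k], "_", k),
             if (k %% 2 == 0) "positive" else "negative",
             decoy_mass[k], decoy_rt[k]), "") else character(0)
  peaks <- do.call(rbind, peak_rows)

  # ---- intensities -------------------------------------------------------
  inten <- matrix(NA_real_, nrow(peaks), nrow(design),
                  dimnames = list(peaks$peak_id, design$sample_id))
  profile <- function(t, tmax, width) exp(-(log2(t / tmax))^2 / (2 * width^2))
  subj_fac <- matrix(exp(clipped_norm(n_c * spec$n_subjects,
                                      spec$subject_sd)),
                     n_c, spec$n_subjects,
                     dimnames = list(cmp$name, subjects))
  meas <- function(n) exp(clipped_norm(n, spec$measurement_sd))
  post <- design[design$class == "post", ]
  for (i in seq_len(n_c)) {
    vals <- cmp$amplitude[i] * subj_fac[i, post$subject] *
      profile(post$timepoint, cmp$tmax[i], cmp$width[i]) *
      meas(nrow(post))
    vals[vals < spec$detection_limit] <- NA
    for (pid in stats::na.omit(c(cmp$peak_id[i], cmp$peak_id2[i])))
      inten[pid, post$sample_id] <- vals * if (pid == cmp$peak_id[i]) 1 else 0.6
    if (spec$include_extract && cmp$in_extract[i])
      inten[stats::na.omit(c(cmp$peak_id[i], cmp$peak_id2[i])), "EXTRACT1"] <-
        cmp$amplitude[i] * 2 * meas(1)
    if (spec$include_herbs && !is.na(cmp$herb[i]))
      inten[stats::na.omit(c(cmp$peak_id[i], cmp$peak_id2[i])),
            paste0("RAT_", cmp$herb[i])] <- cmp$amplitude[i] * 0.5 * meas(1)
  }
  human <- design$sample_id[design$class %in% c("pre", "post")]
  pre_samples <- design$sample_id[design$class == "pre"]
  mock_samples <- design$sample_id[design$class == "mock"]
  for (k in seq_len(n_d)) {
    pid <- decoy_id[k]
    amp <- stats::runif(1, 2e3, 5e4)
    switch(decoy_kind[k],
      background = {
        cols <- c(human, mock_samples)
        inten[pid, cols] <- amp * meas(length(cols))
      },
      pre_only = {
        inten[pid, pre_samples] <- amp * meas(length(pre_samples))
      },
      singleton = {
        inten[pid, post$sample_id[1 + (k %% nrow(post))]] <- amp
      },
      candidate = {
        tmax <- sample(spec$timepoints, 1)
        vals <- amp * profile(post$timepoint, tmax, 1.2) * meas(nrow(post))
        vals[vals < spec$detection_limit] <- NA
        inten[pid, post$sample_id] <- vals
      },
      low_intensity = {
        vals <- stats::runif(nrow(post), 520, 950)
        inten[pid, post$sample_id] <- vals
      })
  }
  table <- feature_table(peaks, inten)

  # ---- spectra and isotope patterns --------------------------------------
  msms <- list()
  isotopes <- list()
  for (i in seq_len(n_c)) {
    f <- parse_formula(cmp$formula[i])
    n_S <- if ("S" %in% names(f)) unname(f["S"]) else 0L
    n_C <- if ("C" %in% names(f)) unname(f["C"]) else 0L
    pid <- cmp$peak_id[i]
    pat <- data.frame(offset_mz = 1.00336,
                      relative_intensity = round(n_C * 0.0107 *
                                                   meas(1), 5))
    if (n_S > 0)
      pat <- rbind(pat, data.frame(
        offset_mz = MASS_OFFSET_34S + round(clipped_norm(1, 0.002), 5),
        relative_intensity = round(n_S * ABUNDANCE_34S * meas(1), 5)))
    isotopes[[pid]] <- pat
    reaction <- cmp$reaction[i]
    if (!is.na(reaction) && reaction %in% c("sulfation", "glucuronidation")) {
      loss <- if (reaction == "sulfation") monoisotopic_mass("SO3") else
        monoisotopic_mass("C6H8O6")
      mz <- peaks$mz[peaks$peak_id == pid]
      frags <- data.frame(
        mz = round(c(mz - loss, mz * stats::runif(2, 0.2, 0.7)), 5),
        intensity = round(c(100, stats::runif(2, 5, 40)), 1))
      frags <- frags[order(frags$mz), ]
      msms[[pid]] <- list(precursor_mz = mz, title = pid, fragments = frags)
    }
  }

  standards <- annotation_table(data.frame(
    name = cmp$name[is.na(cmp$parent)],
    formula = cmp$formula[is.na(cmp$parent)],
    herb = cmp$herb[is.na(cmp$parent)],
    rt = cmp$rt[is.na(cmp$parent)],
    stringsAsFactors = FALSE))

  edges <- rbind(
    data.frame(source = cmp$parent[!is.na(cmp$parent)],
               target = cmp$name[!is.na(cmp$parent)],
               reaction = cmp$reaction[!is.na(cmp$parent)],
               stringsAsFactors = FALSE),
    spec$extra_edges)
  truth <- list(
    compounds = cmp[c("name", "formula", "herb", "rt", "obs_rt", "parent",
                      "reaction", "shift", "true_mass", "obs_mass",
                      "peak_id", "peak_id2", "in_extract")],
    edges = edges,
    maoto_peaks = sort(stats::na.omit(c(cmp$peak_id, cmp$peak_id2))),
    decoy_peaks = sort(decoy_id),
    decoys = data.frame(peak_id = decoy_id, kind = decoy_kind,
                        stringsAsFactors = FALSE)
  )
  exceptions <- list()
  if (all(c("ephedrine", "pseudoephedrine") %in% cmp$name))
    exceptions <- list(c(cmp$peak_id[cmp$name == "ephedrine"],
                         cmp$peak_id[cmp$name == "pseudoephedrine"]))
  structure(list(table = table, design = design, msms = msms,
                 isotopes = isotopes, standards = standards, truth = truth,
                 exceptions = exceptions, spec = spec),
            class = "dacmet_fixture")
}

#' @export
print.dacmet_fixture <- function(x, ...) {
  cat("dacmet_fixture:", nrow(x$table$peaks), "peaks,",
      length(x$table$sample_ids), "samples,",
      nrow(x$truth$compounds), "planted compounds,",
      nrow(x$truth$edges), "planted edges (seed ", x$spec$seed, ")\n")
  invisible(x)
}

#' Write a fixture to canonical text files
#'
#' Writes `feature_table.tsv`, `design.tsv`, `spectra.mgf`,
#' `isotopes.tsv`, `standards.tsv`, `truth_compounds.tsv`,
#' `truth_edges.tsv` into `dir`. Deterministic: the same spec and seed
#' produce byte-identical files.
#'
#' @param fixture A `dacmet_fixture`.
#' @param dir Output directory (created if absent).
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(fixture$table, file.path(dir, "feature_table.tsv"))
  utils::write.table(as.data.frame(fixture$design),
                     file.path(dir, "design.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  write_mgf(fixture$msms, file.path(dir, "spectra.mgf"))
  iso <- do.call(rbind, lapply(names(fixture$isotopes), function(id)
    cbind(peak_id = id, fixture$isotopes[[id]])))
  utils::write.table(iso %||% data.frame(peak_id = character(),
                                         offset_mz = numeric(),
                                         relative_intensity = numeric()),
                     file.path(dir, "isotopes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(fixture$standards),
                     file.path(dir, "standards.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(fixture$truth$compounds,
                     file.path(dir, "truth_compounds.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  utils::write.table(fixture$truth$edges, file.path(dir, "truth_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Compare a pipeline result against a fixture's planted truth
#'
#' @param fixture A `dacmet_fixture`.
#' @param kept Character vector of kept peak ids from
#'   [filter_candidates()].
#' @param network A `conjugation_network` (optional).
#' @return List with `peak_recall` (fraction of planted maoto-derived
#'   peaks kept), `decoy_leakage` (fraction of decoy peaks kept - only
#'   `candidate`/`low_intensity` decoys can legitimately appear), and,
#'   when a network is given, `edge_recall` and `edge_precision` over
#'   within-window edges. For precision, an edge counts as planted when
#'   its unordered node pair and mass delta match a planted relation:
#'   gain reactions and their loss-direction mirrors (glucuronidation /
#'   glucuronide loss) annotate the same pair, and disambiguating the
#'   direction is the role of the RT-shift layer, not pair finding.
#' @export
fixture_recovery <- function(fixture, kept, network = NULL) {
  truth <- fixture$truth
  out <- list(
    peak_recall = mean(truth$maoto_peaks %in% kept),
    decoy_leakage = if (length(truth$decoy_peaks))
      mean(truth$decoy_peaks %in% kept) else 0
  )
  if (!is.null(network)) {
    node_of_peak <- function(pid) {
      hit <- vapply(strsplit(network$nodes$node_id, "/", fixed = TRUE),
                    function(m) pid %in% m, logical(1))
      if (any(hit)) network$nodes$node_id[which(hit)[1]] else NA_character_
    }
    cmp <- truth$compounds
    cmp_node <- vapply(cmp$peak_id, node_of_peak, "")
    names(cmp_node) <- cmp$name
    ed <- network$edges
    ed <- ed[!is.na(ed$within_window) & ed$within_window, , drop = FALSE]
    found <- vapply(seq_len(nrow(truth$edges)), function(k) {
      s <- cmp_node[truth$edges$source[k]]
      t <- cmp_node[truth$edges$target[k]]
      if (is.na(s) || is.na(t)) return(FALSE)
      any(ed$source == s & ed$target == t &
            ed$reaction == truth$edges$reaction[k])
    }, logical(1))
    out$edge_recall <- mean(found)
    if (nrow(ed)) {
      reactions <- default_reaction_table()
      pair_key <- function(a, b, delta) {
        swap <- a > b
        paste(ifelse(swap, b, a), ifelse(swap, a, b), round(delta, 4))
      }
      planted_key <- pair_key(
        cmp_node[truth$edges$source], cmp_node[truth$edges$target],
        reactions$delta_mass[match(truth$edges$reaction, reactions$name)])
      found_key <- pair_key(ed$source, ed$target, ed$delta_mass)
      out$edge_precision <- mean(found_key %in% planted_key)
    } else out$edge_precision <- NA_real_
  }
  out
}
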