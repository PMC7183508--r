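# Shared in-code fixtures: tiny feature tables / designs built
# programmatically, an independent brute-force pair oracle, and a
# collision-free compound preset for exact-recovery checks.

# Minimal peak data frame from neutral masses / RTs; mz derived from
# the adduct so read/write paths stay consistent.
make_peaks <- function(ids, masses, rts, modes = NULL) {
  if (is.null(modes))
    modes <- ifelse(substr(ids, 1, 1) == "P", "positive", "negative")
  shift <- ifelse(modes == "positive", 1.007276467, -1.007276467)
  data.frame(peak_id = ids, ion_mode = modes, mz = masses + shift,
             adduct = ifelse(modes == "positive", "[M+H]+", "[M-H]-"),
             neutral_mass = masses, rt = rts, stringsAsFactors = FALSE)
}

make_table <- function(peaks, intensity = NULL, samples = c("s1", "s2")) {
  if (is.null(intensity))
    intensity <- matrix(1e4, nrow(peaks), length(samples),
                        dimnames = list(peaks$peak_id, samples))
  feature_table(peaks, intensity)
}

# Design with n subjects (pre + post timepoints), mock blanks and
# optional extract / herb-plasma samples.
make_design <- function(subjects = paste0("S", 1:4), timepoints = c(1, 2),
                        n_mock = 2, extract = FALSE, herbs = FALSE) {
  des <- do.call(rbind, lapply(subjects, function(s) rbind(
    data.frame(sample_id = paste0(s, "_pre"), subject = s, class = "pre",
               timepoint = NA_real_, herb = NA_character_),
    data.frame(sample_id = paste0(s, "_t", timepoints), subject = s,
               class = "post", timepoint = timepoints,
               herb = NA_character_))))
  if (n_mock > 0)
    des <- rbind(des, data.frame(sample_id = paste0("MOCK", seq_len(n_mock)),
                                 subject = "mock", class = "mock",
                                 timepoint = NA_real_,
                                 herb = NA_character_))
  if (extract)
    des <- rbind(des, data.frame(sample_id = "EXTRACT1", subject = "extract",
                                 class = "extract", timepoint = NA_real_,
                                 herb = NA_character_))
  if (herbs)
    des <- rbind(des, data.frame(
      sample_id = paste0("RAT_", c("ephedra", "apricot", "cinnamon",
                                   "licorice")),
      subject = paste0("rat_", c("ephedra", "apricot", "cinnamon",
                                 "licorice")),
      class = "herb_plasma", timepoint = NA_real_,
      herb = c("ephedra", "apricot", "cinnamon", "licorice")))
  sample_design(des)
}

# Independent brute-force oracle for delta-matched pair finding:
# plain double loop, direct residual formula, no shared code path.
oracle_pairs <- function(nodes, reactions, ppm = 5) {
  out <- list()
  n <- nrow(nodes)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      lo <- i; hi <- j
      if (nodes$neutral_mass[lo] > nodes$neutral_mass[hi]) { lo <- j; hi <- i }
      dm <- nodes$neutral_mass[hi] - nodes$neutral_mass[lo]
      for (r in seq_len(nrow(reactions))) {
        if (abs(dm - reactions$delta_mass[r]) /
            nodes$neutral_mass[hi] * 1e6 <= ppm) {
          gain <- reactions$direction[r] == "gain"
          out[[length(out) + 1L]] <- data.frame(
            source = nodes$node_id[if (gain) lo else hi],
            target = nodes$node_id[if (gain) hi else lo],
            reaction = reactions$name[r], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(source = character(), target = character(),
                      reaction = character()))
  df <- do.call(rbind, out)
  df[order(df$source, df$target, df$reaction), , drop = FALSE]
}

edge_key <- function(edges) {
  if (!nrow(edges)) return(character())
  sort(paste(edges$source, edges$target, edges$reaction))
}

# Cinnamon-only preset: three sources and five conjugates with no
# isobaric compounds and no cross-pair delta coincidences, so the
# pipeline can be held to exact planted-network recovery.
clean_fixture_spec <- function(seed = 1, mass_noise_ppm = 2,
                               rt_jitter_sd = 0.1) {
  src <- function(name, formula, rt, tmax, amp)
    data.frame(name = name, formula = formula, herb = "cinnamon", rt = rt,
               parent = NA_character_, reaction = NA_character_,
               shift = NA_real_, tmax = tmax, width = 1.2, amplitude = amp,
               in_extract = TRUE, dual_mode = FALSE,
               stringsAsFactors = FALSE)
  cj <- function(name, parent, reaction, shift, tmax, amp)
    data.frame(name = name, formula = NA_character_, herb = NA_character_,
               rt = NA_real_, parent = parent, reaction = reaction,
               shift = shift, tmax = tmax, width = 1.2, amplitude = amp,
               in_extract = FALSE, dual_mode = FALSE,
               stringsAsFactors = FALSE)
  # three kinetic families with well-separated peak times so that
  # conjugate/source co-clustering is the planted signal
  compounds <- rbind(
    src("7-hydroxycoumarin", "C9H6O3", 6.80, 0.5, 6e4),
    src("cinnamic_acid", "C9H8O2", 7.60, 2, 9e4),
    src("eugenol", "C10H12O2", 11.20, 8, 5e4),
    cj("7-hydroxycoumarin_sulfate", "7-hydroxycoumarin", "sulfation",
       -1.4, 0.5, 8e4),
    cj("7-hydroxycoumarin_glucuronide", "7-hydroxycoumarin",
       "glucuronidation", -1.9, 0.5, 7e4),
    cj("eugenol_sulfate", "eugenol", "sulfation", -1.4, 8, 9e4),
    cj("eugenol_glucuronide", "eugenol", "glucuronidation", -1.9, 8, 8e4),
    cj("hippuric_acid", "cinnamic_acid", "glycine_conjugation", -0.5, 2,
       2e5))
  fixture_spec(seed = seed, compounds = compounds,
               extra_edges = data.frame(source = character(),
                                        target = character(),
                                        reaction = character()),
               mass_noise_ppm = mass_noise_ppm,
               rt_jitter_sd = rt_jitter_sd,
               decoys = c(background = 0, pre_only = 0, singleton = 0,
                          candidate = 0, low_intensity = 0))
}
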