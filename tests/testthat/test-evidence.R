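# 34S isotopologue detection, diagnostic neutral losses, MSI rubric.

test_that("34S isotopologues are detected with sulfur counting", {
  one_s <- detect_34S(data.frame(offset_mz = 1.9957,
                                 relative_intensity = 0.043))
  expect_true(one_s$has_34S)
  expect_equal(one_s$estimated_sulfur_count, 1L)
  two_s <- detect_34S(data.frame(offset_mz = 1.9958,
                                 relative_intensity = 0.086))
  expect_true(two_s$has_34S)
  expect_equal(two_s$estimated_sulfur_count, 2L)
  # nothing near +1.9958: no evidence
  none <- detect_34S(data.frame(offset_mz = 1.00336,
                                relative_intensity = 0.15))
  expect_false(none$has_34S)
  # 13C2 isotopologue at +2.00671 is outside the offset tolerance
  c13 <- detect_34S(data.frame(offset_mz = 2.00671,
                               relative_intensity = 0.05))
  expect_false(c13$has_34S)
  # intensity far off the per-sulfur band: rejected
  weak <- detect_34S(data.frame(offset_mz = 1.9958,
                                relative_intensity = 0.005))
  expect_false(weak$has_34S)
})

test_that("an absent pattern is no evidence, not counter-evidence", {
  res <- detect_34S(NULL)
  expect_false(res$has_34S)
  expect_equal(res$note, "no pattern")
  expect_equal(res$estimated_sulfur_count, 0L)
})

test_that("34S detection is pure and monotone in tolerance", {
  pat <- data.frame(offset_mz = 1.988, relative_intensity = 0.044)
  expect_false(detect_34S(pat, offset_tol = 0.005)$has_34S)
  expect_true(detect_34S(pat, offset_tol = 0.01)$has_34S)
  expect_true(detect_34S(pat, offset_tol = 0.02)$has_34S)
  expect_identical(detect_34S(pat), detect_34S(pat))
})

test_that("diagnostic neutral losses match precursor-fragment differences", {
  # LG sulfate [M-H]-: NL-80 to the aglycone fragment
  sulf <- list(precursor_mz = 335.02310,
               fragments = data.frame(mz = 255.06628, intensity = 100))
  hit <- detect_neutral_loss(sulf, frag_tol = 0.01)
  expect_equal(hit$name, "NL-80")
  expect_equal(hit$observed, 79.95682, tolerance = 1e-5)
  # LG glucuronide [M-H]-: NL-176
  gluc <- list(precursor_mz = 431.09837,
               fragments = data.frame(mz = 255.06628, intensity = 100))
  expect_equal(detect_neutral_loss(gluc, frag_tol = 0.01)$name, "NL-176")
  # no fragment near any loss
  far <- list(precursor_mz = 335.0231,
              fragments = data.frame(mz = 300.0, intensity = 50))
  expect_equal(nrow(detect_neutral_loss(far, frag_tol = 0.01)), 0)
  # empty fragment list: empty evidence
  expect_equal(nrow(detect_neutral_loss(
    list(precursor_mz = 335, fragments = data.frame(mz = numeric(),
                                                    intensity = numeric())))),
    0)
  # widening the tolerance never loses a match
  expect_gte(nrow(detect_neutral_loss(sulf, frag_tol = 0.5)), nrow(hit))
  # fragments above the precursor violate the spectrum invariant
  expect_error(detect_neutral_loss(
    list(precursor_mz = 100, fragments = data.frame(mz = 101, intensity = 1))),
    "precursor")
})

msi_num <- function(level) match(level, c("1", "2", "3", "4", "unknown"))

test_that("the MSI rubric assigns the documented levels", {
  # standard match dominates
  expect_equal(assign_msi_level(has_standard_match = TRUE)$level, "1")
  # conjugate with preferred source + orthogonal evidence: level 2
  expect_equal(assign_msi_level(has_preferred_edge = TRUE,
                                has_34S = TRUE)$level, "2")
  expect_equal(assign_msi_level(has_preferred_edge = TRUE,
                                shift_agreement = TRUE)$level, "2")
  # edge without orthogonal evidence does not reach level 2
  expect_equal(assign_msi_level(has_preferred_edge = TRUE)$level, "unknown")
  expect_equal(assign_msi_level(has_annotation = TRUE)$level, "3")
  expect_equal(assign_msi_level(has_formula = TRUE)$level, "4")
  expect_equal(assign_msi_level()$level, "unknown")
})

test_that("adding evidence never worsens the MSI level", {
  flags <- c("has_standard_match", "has_preferred_edge", "has_34S",
             "has_neutral_loss", "shift_agreement", "has_annotation",
             "has_formula")
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(flags)))
  names(combos) <- flags
  for (i in seq_len(nrow(combos))) {
    base <- as.list(combos[i, ])
    lv <- msi_num(do.call(assign_msi_level, base)$level)
    for (f in flags[!unlist(base)]) {
      more <- base; more[[f]] <- TRUE
      expect_lte(msi_num(do.call(assign_msi_level, more)$level), lv)
    }
  }
})

test_that("synthetic sulfate conjugates all reach level 2 or better", {
  fix <- generate_fixture(fixture_spec(seed = 3))
  res <- dacmet_run(fix$table, fix$design,
                    run_config(exceptions = fix$exceptions),
                    msms = fix$msms, isotopes = fix$isotopes,
                    standards = fix$standards)
  cmp <- fix$truth$compounds
  sulfates <- cmp$peak_id[!is.na(cmp$reaction) & cmp$reaction == "sulfation"]
  nd <- res$network$nodes
  for (pid in sulfates) {
    hit <- vapply(strsplit(nd$node_id, "/", fixed = TRUE),
                  function(m) pid %in% m, logical(1))
    expect_lte(msi_num(nd$msi_level[hit][1]), 2)
  }
  # sources with standards are level 1; their labels are the truth names
  expect_true(all(nd$msi_level[!is.na(nd$label)] == "1"))
  # the pseudoephedrine node is not mislabelled as ephedrine
  pseudo <- cmp$peak_id[cmp$name == "pseudoephedrine"]
  expect_equal(nd$label[nd$node_id == pseudo], "pseudoephedrine")
})
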