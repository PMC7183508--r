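# Differential peak filtration and duplicate-ion merging.

# Scenario table: one peak per filtration outcome.
scenario_table <- function() {
  design <- make_design(paste0("S", 1:4), timepoints = c(1, 2), n_mock = 2)
  ids <- c("P_good", "P_mocky", "P_prey", "P_rare", "P_weak", "P_minor")
  peaks <- make_peaks(ids, seq(200, 205, by = 1), rep(5, 6),
                      modes = rep("positive", 6))
  m <- matrix(NA_real_, 6, nrow(design),
              dimnames = list(ids, design$sample_id))
  post2 <- paste0("S", 1:3, "_t2")
  m["P_good", post2] <- 5000                       # 3/4 subjects at 2 h
  m["P_mocky", paste0("S", 1:4, "_t1")] <- 8000
  m["P_mocky", "MOCK1"] <- 300                     # blank contamination
  m["P_prey", paste0("S", 1:4, "_t1")] <- 8000
  m["P_prey", "S1_pre"] <- 700                     # present pre-dose
  m["P_rare", "S1_t1"] <- 9000                     # single sample
  m["P_weak", post2] <- 999                        # below ion-count floor
  m["P_minor", paste0("S", 1:2, "_t1")] <- 6000    # only 2/4 subjects
  m["P_minor", paste0("S", 1:2, "_t2")] <- 6000
  list(table = feature_table(peaks, m), design = design)
}

test_that("each filtration rule fires on its canonical case", {
  sc <- scenario_table()
  res <- filter_candidates(sc$table, sc$design)
  expect_identical(res$kept, "P_good")
  rep <- res$report$peaks
  rule <- function(id) rep$first_failing_rule[rep$peak_id == id]
  expect_identical(rule("P_mocky"), "not_in_mock")
  expect_identical(rule("P_prey"), "not_in_pre")
  expect_identical(rule("P_rare"), "min_samples_detected")
  expect_identical(rule("P_weak"), "min_ion_count")
  expect_identical(rule("P_minor"), "post_majority")
  # exactly at the threshold: 1000 counts is kept
  sc$table$intensity["P_weak", paste0("S", 1:3, "_t2")] <- 1000
  res2 <- filter_candidates(sc$table, sc$design)
  expect_true("P_weak" %in% res2$kept)
})

test_that("report accounting is consistent", {
  sc <- scenario_table()
  res <- filter_candidates(sc$table, sc$design)
  r <- res$report
  expect_equal(sum(r$peaks$status == "kept") +
                 sum(r$peaks$status == "excluded"), 6)
  expect_equal(sum(r$counts[-1]), sum(r$peaks$status == "excluded"))
  expect_equal(r$counts[["kept"]], length(res$kept))
})

test_that("filtration is monotone in its thresholds", {
  set.seed(21)
  design <- make_design(paste0("S", 1:4), c(1, 2), n_mock = 2)
  n <- 40
  peaks <- make_peaks(sprintf("P%03d", 1:n), runif(n, 100, 800),
                      runif(n, 0, 15), modes = rep("positive", n))
  m <- matrix(NA_real_, n, nrow(design),
              dimnames = list(peaks$peak_id, design$sample_id))
  for (i in 1:n) {
    cols <- sample(nrow(design), sample(1:8, 1))
    m[i, cols] <- runif(length(cols), 100, 5e4)
  }
  tab <- feature_table(peaks, m)
  kept_at <- function(minc, frac)
    filter_candidates(tab, design,
                      filtration_params(min_ion_count = minc,
                                        post_fraction = frac))$kept
  base <- kept_at(1000, 0.5)
  expect_true(all(kept_at(5000, 0.5) %in% base))
  expect_true(all(kept_at(1000, 0.75) %in% base))
  expect_true(all(base %in% kept_at(200, 0.5)))
  expect_true(all(base %in% kept_at(1000, 0.25)))
})

test_that("filtration is invariant to input row order", {
  sc <- scenario_table()
  perm <- c(4, 2, 6, 1, 3, 5)
  tab2 <- feature_table(sc$table$peaks[perm, ],
                        sc$table$intensity[perm, ])
  expect_identical(filter_candidates(sc$table, sc$design)$kept,
                   filter_candidates(tab2, sc$design)$kept)
  expect_identical(filter_candidates(sc$table, sc$design)$report$peaks,
                   filter_candidates(tab2, sc$design)$report$peaks)
})

test_that("absent sample classes skip their rules with a warning", {
  sc <- scenario_table()
  design_nomock <- sc$design[sc$design$class != "mock", ]
  tab_nomock <- feature_table(
    sc$table$peaks,
    sc$table$intensity[, design_nomock$sample_id, drop = FALSE])
  expect_warning(res <- filter_candidates(tab_nomock, design_nomock),
                 "mock")
  # the mock-contaminated peak now survives the skipped rule
  expect_true("P_mocky" %in% res$kept)
  expect_true("not_in_mock" %in% res$report$skipped_rules)
})

test_that("duplicate ion forms collapse into metabolite groups", {
  # opposite-mode pair at the same neutral mass, close RT: merged
  peaks <- make_peaks(c("P1", "N1", "N2", "P9"),
                      c(432.10565, 432.10565, 432.10565, 200.1),
                      c(8.30, 8.35, 8.80, 3.0))
  tab <- make_table(peaks)
  g <- merge_duplicate_ions(tab, rt_tol = 0.2)
  expect_equal(nrow(g), 3)
  expect_true("N1/P1" %in% g$group_id)     # merged cross-mode pair
  expect_true("N2" %in% g$group_id)        # 0.45 min away: kept apart
  # exception pairs never merge
  g2 <- merge_duplicate_ions(tab, rt_tol = 0.2,
                             exceptions = list(c("P1", "N1")))
  expect_equal(nrow(g2), 4)
  # declared relations merge same-mode peaks (e.g. in-source fragment)
  g3 <- merge_duplicate_ions(tab, rt_tol = 0.2,
                             relations = data.frame(peak_a = "N1",
                                                    peak_b = "N2"))
  expect_equal(nrow(g3), 3)
})

test_that("group accounting: collapsed count equals kept minus merged", {
  # 10 metabolites, 3 of which carry an extra opposite-mode ion form
  masses <- seq(150, 600, length.out = 10)
  ids <- sprintf("P%02d", 1:10)
  peaks <- make_peaks(ids, masses, seq(1, 10), modes = rep("positive", 10))
  extra <- make_peaks(c("N91", "N92", "N93"), masses[1:3],
                      seq(1, 3) + 0.05, modes = rep("negative", 3))
  tab <- make_table(rbind(peaks, extra))
  g <- merge_duplicate_ions(tab)
  expect_equal(nrow(g), 13 - 3)
})
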