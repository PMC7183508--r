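# Imputation, auto-scaling, Ward clustering, co-clustering report.

test_that("half-minimum imputation fills only missing cells", {
  m <- rbind(a = c(10, NA, 4), b = c(1, 2, 3), c = c(NA, 6, NA))
  out <- impute_half_min(m)
  expect_equal(out["a", ], c(10, 2, 4), ignore_attr = TRUE)
  expect_equal(out["b", ], c(1, 2, 3), ignore_attr = TRUE)
  expect_equal(out["c", ], c(3, 6, 3), ignore_attr = TRUE)
  bad <- rbind(ok = c(1, 2), empty = c(NA_real_, NA_real_))
  expect_error(impute_half_min(bad), "empty")
})

test_that("auto-scaling gives unit-variance rows with n-1 sd", {
  out <- autoscale(rbind(a = c(1, 2, 3)))
  expect_equal(out["a", ], c(-1, 0, 1), ignore_attr = TRUE)
  expect_error(autoscale(rbind(flat = c(5, 5, 5))), "flat")
  expect_error(autoscale(rbind(a = c(1, NA, 3))), "imputed")
})

test_that("imputation and scaling postconditions hold on random matrices", {
  set.seed(61)
  for (rep in 1:10) {
    m <- matrix(rlnorm(15 * 8, 8, 1), 15, 8,
                dimnames = list(sprintf("r%02d", 1:15), sprintf("c%d", 1:8)))
    m[sample(length(m), 20)] <- NA
    # guard: keep at least one observed value per row
    m[, 1] <- rlnorm(15, 8, 1)
    imp <- impute_half_min(m)
    expect_false(anyNA(imp))
    # imputed cells equal half the row minimum of observed values
    for (i in seq_len(nrow(m))) {
      miss <- is.na(m[i, ])
      if (any(miss))
        expect_equal(unname(imp[i, miss]),
                     rep(min(m[i, !miss]) / 2, sum(miss)))
    }
    z <- autoscale(imp)
    expect_lt(max(abs(rowMeans(z))), 1e-9)
    expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-9)
    # impute-then-scale commutes with column permutation
    perm <- sample(ncol(m))
    expect_equal(autoscale(impute_half_min(m[, perm]))[, order(perm)], z)
  }
})

test_that("Ward clustering has monotone heights and groups duplicates", {
  set.seed(62)
  m <- rbind(twin1 = c(1, 5, 9, 2), twin2 = c(1, 5, 9, 2),
             far = c(9, 1, -4, 8))
  cl <- ward_cluster(m, k = 2)
  expect_equal(cl$labels[["twin1"]], cl$labels[["twin2"]])
  expect_false(cl$labels[["far"]] == cl$labels[["twin1"]])
  for (rep in 1:5) {
    r <- matrix(rnorm(20 * 6), 20, 6)
    expect_false(is.unsorted(ward_cluster(r)$tree$height))
  }
  expect_error(ward_cluster(m[1, , drop = FALSE]), "2 rows")
})

test_that("clustering is invariant to row permutation up to relabeling", {
  set.seed(63)
  m <- matrix(rnorm(12 * 7), 12, 7,
              dimnames = list(sprintf("r%02d", 1:12), NULL))
  a <- ward_cluster(m, k = 4)
  perm <- sample(12)
  b <- ward_cluster(m[perm, ], k = 4)
  expect_equal(sort(a$tree$height), sort(b$tree$height), tolerance = 1e-9)
  # identical partitions: same co-membership for every row pair
  co <- function(lab) outer(lab, lab, "==")
  expect_identical(unname(co(a$labels[rownames(m)])),
                   unname(co(b$labels[rownames(m)])))
})

test_that("conjugates co-cluster with their sources on planted profiles", {
  set.seed(64)
  t <- c(0.25, 0.5, 1, 2, 4, 8)
  prof <- function(tmax) exp(-(log2(t / tmax))^2 / 2)
  # three families: early, mid, late; conjugate = source + small noise
  fam <- c(early = 0.5, mid = 2, late = 8)
  rows <- list()
  for (f in names(fam)) {
    p <- prof(fam[[f]])
    rows[[paste0(f, "_src")]] <- p
    rows[[paste0(f, "_conj")]] <- p + rnorm(6, 0, 0.01)
  }
  # a microbial deglycosylation product appearing hours later
  rows[["glycoside"]] <- prof(0.5)
  rows[["aglycone_late"]] <- prof(8) + rnorm(6, 0, 0.01)
  m <- autoscale(do.call(rbind, rows))
  cl <- ward_cluster(m, k = 3)
  nodes <- data.frame(node_id = rownames(m), neutral_mass = seq_len(nrow(m)),
                      rt = seq_len(nrow(m)))
  ed <- rbind(
    data.frame(source = paste0(names(fam), "_src"),
               target = paste0(names(fam), "_conj"),
               reaction = "sulfation", rt_shift = -1, within_window = TRUE),
    data.frame(source = "glycoside", target = "aglycone_late",
               reaction = "hexose_loss", rt_shift = 1, within_window = TRUE))
  rep <- coclustering_report(cl, conjugation_network(nodes, ed))
  by_r <- rep$by_reaction
  expect_equal(by_r$fraction_same[by_r$reaction == "sulfation"], 1)
  expect_equal(by_r$fraction_same[by_r$reaction == "hexose_loss"], 0)
  # edges with endpoints missing from the matrix are skipped
  ed2 <- rbind(ed, data.frame(source = "ghost", target = "early_src",
                              reaction = "sulfation", rt_shift = -1,
                              within_window = TRUE))
  nodes2 <- rbind(nodes, data.frame(node_id = "ghost", neutral_mass = 99,
                                    rt = 99))
  expect_message(rep2 <- coclustering_report(
    cl, conjugation_network(nodes2, ed2)), "skipped")
  expect_equal(nrow(rep2$edges), nrow(rep$edges))
})

test_that("kinetics matrices order columns by subject then time", {
  fix <- generate_fixture(subnetwork_a_spec(1))
  m <- kinetics_matrix(fix$table, fix$design)
  des <- attr(m, "design")
  expect_equal(colnames(m), des$sample_id)
  expect_false(is.unsorted(order(des$subject, des$timepoint)))
  # pre samples sit at timepoint 0
  expect_true(all(des$timepoint[des$class == "pre"] == 0))
  # only plasma samples enter the matrix
  expect_false(any(c("MOCK1", "EXTRACT1") %in% colnames(m)))
})
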