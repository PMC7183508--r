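# Mass-difference network construction, RT windows, co-elution merging,
# calibrant scoring, origin overlay and subnetworks.

lg_family_nodes <- function() {
  data.frame(node_id = c("LG", "LG_sulf", "LG_gluc", "LG_gluc_sulf"),
             neutral_mass = c(256.07356, 336.03038, 432.10565, 512.06247),
             rt = c(9.0, 7.7, 7.3, 6.0), stringsAsFactors = FALSE)
}

test_that("delta matching finds exactly the conjugation gain edges", {
  conj <- default_reaction_table()
  conj <- conj[conj$group == "conjugation", ]
  ed <- find_difference_pairs(lg_family_nodes(), conj)
  expect_identical(edge_key(ed), sort(c(
    "LG LG_sulf sulfation",
    "LG LG_gluc glucuronidation",
    "LG_sulf LG_gluc_sulf glucuronidation",
    "LG_gluc LG_gluc_sulf sulfation")))
  # 256 -> 512 is matched by no single reaction
  expect_false(any(ed$source == "LG" & ed$target == "LG_gluc_sulf"))
  # exact difference gives zero ppm residual
  expect_lt(max(abs(ed$mass_residual_ppm)), 0.1)
})

test_that("single node and empty inputs give empty edge sets", {
  expect_equal(nrow(find_difference_pairs(lg_family_nodes()[1, ])), 0)
  one <- data.frame(node_id = c("a", "b"),
                    neutral_mass = c(100, 100 + 176.03209), rt = c(1, 1))
  ed <- find_difference_pairs(one)
  expect_true(any(ed$reaction == "glucuronidation" & ed$source == "a"))
})

test_that("loss reactions direct heavier to lighter", {
  nodes <- data.frame(node_id = c("glycoside", "aglycone"),
                      neutral_mass = c(418.12638, 256.07356),
                      rt = c(8.2, 9.0))
  ed <- find_difference_pairs(nodes)
  loss <- ed[ed$reaction == "hexose_loss", ]
  expect_equal(loss$source, "glycoside")
  expect_equal(loss$target, "aglycone")
  expect_equal(loss$rt_shift, 0.8)
})

test_that("pair finding equals the brute-force oracle on random instances", {
  set.seed(31)
  tab <- default_reaction_table()
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    nodes <- data.frame(node_id = sprintf("n%02d", 1:n),
                        neutral_mass = runif(n, 120, 620),
                        rt = runif(n, 0.5, 15))
    # seed some true delta relations so hits exist
    for (k in 1:3) {
      i <- sample(n, 1)
      r <- tab[sample(nrow(tab), 1), ]
      nodes$neutral_mass[sample(n, 1)] <-
        nodes$neutral_mass[i] + r$delta_mass * (1 + rnorm(1, 0, 2e-6))
    }
    expect_identical(edge_key(find_difference_pairs(nodes, tab)),
                     edge_key(oracle_pairs(nodes, tab)))
  }
})

test_that("RT windows are closed intervals per reaction", {
  mk_edge <- function(reaction, shift)
    data.frame(source = "s", target = "t", reaction = reaction,
               delta_mass = 1, mass_residual_ppm = 0, rt_shift = shift,
               within_window = NA, shift_score = NA_real_,
               preferred = FALSE, ambiguous = FALSE, evidence = "",
               stringsAsFactors = FALSE)
  win <- function(reaction, shift)
    apply_rt_windows(mk_edge(reaction, shift))$within_window
  expect_true(win("glucuronidation", -1.7))
  expect_true(win("sulfation", -1.3))
  expect_true(win("sulfation", -2.8))
  expect_false(win("glucuronidation", -3.2))
  expect_true(win("sulfation", 0.2))      # boundary closed
  expect_true(win("glucuronidation", -3)) # boundary closed
  expect_false(win("sulfation", 0.201))
  expect_true(win("glycine_conjugation", 4.9))
  expect_false(win("glycine_conjugation", 5.1))
  expect_error(apply_rt_windows(mk_edge("teleportation", 0)), "reaction")
})

test_that("co-eluting equal-mass nodes merge transitively with exceptions", {
  nodes <- data.frame(node_id = c("P8722", "N6061", "far"),
                      neutral_mass = c(432.10565, 432.10565, 432.10565),
                      rt = c(8.30, 8.35, 8.70), stringsAsFactors = FALSE)
  merged <- merge_coeluting_nodes(nodes, rt_tol = 0.2)
  expect_setequal(merged$node_id, c("far", "N6061/P8722"))
  # ΔRT 0.3: stays separate
  nodes2 <- nodes[1:2, ]; nodes2$rt <- c(8.0, 8.3)
  expect_equal(nrow(merge_coeluting_nodes(nodes2, rt_tol = 0.2)), 2)
  # exception pair never merges regardless of ΔRT
  eph <- data.frame(node_id = c("ephedrine", "pseudoephedrine"),
                    neutral_mass = rep(165.11536, 2), rt = c(2.10, 2.12))
  expect_equal(nrow(merge_coeluting_nodes(
    eph, exceptions = list(c("ephedrine", "pseudoephedrine")))), 2)
  expect_equal(nrow(merge_coeluting_nodes(eph)), 1)
})

test_that("co-elution merging is independent of node input order", {
  set.seed(41)
  base <- 300 + cumsum(runif(12, 0, 0.00005))
  nodes <- data.frame(node_id = sprintf("x%02d", 1:12),
                      neutral_mass = base,
                      rt = 5 + cumsum(runif(12, 0, 0.15)))
  a <- merge_coeluting_nodes(nodes)
  for (rep in 1:5) {
    b <- merge_coeluting_nodes(nodes[sample(12), ])
    expect_identical(sort(a$node_id), sort(b$node_id))
  }
})

test_that("calibrant reference shifts rank candidate sources", {
  ed <- rbind(
    data.frame(source = "LG", target = "conj336", reaction = "sulfation",
               delta_mass = 79.95682, mass_residual_ppm = 0,
               rt_shift = -1.3, within_window = TRUE,
               shift_score = NA_real_, preferred = FALSE, ambiguous = FALSE,
               evidence = "", stringsAsFactors = FALSE),
    data.frame(source = "ILG", target = "conj336", reaction = "sulfation",
               delta_mass = 79.95682, mass_residual_ppm = 0,
               rt_shift = -2.8, within_window = TRUE,
               shift_score = NA_real_, preferred = FALSE, ambiguous = FALSE,
               evidence = "", stringsAsFactors = FALSE))
  sc <- score_source_by_reference_shift(ed)
  expect_equal(sc$shift_score, c(0.1, 1.4), tolerance = 1e-9)
  expect_identical(sc$preferred, c(TRUE, FALSE))
  expect_false(any(sc$ambiguous))
  # single candidate is preferred outright
  expect_true(score_source_by_reference_shift(ed[1, ])$preferred)
  # exact ties: both kept, flagged ambiguous
  tie <- ed; tie$rt_shift <- c(-1.0, -1.8)  # scores 0.4 and 0.4
  sct <- score_source_by_reference_shift(tie)
  expect_identical(sct$preferred, c(TRUE, TRUE))
  expect_identical(sct$ambiguous, c(TRUE, TRUE))
  # out-of-window candidates lose to in-window ones
  oow <- ed; oow$within_window <- c(FALSE, TRUE)
  expect_identical(score_source_by_reference_shift(oow)$preferred,
                   c(FALSE, TRUE))
})

test_that("herbal origin overlays from herb-plasma detections", {
  design <- make_design(paste0("S", 1:2), c(1, 2), n_mock = 0,
                        extract = TRUE, herbs = TRUE)
  peaks <- make_peaks(c("N1", "N2", "N3"), c(300, 400, 500), c(5, 6, 7))
  m <- matrix(NA_real_, 3, nrow(design),
              dimnames = list(peaks$peak_id, design$sample_id))
  m[, paste0("S", 1:2, "_t1")] <- 1e4
  m["N1", "RAT_licorice"] <- 5e3
  m["N2", c("RAT_licorice", "RAT_cinnamon")] <- 5e3
  m["N1", "EXTRACT1"] <- 2e4
  tab <- feature_table(peaks, m)
  nodes <- data.frame(node_id = peaks$peak_id, members = peaks$peak_id,
                      neutral_mass = peaks$neutral_mass, rt = peaks$rt)
  net <- conjugation_network(nodes)
  expect_message(net <- overlay_origin(net, tab, design), "multi-origin")
  expect_equal(net$nodes$origin, c("licorice", "cinnamon,licorice", ""))
  expect_identical(net$nodes$in_extract, c(TRUE, FALSE, FALSE))
  expect_identical(net$nodes$in_plasma, c(TRUE, TRUE, TRUE))
})

test_that("subnetworks are components over within-window edges", {
  nodes <- data.frame(node_id = c("a", "b", "c", "d", "e"),
                      neutral_mass = c(100, 150, 200, 400, 480),
                      rt = 1:5)
  ed <- rbind(
    data.frame(source = "a", target = "b", reaction = "sulfation",
               rt_shift = -1, within_window = TRUE),
    data.frame(source = "b", target = "c", reaction = "sulfation",
               rt_shift = -1, within_window = TRUE),
    data.frame(source = "d", target = "e", reaction = "sulfation",
               rt_shift = 2, within_window = FALSE))
  net <- extract_subnetworks(conjugation_network(nodes, ed))
  lab <- setNames(net$nodes$subnetwork, net$nodes$node_id)
  # a-b-c is the biggest component: labelled A; d and e are singletons
  expect_equal(unname(lab[c("a", "b", "c")]), rep("A", 3))
  expect_false(lab[["d"]] == lab[["e"]])
  # edgeless network: one component per node
  net2 <- extract_subnetworks(conjugation_network(nodes))
  expect_equal(length(unique(net2$nodes$subnetwork)), 5)
  # dropping within-window edges never decreases the component count
  ed3 <- ed; ed3$within_window <- FALSE
  net3 <- extract_subnetworks(conjugation_network(nodes, ed3))
  expect_gte(length(unique(net3$nodes$subnetwork)),
             length(unique(net$nodes$subnetwork)))
})

test_that("network summary reports the plasma-only fraction", {
  nodes <- data.frame(node_id = sprintf("n%02d", 1:10),
                      neutral_mass = runif(10, 100, 500), rt = 1:10,
                      in_extract = rep(c(TRUE, FALSE), c(3, 7)))
  s <- network_summary(conjugation_network(nodes))
  expect_equal(s$percent_plasma_only, 70)
})
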