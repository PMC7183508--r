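# Two-step differential peak filtration selecting administration-
# dependent peaks, and duplicate-ion merging into metabolite groups.

#' Filtration parameters
#'
#' @param min_samples_detected Minimum number of samples (any class) a
#'   peak must be detected in (default 2).
#' @param min_ion_count Minimum of the peak's maximum post-dose
#'   intensity (default 1000 counts).
#' @param post_fraction A peak must be detected in strictly more than
#'   this fraction of subjects at at least one post timepoint
#'   (default 0.5, i.e. a strict majority).
#' @param rt_merge_tol RT tolerance (minutes) for duplicate-ion and
#'   co-elution merging (default 0.2).
#' @param merge_exceptions List of length-2 character vectors (peak or
#'   node id pairs) that must never merge, e.g. ephedrine and
#'   pseudoephedrine which co-elute at the same mass.
#' @return List of class `filtration_params`.
#' @export
filtration_params <- function(min_samples_detected = 2,
                              min_ion_count = 1000,
                              post_fraction = 0.5,
                              rt_merge_tol = 0.2,
                              merge_exceptions = list()) {
  stopifnot(min_samples_detected > 0, min_ion_count > 0,
            post_fraction > 0, post_fraction <= 1, rt_merge_tol > 0)
  structure(list(min_samples_detected = min_samples_detected,
                 min_ion_count = min_ion_count,
                 post_fraction = post_fraction,
                 rt_merge_tol = rt_merge_tol,
                 merge_exceptions = merge_exceptions),
            class = "filtration_params")
}

RULE_NAMES <- c("min_samples_detected", "not_in_mock", "not_in_pre",
                "post_majority", "min_ion_count")

#' Select administration-dependent candidate peaks
#'
#' A peak is kept iff, in order: (i) it is detected in at least
#' `min_samples_detected` samples overall; (ii) it is never detected in
#' any mock (solvent blank) sample; (iii) it is never detected in any
#' pre-administration sample of any subject; (iv) at at least one post
#' timepoint it is detected in strictly more than `post_fraction` of
#' subjects; (v) its maximum intensity across post samples is at least
#' `min_ion_count`. The first failing rule is recorded per peak in the
#' report, which replaces manual chromatogram curation with a
#' machine-readable audit trail.
#'
#' If a sample class required by a rule is absent from the design (e.g.
#' no mock samples were run), that rule is skipped with a warning and
#' noted in the report.
#'
#' @param table A [feature_table()].
#' @param design A [sample_design()] covering all samples in the table.
#' @param params A [filtration_params()].
#' @return List with `kept` (character vector of peak ids, sorted) and
#'   `report` (a `filtration_report`: per-peak status and first failing
#'   rule, per-rule exclusion counts, skipped rules).
#' @export
filter_candidates <- function(table, design, params = filtration_params()) {
  stopifnot(inherits(table, "feature_table"))
  design <- sample_design(as.data.frame(design))
  missing_samples <- setdiff(table$sample_ids, design$sample_id)
  if (length(missing_samples))
    stop("design does not cover sample(s): ",
         paste(missing_samples, collapse = ", "))
  ord <- order(table$peaks$peak_id)
  ids <- table$peaks$peak_id[ord]
  det <- !is.na(table$intensity[ord, , drop = FALSE]) &
    table$intensity[ord, , drop = FALSE] > 0
  inten <- table$intensity[ord, , drop = FALSE]
  cls <- design$class[match(colnames(det), design$sample_id)]

  skipped <- character()
  n <- length(ids)
  pass <- matrix(TRUE, n, length(RULE_NAMES),
                 dimnames = list(ids, RULE_NAMES))

  pass[, "min_samples_detected"] <-
    rowSums(det) >= params$min_samples_detected

  mock_cols <- cls == "mock"
  if (!any(mock_cols)) {
    warning("no mock samples in design; mock-exclusion rule skipped")
    skipped <- c(skipped, "not_in_mock")
  } else {
    pass[, "not_in_mock"] <- rowSums(det[, mock_cols, drop = FALSE]) == 0
  }

  pre_cols <- cls == "pre"
  if (!any(pre_cols)) {
    warning("no pre-administration samples in design; pre-exclusion rule skipped")
    skipped <- c(skipped, "not_in_pre")
  } else {
    pass[, "not_in_pre"] <- rowSums(det[, pre_cols, drop = FALSE]) == 0
  }

  post_cols <- which(cls == "post")
  if (!length(post_cols)) {
    warning("no post samples in design; majority and ion-count rules skipped")
    skipped <- c(skipped, "post_majority", "min_ion_count")
  } else {
    post_design <- design[match(colnames(det)[post_cols], design$sample_id), ]
    tps <- unique(post_design$timepoint)
    majority <- rep(FALSE, n)
    for (tp in tps) {
      jj <- post_cols[post_design$timepoint == tp]
      n_subj <- length(unique(post_design$subject[post_design$timepoint == tp]))
      det_subj <- det[, jj, drop = FALSE]
      # count distinct subjects detected at this timepoint
      subj <- post_design$subject[post_design$timepoint == tp]
      counts <- sapply(unique(subj), function(s)
        rowSums(det_subj[, subj == s, drop = FALSE]) > 0)
      if (is.null(dim(counts))) counts <- matrix(counts, nrow = n)
      majority <- majority | (rowSums(counts) > params$post_fraction * n_subj)
    }
    pass[, "post_majority"] <- majority
    post_max <- apply(inten[, post_cols, drop = FALSE], 1,
                      function(x) if (all(is.na(x))) 0 else max(x, na.rm = TRUE))
    pass[, "min_ion_count"] <- post_max >= params$min_ion_count
  }

  first_fail <- apply(pass, 1, function(p)
    if (all(p)) NA_character_ else RULE_NAMES[which(!p)[1]])
  kept <- ids[is.na(first_fail)]
  counts <- base::table(factor(first_fail, levels = RULE_NAMES))
  report <- structure(list(
    peaks = data.frame(peak_id = ids,
                       status = ifelse(is.na(first_fail), "kept", "excluded"),
                       first_failing_rule = first_fail,
                       stringsAsFactors = FALSE),
    counts = c(kept = length(kept), as.vector(counts)) |>
      stats::setNames(c("kept", RULE_NAMES)),
    skipped_rules = skipped
  ), class = "filtration_report")
  list(kept = kept, report = report)
}

#' @export
print.filtration_report <- function(x, ...) {
  cat("filtration_report:", sum(x$peaks$status == "kept"), "kept,",
      sum(x$peaks$status == "excluded"), "excluded\n")
  cat("  exclusions by first failing rule:\n")
  for (r in RULE_NAMES)
    cat(sprintf("    %-22s %d\n", r, x$counts[[r]]))
  if (length(x$skipped_rules))
    cat("  skipped rules:", paste(x$skipped_rules, collapse = ", "), "\n")
  invisible(x)
}

#' Merge duplicate ion forms into metabolite groups
#'
#' Peaks that are alternate ion forms of the same metabolite (opposite
#' ion mode at the same neutral mass, or a user-declared adduct or
#' in-source-fragment relation) are collapsed into one group when they
#' co-elute within `rt_tol` minutes. Pairs listed in `exceptions` never
#' collapse. The group's representative mass/RT are those of the most
#' intense member peak; the group id joins member ids with `/` (e.g.
#' `P8722/N6061`).
#'
#' @param table A [feature_table()].
#' @param kept Peak ids to group (default: all peaks).
#' @param rt_tol Co-elution tolerance, minutes (default 0.2).
#' @param ppm Neutral-mass agreement tolerance (default 5).
#' @param relations Optional data frame (`peak_a`, `peak_b`) of declared
#'   relations (adduct pairs, in-source fragments) merged regardless of
#'   mass agreement, still subject to `rt_tol`.
#' @param exceptions List of length-2 character vectors of peak ids that
#'   must never merge.
#' @return Data frame of class `metabolite_groups`: `group_id`,
#'   `members` ("/"-joined), `n_members`, `neutral_mass`, `rt`,
#'   `ion_modes`, `representative`.
#' @export
merge_duplicate_ions <- function(table, kept = table$peaks$peak_id,
                                 rt_tol = 0.2, ppm = 5, relations = NULL,
                                 exceptions = list()) {
  pk <- table$peaks[table$peaks$peak_id %in% kept, , drop = FALSE]
  pk <- pk[order(pk$peak_id), , drop = FALSE]
  n <- nrow(pk)
  max_int <- apply(table$intensity[pk$peak_id, , drop = FALSE], 1,
                   function(x) if (all(is.na(x))) 0 else max(x, na.rm = TRUE))
  links <- matrix(integer(), 0, 2)
  if (n > 1) {
    cand <- which(outer(pk$ion_mode, pk$ion_mode, "!=") &
                    upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    if (nrow(cand)) {
      i <- cand[, 1]; j <- cand[, 2]
      dm_ok <- abs(pk$neutral_mass[i] - pk$neutral_mass[j]) /
        pmax(pk$neutral_mass[i], pk$neutral_mass[j]) * 1e6 <= ppm
      rt_ok <- abs(pk$rt[i] - pk$rt[j]) <= rt_tol
      links <- cand[dm_ok & rt_ok, , drop = FALSE]
    }
  }
  if (!is.null(relations) && nrow(relations)) {
    ia <- match(relations$peak_a, pk$peak_id)
    ib <- match(relations$peak_b, pk$peak_id)
    ok <- !is.na(ia) & !is.na(ib) &
      abs(pk$rt[ia] - pk$rt[ib]) <= rt_tol
    links <- rbind(links, cbind(ia[ok], ib[ok]))
  }
  if (length(exceptions) && nrow(links)) {
    keypair <- function(a, b) paste(pmin(a, b), pmax(a, b))
    excl <- vapply(exceptions, function(p) keypair(p[1], p[2]), "")
    lk <- keypair(pk$peak_id[links[, 1]], pk$peak_id[links[, 2]])
    links <- links[!lk %in% excl, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(
    matrix(pk$peak_id[t(links)], ncol = 2, byrow = TRUE), directed = FALSE)
  g <- igraph::add_vertices(
    g, length(setdiff(pk$peak_id, igraph::V(g)$name)),
    name = setdiff(pk$peak_id, igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  comp <- comp[pk$peak_id]
  groups <- split(seq_len(n), comp)
  rows <- lapply(groups, function(idx) {
    rep_i <- idx[which.max(max_int[idx])]
    members <- sort(pk$peak_id[idx])
    data.frame(group_id = paste(members, collapse = "/"),
               members = paste(members, collapse = "/"),
               n_members = length(idx),
               neutral_mass = pk$neutral_mass[rep_i],
               rt = pk$rt[rep_i],
               ion_modes = paste(sort(unique(pk$ion_mode[idx])),
                                 collapse = "/"),
               representative = pk$peak_id[rep_i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$group_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("metabolite_groups", "data.frame")
  out
}
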