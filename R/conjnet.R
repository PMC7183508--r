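# Mass-difference conjugation network: delta-matched pair finding,
# RT-shift windows, co-elution merging, calibrant-based source scoring,
# herbal-origin overlay and subnetwork extraction.

#' Construct a conjugation network
#'
#' Container pairing a node table (metabolites) with an edge table
#' (putative biotransformations). Normally produced by
#' [build_conjugation_network()]; the constructor validates referential
#' integrity.
#'
#' @param nodes Data frame with at least `node_id`, `neutral_mass`,
#'   `rt`; optional `members`, `label`, `origin`, `in_extract`,
#'   `in_plasma`, `msi_level`, `subnetwork`.
#' @param edges Data frame with at least `source`, `target`, `reaction`;
#'   optional `mass_residual_ppm`, `rt_shift`, `within_window`,
#'   `shift_score`, `preferred`, `ambiguous`, `evidence`.
#' @return Object of class `conjugation_network`.
#' @export
conjugation_network <- function(nodes, edges = empty_edges()) {
  stopifnot(is.data.frame(nodes))
  if (!"node_id" %in% names(nodes)) stop("nodes need a node_id column")
  if (anyDuplicated(nodes$node_id)) stop("duplicated node_id")
  if (nrow(edges)) {
    bad <- setdiff(c(edges$source, edges$target), nodes$node_id)
    if (length(bad))
      stop("edges reference unknown node(s): ", paste(bad, collapse = ", "))
  }
  structure(list(nodes = nodes, edges = edges),
            class = "conjugation_network")
}

empty_edges <- function() {
  data.frame(source = character(), target = character(),
             reaction = character(), delta_mass = numeric(),
             mass_residual_ppm = numeric(), rt_shift = numeric(),
             within_window = logical(), shift_score = numeric(),
             preferred = logical(), ambiguous = logical(),
             evidence = character(), stringsAsFactors = FALSE)
}

#' @export
print.conjugation_network <- function(x, ...) {
  cat("conjugation_network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges")
  if (nrow(x$edges))
    cat(" (", sum(x$edges$within_window), "within RT window)")
  cat("\n")
  if ("subnetwork" %in% names(x$nodes) && any(!is.na(x$nodes$subnetwork)))
    cat("  subnetworks:",
        paste(names(base::table(x$nodes$subnetwork)), collapse = ", "), "\n")
  invisible(x)
}

#' Find reaction-delta-matched node pairs
#'
#' Exhaustively tests every unordered node pair against every reaction
#' delta (equivalent to the O(n^2) brute force): a pair is an edge
#' candidate when the absolute neutral-mass difference matches the
#' delta within `ppm` of the heavier mass. Gain reactions are directed
#' lighter to heavier; loss reactions (deglycosylation) heavier to
#' lighter. `rt_shift` is target RT minus source RT.
#'
#' @param nodes Data frame with `node_id`, `neutral_mass`, `rt` (e.g.
#'   [merge_duplicate_ions()] output with `group_id` renamed, or any
#'   table of metabolites).
#' @param reactions A `reaction_table` (default
#'   [default_reaction_table()]).
#' @param ppm Mass tolerance (default 5).
#' @return Edge data frame (see [conjugation_network()]); RT windows are
#'   not yet applied (`within_window` is NA until [apply_rt_windows()]).
#' @export
find_difference_pairs <- function(nodes, reactions = default_reaction_table(),
                                  ppm = 5) {
  nodes <- as_node_table(nodes)
  n <- nrow(nodes)
  if (n < 2) return(empty_edges())
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  # orient lo -> hi by mass
  swap <- nodes$neutral_mass[i] > nodes$neutral_mass[j]
  lo <- ifelse(swap, j, i); hi <- ifelse(swap, i, j)
  m_lo <- nodes$neutral_mass[lo]; m_hi <- nodes$neutral_mass[hi]
  out <- list()
  for (r in seq_len(nrow(reactions))) {
    res <- ppm_residual(m_lo, m_hi, reactions$delta_mass[r])
    hit <- abs(res) <= ppm
    if (!any(hit)) next
    gain <- reactions$direction[r] == "gain"
    src <- if (gain) lo[hit] else hi[hit]
    tgt <- if (gain) hi[hit] else lo[hit]
    out[[length(out) + 1L]] <- data.frame(
      source = nodes$node_id[src],
      target = nodes$node_id[tgt],
      reaction = reactions$name[r],
      delta_mass = reactions$delta_mass[r],
      mass_residual_ppm = res[hit],
      rt_shift = nodes$rt[tgt] - nodes$rt[src],
      within_window = NA,
      shift_score = NA_real_,
      preferred = FALSE,
      ambiguous = FALSE,
      evidence = "",
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) return(empty_edges())
  ed <- do.call(rbind, out)
  ed <- ed[order(ed$source, ed$target, ed$reaction), , drop = FALSE]
  rownames(ed) <- NULL
  ed
}

# Accept metabolite_groups or any data frame with node columns.
as_node_table <- function(nodes) {
  nodes <- as.data.frame(nodes)
  if (!"node_id" %in% names(nodes) && "group_id" %in% names(nodes))
    nodes$node_id <- nodes$group_id
  for (col in c("node_id", "neutral_mass", "rt"))
    if (!col %in% names(nodes))
      stop("node table missing column '", col, "'")
  nodes
}

#' Flag edges by retention-time-shift window
#'
#' Sets `within_window` to TRUE where the edge's RT shift (target minus
#' source) lies inside the reaction's window, boundaries closed.
#' Out-of-window edges are retained but flagged, so the audit trail
#' survives to export.
#'
#' @param edges Edge data frame from [find_difference_pairs()].
#' @param reactions The `reaction_table` supplying the windows.
#' @return The edge data frame with `within_window` filled in.
#' @export
apply_rt_windows <- function(edges, reactions = default_reaction_table()) {
  if (!nrow(edges)) { edges$within_window <- logical(0); return(edges) }
  r <- match(edges$reaction, reactions$name)
  if (anyNA(r))
    stop("edge reaction(s) not in reaction table: ",
         paste(unique(edges$reaction[is.na(r)]), collapse = ", "))
  edges$within_window <- edges$rt_shift >= reactions$rt_min[r] &
    edges$rt_shift <= reactions$rt_max[r]
  edges
}

#' Merge co-eluting nodes of equal mass
#'
#' Nodes whose neutral masses agree within `ppm` and whose RTs differ by
#' at most `rt_tol` minutes merge (transitive closure over pairwise
#' links, processed in ascending RT order so the result is independent
#' of input order). Exception pairs - such as ephedrine and
#' pseudoephedrine, isobaric stereoisomers that nearly co-elute - never
#' merge.
#'
#' @param nodes Node data frame (`node_id`, `neutral_mass`, `rt`,
#'   optional `members`).
#' @param rt_tol Minutes (default 0.2).
#' @param ppm Mass tolerance (default 5).
#' @param exceptions List of length-2 character vectors of node ids (or
#'   member peak ids) that must never merge.
#' @return Merged node data frame; merged ids join with `/`.
#' @export
merge_coeluting_nodes <- function(nodes, rt_tol = 0.2, ppm = 5,
                                  exceptions = list()) {
  nodes <- as_node_table(nodes)
  nodes <- nodes[order(nodes$rt, nodes$node_id), , drop = FALSE]
  n <- nrow(nodes)
  if (n < 2) { rownames(nodes) <- NULL; return(nodes) }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  ok <- abs(nodes$neutral_mass[i] - nodes$neutral_mass[j]) /
    pmax(nodes$neutral_mass[i], nodes$neutral_mass[j]) * 1e6 <= ppm &
    abs(nodes$rt[i] - nodes$rt[j]) <= rt_tol
  links <- pairs[ok, , drop = FALSE]
  if (length(exceptions) && nrow(links)) {
    touches <- function(id, p) {
      parts <- strsplit(id, "/", fixed = TRUE)[[1]]
      p %in% parts || p == id
    }
    drop <- vapply(seq_len(nrow(links)), function(k) {
      a <- nodes$node_id[links[k, 1]]; b <- nodes$node_id[links[k, 2]]
      any(vapply(exceptions, function(ex) {
        (touches(a, ex[1]) && touches(b, ex[2])) ||
          (touches(a, ex[2]) && touches(b, ex[1]))
      }, logical(1)))
    }, logical(1))
    links <- links[!drop, , drop = FALSE]
  }
  memb <- seq_len(n)
  if (nrow(links)) {
    g <- igraph::graph_from_edgelist(cbind(links[, 1], links[, 2]),
                                     directed = FALSE)
    g <- igraph::add_vertices(g, n - igraph::gorder(g))
    memb <- igraph::components(g)$membership[seq_len(n)]
  }
  rows <- lapply(split(seq_len(n), memb), function(idx) {
    out <- nodes[idx[1], , drop = FALSE]  # lowest RT is representative
    ids <- sort(unlist(strsplit(nodes$node_id[idx], "/", fixed = TRUE)))
    out$node_id <- paste(ids, collapse = "/")
    if ("members" %in% names(nodes))
      out$members <- paste(sort(unlist(
        strsplit(nodes$members[idx], "/", fixed = TRUE))), collapse = "/")
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$node_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank candidate sources of a conjugate by calibrant RT shift
#'
#' When several nodes could be the source of the same conjugate (e.g.
#' two isomeric aglycones both one sulfation delta below it), the
#' observed RT shift of each candidate edge is compared to the expected
#' shift of the reaction, calibrated on a reference compound (defaults:
#' 7-hydroxycoumarin, sulfation -1.4 min, glucuronidation -1.9 min).
#' `shift_score = |rt_shift - reference_shift|`; for each (target,
#' reaction) group the lowest-scoring within-window edge is marked
#' `preferred` (ties are all retained and flagged `ambiguous`).
#' Reactions without a configured reference shift are left unscored.
#'
#' @param edges Edge data frame with `within_window` set.
#' @param reactions `reaction_table` carrying `reference_shift`.
#' @return Edge data frame with `shift_score`, `preferred`, `ambiguous`
#'   filled in.
#' @export
score_source_by_reference_shift <- function(edges,
                                            reactions = default_reaction_table()) {
  if (!nrow(edges)) return(edges)
  r <- match(edges$reaction, reactions$name)
  ref <- reactions$reference_shift[r]
  edges$shift_score <- abs(edges$rt_shift - ref)
  edges$preferred <- FALSE
  edges$ambiguous <- FALSE
  grp <- paste(edges$target, edges$reaction)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) == 1L) { edges$preferred[idx] <- TRUE; next }
    # prefer within-window candidates when any exist
    pool <- idx[which(edges$within_window[idx])]
    if (!length(pool)) pool <- idx
    sc <- edges$shift_score[pool]
    if (all(is.na(sc))) next  # no reference shift for this reaction
    best <- min(sc, na.rm = TRUE)
    winners <- pool[!is.na(sc) & sc <= best + 1e-9]
    edges$preferred[winners] <- TRUE
    if (length(winners) > 1L) edges$ambiguous[winners] <- TRUE
  }
  edges
}

#' Overlay herbal origin and sample-type presence onto a network
#'
#' For each node, `origin` is the set of herbs whose herb-plasma (rat)
#' samples contain any member peak; `in_extract` / `in_plasma` flag
#' detection in the extract sample and in human pre/post plasma.
#' Multi-origin nodes are retained and flagged rather than resolved.
#'
#' @param network A `conjugation_network` whose node `members` reference
#'   peak ids of `table`.
#' @param table The [feature_table()].
#' @param design The [sample_design()].
#' @return The network with `origin`, `in_extract`, `in_plasma` set on
#'   nodes, and a component-level origin on `subnetwork_origin` if
#'   subnetworks are present.
#' @export
overlay_origin <- function(network, table, design) {
  nd <- network$nodes
  det <- !is.na(table$intensity) & table$intensity > 0
  cls <- design$class[match(colnames(det), design$sample_id)]
  herb <- design$herb[match(colnames(det), design$sample_id)]
  member_list <- strsplit(if ("members" %in% names(nd)) nd$members else
    nd$node_id, "/", fixed = TRUE)
  node_det <- function(cols, members) {
    members <- intersect(members, rownames(det))
    if (!length(members) || !any(cols)) return(FALSE)
    any(det[members, cols, drop = FALSE])
  }
  nd$origin <- vapply(member_list, function(m) {
    hs <- Filter(function(h) node_det(cls == "herb_plasma" &
                                        !is.na(herb) & herb == h, m), HERBS)
    paste(hs, collapse = ",")
  }, "")
  nd$in_extract <- vapply(member_list, function(m)
    node_det(cls == "extract", m), logical(1))
  nd$in_plasma <- vapply(member_list, function(m)
    node_det(cls %in% c("pre", "post"), m), logical(1))
  multi <- lengths(strsplit(nd$origin, ",", fixed = TRUE)) > 1
  if (any(multi))
    message(sum(multi), " node(s) detected for multiple herbs (multi-origin)")
  network$nodes <- nd
  network
}

#' Partition a network into subnetworks
#'
#' Connected components over within-window edges (out-of-window edges do
#' not connect). Components are labelled `A`, `B`, ... deterministically
#' by descending size, then ascending smallest member mass.
#'
#' @param network A `conjugation_network`.
#' @return The network with a `subnetwork` label per node.
#' @export
extract_subnetworks <- function(network) {
  nd <- network$nodes
  ed <- network$edges
  keep <- if (nrow(ed)) ed[!is.na(ed$within_window) & ed$within_window, ,
                           drop = FALSE] else ed
  g <- igraph::graph_from_data_frame(
    if (nrow(keep)) keep[, c("source", "target")] else
      data.frame(from = character(), to = character()),
    directed = FALSE,
    vertices = data.frame(name = nd$node_id))
  memb <- igraph::components(g)$membership[nd$node_id]
  comp_ids <- unique(memb)
  size <- vapply(comp_ids, function(cid) sum(memb == cid), 0L)
  min_mass <- vapply(comp_ids, function(cid)
    min(nd$neutral_mass[memb == cid]), 0)
  ord <- order(-size, min_mass)
  labels <- component_labels(length(comp_ids))
  lab_of <- stats::setNames(labels, comp_ids[ord])
  nd$subnetwork <- unname(lab_of[as.character(memb)])
  network$nodes <- nd
  network
}

# A, B, ..., Z, AA, AB, ... labels.
component_labels <- function(n) {
  if (n <= 26) return(LETTERS[seq_len(n)])
  c(LETTERS, as.vector(outer(LETTERS, LETTERS,
                             function(a, b) paste0(a, b))))[seq_len(n)]
}

#' Build a conjugation network from metabolite groups
#'
#' Convenience wrapper chaining [merge_coeluting_nodes()],
#' [find_difference_pairs()], [apply_rt_windows()],
#' [score_source_by_reference_shift()] and [extract_subnetworks()]; if
#' `table` and `design` are supplied, [overlay_origin()] runs as well.
#'
#' @param groups Node table ([merge_duplicate_ions()] output or any data
#'   frame with `node_id`/`group_id`, `neutral_mass`, `rt`).
#' @param reactions `reaction_table` (default [default_reaction_table()]).
#' @param ppm Mass tolerance (default 5).
#' @param rt_merge_tol Co-elution merge tolerance, minutes (default 0.2).
#' @param exceptions Never-merge id pairs (see [merge_coeluting_nodes()]).
#' @param table,design Optional feature table and design for origin
#'   overlay.
#' @return A `conjugation_network` with scored, windowed edges and
#'   subnetwork labels.
#' @export
build_conjugation_network <- function(groups,
                                      reactions = default_reaction_table(),
                                      ppm = 5, rt_merge_tol = 0.2,
                                      exceptions = list(),
                                      table = NULL, design = NULL) {
  nodes <- as_node_table(groups)
  nodes <- merge_coeluting_nodes(nodes, rt_tol = rt_merge_tol, ppm = ppm,
                                 exceptions = exceptions)
  edges <- find_difference_pairs(nodes, reactions, ppm)
  edges <- apply_rt_windows(edges, reactions)
  edges <- score_source_by_reference_shift(edges, reactions)
  net <- conjugation_network(nodes, edges)
  if (!is.null(table) && !is.null(design))
    net <- overlay_origin(net, table, design)
  extract_subnetworks(net)
}

#' Summarize a conjugation network
#'
#' Counts nodes, edges, within-window edges and subnetworks, and the
#' percentage of nodes detected only in plasma (i.e. converted in vivo,
#' not present in the administered extract) when presence flags exist.
#'
#' @param network A `conjugation_network`.
#' @return Named list; notably `percent_plasma_only` when `in_extract`
#'   is available.
#' @export
network_summary <- function(network) {
  nd <- network$nodes
  out <- list(n_nodes = nrow(nd), n_edges = nrow(network$edges),
              n_within_window = if (nrow(network$edges))
                sum(network$edges$within_window, na.rm = TRUE) else 0L,
              n_subnetworks = if ("subnetwork" %in% names(nd))
                length(unique(nd$subnetwork)) else NA_integer_)
  if ("in_extract" %in% names(nd)) {
    out$n_in_extract <- sum(nd$in_extract)
    out$percent_plasma_only <- 100 * mean(!nd$in_extract)
  }
  out
}
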