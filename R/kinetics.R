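# Kinetic time-course analysis: metabolite-by-(subject, timepoint)
# matrix, half-minimum imputation, auto-scaling, Ward clustering, and
# conjugate/source co-clustering checks.

#' Build a kinetics matrix from a feature table
#'
#' Rows are metabolite nodes (or raw peaks when `groups` is NULL);
#' columns are the plasma samples (classes pre and post), ordered by
#' subject then timepoint (pre is placed at timepoint 0). Values are
#' the representative member peak's intensities; not-detected stays
#' `NA` until [impute_half_min()].
#'
#' @param table A [feature_table()].
#' @param design A [sample_design()].
#' @param groups Optional `metabolite_groups` (or node table with
#'   `node_id`/`group_id` and `representative`); defaults to one row
#'   per peak.
#' @param values Optional externally measured values (e.g. targeted
#'   concentrations): a matrix with rownames matching node ids whose
#'   rows override the intensities.
#' @return Numeric matrix with attribute `design` (the column design).
#' @export
kinetics_matrix <- function(table, design, groups = NULL, values = NULL) {
  design <- sample_design(as.data.frame(design))
  keep <- design[design$class %in% c("pre", "post"), , drop = FALSE]
  keep$timepoint[keep$class == "pre"] <- 0
  keep <- keep[order(keep$subject, keep$timepoint, keep$sample_id), ,
               drop = FALSE]
  cols <- intersect(keep$sample_id, colnames(table$intensity))
  keep <- keep[keep$sample_id %in% cols, , drop = FALSE]
  if (is.null(groups)) {
    m <- table$intensity[, keep$sample_id, drop = FALSE]
  } else {
    groups <- as_node_table_kin(groups)
    reps <- groups$representative
    m <- table$intensity[reps, keep$sample_id, drop = FALSE]
    rownames(m) <- groups$node_id
  }
  if (!is.null(values)) {
    common <- intersect(rownames(values), rownames(m))
    m[common, ] <- values[common, colnames(m), drop = FALSE]
  }
  attr(m, "design") <- keep
  m
}

as_node_table_kin <- function(groups) {
  groups <- as.data.frame(groups)
  if (!"node_id" %in% names(groups) && "group_id" %in% names(groups))
    groups$node_id <- groups$group_id
  if (!"representative" %in% names(groups))
    stop("groups need a representative peak column")
  groups
}

#' Replace missing values with the row half-minimum
#'
#' Every missing cell of a row is set to half the minimum non-missing
#' value of that row; measured values are unchanged. A fully missing
#' row cannot be imputed and is rejected by name.
#'
#' @param m Numeric matrix with `NA` for not-detected.
#' @return The imputed matrix (no `NA` remain).
#' @examples
#' impute_half_min(rbind(a = c(10, NA, 4)))
#' @export
impute_half_min <- function(m) {
  stopifnot(is.matrix(m))
  all_na <- rowSums(!is.na(m)) == 0
  if (any(all_na))
    stop("row(s) with no non-missing value: ",
         paste(rownames(m)[all_na] %||% which(all_na), collapse = ", "))
  for (i in which(rowSums(is.na(m)) > 0)) {
    m[i, is.na(m[i, ])] <- min(m[i, ], na.rm = TRUE) / 2
  }
  m
}

#' Auto-scale a kinetics matrix
#'
#' Row-wise z-scores: subtract the row mean and divide by the row
#' sample standard deviation (n-1 denominator, as in MetaboAnalyst).
#' After scaling every row has mean 0 and standard deviation 1.
#'
#' @param m Imputed numeric matrix (no `NA`); every row must have
#'   nonzero variance.
#' @return The scaled matrix.
#' @examples
#' autoscale(rbind(a = c(1, 2, 3)))
#' @export
autoscale <- function(m) {
  stopifnot(is.matrix(m))
  if (anyNA(m)) stop("matrix must be imputed before scaling")
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  zero <- sdv == 0 | !is.finite(sdv)
  if (any(zero))
    stop("zero-variance row(s): ",
         paste(rownames(m)[zero] %||% which(zero), collapse = ", "))
  (m - mu) / sdv
}

#' Hierarchical clustering of metabolite time courses
#'
#' Agglomerative clustering with Ward's criterion on Euclidean
#' distances (`hclust` method `ward.D2`, whose merge heights are
#' non-decreasing; ties break deterministically by row order). Flat
#' labels come from cutting at `k` clusters or height `h`.
#'
#' @param m Scaled matrix (>= 2 rows).
#' @param k Number of flat clusters (optional).
#' @param h Cut height (optional, used when `k` is NULL).
#' @return List of class `kinetic_clusters`: `tree` (hclust), `labels`
#'   (named integer vector or NULL), `order` (row order along the
#'   dendrogram).
#' @export
ward_cluster <- function(m, k = NULL, h = NULL) {
  stopifnot(is.matrix(m))
  if (nrow(m) < 2) stop("clustering needs at least 2 rows")
  tree <- stats::hclust(stats::dist(m, method = "euclidean"),
                        method = "ward.D2")
  if (is.unsorted(tree$height))
    stop("internal error: non-monotone merge heights")
  labels <- if (!is.null(k)) stats::cutree(tree, k = k)
  else if (!is.null(h)) stats::cutree(tree, h = h)
  structure(list(tree = tree, labels = labels, order = tree$order),
            class = "kinetic_clusters")
}

#' @export
print.kinetic_clusters <- function(x, ...) {
  cat("kinetic_clusters:", length(x$tree$order), "rows")
  if (!is.null(x$labels))
    cat(",", length(unique(x$labels)), "flat clusters")
  cat("\n")
  invisible(x)
}

#' Conjugate/source co-clustering report
#'
#' For each within-window network edge whose endpoints both appear in
#' the clustering, reports whether source and conjugate received the
#' same flat label, plus the co-clustering fraction per reaction type.
#' Edges with an endpoint missing from the matrix are skipped with a
#' message. Microbiome products (e.g. deglycosylation) typically appear
#' hours later than their precursors and are expected not to co-cluster.
#'
#' @param clusters A `kinetic_clusters` with flat labels.
#' @param network A `conjugation_network`.
#' @return List: `edges` (per-edge data frame with `same_cluster`) and
#'   `by_reaction` (reaction, n, fraction_same).
#' @export
coclustering_report <- function(clusters, network) {
  if (is.null(clusters$labels))
    stop("clusters have no flat labels; supply k or h to ward_cluster()")
  lab <- clusters$labels
  ed <- network$edges
  ed <- ed[!is.na(ed$within_window) & ed$within_window, , drop = FALSE]
  if (!nrow(ed))
    return(list(edges = data.frame(source = character(), target = character(),
                                   reaction = character(),
                                   same_cluster = logical()),
                by_reaction = data.frame(reaction = character(), n = integer(),
                                         fraction_same = numeric())))
  known <- ed$source %in% names(lab) & ed$target %in% names(lab)
  if (any(!known))
    message(sum(!known), " edge(s) skipped: endpoint absent from matrix")
  ed <- ed[known, , drop = FALSE]
  edges <- data.frame(source = ed$source, target = ed$target,
                      reaction = ed$reaction,
                      same_cluster = lab[ed$source] == lab[ed$target],
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  by_r <- do.call(rbind, lapply(split(edges, edges$reaction), function(d)
    data.frame(reaction = d$reaction[1], n = nrow(d),
               fraction_same = mean(d$same_cluster))))
  rownames(by_r) <- NULL
  list(edges = edges, by_reaction = by_r)
}

#' Write a clustered time-course heatmap
#'
#' Simple image rendering of the scaled matrix in dendrogram order; the
#' matrix and tree remain the analysis contract, the image is a
#' convenience output.
#'
#' @param m Scaled matrix.
#' @param clusters `kinetic_clusters` for row ordering.
#' @param path PNG output path.
#' @export
write_heatmap <- function(m, clusters, path) {
  grDevices::png(path, width = 900, height = 200 + 22 * nrow(m))
  on.exit(grDevices::dev.off())
  ord <- clusters$order
  graphics::par(mar = c(6, 10, 2, 2))
  graphics::image(t(m[rev(ord), , drop = FALSE]), axes = FALSE,
                  col = grDevices::hcl.colors(51, "RdBu", rev = TRUE))
  graphics::axis(2, at = seq(0, 1, length.out = nrow(m)),
                 labels = rownames(m)[rev(ord)], las = 2, cex.axis = 0.7)
  graphics::axis(1, at = seq(0, 1, length.out = ncol(m)),
                 labels = colnames(m), las = 2, cex.axis = 0.7)
  invisible(path)
}
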