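# End-to-end pipeline: filter -> merge -> network -> evidence ->
# kinetics, with file-based configuration and a structured run log.

#' Run configuration
#'
#' Collects every tunable of the pipeline in one serializable object.
#' Precedence when loaded through [run_all()]: explicit argument >
#' config file > built-in default; every effective threshold is written
#' to the run log exactly once.
#'
#' @param table,design,msms,isotopes,standards,annotations Input paths
#'   (feature table and design are required for [run_all()]; the rest
#'   optional).
#' @param out_dir Output directory.
#' @param params A [filtration_params()].
#' @param reactions A `reaction_table` or a path readable by
#'   [read_reaction_table()].
#' @param ppm Mass tolerance (default 5).
#' @param rt_merge_tol Co-elution merge tolerance, minutes (default 0.2).
#' @param exceptions Never-merge id pairs.
#' @param shift_tol Calibrant RT-shift agreement tolerance, minutes
#'   (default 0.5).
#' @param frag_tol MS/MS fragment tolerance, Da (default 0.5).
#' @param k Flat cluster count for the kinetics stage (default 6).
#' @return List of class `run_config`.
#' @export
run_config <- function(table = NULL, design = NULL, msms = NULL,
                       isotopes = NULL, standards = NULL,
                       annotations = NULL, out_dir = "dacmet_out",
                       params = filtration_params(),
                       reactions = default_reaction_table(), ppm = 5,
                       rt_merge_tol = 0.2, exceptions = list(),
                       shift_tol = 0.5, frag_tol = 0.5, k = 6) {
  if (is.character(reactions)) reactions <- read_reaction_table(reactions)
  structure(list(table = table, design = design, msms = msms,
                 isotopes = isotopes, standards = standards,
                 annotations = annotations, out_dir = out_dir,
                 params = params, reactions = reactions, ppm = ppm,
                 rt_merge_tol = rt_merge_tol, exceptions = exceptions,
                 shift_tol = shift_tol, frag_tol = frag_tol, k = k),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys mirror the arguments of [run_config()]; filtration
#' thresholds sit under `filtration:`; `exceptions` is a list of
#' two-element id lists.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  fp <- do.call(filtration_params, c(y$filtration %||% list()))
  run_config(table = y$table, design = y$design, msms = y$msms,
             isotopes = y$isotopes, standards = y$standards,
             annotations = y$annotations,
             out_dir = y$out_dir %||% "dacmet_out", params = fp,
             reactions = y$reactions %||% default_reaction_table(),
             ppm = y$ppm %||% 5, rt_merge_tol = y$rt_merge_tol %||% 0.2,
             exceptions = lapply(y$exceptions %||% list(), unlist),
             shift_tol = y$shift_tol %||% 0.5,
             frag_tol = y$frag_tol %||% 0.5, k = y$k %||% 6)
}

#' Run the full annotation pipeline in memory
#'
#' Chains differential filtration, duplicate-ion merging, conjugation
#' network construction (delta matching, RT windows, calibrant
#' scoring, origin overlay, subnetworks), evidence-based MSI
#' annotation, and kinetic clustering. Deterministic: identical inputs
#' and configuration give identical results.
#'
#' @param table A [feature_table()].
#' @param design A [sample_design()].
#' @param config A [run_config()] (paths in it are ignored here).
#' @param msms,isotopes,standards,annotations Optional in-memory
#'   evidence objects (see [read_mgf()], [read_isotope_patterns()],
#'   [annotation_table()]).
#' @return List of class `dacmet_result`: `kept`, `report`, `groups`,
#'   `network`, `kinetics` (list with `matrix`, `scaled`, `clusters`,
#'   `cocluster`, possibly NULL for degenerate inputs), `config`.
#' @export
dacmet_run <- function(table, design, config = run_config(), msms = NULL,
                       isotopes = NULL, standards = NULL,
                       annotations = NULL) {
  if (nrow(table$peaks) == 0L) {
    warning("empty feature table; producing empty results")
    empty_net <- conjugation_network(
      data.frame(node_id = character(), neutral_mass = numeric(),
                 rt = numeric()))
    return(structure(list(kept = character(), report = NULL,
                          groups = NULL, network = empty_net,
                          kinetics = NULL, config = config),
                     class = "dacmet_result"))
  }
  filt <- filter_candidates(table, design, config$params)
  groups <- merge_duplicate_ions(
    table, filt$kept, rt_tol = config$params$rt_merge_tol, ppm = config$ppm,
    exceptions = c(config$exceptions, config$params$merge_exceptions))
  network <- if (nrow(groups)) {
    build_conjugation_network(groups, reactions = config$reactions,
                              ppm = config$ppm,
                              rt_merge_tol = config$rt_merge_tol,
                              exceptions = c(config$exceptions,
                                             config$params$merge_exceptions),
                              table = table, design = design)
  } else conjugation_network(data.frame(node_id = character(),
                                        neutral_mass = numeric(),
                                        rt = numeric()))
  network <- annotate_network(network, standards = standards,
                              annotations = annotations, msms = msms,
                              isotopes = isotopes, ppm = config$ppm,
                              rt_tol = config$rt_merge_tol,
                              shift_tol = config$shift_tol,
                              frag_tol = config$frag_tol)
  kin <- NULL
  if (nrow(network$nodes) >= 2) {
    # map merged node ids back to their representative member peak
    reps <- vapply(strsplit(if ("members" %in% names(network$nodes))
      network$nodes$members else network$nodes$node_id, "/", fixed = TRUE),
      function(m) {
        m <- intersect(m, rownames(table$intensity))
        mx <- apply(table$intensity[m, , drop = FALSE], 1, function(x)
          if (all(is.na(x))) 0 else max(x, na.rm = TRUE))
        m[which.max(mx)]
      }, "")
    gk <- data.frame(node_id = network$nodes$node_id, representative = reps,
                     stringsAsFactors = FALSE)
    m <- kinetics_matrix(table, design, groups = gk)
    m <- impute_half_min(m)
    keep_rows <- apply(m, 1, stats::sd) > 0
    if (sum(keep_rows) >= 2) {
      if (any(!keep_rows))
        message(sum(!keep_rows), " constant row(s) dropped before scaling: ",
                paste(rownames(m)[!keep_rows], collapse = ", "))
      z <- autoscale(m[keep_rows, , drop = FALSE])
      cl <- ward_cluster(z, k = min(config$k, nrow(z)))
      kin <- list(matrix = m, scaled = z, clusters = cl,
                  cocluster = coclustering_report(cl, network))
    }
  }
  structure(list(kept = filt$kept, report = filt$report, groups = groups,
                 network = network, kinetics = kin, config = config),
            class = "dacmet_result")
}

#' @export
print.dacmet_result <- function(x, ...) {
  cat("dacmet_result:", length(x$kept), "kept peaks")
  if (!is.null(x$groups)) cat(",", nrow(x$groups), "metabolite groups")
  cat(",", nrow(x$network$nodes), "network nodes,",
      nrow(x$network$edges), "edges\n")
  invisible(x)
}

#' Run the pipeline from files and write every artifact
#'
#' Reads the inputs named in the config, executes [dacmet_run()], and
#' writes `kept.tsv`, `report.tsv`, `net.graphml`, `net.sif`,
#' `nodes.tsv`, `edges.tsv`, `clusters.tsv`, `cocluster.tsv` and
#' `run_log.txt` into the config's output directory. Reruns on the
#' same inputs produce byte-identical outputs.
#'
#' @param config A [run_config()] with at least `table` and `design`
#'   paths set, or the path of a YAML config.
#' @return The `dacmet_result`, invisibly.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$table) || is.null(config$design))
    stop("config must name a feature table and a sample design")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  table <- stage("read_table", read_feature_table(config$table))
  design <- stage("read_design", read_sample_design(config$design))
  msms <- if (!is.null(config$msms)) stage("read_msms",
                                           read_mgf(config$msms))
  isotopes <- if (!is.null(config$isotopes))
    stage("read_isotopes", read_isotope_patterns(config$isotopes))
  standards <- if (!is.null(config$standards))
    stage("read_standards", read_annotation_table(config$standards))
  annotations <- if (!is.null(config$annotations))
    stage("read_annotations", read_annotation_table(config$annotations))

  res <- dacmet_run(table, design, config, msms = msms,
                    isotopes = isotopes, standards = standards,
                    annotations = annotations)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)
  writeLines(res$kept, outp("kept.tsv"))
  if (!is.null(res$report))
    utils::write.table(res$report$peaks, outp("report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  write_network_graphml(res$network, outp("net.graphml"))
  write_network_sif(res$network, outp("net.sif"))
  write_node_edge_tables(res$network, outp("nodes.tsv"), outp("edges.tsv"))
  if (!is.null(res$kinetics)) {
    lab <- res$kinetics$clusters$labels
    utils::write.table(data.frame(node_id = names(lab), cluster = lab),
                       outp("clusters.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(res$kinetics$cocluster$edges, outp("cocluster.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    writeLines("node_id\tcluster", outp("clusters.tsv"))
  }
  writeLines(run_log_lines(config, res), outp("run_log.txt"))
  invisible(res)
}

# One line per effective threshold; each appears exactly once.
run_log_lines <- function(config, res) {
  p <- config$params
  c(paste0("dacmet ", as.character(utils::packageVersion("dacmet"))),
    paste0("ppm_tolerance\t", config$ppm),
    paste0("min_samples_detected\t", p$min_samples_detected),
    paste0("min_ion_count\t", p$min_ion_count),
    paste0("post_fraction\t", p$post_fraction),
    paste0("rt_merge_tol\t", config$rt_merge_tol),
    paste0("shift_tol\t", config$shift_tol),
    paste0("frag_tol\t", config$frag_tol),
    paste0("cluster_k\t", config$k),
    paste0("n_reactions\t", nrow(config$reactions)),
    paste0("reactions\t",
           paste(config$reactions$name, collapse = ",")),
    paste0("kept_peaks\t", length(res$kept)),
    paste0("network_nodes\t", nrow(res$network$nodes)),
    paste0("network_edges\t", nrow(res$network$edges)))
}
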