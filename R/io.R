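# Readers and writers for every external artifact: feature tables,
# sample designs, MGF spectra, isotopologue patterns, annotation tables,
# and network exports (SIF / GraphML / node-edge TSVs).

SAMPLE_CLASSES <- c("pre", "post", "mock", "extract", "herb_plasma")
HERBS <- c("ephedra", "apricot", "cinnamon", "licorice")

#' Default adduct map
#'
#' Mass shift (Da) from neutral monoisotopic mass to singly charged ion
#' m/z: `mz = neutral_mass + shift`. Deionization inverts this.
#'
#' @return Data frame with columns `adduct`, `shift`, `ion_mode`.
#' @export
default_adducts <- function() {
  data.frame(
    adduct = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+NH4]+",
               "[M-H]-", "[M+Cl]-", "[M+FA-H]-"),
    shift = c(PROTON_MASS,
              22.98976928 - ELECTRON_MASS,
              38.96370649 - ELECTRON_MASS,
              18.03382554,
              -PROTON_MASS,
              34.96885268 + ELECTRON_MASS,
              44.99820284),
    ion_mode = c("positive", "positive", "positive", "positive",
                 "negative", "negative", "negative"),
    stringsAsFactors = FALSE
  )
}

# Normalize unicode minus signs so "[M−H]−" matches "[M-H]-".
normalize_adduct <- function(x) gsub("−", "-", x)

#' Construct an aligned feature table
#'
#' The in-memory representation of a PowerGet-style aligned peak list: a
#' data frame of peaks (id, ion mode, m/z, adduct, deionized neutral
#' mass, RT in minutes) plus a peaks-by-samples intensity matrix in
#' which `NA` means not detected (a measured zero is kept as 0).
#'
#' @param peaks Data frame with columns `peak_id`, `ion_mode`, `mz`,
#'   `adduct`, `neutral_mass`, `rt`.
#' @param intensity Numeric matrix, rows matching `peaks$peak_id`,
#'   columns named by sample id; `NA` = not detected.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(peaks, intensity) {
  stopifnot(is.data.frame(peaks), is.matrix(intensity))
  req <- c("peak_id", "ion_mode", "mz", "adduct", "neutral_mass", "rt")
  miss <- setdiff(req, names(peaks))
  if (length(miss))
    stop("peaks missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(peaks$peak_id))
    stop("duplicated peak_id: ",
         paste(unique(peaks$peak_id[duplicated(peaks$peak_id)]), collapse = ", "))
  if (nrow(intensity) != nrow(peaks))
    stop("intensity matrix has ", nrow(intensity), " rows for ",
         nrow(peaks), " peaks")
  if (is.null(colnames(intensity)))
    stop("intensity matrix must have sample ids as column names")
  if (any(intensity < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  if (any(!is.na(peaks$neutral_mass) & peaks$neutral_mass <= 0))
    stop("neutral_mass must be positive")
  if (any(peaks$rt < 0)) stop("rt must be non-negative")
  rownames(intensity) <- peaks$peak_id
  structure(list(peaks = peaks, intensity = intensity,
                 sample_ids = colnames(intensity)),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$peaks), "peaks x",
      length(x$sample_ids), "samples\n")
  cat("  ion modes:", paste(names(table(x$peaks$ion_mode)),
                            table(x$peaks$ion_mode), collapse = ", "), "\n")
  invisible(x)
}

#' Read an aligned feature table from delimited text
#'
#' The canonical layout is a TSV/CSV with header columns `peak_id`,
#' `mz`, `adduct`, `rt`, optionally `ion_mode` (otherwise inferred from
#' a leading `P`/`N` in the peak id), followed by one intensity column
#' per sample. Blank, `NA` or zero cells are recorded as not detected.
#' Neutral masses are computed from m/z and the adduct hypothesis
#' (proton 1.00728 Da; see [default_adducts()]); rows whose adduct is
#' not in the map fall back to \eqn{\pm}H for their ion mode with a
#' warning.
#'
#' @param path Delimited text file.
#' @param dialect Optional named character vector remapping canonical
#'   column names to the file's headers, e.g. `c(peak_id = "ID")`.
#' @param adducts Adduct map data frame (see [default_adducts()]).
#' @param sep Field separator; guessed from the extension by default.
#' @param zero_is_missing Treat 0 as not detected (default TRUE).
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, dialect = NULL,
                               adducts = default_adducts(),
                               sep = NULL, zero_is_missing = TRUE) {
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "")
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      j <- match(dialect[[canon]], names(raw))
      if (!is.na(j)) names(raw)[j] <- canon
    }
  }
  for (col in c("peak_id", "mz", "adduct", "rt"))
    if (!col %in% names(raw))
      stop("feature table missing required column '", col, "'")
  meta_cols <- intersect(c("peak_id", "ion_mode", "mz", "adduct", "rt"),
                         names(raw))
  sample_cols <- setdiff(names(raw), meta_cols)
  if (length(sample_cols) == 0L)
    stop("feature table has no sample intensity columns")
  peaks <- raw[meta_cols]
  peaks$peak_id <- as.character(peaks$peak_id)
  if (!"ion_mode" %in% names(peaks)) {
    pref <- substr(peaks$peak_id, 1, 1)
    if (!all(pref %in% c("P", "N")))
      stop("no ion_mode column and peak ids lack P/N prefix ",
           "(first offending row ", which(!pref %in% c("P", "N"))[1], ")")
    peaks$ion_mode <- ifelse(pref == "P", "positive", "negative")
  }
  peaks$adduct <- normalize_adduct(peaks$adduct)
  j <- match(peaks$adduct, adducts$adduct)
  unknown <- is.na(j)
  if (any(unknown)) {
    warning("unparseable adduct(s) ",
            paste(unique(peaks$adduct[unknown]), collapse = ", "),
            "; assuming +/-H for the peak's ion mode")
    fallback <- ifelse(peaks$ion_mode == "positive", PROTON_MASS, -PROTON_MASS)
  }
  shift <- adducts$shift[j]
  if (any(unknown)) shift[unknown] <- fallback[unknown]
  peaks$neutral_mass <- peaks$mz - shift
  mode_of_adduct <- adducts$ion_mode[j]
  bad_mode <- !unknown & mode_of_adduct != peaks$ion_mode
  if (any(bad_mode))
    stop("ion_mode inconsistent with adduct sign at row ",
         which(bad_mode)[1], " (peak ", peaks$peak_id[which(bad_mode)[1]], ")")
  intensity <- as.matrix(raw[sample_cols])
  mode(intensity) <- "numeric"
  if (zero_is_missing) intensity[!is.na(intensity) & intensity == 0] <- NA
  peaks <- peaks[c("peak_id", "ion_mode", "mz", "adduct", "neutral_mass", "rt")]
  feature_table(peaks, intensity)
}

#' Write a feature table to TSV
#'
#' Inverse of [read_feature_table()]; not-detected cells are written as
#' empty fields. Full-precision intensities round-trip bit-for-bit.
#'
#' @param table A [feature_table()].
#' @param path Output path.
#' @export
write_feature_table <- function(table, path) {
  m <- table$intensity
  df <- cbind(table$peaks[c("peak_id", "ion_mode", "mz", "adduct", "rt")],
              as.data.frame(m, check.names = FALSE))
  utils::write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a sample-design sheet
#'
#' TSV/CSV with columns `sample_id`, `subject`, `class`
#' (pre/post/mock/extract/herb_plasma), `timepoint` (hours, required for
#' post samples) and `herb` (required for herb_plasma samples).
#'
#' @param path Delimited text file.
#' @return A validated `sample_design` data frame.
#' @export
read_sample_design <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  sample_design(df)
}

#' Validate a sample design
#'
#' @param df Data frame with columns `sample_id`, `subject`, `class`,
#'   and optionally `timepoint` (hours) and `herb`.
#' @return The validated data frame with class `sample_design`.
#' @export
sample_design <- function(df) {
  for (col in c("sample_id", "subject", "class"))
    if (!col %in% names(df))
      stop("sample design missing required column '", col, "'")
  if (!"timepoint" %in% names(df)) df$timepoint <- NA_real_
  if (!"herb" %in% names(df)) df$herb <- NA_character_
  df$timepoint <- as.numeric(df$timepoint)
  df$herb[!is.na(df$herb) & !nzchar(df$herb)] <- NA_character_
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in design")
  bad <- !df$class %in% SAMPLE_CLASSES
  if (any(bad))
    stop("unknown sample class '", df$class[which(bad)[1]], "' at row ",
         which(bad)[1])
  i <- df$class == "herb_plasma" & is.na(df$herb)
  if (any(i)) stop("herb_plasma sample without herb at row ", which(i)[1])
  i <- df$class == "post" & is.na(df$timepoint)
  if (any(i)) stop("post sample without timepoint at row ", which(i)[1])
  bad_herb <- !is.na(df$herb) & !df$herb %in% HERBS
  if (any(bad_herb))
    stop("unknown herb '", df$herb[which(bad_herb)[1]], "' at row ",
         which(bad_herb)[1])
  class(df) <- c("sample_design", "data.frame")
  df
}

#' Union of two aligned feature tables
#'
#' Merges two feature tables given an alignment of matched peak pairs
#' (e.g. plasma peaks vs extract peaks matched by the upstream aligner).
#' Matched pairs collapse to the peak from `a`; intensities from both
#' tables are carried over (samples must not overlap). The resulting
#' peak count satisfies inclusion-exclusion:
#' `|a| + |b| - nrow(alignment)`.
#'
#' @param a,b [feature_table()] objects with disjoint sample ids.
#' @param alignment Data frame with columns `id_a`, `id_b` of matched
#'   peak ids (possibly 0 rows).
#' @return A [feature_table()] over the union of samples.
#' @export
union_feature_tables <- function(a, b,
                                 alignment = data.frame(id_a = character(),
                                                        id_b = character())) {
  stopifnot(inherits(a, "feature_table"), inherits(b, "feature_table"))
  if (!all(c("id_a", "id_b") %in% names(alignment)))
    stop("alignment needs columns id_a, id_b")
  if (length(intersect(a$sample_ids, b$sample_ids)))
    stop("feature tables share sample ids; samples must be disjoint")
  if (anyDuplicated(alignment$id_a) || anyDuplicated(alignment$id_b))
    stop("alignment pairs must be one-to-one")
  bad_a <- setdiff(alignment$id_a, a$peaks$peak_id)
  bad_b <- setdiff(alignment$id_b, b$peaks$peak_id)
  if (length(bad_a) || length(bad_b))
    stop("alignment references unknown peak id(s): ",
         paste(c(bad_a, bad_b), collapse = ", "))
  keep_b <- !(b$peaks$peak_id %in% alignment$id_b)
  # resolve id collisions between unmatched peaks of b and peaks of a
  b_ids <- b$peaks$peak_id
  clash <- keep_b & b_ids %in% a$peaks$peak_id
  b_ids[clash] <- paste0(b_ids[clash], ".b")
  peaks <- rbind(a$peaks,
                 transform(b$peaks[keep_b, , drop = FALSE],
                           peak_id = b_ids[keep_b]))
  n_tot <- nrow(peaks)
  inten <- matrix(NA_real_, n_tot, length(a$sample_ids) + length(b$sample_ids),
                  dimnames = list(peaks$peak_id,
                                  c(a$sample_ids, b$sample_ids)))
  inten[rownames(a$intensity), a$sample_ids] <- a$intensity
  inten[b_ids[keep_b], b$sample_ids] <- b$intensity[keep_b, , drop = FALSE]
  if (nrow(alignment)) {
    inten[alignment$id_a, b$sample_ids] <-
      b$intensity[alignment$id_b, , drop = FALSE]
  }
  feature_table(peaks, inten)
}

# ---- MS/MS (MGF) ---------------------------------------------------------

#' Read MS/MS peak lists from an MGF file
#'
#' Minimal Mascot Generic Format reader: each `BEGIN IONS` block yields
#' a spectrum with `precursor_mz` (PEPMASS), optional `title`, and a
#' fragment data frame (`mz`, `intensity`). Spectra are keyed by TITLE
#' when present, so the convention `TITLE=<peak_id>` links spectra to
#' feature-table peaks.
#'
#' @param path MGF file.
#' @return Named list of spectra, each
#'   `list(precursor_mz =, title =, fragments = data.frame(mz, intensity))`.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends))
    stop("malformed MGF: unbalanced BEGIN/END IONS")
  out <- vector("list", length(starts))
  keys <- character(length(starts))
  for (k in seq_along(starts)) {
    block <- lines[(starts[k] + 1):(ends[k] - 1)]
    hdr <- grepl("=", block, fixed = TRUE)
    kv <- strsplit(block[hdr], "=", fixed = TRUE)
    key <- toupper(vapply(kv, `[`, "", 1L))
    val <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
    pep <- val[match("PEPMASS", key)]
    title <- val[match("TITLE", key)]
    frag_lines <- block[!hdr & nzchar(trimws(block))]
    frags <- if (length(frag_lines)) {
      parts <- strsplit(trimws(frag_lines), "[ \t]+")
      data.frame(mz = as.numeric(vapply(parts, `[`, "", 1L)),
                 intensity = as.numeric(vapply(parts, function(x)
                   if (length(x) > 1) x[2] else "0", "")))
    } else data.frame(mz = numeric(), intensity = numeric())
    if (any(frags$intensity < 0, na.rm = TRUE))
      stop("negative fragment intensity in MGF block ", k)
    out[[k]] <- list(
      precursor_mz = as.numeric(strsplit(trimws(pep), "[ \t]+")[[1]][1]),
      title = if (is.na(title)) NULL else title,
      fragments = frags
    )
    keys[k] <- if (is.na(title)) paste0("spectrum_", k) else title
  }
  stats::setNames(out, keys)
}

#' Write MS/MS peak lists to an MGF file
#'
#' @param spectra Named list as returned by [read_mgf()].
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (key in names(spectra)) {
    sp <- spectra[[key]]
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", sp$title %||% key),
                 paste0("PEPMASS=", format(sp$precursor_mz, digits = 12)),
                 paste(format(sp$fragments$mz, digits = 12, trim = TRUE),
                       format(sp$fragments$intensity, digits = 12,
                              trim = TRUE)),
                 "END IONS", ""), con)
  }
  invisible(path)
}

#' Read isotopologue patterns
#'
#' TSV with columns `peak_id`, `offset_mz` (Da above the monoisotopic
#' peak) and `relative_intensity` (fraction of the monoisotopic peak).
#'
#' @param path TSV file.
#' @return Named list (by peak id) of data frames with columns
#'   `offset_mz`, `relative_intensity`.
#' @export
read_isotope_patterns <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (col in c("peak_id", "offset_mz", "relative_intensity"))
    if (!col %in% names(df))
      stop("isotope pattern table missing column '", col, "'")
  split(df[c("offset_mz", "relative_intensity")], df$peak_id)
}

#' Read a compound annotation / standards table
#'
#' TSV/CSV with columns `name`, `formula`, and optionally `herb`
#' (comma-separated origins), `rt` (reference RT of an authentic
#' standard, minutes) and `msi_level`.
#'
#' @param path Delimited text file.
#' @return Data frame of class `annotation_table`.
#' @export
read_annotation_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  annotation_table(df)
}

#' Validate an annotation table
#' @param df Data frame with at least `name` and `formula`.
#' @return The data frame with class `annotation_table`; a
#'   `neutral_mass` column is derived from the formulas.
#' @export
annotation_table <- function(df) {
  for (col in c("name", "formula"))
    if (!col %in% names(df))
      stop("annotation table missing column '", col, "'")
  if (anyDuplicated(df$name)) stop("duplicated compound name in annotations")
  df$neutral_mass <- vapply(df$formula, monoisotopic_mass, 0)
  if (!"rt" %in% names(df)) df$rt <- NA_real_
  if (!"herb" %in% names(df)) df$herb <- NA_character_
  class(df) <- c("annotation_table", "data.frame")
  df
}

# ---- network exports -----------------------------------------------------

#' Write a conjugation network as SIF
#'
#' One line per edge: `source<TAB>reaction<TAB>target`; isolated nodes
#' are appended as single-column lines so Cytoscape keeps them.
#'
#' @param network A `conjugation_network`.
#' @param path Output path.
#' @param within_window_only Drop out-of-window edges (default TRUE).
#' @export
write_network_sif <- function(network, path, within_window_only = TRUE) {
  ed <- network$edges
  if (within_window_only && nrow(ed)) ed <- ed[ed$within_window, , drop = FALSE]
  lines <- if (nrow(ed))
    paste(ed$source, ed$reaction, ed$target, sep = "\t") else character()
  used <- unique(c(ed$source, ed$target))
  iso <- setdiff(network$nodes$node_id, used)
  writeLines(c(lines, iso), path)
  invisible(path)
}

# igraph object carrying all node/edge attributes of the network.
network_igraph <- function(network) {
  nd <- network$nodes
  v <- data.frame(name = nd$node_id, stringsAsFactors = FALSE)
  for (col in setdiff(names(nd), c("node_id", "members")))
    v[[col]] <- nd[[col]]
  if ("members" %in% names(nd)) v$members <- nd$members
  ed <- network$edges
  if (nrow(ed) == 0L) {
    return(igraph::graph_from_data_frame(
      data.frame(from = character(), to = character()),
      directed = TRUE, vertices = v))
  }
  e <- data.frame(from = ed$source, to = ed$target, stringsAsFactors = FALSE)
  for (col in setdiff(names(ed), c("source", "target")))
    e[[col]] <- ed[[col]]
  igraph::graph_from_data_frame(e, directed = TRUE, vertices = v)
}

#' Write a conjugation network as GraphML
#'
#' Node attributes carry neutral mass, RT, origin, evidence flags and
#' MSI level; edge attributes carry the reaction name, ppm residual and
#' RT shift. Readable back with [read_network_graphml()].
#'
#' @param network A `conjugation_network`.
#' @param path Output path.
#' @export
write_network_graphml <- function(network, path) {
  g <- network_igraph(network)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network export
#'
#' @param path GraphML file written by [write_network_graphml()].
#' @return A `conjugation_network` (nodes + edges data frames).
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nd <- igraph::as_data_frame(g, what = "vertices")
  names(nd)[names(nd) == "name"] <- "node_id"
  rownames(nd) <- NULL
  ed <- igraph::as_data_frame(g, what = "edges")
  if (nrow(ed)) names(ed)[1:2] <- c("source", "target")
  conjugation_network(nd, ed)
}

#' Write node and edge attribute tables
#'
#' TSVs carrying the same attributes as the GraphML export.
#'
#' @param network A `conjugation_network`.
#' @param node_path,edge_path Output paths.
#' @export
write_node_edge_tables <- function(network, node_path, edge_path) {
  utils::write.table(network$nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(c(node_path, edge_path))
}
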