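#' Construct a validated two-condition count matrix
#'
#' The basic container for the pipeline: an integer gene x sample count
#' matrix plus a condition label per sample (exactly two distinct labels)
#' and, optionally, a donor/pair label per sample. The first element of
#' `condition_levels` is "condition 1" for every downstream contrast
#' (log-fold-changes, PIF, DW, RIF signs all depend on this orientation).
#'
#' @param counts integer matrix with gene IDs as rownames and sample IDs as
#'   colnames; all entries non-negative integers.
#' @param condition named character vector mapping every sample ID to one of
#'   two condition labels.
#' @param pair optional named character vector mapping sample IDs to
#'   donor/pair labels. Carried through but not used by the (unpaired)
#'   exact test.
#' @param condition_levels optional length-2 character vector fixing which
#'   label is condition 1. Defaults to order of first appearance across
#'   samples.
#' @return an object of class `count_matrix`: a list with elements
#'   `counts`, `condition`, `condition_levels`, `pair`.
#' @export
count_matrix <- function(counts, condition, pair = NULL, condition_levels = NULL) {
  if (!is.matrix(counts)) stop("'counts' must be a matrix")
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("'counts' must carry gene rownames and sample colnames")
  if (anyDuplicated(gene_ids)) stop("duplicate gene IDs in count matrix")
  if (anyDuplicated(sample_ids)) stop("duplicate sample IDs in count matrix")
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be finite numbers")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"

  if (is.null(names(condition))) stop("'condition' must be named by sample ID")
  condition <- condition[sample_ids]
  if (any(is.na(condition)))
    stop("samples present in counts but absent from the condition map: ",
         paste(setdiff(sample_ids, names(condition)), collapse = ", "))
  condition <- as.character(condition)
  names(condition) <- sample_ids
  labs <- unique(condition)
  if (length(labs) != 2L)
    stop("exactly two condition labels required, got ", length(labs))
  if (min(table(condition)) < 2L)
    stop("each condition needs at least 2 samples")
  if (!is.null(condition_levels)) {
    if (!setequal(condition_levels, labs))
      stop("'condition_levels' must be a permutation of the observed labels")
    labs <- as.character(condition_levels)
  }
  if (!is.null(pair)) {
    pair <- pair[sample_ids]
    if (any(is.na(pair))) stop("'pair' must cover every sample or be NULL")
    pair <- as.character(pair)
    names(pair) <- sample_ids
  }
  structure(list(counts = counts, condition = condition,
                 condition_levels = labs, pair = pair),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  tab <- table(factor(x$condition, levels = x$condition_levels))
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Read a count matrix and its condition map from TSV files
#'
#' The count file is tab-delimited with a header row of sample IDs and gene
#' IDs in the first column. The condition map is a headerless two- or
#' three-column TSV (sample_id, condition[, pair]); a header line whose
#' first field is `sample` or `sample_id` is tolerated and skipped.
#' Gene and sample order is preserved from the file. Gene identifiers are
#' opaque, case-sensitive strings; no ID conversion is attempted, and
#' missing values are rejected rather than imputed.
#'
#' @param path count matrix TSV.
#' @param condition_map_path condition map TSV.
#' @param condition_levels optional explicit condition orientation, see
#'   [count_matrix()].
#' @return a [count_matrix()].
#' @export
read_counts <- function(path, condition_map_path, condition_levels = NULL) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("count file needs a gene column plus >= 1 sample")
  gene_ids <- raw[[1L]]
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(mat), nrow = nrow(mat)))
  if (any(is.na(num))) stop("non-numeric or missing count values in ", path)
  dimnames(num) <- list(gene_ids, colnames(raw)[-1L])

  cmap <- utils::read.delim(condition_map_path, header = FALSE,
                            colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(cmap) < 2L) stop("condition map needs two columns (sample, condition)")
  if (tolower(cmap[1L, 1L]) %in% c("sample", "sample_id")) cmap <- cmap[-1L, , drop = FALSE]
  condition <- stats::setNames(cmap[[2L]], cmap[[1L]])
  pair <- if (ncol(cmap) >= 3L) stats::setNames(cmap[[3L]], cmap[[1L]]) else NULL
  missing <- setdiff(colnames(num), names(condition))
  if (length(missing))
    stop("samples present in counts but absent from the condition map: ",
         paste(missing, collapse = ", "))
  count_matrix(num, condition, pair = pair, condition_levels = condition_levels)
}

#' Write a count matrix (and its condition map) to TSV files
#'
#' Inverse of [read_counts()]: `read_counts(write_counts(x))` reproduces
#' `x` exactly (counts are integers, so the round trip is lossless).
#'
#' @param m a [count_matrix()].
#' @param path destination for the counts TSV.
#' @param condition_map_path destination for the condition map TSV.
#' @return invisibly, `m`.
#' @export
write_counts <- function(m, path, condition_map_path) {
  df <- data.frame(gene = rownames(m$counts),
                   format(m$counts, scientific = FALSE, trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cmap <- data.frame(sample = colnames(m$counts),
                     condition = unname(m$condition),
                     stringsAsFactors = FALSE)
  if (!is.null(m$pair)) cmap$pair <- unname(m$pair)
  utils::write.table(cmap, condition_map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(m)
}

.regulator_classes <- c("TF", "EF", "lncRNA")

#' Build a regulator catalog from explicit class assignments
#'
#' @param classes_of named list mapping gene ID to a non-empty character
#'   subset of TF / EF / lncRNA. A gene may carry multiple classes (the
#'   classes are not disjoint: many epigenetic factors are also
#'   transcription factors).
#' @return object of class `regulator_catalog`.
#' @export
regulator_catalog <- function(classes_of) {
  if (is.null(names(classes_of)) && length(classes_of))
    stop("'classes_of' must be named by gene ID")
  classes_of <- lapply(classes_of, function(cl) {
    cl <- sort(unique(as.character(cl)))
    if (!length(cl) || !all(cl %in% .regulator_classes))
      stop("regulator classes must be a non-empty subset of ",
           paste(.regulator_classes, collapse = "/"))
    cl
  })
  structure(list(classes_of = classes_of), class = "regulator_catalog")
}

#' Read a regulator gene list
#'
#' Plain text, one gene ID per line; anything after a `#` is a comment.
#' Duplicate IDs collapse to one entry (set semantics).
#'
#' @param path file path.
#' @param class_label one of `"TF"`, `"EF"`, `"lncRNA"`.
#' @return a [regulator_catalog()] assigning `class_label` to every listed
#'   gene.
#' @export
read_gene_list <- function(path, class_label = c("TF", "EF", "lncRNA")) {
  class_label <- match.arg(class_label)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  genes <- unique(lines[nzchar(lines)])
  if (!length(genes)) warning("empty gene list: ", path)
  regulator_catalog(stats::setNames(rep(list(class_label), length(genes)), genes))
}

#' Merge regulator catalogs, unioning class sets per gene
#'
#' Commutative and idempotent: merging in any order, or merging a catalog
#' with itself, yields the same class sets.
#'
#' @param ... regulator catalogs.
#' @return a merged [regulator_catalog()]; gene order is first appearance.
#' @export
merge_catalogs <- function(...) {
  cats <- list(...)
  out <- list()
  for (cat. in cats) {
    stopifnot(inherits(cat., "regulator_catalog"))
    for (g in names(cat.$classes_of))
      out[[g]] <- sort(unique(c(out[[g]], cat.$classes_of[[g]])))
  }
  regulator_catalog(out)
}

## repr-style full precision: survives a text round trip to < 1e-15 relative
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.rif_table_cols <- c("regulator", "classes", "metric", "rif1_raw", "rif2_raw",
                     "rif1_z", "rif2_z", "rank1", "rank2", "selected")

#' Write a RIF score table to TSV
#'
#' Columns: regulator, classes, metric, rif1_raw, rif2_raw, rif1_z, rif2_z,
#' rank1, rank2, selected; rows ordered by metric then rank1 (ties by
#' regulator ID). Floats are written with full precision so that
#' [read_rif_table()] reproduces them to better than 10 significant digits.
#'
#' @param table a `rif_table` data frame from [standardize_and_select()]
#'   (possibly several metrics row-bound).
#' @param path destination TSV.
#' @return invisibly, the path.
#' @export
write_rif_table <- function(table, path) {
  stopifnot(all(.rif_table_cols %in% names(table)))
  num <- c("rif1_raw", "rif2_raw", "rif1_z", "rif2_z")
  if (!all(vapply(table[num], function(x) all(is.finite(x)), logical(1))))
    stop("RIF table contains non-finite scores")
  table <- table[order(table$metric, table$rank1, table$regulator), , drop = FALSE]
  out <- table[, .rif_table_cols, drop = FALSE]
  for (cl in num) out[[cl]] <- .fmt_num(table[[cl]])
  out$selected <- ifelse(table$selected, "TRUE", "FALSE")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a RIF score table written by [write_rif_table()]
#'
#' @param path TSV path.
#' @return a `rif_table` data frame.
#' @export
read_rif_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  stopifnot(identical(names(df), .rif_table_cols))
  for (cl in c("rif1_raw", "rif2_raw", "rif1_z", "rif2_z"))
    df[[cl]] <- as.numeric(df[[cl]])
  for (cl in c("rank1", "rank2")) df[[cl]] <- as.integer(df[[cl]])
  df$selected <- df$selected == "TRUE"
  class(df) <- c("rif_table", "data.frame")
  df
}

#' Construct a regulator interaction network object
#'
#' @param nodes data frame with columns `node`, `classes`,
#'   `metrics_found_by`.
#' @param edges data frame with columns `node_a`, `node_b`,
#'   `direct_correlation`, `metric`; endpoints are canonicalized so
#'   `node_a < node_b` lexicographically.
#' @return object of class `regulator_network`.
#' @export
regulator_network <- function(nodes, edges) {
  stopifnot(all(c("node", "classes", "metrics_found_by") %in% names(nodes)),
            all(c("node_a", "node_b", "direct_correlation", "metric") %in% names(edges)))
  if (nrow(edges)) {
    swap <- edges$node_a > edges$node_b
    tmp <- edges$node_a[swap]
    edges$node_a[swap] <- edges$node_b[swap]
    edges$node_b[swap] <- tmp
    if (!all(edges$node_a %in% nodes$node) || !all(edges$node_b %in% nodes$node))
      stop("edge endpoint missing from node table")
    if (any(abs(edges$direct_correlation) > 1 + 1e-9))
      stop("|direct correlation| must be <= 1")
    edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "regulator_network")
}

#' Write a regulator network as edge-list and node-attribute TSVs
#'
#' The edge list has columns node_a, node_b, direct_correlation, metric
#' with `node_a < node_b` lexicographically (byte-stable across runs); the
#' node table has columns node, classes, metrics_found_by. Isolated nodes
#' appear in the node table only.
#'
#' @param net a [regulator_network()].
#' @param path destination for the edge-list TSV.
#' @param nodes_path destination for the node table; defaults to `path`
#'   with a `_nodes` suffix before the extension.
#' @return invisibly, `c(path, nodes_path)`.
#' @export
write_network <- function(net, path, nodes_path = NULL) {
  stopifnot(inherits(net, "regulator_network"))
  if (is.null(nodes_path)) {
    nodes_path <- if (grepl("\\.[^./]+$", path))
      sub("(\\.[^./]+)$", "_nodes\\1", path) else paste0(path, "_nodes")
  }
  edges <- net$edges
  out <- data.frame(node_a = character(0), node_b = character(0),
                    direct_correlation = character(0), metric = character(0),
                    stringsAsFactors = FALSE)
  if (nrow(edges))
    out <- data.frame(node_a = edges$node_a, node_b = edges$node_b,
                      direct_correlation = .fmt_num(edges$direct_correlation),
                      metric = edges$metric, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(net$nodes[, c("node", "classes", "metrics_found_by")],
                     nodes_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, nodes_path))
}
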