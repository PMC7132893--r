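.all_metrics <- c("pearson", "spearman", "fisher", "sobolev")

#' Assemble a pipeline run configuration
#'
#' All tunables of every stage in one serializable list. The condition
#' orientation (`condition1`) is explicit and never inferred, because every
#' RIF sign depends on it.
#'
#' @param counts path to the count TSV.
#' @param condition_map path to the sample-condition TSV.
#' @param condition1 label of condition 1 (e.g. the tumor label).
#' @param out_dir output directory (created if needed).
#' @param tf_list,ef_list,lncrna_list optional regulator list paths.
#' @param de_list optional precomputed DE gene list (one ID per line);
#'   bypasses the exact-test DE call (expression summaries are still
#'   computed).
#' @param metrics association metrics to run (subset of pearson, spearman,
#'   fisher, sobolev).
#' @param fdr FDR cutoff for the DE call.
#' @param dispersion `"tagwise"` or `"common"`.
#' @param pseudocount log-CPM pseudocount.
#' @param top_k regulators taken per RIF score.
#' @param select ranking criterion, see [standardize_and_select()].
#' @param rif1_linear_dw use DW linearly (unsquared) inside RIF1.
#' @param sobolev_order Sobolev derivative order.
#' @param signed_geometric sign geometric associations by Pearson sign.
#' @param edge_threshold minimum |direct correlation| for network edges.
#' @param min_partial optional minimum |partial correlation| for edges.
#' @return a list of class `run_config`.
#' @export
run_config <- function(counts, condition_map, condition1, out_dir,
                       tf_list = NULL, ef_list = NULL, lncrna_list = NULL,
                       de_list = NULL,
                       metrics = .all_metrics, fdr = 0.05,
                       dispersion = c("tagwise", "common"), pseudocount = 0.5,
                       top_k = 10, select = c("abs", "positive", "negative"),
                       rif1_linear_dw = FALSE, sobolev_order = 1,
                       signed_geometric = FALSE, edge_threshold = 0.90,
                       min_partial = NULL) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  structure(list(counts = counts, condition_map = condition_map,
                 condition1 = condition1, out_dir = out_dir,
                 tf_list = tf_list, ef_list = ef_list,
                 lncrna_list = lncrna_list, de_list = de_list,
                 metrics = metrics, fdr = fdr,
                 dispersion = match.arg(dispersion),
                 pseudocount = pseudocount, top_k = top_k,
                 select = match.arg(select),
                 rif1_linear_dw = rif1_linear_dw,
                 sobolev_order = sobolev_order,
                 signed_geometric = signed_geometric,
                 edge_threshold = edge_threshold,
                 min_partial = min_partial),
            class = "run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full regulator-scoring workflow
#'
#' normalize -> DE -> per-metric associations -> RIF -> selection -> PCIT
#' -> network, writing under `cfg$out_dir`: the DE table
#' (`de_table.tsv`), one RIF table (`rif_<metric>.tsv`) and one network
#' (`network_<metric>.tsv` + `..._nodes.tsv`) per metric, the overlap
#' summary (`summary.tsv`), a log (`log.txt`), and the resolved
#' configuration (`config.txt`). The pipeline is deterministic: rerunning
#' an identical configuration on identical inputs reproduces every output
#' byte for byte. Any stage failure aborts with the stage name and cause.
#'
#' @param cfg a [run_config()].
#' @return invisibly, a list with `de`, `rif_tables`, `networks`,
#'   `summary`, `out_dir`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  .stage("config", {
    paths <- c(counts = cfg$counts, condition_map = cfg$condition_map,
               tf_list = cfg$tf_list, ef_list = cfg$ef_list,
               lncrna_list = cfg$lncrna_list, de_list = cfg$de_list)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("missing input file(s): ",
           paste(sprintf("%s (%s)", missing, names(missing)), collapse = ", "))
    if (is.null(cfg$tf_list) && is.null(cfg$ef_list) && is.null(cfg$lncrna_list))
      stop("at least one regulator list is required")
  })
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  m <- .stage("read_counts",
              read_counts(cfg$counts, cfg$condition_map))
  .stage("orientation", {
    if (!cfg$condition1 %in% m$condition_levels)
      stop("condition1 label '", cfg$condition1, "' not found in the condition map")
  })
  m <- count_matrix(m$counts, m$condition, pair = m$pair,
                    condition_levels = c(cfg$condition1,
                                         setdiff(m$condition_levels, cfg$condition1)))
  say("condition 1 = %s, condition 2 = %s", m$condition_levels[1], m$condition_levels[2])

  cat. <- .stage("regulators", {
    cats <- list()
    if (!is.null(cfg$tf_list)) cats <- c(cats, list(read_gene_list(cfg$tf_list, "TF")))
    if (!is.null(cfg$ef_list)) cats <- c(cats, list(read_gene_list(cfg$ef_list, "EF")))
    if (!is.null(cfg$lncrna_list)) cats <- c(cats, list(read_gene_list(cfg$lncrna_list, "lncRNA")))
    do.call(merge_catalogs, cats)
  })
  say("regulator catalog: %d genes", length(cat.$classes_of))

  n_before <- nrow(m$counts)
  m <- .stage("filter", suppressMessages(drop_zero_genes(m)))
  say("dropped %d all-zero gene(s); %d genes remain", n_before - nrow(m$counts), nrow(m$counts))

  factors <- .stage("normalize", tmm_factors(m))
  nm <- .stage("normalize", log_cpm(m, factors, pseudocount = cfg$pseudocount))
  say("TMM factors in [%.4f, %.4f]; pseudocount = %g (default unless set)",
      min(factors), max(factors), cfg$pseudocount)

  de <- .stage("de", {
    if (!is.null(cfg$de_list)) {
      de_ids <- names(read_gene_list(cfg$de_list, "TF")$classes_of)
      say("precomputed DE list: %d genes (exact test bypassed)", length(de_ids))
      in1 <- nm$condition == nm$condition_levels[1]
      e1 <- rowMeans(nm$log_expr[, in1, drop = FALSE])
      e2 <- rowMeans(nm$log_expr[, !in1, drop = FALSE])
      out <- data.frame(gene = rownames(m$counts), e1 = e1, e2 = e2,
                        logFC = e1 - e2, pvalue = NA_real_, fdr = NA_real_,
                        is_de = rownames(m$counts) %in% de_ids,
                        row.names = NULL, stringsAsFactors = FALSE)
      class(out) <- c("de_result", "data.frame")
      out
    } else {
      disp <- estimate_common_dispersion(m, factors,
                                         tagwise = cfg$dispersion == "tagwise")
      say("common dispersion alpha = %.4f (dispersion mode: %s)",
          disp$alpha_common, cfg$dispersion)
      pv <- nb_exact_test(m, factors, disp, dispersion = cfg$dispersion)
      say("FDR cutoff = %g (default 0.05 unless set)", cfg$fdr)
      select_de(m, factors, pv, fdr_cutoff = cfg$fdr,
                pseudocount = cfg$pseudocount)
    }
  })
  say("DE genes: %d of %d", sum(de$is_de), nrow(de))
  .write_de_table(de, file.path(cfg$out_dir, "de_table.tsv"))

  rif_tables <- list()
  networks <- list()
  for (met in cfg$metrics) {
    a <- .stage(paste0("associations_", met),
                association_matrices(nm, de, cat., metric = met,
                                     sobolev_order = cfg$sobolev_order,
                                     signed_geometric = cfg$signed_geometric))
    tab <- .stage(paste0("rif_", met), {
      pif <- pif_scores(de)[a$de_genes]
      r1 <- rif1(pif, dw_matrix(a), squared_dw = !cfg$rif1_linear_dw)
      r2 <- rif2(de, a)
      standardize_and_select(r1, r2, top_k = cfg$top_k, select = cfg$select,
                             metric = met, catalog = cat.)
    })
    net <- .stage(paste0("network_", met),
                  build_network(tab, nm, edge_threshold = cfg$edge_threshold,
                                min_partial = cfg$min_partial))
    say("%s: %d selected regulators, %d network edges",
        met, sum(tab$selected), nrow(net$edges))
    write_rif_table(tab, file.path(cfg$out_dir, paste0("rif_", met, ".tsv")))
    write_network(net, file.path(cfg$out_dir, paste0("network_", met, ".tsv")))
    rif_tables[[met]] <- tab
    networks[[met]] <- net
  }

  summ <- .stage("summary", overlap_summary(networks))
  .write_summary(summ, file.path(cfg$out_dir, "summary.tsv"))
  .write_config(cfg, file.path(cfg$out_dir, "config.txt"))
  writeLines(log_lines, file.path(cfg$out_dir, "log.txt"))
  invisible(list(de = de, rif_tables = rif_tables, networks = networks,
                 summary = summ, out_dir = cfg$out_dir))
}

.write_de_table <- function(de, path) {
  out <- data.frame(gene = de$gene, e1 = .fmt_num(de$e1), e2 = .fmt_num(de$e2),
                    logFC = .fmt_num(de$logFC), pvalue = .fmt_num(de$pvalue),
                    fdr = .fmt_num(de$fdr),
                    is_de = ifelse(de$is_de, "TRUE", "FALSE"),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_config <- function(cfg, path) {
  vals <- vapply(cfg, function(v)
    if (is.null(v)) "" else paste(as.character(v), collapse = ","), character(1))
  writeLines(sprintf("%s=%s", names(vals), vals), path)
}

#' Summarize significant regulators across metrics
#'
#' The "significant regulators" of a metric are the node set of its PCIT
#' network. The summary reports, per metric, counts per regulator class (a
#' multi-class gene is counted once per class it carries, so class counts
#' can sum to more than the number of unique nodes), per-metric totals, the
#' deduplicated total across metrics, and the counts of every non-empty
#' intersection region (Venn analog).
#'
#' @param networks named list (metric -> [regulator_network()]).
#' @return a list of class `overlap_summary` with elements `class_counts`
#'   (data frame metric x class + per-metric sum), `total_unique`, and
#'   `venn` (data frame region/count over all `2^m - 1` regions).
#' @export
overlap_summary <- function(networks) {
  stopifnot(length(networks) >= 1, !is.null(names(networks)))
  sets <- lapply(networks, function(n) n$nodes$node)
  class_of <- do.call(rbind, lapply(networks, function(n) n$nodes))
  class_of <- class_of[!duplicated(class_of$node), c("node", "classes")]
  cls <- stats::setNames(strsplit(class_of$classes, ",", fixed = TRUE), class_of$node)

  class_counts <- do.call(rbind, lapply(names(sets), function(met) {
    members <- unlist(cls[sets[[met]]])
    data.frame(metric = met,
               TF = sum(members == "TF"),
               EF = sum(members == "EF"),
               lncRNA = sum(members == "lncRNA"),
               n_regulators = length(sets[[met]]),
               stringsAsFactors = FALSE)
  }))
  class_counts$sum <- class_counts$TF + class_counts$EF + class_counts$lncRNA

  all_nodes <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) all_nodes %in% s,
                       logical(length(all_nodes)))
  if (length(all_nodes) == 1L) membership <- matrix(membership, nrow = 1L,
                                                   dimnames = list(NULL, names(sets)))
  mets <- names(sets)
  regions <- unlist(lapply(seq_along(mets), function(k)
    utils::combn(mets, k, paste, collapse = "&", simplify = FALSE)))
  venn <- data.frame(region = regions, count = 0L, stringsAsFactors = FALSE)
  if (length(all_nodes)) {
    key <- apply(membership, 1L, function(z) paste(mets[z], collapse = "&"))
    tab <- table(key)
    venn$count <- as.integer(tab[venn$region])
    venn$count[is.na(venn$count)] <- 0L
  }
  structure(list(class_counts = class_counts,
                 total_unique = length(all_nodes), venn = venn),
            class = "overlap_summary")
}

.write_summary <- function(summ, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(summ$class_counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(sprintf("total_unique\t%d", summ$total_unique), con)
  utils::write.table(summ$venn, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Parse a flat key=value configuration file into a [run_config()]
#'
#' Lines are `key=value`; blank lines and `#` comments are skipped;
#' comma-separated values become vectors; `TRUE`/`FALSE` and numbers are
#' coerced.
#'
#' @param path configuration file.
#' @return a [run_config()].
#' @export
read_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexpr("=", lines, fixed = TRUE), invert = TRUE)
  args <- stats::setNames(lapply(kv, function(p) {
    v <- strsplit(trimws(p[2L]), ",", fixed = TRUE)[[1L]]
    if (!length(v)) return(NULL)
    if (all(v %in% c("TRUE", "FALSE"))) return(as.logical(v))
    suppressWarnings(num <- as.numeric(v))
    if (!any(is.na(num))) num else v
  }), vapply(kv, function(p) trimws(p[1L]), character(1)))
  args <- args[!vapply(args, is.null, logical(1))]
  do.call(run_config, args)
}
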