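#' Phenotype impact factor per DE gene
#'
#' `PIF_i = (e1_i^2 - e2_i^2) / 2` on the log2-CPM scale: the half-difference
#' of squared mean expression between the two conditions, large for genes
#' that are both abundant and strongly shifted. DE genes only.
#'
#' @param de a `de_result` with at least one DE gene.
#' @return named vector of PIF values over the DE genes.
#' @export
pif_scores <- function(de) {
  d <- de[de$is_de, , drop = FALSE]
  if (!nrow(d)) stop("no DE genes")
  stats::setNames(0.5 * (d$e1^2 - d$e2^2), d$gene)
}

#' Differential wiring matrix
#'
#' `DW_ji = r1_ji - r2_ji`: the change in regulator-gene association between
#' condition 1 and condition 2.
#'
#' @param a an `association_set` from [association_matrices()].
#' @return regulators x DE-genes matrix.
#' @export
dw_matrix <- function(a) a$r1 - a$r2

#' RIF1: phenotype-impact-weighted differential wiring
#'
#' `RIF1_j = mean_i(PIF_i * DW_ji^2)`, averaging over the DE genes. The
#' differential wiring enters squared, following the original definition of
#' the score; `squared_dw = FALSE` gives the variant that is linear in DW.
#'
#' @param pif PIF vector over DE genes (see [pif_scores()]).
#' @param dw DW matrix, regulators x DE genes, columns aligned with `pif`.
#' @param squared_dw square DW before weighting (default TRUE).
#' @return named per-regulator RIF1 vector.
#' @export
rif1 <- function(pif, dw, squared_dw = TRUE) {
  if (!is.matrix(dw) || ncol(dw) != length(pif)) stop("dimension mismatch")
  if (!length(pif)) stop("no DE genes")
  w <- if (squared_dw) dw^2 else dw
  drop(w %*% pif) / length(pif)
}

#' RIF2: change in correlation-weighted predicted abundance
#'
#' `RIF2_j = mean_i[(e1_i * r1_ji)^2 - (e2_i * r2_ji)^2]`: contrasts, across
#' DE genes, the squared expression weighted by the squared regulator-gene
#' association in each condition — high for regulators that predict DE-gene
#' abundance in one condition but not the other.
#'
#' @param de a `de_result`.
#' @param a an `association_set` over the same DE genes.
#' @return named per-regulator RIF2 vector.
#' @export
rif2 <- function(de, a) {
  d <- de[de$is_de, , drop = FALSE]
  idx <- match(a$de_genes, d$gene)
  if (any(is.na(idx))) stop("association set and DE result disagree on DE genes")
  if (!length(idx)) stop("no DE genes")
  e1 <- d$e1[idx]
  e2 <- d$e2[idx]
  (drop((a$r1^2) %*% (e1^2)) - drop((a$r2^2) %*% (e2^2))) / length(idx)
}

.dense_rank_desc <- function(score) match(score, sort(unique(score), decreasing = TRUE))

#' Standardize RIF scores and select top regulators
#'
#' Each raw score vector is z-scored across regulators within the metric;
#' regulators are ranked by descending score magnitude (dense ranks, ties
#' broken by ascending gene ID for selection), and the selected set is the
#' union of the top-k by |rif1_z| and the top-k by |rif2_z| (at most `2 *
#' top_k` regulators). `select` switches the ranking criterion from |z| to
#' signed z in either direction.
#'
#' @param rif1_raw,rif2_raw named per-regulator raw scores (same names).
#' @param top_k how many regulators to take per score (default 10).
#' @param select rank by `"abs"` (default), `"positive"`, or `"negative"` z.
#' @param metric metric label recorded in the table.
#' @param catalog optional [regulator_catalog()] supplying the class column.
#' @return a `rif_table` data frame ordered by rank1 (see
#'   [write_rif_table()] for columns).
#' @export
standardize_and_select <- function(rif1_raw, rif2_raw, top_k = 10,
                                   select = c("abs", "positive", "negative"),
                                   metric = "pearson", catalog = NULL) {
  select <- match.arg(select)
  stopifnot(top_k >= 1, length(rif1_raw) >= 1,
            identical(names(rif1_raw), names(rif2_raw)))
  regs <- names(rif1_raw)
  zscore <- function(x) {
    s <- stats::sd(x)
    if (length(x) < 2L || !is.finite(s) || s == 0) {
      warning("zero spread in RIF scores; z-scores defined as 0")
      return(rep(0, length(x)))
    }
    (x - mean(x)) / s
  }
  z1 <- zscore(rif1_raw)
  z2 <- zscore(rif2_raw)
  crit <- switch(select, abs = abs, positive = identity, negative = function(x) -x)
  s1 <- crit(z1)
  s2 <- crit(z2)
  rank1 <- .dense_rank_desc(s1)
  rank2 <- .dense_rank_desc(s2)
  ## ties in the criterion fall back on the raw score (an extreme raw value
  ## beats a symmetric counterpart), then ascending gene ID
  raw_key <- if (select == "negative") function(x) x else function(x) -x
  top1 <- regs[order(-s1, raw_key(rif1_raw), regs)][seq_len(min(top_k, length(regs)))]
  top2 <- regs[order(-s2, raw_key(rif2_raw), regs)][seq_len(min(top_k, length(regs)))]
  selected <- regs %in% union(top1, top2)
  classes <- if (is.null(catalog)) rep("", length(regs)) else
    vapply(regs, function(g) paste(catalog$classes_of[[g]], collapse = ","), character(1))
  out <- data.frame(regulator = regs, classes = unname(classes),
                    metric = metric,
                    rif1_raw = unname(rif1_raw), rif2_raw = unname(rif2_raw),
                    rif1_z = unname(z1), rif2_z = unname(z2),
                    rank1 = rank1, rank2 = rank2, selected = selected,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$rank1, out$regulator), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("rif_table", "data.frame")
  out
}
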