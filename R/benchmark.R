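#' One planted-regulator recovery run
#'
#' Generates a wired fixture (by default one wired regulator against 50
#' decoy regulators, 20 targets among 100 planted DE genes at 4-fold
#' change, wiring strength 0.9, 300 genes, 20 + 20 samples, dispersion
#' 0.1), runs normalization, the DE call and the RIF scoring for each
#' requested metric, and reports where the planted regulator ranks and
#' whether it enters the PCIT network node set. Used by the recovery
#' simulation studies.
#'
#' @param seed integer seed for the fixture.
#' @param metrics metrics to score.
#' @param params fixture parameters ([synth_params()]).
#' @param n_de,fold_change,n_targets,rho planted truth, see
#'   [synthetic_truth()].
#' @param top_k selection depth (default 10).
#' @param dispersion dispersion mode for the exact test.
#' @return data frame with one row per metric: `metric`, `rank1`,
#'   `selected`, `in_network`, `n_regulators`, `n_de_detected`.
#' @export
rif_recovery_run <- function(seed, metrics = .all_metrics,
                             params = synth_params(n_genes = 300,
                                                   n_per_condition = 20,
                                                   dispersion = 0.1,
                                                   n_tf = 51, n_ef = 0,
                                                   n_tf_ef_overlap = 0,
                                                   n_lncrna = 0),
                             n_de = 100, fold_change = 4, n_targets = 20,
                             rho = 0.9, top_k = 10,
                             dispersion = c("common", "tagwise")) {
  dispersion <- match.arg(dispersion)
  truth <- synthetic_truth(params, seed, n_de = n_de, fold_change = fold_change,
                           n_wired = 1, n_targets = n_targets, rho = rho)
  fx <- generate_wired(params, truth)
  m <- fx$matrix
  planted <- names(truth$wired_regulators)[1L]

  factors <- tmm_factors(m)
  nm <- log_cpm(m, factors)
  disp <- estimate_common_dispersion(m, factors, tagwise = dispersion == "tagwise")
  pv <- nb_exact_test(m, factors, disp, dispersion = dispersion)
  de <- select_de(m, factors, pv)

  do.call(rbind, lapply(metrics, function(met) {
    a <- association_matrices(nm, de, fx$catalog, metric = met)
    pif <- pif_scores(de)[a$de_genes]
    tab <- standardize_and_select(rif1(pif, dw_matrix(a)), rif2(de, a),
                                  top_k = top_k, metric = met,
                                  catalog = fx$catalog)
    net <- suppressWarnings(build_network(tab, nm))
    row <- tab[tab$regulator == planted, ]
    data.frame(metric = met, rank1 = row$rank1, selected = row$selected,
               in_network = planted %in% net$nodes$node,
               n_regulators = nrow(tab), n_de_detected = sum(de$is_de),
               stringsAsFactors = FALSE)
  }))
}

#' One null-calibration run
#'
#' Generates a null fixture (no DE, no wiring), runs normalization,
#' dispersion estimation, the exact test and BH adjustment, and reports the
#' p-values, the fraction of genes called DE at the given FDR cutoff, and
#' the estimated common dispersion.
#'
#' @param seed integer seed.
#' @param params fixture parameters; defaults to 2000 genes, 10 + 10
#'   samples, dispersion 0.4.
#' @param fdr_cutoff DE cutoff (default 0.05).
#' @param dispersion dispersion mode for the exact test.
#' @return list with `pvalues`, `de_fraction`, `alpha_common`.
#' @export
null_calibration_run <- function(seed,
                                 params = synth_params(n_genes = 2000,
                                                       n_per_condition = 10,
                                                       dispersion = 0.4),
                                 fdr_cutoff = 0.05,
                                 dispersion = c("tagwise", "common")) {
  dispersion <- match.arg(dispersion)
  m <- generate_null(params, seed)
  m <- suppressMessages(drop_zero_genes(m))
  factors <- tmm_factors(m)
  disp <- estimate_common_dispersion(m, factors, tagwise = dispersion == "tagwise")
  pv <- nb_exact_test(m, factors, disp, dispersion = dispersion)
  de <- select_de(m, factors, pv, fdr_cutoff = fdr_cutoff)
  list(pvalues = pv, de_fraction = mean(de$is_de),
       alpha_common = disp$alpha_common)
}
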