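#' Parameters for the synthetic count generator
#'
#' Defaults emulate a paired two-condition RNA-seq design at desk scale:
#' 2000 genes, 20 + 20 paired samples, NB dispersion 0.1 (typical
#' biological replication), gene baseline means log-uniform on
#' `[10, 1000]`, and a regulator catalog of 60 TFs, 30 EFs (10 of them
#' also TFs, mirroring the overlap between published TF and epigenetic
#' factor lists) and 10 lncRNAs. The regulator genes are the first genes
#' of the matrix.
#'
#' @param n_genes number of genes.
#' @param n_per_condition samples per condition (paired by donor).
#' @param dispersion NB dispersion `alpha` in `v = mu + alpha * mu^2`
#'   (0 means Poisson).
#' @param mu_range baseline mean range (log-uniform).
#' @param conditions length-2 labels; the first is condition 1.
#' @param n_tf,n_ef,n_tf_ef_overlap,n_lncrna catalog composition.
#' @param bio_sd standard deviation (natural log scale) of the shared
#'   biological factor used by [generate_wired()].
#' @return a list of class `synth_params`.
#' @export
synth_params <- function(n_genes = 2000, n_per_condition = 20, dispersion = 0.1,
                         mu_range = c(10, 1000),
                         conditions = c("tumor", "normal"),
                         n_tf = 60, n_ef = 30, n_tf_ef_overlap = 10,
                         n_lncrna = 10, bio_sd = 1) {
  stopifnot(n_genes >= 1, n_per_condition >= 2, dispersion >= 0,
            length(mu_range) == 2, mu_range[1] > 0, mu_range[2] >= mu_range[1],
            length(conditions) == 2, conditions[1] != conditions[2],
            n_tf >= 0, n_ef >= 0, n_tf_ef_overlap >= 0, n_lncrna >= 0,
            n_tf_ef_overlap <= min(n_tf, n_ef), bio_sd >= 0)
  n_reg <- n_tf + (n_ef - n_tf_ef_overlap) + n_lncrna
  if (n_reg > n_genes) stop("more regulators than genes")
  structure(list(n_genes = n_genes, n_per_condition = n_per_condition,
                 dispersion = dispersion, mu_range = mu_range,
                 conditions = conditions, n_tf = n_tf, n_ef = n_ef,
                 n_tf_ef_overlap = n_tf_ef_overlap, n_lncrna = n_lncrna,
                 bio_sd = bio_sd),
            class = "synth_params")
}

.gene_ids <- function(n) sprintf("gene_%05d", seq_len(n))

## catalog over the leading genes: TFs first, EFs overlap the tail of the
## TF block, lncRNAs follow
.synth_catalog <- function(params) {
  ids <- .gene_ids(params$n_genes)
  out <- list()
  tf <- if (params$n_tf) ids[seq_len(params$n_tf)] else character(0)
  ef_start <- params$n_tf - params$n_tf_ef_overlap + 1L
  ef <- if (params$n_ef) ids[seq(ef_start, ef_start + params$n_ef - 1L)] else character(0)
  lnc_start <- params$n_tf + params$n_ef - params$n_tf_ef_overlap + 1L
  lnc <- if (params$n_lncrna) ids[seq(lnc_start, lnc_start + params$n_lncrna - 1L)] else character(0)
  for (g in tf) out[[g]] <- c(out[[g]], "TF")
  for (g in ef) out[[g]] <- c(out[[g]], "EF")
  for (g in lnc) out[[g]] <- c(out[[g]], "lncRNA")
  regulator_catalog(out)
}

.synth_dimnames <- function(params) {
  n <- params$n_per_condition
  donors <- sprintf("d%03d", seq_len(n))
  samples <- c(paste0(params$conditions[1], "_", donors),
               paste0(params$conditions[2], "_", donors))
  condition <- stats::setNames(rep(params$conditions, each = n), samples)
  pair <- stats::setNames(rep(donors, 2L), samples)
  list(samples = samples, condition = condition, pair = pair)
}

.rcounts <- function(n, mu, alpha) {
  if (alpha <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / alpha)
}

#' Generate a null two-condition count matrix
#'
#' Counts are drawn per gene from NB(mean `mu_g`, dispersion `alpha`), with
#' `mu_g` log-uniform over the configured range and the identical law in
#' both conditions — no differential expression, no wiring. Deterministic
#' given the seed.
#'
#' @param params a [synth_params()].
#' @param seed integer RNG seed.
#' @return a [count_matrix()] with paired sample labels.
#' @export
generate_null <- function(params, seed) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(seed)
  dn <- .synth_dimnames(params)
  G <- params$n_genes
  n <- length(dn$samples)
  mu <- exp(stats::runif(G, log(params$mu_range[1]), log(params$mu_range[2])))
  counts <- matrix(.rcounts(G * n, rep(mu, n), params$dispersion), nrow = G,
                   dimnames = list(.gene_ids(G), dn$samples))
  count_matrix(counts, dn$condition, pair = dn$pair,
               condition_levels = params$conditions)
}

#' Define the planted truth for a wired fixture
#'
#' Chooses (reproducibly from the seed) a set of DE genes with planted
#' fold-changes (alternating up/down in condition 1) among the
#' non-regulator genes, and designates wired regulators whose targets are
#' the first DE genes.
#'
#' @param params a [synth_params()].
#' @param seed integer seed (stored; [generate_wired()] reuses it).
#' @param n_de number of planted DE genes.
#' @param fold_change fold-change magnitude applied in condition 1.
#' @param n_wired number of wired regulators (taken from the start of the
#'   catalog, i.e. TFs).
#' @param n_targets targets per wired regulator (must be `<= n_de`).
#' @param rho wiring strength in `[0, 1]`: the latent co-expression between
#'   a wired regulator and its targets in condition 1.
#' @return a list of class `synthetic_truth` with elements `de_genes`
#'   (named fold-change vector), `wired_regulators` (named list with
#'   `targets` and `rho`), `seed`, `params`.
#' @export
synthetic_truth <- function(params, seed, n_de = 100, fold_change = 4,
                            n_wired = 1, n_targets = 20, rho = 0.9) {
  stopifnot(inherits(params, "synth_params"), rho >= 0, rho <= 1,
            fold_change > 0, n_targets <= n_de)
  ids <- .gene_ids(params$n_genes)
  cat. <- .synth_catalog(params)
  regs <- names(cat.$classes_of)
  if (n_wired > length(regs)) stop("more wired regulators than catalog entries")
  pool <- setdiff(ids, regs)
  if (n_de > length(pool)) stop("not enough non-regulator genes for the DE set")
  set.seed(seed)
  de <- sort(sample(pool, n_de))
  ## wired targets (the first n_targets DE genes) form a coherent module,
  ## all up-regulated in condition 1; the remaining DE genes alternate
  ## direction so the background is balanced
  fc <- rep(c(fold_change, 1 / fold_change), length.out = n_de)
  fc[seq_len(n_targets)] <- fold_change
  de_genes <- stats::setNames(fc, de)
  wired <- stats::setNames(lapply(seq_len(n_wired), function(i)
    list(targets = de[seq_len(n_targets)], rho = rho)), regs[seq_len(n_wired)])
  structure(list(de_genes = de_genes, wired_regulators = wired,
                 seed = seed, params = params),
            class = "synthetic_truth")
}

#' Generate a wired two-condition count matrix
#'
#' Planted DE genes have their mean multiplied by the fold-change in
#' condition 1. Each wired regulator shares a latent per-sample lognormal
#' factor (sd `bio_sd` on the natural-log scale, mean-corrected) with its
#' targets in condition 1 only, mixed with weight `rho` against independent
#' noise, so the latent log-profiles of regulator and target correlate at
#' `rho` in condition 1 and 0 in condition 2. Counts are Poisson-gamma
#' (negative binomial) around the exponentiated latent. With `rho = 0` no
#' latent factor is injected at all, and the output reduces to the null
#' generator plus fold-changes.
#'
#' @param params a [synth_params()].
#' @param truth a [synthetic_truth()] (targets must be planted DE genes).
#' @return list with elements `matrix` (a [count_matrix()]), `catalog`
#'   (a [regulator_catalog()]), `truth`.
#' @export
generate_wired <- function(params, truth) {
  stopifnot(inherits(params, "synth_params"), inherits(truth, "synthetic_truth"))
  for (w in truth$wired_regulators)
    if (!all(w$targets %in% names(truth$de_genes)))
      stop("wired targets must be planted DE genes")
  set.seed(truth$seed + 1L)
  dn <- .synth_dimnames(params)
  G <- params$n_genes
  n1 <- params$n_per_condition
  ids <- .gene_ids(G)
  mu <- exp(stats::runif(G, log(params$mu_range[1]), log(params$mu_range[2])))
  names(mu) <- ids

  ## latent log-means; condition 1 carries fold changes and wiring
  L1 <- matrix(log(mu), G, n1, dimnames = list(ids, NULL))
  L2 <- L1
  de <- names(truth$de_genes)
  L1[de, ] <- L1[de, ] + log(truth$de_genes)
  sb <- params$bio_sd
  for (reg in names(truth$wired_regulators)) {
    w <- truth$wired_regulators[[reg]]
    if (w$rho == 0 || sb == 0) next
    u <- stats::rnorm(n1)
    L1[reg, ] <- L1[reg, ] + sb * u - sb^2 / 2
    for (tg in w$targets) {
      eps <- stats::rnorm(n1)
      L1[tg, ] <- L1[tg, ] + sb * (w$rho * u + sqrt(1 - w$rho^2) * eps) - sb^2 / 2
    }
  }
  c1 <- matrix(.rcounts(length(L1), exp(L1), params$dispersion), nrow = G)
  c2 <- matrix(.rcounts(length(L2), exp(L2), params$dispersion), nrow = G)
  counts <- cbind(c1, c2)
  dimnames(counts) <- list(ids, dn$samples)
  m <- count_matrix(counts, dn$condition, pair = dn$pair,
                    condition_levels = params$conditions)
  list(matrix = m, catalog = .synth_catalog(params), truth = truth)
}

#' Write the planted truth to a sidecar TSV
#'
#' @param truth a [synthetic_truth()].
#' @param path destination TSV.
#' @return invisibly, the path.
#' @export
write_truth <- function(truth, path) {
  rows <- data.frame(record = "seed", id = "seed",
                     value = as.character(truth$seed), extra = "",
                     stringsAsFactors = FALSE)
  if (length(truth$de_genes))
    rows <- rbind(rows, data.frame(record = "de_gene",
                                   id = names(truth$de_genes),
                                   value = .fmt_num(unname(truth$de_genes)),
                                   extra = "", stringsAsFactors = FALSE))
  for (reg in names(truth$wired_regulators)) {
    w <- truth$wired_regulators[[reg]]
    rows <- rbind(rows, data.frame(record = "wired_regulator", id = reg,
                                   value = .fmt_num(w$rho),
                                   extra = paste(w$targets, collapse = ","),
                                   stringsAsFactors = FALSE))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a truth sidecar written by [write_truth()]
#'
#' @param path TSV path.
#' @return a `synthetic_truth` (without the generating `params`).
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          stringsAsFactors = FALSE)
  de <- df[df$record == "de_gene", , drop = FALSE]
  wr <- df[df$record == "wired_regulator", , drop = FALSE]
  wired <- stats::setNames(lapply(seq_len(nrow(wr)), function(i)
    list(targets = strsplit(wr$extra[i], ",", fixed = TRUE)[[1L]],
         rho = as.numeric(wr$value[i]))), wr$id)
  structure(list(de_genes = stats::setNames(as.numeric(de$value), de$id),
                 wired_regulators = wired,
                 seed = as.integer(df$value[df$record == "seed"][1L]),
                 params = NULL),
            class = "synthetic_truth")
}
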