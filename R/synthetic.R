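#' Simulation configuration for synthetic trio cohorts
#'
#' Defines the study conditions of the synthetic generator. Defaults mirror
#' the published compendium: five case cohorts at their curated trio
#' counts, and marginal per-trio DNM rates taken from the control cohort
#' (411 LoF, 2257 missense, 932 synonymous DNMs over 3391 trios), with the
#' deleterious fraction of missense set to the control Dmis share
#' (662/2257). Risk-gene structure follows the gamma-Poisson model:
#' a fraction `pi` of genes are risk genes per disorder, drawn partly from
#' a common cross-disorder pool, with class relative risks sampled from
#' Gamma(gamma_bar*beta, beta).
#'
#' @param n_genes Number of genes in the universe (default 2000, a desk
#'   scale; larger universes are supported).
#' @param cohorts Named trio counts of the case cohorts.
#' @param control_trios Trio count of the unaffected control cohort.
#' @param per_trio_rate Named expected DNMs per trio for classes `LoF`,
#'   `mis`, `synonymous`.
#' @param dmis_fraction Fraction of missense that is deleterious, in
#'   \[0,1\].
#' @param pi Named fraction of risk genes per disorder, in \[0,1\].
#' @param shared_pool_fraction Fraction of each disorder's risk genes drawn
#'   from the common cross-disorder pool, in \[0,1\].
#' @param gamma_bar Named mean relative risks (>= 1) for `LoF` and `Dmis`.
#' @param beta Gamma-prior rate parameter (> 0).
#' @param sigma_log SD of the log-normal per-gene mutability spread.
#' @param dmis_threshold Deleteriousness-score threshold used when emitting
#'   missense records (scores are generated consistently with it).
#' @param seed Integer seed.
#' @return List with class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       cohorts = c(ASD = 6511, UDD = 4293, EE = 933,
                                   ID = 1022, SCZ = 1094),
                       control_trios = 3391,
                       per_trio_rate = c(LoF = 411 / 3391, mis = 2257 / 3391,
                                         synonymous = 932 / 3391),
                       dmis_fraction = 662 / 2257,
                       pi = c(ASD = 0.05, UDD = 0.05, EE = 0.05,
                              ID = 0.05, SCZ = 0.05),
                       shared_pool_fraction = 0.5,
                       gamma_bar = c(LoF = 20, Dmis = 4.7),
                       beta = 1,
                       sigma_log = 1,
                       dmis_threshold = 0.7,
                       seed = 1) {
  stopifnot(n_genes >= 1, all(cohorts > 0), control_trios > 0,
            all(per_trio_rate > 0),
            all(c("LoF", "mis", "synonymous") %in% names(per_trio_rate)),
            dmis_fraction >= 0, dmis_fraction <= 1,
            all(pi >= 0), all(pi <= 1),
            shared_pool_fraction >= 0, shared_pool_fraction <= 1,
            all(gamma_bar >= 1), beta > 0, sigma_log >= 0)
  if (!setequal(names(pi), names(cohorts))) {
    stop("'pi' must be named for exactly the case cohorts")
  }
  structure(list(n_genes = as.integer(n_genes), cohorts = cohorts,
                 control_trios = control_trios,
                 per_trio_rate = per_trio_rate,
                 dmis_fraction = dmis_fraction, pi = pi[names(cohorts)],
                 shared_pool_fraction = shared_pool_fraction,
                 gamma_bar = gamma_bar, beta = beta, sigma_log = sigma_log,
                 dmis_threshold = dmis_threshold, seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @param path YAML file path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(lapply(unclass(config), function(x) {
    if (!is.null(names(x))) as.list(x) else x
  }), path, precision = 17)  # full double precision so reloads are identical
  invisible(path)
}

#' @rdname sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(sim_config, lapply(raw, function(x) {
    if (is.list(x)) unlist(x) else x
  }))
}

#' Build the synthetic gene universe with per-gene mutation rates
#'
#' Per-gene per-class mutability is drawn log-normally across genes (a
#' coarse stand-in for gene length and trinucleotide context effects) and
#' rescaled so that for every class the genome-wide per-trio rate
#' sum(2*mu) matches the configured marginal exactly. The missense rate is
#' split into Dmis (`dmis_fraction`) and Tmis (the remainder).
#'
#' @param config [sim_config()] object.
#' @param set_seed Seed the RNG from `config$seed` (default TRUE; turned
#'   off when called inside [simulate_study()], which seeds once).
#' @return data.frame: gene, mu_lof, mu_dmis, mu_tmis, mu_syn.
#' @export
build_gene_universe <- function(config, set_seed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (set_seed) set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("G%05d", seq_len(n))
  scaled <- function(rate) {
    w <- stats::rlnorm(n, 0, config$sigma_log)
    w / sum(w) * rate / 2   # sum(2*mu) == rate exactly
  }
  mu_lof <- scaled(config$per_trio_rate[["LoF"]])
  mu_mis <- scaled(config$per_trio_rate[["mis"]])
  mu_syn <- scaled(config$per_trio_rate[["synonymous"]])
  data.frame(gene = genes,
             mu_lof = mu_lof,
             mu_dmis = mu_mis * config$dmis_fraction,
             mu_tmis = mu_mis * (1 - config$dmis_fraction),
             mu_syn = mu_syn,
             stringsAsFactors = FALSE)
}

#' Assign risk genes and relative risks across disorders
#'
#' For each disorder, floor(pi * n_genes) genes become risk genes. A
#' fraction `shared_pool_fraction` of them is sampled from one common pool
#' of size max over disorders of the per-disorder risk count (inducing
#' cross-disorder overlap); the remainder is drawn disjointly across
#' disorders. Each risk gene receives LoF and Dmis relative risks sampled
#' from Gamma(gamma_bar*beta, beta) — the same prior the Bayes factor
#' integrates — while Tmis and synonymous risks stay at 1 everywhere.
#'
#' @param universe Output of [build_gene_universe()].
#' @param config [sim_config()] object.
#' @return The universe with logical columns `risk_<disorder>` and numeric
#'   columns `gamma_lof_<disorder>`, `gamma_dmis_<disorder>`.
#' @export
assign_risk_genes <- function(universe, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(universe)
  disorders <- names(config$cohorts)
  n_risk <- floor(config$pi * n)
  if (any(config$pi > 0 & n_risk < 1)) {
    warning("pi * n_genes < 1 for disorder(s): ",
            paste(disorders[config$pi > 0 & n_risk < 1], collapse = ", "),
            "; zero risk genes assigned")
  }
  pool_size <- max(n_risk, 0)
  pool <- if (pool_size > 0) sample(universe$gene, pool_size) else character(0)
  available <- setdiff(universe$gene, pool)
  for (d in disorders) {
    nr <- n_risk[[d]]
    n_shared <- round(config$shared_pool_fraction * nr)
    shared <- if (n_shared > 0) sample(pool, n_shared) else character(0)
    n_uniq <- nr - n_shared
    uniq <- if (n_uniq > 0) {
      picked <- sample(available, n_uniq)
      available <- setdiff(available, picked)
      picked
    } else character(0)
    risk <- universe$gene %in% c(shared, uniq)
    g_lof <- g_dmis <- rep(1, n)
    k <- sum(risk)
    if (k > 0) {
      g_lof[risk] <- stats::rgamma(k, shape = config$gamma_bar[["LoF"]] *
                                     config$beta, rate = config$beta)
      g_dmis[risk] <- stats::rgamma(k, shape = config$gamma_bar[["Dmis"]] *
                                      config$beta, rate = config$beta)
    }
    universe[[paste0("risk_", d)]] <- risk
    universe[[paste0("gamma_lof_", d)]] <- g_lof
    universe[[paste0("gamma_dmis_", d)]] <- g_dmis
  }
  universe
}

#' Simulate one trio cohort of de novo mutations
#'
#' Per gene and class the DNM count is Poisson(2 * n_trios * mu * gamma),
#' with gamma = 1 for controls, for non-risk genes, and always for Tmis and
#' synonymous. Counts are expanded to one record per DNM with synthetic
#' sample ids; missense records carry a deleteriousness score on the
#' correct side of the configured threshold, so classification round-trips
#' exactly.
#'
#' @param universe Universe with risk columns (see [assign_risk_genes()]);
#'   a plain universe is treated as all-non-risk (e.g. controls).
#' @param disorder Cohort label; `"control"` or a configured disorder.
#' @param n_trios Number of trios (0 gives an empty cohort).
#' @param config [sim_config()] object (threshold and labels).
#' @param seed Optional integer seed.
#' @return List with class `simulated_cohort`: `disorder`, `n_trios`,
#'   `records` (DNM table rows), `truth` (gene, risk, gamma_lof,
#'   gamma_dmis).
#' @export
simulate_cohort <- function(universe, disorder, n_trios, config,
                            seed = NULL) {
  stopifnot(inherits(config, "sim_config"), n_trios >= 0)
  if (!is.null(seed)) set.seed(seed)
  is_control <- identical(disorder, "control")
  if (!is_control && !disorder %in% names(config$cohorts)) {
    stop("unknown disorder label: ", disorder)
  }
  n <- nrow(universe)
  has_risk <- paste0("risk_", disorder) %in% names(universe)
  g_lof <- if (!is_control && has_risk)
    universe[[paste0("gamma_lof_", disorder)]] else rep(1, n)
  g_dmis <- if (!is_control && has_risk)
    universe[[paste0("gamma_dmis_", disorder)]] else rep(1, n)
  counts <- list(
    LoF = stats::rpois(n, 2 * n_trios * universe$mu_lof * g_lof),
    Dmis = stats::rpois(n, 2 * n_trios * universe$mu_dmis * g_dmis),
    Tmis = stats::rpois(n, 2 * n_trios * universe$mu_tmis),
    synonymous = stats::rpois(n, 2 * n_trios * universe$mu_syn))
  thr <- config$dmis_threshold
  recs <- lapply(names(counts), function(cl) {
    x <- counts[[cl]]
    total <- sum(x)
    if (total == 0) return(NULL)
    gene <- rep(universe$gene, x)
    consequence <- switch(cl,
      LoF = sample(c("stopgain", "stoploss", "splicing", "frameshift"),
                   total, replace = TRUE),
      Dmis = rep("missense", total),
      Tmis = rep("missense", total),
      synonymous = rep("synonymous", total))
    score <- switch(cl,
      Dmis = thr + stats::runif(total) * (1 - thr),
      Tmis = stats::runif(total) * thr * 0.999,
      rep(NA_real_, total))
    data.frame(study_id = "synthetic", disorder = disorder,
               sample_id = paste0(disorder, "_trio",
                                  sample.int(max(n_trios, 1), total,
                                             replace = TRUE)),
               gene = gene, consequence = consequence, score = score,
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, recs)
  if (is.null(records)) {
    records <- data.frame(study_id = character(0), disorder = character(0),
                          sample_id = character(0), gene = character(0),
                          consequence = character(0), score = numeric(0),
                          stringsAsFactors = FALSE)
  }
  truth <- data.frame(gene = universe$gene,
                      risk = if (!is_control && has_risk)
                        universe[[paste0("risk_", disorder)]] else
                          rep(FALSE, n),
                      gamma_lof = g_lof, gamma_dmis = g_dmis,
                      stringsAsFactors = FALSE)
  structure(list(disorder = disorder, n_trios = n_trios,
                 records = records, truth = truth),
            class = "simulated_cohort")
}

#' Simulate a full multi-cohort trio study
#'
#' Seeds the RNG once from the config, builds the universe, assigns risk
#' genes, and simulates every case cohort plus the control. The combined
#' record table, trio counts, rates and per-disorder truth give every
#' downstream stage a complete, self-consistent input.
#'
#' @param config [sim_config()] object.
#' @return List: `config`, `universe`, `cohorts` (named list of
#'   [simulate_cohort()] results incl. `control`), `records` (all rows
#'   bound), `trio_counts` (named, incl. control).
#' @export
simulate_study <- function(config = sim_config()) {
  set.seed(config$seed)
  universe <- build_gene_universe(config, set_seed = FALSE)
  universe <- assign_risk_genes(universe, config)
  cohorts <- lapply(names(config$cohorts), function(d) {
    simulate_cohort(universe, d, config$cohorts[[d]], config)
  })
  names(cohorts) <- names(config$cohorts)
  cohorts$control <- simulate_cohort(universe, "control",
                                     config$control_trios, config)
  records <- do.call(rbind, lapply(cohorts, `[[`, "records"))
  rownames(records) <- NULL
  trio_counts <- c(config$cohorts, control = config$control_trios)
  list(config = config, universe = universe, cohorts = cohorts,
       records = records, trio_counts = trio_counts)
}

#' Simulate a toy expression matrix with planted coexpression modules
#'
#' Genes are split into K modules, each with a smooth stage-dependent mean
#' profile over samples drawn from the cosine basis cos(pi*k*stage)
#' (module 1 high early / low late, module 2 U-shaped, and so on). The
#' basis profiles are near-orthogonal across the stage grid, so
#' between-module correlations sit near zero — required for module
#' recovery under an absolute-correlation edge rule. Each gene is a
#' positive scaling of its module profile plus i.i.d. Gaussian noise; with
#' zero noise, within-module correlations are exactly 1.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param k_modules Number of modules K (<= n_genes).
#' @param noise_sd Gaussian noise SD, default 0.2.
#' @param seed Optional integer seed.
#' @param profiles Optional K x n_samples matrix of module mean profiles.
#' @return List: `expr` (genes x samples matrix), `modules` (data.frame
#'   gene, module).
#' @export
simulate_expression <- function(n_genes, n_samples, k_modules = 2,
                                noise_sd = 0.2, seed = NULL,
                                profiles = NULL) {
  if (k_modules > n_genes) stop("more modules than genes")
  stopifnot(n_samples >= 3, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  stage <- seq(0, 1, length.out = n_samples)
  if (is.null(profiles)) {
    profiles <- t(sapply(seq_len(k_modules), function(k) cos(pi * k * stage)))
  }
  stopifnot(nrow(profiles) == k_modules, ncol(profiles) == n_samples)
  module <- rep_len(seq_len(k_modules), n_genes)
  loading <- stats::runif(n_genes, 0.5, 1.5)
  expr <- profiles[module, , drop = FALSE] * loading +
    matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd), n_genes)
  rownames(expr) <- sprintf("G%05d", seq_len(n_genes))
  colnames(expr) <- sprintf("S%03d", seq_len(n_samples))
  list(expr = expr,
       modules = data.frame(gene = rownames(expr),
                            module = paste0("M", module),
                            stringsAsFactors = FALSE))
}

#' Simulate a protein-protein interaction table
#'
#' Stochastic block edges: pairs within the same module connect with
#' probability `p_within`, across modules with `p_between`; combined
#' scores are uniform on `score_range`. No self-edges, no duplicate pairs.
#'
#' @param genes Character vector of gene ids.
#' @param modules data.frame (gene, module) covering `genes`; genes
#'   without a module never share one.
#' @param p_within,p_between Edge probabilities, 0 <= p_between <=
#'   p_within <= 1.
#' @param score_range Length-2 numeric, default c(150, 999).
#' @param seed Optional integer seed.
#' @return data.frame: gene_a, gene_b, combined_score.
#' @export
simulate_ppi <- function(genes, modules, p_within = 0.3, p_between = 0.02,
                         score_range = c(150, 999), seed = NULL) {
  stopifnot(p_between >= 0, p_within <= 1, p_between <= p_within)
  if (!is.null(seed)) set.seed(seed)
  mod <- modules$module[match(genes, modules$gene)]
  n <- length(genes)
  if (n < 2) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      combined_score = numeric(0)))
  }
  idx <- utils::combn(n, 2)
  same <- !is.na(mod[idx[1, ]]) & !is.na(mod[idx[2, ]]) &
    mod[idx[1, ]] == mod[idx[2, ]]
  prob <- ifelse(same, p_within, p_between)
  keep <- stats::runif(ncol(idx)) < prob
  data.frame(gene_a = genes[idx[1, keep]],
             gene_b = genes[idx[2, keep]],
             combined_score = stats::runif(sum(keep), score_range[1],
                                           score_range[2]),
             stringsAsFactors = FALSE)
}
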