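#' TADA-Denovo hyperparameters
#'
#' The gamma-Poisson gene model: in a risk gene the DNM count of class c is
#' Poisson(2 N mu_c gamma) with relative risk gamma ~ Gamma(shape =
#' gamma_bar * beta, rate = beta) (mean gamma_bar); in a non-risk gene
#' gamma = 1. `pi` is the prior fraction of risk genes. Defaults follow the
#' values long used with this model in trio studies: pi = 0.05,
#' gamma_bar 20 for LoF and 4.7 for Dmis with beta = 1; the aggregate Pfun
#' class defaults to gamma_bar = 10, roughly the mutation-rate-weighted
#' mean of the two.
#'
#' @param classes Variant classes modeled jointly: `"Pfun"` (default, the
#'   aggregate of LoF and Dmis) or `c("LoF", "Dmis")`.
#' @param pi Prior risk-gene fraction in (0, 1).
#' @param gamma_bar Named mean relative risks (>= 1) per class.
#' @param beta Named gamma-prior rate parameters (> 0) per class.
#' @return List with class `tada_hyperparams`.
#' @export
tada_hyperparams <- function(classes = "Pfun", pi = 0.05,
                             gamma_bar = c(LoF = 20, Dmis = 4.7, Pfun = 10),
                             beta = c(LoF = 1, Dmis = 1, Pfun = 1)) {
  stopifnot(length(classes) >= 1, pi > 0, pi < 1)
  missing_gb <- setdiff(classes, names(gamma_bar))
  missing_b <- setdiff(classes, names(beta))
  if (length(missing_gb) || length(missing_b)) {
    stop("gamma_bar/beta must be named for every modeled class")
  }
  stopifnot(all(gamma_bar[classes] >= 1), all(beta[classes] > 0))
  structure(list(classes = classes, pi = pi,
                 gamma_bar = gamma_bar[classes], beta = beta[classes]),
            class = "tada_hyperparams")
}

#' Log Bayes factor of the gamma-Poisson de novo model for one class
#'
#' Marginal likelihood ratio of x ~ Poisson(lambda0 * gamma), gamma ~
#' Gamma(gamma_bar*beta, beta), against x ~ Poisson(lambda0), with
#' lambda0 = 2 * n_trios * mu. Closed form, evaluated in log space:
#' lgamma(x + a) - lgamma(a) + a*log(beta/(beta+lambda0))
#' - x*log(beta+lambda0) + lambda0, with shape a = gamma_bar*beta.
#' Vectorized over `x` and `mu`.
#'
#' @param x Observed DNM count(s), non-negative integer.
#' @param mu Per-chromosome per-generation mutation rate(s) of the class.
#' @param n_trios Number of trios N (2N chromosomes).
#' @param gamma_bar Mean relative risk of the prior.
#' @param beta Rate parameter of the gamma prior.
#' @return Log Bayes factor(s).
#' @export
log_bf_class <- function(x, mu, n_trios, gamma_bar, beta) {
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers")
  }
  stopifnot(all(mu > 0), n_trios > 0, gamma_bar > 0, beta > 0)
  lambda0 <- 2 * n_trios * mu
  a <- gamma_bar * beta
  lgamma(x + a) - lgamma(a) + a * log(beta / (beta + lambda0)) -
    x * log(beta + lambda0) + lambda0
}

#' Total log Bayes factor of a gene across classes
#'
#' Classes contribute independent evidence, so the total is the sum of
#' per-class log Bayes factors. Classes with zero mutation rate are
#' excluded with a warning (no evidence can be assessed for them).
#'
#' @param counts Named counts per class (must cover `params$classes`).
#' @param rates Named mutation rates per class.
#' @param n_trios Number of trios.
#' @param params [tada_hyperparams()] object.
#' @return Total log Bayes factor (scalar).
#' @export
gene_bf <- function(counts, rates, n_trios, params) {
  stopifnot(inherits(params, "tada_hyperparams"))
  missing_rate <- setdiff(params$classes, names(rates))
  if (length(missing_rate)) {
    stop("missing mutation rate for class(es): ",
         paste(missing_rate, collapse = ", "))
  }
  missing_count <- setdiff(params$classes, names(counts))
  if (length(missing_count)) {
    stop("missing count for class(es): ",
         paste(missing_count, collapse = ", "))
  }
  total <- 0
  for (cl in params$classes) {
    if (rates[[cl]] <= 0) {
      warning("class ", cl, " has zero mutation rate; excluded")
      next
    }
    total <- total + log_bf_class(counts[[cl]], rates[[cl]], n_trios,
                                  params$gamma_bar[[cl]], params$beta[[cl]])
  }
  total
}

#' Bayesian FDR (q-values) from Bayes factors
#'
#' Posterior probability of the null for gene i is
#' P0_i = (1-pi) / ((1-pi) + pi*BF_i). Genes are ranked by decreasing
#' Bayes factor and q_i is the running mean of P0 over the top-i genes —
#' the expected proportion of nulls among genes called at or above i. Tied
#' Bayes factors share the q of the last tied position (the most
#' conservative of the block). Output is in input order.
#'
#' @param log_bf Numeric vector of log Bayes factors.
#' @param pi Prior risk-gene fraction in (0, 1).
#' @return q-values in \[0, 1\], same order as `log_bf`.
#' @export
bayesian_fdr <- function(log_bf, pi) {
  stopifnot(pi > 0, pi < 1)
  n <- length(log_bf)
  if (n == 0) return(numeric(0))
  # P0 computed stably: 1/(1 + exp(log(pi/(1-pi)) + log_bf))
  p0 <- stats::plogis(log(pi / (1 - pi)) + log_bf, lower.tail = FALSE)
  ord <- order(log_bf, decreasing = TRUE)
  q_sorted <- cumsum(p0[ord]) / seq_len(n)
  # ties share the q at the end of their block
  bf_sorted <- log_bf[ord]
  last_of_block <- rev(!duplicated(rev(bf_sorted)))
  idx <- cummax_from_last(last_of_block)
  q_sorted <- q_sorted[idx]
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

# index of the next position (>= i) where flag is TRUE
cummax_from_last <- function(flag) {
  n <- length(flag)
  idx <- integer(n)
  nxt <- n
  for (i in n:1) {
    if (flag[i]) nxt <- i
    idx[i] <- nxt
  }
  idx
}

#' Candidate-gene tiers from the q-value
#'
#' Tier 1: q <= 1e-4; tier 2: (1e-4, 1e-3]; tier 3: (1e-3, 1e-2];
#' tier 4: (1e-2, 0.05); `"none"` otherwise (q = 0.05 is not a candidate).
#'
#' @param q Numeric vector of q-values in \[0,1\].
#' @return Character vector of tiers.
#' @export
assign_tiers <- function(q) {
  stopifnot(all(q >= 0), all(q <= 1))
  out <- rep("none", length(q))
  out[q < 0.05] <- "4"
  out[q <= 1e-2] <- "3"
  out[q <= 1e-3] <- "2"
  out[q <= 1e-4] <- "1"
  out
}

#' Shared versus unique candidate genes
#'
#' A gene with putative functional (Pfun) DNMs in at least two case
#' cohorts is shared; in exactly one, unique.
#'
#' @param pfun_counts Matrix or data.frame of Pfun counts, genes x case
#'   cohorts.
#' @return data.frame: gene (rownames if present), `n_disorders`, `status`
#'   (`"shared"`, `"unique"`, or `"none"` when no cohort carries a hit).
#' @export
classify_shared_unique <- function(pfun_counts) {
  m <- as.matrix(pfun_counts)
  if (any(m < 0)) stop("counts must be non-negative")
  n_dis <- rowSums(m > 0)
  status <- ifelse(n_dis >= 2, "shared", ifelse(n_dis == 1, "unique", "none"))
  data.frame(gene = if (!is.null(rownames(m))) rownames(m) else
               as.character(seq_len(nrow(m))),
             n_disorders = as.integer(n_dis), status = status,
             stringsAsFactors = FALSE)
}

#' Exact conditional disorder-bias test
#'
#' Tests whether a gene's per-trio DNM rate in one disorder exceeds the
#' pooled rate of the remaining disorders. Conditional on the total count,
#' under equal per-trio rates x_d ~ Binomial(x_d + x_rest,
#' N_d / (N_d + N_rest)); the one-sided p is P(X >= x_d).
#'
#' @param x_d Count in the focal disorder.
#' @param n_d Trios in the focal disorder.
#' @param x_rest Count pooled over the other disorders.
#' @param n_rest Trios pooled over the other disorders.
#' @return One-sided p-value.
#' @export
poisson_bias_test <- function(x_d, n_d, x_rest, n_rest) {
  stopifnot(x_d >= 0, x_rest >= 0, x_d + x_rest >= 1, n_d > 0, n_rest > 0)
  stats::pbinom(x_d - 1, x_d + x_rest, n_d / (n_d + n_rest),
                lower.tail = FALSE)
}

#' Per-cohort gene-by-class DNM count matrices
#'
#' @param records Classified DNM records (a `class` column is added via
#'   [classify_dnm()] if absent).
#' @param genes Character vector: the gene universe (rows of each matrix).
#' @param dmis_threshold Passed to [classify_dnm()] when classifying.
#' @return Named list (by cohort) of genes x class count matrices with
#'   columns LoF, Dmis, Tmis, synonymous and derived Pfun.
#' @export
tada_count_matrices <- function(records, genes, dmis_threshold = 0.7) {
  if (!"class" %in% names(records)) {
    records$class <- classify_dnm(records$consequence, records$score,
                                  dmis_threshold)
  }
  unknown <- setdiff(unique(records$gene), genes)
  if (length(unknown)) {
    stop("record gene(s) outside the universe: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if ("sample_id" %in% names(records)) {
    dup <- unique(records[, c("disorder", "sample_id")])
    shared <- dup$sample_id[duplicated(dup$sample_id)]
    if (length(shared)) {
      warning(length(shared), " sample id(s) appear in multiple cohorts; ",
              "pooled analyses may double-count them")
    }
  }
  lapply(split(records, records$disorder), function(r) {
    m <- table(factor(r$gene, levels = genes),
               factor(r$class, levels = c("LoF", "Dmis", "Tmis", "synonymous")))
    m <- unclass(m)[, , drop = FALSE]
    m <- cbind(m, Pfun = m[, "LoF"] + m[, "Dmis"])
    storage.mode(m) <- "integer"
    m
  })
}

#' TADA-Denovo gene prioritization across cohorts
#'
#' Two complementary strategies: per-disorder analysis of each case cohort,
#' and a combined analysis pooling counts (and trios) over all case cohorts
#' on the premise that the disorders share genetic components. A gene is a
#' candidate when its q-value falls below `q_cutoff` under either strategy
#' (the union, deduplicated). Tiers are assigned from the best (smallest)
#' q across strategies; shared/unique status counts the case cohorts with
#' at least one Pfun DNM.
#'
#' @param counts Named list of genes x class count matrices, one per case
#'   cohort (see [tada_count_matrices()]). All matrices must share rownames.
#' @param rates data.frame of per-gene rates with columns `gene`, `mu_lof`,
#'   `mu_dmis`, `mu_tmis`, `mu_syn`.
#' @param trios Named vector of trio counts covering every cohort in
#'   `counts`.
#' @param params [tada_hyperparams()] object.
#' @param mode `"both"` (default), `"per_disorder"`, or `"combined"`.
#' @param q_cutoff Candidate threshold on the q-value, default 0.05.
#' @return data.frame with one row per gene: pooled counts per class,
#'   `log_bf_combined`, `q_combined`, `q_best_single`, `best_disorder`,
#'   `q` (best across strategies), `candidate`, `tier`, `n_disorders`,
#'   `status`; per-disorder q-values are attached as attribute `q_matrix`.
#' @export
run_tada <- function(counts, rates, trios, params = tada_hyperparams(),
                     mode = c("both", "per_disorder", "combined"),
                     q_cutoff = 0.05) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "tada_hyperparams"))
  cohorts <- names(counts)
  missing_trios <- setdiff(cohorts, names(trios))
  if (length(missing_trios)) {
    stop("missing trio counts for cohort(s): ",
         paste(missing_trios, collapse = ", "))
  }
  genes <- rownames(counts[[1]])
  for (m in counts) stopifnot(identical(rownames(m), genes))
  rates <- rates[match(genes, rates$gene), ]
  if (any(is.na(rates$gene))) stop("rates missing for some genes")
  mu <- cbind(LoF = rates$mu_lof, Dmis = rates$mu_dmis,
              Pfun = rates$mu_lof + rates$mu_dmis)

  bf_of <- function(count_mat, n) {
    total <- rep(0, length(genes))
    for (cl in params$classes) {
      total <- total + log_bf_class(count_mat[, cl], mu[, cl], n,
                                    params$gamma_bar[[cl]], params$beta[[cl]])
    }
    total
  }

  q_mat <- NULL
  if (mode %in% c("both", "per_disorder")) {
    q_mat <- sapply(cohorts, function(d) {
      bayesian_fdr(bf_of(counts[[d]], trios[[d]]), params$pi)
    })
    rownames(q_mat) <- genes
  }
  log_bf_combined <- q_combined <- rep(NA_real_, length(genes))
  if (mode %in% c("both", "combined")) {
    pooled <- Reduce(`+`, counts)
    log_bf_combined <- bf_of(pooled, sum(trios[cohorts]))
    q_combined <- bayesian_fdr(log_bf_combined, params$pi)
  }

  q_best_single <- if (!is.null(q_mat)) apply(q_mat, 1, min) else
    rep(NA_real_, length(genes))
  best_disorder <- if (!is.null(q_mat)) {
    cohorts[apply(q_mat, 1, which.min)]
  } else NA_character_
  q <- pmin(q_best_single, q_combined, na.rm = TRUE)

  pooled_all <- Reduce(`+`, counts)
  pfun_by_cohort <- sapply(counts, function(m) m[, "Pfun"])
  su <- classify_shared_unique(pfun_by_cohort)

  out <- data.frame(gene = genes,
                    x_LoF = pooled_all[, "LoF"], x_Dmis = pooled_all[, "Dmis"],
                    x_Pfun = pooled_all[, "Pfun"],
                    log_bf_combined = log_bf_combined,
                    q_combined = q_combined,
                    q_best_single = q_best_single,
                    best_disorder = best_disorder,
                    q = q,
                    candidate = q < q_cutoff,
                    tier = assign_tiers(q),
                    n_disorders = su$n_disorders,
                    status = su$status,
                    stringsAsFactors = FALSE)
  flagged_zero <- out$candidate & out$n_disorders == 0
  if (any(flagged_zero)) {
    warning(sum(flagged_zero),
            " candidate gene(s) without any Pfun DNM; flagged as 'none'")
  }
  rownames(out) <- NULL
  attr(out, "q_matrix") <- q_mat
  attr(out, "params") <- params
  out
}

#' Disorder-bias screen for shared candidate genes
#'
#' For each shared gene (Pfun DNMs in >= 2 cohorts), tests every cohort
#' carrying a hit against the pooled remainder with
#' [poisson_bias_test()]; BH adjustment across all tests performed.
#'
#' @param counts Named list of genes x class count matrices (case cohorts).
#' @param trios Named trio counts.
#' @param tada_results Output of [run_tada()]; only candidate shared genes
#'   are screened.
#' @param alpha Significance threshold on the adjusted p, default 0.05.
#' @return data.frame: gene, disorder, x_d, x_rest, p, p_adj, biased.
#' @export
bias_screen <- function(counts, trios, tada_results, alpha = 0.05) {
  shared <- tada_results$gene[tada_results$candidate &
                                tada_results$status == "shared"]
  cohorts <- names(counts)
  rows <- list()
  for (g in shared) {
    x <- vapply(counts, function(m) m[g, "Pfun"], numeric(1))
    for (d in cohorts[x > 0]) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, disorder = d, x_d = x[[d]], x_rest = sum(x) - x[[d]],
        p = poisson_bias_test(x[[d]], trios[[d]], sum(x) - x[[d]],
                              sum(trios[cohorts]) - trios[[d]]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(gene = character(0), disorder = character(0),
                      x_d = integer(0), x_rest = integer(0),
                      p = numeric(0), p_adj = numeric(0),
                      biased = logical(0)))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$biased <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}
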