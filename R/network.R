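#' Coexpression edges at an absolute-correlation threshold
#'
#' Pearson correlation for every unordered gene pair of an expression
#' matrix; pairs with |R| strictly above the threshold become edges.
#' Constant-expression genes (zero variance) are excluded with a warning
#' since their correlation is undefined.
#'
#' @param expr Numeric matrix, genes x samples, with rownames.
#' @param threshold Absolute-correlation cutoff, default 0.8 (strict).
#' @return data.frame: gene_a, gene_b, r, weight = |r|.
#' @export
coexpression_edges <- function(expr, threshold = 0.8) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (ncol(expr) < 3) stop("need at least 3 samples for correlation")
  v <- apply(expr, 1, stats::var)
  if (any(v == 0)) {
    warning("excluding ", sum(v == 0), " constant-expression gene(s)")
    expr <- expr[v > 0, , drop = FALSE]
  }
  cm <- stats::cor(t(expr))
  idx <- which(abs(cm) > threshold & upper.tri(cm), arr.ind = TRUE)
  data.frame(gene_a = rownames(cm)[idx[, 1]],
             gene_b = rownames(cm)[idx[, 2]],
             r = cm[idx],
             weight = abs(cm[idx]),
             stringsAsFactors = FALSE)
}

#' Filter a protein-protein interaction table by combined score
#'
#' Keeps edges with score strictly above `min_score` (the "higher than"
#' convention; set `strict = FALSE` for >=). Self-edges are dropped with a
#' warning; symmetric duplicates collapse to one edge keeping the maximal
#' score.
#'
#' @param ppi data.frame with columns `gene_a`, `gene_b`, `combined_score`.
#' @param min_score Score cutoff, default 400.
#' @param strict Use strict inequality (default TRUE).
#' @return data.frame: gene_a, gene_b (canonical order), combined_score.
#' @export
filter_ppi <- function(ppi, min_score = 400, strict = TRUE) {
  stopifnot(all(c("gene_a", "gene_b", "combined_score") %in% names(ppi)),
            is.numeric(ppi$combined_score))
  self <- ppi$gene_a == ppi$gene_b
  if (any(self)) {
    warning("dropping ", sum(self), " self-edge(s)")
    ppi <- ppi[!self, , drop = FALSE]
  }
  a <- pmin(ppi$gene_a, ppi$gene_b)
  b <- pmax(ppi$gene_a, ppi$gene_b)
  key <- paste(a, b, sep = "\r")
  score <- tapply(ppi$combined_score, key, max)
  pair <- strsplit(names(score), "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(pair, `[`, "", 1),
                    gene_b = vapply(pair, `[`, "", 2),
                    combined_score = as.numeric(score),
                    stringsAsFactors = FALSE)
  keep <- if (strict) out$combined_score > min_score else
    out$combined_score >= min_score
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge coexpression and PPI edges into one annotated network
#'
#' Union graph over both edge types; per-node degrees are reported
#' separately per type, and annotated genes without edges remain as
#' degree-0 nodes (they are needed for in-network versus out-of-network
#' comparisons).
#'
#' @param coexpr Edge data.frame from [coexpression_edges()] (may be
#'   empty).
#' @param ppi Edge data.frame from [filter_ppi()] (may be empty).
#' @param annotations data.frame with at least columns `gene` and
#'   `n_disorders` (number of case cohorts with a Pfun DNM in the gene);
#'   must cover every gene appearing in an edge.
#' @return List with class `dnm_network`: `nodes` (annotations plus
#'   `degree_coexpression`, `degree_ppi`, `degree_total`, `in_network`) and
#'   `edges` (gene_a, gene_b, type, weight).
#' @export
merge_network <- function(coexpr, ppi, annotations) {
  stopifnot(all(c("gene", "n_disorders") %in% names(annotations)))
  ce <- if (nrow(coexpr)) {
    data.frame(gene_a = coexpr$gene_a, gene_b = coexpr$gene_b,
               type = "coexpression", weight = coexpr$weight,
               stringsAsFactors = FALSE)
  } else NULL
  pe <- if (nrow(ppi)) {
    data.frame(gene_a = ppi$gene_a, gene_b = ppi$gene_b,
               type = "ppi", weight = ppi$combined_score,
               stringsAsFactors = FALSE)
  } else NULL
  edges <- rbind(ce, pe)
  if (is.null(edges)) {
    edges <- data.frame(gene_a = character(0), gene_b = character(0),
                        type = character(0), weight = numeric(0),
                        stringsAsFactors = FALSE)
  }
  if (any(edges$gene_a == edges$gene_b)) stop("self-loop in edge input")
  edge_genes <- unique(c(edges$gene_a, edges$gene_b))
  unannot <- setdiff(edge_genes, annotations$gene)
  if (length(unannot)) {
    stop("unannotated node(s): ", paste(utils::head(unannot, 5), collapse = ", "))
  }
  nodes <- annotations
  deg <- function(type) {
    e <- edges[edges$type == type, ]
    tab <- table(c(e$gene_a, e$gene_b))
    out <- as.integer(tab[nodes$gene])
    out[is.na(out)] <- 0L
    out
  }
  nodes$degree_coexpression <- deg("coexpression")
  nodes$degree_ppi <- deg("ppi")
  nodes$degree_total <- nodes$degree_coexpression + nodes$degree_ppi
  nodes$in_network <- nodes$degree_total > 0
  structure(list(nodes = nodes, edges = edges), class = "dnm_network")
}

#' Degree versus number of disorders sharing a gene
#'
#' Spearman rank correlation (mid-rank ties) between a node's typed degree
#' and the number of disorders in which it carries Pfun DNMs — the
#' "shared genes are hubs" statistic. The p-value uses the large-sample t
#' approximation; for n <= 10 nodes a Monte Carlo permutation p (20,000
#' draws) replaces it. All-tied input is flagged and returns NA.
#'
#' @param network [merge_network()] result.
#' @param type `"coexpression"`, `"ppi"` or `"total"`.
#' @return List: `rho`, `p`, `n`, `method`.
#' @export
degree_vs_shared <- function(network, type = c("coexpression", "ppi", "total")) {
  type <- match.arg(type)
  nodes <- network$nodes
  if (nrow(nodes) < 3) stop("need at least 3 annotated nodes")
  deg <- nodes[[paste0("degree_", type)]]
  nd <- nodes$n_disorders
  if (length(unique(deg)) == 1 || length(unique(nd)) == 1) {
    warning("degree or disorder counts are all tied; correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = nrow(nodes),
                method = "undefined"))
  }
  rho <- stats::cor(deg, nd, method = "spearman")
  n <- length(deg)
  if (n <= 10) {
    set.seed(20240L)
    null_rho <- replicate(20000, stats::cor(deg, sample(nd),
                                            method = "spearman"))
    p <- (1 + sum(abs(null_rho) >= abs(rho))) / (length(null_rho) + 1)
    method <- "permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    method <- "t-approximation"
  }
  list(rho = rho, p = p, n = n, method = method)
}

#' Module-membership enrichment of a gene set
#'
#' One 2x2 Fisher test per module within the stated background: gene in
#' the set or not, versus gene in the module or not. Odds ratios use the
#' Haldane correction on zero cells; BH adjustment across modules.
#'
#' @param gene_set Character vector, subset of `background`.
#' @param modules data.frame with columns `gene`, `module`; module genes
#'   must lie in the background (genes outside any module simply count as
#'   not-in-module).
#' @param background Character vector: the universe for the contingency
#'   margins.
#' @return data.frame: module, k (set-in-module), set_size, module_size,
#'   background_size, or, p, p_adj.
#' @export
module_enrichment <- function(gene_set, modules, background) {
  if (!length(background)) stop("empty background")
  background <- unique(background)
  outside <- setdiff(gene_set, background)
  if (length(outside)) {
    stop("gene set members outside background: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  modules <- modules[modules$gene %in% background, , drop = FALSE]
  gene_set <- unique(gene_set)
  n_bg <- length(background)
  n_set <- length(gene_set)
  rows <- lapply(split(modules$gene, modules$module), function(mg) {
    mg <- unique(mg)
    k <- length(intersect(gene_set, mg))
    a <- k
    b <- n_set - k
    c <- length(mg) - k
    d <- n_bg - n_set - c
    orci <- odds_ratio_ci(a, b, c, d)
    data.frame(k = k, set_size = n_set, module_size = length(mg),
               background_size = n_bg, or = orci$or,
               p = fisher_two_tailed(a, b, c, d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- cbind(module = names(rows), out)
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Trend of a binary gene property with the number of sharing disorders
#'
#' Logistic regression of the indicator (e.g., module membership, network
#' membership) on the number of disorders carrying Pfun DNMs in the gene,
#' treated as a numeric score; the p-value is the likelihood-ratio test of
#' the slope, read as a monotone-trend test. Under perfect separation the
#' unpenalized fit diverges, so a Firth-penalized fit supplies the slope
#' and a penalized likelihood-ratio p, flagged in the output.
#'
#' @param indicator Logical (or 0/1) outcome per gene.
#' @param n_disorders Ordinal predictor per gene.
#' @return List: `slope`, `p`, `separation` (logical), `method`.
#' @export
shared_trend_test <- function(indicator, n_disorders) {
  y <- as.integer(indicator)
  stopifnot(length(y) == length(n_disorders), all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2) stop("need both outcome levels present")
  x <- as.numeric(n_disorders)
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  mu <- stats::fitted(fit)
  separated <- any(mu < 1e-8 | mu > 1 - 1e-8) || abs(stats::coef(fit)[2]) > 15
  if (!separated) {
    null_fit <- stats::glm(y ~ 1, family = stats::binomial())
    lr <- null_fit$deviance - fit$deviance
    return(list(slope = unname(stats::coef(fit)[2]),
                p = stats::pchisq(lr, df = 1, lower.tail = FALSE),
                separation = FALSE, method = "ml"))
  }
  full <- firth_logistic(y, x)
  null <- firth_logistic(y, NULL)
  lr <- 2 * (full$penalized_loglik - null$penalized_loglik)
  list(slope = unname(full$coef[2]), p = stats::pchisq(max(lr, 0), df = 1,
                                               lower.tail = FALSE),
       separation = TRUE, method = "firth")
}

# Firth-penalized logistic regression (intercept + optional single
# covariate), fitted by Newton steps on the bias-adjusted score.
firth_logistic <- function(y, x = NULL, max_iter = 200, tol = 1e-8) {
  X <- if (is.null(x)) matrix(1, length(y)) else cbind(1, x)
  beta <- rep(0, ncol(X))
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * w
    info <- crossprod(X, XW)
    h <- rowSums((X %*% solve(info)) * XW)
    score <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- solve(info, score)
    beta <- beta + drop(step)
    if (max(abs(score)) < tol) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  ll <- sum(y * log(mu) + (1 - y) * log1p(-mu))
  info <- crossprod(X, X * (mu * (1 - mu)))
  list(coef = beta, penalized_loglik = ll + 0.5 * determinant(info)$modulus[1])
}
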