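test_that("coexpression edges equal a brute-force recomputation", {
  set.seed(51)
  expr <- matrix(stats::rnorm(60), nrow = 6,
                 dimnames = list(paste0("g", 1:6), NULL))
  expr[2, ] <- expr[1, ]  # duplicated gene under two ids
  edges <- coexpression_edges(expr, threshold = 0.5)
  # brute force over all pairs
  brute <- list()
  for (i in 1:5) for (j in (i + 1):6) {
    r <- stats::cor(expr[i, ], expr[j, ])
    if (abs(r) > 0.5) brute[[length(brute) + 1]] <-
        data.frame(gene_a = paste0("g", i), gene_b = paste0("g", j), r = r)
  }
  brute <- do.call(rbind, brute)
  expect_equal(nrow(edges), nrow(brute))
  expect_equal(edges[order(edges$gene_a, edges$gene_b),
                     c("gene_a", "gene_b", "r")],
               brute[order(brute$gene_a, brute$gene_b), ],
               ignore_attr = TRUE)
  dup <- edges[edges$gene_a == "g1" & edges$gene_b == "g2", ]
  expect_equal(dup$weight, 1)

  expect_error(coexpression_edges(expr[, 1:2]), "3 samples")
  expr[3, ] <- 7
  expect_warning(coexpression_edges(expr, 0.5), "constant")
})

test_that("independent noise yields essentially no high-correlation edges", {
  set.seed(52)
  expr <- matrix(stats::rnorm(50 * 100), nrow = 50,
                 dimnames = list(paste0("g", 1:50), NULL))
  edges <- coexpression_edges(expr, threshold = 0.8)
  # analytic tail P(|r| > .8) at n = 100 is ~1e-17; 1225 pairs -> expect 0
  expect_equal(nrow(edges), 0)
})

test_that("PPI filtering is strict, deduplicating and self-loop aware", {
  ppi <- data.frame(gene_a = c("A", "A", "B", "C", "D"),
                    gene_b = c("B", "B", "A", "C", "E"),
                    combined_score = c(500, 450, 520, 900, 400))
  expect_warning(out <- filter_ppi(ppi), "self-edge")
  expect_equal(nrow(out), 1)  # (A,B) kept at max score; 400 excluded (strict)
  expect_equal(out$combined_score, 520)
  out2 <- suppressWarnings(filter_ppi(ppi, strict = FALSE))
  expect_true(any(out2$combined_score == 400))
  expect_equal(nrow(suppressWarnings(
    filter_ppi(transform(ppi, combined_score = 401)))), 2)
})

test_that("merged network keeps typed degrees and isolated annotated nodes", {
  ann <- data.frame(gene = c("A", "B", "C", "D"), n_disorders = c(3, 2, 1, 0))
  empty <- merge_network(data.frame(), data.frame(), ann)
  expect_equal(nrow(empty$edges), 0)
  expect_equal(empty$nodes$degree_total, rep(0L, 4))

  ce <- data.frame(gene_a = "A", gene_b = "B", r = 0.9, weight = 0.9)
  pe <- data.frame(gene_a = "A", gene_b = "B", combined_score = 700)
  net <- merge_network(ce, pe, ann)
  a <- net$nodes[net$nodes$gene == "A", ]
  expect_equal(a$degree_coexpression, 1L)
  expect_equal(a$degree_ppi, 1L)
  expect_equal(a$degree_total, 2L)
  expect_equal(nrow(net$edges), 2)
  expect_equal(sum(net$nodes$in_network), 2)  # connected fraction 2/4
  expect_error(merge_network(ce, data.frame(gene_a = "A", gene_b = "Z",
                                            combined_score = 500), ann),
               "unannotated")
})

test_that("degree-pleiotropy correlation is exact on a monotone fixture and null-centred", {
  # threshold graph whose degree sequence (3,3,2,4,1,5) equals the
  # n_disorders annotation: identical rank vectors give rho = 1
  edges <- data.frame(gene_a = c("g1", "g4", "g4", "g4", "g6", "g6", "g6",
                                 "g6", "g6"),
                      gene_b = c("g2", "g1", "g2", "g3", "g1", "g2", "g3",
                                 "g4", "g5"),
                      combined_score = 600)
  ann <- data.frame(gene = paste0("g", 1:6), n_disorders = c(3, 3, 2, 4, 1, 5))
  net <- merge_network(data.frame(), edges, ann)
  r <- degree_vs_shared(net, "ppi")
  expect_equal(r$rho, 1)
  expect_lt(r$p, 0.01)

  # permuted annotations: mean rho across runs is centred at zero
  set.seed(53)
  big_ann <- data.frame(gene = paste0("g", 1:200),
                        n_disorders = sample(0:5, 200, TRUE))
  big_edges <- data.frame(gene_a = sample(big_ann$gene, 400, TRUE),
                          gene_b = sample(big_ann$gene, 400, TRUE),
                          combined_score = 600)
  big_edges <- big_edges[big_edges$gene_a != big_edges$gene_b, ]
  rhos <- vapply(1:100, function(i) {
    shuf <- big_ann
    shuf$n_disorders <- sample(shuf$n_disorders)
    degree_vs_shared(merge_network(data.frame(), big_edges, shuf), "ppi")$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 3 * stats::sd(rhos) / sqrt(length(rhos)))

  # all-tied annotation is flagged as undefined
  tied <- data.frame(gene = c("A", "B", "C"), n_disorders = 2)
  net0 <- merge_network(data.frame(),
                        data.frame(gene_a = "A", gene_b = "B",
                                   combined_score = 500), tied)
  expect_warning(u <- degree_vs_shared(net0, "ppi"), "tied")
  expect_true(is.na(u$rho))
})

test_that("module enrichment matches direct hypergeometric computation", {
  # the published-style contingency: 26 of 43 set genes in a 79-gene module
  # within a 250-gene background
  bg <- paste0("g", 1:250)
  mod <- data.frame(gene = bg[1:79], module = "M2")
  gene_set <- c(bg[1:26], bg[80:96])  # 26 in-module, 17 outside; 43 total
  res <- module_enrichment(gene_set, mod, bg)
  expect_equal(res$k, 26)
  expect_equal(res$set_size, 43)
  expect_equal(res$module_size, 79)
  # enumeration oracle for the two-tailed exact p
  expect_equal(res$p, fisher_enum_oracle(26, 17, 53, 154), tolerance = 1e-9)
  expect_equal(res$or, (26 * 154) / (17 * 53))
  # margins are consistent with the background
  expect_equal(res$k + (res$set_size - res$k) + (res$module_size - res$k) +
                 (res$background_size - res$set_size - res$module_size + res$k),
               250)

  # a set equal to its module is maximally enriched
  mods2 <- data.frame(gene = bg[1:40],
                      module = rep(c("Ma", "Mb"), each = 20))
  res2 <- module_enrichment(bg[1:20], mods2, bg)
  expect_lt(res2$p[res2$module == "Ma"], res2$p[res2$module == "Mb"])
  expect_true(res2$or[res2$module == "Ma"] > 1)

  expect_error(module_enrichment("zzz", mod, bg), "outside background")
  expect_error(module_enrichment("g1", mod, character(0)), "empty")
})

test_that("trend test flags separation and recovers a planted slope", {
  nd <- rep(0:4, each = 60)
  # deterministic indicator: perfect separation
  r <- shared_trend_test(nd >= 2, nd)
  expect_true(r$separation)
  expect_equal(r$method, "firth")
  expect_lt(r$p, 1e-6)

  # planted log-odds slope 0.8 recovered within 2 SE most of the time
  set.seed(54)
  hits <- 0L
  est <- numeric(25)
  for (i in 1:25) {
    y <- stats::rbinom(length(nd), 1, stats::plogis(-1.5 + 0.8 * nd))
    f <- shared_trend_test(y, nd)
    fit <- stats::glm(y ~ nd, family = stats::binomial())
    se <- sqrt(diag(stats::vcov(fit)))[2]
    est[i] <- f$slope
    if (abs(f$slope - 0.8) <= 2 * se) hits <- hits + 1L
  }
  expect_gte(hits / 25, 0.9)
  expect_equal(mean(est), 0.8, tolerance = 0.1)
  expect_error(shared_trend_test(rep(TRUE, 10), rep(1:5, 2)), "both outcome")
})
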