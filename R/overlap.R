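#' Mutated gene set of one disorder and variant class
#'
#' The multiset of gene hits (one entry per DNM) of a given class in a
#' given disorder; overlap statistics use the distinct-gene collapse.
#'
#' @param disorder Cohort label.
#' @param class Variant class, one of LoF, Dmis, Pfun.
#' @param hits Character vector of gene ids, one per DNM.
#' @return List with class `mutated_gene_set` (`genes` holds the distinct
#'   set).
#' @export
mutated_gene_set <- function(disorder, class, hits) {
  stopifnot(class %in% c("LoF", "Dmis", "Pfun"))
  structure(list(disorder = disorder, class = class,
                 hits = as.character(hits),
                 genes = unique(as.character(hits))),
            class = "mutated_gene_set")
}

#' Observed overlap of two mutated gene sets
#'
#' Number of distinct genes mutated in both sets; both sides must carry the
#' same variant class.
#'
#' @param set_1,set_2 [mutated_gene_set()] objects or plain character
#'   vectors of hits.
#' @return Integer overlap.
#' @export
observed_overlap <- function(set_1, set_2) {
  if (inherits(set_1, "mutated_gene_set") &&
      inherits(set_2, "mutated_gene_set") &&
      !identical(set_1$class, set_2$class)) {
    stop("variant class mismatch: ", set_1$class, " vs ", set_2$class)
  }
  g1 <- if (inherits(set_1, "mutated_gene_set")) set_1$genes else unique(set_1)
  g2 <- if (inherits(set_2, "mutated_gene_set")) set_2$genes else unique(set_2)
  length(intersect(g1, g2))
}

#' Mutability-weighted permutation null for shared-gene counts
#'
#' Each permutation independently reassigns the observed numbers of
#' mutations of the two sets to genes by weighted sampling with replacement
#' (multinomial with probabilities proportional to the per-gene class
#' weights — the stand-in for gene size, structure and local trinucleotide
#' mutation rate), then records the distinct-gene overlap. A gene drawn
#' more than once counts once, matching the multiset nature of DNM hits.
#'
#' @param hits_1,hits_2 Character vectors of gene hits (multisets) or
#'   [mutated_gene_set()] objects.
#' @param weights Named positive weights over the gene universe; every hit
#'   gene must appear.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed (reproducibility).
#' @return Integer vector of permuted overlaps, length `n_perm`.
#' @export
permutation_null <- function(hits_1, hits_2, weights, n_perm = 10000,
                             seed = NULL) {
  if (inherits(hits_1, "mutated_gene_set")) hits_1 <- hits_1$hits
  if (inherits(hits_2, "mutated_gene_set")) hits_2 <- hits_2$hits
  stopifnot(n_perm >= 1, all(weights > 0), !is.null(names(weights)))
  absent <- setdiff(unique(c(hits_1, hits_2)), names(weights))
  if (length(absent)) {
    stop("gene(s) absent from weights: ",
         paste(utils::head(absent, 5), collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  h1 <- length(hits_1)
  h2 <- length(hits_2)
  if (h1 == 0 || h2 == 0) return(integer(n_perm))
  cw <- cumsum(weights) / sum(weights)
  perm_overlap(cw, h1, h2, as.integer(n_perm))
}

#' Observed/expected ratio and empirical enrichment p
#'
#' expected = mean permuted overlap; O/E = observed/expected (Inf when the
#' expectation is zero); p = (1 + #permutations >= observed) / (n_perm + 1),
#' the add-one estimator that can never return exactly zero. One-sided:
#' enrichment only; depletion shows up in O/E < 1.
#'
#' @param observed Observed overlap.
#' @param permuted Integer vector from [permutation_null()].
#' @return List: `expected`, `oe`, `p`.
#' @export
oe_and_p <- function(observed, permuted) {
  stopifnot(length(permuted) >= 1)
  expected <- mean(permuted)
  list(expected = expected,
       oe = if (expected == 0) Inf else observed / expected,
       p = (1 + sum(permuted >= observed)) / (length(permuted) + 1))
}

#' Cross-disorder overlap tests for all pairs and classes
#'
#' Runs the weighted permutation test for every unordered disorder pair and
#' every variant class present, then BH-adjusts across all results of the
#' run. Disorders are processed in sorted label order with a per-pair
#' derived seed, so results do not depend on input ordering.
#'
#' @param sets Nested named list: `sets[[disorder]][[class]]` is the hit
#'   multiset (character vector) of that disorder/class.
#' @param weights Named list of weight vectors per class (or a single named
#'   vector used for all classes).
#' @param n_perm Permutations per pair, default 10000 (use 100000 for
#'   production runs).
#' @param seed Integer master seed.
#' @return data.frame: disorder_1, disorder_2 (sorted), class, observed,
#'   expected, oe, p, p_adj, n_perm, seed.
#' @export
run_all_pairs <- function(sets, weights, n_perm = 10000, seed = 1) {
  disorders <- sort(names(sets))
  if (length(disorders) < 2) stop("need at least two disorders")
  classes <- sort(unique(unlist(lapply(sets, names))))
  rows <- list()
  k <- 0L
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    w <- if (is.list(weights)) weights[[cl]] else weights
    for (i in seq_len(length(disorders) - 1)) {
      for (j in (i + 1):length(disorders)) {
        k <- k + 1L
        d1 <- disorders[i]; d2 <- disorders[j]
        h1 <- sets[[d1]][[cl]]
        h2 <- sets[[d2]][[cl]]
        if (is.null(h1) || is.null(h2)) next
        pair_seed <- (seed + 7919L * k) %% .Machine$integer.max
        perm <- permutation_null(h1, h2, w, n_perm, seed = pair_seed)
        obs <- observed_overlap(h1, h2)
        st <- oe_and_p(obs, perm)
        rows[[length(rows) + 1L]] <- data.frame(
          disorder_1 = d1, disorder_2 = d2, class = cl,
          observed = obs, expected = st$expected, oe = st$oe, p = st$p,
          n_perm = n_perm, seed = pair_seed, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out[, c("disorder_1", "disorder_2", "class", "observed", "expected",
          "oe", "p", "p_adj", "n_perm", "seed")]
}

#' Hit multisets per disorder and class from classified records
#'
#' @param records Classified DNM records (a `class` column is added if
#'   absent).
#' @param classes Classes to collect; Pfun pools LoF and Dmis hits.
#' @param dmis_threshold Passed to [classify_dnm()] when classifying.
#' @return Nested list `sets[[disorder]][[class]]` of gene-hit vectors.
#' @export
gene_hit_sets <- function(records, classes = c("LoF", "Dmis", "Pfun"),
                          dmis_threshold = 0.7) {
  if (!"class" %in% names(records)) {
    records$class <- classify_dnm(records$consequence, records$score,
                                  dmis_threshold)
  }
  lapply(split(records, records$disorder), function(r) {
    out <- lapply(classes, function(cl) {
      if (cl == "Pfun") r$gene[r$class %in% c("LoF", "Dmis")]
      else r$gene[r$class == cl]
    })
    names(out) <- classes
    out
  })
}
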