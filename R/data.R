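#' Published cross-disorder DNM class counts
#'
#' Per-cohort de novo mutation counts by variant class from a published
#' compendium of trio sequencing studies covering five neuropsychiatric
#' disorders — autism spectrum disorder (ASD), undiagnosed developmental
#' disorder (UDD), epileptic encephalopathy (EE), intellectual disability
#' (ID), schizophrenia (SCZ) — plus unaffected controls. These counts are
#' the substrate of the burden and contribution analyses and of the worked
#' examples; they are bundled because the analyses operate on the printed
#' per-class tallies, not on individual variants.
#'
#' @param pooled If TRUE (default), append an `NPD` row pooling the five
#'   case cohorts (sum of counts and trios).
#' @return data.frame in [count_matrix()] layout: `cohort`, `n_trios`,
#'   `LoF`, `Dmis`, `Tmis`, `synonymous`, `other`, `Pfun`.
#' @export
npd_class_counts <- function(pooled = TRUE) {
  out <- data.frame(
    cohort     = c("ASD", "UDD", "EE", "ID", "SCZ", "control"),
    n_trios    = c(6511L, 4293L, 933L, 1022L, 1094L, 3391L),
    LoF        = c(1228L, 1382L, 192L, 309L, 136L, 411L),
    Dmis       = c(1633L, 1898L, 350L, 366L, 217L, 662L),
    Tmis       = c(3406L, 2676L, 414L, 447L, 450L, 1595L),
    synonymous = c(1864L, 1607L, 192L, 248L, 241L, 932L),
    other      = c(0L, 0L, 0L, 0L, 0L, 0L),
    stringsAsFactors = FALSE
  )
  if (pooled) {
    case <- out$cohort != "control"
    npd <- data.frame(cohort = "NPD",
                      n_trios = sum(out$n_trios[case]),
                      LoF = sum(out$LoF[case]), Dmis = sum(out$Dmis[case]),
                      Tmis = sum(out$Tmis[case]),
                      synonymous = sum(out$synonymous[case]),
                      other = 0L, stringsAsFactors = FALSE)
    out <- rbind(out[case, ], npd, out[!case, ])
  }
  out$Pfun <- out$LoF + out$Dmis
  rownames(out) <- NULL
  out
}
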