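#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Probability, under fixed margins, of all tables at most as likely as the
#' observed one (the convention of standard exact-test implementations).
#' Thin wrapper over [stats::fisher.test()] taking the four cells directly,
#' in the orientation used throughout the burden analysis: (a, b) = case
#' class count and case synonymous count, (c, d) = the control pair.
#'
#' @param a,b,c,d Non-negative integer cell counts; at least one margin > 0.
#' @return Two-tailed p-value in (0, 1].
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  check_cells(a, b, c, d)
  stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value
}

check_cells <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) stop("all-zero table: at least one margin must be > 0")
  invisible(cells)
}

#' Sample odds ratio with Wald confidence interval
#'
#' Cross-product ratio (a*d)/(b*c) with a log-scale Wald interval
#' exp(log OR +/- z*sqrt(1/a+1/b+1/c+1/d)). When any cell is zero, the
#' Haldane-Anscombe 0.5 correction is applied to all cells (flagged in the
#' output); with two zero cells in one row the ratio is undefined and
#' returned as NA.
#'
#' @inheritParams fisher_two_tailed
#' @param level Confidence level, default 0.95.
#' @return Named list: `or`, `ci_low`, `ci_high`, `haldane` (logical).
#' @export
odds_ratio_ci <- function(a, b, c, d, level = 0.95) {
  check_cells(a, b, c, d)
  stopifnot(level > 0, level < 1)
  if ((a == 0 && b == 0) || (c == 0 && d == 0)) {
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                haldane = FALSE))
  }
  haldane <- any(c(a, b, c, d) == 0)
  or <- (a * d) / (b * c)
  if (haldane) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
    or <- (a * d) / (b * c)
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       haldane = haldane)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate control with monotonicity enforcement;
#' output has the same length and order as the input.
#'
#' @param p Numeric vector of p-values in \[0,1\].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Synonymous-normalized DNM burden table
#'
#' For every case cohort and variant class, compares the class count against
#' the cohort's own synonymous count and the control pair in a 2x2 Fisher
#' test. Synonymous counts act as the denominator to cancel per-study
#' differences in DNM detection rate, so the odds ratio reads as the excess
#' of class-specific DNM rate in cases over controls. BH adjustment is
#' applied within each cohort across its tested classes (m = 4 by default),
#' the family under which published per-disorder adjusted values are
#' internally consistent.
#'
#' @param counts Class-count matrix from [count_matrix()] (or
#'   [npd_class_counts()]).
#' @param control_label Cohort label of the unaffected controls.
#' @param classes Classes to test; default LoF, Dmis, Pfun, Tmis.
#' @param bh_family `"cohort"` (default) adjusts within each cohort;
#'   `"all"` across every test in the table.
#' @return data.frame: cohort, class, the 2x2 cells (`a`,`b`,`c`,`d`),
#'   `or`, `ci_low`, `ci_high`, `p`, `p_adj`.
#' @export
burden_table <- function(counts, control_label = "control",
                         classes = c("LoF", "Dmis", "Pfun", "Tmis"),
                         bh_family = c("cohort", "all")) {
  bh_family <- match.arg(bh_family)
  if (!control_label %in% counts$cohort) {
    stop("control cohort '", control_label, "' not present")
  }
  ctrl <- counts[counts$cohort == control_label, ]
  if (ctrl$synonymous <= 0) stop("control synonymous count must be > 0")
  cases <- counts[counts$cohort != control_label, , drop = FALSE]
  if (any(cases$synonymous <= 0)) {
    stop("zero synonymous count in cohort(s): ",
         paste(cases$cohort[cases$synonymous <= 0], collapse = ", "),
         " - synonymous normalization impossible")
  }
  rows <- lapply(seq_len(nrow(cases)), function(i) {
    r <- cases[i, ]
    do.call(rbind, lapply(classes, function(cl) {
      a <- r[[cl]]; b <- r$synonymous; c <- ctrl[[cl]]; d <- ctrl$synonymous
      orci <- odds_ratio_ci(a, b, c, d)
      data.frame(cohort = r$cohort, class = cl, a = a, b = b, c = c, d = d,
                 or = orci$or, ci_low = orci$ci_low, ci_high = orci$ci_high,
                 p = fisher_two_tailed(a, b, c, d), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (bh_family == "cohort") {
    stats::ave(out$p, out$cohort, FUN = bh_adjust)
  } else {
    bh_adjust(out$p)
  }
  rownames(out) <- NULL
  out
}

#' Ascertainment differential
#'
#' Fraction of case DNMs of a class implicated in etiology:
#' f = 1 - (c/d)/(a/b), where a/b is the case class-to-synonymous ratio and
#' c/d the control one. May be negative (a depletion), in which case it is
#' reported as-is here and clipped only when converted to a patient
#' contribution.
#'
#' @inheritParams fisher_two_tailed
#' @return Implicated fraction in (-Inf, 1\].
#' @export
ascertainment_differential <- function(a, b, c, d) {
  check_cells(a, b, c, d)
  if (a == 0 || b == 0 || d == 0) {
    stop("ascertainment differential needs a, b, d > 0")
  }
  1 - (c / d) / (a / b)
}

#' Patient contribution of a variant class
#'
#' Fraction of probands attributable to a class of DNMs:
#' max(f, 0) * class_count / n_trios, where f is the ascertainment
#' differential. A negative f (depletion) contributes zero, with a message
#' noting the depletion.
#'
#' @param f Implicated fraction from [ascertainment_differential()].
#' @param class_count Number of case DNMs of the class.
#' @param n_trios Number of case trios (> 0).
#' @return Fraction of patients in \[0, 1\].
#' @export
patient_contribution <- function(f, class_count, n_trios) {
  stopifnot(n_trios > 0, class_count >= 0, f <= 1)
  if (f < 0) {
    message("negative implicated fraction (depletion); contribution clipped to 0")
    return(0)
  }
  f * class_count / n_trios
}

#' Contribution table for functional variant classes
#'
#' Per cohort and class (LoF, Dmis, Pfun), the implicated fraction of DNMs
#' and the resulting fraction of patients attributable to the class, both
#' as fractions (multiply by 100 for percentages).
#'
#' @inheritParams burden_table
#' @param classes Classes to report; default the functional ones.
#' @return data.frame: cohort, class, `implicated_fraction`,
#'   `patient_contribution`.
#' @export
contribution_table <- function(counts, control_label = "control",
                               classes = c("LoF", "Dmis", "Pfun")) {
  if (!control_label %in% counts$cohort) {
    stop("control cohort '", control_label, "' not present")
  }
  ctrl <- counts[counts$cohort == control_label, ]
  cases <- counts[counts$cohort != control_label, , drop = FALSE]
  rows <- lapply(seq_len(nrow(cases)), function(i) {
    r <- cases[i, ]
    do.call(rbind, lapply(classes, function(cl) {
      f <- ascertainment_differential(r[[cl]], r$synonymous,
                                      ctrl[[cl]], ctrl$synonymous)
      data.frame(cohort = r$cohort, class = cl,
                 implicated_fraction = f,
                 patient_contribution = suppressMessages(
                   patient_contribution(f, r[[cl]], r$n_trios)),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
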