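#' @keywords internal
"_PACKAGE"

#' Controlled vocabularies for DNM records and variant classes
#'
#' `dnm_consequences()` lists the accepted consequence terms for a de novo
#' mutation record; `variant_classes()` the derived analysis classes. LoF
#' covers stopgain, stoploss, canonical splicing and frameshift calls;
#' missense splits into Dmis/Tmis by an in-silico deleteriousness score;
#' Pfun (LoF + Dmis) is always derived by summation, never stored.
#'
#' @return Character vector of terms.
#' @export
dnm_consequences <- function() {
  c("stopgain", "stoploss", "splicing", "frameshift",
    "missense", "synonymous", "other")
}

#' @rdname dnm_consequences
#' @export
variant_classes <- function() {
  c("LoF", "Dmis", "Tmis", "synonymous", "other")
}

lof_consequences <- function() c("stopgain", "stoploss", "splicing", "frameshift")

#' Classify de novo mutations into variant classes
#'
#' Maps consequence terms (and, for missense, a deleteriousness score in
#' \[0,1\]) to the four analysis classes plus "other". Missense calls with
#' score >= `dmis_threshold` are deleterious (Dmis), the rest tolerated
#' (Tmis); the boundary is inclusive so classification is deterministic.
#'
#' @param consequence Character vector of consequence terms
#'   (see [dnm_consequences()]).
#' @param score Numeric vector of missense deleteriousness scores in
#'   \[0,1\]; ignored (with a warning) for non-missense records, required for
#'   missense ones.
#' @param dmis_threshold Score at or above which a missense call is Dmis.
#'   Default 0.7, the published operating point of the ReVe-style
#'   classifiers; always configurable since curated tables may use another
#'   scorer.
#' @return Character vector of classes, one per record.
#' @export
classify_dnm <- function(consequence, score = NULL, dmis_threshold = 0.7) {
  stopifnot(length(dmis_threshold) == 1L, is.numeric(dmis_threshold),
            dmis_threshold >= 0, dmis_threshold <= 1)
  consequence <- trimws(as.character(consequence))
  bad <- !consequence %in% dnm_consequences()
  if (any(bad)) {
    stop("unknown consequence term(s): ",
         paste(unique(consequence[bad]), collapse = ", "))
  }
  if (is.null(score)) score <- rep(NA_real_, length(consequence))
  score <- as.numeric(score)
  if (length(score) != length(consequence)) {
    stop("'score' must have one entry per record")
  }
  is_mis <- consequence == "missense"
  if (any(is_mis & is.na(score))) {
    stop("missense record(s) without a deleteriousness score at position(s): ",
         paste(utils::head(which(is_mis & is.na(score)), 10L), collapse = ", "))
  }
  if (any(!is_mis & !is.na(score))) {
    warning("score ignored for ", sum(!is_mis & !is.na(score)),
            " non-missense record(s)")
  }
  cls <- rep("other", length(consequence))
  cls[consequence %in% lof_consequences()] <- "LoF"
  cls[consequence == "synonymous"] <- "synonymous"
  cls[is_mis] <- ifelse(score[is_mis] >= dmis_threshold, "Dmis", "Tmis")
  cls
}

dnm_mandatory_cols <- c("study_id", "disorder", "sample_id", "gene", "consequence")

#' Read and write de novo mutation tables
#'
#' DNM tables are tab-separated with a header and at least the columns
#' `study_id`, `disorder`, `sample_id`, `gene`, `consequence` and optionally
#' `score`; unknown columns are preserved on round-trip. Rows with a
#' consequence outside the vocabulary, or missense rows without a score, are
#' excluded from the returned records and collected (with their line
#' numbers) in the `error_report` attribute rather than silently dropped.
#'
#' @param path File path of the tab-separated table.
#' @return For `read_dnm_table`, a data.frame of valid records with
#'   attribute `error_report` (a data.frame with columns `line`, `problem`,
#'   zero rows if the table is clean). Gene symbols are whitespace-trimmed
#'   and matched case-sensitively downstream.
#' @export
read_dnm_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  missing_cols <- setdiff(dnm_mandatory_cols, names(tab))
  if (length(missing_cols)) {
    stop("DNM table ", path, " lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"score" %in% names(tab)) tab$score <- NA_character_
  tab$score <- suppressWarnings(as.numeric(tab$score))
  tab$gene <- trimws(tab$gene)
  line <- seq_len(nrow(tab)) + 1L  # header is line 1
  bad_cons <- !tab$consequence %in% dnm_consequences()
  bad_score <- tab$consequence == "missense" & is.na(tab$score)
  problems <- character(0)
  bad_lines <- integer(0)
  if (any(bad_cons)) {
    bad_lines <- c(bad_lines, line[bad_cons])
    problems <- c(problems,
                  paste0("invalid consequence '", tab$consequence[bad_cons], "'"))
  }
  if (any(bad_score)) {
    bad_lines <- c(bad_lines, line[bad_score])
    problems <- c(problems, rep("missense record without score", sum(bad_score)))
  }
  report <- data.frame(line = bad_lines, problem = problems,
                       stringsAsFactors = FALSE)
  report <- report[order(report$line), , drop = FALSE]
  rownames(report) <- NULL
  keep <- !(bad_cons | bad_score)
  records <- tab[keep, , drop = FALSE]
  rownames(records) <- NULL
  attr(records, "error_report") <- report
  records
}

#' @rdname read_dnm_table
#' @param records data.frame of DNM records.
#' @export
write_dnm_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Per-cohort variant-class count matrix
#'
#' Tallies records into the per-cohort class counts that all burden and
#' contribution statistics consume. Pfun is derived as LoF + Dmis; cohorts
#' with trio counts but no records appear with zero counts; classification
#' uses [classify_dnm()] unless the records already carry a `class` column.
#'
#' @param records data.frame of DNM records (see [read_dnm_table()]).
#' @param trio_counts Named integer vector: number of sequenced trios per
#'   cohort label. Every record's disorder must appear here.
#' @param dmis_threshold Passed to [classify_dnm()].
#' @return data.frame with one row per cohort: `cohort`, `n_trios`, counts
#'   for LoF, Dmis, Tmis, synonymous, other, and derived Pfun.
#' @export
count_matrix <- function(records, trio_counts, dmis_threshold = 0.7) {
  stopifnot(is.numeric(trio_counts), !is.null(names(trio_counts)),
            all(trio_counts > 0))
  if (nrow(records) > 0) {
    unknown <- setdiff(unique(records$disorder), names(trio_counts))
    if (length(unknown)) {
      stop("records carry disorder label(s) without trio counts: ",
           paste(unknown, collapse = ", "),
           " (known: ", paste(names(trio_counts), collapse = ", "), ")")
    }
  }
  cls <- if ("class" %in% names(records) && nrow(records) > 0) {
    records$class
  } else if (nrow(records) > 0) {
    classify_dnm(records$consequence, records$score, dmis_threshold)
  } else {
    character(0)
  }
  cohorts <- names(trio_counts)
  classes <- variant_classes()
  tab <- table(factor(records$disorder, levels = cohorts),
               factor(cls, levels = classes))
  out <- data.frame(cohort = cohorts,
                    n_trios = as.integer(trio_counts),
                    as.data.frame.matrix(tab),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out$Pfun <- out$LoF + out$Dmis
  rownames(out) <- NULL
  out
}
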