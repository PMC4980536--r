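#' Parse a profile-combination string into the four flags
#'
#' Combinations name the profiles in which a target resembles the
#' established targets: A (sequence), B (binding-domain structural fold),
#' C (physicochemical features), D (system profile). Accepts compact
#' (`"A,C,D"`) and prose (`"Combination of A, C, and D"`) forms.
#'
#' @param x Character vector of combination strings.
#' @return Logical matrix with columns `A`, `B`, `C`, `D`.
#' @export
parse_combination <- function(x) {
  out <- t(vapply(x, function(s) {
    letters_found <- regmatches(s, gregexpr("\\b[ABCD]\\b", s))[[1L]]
    c(A = "A" %in% letters_found, B = "B" %in% letters_found,
      C = "C" %in% letters_found, D = "D" %in% letters_found)
  }, logical(4L)))
  rownames(out) <- NULL
  out
}

#' The promising-target rule
#'
#' A target is called promising when it resembles the established targets
#' in at least 3 of the 4 profiles (A sequence, B structural fold,
#' C physicochemical, D system). The rule is monotone: turning any flag
#' on never revokes a promising call.
#'
#' @param flags Logical matrix/data frame with columns `A`, `B`, `C`,
#'   `D` (one row per target), or a single logical vector of length 4.
#' @return Logical vector, one value per target.
#' @export
is_promising <- function(flags) {
  if (is.vector(flags) && length(flags) == 4L) {
    flags <- matrix(flags, nrow = 1L, dimnames = list(NULL, c("A", "B", "C", "D")))
  }
  flags <- as.matrix(as.data.frame(flags)[, c("A", "B", "C", "D")])
  storage.mode(flags) <- "logical"
  if (anyNA(flags)) stop("profile flags must be definite booleans", call. = FALSE)
  unname(rowSums(flags) >= 3L)
}

#' Parse development-status strings into outcome labels
#'
#' Keyword rules, case-insensitive on whole words, applied with
#' precedence: `approved` wins over `positive`, which wins over
#' `discontinued` / `negative` / `not approvable`; anything else
#' (including the empty string) is `other`. The whole-word rule means
#' "approval" does not trigger the approved label.
#'
#' @param x Character vector of status strings (may be empty strings).
#' @return Factor with levels `approved`, `positive_phase3`,
#'   `negative_or_discontinued`, `other`.
#' @export
parse_status <- function(x) {
  x <- ifelse(is.na(x), "", x)
  lev <- c("approved", "positive_phase3", "negative_or_discontinued", "other")
  lab <- ifelse(grepl("\\bapproved\\b", x, ignore.case = TRUE), lev[1L],
         ifelse(grepl("\\bpositive\\b", x, ignore.case = TRUE), lev[2L],
         ifelse(grepl("\\b(discontinued|negative)\\b|\\bnot approvable\\b",
                      x, ignore.case = TRUE), lev[3L], lev[4L])))
  factor(lab, levels = lev)
}

#' Retrospective outcome evaluation of a phase-3 target table
#'
#' Takes a table of targets with their profile combination and latest
#' development-status text, derives the promising flag and the outcome
#' label for each row, and tabulates counts with report-style truncated
#' percentages plus the promising-by-outcome cross-tabulation.
#'
#' @param rows Data frame with columns `target`, `combination`, `status`.
#' @return List with `n`, `rows` (input plus `promising` and `label`),
#'   `counts` (named integer per label), `pct` (raw percentages),
#'   `pct_printed` (truncated), `crosstab` (promising x label).
#' @export
evaluate_cohort <- function(rows) {
  stopifnot(is.data.frame(rows))
  if (!nrow(rows)) stop("empty status table", call. = FALSE)
  stopifnot(all(c("target", "combination", "status") %in% names(rows)))
  flags <- parse_combination(rows$combination)
  rows$promising <- is_promising(flags)
  rows$label <- parse_status(rows$status)
  counts <- table(rows$label)
  pct <- 100 * as.numeric(counts) / nrow(rows)
  names(pct) <- names(counts)
  list(n = nrow(rows), rows = rows,
       counts = setNames(as.integer(counts), names(counts)),
       pct = pct, pct_printed = setNames(format_pct(pct), names(pct)),
       crosstab = table(promising = rows$promising, label = rows$label))
}

#' Fraction of promising targets per development phase
#'
#' @param targets Data frame with a `phase` column (one of
#'   `established`, `phase3`, `phase2`, `phase1`, `nonclinical`) and the
#'   four logical flag columns `A`, `B`, `C`, `D`.
#' @return Data frame `phase`, `n`, `promising`, `fraction`. Phases
#'   present in the label set but with no targets are omitted with a
#'   warning.
#' @export
prediction_rates <- function(targets) {
  stopifnot(all(c("phase", "A", "B", "C", "D") %in% names(targets)))
  bad <- setdiff(unique(targets$phase), cohort_labels())
  if (length(bad)) {
    stop("unknown phase label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  prom <- is_promising(targets[, c("A", "B", "C", "D")])
  phases <- intersect(cohort_labels(), unique(targets$phase))
  out <- do.call(rbind, lapply(phases, function(ph) {
    sel <- targets$phase == ph
    data.frame(phase = ph, n = sum(sel), promising = sum(prom[sel]),
               fraction = mean(prom[sel]), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Packaged development-status table of the 16 promising phase-3 targets
#'
#' The retrospective evaluation fixture: the 16 phase-3 targets
#' previously called promising (similar to established targets in at
#' least 3 of the 4 profiles), with their profile combination, targeted
#' disease and latest reported development status. Shipped as a
#' plain-text TSV with the package.
#'
#' @return Data frame with columns `target`, `combination`, `disease`,
#'   `status` (16 rows; blank status cells are empty strings).
#' @export
phase3_status_table <- function() {
  path <- system.file("extdata", "phase3_target_status.tsv",
                      package = "dtprofiler", mustWork = TRUE)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = NULL, quote = "")
  df$status[is.na(df$status)] <- ""
  df
}
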