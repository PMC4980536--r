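#' Druggability compliance rules for system profiles
#'
#' The three rules: fewer than `ns_max_exclusive` similar human proteins
#' outside the target family (strict `<`), at most `np_max_inclusive`
#' affiliated signaling pathways, at most `nt_max_inclusive` tissues of
#' expression.
#'
#' @param ns_max_exclusive,np_max_inclusive,nt_max_inclusive Positive
#'   integer thresholds (defaults 15, 3, 5).
#' @return A `profile_rules` object.
#' @export
profile_rules <- function(ns_max_exclusive = 15L, np_max_inclusive = 3L,
                          nt_max_inclusive = 5L) {
  stopifnot(ns_max_exclusive >= 1, np_max_inclusive >= 1,
            nt_max_inclusive >= 1)
  structure(list(ns_max_exclusive = as.integer(ns_max_exclusive),
                 np_max_inclusive = as.integer(np_max_inclusive),
                 nt_max_inclusive = as.integer(nt_max_inclusive)),
            class = "profile_rules")
}

#' Assemble per-target system profiles
#'
#' NP is the number of distinct pathway ids and NT the number of distinct
#' tissue labels annotated to each target; NS is supplied (from
#' [count_similarity_proteins()] or a cohort generator). Compliance flags
#' are applied per [profile_rules()]. Targets absent from an annotation
#' table either count 0 with a warning (default) or are excluded.
#'
#' @param targets Data frame with column `target_id` (extra columns such
#'   as `cohort` are carried through) or a character vector of ids.
#' @param ns Named integer vector of NS values, or a data frame with
#'   columns `target_id`, `NS`.
#' @param pathway_table Data frame `target_id`, `pathway_id`.
#' @param tissue_table Data frame `target_id`, `tissue`.
#' @param rules A [profile_rules()] object.
#' @param missing `"zero"` or `"exclude"`.
#' @return Data frame with `target_id`, carried columns, `NS`, `NP`, `NT`
#'   and logical `compliant_ns`, `compliant_np`, `compliant_nt`.
#' @export
assemble_profiles <- function(targets, ns, pathway_table, tissue_table,
                              rules = profile_rules(),
                              missing = c("zero", "exclude")) {
  missing <- match.arg(missing)
  if (is.character(targets)) {
    targets <- data.frame(target_id = targets, stringsAsFactors = FALSE)
  }
  stopifnot("target_id" %in% names(targets))
  if (is.data.frame(ns)) ns <- setNames(ns$NS, ns$target_id)
  if (!all(targets$target_id %in% names(ns))) {
    stop("NS missing for some targets", call. = FALSE)
  }
  count_distinct <- function(tab, value_col) {
    stats::aggregate(tab[[value_col]], by = list(target_id = tab$target_id),
                     FUN = function(v) length(unique(v)))
  }
  np <- count_distinct(pathway_table, "pathway_id")
  nt <- count_distinct(tissue_table, "tissue")
  np_v <- setNames(np$x, np$target_id)[targets$target_id]
  nt_v <- setNames(nt$x, nt$target_id)[targets$target_id]
  absent <- is.na(np_v) | is.na(nt_v)
  if (any(absent)) {
    if (missing == "exclude") {
      warning(sum(absent), " target(s) absent from annotation tables; excluded")
      targets <- targets[!absent, , drop = FALSE]
      np_v <- np_v[!absent]
      nt_v <- nt_v[!absent]
    } else {
      warning(sum(absent),
              " target(s) absent from annotation tables; counted as 0")
      np_v[is.na(np_v)] <- 0L
      nt_v[is.na(nt_v)] <- 0L
    }
  }
  out <- targets
  out$NS <- as.integer(ns[out$target_id])
  out$NP <- as.integer(np_v)
  out$NT <- as.integer(nt_v)
  apply_rules(out, rules)
}

# Set/refresh the three compliance flags on a profile table with NS/NP/NT.
apply_rules <- function(profiles, rules = profile_rules()) {
  stopifnot(all(c("NS", "NP", "NT") %in% names(profiles)))
  if (any(profiles$NS < 0 | profiles$NP < 0 | profiles$NT < 0)) {
    stop("NS/NP/NT must be nonnegative", call. = FALSE)
  }
  profiles$compliant_ns <- profiles$NS < rules$ns_max_exclusive
  profiles$compliant_np <- profiles$NP <= rules$np_max_inclusive
  profiles$compliant_nt <- profiles$NT <= rules$nt_max_inclusive
  profiles
}

#' Default histogram bin edges for the three statistics
#'
#' Right-open bins `[a, b)` whose boundaries coincide with the compliance
#' thresholds: NS in steps of 5 to 20 then open, NP and NT 1-wide then
#' open above the threshold band.
#'
#' @return Named list of numeric break vectors.
#' @export
default_bins <- function() {
  list(NS = c(0, 5, 10, 15, 20, Inf),
       NP = c(0, 1, 2, 3, 4, 5, Inf),
       NT = c(0, 1, 2, 3, 4, 5, 6, Inf))
}

#' Summarize one cohort's system profiles
#'
#' Computes compliance percentages, binned count distributions and
#' five-number boxplot statistics (Tukey 1.5 IQR whiskers, as in R's
#' `boxplot.stats`) for NS, NP and NT.
#'
#' @param profiles Profile table with `NS`, `NP`, `NT` and the three
#'   `compliant_*` flags (see [assemble_profiles()] / [apply_rules()]).
#' @param cohort_label Label recorded in the summary.
#' @param bins Named list of break vectors (see [default_bins()]).
#' @return A `cohort_summary`: list with `cohort_label`, `n`, `pct`
#'   (named numeric, raw percentages), `bins` (list of data frames
#'   `bin`, `count`), `boxplot` (list of `boxplot.stats` results).
#' @export
summarize_cohort <- function(profiles, cohort_label = "cohort",
                             bins = default_bins()) {
  if (!nrow(profiles)) stop("empty cohort", call. = FALSE)
  stopifnot(all(c("compliant_ns", "compliant_np", "compliant_nt")
                %in% names(profiles)))
  n <- nrow(profiles)
  pct <- c(ns = 100 * sum(profiles$compliant_ns) / n,
           np = 100 * sum(profiles$compliant_np) / n,
           nt = 100 * sum(profiles$compliant_nt) / n)
  stat_bins <- lapply(names(bins), function(s) {
    br <- bins[[s]]
    cuts <- cut(profiles[[s]], breaks = br, right = FALSE,
                include.lowest = FALSE)
    data.frame(bin = levels(cuts), count = as.integer(table(cuts)),
               stringsAsFactors = FALSE)
  })
  names(stat_bins) <- names(bins)
  box <- lapply(names(bins), function(s) grDevices::boxplot.stats(profiles[[s]]))
  names(box) <- names(bins)
  structure(list(cohort_label = cohort_label, n = n, pct = pct,
                 bins = stat_bins, boxplot = box),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort %s (n = %d): NS<rule %s%%, NP %s%%, NT %s%%\n",
              x$cohort_label, x$n, format_pct(x$pct["ns"]),
              format_pct(x$pct["np"]), format_pct(x$pct["nt"])))
  invisible(x)
}

#' Truncated percentage formatting
#'
#' Report-style percentages are truncated toward zero (37.5 prints as
#' 37); raw values are kept for computation.
#'
#' @param pct Numeric percentage(s).
#' @return Character vector of truncated integers.
#' @export
format_pct <- function(pct) {
  as.character(trunc(pct))
}

#' Median trend across ordered cohorts
#'
#' Given cohort summaries in development order (established, phase 3,
#' phase 2, phase 1), reports the median sequence of one statistic,
#' whether it is monotone nondecreasing, and the first violating adjacent
#' pair otherwise.
#'
#' @param summaries List of `cohort_summary` objects in cohort order, or
#'   a named numeric vector of medians (names = cohort labels).
#' @param statistic `"NS"`, `"NP"` or `"NT"`.
#' @return List with `statistic`, `cohorts`, `medians`, `monotone`
#'   (logical) and `violation` (character pair or `NULL`).
#' @export
median_trend <- function(summaries, statistic = c("NS", "NP", "NT")) {
  statistic <- match.arg(statistic)
  if (length(summaries) < 2L) {
    stop("median trend needs at least 2 cohorts", call. = FALSE)
  }
  if (is.numeric(summaries)) {
    labs <- names(summaries) %||% as.character(seq_along(summaries))
    med <- unname(summaries)
  } else {
    labs <- vapply(summaries, function(s) s$cohort_label, "")
    med <- vapply(summaries, function(s) s$boxplot[[statistic]]$stats[3L], 0)
  }
  diffs <- diff(med)
  viol <- which(diffs < 0)
  list(statistic = statistic, cohorts = labs, medians = med,
       monotone = !length(viol),
       violation = if (length(viol)) c(labs[viol[1L]], labs[viol[1L] + 1L]))
}

#' Similarity-level distribution of clinical targets per phase
#'
#' For each clinical-trial target, the best-hit E-value against the
#' established-target sequences is classified into very / marginally /
#' unsimilar; fractions are aggregated per phase.
#'
#' @param clinical_targets Data frame with columns `target_id`, `phase`
#'   and `sequence`.
#' @param established_seqs Named character vector of established-target
#'   sequences (nonempty).
#' @param params An [evalue_params()] object.
#' @param thresholds A [similarity_thresholds()] object.
#' @return Data frame `phase`, `n`, `very_similar`, `marginally_similar`,
#'   `unsimilar` (fractions summing to 1 per phase). Phases with no
#'   targets are omitted with a warning.
#' @export
similarity_level_distribution <- function(clinical_targets, established_seqs,
                                          params = evalue_params(),
                                          thresholds = similarity_thresholds()) {
  stopifnot(all(c("target_id", "phase", "sequence") %in%
                  names(clinical_targets)))
  if (!length(established_seqs)) {
    stop("established sequence set is empty", call. = FALSE)
  }
  phases <- unique(clinical_targets$phase)
  empty <- setdiff(c("phase3", "phase2", "phase1"), phases)
  if (length(empty)) {
    warning("phase(s) with zero targets omitted: ",
            paste(empty, collapse = ", "))
  }
  E <- vapply(seq_len(nrow(clinical_targets)), function(i) {
    best_hit_evalue(clinical_targets$sequence[i], established_seqs, params)
  }, 0)
  cls <- classify_similarity(E, thresholds)
  out <- do.call(rbind, lapply(phases, function(ph) {
    sel <- clinical_targets$phase == ph
    tab <- table(cls[sel]) / sum(sel)
    data.frame(phase = ph, n = sum(sel),
               very_similar = as.numeric(tab["very_similar"]),
               marginally_similar = as.numeric(tab["marginally_similar"]),
               unsimilar = as.numeric(tab["unsimilar"]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
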