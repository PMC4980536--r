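#' Bipartite realizability of a degree-sequence pair (Gale-Ryser)
#'
#' A pair of degree multisets is realizable as a simple bipartite graph
#' iff both sides sum to the same total and, with the first side sorted
#' descending \eqn{a_1 \ge a_2 \ge \dots}, for every k
#' \eqn{\sum_{i \le k} a_i \le \sum_j \min(b_j, k)}.
#'
#' @param drug_degrees,target_degrees Multisets of positive integers.
#' @return `TRUE` invisibly; otherwise an error naming the failing
#'   condition.
#' @export
gale_ryser_check <- function(drug_degrees, target_degrees) {
  chk_degs <- function(d, side) {
    if (!length(d) || any(d != round(d)) || any(d < 1)) {
      stop(side, " degrees must be positive integers", call. = FALSE)
    }
  }
  chk_degs(drug_degrees, "drug")
  chk_degs(target_degrees, "target")
  if (sum(drug_degrees) != sum(target_degrees)) {
    stop("infeasible degree pair: degree sums differ (",
         sum(drug_degrees), " vs ", sum(target_degrees), ")", call. = FALSE)
  }
  a <- sort(as.integer(drug_degrees), decreasing = TRUE)
  b <- as.integer(target_degrees)
  for (k in seq_along(a)) {
    lhs <- sum(a[seq_len(k)])
    rhs <- sum(pmin(b, k))
    if (lhs > rhs) {
      stop("infeasible degree pair: Gale-Ryser condition fails at k = ", k,
           " (", lhs, " > ", rhs, ")", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Realize a bipartite drug-target network from a degree-sequence pair
#'
#' Deterministic greedy construction: node ids are assigned in descending
#' degree order (then lexicographically), and each drug is connected to
#' the targets with the largest remaining capacity, ties broken by id.
#' The output graph's per-side degree multisets equal the inputs exactly.
#'
#' @param drug_degrees,target_degrees Multisets of positive integers with
#'   equal sums satisfying the Gale-Ryser condition.
#' @param mode Interaction mode recorded on every edge.
#' @param modality,stage Drug attributes recorded on every drug.
#' @param target_cohort Cohort label recorded on every target.
#' @param drug_prefix,target_prefix Id prefixes.
#' @return A [build_network()] object (`dtnetwork`).
#' @export
realize_bipartite <- function(drug_degrees, target_degrees,
                              mode = "inhibition",
                              modality = "small_molecule",
                              stage = "approved",
                              target_cohort = "established",
                              drug_prefix = "DRUG", target_prefix = "KIN") {
  gale_ryser_check(drug_degrees, target_degrees)
  a <- sort(as.integer(drug_degrees), decreasing = TRUE)
  b <- sort(as.integer(target_degrees), decreasing = TRUE)
  did <- sprintf("%s%03d", drug_prefix, seq_along(a))
  tid <- sprintf("%s%03d", target_prefix, seq_along(b))
  cap <- setNames(b, tid)
  edges <- vector("list", length(a))
  for (i in seq_along(a)) {
    # ids are in descending-capacity-at-birth order, so ordering by
    # (-capacity, id) is deterministic
    ord <- order(-cap, names(cap))
    pick <- names(cap)[ord][seq_len(a[i])]
    if (any(cap[pick] < 1L)) {
      stop("internal: greedy realization exhausted target capacity",
           call. = FALSE)
    }
    cap[pick] <- cap[pick] - 1L
    edges[[i]] <- data.frame(drug_id = did[i], target_id = pick,
                             stringsAsFactors = FALSE)
  }
  interactions <- do.call(rbind, edges)
  interactions$mode <- mode
  interactions$primary <- TRUE
  drugs <- data.frame(drug_id = did, name = did, modality = modality,
                      stage = stage, icd_codes = "", stringsAsFactors = FALSE)
  targets <- data.frame(target_id = tid, cohort = target_cohort,
                        stringsAsFactors = FALSE)
  build_network(drugs, targets, interactions)
}

#' Printed degree multisets of the approved-drug kinase network
#'
#' The approved-drug network: 46 kinase inhibitors (one of degree 5, four
#' of degree 3, ten of degree 2, thirty-one of degree 1) against 25
#' kinase targets (one each of degrees 10, 9, 7, 6, 5 and 4, three of
#' degree 3, two of degree 2, fourteen of degree 1; there is no degree-8
#' class, transcribed as printed). Both sides sum to 68 interactions.
#'
#' @return List with integer vectors `drug` and `target`.
#' @export
approved_network_degrees <- function() {
  list(drug = rep(c(5L, 3L, 2L, 1L), times = c(1L, 4L, 10L, 31L)),
       target = rep(c(10L, 9L, 7L, 6L, 5L, 4L, 3L, 2L, 1L),
                    times = c(1L, 1L, 1L, 1L, 1L, 1L, 3L, 2L, 14L)))
}

#' @describeIn approved_network_degrees degree multisets of the
#'   clinical-trial subnetwork for malignant neoplasms of the female
#'   genital organs (ICD C51-C58): 13 drugs (three of degree 2, ten of
#'   degree 1) against 9 targets (one each of degrees 5, 3 and 2, six of
#'   degree 1); both sides sum to 16.
#' @export
genital_cancer_subnet_degrees <- function() {
  list(drug = rep(c(2L, 1L), times = c(3L, 10L)),
       target = rep(c(5L, 3L, 2L, 1L), times = c(1L, 1L, 1L, 6L)))
}
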