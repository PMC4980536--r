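#' Smith-Waterman local alignment
#'
#' Exact local alignment under a substitution matrix and affine gap
#' penalties (Gotoh recurrences, score only). The raw score is converted
#' to a Karlin-Altschul expectation value using the ungapped lambda and K
#' stored in `params`, with effective lengths equal to the raw sequence
#' lengths.
#'
#' @param query,subject Amino-acid sequences as character strings; names
#'   (or `query_id`/`subject_id`) label the result.
#' @param params An [evalue_params()] object.
#' @param query_id,subject_id Identifiers recorded in the result.
#' @param unknown How to handle residues absent from the matrix:
#'   `"error"` (strict) or `"X"` (score as the ambiguity residue X).
#' @return An `alignment_result`: list with `query_id`, `subject_id`,
#'   `S` (raw score), `m`, `n` (lengths) and `E` (expectation value).
#' @examples
#' p <- evalue_params()
#' smith_waterman("HEAGAWGHEE", "PAWHEAE", p)
#' @export
smith_waterman <- function(query, subject, params = evalue_params(),
                           query_id = NULL, subject_id = NULL,
                           unknown = c("error", "X")) {
  stopifnot(inherits(params, "evalue_params"))
  unknown <- match.arg(unknown)
  if (!nzchar(query) || !nzchar(subject)) {
    stop("sequences must be nonempty", call. = FALSE)
  }
  if (is.null(query_id)) query_id <- names(query) %||% "query"
  if (is.null(subject_id)) subject_id <- names(subject) %||% "subject"
  qi <- encode_seq(query, params$mat, unknown)
  si <- encode_seq(subject, params$mat, unknown)
  S <- sw_score_cpp(qi, si, params$mat, params$gap_open, params$gap_extend)
  m <- length(qi)
  n <- length(si)
  structure(list(query_id = query_id, subject_id = subject_id,
                 S = S, m = m, n = n, E = evalue(S, m, n, params)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("%s vs %s: S = %g (m = %d, n = %d), E = %.4g\n",
              x$query_id, x$subject_id, x$S, x$m, x$n, x$E))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify E-values into similarity levels
#'
#' Partitions the positive E-value axis into three classes:
#' `very_similar` (E at or below the first threshold), `marginally_similar`
#' (between the thresholds, upper bound inclusive) and `unsimilar`.
#'
#' @param E Positive E-value(s).
#' @param thresholds A [similarity_thresholds()] object.
#' @return A factor with levels `very_similar`, `marginally_similar`,
#'   `unsimilar`.
#' @export
classify_similarity <- function(E, thresholds = similarity_thresholds()) {
  if (any(!is.finite(E) | E <= 0)) {
    stop("E-values must be positive and finite", call. = FALSE)
  }
  lev <- c("very_similar", "marginally_similar", "unsimilar")
  out <- ifelse(E <= thresholds$very_similar_max, lev[1L],
                ifelse(E <= thresholds$marginal_max, lev[2L], lev[3L]))
  factor(out, levels = lev)
}

#' @describeIn classify_similarity E-value cutoffs separating the classes;
#'   defaults 0.001 and 0.1, both inclusive on the smaller class.
#' @param very_similar_max,marginal_max Class boundaries.
#' @export
similarity_thresholds <- function(very_similar_max = 0.001,
                                  marginal_max = 0.1) {
  stopifnot(very_similar_max > 0, very_similar_max < marginal_max)
  structure(list(very_similar_max = very_similar_max,
                 marginal_max = marginal_max),
            class = "similarity_thresholds")
}

#' Count similar proteins outside a target's family (NS)
#'
#' NS is the number of proteome entries from a *different* family whose
#' local-alignment E-value against the target is at or below `ns_cutoff`.
#' The target itself is always excluded.
#'
#' @param target_id Identifier of the target; must appear in `sequences`.
#' @param sequences Named character vector of protein sequences (the
#'   search set, normally including the target).
#' @param family_map Data frame with columns `seq_id`, `family` covering
#'   every entry of `sequences`.
#' @param params An [evalue_params()] object.
#' @param ns_cutoff E-value cutoff (default 0.001, the very-similar bound).
#' @param target_seq The target's sequence; defaults to
#'   `sequences[[target_id]]`.
#' @return Integer NS count.
#' @export
count_similarity_proteins <- function(target_id, sequences, family_map,
                                      params = evalue_params(),
                                      ns_cutoff = 0.001, target_seq = NULL) {
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  miss <- setdiff(names(sequences), family_map$seq_id)
  if (length(miss)) {
    stop("no family label for: ", paste(head(miss, 5L), collapse = ", "),
         call. = FALSE)
  }
  fam <- setNames(as.character(family_map$family), family_map$seq_id)
  if (is.null(target_seq)) {
    if (!target_id %in% names(sequences)) {
      stop("target '", target_id, "' not found in the sequence set",
           call. = FALSE)
    }
    target_seq <- sequences[[target_id]]
  }
  if (!target_id %in% names(fam)) {
    stop("target '", target_id, "' has no family label", call. = FALSE)
  }
  others <- setdiff(names(sequences), target_id)
  others <- others[fam[others] != fam[[target_id]]]
  hits <- vapply(others, function(id) {
    smith_waterman(target_seq, sequences[[id]], params,
                   query_id = target_id, subject_id = id)$E <= ns_cutoff
  }, logical(1L))
  sum(hits)
}

#' Best-hit E-value against a reference sequence set
#'
#' The similarity of a target to a reference cohort is summarized as the
#' minimum E-value over all reference sequences (best hit).
#'
#' @param seq Query sequence.
#' @param reference Named character vector of reference sequences.
#' @param params An [evalue_params()] object.
#' @return The minimum E-value.
#' @export
best_hit_evalue <- function(seq, reference, params = evalue_params()) {
  if (!length(reference)) stop("reference set is empty", call. = FALSE)
  min(vapply(seq_along(reference), function(i) {
    smith_waterman(seq, reference[[i]], params)$E
  }, 0))
}
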