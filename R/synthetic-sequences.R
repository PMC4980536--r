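#' Specification of synthetic protein sequence families
#'
#' Each family descends from one random seed sequence; members are derived
#' by independent point mutation at rate `1 - within_family_identity`.
#' Distinct families are generated independently, so the expected identity
#' between families is the background coincidence rate
#' \eqn{\sum_i p_i^2} of the residue frequencies.
#'
#' @param n_families,members_per_family Positive integers.
#' @param seed_length Sequence length in residues (>= 20).
#' @param within_family_identity Expected identity of a member to its
#'   family seed, in `[0, 1]`.
#' @param alphabet Residue alphabet (default the 20 standard residues).
#' @param freqs Residue frequencies used to draw seed sequences; default
#'   uniform, which keeps the between-family identity oracle simple.
#' @return A `family_spec` object.
#' @export
family_spec <- function(n_families, members_per_family, seed_length = 120L,
                        within_family_identity = 0.9,
                        alphabet = aa_alphabet(),
                        freqs = NULL) {
  stopifnot(n_families >= 1, members_per_family >= 1)
  if (seed_length < 20) stop("seed_length must be >= 20", call. = FALSE)
  if (within_family_identity < 0 || within_family_identity > 1) {
    stop("within_family_identity must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(freqs)) {
    freqs <- setNames(rep(1 / length(alphabet), length(alphabet)), alphabet)
  }
  stopifnot(length(freqs) == length(alphabet))
  structure(list(n_families = as.integer(n_families),
                 members_per_family = as.integer(members_per_family),
                 seed_length = as.integer(seed_length),
                 within_family_identity = within_family_identity,
                 alphabet = alphabet, freqs = freqs / sum(freqs)),
            class = "family_spec")
}

#' Generate synthetic sequence families
#'
#' @param spec A [family_spec()].
#' @param seed Integer seed; the output is deterministic given the seed.
#' @return A list with `sequences` (named character vector, ids
#'   `F<i>_S<j>`) and `family_map` (data frame `seq_id`, `family`).
#' @export
generate_sequence_families <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "family_spec"))
  withr::with_seed(as.integer(seed), {
    seqs <- character(0)
    fams <- character(0)
    for (f in seq_len(spec$n_families)) {
      fam_id <- sprintf("F%02d", f)
      seed_seq <- sample(spec$alphabet, spec$seed_length,
                         replace = TRUE, prob = spec$freqs)
      for (s in seq_len(spec$members_per_family)) {
        member <- mutate_seq(seed_seq, 1 - spec$within_family_identity,
                             spec$alphabet)
        seqs[sprintf("%s_S%02d", fam_id, s)] <- paste(member, collapse = "")
        fams <- c(fams, fam_id)
      }
    }
    list(sequences = seqs,
         family_map = data.frame(seq_id = names(seqs), family = fams,
                                 stringsAsFactors = FALSE))
  })
}

# Point mutation: each position flips with probability `rate` to a residue
# drawn uniformly from the rest of the alphabet, so realized identity to
# the seed has expectation 1 - rate.
mutate_seq <- function(chars, rate, alphabet) {
  if (rate <= 0) return(chars)
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(r) {
      sample(setdiff(alphabet, r), 1L)
    }, "")
  }
  chars
}
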