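#' Karlin-Altschul parameters for an ungapped scoring system
#'
#' `solve_lambda()` finds the unique positive root of
#' \deqn{\sum_{i,j} p_i p_j e^{\lambda s_{ij}} = 1,}
#' the scale parameter of the extreme-value distribution of ungapped
#' local-alignment scores. A root exists when the matrix has at least one
#' positive score and a negative expected score under the background
#' frequencies.
#'
#' @param mat Substitution matrix; only rows/columns named in
#'   `names(freqs)` are used.
#' @param freqs Named background residue frequencies (need not sum to 1;
#'   they are renormalized).
#' @param tol Relative tolerance of the root.
#' @return The positive root lambda (per score unit).
#' @export
solve_lambda <- function(mat, freqs = default_aa_freqs(), tol = 1e-12) {
  sub <- score_distribution(mat, freqs)
  s <- sub$score
  p <- sub$prob
  if (all(s <= 0)) {
    stop("no positive score in the matrix: lambda undefined", call. = FALSE)
  }
  if (all(s >= 0) || sum(p * s) >= 0) {
    stop("expected score must be negative for Karlin-Altschul statistics",
         call. = FALSE)
  }
  f <- function(l) sum(p * exp(l * s)) - 1
  # f(0) = 0 with f'(0) = E[s] < 0; bracket the positive root from above
  hi <- 0.5
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(1e-10, hi), tol = tol)$root
}

#' @describeIn solve_lambda the Karlin-Altschul prefactor K, computed by the
#'   standard lattice series approximation: with score span `d` (gcd of the
#'   attainable scores), relative entropy `H`, and
#'   \eqn{\sigma = \sum_{k\ge1} k^{-1}\{P(S_k \ge 0) + E[e^{\lambda S_k};
#'   S_k < 0]\}} accumulated over k-fold convolutions of the pair-score
#'   distribution,
#'   \eqn{K = d\lambda e^{-2\sigma} / (H (1 - e^{-\lambda d}))}.
#' @param lambda Scale parameter; computed from `mat`/`freqs` when `NULL`.
#' @param max_iter Number of convolution terms accumulated in the series.
#' @export
karlin_K <- function(mat, freqs = default_aa_freqs(), lambda = NULL,
                     max_iter = 120L) {
  sub <- score_distribution(mat, freqs)
  s <- sub$score
  p <- sub$prob
  if (is.null(lambda)) lambda <- solve_lambda(mat, freqs)
  d <- Reduce(function(a, b) if (b == 0) a else Recall(b, a %% b), abs(s[s != 0]))
  H <- lambda * sum(p * s * exp(lambda * s))

  lo <- min(s)
  hi <- max(s)
  P1 <- numeric(hi - lo + 1L)
  P1[s - lo + 1L] <- p
  cur <- P1
  curlo <- lo
  sigma <- 0
  for (k in seq_len(max_iter)) {
    vals <- seq.int(curlo, curlo + length(cur) - 1L)
    neg <- vals < 0
    term <- sum(cur[!neg]) + sum(cur[neg] * exp(lambda * vals[neg]))
    sigma <- sigma + term / k
    if (term / k < 1e-10) break
    new <- numeric(length(cur) + length(P1) - 1L)
    nz <- which(P1 > 0)
    for (j in nz) {
      idx <- seq_along(cur) + (j - 1L)
      new[idx] <- new[idx] + cur * P1[j]
    }
    cur <- new
    curlo <- curlo + lo
  }
  d * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * d)))
}

# Distribution of the single-pair score s_ij under p_i p_j, collapsed to
# unique integer score values.
score_distribution <- function(mat, freqs) {
  res <- intersect(names(freqs), rownames(mat))
  if (length(res) < 2L) {
    stop("background frequencies and matrix share fewer than 2 residues",
         call. = FALSE)
  }
  p <- freqs[res] / sum(freqs[res])
  m <- mat[res, res, drop = FALSE]
  if (any(m != round(m))) {
    stop("lattice K computation requires integer scores", call. = FALSE)
  }
  pp <- outer(p, p)
  sc <- sort(unique(as.vector(m)))
  list(score = as.integer(sc),
       prob = vapply(sc, function(x) sum(pp[m == x]), 0))
}

#' Alignment E-value statistics
#'
#' `evalue_params()` bundles a substitution matrix, affine gap penalties
#' and background frequencies, and precomputes the ungapped
#' Karlin-Altschul parameters lambda and K used to convert raw
#' Smith-Waterman scores into expectation values
#' \eqn{E = K m n e^{-\lambda S}}.
#'
#' @param mat Substitution matrix (default BLOSUM62).
#' @param gap_open,gap_extend Affine gap penalties; a gap of length L
#'   costs `gap_open + L * gap_extend` score units.
#' @param freqs Background residue frequencies.
#' @return An object of class `evalue_params` with elements `mat`,
#'   `gap_open`, `gap_extend`, `freqs`, `lambda`, `K`.
#' @export
evalue_params <- function(mat = blosum62(), gap_open = 11, gap_extend = 1,
                          freqs = default_aa_freqs()) {
  stopifnot(gap_open >= 0, gap_extend > 0)
  lambda <- solve_lambda(mat, freqs)
  K <- karlin_K(mat, freqs, lambda = lambda)
  structure(list(mat = mat, gap_open = gap_open, gap_extend = gap_extend,
                 freqs = freqs, lambda = lambda, K = K),
            class = "evalue_params")
}

#' @export
print.evalue_params <- function(x, ...) {
  cat("E-value parameters: lambda =", signif(x$lambda, 6),
      " K =", signif(x$K, 4),
      " gap =", x$gap_open, "/", x$gap_extend, "\n")
  invisible(x)
}

#' @describeIn evalue_params the expectation value
#'   \eqn{E = K m n e^{-\lambda S}} for a raw score `S` against effective
#'   query/subject lengths `m` and `n` (vectorized over `S`).
#' @param S Raw alignment score(s).
#' @param m,n Effective query and subject lengths (residues).
#' @param params An `evalue_params` object.
#' @export
evalue <- function(S, m, n, params) {
  stopifnot(inherits(params, "evalue_params"), m >= 1, n >= 1)
  params$K * m * n * exp(-params$lambda * S)
}
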