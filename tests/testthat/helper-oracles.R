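# Shared fixtures and independent oracles.

# One Karlin-Altschul parameter set for the whole suite (BLOSUM62, 11/1).
shared_params <- evalue_params()

rand_seq <- function(n, alphabet = aa_alphabet()) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Simple match/mismatch matrix over a small alphabet (A, C, G, T are all
# valid amino-acid codes, so the alignment machinery accepts them).
toy_matrix <- function(match = 1, mismatch = -1,
                       alphabet = c("A", "C", "G", "T")) {
  k <- length(alphabet)
  m <- matrix(mismatch, k, k, dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

toy_params <- function(match = 1, mismatch = -1, gap_open = 2,
                       gap_extend = 1) {
  al <- c("A", "C", "G", "T")
  evalue_params(toy_matrix(match, mismatch, al),
                gap_open = gap_open, gap_extend = gap_extend,
                freqs = setNames(rep(0.25, 4), al))
}

# Independent local-alignment oracle: the best local alignment is the best
# globally aligned pair of substrings, so enumerate every substring pair
# and score it with a separately written global affine-gap recursion.
ref_global_affine <- function(x, y, mat, go, ge) {
  xn <- strsplit(x, "")[[1]]
  yn <- strsplit(y, "")[[1]]
  n <- length(xn); m <- length(yn)
  gf <- go + ge
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  for (j in 2:(m + 1)) Iy[1, j] <- -(go + (j - 1) * ge)
  if (n >= 1) for (i in 2:(n + 1)) Ix[i, 1] <- -(go + (i - 1) * ge)
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- mat[xn[i - 1], yn[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - gf, Ix[i - 1, j] - ge)
      Iy[i, j] <- max(M[i, j - 1] - gf, Iy[i, j - 1] - ge)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

ref_local_score <- function(a, b, mat, go, ge) {
  best <- 0
  na <- nchar(a); nb <- nchar(b)
  for (i1 in seq_len(na)) for (i2 in i1:na) {
    x <- substr(a, i1, i2)
    for (j1 in seq_len(nb)) for (j2 in j1:nb) {
      y <- substr(b, j1, j2)
      best <- max(best, ref_global_affine(x, y, mat, go, ge))
    }
  }
  best
}

# Independent root-finder for lambda: plain bisection on
# sum p_i p_j exp(lambda s_ij) - 1.
bisect_lambda <- function(mat, freqs, tol = 1e-12) {
  res <- intersect(names(freqs), rownames(mat))
  p <- freqs[res] / sum(freqs[res])
  pp <- outer(p, p)
  m <- mat[res, res]
  f <- function(l) sum(pp * exp(l * m)) - 1
  lo <- 1e-9; hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Random bipartite interaction tables with at least one edge.
rand_bipartite_tables <- function(nd, nt, p = 0.35) {
  repeat {
    adj <- matrix(runif(nd * nt) < p, nd, nt)
    if (any(adj)) break
  }
  did <- sprintf("d%02d", seq_len(nd))
  tid <- sprintf("t%02d", seq_len(nt))
  idx <- which(adj, arr.ind = TRUE)
  list(
    drugs = data.frame(drug_id = did, stringsAsFactors = FALSE),
    targets = data.frame(target_id = tid, stringsAsFactors = FALSE),
    interactions = data.frame(drug_id = did[idx[, 1]],
                              target_id = tid[idx[, 2]],
                              stringsAsFactors = FALSE)
  )
}
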