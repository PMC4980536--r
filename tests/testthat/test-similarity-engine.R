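test_that("self-alignment scores the diagonal sum and unrelated pairs score 0", {
  s <- "MKVLAWH"
  res <- smith_waterman(s, s, shared_params)
  diag_sum <- sum(vapply(strsplit(s, "")[[1]],
                         function(r) shared_params$mat[r, r], 0))
  expect_equal(res$S, diag_sum)
  expect_equal(res$m, nchar(s))

  tp <- toy_params()
  expect_equal(smith_waterman("AAAA", "CCCC", tp)$S, 0)
})

test_that("Smith-Waterman matches the exhaustive substring oracle on short pairs", {
  tp <- toy_params(match = 2, mismatch = -3, gap_open = 2, gap_extend = 1)
  set.seed(101)
  for (i in 1:15) {
    a <- rand_seq(sample(1:8, 1), c("A", "C", "G", "T"))
    b <- rand_seq(sample(1:8, 1), c("A", "C", "G", "T"))
    expect_equal(smith_waterman(a, b, tp)$S,
                 ref_local_score(a, b, tp$mat, 2, 1),
                 info = paste(a, b))
  }
  for (i in 1:10) {
    a <- rand_seq(sample(2:8, 1))
    b <- rand_seq(sample(2:8, 1))
    expect_equal(smith_waterman(a, b, shared_params)$S,
                 ref_local_score(a, b, shared_params$mat, 11, 1),
                 info = paste(a, b))
  }
})

test_that("Smith-Waterman agrees with Biostrings local alignment on longer pairs", {
  set.seed(202)
  for (i in 1:12) {
    a <- rand_seq(sample(20:60, 1))
    b <- rand_seq(sample(20:60, 1))
    bs <- Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(smith_waterman(a, b, shared_params)$S, bs)
  }
})

test_that("alignment score is symmetric for symmetric matrices", {
  set.seed(303)
  for (i in 1:8) {
    a <- rand_seq(sample(5:30, 1))
    b <- rand_seq(sample(5:30, 1))
    expect_equal(smith_waterman(a, b, shared_params)$S,
                 smith_waterman(b, a, shared_params)$S)
  }
})

test_that("unknown residues error in strict mode and map to X otherwise", {
  expect_error(smith_waterman("MKVU", "MKVL", shared_params),
               "unknown residue")
  res <- smith_waterman("MKVU", "MKVL", shared_params, unknown = "X")
  expect_equal(res$S, smith_waterman("MKVX", "MKVL", shared_params)$S)
  expect_error(smith_waterman("", "MKVL", shared_params), "nonempty")
})

test_that("lambda solver recovers ln 3 for the +1/-1 uniform 4-letter scheme", {
  al <- c("A", "C", "G", "T")
  fr <- setNames(rep(0.25, 4), al)
  expect_equal(solve_lambda(toy_matrix(1, -1), fr), log(3), tolerance = 1e-9)
})

test_that("lambda solver matches independent bisection", {
  al <- c("A", "C", "G", "T")
  fr <- setNames(rep(0.25, 4), al)
  m23 <- toy_matrix(2, -3)
  expect_equal(solve_lambda(m23, fr), bisect_lambda(m23, fr),
               tolerance = 1e-9)
  expect_equal(shared_params$lambda,
               bisect_lambda(blosum62(), default_aa_freqs()),
               tolerance = 1e-3)
})

test_that("lambda solver rejects matrices without a positive root", {
  al <- c("A", "C", "G", "T")
  fr <- setNames(rep(0.25, 4), al)
  expect_error(solve_lambda(toy_matrix(1, 1), fr), "no positive|negative")
  expect_error(solve_lambda(toy_matrix(3, -1), fr), "negative")
})

test_that("K is positive and near the published ungapped BLOSUM62 value", {
  expect_gt(shared_params$K, 0)
  expect_equal(shared_params$K, 0.134, tolerance = 0.02)
  expect_equal(shared_params$lambda, 0.3176, tolerance = 1e-3)
})

test_that("E-value formula: boundary, linearity and direct arithmetic", {
  p <- shared_params
  expect_equal(evalue(0, 100, 200, p), p$K * 100 * 200)
  expect_equal(evalue(30, 100, 400, p), 2 * evalue(30, 100, 200, p))
  q <- p
  q$K <- 0.13
  q$lambda <- 0.318
  expect_equal(evalue(50, 250, 250, q),
               0.13 * 250 * 250 * exp(-0.318 * 50), tolerance = 1e-6)
})

test_that("similarity classes partition the E axis with inclusive lower bounds", {
  expect_equal(as.character(classify_similarity(c(1e-5, 0.001, 0.05, 0.1, 0.5))),
               c("very_similar", "very_similar", "marginally_similar",
                 "marginally_similar", "unsimilar"))
  set.seed(404)
  E <- 10^runif(200, -8, 2)
  cls <- classify_similarity(E)
  expect_false(anyNA(cls))
  expect_equal(length(cls), 200L)
  expect_error(classify_similarity(0), "positive")
  expect_error(classify_similarity(-1), "positive")
  expect_error(similarity_thresholds(0.1, 0.001))
})

test_that("NS counts cross-family similar proteins only", {
  set.seed(505)
  fam <- generate_sequence_families(
    family_spec(3, 3, seed_length = 60, within_family_identity = 0.9),
    seed = 11)
  seqs <- fam$sequences
  fmap <- fam$family_map

  # same-family-only proteome: NS = 0
  own <- fmap$seq_id[fmap$family == "F01"]
  expect_equal(count_similarity_proteins("F01_S01", seqs[own],
                                         fmap[fmap$family == "F01", ],
                                         shared_params), 0L)

  # engineered cross-family homolog: mildly mutated copy placed in F02
  hom <- paste(dtprofiler:::mutate_seq(strsplit(seqs[["F01_S01"]], "")[[1]],
                                       0.05, aa_alphabet()), collapse = "")
  seqs2 <- c(seqs, HOM_X = hom)
  fmap2 <- rbind(fmap, data.frame(seq_id = "HOM_X", family = "F02"))
  expect_equal(count_similarity_proteins("F01_S01", seqs2, fmap2,
                                         shared_params), 1L)

  # NS is monotone in the cutoff; vanishing cutoff gives 0
  ns_tight <- count_similarity_proteins("F01_S01", seqs2, fmap2,
                                        shared_params, ns_cutoff = 1e-300)
  ns_loose <- count_similarity_proteins("F01_S01", seqs2, fmap2,
                                        shared_params, ns_cutoff = 10)
  expect_equal(ns_tight, 0L)
  expect_gte(ns_loose, 1L)

  # adding same-family proteins never changes NS
  seqs3 <- c(seqs2, F01_EXTRA = seqs[["F01_S02"]])
  fmap3 <- rbind(fmap2, data.frame(seq_id = "F01_EXTRA", family = "F01"))
  expect_equal(count_similarity_proteins("F01_S01", seqs3, fmap3,
                                         shared_params), 1L)
  expect_error(count_similarity_proteins("NOPE", seqs2, fmap2, shared_params),
               "not found")
})

test_that("BLAST tabular reader parses, rejects malformed rows, round-trips", {
  hits <- data.frame(
    qseqid = c("q1", "q1", "q2"), sseqid = c("s1", "s2", "s1"),
    pident = c(98.5, 45.2, 77.0), length = c(100, 80, 60),
    mismatch = c(1, 40, 12), gapopen = c(0, 2, 1),
    qstart = c(1, 5, 2), qend = c(100, 84, 61),
    sstart = c(1, 3, 4), send = c(100, 82, 63),
    evalue = c(1e-50, 0.002, 0.2), bitscore = c(200.1, 50.3, 30.2),
    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".tsv")
  write_blast_tabular(hits, f)
  back <- read_blast_tabular(f)
  expect_equal(nrow(back), 3L)
  expect_equal(back$qseqid, hits$qseqid)
  expect_equal(back$sseqid, hits$sseqid)
  expect_equal(back$evalue, hits$evalue)

  bad <- readLines(f)
  bad[2] <- sub("0\\.002", "abc", bad[2])
  writeLines(bad, f)
  expect_error(read_blast_tabular(f), "line 2.*non-numeric|non-numeric.*line 2")

  writeLines(c("a\tb\tc"), f)
  expect_error(read_blast_tabular(f), "line 1")
})

test_that("NCBI matrix text format reader recovers a scoring matrix", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("# toy matrix", "   A  C  G  T",
               "A  1 -1 -1 -1", "C -1  1 -1 -1",
               "G -1 -1  1 -1", "T -1 -1 -1  1"), f)
  m <- read_score_matrix(f)
  expect_equal(m, toy_matrix(), ignore_attr = FALSE)
  writeLines(c("   A  C", "A  1 -1", "C -1"), f)
  expect_error(read_score_matrix(f), "row")
})
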