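test_that("cohort specs validate their inputs", {
  expect_error(cohort_spec("phase3", 0, dist_point(1), dist_point(1),
                           dist_point(1)), "positive integer")
  expect_error(cohort_spec("phaseX", 5, dist_point(1), dist_point(1),
                           dist_point(1)))
  expect_error(dist_nbinom(-1, 2), "mu > 0")
  expect_error(dist_nbinom(5, 0), "size > 0")
  expect_error(dist_point(2.5), "nonnegative integer")
  expect_error(cohort_spec("phase3", 5, ns = 3, np = dist_point(1),
                           nt = dist_point(1)), "dist_")
})

test_that("degenerate point-mass cohorts are constant and seeds reproduce", {
  sp <- cohort_spec("established", 2000, dist_point(10), dist_point(2),
                    dist_point(1), seed = 7)
  co <- generate_cohort(sp)
  expect_equal(nrow(co), 2000L)
  expect_true(all(co$NS == 10L))
  expect_identical(co, generate_cohort(sp))

  spb <- cohort_presets(200, seed = 5)$phase2
  expect_identical(generate_cohort(spb), generate_cohort(spb))
  spc <- cohort_presets(200, seed = 6)$phase2
  expect_false(identical(generate_cohort(spb)$NS, generate_cohort(spc)$NS))
})

test_that("empirical compliance converges to the generating CDF", {
  sp <- cohort_spec("phase1", 2000, dist_nbinom(10.8, 3), dist_nbinom(2.05, 4),
                    dist_nbinom(2.7, 6), seed = 31)
  co <- generate_cohort(sp)
  p_ns <- pnbinom(14, size = 3, mu = 10.8)
  se <- sqrt(p_ns * (1 - p_ns) / 2000)
  expect_lt(abs(mean(co$NS < 15) - p_ns), 3 * se)
})

test_that("sequence families honour identity parameters", {
  spec1 <- family_spec(2, 4, seed_length = 50, within_family_identity = 1.0)
  fam1 <- generate_sequence_families(spec1, seed = 3)
  for (f in c("F01", "F02")) {
    member_seqs <- fam1$sequences[fam1$family_map$family == f]
    expect_equal(length(unique(member_seqs)), 1L)
  }

  spec2 <- family_spec(3, 1, seed_length = 40)
  fam2 <- generate_sequence_families(spec2, seed = 4)
  expect_equal(length(fam2$sequences), 3L)
  expect_equal(anyDuplicated(fam2$family_map$family), 0L)

  expect_error(family_spec(2, 2, seed_length = 10), ">= 20")
  expect_error(family_spec(2, 2, within_family_identity = 1.2), "\\[0, 1\\]")
})

test_that("between-family identity sits at the background coincidence rate", {
  # independent uniform sequences: expected identity = sum p_i^2 = 1/20
  spec <- family_spec(10, 1, seed_length = 300, within_family_identity = 1)
  fam <- generate_sequence_families(spec, seed = 12)
  chars <- lapply(fam$sequences, function(s) strsplit(s, "")[[1]])
  ids <- c()
  for (i in 1:9) for (j in (i + 1):10) {
    ids <- c(ids, mean(chars[[i]] == chars[[j]]))
  }
  # 45 pairs x 300 positions; 3-s.e. band around 0.05
  se <- sqrt(0.05 * 0.95 / (45 * 300))
  expect_lt(abs(mean(ids) - 0.05), 3 * se)
})

test_that("deterministic family generation under a fixed seed", {
  spec <- family_spec(2, 3, seed_length = 30)
  expect_identical(generate_sequence_families(spec, seed = 9),
                   generate_sequence_families(spec, seed = 9))
  expect_false(identical(generate_sequence_families(spec, seed = 9)$sequences,
                         generate_sequence_families(spec, seed = 10)$sequences))
})

test_that("Gale-Ryser feasibility is checked and named in errors", {
  expect_error(gale_ryser_check(1, 2), "sums differ")
  expect_error(gale_ryser_check(c(2, 2), 4), "Gale-Ryser")
  expect_true(gale_ryser_check(c(2, 1), c(2, 1)))
  expect_error(gale_ryser_check(c(0, 1), c(1)), "positive integers")
})

test_that("realized graphs reproduce the requested degree multisets", {
  # {2,1} vs {2,1}: the unique simple realization has 3 edges
  net <- realize_bipartite(c(2, 1), c(2, 1))
  expect_equal(nrow(net$interactions), 3L)
  dh <- degree_histogram(net, "drug")
  expect_equal(sort(rep(dh$degree, dh$count)), c(1, 2))
  th <- degree_histogram(net, "target")
  expect_equal(sort(rep(th$degree, th$count)), c(1, 2))

  expect_error(realize_bipartite(1, 2), "sums differ")

  set.seed(77)
  for (i in 1:25) {
    tabs <- rand_bipartite_tables(sample(3:8, 1), sample(3:8, 1))
    dd <- as.integer(table(tabs$interactions$drug_id))
    td <- as.integer(table(tabs$interactions$target_id))
    net <- realize_bipartite(dd, td)
    expect_equal(sort(unname(dtprofiler:::node_degrees(net, "drug"))),
                 sort(dd))
    expect_equal(sort(unname(dtprofiler:::node_degrees(net, "target"))),
                 sort(td))
  }
})

test_that("the approved-network degree fixture realizes 46 drugs and 25 targets", {
  deg <- approved_network_degrees()
  expect_equal(sum(deg$drug), sum(deg$target))
  net <- realize_bipartite(deg$drug, deg$target)
  expect_equal(nrow(net$drugs), 46L)
  expect_equal(nrow(net$targets), 25L)
  expect_equal(sort(unname(dtprofiler:::node_degrees(net, "drug"))),
               sort(deg$drug))
  expect_equal(sort(unname(dtprofiler:::node_degrees(net, "target"))),
               sort(deg$target))
  # no degree-8 target class, as transcribed
  expect_false(8 %in% degree_histogram(net, "target")$degree)
})

test_that("the packaged status table transcription is intact", {
  tab <- phase3_status_table()
  expect_equal(nrow(tab), 16L)
  ntrk1 <- tab[grepl("NTRK1", tab$target), ]
  expect_equal(unname(parse_combination(ntrk1$combination)[1, ]),
               c(TRUE, TRUE, TRUE, TRUE))
  expect_match(ntrk1$status, "Lestaurtinib approved")
  expect_identical(tab$status[grepl("NPYR5", tab$target)], "")
})
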