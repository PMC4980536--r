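two_drug_net <- function() {
  build_network(
    data.frame(drug_id = c("d1", "d2"), icd_codes = c("C54.1", "C61")),
    data.frame(target_id = "t1"),
    data.frame(drug_id = c("d1", "d2"), target_id = "t1",
               mode = c("inhibition", "activation")))
}

test_that("network construction validates integrity and attaches attributes", {
  net <- two_drug_net()
  expect_equal(unname(dtprofiler:::node_degrees(net, "target")), 2)

  expect_error(build_network(
    data.frame(drug_id = "d1"), data.frame(target_id = "t1"),
    data.frame(drug_id = c("d1", "d1"), target_id = c("t1", "t1"))),
    "duplicate")
  expect_error(build_network(
    data.frame(drug_id = "d1"), data.frame(target_id = "t1"),
    data.frame(drug_id = "dX", target_id = "t1")),
    "dX")
  expect_error(build_network(
    data.frame(drug_id = "d1", modality = "nanobody"),
    data.frame(target_id = "t1"),
    data.frame(drug_id = "d1", target_id = "t1")),
    "modality")
})

test_that("degree histograms match the printed fixtures", {
  deg <- approved_network_degrees()
  net <- realize_bipartite(deg$drug, deg$target)
  dh <- degree_histogram(net, "drug")
  expect_equal(dh$count[match(c(5, 3, 2, 1), dh$degree)],
               c(1L, 4L, 10L, 31L))
  expect_equal(sum(dh$count), 46L)

  sub <- genital_cancer_subnet_degrees()
  snet <- realize_bipartite(sub$drug, sub$target)
  sh <- degree_histogram(snet, "drug")
  expect_equal(sh$count[match(c(2, 1), sh$degree)], c(3L, 10L))
  expect_equal(sum(sh$count), 13L)
  expect_equal(sum(degree_histogram(snet, "target")$count), 9L)

  one <- build_network(data.frame(drug_id = "d"),
                       data.frame(target_id = "t"),
                       data.frame(drug_id = "d", target_id = "t"))
  expect_equal(degree_histogram(one, "drug"),
               data.frame(degree = 1L, count = 1L))
  expect_equal(degree_histogram(one, "target"),
               data.frame(degree = 1L, count = 1L))
})

test_that("popular nodes are thresholded strictly and ordered deterministically", {
  deg <- approved_network_degrees()
  net <- realize_bipartite(deg$drug, deg$target)
  top <- popular_nodes(net, "target", 8)
  expect_equal(top$degree, c(10L, 9L))
  expect_equal(nrow(popular_nodes(net, "target", 10)), 0L)
  # threshold 0 returns every (non-isolated) node of the class
  expect_equal(nrow(popular_nodes(net, "drug", 0)), 46L)
  # ties resolve lexicographically
  tie <- realize_bipartite(c(2, 2, 2), c(3, 3))
  pop <- popular_nodes(tie, "target", 0)
  expect_equal(pop$id, sort(pop$id))
})

test_that("multitarget drugs are exactly those of degree >= 2", {
  deg <- approved_network_degrees()
  net <- realize_bipartite(deg$drug, deg$target)
  mt <- multitarget_drugs(net)
  expect_equal(nrow(mt), 15L)
  expect_true(all(mt$degree >= 2))
  expect_equal(max(mt$degree), 5L)

  flat <- realize_bipartite(c(1, 1), c(1, 1))
  expect_equal(nrow(multitarget_drugs(flat)), 0L)
})

test_that("ICD subnetworks filter by 3-character category within the range", {
  net <- two_drug_net()
  sub <- subnetwork_by_icd(net, "C51-C58")
  expect_equal(sub$drugs$drug_id, "d1")   # C54.1 in range, C61 out
  expect_equal(sub$targets$target_id, "t1")

  expect_error(subnetwork_by_icd(net, "C51C58"), "malformed")
  expect_error(subnetwork_by_icd(net, "C51-D58"), "letter")
  expect_error(subnetwork_by_icd(net, "C58-C51"), "lo > hi")

  # induced subgraph: every retained edge exists in the parent
  set.seed(88)
  for (i in 1:10) {
    tabs <- rand_bipartite_tables(6, 5)
    tabs$drugs$icd_codes <- sample(c("C52", "C61", "E11", ""), 6, replace = TRUE)
    parent <- build_network(tabs$drugs, tabs$targets, tabs$interactions)
    sub <- subnetwork_by_icd(parent, "C51-C58")
    pk <- paste(parent$interactions$drug_id, parent$interactions$target_id)
    sk <- paste(sub$interactions$drug_id, sub$interactions$target_id)
    expect_true(all(sk %in% pk))
    # all retained targets still have at least one drug
    expect_true(all(sub$targets$target_id %in% sub$interactions$target_id))
  }
})

test_that("exports produce SIF lines, GraphML round trips, and empty docs", {
  net <- two_drug_net()
  dir <- tempfile()
  paths <- export_network(net, dir)
  sif <- readLines(paths[["sif"]])
  expect_setequal(sif, c("d1\tinhibits\tt1", "d2\tactivates\tt1"))

  g2 <- read_network_graphml(paths[["graphml"]])
  expect_setequal(igraph::V(g2)$name, c("d1", "d2", "t1"))
  expect_equal(igraph::ecount(g2), 2)
  expect_setequal(igraph::E(g2)$mode, c("inhibition", "activation"))
  expect_setequal(igraph::V(g2)$class, c("drug", "drug", "target"))

  nodes <- read.delim(paths[["nodes_tsv"]])
  expect_equal(nrow(nodes), 3L)

  empty <- build_network(data.frame(drug_id = character(0)),
                         data.frame(target_id = character(0)),
                         data.frame(drug_id = character(0),
                                    target_id = character(0)))
  ep <- export_network(empty, tempfile())
  expect_equal(length(readLines(ep[["sif"]])), 0L)
  expect_silent(read_network_graphml(ep[["graphml"]]))
})
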