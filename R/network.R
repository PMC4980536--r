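#' Build a bipartite drug-target interaction network
#'
#' Validates referential integrity and uniqueness, then assembles a
#' strictly bipartite graph (igraph backend) with node attributes
#' (class, modality, development stage, target cohort, ICD codes) and the
#' interaction mode on every edge.
#'
#' @param drugs Data frame with columns `drug_id` and optionally `name`,
#'   `modality` (`small_molecule`, `monoclonal_antibody`, `biologic`),
#'   `stage` (`approved`, `phase3`, `phase2`, `phase1`) and `icd_codes`
#'   (`;`-separated ICD code strings, may be empty).
#' @param targets Data frame with columns `target_id` and optionally
#'   `cohort` (`established` or `clinical_trial`).
#' @param interactions Data frame with columns `drug_id`, `target_id` and
#'   optionally `mode` (`activation` or `inhibition`) and `primary`.
#' @return A `dtnetwork`: list with the igraph `graph` and the validated
#'   `drugs`, `targets`, `interactions` tables.
#' @export
build_network <- function(drugs, targets, interactions) {
  req <- function(df, col, what) {
    if (!col %in% names(df)) stop(what, " table lacks column '", col, "'",
                                  call. = FALSE)
  }
  req(drugs, "drug_id", "drug"); req(targets, "target_id", "target")
  req(interactions, "drug_id", "interaction")
  req(interactions, "target_id", "interaction")
  drugs$drug_id <- as.character(drugs$drug_id)
  targets$target_id <- as.character(targets$target_id)
  if (anyDuplicated(drugs$drug_id)) stop("duplicate drug_id", call. = FALSE)
  if (anyDuplicated(targets$target_id)) stop("duplicate target_id", call. = FALSE)
  if (length(shared <- intersect(drugs$drug_id, targets$target_id))) {
    stop("ids used on both sides: ", paste(head(shared, 5L), collapse = ", "),
         call. = FALSE)
  }

  nd <- nrow(drugs); ni <- nrow(interactions)
  if (is.null(drugs$name)) drugs$name <- drugs$drug_id
  if (is.null(drugs$modality)) drugs$modality <- rep("small_molecule", nd)
  if (is.null(drugs$stage)) drugs$stage <- rep("approved", nd)
  if (is.null(drugs$icd_codes)) drugs$icd_codes <- rep("", nd)
  drugs$icd_codes[is.na(drugs$icd_codes)] <- ""
  if (is.null(targets$cohort)) targets$cohort <- rep("established", nrow(targets))
  if (is.null(interactions$mode)) interactions$mode <- rep("inhibition", ni)
  if (is.null(interactions$primary)) interactions$primary <- rep(TRUE, ni)

  bad <- setdiff(drugs$modality,
                 c("small_molecule", "monoclonal_antibody", "biologic"))
  if (length(bad)) stop("unknown modality: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(interactions$mode, c("activation", "inhibition"))
  if (length(bad)) stop("unknown interaction mode: ",
                        paste(bad, collapse = ", "), call. = FALSE)

  dang_d <- setdiff(interactions$drug_id, drugs$drug_id)
  dang_t <- setdiff(interactions$target_id, targets$target_id)
  if (length(dang_d) || length(dang_t)) {
    stop("interactions reference unknown ids: ",
         paste(c(dang_d, dang_t), collapse = ", "), call. = FALSE)
  }
  key <- paste(interactions$drug_id, interactions$target_id)
  if (anyDuplicated(key)) {
    stop("duplicate drug-target interaction(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  }

  vdf <- rbind(
    data.frame(name = drugs$drug_id, class = rep("drug", nd),
               modality = drugs$modality, stage = drugs$stage,
               cohort = rep(NA_character_, nd), icd_codes = drugs$icd_codes,
               stringsAsFactors = FALSE),
    data.frame(name = targets$target_id,
               class = rep("target", nrow(targets)),
               modality = rep(NA_character_, nrow(targets)),
               stage = rep(NA_character_, nrow(targets)),
               cohort = targets$cohort,
               icd_codes = rep(NA_character_, nrow(targets)),
               stringsAsFactors = FALSE)
  )
  edf <- data.frame(from = interactions$drug_id, to = interactions$target_id,
                    mode = interactions$mode, primary = interactions$primary,
                    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
  igraph::V(g)$type <- igraph::V(g)$class == "target"
  structure(list(graph = g, drugs = drugs, targets = targets,
                 interactions = interactions),
            class = "dtnetwork")
}

#' @export
print.dtnetwork <- function(x, ...) {
  cat("Drug-target network:", nrow(x$drugs), "drugs,", nrow(x$targets),
      "targets,", nrow(x$interactions), "interactions\n")
  invisible(x)
}

node_degrees <- function(net, node_class = c("drug", "target")) {
  node_class <- match.arg(node_class)
  g <- net$graph
  keep <- igraph::V(g)$class == node_class
  setNames(igraph::degree(g)[keep], igraph::V(g)$name[keep])
}

#' Degree histogram of one side of the network
#'
#' @param net A `dtnetwork`.
#' @param node_class `"drug"` or `"target"`.
#' @return Data frame `degree`, `count`, sorted by degree. Isolated nodes
#'   (degree 0) are included in the count when present in the node tables.
#' @export
degree_histogram <- function(net, node_class = c("drug", "target")) {
  deg <- node_degrees(net, node_class)
  if (!length(deg)) {
    return(data.frame(degree = integer(0), count = integer(0)))
  }
  tab <- table(deg)
  data.frame(degree = as.integer(names(tab)), count = as.integer(tab))
}

#' Popular nodes above a degree threshold
#'
#' @param net A `dtnetwork`.
#' @param node_class `"drug"` or `"target"`.
#' @param min_degree_exclusive Retain nodes with degree strictly greater
#'   than this (>= 0).
#' @return Data frame `id`, `degree`, sorted by degree descending then id.
#' @export
popular_nodes <- function(net, node_class = c("drug", "target"),
                          min_degree_exclusive = 0) {
  stopifnot(min_degree_exclusive >= 0)
  deg <- node_degrees(net, node_class)
  deg <- deg[deg > min_degree_exclusive]
  out <- data.frame(id = names(deg), degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out[order(-out$degree, out$id), , drop = FALSE]
}

#' Multitarget drugs
#'
#' @param net A `dtnetwork`.
#' @return Data frame of drugs with degree >= 2, sorted by degree
#'   descending then id.
#' @export
multitarget_drugs <- function(net) {
  popular_nodes(net, "drug", min_degree_exclusive = 1)
}

#' Extract the subnetwork of an ICD disease-class code range
#'
#' Retains drugs carrying at least one ICD code whose 3-character
#' category (letter plus two digits; `C54.1` matches as `C54`) falls in
#' the given range, together with their targets, and restricts edges to
#' the retained nodes (induced subgraph). Targets left without any drug
#' are dropped by default.
#'
#' @param net A `dtnetwork`.
#' @param code_range Range string such as `"C51-C58"` (same letter on
#'   both ends, lo <= hi).
#' @param drop_isolated Drop targets with no retained drug (default TRUE).
#' @return A `dtnetwork`.
#' @export
subnetwork_by_icd <- function(net, code_range, drop_isolated = TRUE) {
  rng <- parse_icd_range(code_range)
  codes <- strsplit(net$drugs$icd_codes, ";", fixed = TRUE)
  keep <- vapply(codes, function(cs) {
    cs <- trimws(cs)
    cs <- cs[nzchar(cs)]
    any(icd_in_range(cs, rng))
  }, logical(1L))
  drugs <- net$drugs[keep, , drop = FALSE]
  inter <- net$interactions[net$interactions$drug_id %in% drugs$drug_id, ,
                            drop = FALSE]
  targets <- net$targets
  if (drop_isolated) {
    targets <- targets[targets$target_id %in% inter$target_id, , drop = FALSE]
  }
  build_network(drugs, targets, inter)
}

parse_icd_range <- function(code_range) {
  m <- regmatches(code_range,
                  regexec("^([A-Z])([0-9]{2})-([A-Z])([0-9]{2})$", code_range))[[1L]]
  if (!length(m)) {
    stop("malformed ICD range '", code_range,
         "': expected e.g. \"C51-C58\"", call. = FALSE)
  }
  if (m[2L] != m[4L]) {
    stop("ICD range '", code_range, "' mixes letter prefixes", call. = FALSE)
  }
  lo <- as.integer(m[3L]); hi <- as.integer(m[5L])
  if (lo > hi) stop("ICD range '", code_range, "' has lo > hi", call. = FALSE)
  list(letter = m[2L], lo = lo, hi = hi)
}

icd_in_range <- function(codes, rng) {
  m <- regmatches(codes, regexec("^([A-Z])([0-9]{2})", codes))
  vapply(m, function(x) {
    length(x) == 3L && x[2L] == rng$letter &&
      as.integer(x[3L]) >= rng$lo && as.integer(x[3L]) <= rng$hi
  }, logical(1L))
}

#' Export a network for Cytoscape
#'
#' Writes any of: SIF (`drug<TAB>activates|inhibits<TAB>target`), GraphML
#' with node attributes (class, modality, stage, cohort) and the edge
#' mode, and node/edge attribute TSV tables keyed by id.
#'
#' @param net A `dtnetwork`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("sif", "graphml", "tsv")`.
#' @param basename File stem.
#' @return Named character vector of written paths, invisibly.
#' @export
export_network <- function(net, dir, formats = c("sif", "graphml", "tsv"),
                           basename = "network") {
  formats <- match.arg(formats, several.ok = TRUE)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir, call. = FALSE)
  }
  paths <- character(0)
  if ("sif" %in% formats) {
    p <- file.path(dir, paste0(basename, ".sif"))
    rel <- ifelse(net$interactions$mode == "activation", "activates", "inhibits")
    writeLines(paste(net$interactions$drug_id, rel, net$interactions$target_id,
                     sep = "\t"), p)
    paths["sif"] <- p
  }
  if ("graphml" %in% formats) {
    p <- file.path(dir, paste0(basename, ".graphml"))
    igraph::write_graph(net$graph, p, format = "graphml")
    paths["graphml"] <- p
  }
  if ("tsv" %in% formats) {
    pn <- file.path(dir, paste0(basename, "_nodes.tsv"))
    pe <- file.path(dir, paste0(basename, "_edges.tsv"))
    k1 <- nrow(net$drugs); k2 <- nrow(net$targets)
    nd <- rbind(
      data.frame(id = net$drugs$drug_id, class = rep("drug", k1),
                 modality = net$drugs$modality, stage = net$drugs$stage,
                 cohort = rep(NA_character_, k1), stringsAsFactors = FALSE),
      data.frame(id = net$targets$target_id, class = rep("target", k2),
                 modality = rep(NA_character_, k2),
                 stage = rep(NA_character_, k2),
                 cohort = net$targets$cohort, stringsAsFactors = FALSE)
    )
    write.table(nd, pn, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(net$interactions, pe, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths["nodes_tsv"] <- pn
    paths["edges_tsv"] <- pe
  }
  invisible(paths)
}

#' @describeIn export_network read back a GraphML file written by
#'   `export_network()` as an igraph graph (round-trip checkable).
#' @param path GraphML file path.
#' @export
read_network_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
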