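#' Pipeline configuration
#'
#' Collects the file locations and tunable parameters of the full
#' analysis. Dataset files follow a fixed naming convention inside
#' `data_dir` (as written by [simulate_dataset()]): `sequences.fasta`,
#' `targets.tsv`, `pathways.tsv`, `tissues.tsv`, `flags.tsv`,
#' `drugs.tsv`, `interactions.tsv`.
#'
#' @param data_dir Directory holding the input dataset.
#' @param out_dir Directory for result tables and exports.
#' @param seed Integer seed governing every stochastic stage.
#' @param thresholds A [similarity_thresholds()] object.
#' @param rules A [profile_rules()] object.
#' @param ns_cutoff E-value cutoff for the NS count.
#' @param icd_range ICD disease-class range for the subnetwork stage.
#' @param popular_min_degree Exclusive degree threshold for popular
#'   targets.
#' @param trend_n Cohort size used for the simulated median-trend stage.
#' @param gap_open,gap_extend Affine gap penalties for alignments.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(data_dir, out_dir, seed = 1L,
                            thresholds = similarity_thresholds(),
                            rules = profile_rules(), ns_cutoff = 0.001,
                            icd_range = "C51-C58",
                            popular_min_degree = 8,
                            trend_n = 500L,
                            gap_open = 11, gap_extend = 1) {
  files <- file.path(data_dir, c(
    sequences = "sequences.fasta", targets = "targets.tsv",
    pathways = "pathways.tsv", tissues = "tissues.tsv",
    flags = "flags.tsv", drugs = "drugs.tsv",
    interactions = "interactions.tsv"))
  names(files) <- c("sequences", "targets", "pathways", "tissues",
                    "flags", "drugs", "interactions")
  structure(list(data_dir = data_dir, out_dir = out_dir, files = files,
                 seed = as.integer(seed), thresholds = thresholds,
                 rules = rules, ns_cutoff = ns_cutoff,
                 icd_range = icd_range,
                 popular_min_degree = popular_min_degree,
                 trend_n = as.integer(trend_n),
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "pipeline_config")
}

#' @describeIn pipeline_config read a YAML configuration file whose keys
#'   mirror the `pipeline_config()` arguments (scalar fields only;
#'   `thresholds` and `rules` as nested maps).
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(data_dir = y$data_dir, out_dir = y$out_dir)
  for (k in c("seed", "ns_cutoff", "icd_range", "popular_min_degree",
              "trend_n", "gap_open", "gap_extend")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$thresholds)) {
    args$thresholds <- similarity_thresholds(y$thresholds$very_similar_max,
                                             y$thresholds$marginal_max)
  }
  if (!is.null(y$rules)) {
    args$rules <- profile_rules(y$rules$ns_max_exclusive,
                                y$rules$np_max_inclusive,
                                y$rules$nt_max_inclusive)
  }
  do.call(pipeline_config, args)
}

#' Simulate a complete demo dataset on disk
#'
#' Writes a small synthetic study to `dir`: sequence families (FASTA)
#' split into established and phase 3/2/1 targets plus unrelated decoys,
#' pathway/tissue annotation tables drawn from the cohort presets, a
#' stub structural/physicochemical flag table, and a drug-target
#' interaction set with ICD disease codes. With
#' `preset = "degree-fixtures"` the interaction tables realize the
#' printed degree histograms of the approved-drug kinase network instead.
#'
#' @param dir Output directory.
#' @param seed Integer seed; same seed, byte-identical files.
#' @param preset `"demo"` or `"degree-fixtures"`.
#' @return Named character vector of written paths, invisibly.
#' @export
simulate_dataset <- function(dir, seed = 1L, preset = c("demo",
                                                        "degree-fixtures")) {
  preset <- match.arg(preset)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create dataset directory: ", dir, call. = FALSE)
  }
  if (preset == "degree-fixtures") {
    return(write_degree_fixture_dataset(dir))
  }
  withr::with_seed(as.integer(seed), simulate_demo_dataset(dir))
}

simulate_demo_dataset <- function(dir) {
  tsv <- function(df, file) {
    p <- file.path(dir, file)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  # Six 5-member families at 92% within-family identity; three families
  # carry the targets, the rest are proteome decoys.
  fam <- generate_sequence_families(
    family_spec(6, 5, seed_length = 90, within_family_identity = 0.92),
    seed = sample.int(1e6, 1))
  seqs <- fam$sequences
  assign_phase <- c(F01_S01 = "established", F01_S02 = "established",
                    F02_S01 = "established", F02_S02 = "established",
                    F03_S01 = "established", F03_S02 = "established",
                    F01_S03 = "phase3", F02_S03 = "phase3",
                    F01_S04 = "phase2", F02_S04 = "phase2", F03_S03 = "phase2",
                    F03_S04 = "phase1", F01_S05 = "phase1", F04_S01 = "phase1")
  targets <- data.frame(
    target_id = names(assign_phase), phase = unname(assign_phase),
    family = fam$family_map$family[match(names(assign_phase),
                                         fam$family_map$seq_id)],
    stringsAsFactors = FALSE)

  presets <- cohort_presets(n_targets = 1L)
  pathway_pool <- sprintf("PTH%03d", 1:40)
  tissue_pool <- c("brain", "heart", "liver", "kidney", "lung", "spleen",
                   "muscle", "skin", "bone_marrow", "pancreas", "thymus",
                   "ovary", "testis", "colon", "stomach", "placenta")
  ann <- lapply(seq_len(nrow(targets)), function(i) {
    ph <- targets$phase[i]
    np <- max(1L, as.integer(presets[[ph]]$np$r(1)))
    nt <- max(1L, as.integer(presets[[ph]]$nt$r(1)))
    list(pw = data.frame(target_id = targets$target_id[i],
                         pathway_id = sample(pathway_pool, min(np, 40L)),
                         stringsAsFactors = FALSE),
         ti = data.frame(target_id = targets$target_id[i],
                         tissue = sample(tissue_pool, min(nt, 16L)),
                         stringsAsFactors = FALSE))
  })
  pathways <- do.call(rbind, lapply(ann, `[[`, "pw"))
  tissues <- do.call(rbind, lapply(ann, `[[`, "ti"))

  # stub provider for the structural-fold (B) and physicochemical (C)
  # profile flags: their computation lives outside this package
  flags <- data.frame(target_id = targets$target_id,
                      B = runif(nrow(targets)) < 0.6,
                      C = runif(nrow(targets)) < 0.6,
                      stringsAsFactors = FALSE)

  # drugs: 1-3 per target; clinical drugs carry ICD codes, with the
  # female-genital-organ cancer range represented
  icd_pool <- c("C50.9", "C54.1", "C56", "C61", "E11", "G30", "C18.9")
  drows <- list(); irows <- list(); k <- 0L
  for (i in seq_len(nrow(targets))) {
    nd <- sample(1:3, 1L)
    for (j in seq_len(nd)) {
      k <- k + 1L
      did <- sprintf("DRG%03d", k)
      stage <- if (targets$phase[i] == "established") "approved"
               else targets$phase[i]
      drows[[k]] <- data.frame(
        drug_id = did, name = did,
        modality = sample(c("small_molecule", "monoclonal_antibody",
                            "biologic"), 1L, prob = c(0.8, 0.1, 0.1)),
        stage = stage,
        icd_codes = paste(sample(icd_pool, sample(1:2, 1L)), collapse = ";"),
        stringsAsFactors = FALSE)
      irows[[k]] <- data.frame(
        drug_id = did, target_id = targets$target_id[i],
        mode = sample(c("inhibition", "activation"), 1L, prob = c(0.9, 0.1)),
        primary = TRUE, stringsAsFactors = FALSE)
    }
  }
  drugs <- do.call(rbind, drows)
  interactions <- do.call(rbind, irows)
  # a few multitarget drugs: rewire some degree-1 drugs onto a second target
  extra <- head(which(targets$phase == "established"), 3L)
  for (e in seq_along(extra)) {
    cand <- setdiff(drugs$drug_id, interactions$drug_id[
      interactions$target_id == targets$target_id[extra[e]]])
    add <- cand[e]
    interactions <- rbind(interactions, data.frame(
      drug_id = add, target_id = targets$target_id[extra[e]],
      mode = "inhibition", primary = FALSE, stringsAsFactors = FALSE))
  }

  paths <- c(
    sequences = {
      p <- file.path(dir, "sequences.fasta"); write_fasta(seqs, p); p
    },
    targets = tsv(targets, "targets.tsv"),
    pathways = tsv(pathways, "pathways.tsv"),
    tissues = tsv(tissues, "tissues.tsv"),
    flags = tsv(flags, "flags.tsv"),
    drugs = tsv(drugs, "drugs.tsv"),
    interactions = tsv(interactions, "interactions.tsv"))
  invisible(paths)
}

write_degree_fixture_dataset <- function(dir) {
  deg <- approved_network_degrees()
  net <- realize_bipartite(deg$drug, deg$target)
  paths <- c(
    drugs = file.path(dir, "drugs.tsv"),
    targets = file.path(dir, "targets.tsv"),
    interactions = file.path(dir, "interactions.tsv"))
  write.table(net$drugs, paths["drugs"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(net$targets, paths["targets"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(net$interactions, paths["interactions"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Run the full comparative analysis
#'
#' Chains the pipeline stages over a dataset directory: sequence
#' similarity levels per phase, NS counts, system-profile assembly and
#' cohort summaries, the simulated median-trend comparison, the
#' retrospective status-table evaluation and per-phase prediction rates,
#' and the drug-target network statistics with Cytoscape-compatible
#' exports. Every output is listed in a JSON manifest; any stage failure
#' aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (named list of output paths), invisibly.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out) && !dir.create(out, recursive = TRUE)) {
    stop("cannot create output directory: ", out, call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  tsv <- function(df, file) {
    p <- file.path(out, file)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  manifest <- list()

  dat <- stage("load", {
    f <- config$files
    miss <- f[!file.exists(f)]
    if (length(miss)) stop("missing input file(s): ",
                           paste(miss, collapse = ", "))
    list(seqs = read_fasta(f[["sequences"]]),
         targets = read.delim(f[["targets"]], stringsAsFactors = FALSE),
         pathways = read.delim(f[["pathways"]], stringsAsFactors = FALSE),
         tissues = read.delim(f[["tissues"]], stringsAsFactors = FALSE),
         flags = read.delim(f[["flags"]], stringsAsFactors = FALSE),
         drugs = read.delim(f[["drugs"]], stringsAsFactors = FALSE),
         interactions = read.delim(f[["interactions"]],
                                   stringsAsFactors = FALSE))
  })

  params <- stage("alignment_setup",
                  evalue_params(gap_open = config$gap_open,
                                gap_extend = config$gap_extend))

  sim <- stage("similarity", {
    est <- dat$targets$target_id[dat$targets$phase == "established"]
    clin <- dat$targets[dat$targets$phase != "established", , drop = FALSE]
    clin$sequence <- unname(dat$seqs[clin$target_id])
    lev <- similarity_level_distribution(
      data.frame(target_id = clin$target_id, phase = clin$phase,
                 sequence = clin$sequence, stringsAsFactors = FALSE),
      dat$seqs[est], params, config$thresholds)
    manifest$similarity_levels <- tsv(lev, "similarity_levels.tsv")
    best <- vapply(clin$target_id, function(id) {
      best_hit_evalue(dat$seqs[[id]], dat$seqs[est], params)
    }, 0)
    list(levels = lev, best = best, established = est)
  })

  profs <- stage("profiles", {
    fmap <- data.frame(seq_id = names(dat$seqs),
                       family = dat$targets$family[
                         match(names(dat$seqs), dat$targets$target_id)],
                       stringsAsFactors = FALSE)
    # decoy sequences keep their family prefix as label
    fmap$family[is.na(fmap$family)] <-
      sub("_S[0-9]+$", "", fmap$seq_id[is.na(fmap$family)])
    ns <- vapply(dat$targets$target_id, function(id) {
      count_similarity_proteins(id, dat$seqs, fmap, params,
                                ns_cutoff = config$ns_cutoff)
    }, 0L)
    pr <- assemble_profiles(dat$targets, ns, dat$pathways, dat$tissues,
                            config$rules)
    manifest$profiles <- tsv(pr, "profiles.tsv")
    comp <- do.call(rbind, lapply(split(pr, pr$phase), function(g) {
      s <- summarize_cohort(g, g$phase[1L])
      data.frame(cohort = s$cohort_label, n = s$n,
                 pct_compliant_ns = s$pct[["ns"]],
                 pct_compliant_np = s$pct[["np"]],
                 pct_compliant_nt = s$pct[["nt"]],
                 stringsAsFactors = FALSE)
    }))
    rownames(comp) <- NULL
    manifest$cohort_compliance <- tsv(comp, "cohort_compliance.tsv")
    pr
  })

  stage("median_trend", {
    specs <- cohort_presets(n_targets = config$trend_n,
                            seed = config$seed)
    sums <- lapply(specs[c("established", "phase3", "phase2", "phase1")],
                   function(sp) {
      summarize_cohort(apply_rules(generate_cohort(sp), config$rules),
                       sp$cohort_label)
    })
    trend <- do.call(rbind, lapply(c("NS", "NP", "NT"), function(st) {
      tr <- median_trend(sums, st)
      data.frame(statistic = st,
                 medians = paste(tr$medians, collapse = ","),
                 monotone = tr$monotone,
                 violation = if (is.null(tr$violation)) "" else
                   paste(tr$violation, collapse = "->"),
                 stringsAsFactors = FALSE)
    }))
    manifest$median_trend <- tsv(trend, "median_trend.tsv")
    box <- do.call(rbind, lapply(sums, function(s) {
      do.call(rbind, lapply(c("NS", "NP", "NT"), function(st) {
        bs <- s$boxplot[[st]]$stats
        data.frame(cohort = s$cohort_label, statistic = st,
                   whisker_lo = bs[1L], q1 = bs[2L], median = bs[3L],
                   q3 = bs[4L], whisker_hi = bs[5L],
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(box) <- NULL
    manifest$boxplot_stats <- tsv(box, "boxplot_stats.tsv")
  })

  stage("druggability", {
    ev <- evaluate_cohort(phase3_status_table())
    st <- data.frame(label = names(ev$counts), count = ev$counts,
                     pct = ev$pct, pct_printed = ev$pct_printed,
                     stringsAsFactors = FALSE)
    rownames(st) <- NULL
    manifest$status_evaluation <- tsv(st, "status_evaluation.tsv")
    # A: very similar in sequence to the established set (best hit);
    # D: obeys all three system-profile rules; B, C from the stub file
    clin_ids <- names(sim$best)
    fl <- data.frame(target_id = clin_ids,
                     phase = profs$phase[match(clin_ids, profs$target_id)],
                     A = sim$best <= config$thresholds$very_similar_max,
                     D = (profs$compliant_ns & profs$compliant_np &
                            profs$compliant_nt)[match(clin_ids,
                                                      profs$target_id)],
                     stringsAsFactors = FALSE)
    fl$B <- dat$flags$B[match(fl$target_id, dat$flags$target_id)]
    fl$C <- dat$flags$C[match(fl$target_id, dat$flags$target_id)]
    rates <- prediction_rates(fl)
    manifest$prediction_rates <- tsv(rates, "prediction_rates.tsv")
  })

  stage("network", {
    net <- build_network(dat$drugs, dat$targets[, "target_id", drop = FALSE],
                         dat$interactions)
    manifest$degree_drug <- tsv(degree_histogram(net, "drug"),
                                 "degree_histogram_drug.tsv")
    manifest$degree_target <- tsv(degree_histogram(net, "target"),
                                   "degree_histogram_target.tsv")
    manifest$popular_targets <- tsv(
      popular_nodes(net, "target", config$popular_min_degree),
      "popular_targets.tsv")
    manifest$multitarget_drugs <- tsv(multitarget_drugs(net),
                                       "multitarget_drugs.tsv")
    sub <- subnetwork_by_icd(net, config$icd_range)
    manifest$subnetwork_summary <- tsv(
      data.frame(icd_range = config$icd_range, drugs = nrow(sub$drugs),
                 targets = nrow(sub$targets),
                 interactions = nrow(sub$interactions)),
      "subnetwork_summary.tsv")
    ex <- export_network(net, out, basename = "network")
    for (nm in names(ex)) manifest[[paste0("network_", nm)]] <- ex[[nm]]
  })

  mp <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  manifest$manifest <- mp
  invisible(manifest)
}
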