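#' Specification of a synthetic target cohort
#'
#' A cohort is a set of targets whose three system-profile counts
#' (NS: similar proteins outside the family, NP: affiliated pathways,
#' NT: tissues of expression) are drawn i.i.d. from stated discrete
#' distributions.
#'
#' @param cohort_label One of `established`, `phase3`, `phase2`, `phase1`,
#'   `nonclinical`.
#' @param n_targets Number of targets (>= 1).
#' @param ns,np,nt Distribution specs from [dist_nbinom()], [dist_pois()]
#'   or [dist_point()].
#' @param seed Integer seed making the cohort reproducible.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(cohort_label, n_targets, ns, np, nt, seed = 1L) {
  cohort_label <- match.arg(cohort_label, cohort_labels())
  if (!is.numeric(n_targets) || length(n_targets) != 1L ||
      n_targets < 1 || n_targets != round(n_targets)) {
    stop("n_targets must be a positive integer", call. = FALSE)
  }
  for (d in list(ns, np, nt)) {
    if (!inherits(d, "count_dist")) {
      stop("ns/np/nt must be dist_nbinom(), dist_pois() or dist_point() specs",
           call. = FALSE)
    }
  }
  structure(list(cohort_label = cohort_label, n_targets = as.integer(n_targets),
                 ns = ns, np = np, nt = nt, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
cohort_labels <- function() {
  c("established", "phase3", "phase2", "phase1", "nonclinical")
}

#' Discrete count distributions for cohort specs
#'
#' Each constructor returns a spec with a sampler (`r`) and CDF (`p`).
#' `dist_nbinom()` is parameterized by mean and dispersion (`size`);
#' `dist_point()` is a point mass used for degenerate fixtures.
#'
#' @param mu,size Negative-binomial mean and dispersion (both > 0).
#' @return A `count_dist` object.
#' @export
dist_nbinom <- function(mu, size) {
  if (!is.finite(mu) || !is.finite(size) || mu <= 0 || size <= 0) {
    stop("nbinom requires mu > 0 and size > 0", call. = FALSE)
  }
  structure(list(name = "nbinom", mu = mu, size = size,
                 r = function(n) rnbinom(n, size = size, mu = mu),
                 p = function(q) pnbinom(q, size = size, mu = mu)),
            class = "count_dist")
}

#' @rdname dist_nbinom
#' @param lambda Poisson mean (> 0).
#' @export
dist_pois <- function(lambda) {
  if (!is.finite(lambda) || lambda <= 0) {
    stop("pois requires lambda > 0", call. = FALSE)
  }
  structure(list(name = "pois", lambda = lambda,
                 r = function(n) rpois(n, lambda),
                 p = function(q) stats::ppois(q, lambda)),
            class = "count_dist")
}

#' @rdname dist_nbinom
#' @param value Nonnegative integer at which the mass sits.
#' @export
dist_point <- function(value) {
  if (!is.finite(value) || value < 0 || value != round(value)) {
    stop("point mass must be a nonnegative integer", call. = FALSE)
  }
  structure(list(name = "point", value = value,
                 r = function(n) rep(as.integer(value), n),
                 p = function(q) as.numeric(q >= value)),
            class = "count_dist")
}

#' Generate a synthetic cohort of targets
#'
#' Draws `n_targets` records with NS/NP/NT sampled i.i.d. from the spec's
#' distributions; bit-reproducible under the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return A data frame with columns `target_id`, `cohort`, `NS`, `NP`,
#'   `NT`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_targets
    data.frame(
      target_id = sprintf("%s_T%04d", spec$cohort_label, seq_len(n)),
      cohort = spec$cohort_label,
      NS = as.integer(spec$ns$r(n)),
      NP = as.integer(spec$np$r(n)),
      NT = as.integer(spec$nt$r(n)),
      stringsAsFactors = FALSE
    )
  })
}

#' Default cohort presets
#'
#' Negative-binomial presets for the five development cohorts. The
#' parameters were calibrated so that (i) compliance rates at the
#' druggability thresholds (NS < 15, NP <= 3, NT <= 5) sit near the rates
#' reported for real kinase-target cohorts, and (ii) cohort medians of NS
#' and NT ascend from established through phase 3, 2 and 1, while NP
#' ascends with a dip at phase 1 -- the characteristic trend this package's
#' median-trend check is designed to detect.
#'
#' @param n_targets Targets per cohort.
#' @param seed Base seed; cohort i uses `seed + i`.
#' @return Named list of [cohort_spec()]s in the order established,
#'   phase3, phase2, phase1, nonclinical.
#' @export
cohort_presets <- function(n_targets = 2000L, seed = 20160728L) {
  par <- list(
    established = list(ns = c(8.0, 3), np = c(2.67, 4), nt = c(1.2, 6)),
    phase3      = list(ns = c(8.5, 3), np = c(3.0, 4),  nt = c(1.45, 6)),
    phase2      = list(ns = c(8.7, 3), np = c(4.0, 4),  nt = c(2.2, 6)),
    phase1      = list(ns = c(10.8, 3), np = c(2.05, 4), nt = c(2.7, 6)),
    nonclinical = list(ns = c(16.0, 3), np = c(5.0, 4),  nt = c(4.0, 6))
  )
  out <- lapply(seq_along(par), function(i) {
    p <- par[[i]]
    cohort_spec(names(par)[i], n_targets,
                ns = dist_nbinom(p$ns[1], p$ns[2]),
                np = dist_nbinom(p$np[1], p$np[2]),
                nt = dist_nbinom(p$nt[1], p$nt[2]),
                seed = seed + i)
  })
  names(out) <- names(par)
  out
}
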