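#' Simulation configuration for a cytokine time-course experiment
#'
#' Builds the configuration object consumed by [simulate_timecourse()]. The
#' defaults emulate an in vitro plasmablast-to-plasma-cell differentiation
#' experiment: three cytokine conditions (no IFN, IFN-alpha, IFN-gamma)
#' sampled at eight time points over four days in three donors, with five
#' planted coexpression modules:
#'
#' * `cell_cycle` (400 probes, monotone down) -- the proliferation programme
#'   shutting down as plasmablasts mature, shared by all conditions;
#' * `secretory` (300 probes, monotone up) -- the secretory/UPR programme
#'   ramping up late, shared;
#' * `late_step` (50 probes, late step) -- genes switching on only at the
#'   final maturation step, shared;
#' * `ifng_gradual` (300 probes, gradual up) -- an IFN-gamma-specific
#'   response, early change sustained and gradually increasing;
#' * `ifna_early` (250 probes, early pulse) -- an IFN-alpha-specific response
#'   peaking at the grid point nearest 6 h and sustained at 85% of peak.
#'
#' @param n_probes Number of probes on the synthetic platform.
#' @param timepoints Strictly increasing sampling times in hours.
#' @param conditions Subset of `"none"`, `"ifn_alpha"`, `"ifn_gamma"`.
#' @param n_donors Number of donors (biological replicates per time point).
#' @param modules Tibble describing planted modules with columns `name`,
#'   `size`, `kind` (one of `"monotone_up"`, `"monotone_down"`,
#'   `"early_pulse"`, `"gradual_up"`, `"late_step"`), `amplitude` (log2
#'   units, peak deviation from baseline) and `conditions` (list-column of
#'   condition names in which the module is active).
#' @param noise_sd Baseline per-measurement Gaussian noise SD in log2 units.
#' @param noise_sd_jitter Length-2 range of the log-uniform per-probe factor
#'   on `noise_sd`, emulating intensity-dependent measurement noise (probes
#'   genuinely differ in variance, as on real arrays).
#' @param donor_sd SD of the additive per-probe, per-donor offset
#'   (log2 units), shared by all of a donor's samples.
#' @param amplitude_jitter Length-2 range of the log-uniform per-probe
#'   multiplier applied to the module amplitude, so module members span a
#'   realistic (right-skewed) range of dynamic ranges with substantial mass
#'   near the detection limit.
#' @param detection_dropout_rate Baseline probability that a measurement is
#'   called undetected; the realized probability is higher for low-intensity
#'   probes (logistic link on the log2 mean).
#' @param seed Integer seed; a fixed seed makes the output byte-identical.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_timecourse()]
#' @export
simulation_config <- function(n_probes = 2000,
                              timepoints = c(0, 2, 4, 6, 12, 24, 48, 96),
                              conditions = c("none", "ifn_alpha", "ifn_gamma"),
                              n_donors = 3,
                              modules = default_modules(),
                              noise_sd = 0.5,
                              noise_sd_jitter = c(0.6, 1.6),
                              donor_sd = 0.3,
                              amplitude_jitter = c(0.45, 1.35),
                              detection_dropout_rate = 0.01,
                              seed = 1L) {
  stopifnot(is.numeric(n_probes), n_probes >= 1,
            is.numeric(timepoints), length(timepoints) >= 2,
            is.numeric(n_donors), n_donors >= 1,
            is.numeric(noise_sd), noise_sd >= 0,
            length(noise_sd_jitter) == 2, all(noise_sd_jitter > 0),
            is.numeric(donor_sd), donor_sd >= 0,
            length(amplitude_jitter) == 2, all(amplitude_jitter > 0),
            detection_dropout_rate >= 0, detection_dropout_rate < 1)
  if (any(diff(timepoints) <= 0)) {
    stop("`timepoints` must be strictly increasing", call. = FALSE)
  }
  known <- c("none", "ifn_alpha", "ifn_gamma")
  if (!all(conditions %in% known) || anyDuplicated(conditions)) {
    stop("`conditions` must be distinct values among ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  modules <- tibble::as_tibble(modules)
  req <- c("name", "size", "kind", "amplitude", "conditions")
  if (!all(req %in% names(modules))) {
    stop("`modules` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(modules)) {
    if (anyDuplicated(modules$name)) stop("module names must be unique", call. = FALSE)
    if (!all(modules$kind %in% names(profile_kinds()))) {
      stop("unknown profile kind; use one of ",
           paste(names(profile_kinds()), collapse = ", "), call. = FALSE)
    }
    if (any(modules$amplitude <= 0)) stop("amplitudes must be > 0", call. = FALSE)
    if (sum(modules$size) > n_probes) {
      stop("planted module sizes (", sum(modules$size),
           ") exceed n_probes (", n_probes, ")", call. = FALSE)
    }
  }
  structure(
    list(n_probes = as.integer(n_probes), timepoints = as.numeric(timepoints),
         conditions = conditions, n_donors = as.integer(n_donors),
         modules = modules, noise_sd = noise_sd,
         noise_sd_jitter = sort(noise_sd_jitter), donor_sd = donor_sd,
         amplitude_jitter = sort(amplitude_jitter),
         detection_dropout_rate = detection_dropout_rate,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Default planted-module table
#'
#' @return Tibble of the five default modules (see [simulation_config()]).
#' @export
default_modules <- function() {
  all3 <- list(c("none", "ifn_alpha", "ifn_gamma"))
  tibble::tibble(
    name = c("cell_cycle", "secretory", "late_step", "ifng_gradual", "ifna_early"),
    size = c(400L, 300L, 50L, 300L, 250L),
    kind = c("monotone_down", "monotone_up", "late_step", "gradual_up", "early_pulse"),
    amplitude = c(4.5, 4.5, 6, 3, 3),
    conditions = c(all3, all3, all3, list("ifn_gamma"), list("ifn_alpha")))
}

## Canonical unit profiles, defined on the default grid and interpolated in
## log-time for other grids. Transition windows are deliberately staggered so
## that co-occurring profiles stay distinguishable under absolute correlation
## raised to the soft-threshold power (unsigned network).
profile_kinds <- function() {
  grid <- c(0, 2, 4, 6, 12, 24, 48, 96)
  list(
    monotone_down = list(t = grid, v = c(1, 1, 1, 1, .9, .05, 0, 0)),
    monotone_up   = list(t = grid, v = c(0, 0, 0, 0, .05, .15, 1, 1)),
    late_step     = list(t = grid, v = c(0, 0, 0, 0, 0, 0, .1, 1)),
    gradual_up    = list(t = grid, v = c(0, .55, .61, .67, .74, .82, .90, 1)),
    early_pulse   = NULL)  # computed from the grid (peak nearest 6 h)
}

#' Unit temporal profile for a planted-module kind
#'
#' Profiles are scaled to `[0, 1]`; the module amplitude multiplies them.
#' The early pulse rises linearly from 0 h to the grid point nearest 6 h
#' and is sustained at 85% of peak afterwards.
#'
#' @param kind Profile kind (see [simulation_config()]).
#' @param timepoints Hours at which to evaluate the profile.
#' @return Numeric vector of the same length as `timepoints`.
#' @export
profile_shape <- function(kind, timepoints) {
  kinds <- profile_kinds()
  if (!kind %in% names(kinds)) stop("unknown profile kind: ", kind, call. = FALSE)
  if (kind == "early_pulse") {
    peak <- timepoints[which.min(abs(timepoints - 6))]
    if (peak <= 0) peak <- max(timepoints[timepoints > 0][1], 1)
    return(ifelse(timepoints <= peak, timepoints / peak, 0.85))
  }
  ref <- kinds[[kind]]
  stats::approx(log1p(ref$t), ref$v, xout = log1p(timepoints), rule = 2)$y
}

#' Simulate a cytokine-stimulation expression time course
#'
#' Generates a log2 probe-by-sample expression matrix with the statistical
#' structure the downstream network analysis assumes: planted modules share a
#' condition-dependent mean temporal profile (scaled per probe by an
#' amplitude multiplier), every probe carries an additive per-donor offset,
#' and background probes fluctuate around a constant baseline. A matching
#' detection p-value matrix marks measurements as undetected with a
#' probability that increases for low-intensity probes.
#'
#' Sample columns are named `<condition>_t<hours>_d<donor>` so that
#' [parse_sample_ids()] can recover the design from column names alone.
#'
#' @param config A [simulation_config()] object.
#' @return A list of class `sim_timecourse` with elements `exprs` (log2
#'   matrix), `detection` (detection p-values, same shape), `samples`
#'   (tibble: sample, condition, timepoint, donor), `truth` (tibble: probe,
#'   module, with `"background"` for unplanted probes), `profiles` (tibble of
#'   planted per-module, per-condition mean profiles in log2 units above
#'   baseline) and `config`.
#' @export
simulate_timecourse <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_probes
    probes <- sprintf("P%05d", seq_len(n))
    samples <- tidyr::expand_grid(
      condition = config$conditions,
      timepoint = config$timepoints,
      donor = seq_len(config$n_donors))
    samples$sample <- sprintf("%s_t%03d_d%d", samples$condition,
                              round(samples$timepoint), samples$donor)
    samples <- samples[, c("sample", "condition", "timepoint", "donor")]

    truth <- rep("background", n)
    at <- 1L
    for (m in seq_len(nrow(config$modules))) {
      sz <- config$modules$size[m]
      truth[at:(at + sz - 1L)] <- config$modules$name[m]
      at <- at + sz
    }

    base <- stats::runif(n, 6, 12)
    ampj <- exp(stats::runif(n, log(config$amplitude_jitter[1]),
                             log(config$amplitude_jitter[2])))
    donor_off <- matrix(stats::rnorm(n * config$n_donors, 0, config$donor_sd),
                        n, config$n_donors)

    shape_of <- lapply(seq_len(nrow(config$modules)), function(m)
      profile_shape(config$modules$kind[m], config$timepoints))

    mu <- matrix(base, n, nrow(samples))
    for (m in seq_len(nrow(config$modules))) {
      idx <- which(truth == config$modules$name[m])
      active <- samples$condition %in% config$modules$conditions[[m]]
      sh <- shape_of[[m]][match(samples$timepoint, config$timepoints)]
      contrib <- outer(config$modules$amplitude[m] * ampj[idx], sh * active)
      mu[idx, ] <- mu[idx, ] + contrib
    }
    noise_scale <- config$noise_sd *
      exp(stats::runif(n, log(config$noise_sd_jitter[1]),
                       log(config$noise_sd_jitter[2])))
    x <- mu + donor_off[, samples$donor] +
      matrix(stats::rnorm(n * nrow(samples), 0, rep(noise_scale, nrow(samples))),
             n, nrow(samples))
    dimnames(x) <- list(probes, samples$sample)

    ## detection dropout: logistic in the underlying mean intensity
    p_undet <- stats::plogis(stats::qlogis(max(config$detection_dropout_rate, 1e-8)) +
                               0.5 * (stats::median(mu) - mu))
    undet <- matrix(stats::runif(length(mu)) < p_undet, n, nrow(samples))
    detection <- matrix(stats::runif(length(mu), 0, 0.049), n, nrow(samples))
    detection[undet] <- stats::runif(sum(undet), 0.051, 1)
    dimnames(detection) <- dimnames(x)

    profiles <- tidyr::expand_grid(
      module = config$modules$name,
      condition = config$conditions,
      timepoint = config$timepoints)
    if (nrow(profiles)) {
      profiles$mean <- unlist(lapply(seq_len(nrow(config$modules)), function(m) {
        sapply(config$conditions, function(cc) {
          if (cc %in% config$modules$conditions[[m]])
            config$modules$amplitude[m] * shape_of[[m]]
          else rep(0, length(config$timepoints))
        })
      }))
    } else profiles$mean <- numeric(0)

    structure(
      list(exprs = x, detection = detection,
           samples = samples,
           truth = tibble::tibble(probe = probes, module = truth),
           profiles = profiles, config = config),
      class = "sim_timecourse")
  })
}

#' @export
print.sim_timecourse <- function(x, ...) {
  cat("Simulated expression time course:", nrow(x$exprs), "probes x",
      ncol(x$exprs), "samples\n")
  cat("  conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  cat("  timepoints (h):", paste(unique(x$samples$timepoint), collapse = ", "), "\n")
  cat("  donors:", max(x$samples$donor), "\n")
  cat("  planted modules:",
      paste(setdiff(unique(x$truth$module), "background"), collapse = ", "), "\n")
  invisible(x)
}

#' Parse condition/timepoint/donor sample annotations from column names
#'
#' Sample identifiers follow `<condition>_t<hours>_d<donor>`, e.g.
#' `ifn_alpha_t006_d2`.
#'
#' @param ids Character vector of sample identifiers (or a matrix whose
#'   column names should be parsed).
#' @return Tibble with columns `sample`, `condition`, `timepoint`, `donor`.
#' @export
parse_sample_ids <- function(ids) {
  if (is.matrix(ids)) ids <- colnames(ids)
  m <- regmatches(ids, regexec("^(.*)_t([0-9]+)_d([0-9]+)$", ids))
  bad <- lengths(m) != 4
  if (any(bad)) {
    stop("sample ids not in <condition>_t<hours>_d<donor> form: ",
         paste(utils::head(ids[bad], 3), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(sample = ids,
                 condition = vapply(m, `[`, "", 2),
                 timepoint = as.numeric(vapply(m, `[`, "", 3)),
                 donor = as.integer(vapply(m, `[`, "", 4)))
}

#' Simulate a signature collection from planted ground truth
#'
#' Builds one signature per planted module containing a stated fraction of
#' the module's probes plus unrelated decoys, together with a number of
#' purely random signatures drawn uniformly from the probe universe. The
#' collection stands in for merged public gene-signature databases when
#' exercising the enrichment stage.
#'
#' @param truth Tibble `probe`/`module` as produced by
#'   [simulate_timecourse()] (`$truth`).
#' @param n_random Number of random signatures.
#' @param seed Integer seed.
#' @param fraction Fraction of each module's probes included in its signature.
#' @param decoy_fraction Decoys added per planted signature, as a fraction of
#'   its true-member count.
#' @param random_size Length-2 range of random-signature sizes.
#' @return Tibble with columns `set`, `gene`, `source`
#'   (`"planted"`/`"random"`).
#' @export
simulate_signatures <- function(truth, n_random = 50, seed = 1L,
                                fraction = 0.8, decoy_fraction = 0.25,
                                random_size = c(20, 200)) {
  stopifnot(nrow(truth) > 0, fraction > 0, fraction <= 1, n_random >= 0)
  withr::with_seed(seed, {
    universe <- truth$probe
    mods <- setdiff(unique(truth$module), "background")
    planted <- purrr::map_dfr(mods, function(m) {
      members <- truth$probe[truth$module == m]
      keep <- sample(members, round(fraction * length(members)))
      n_decoy <- round(decoy_fraction * length(keep))
      decoys <- sample(setdiff(universe, members), n_decoy)
      tibble::tibble(set = paste0("SIG_", m), gene = c(keep, decoys),
                     source = "planted")
    })
    size_choices <- seq(random_size[1], random_size[2])
    random <- purrr::map_dfr(seq_len(n_random), function(i) {
      sz <- if (length(size_choices) == 1) size_choices else sample(size_choices, 1)
      tibble::tibble(set = sprintf("RANDOM_%03d", i),
                     gene = sample(universe, sz), source = "random")
    })
    dplyr::bind_rows(planted, random)
  })
}

#' Simulate a toy ontology and leaf-level annotations
#'
#' Builds a rooted is_a DAG with one branch of `depth` terms per planted
#' module; annotations are placed only at the leaf terms so that ancestor
#' propagation is genuinely exercised downstream. With probability
#' `extra_parent_prob` a term below the root gains a second parent from
#' another branch (relation `part_of`), making the graph a DAG rather than a
#' tree.
#'
#' @param truth Tibble `probe`/`module` (see [simulate_timecourse()]).
#' @param depth Number of terms between root and leaf inclusive of the leaf
#'   (`depth = 1` gives a star: root plus one leaf per module).
#' @param seed Integer seed.
#' @param extra_parent_prob Probability of adding a second (cross-branch)
#'   parent to a non-root term.
#' @return List with `ontology` (list of `terms` and `edges` tibbles; edges
#'   are child -> parent with a `relation` column) and `annotations`
#'   (tibble `gene`/`term`, leaf terms only).
#' @export
simulate_ontology <- function(truth, depth = 3, seed = 1L,
                              extra_parent_prob = 0.25) {
  stopifnot(depth >= 1)
  withr::with_seed(seed, {
    mods <- setdiff(unique(truth$module), "background")
    root <- "T:0000000"
    terms <- tibble::tibble(id = root, name = "root")
    edges <- tibble::tibble(child = character(), parent = character(),
                            relation = character())
    ann <- tibble::tibble(gene = character(), term = character())
    for (mi in seq_along(mods)) {
      chain <- sprintf("T:%03d%04d", mi, seq_len(depth))
      terms <- dplyr::bind_rows(terms, tibble::tibble(
        id = chain,
        name = paste0(mods[mi], "_level", seq_len(depth))))
      parents <- c(root, chain[-depth])
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        child = chain, parent = parents, relation = "is_a"))
      leaf <- chain[depth]
      members <- truth$probe[truth$module == mods[mi]]
      ann <- dplyr::bind_rows(ann, tibble::tibble(gene = members, term = leaf))
    }
    ## optional second parents across branches (kept acyclic by only linking
    ## to strictly shallower levels of other branches)
    if (depth >= 2 && length(mods) >= 2) {
      for (mi in seq_along(mods)) {
        for (lv in 2:depth) {
          if (stats::runif(1) < extra_parent_prob) {
            other <- sample(setdiff(seq_along(mods), mi), 1)
            up <- sample(seq_len(lv - 1), 1)
            edges <- dplyr::bind_rows(edges, tibble::tibble(
              child = sprintf("T:%03d%04d", mi, lv),
              parent = sprintf("T:%03d%04d", other, up),
              relation = "part_of"))
          }
        }
      }
    }
    list(ontology = list(terms = terms, edges = edges), annotations = ann)
  })
}
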