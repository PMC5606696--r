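# Seeded generators for every input the pipeline consumes: noisy
# rate-vs-concentration observations, multinomial ppk1 clone libraries drawn
# from known clade compositions, and weekly reactor cycle records following a
# logistic enrichment curve. All generators are deterministic under the spec
# seed and never disturb the caller's RNG state.

with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specification of a synthetic study
#'
#' Fixes the ground truth and noise structure for all synthetic generators.
#' Defaults emulate the five-run enrichment study: aerobic phosphate held at
#' 0.05/0.5/5/50/500 mg P L^-1 (Runs 1-5), 9 h aerobic / 3 h anaerobic
#' cycles at 3.24 L d^-1 over a 6 cm^3 sponge, 70 mL anaerobic batches of
#' 200 mg COD L^-1, clone libraries of 13-24 clones, and phosphate-removal
#' activity rising along a logistic enrichment curve that plateaus by day 85.
#'
#' @param seed Integer master seed; every generator derives its stream from
#'   it deterministically.
#' @param kinetics_truth List of [kinetic_params] used as ground truth for
#'   rate observations (default [default_accumulibacter_params()]).
#' @param noise_sd Relative (multiplicative Gaussian) noise on rates.
#' @param composition_truth Named list, one clade-probability vector per run.
#' @param clones_per_run Integer clone-library sizes, one per run.
#' @param mutation_rate Per-base substitution rate of clones away from their
#'   clade reference, in [0, 0.05).
#' @param run_p Aerobic phosphate concentration per run, mg P L^-1.
#' @param plateau_removal Aerobic phosphate removal (influent minus effluent)
#'   reached at plateau, mg P L^-1, one per run.
#' @param cod_fraction_remaining Fraction of anaerobic COD remaining at
#'   plateau, one per run.
#' @param enrichment_lag_days,enrichment_rate Logistic enrichment curve:
#'   midpoint (days) and steepness (d^-1).
#' @param release_uptake_ratio Stoichiometric ratio of anaerobic P release to
#'   aerobic P uptake at steady state (1 = balanced cycling).
#' @param measurement_noise_sd Relative noise on generated concentrations.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1,
                       kinetics_truth = default_accumulibacter_params(),
                       noise_sd = 0.01,
                       composition_truth = list(
                         "Run 1" = c(IA = 8 / 13, IIA = 3 / 13, IIB = 2 / 13),
                         "Run 2" = c(IA = 0.20, IIA = 0.45, IIB = 0.35),
                         "Run 3" = c(IIB = 20 / 24, IIC = 2 / 24,
                                     IID = 2 / 24),
                         "Run 4" = c(IA = 0.85, IIB = 0.15),
                         "Run 5" = c(IA = 1.0)
                       ),
                       clones_per_run = c(13L, 20L, 24L, 18L, 15L),
                       mutation_rate = 0.005,
                       run_p = c(0.05, 0.5, 5, 50, 500),
                       plateau_removal = c(0.02, 0.08, 0.32, 1.2, 0),
                       cod_fraction_remaining = c(0.60, 0.35, 0.02, 0.02,
                                                  0.02),
                       enrichment_lag_days = 40,
                       enrichment_rate = 0.15,
                       release_uptake_ratio = 1,
                       measurement_noise_sd = 0.05) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  for (p in composition_truth) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop("each composition_truth vector must be a probability vector",
           call. = FALSE)
    }
  }
  if (mutation_rate < 0 || mutation_rate >= 0.05) {
    stop("'mutation_rate' must be in [0, 0.05)", call. = FALSE)
  }
  if (noise_sd < 0 || measurement_noise_sd < 0) {
    stop("noise standard deviations must be >= 0", call. = FALSE)
  }
  nruns <- length(run_p)
  stopifnot(length(composition_truth) == nruns,
            length(clones_per_run) == nruns,
            length(plateau_removal) == nruns,
            length(cod_fraction_remaining) == nruns)
  structure(
    list(seed = as.integer(seed), kinetics_truth = kinetics_truth,
         noise_sd = noise_sd, composition_truth = composition_truth,
         clones_per_run = as.integer(clones_per_run),
         mutation_rate = mutation_rate, run_p = run_p,
         plateau_removal = plateau_removal,
         cod_fraction_remaining = cod_fraction_remaining,
         enrichment_lag_days = enrichment_lag_days,
         enrichment_rate = enrichment_rate,
         release_uptake_ratio = release_uptake_ratio,
         measurement_noise_sd = measurement_noise_sd,
         run_ids = names(composition_truth)),
    class = "synth_spec"
  )
}

#' Noisy rate-vs-concentration observations
#'
#' For each ground-truth population, draws `n` observations at log-spaced
#' concentrations in `s_range` with multiplicative Gaussian noise:
#' `rate = nu_truth(s) * (1 + eps)`, `eps ~ N(0, noise_sd)`. Multiplicative
#' noise is used because rates span orders of magnitude over the
#' concentration range.
#'
#' @param spec A [synth_spec].
#' @param n Observations per population (default 50).
#' @param s_range Concentration range, mg P L^-1 (default the study's
#'   0.05-500).
#' @return A `data.frame` with columns `label`, `s`, `rate`.
#' @export
gen_rate_observations <- function(spec, n = 50, s_range = c(0.05, 500)) {
  stopifnot(inherits(spec, "synth_spec"))
  s <- exp(seq(log(s_range[1]), log(s_range[2]), length.out = n))
  with_local_seed(spec$seed + 11L, {
    do.call(rbind, lapply(spec$kinetics_truth, function(p) {
      eps <- stats::rnorm(n, 0, spec$noise_sd)
      data.frame(label = p$label, s = s,
                 rate = pmax(specific_rate(p, s) * (1 + eps), 0),
                 stringsAsFactors = FALSE)
    }))
  })
}

# mutate a reference sequence by iid substitution at the given per-base rate
mutate_sequence <- function(seq, rate) {
  bases <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(bases)) < rate)
  for (i in hit) {
    bases[i] <- sample(setdiff(c("A", "C", "G", "T"), bases[i]), 1L)
  }
  paste(bases, collapse = "")
}

#' Synthetic ppk1-like clade reference panel
#'
#' Builds a labelled reference panel of synthetic 300-nt sequences with the
#' discrimination structure real ppk1 clade references show: clades within a
#' type at roughly 85-92% pairwise identity, clades across the Type I / II
#' split at roughly 75-85%. Sequences are simulated (type ancestors diverged
#' by ~11% substitution, clades by a further ~5.5% each); they carry no real
#' biological information beyond that distance structure.
#'
#' @param clades Clade labels to generate (default the clades observed in
#'   the enrichments: IA, IB, IIA, IIB, IIC, IID).
#' @param length Sequence length, nt.
#' @param seed Seed (default 74, the seed used for the shipped fixture
#'   `inst/extdata/ppk1_clade_panel_synthetic.fasta`).
#' @return A [clade_panel].
#' @export
make_clade_panel <- function(clades = c("IA", "IB", "IIA", "IIB", "IIC",
                                        "IID"),
                             length = 300, seed = 74) {
  with_local_seed(seed, {
    root <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                  collapse = "")
    anc <- list(I = root, II = mutate_sequence(root, 0.11))
    seqs <- vapply(clades, function(cl) {
      type <- if (startsWith(cl, "II")) "II" else "I"
      mutate_sequence(anc[[type]], 0.055)
    }, character(1))
    clade_panel(clades, seqs)
  })
}

#' Synthetic clone library with known clade truth
#'
#' Clade counts are drawn `Multinomial(clones_per_run, composition_truth)`;
#' each clone is its clade's panel reference with i.i.d. substitutions at
#' `mutation_rate`. The generating truth is returned alongside the library so
#' downstream assignment can be scored exactly.
#'
#' @param spec A [synth_spec].
#' @param run Run index (1-based) or run id.
#' @param panel A [clade_panel] containing every clade with positive
#'   probability.
#' @return A list: `library` ([clone_library]), `truth` (named character,
#'   clade per clone), `counts` (named integer, the multinomial draw).
#' @export
gen_clone_library <- function(spec, run, panel) {
  stopifnot(inherits(spec, "synth_spec"))
  if (is.character(run)) run <- match(run, spec$run_ids)
  if (is.na(run) || run < 1 || run > length(spec$run_ids)) {
    stop("unknown run", call. = FALSE)
  }
  probs <- spec$composition_truth[[run]]
  missing_ref <- setdiff(names(probs)[probs > 0], panel$clade)
  if (length(missing_ref)) {
    stop("no panel reference for clade(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  n <- spec$clones_per_run[run]
  run_id <- spec$run_ids[run]
  with_local_seed(spec$seed + 1000L * run, {
    counts <- as.integer(stats::rmultinom(1, n, probs))
    names(counts) <- names(probs)
    clades <- rep(names(counts), counts)
    seqs <- vapply(clades, function(cl) {
      ref <- panel$sequence[panel$clade == cl]
      mutate_sequence(ref, spec$mutation_rate)
    }, character(1), USE.NAMES = FALSE)
    ids <- sprintf("%s_clone%02d", gsub(" ", "", run_id), seq_along(seqs))
    names(seqs) <- ids
    truth <- stats::setNames(clades, ids)
    list(library = clone_library(run_id, seqs), truth = truth,
         counts = counts[counts > 0])
  })
}

#' Synthetic weekly reactor cycle records
#'
#' Emulates the weekly monitoring of one enrichment run: aerobic phosphate
#' removal rises along a logistic enrichment curve
#' `removal(day) = plateau / (1 + exp(-rate * (day - lag)))`, anaerobic
#' release tracks uptake through `release_uptake_ratio` (balanced phosphate
#' cycling at plateau), and anaerobic COD consumption follows the same
#' enrichment curve toward the run's plateau fraction remaining.
#' Multiplicative measurement noise is applied to removal, release and COD.
#'
#' @param spec A [synth_spec].
#' @param run Run index (1-based) or run id.
#' @param n_days Horizon, days (default 85).
#' @param sampling_interval_days Days between samples (default 7).
#' @return A [cycle_records] data.frame, one row per sampling day.
#' @export
gen_reactor_timeseries <- function(spec, run, n_days = 85,
                                   sampling_interval_days = 7) {
  stopifnot(inherits(spec, "synth_spec"))
  if (is.character(run)) run <- match(run, spec$run_ids)
  if (is.na(run) || run < 1 || run > length(spec$run_ids)) {
    stop("unknown run", call. = FALSE)
  }
  if (n_days < sampling_interval_days) {
    stop("'n_days' must cover at least one sampling interval", call. = FALSE)
  }
  days <- seq(sampling_interval_days, n_days, by = sampling_interval_days)
  influent <- spec$run_p[run]
  run_id <- spec$run_ids[run]
  logistic <- 1 / (1 + exp(-spec$enrichment_rate *
                             (days - spec$enrichment_lag_days)))
  flow <- 3.24; aerobic_h <- 9; fill <- 0.070
  retained <- 0.006  # sponge holds ~its own volume (6 cm^3) of liquid
  with_local_seed(spec$seed + 100L * run + 7L, {
    sdm <- spec$measurement_noise_sd
    removal <- spec$plateau_removal[run] * logistic *
      (1 + stats::rnorm(length(days), 0, sdm))
    removal <- pmin(pmax(removal, 0), influent)
    effluent <- influent - removal
    uptake_mass <- flow * (aerobic_h / 24) * removal
    release_mass <- spec$release_uptake_ratio * uptake_mass *
      (1 + stats::rnorm(length(days), 0, sdm))
    release_mass <- pmax(release_mass, 0)
    end_p <- (release_mass + retained * effluent) / fill
    cod_in <- 200
    frac_rem <- spec$cod_fraction_remaining[run]
    end_cod <- cod_in * (1 - (1 - frac_rem) * logistic) *
      (1 + stats::rnorm(length(days), 0, sdm))
    end_cod <- pmin(pmax(end_cod, 0), cod_in)
    cycle_records(
      run_id = run_id, day = days,
      aerobic_influent_p = influent, aerobic_effluent_p = effluent,
      aerobic_flow = flow, aerobic_hours = aerobic_h, anaerobic_hours = 3,
      anaerobic_fill_volume = fill, anaerobic_end_p = end_p,
      retained_liquid_volume = retained,
      anaerobic_influent_cod = cod_in, anaerobic_end_cod = end_cod,
      sponge_volume = 6
    )
  })
}
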