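# Readers and writers for the plain-text interchange formats: kinetic
# parameter CSV (label,vmax,km,ki), cycle-record CSV, FASTA clone libraries
# and clade panels (clade parsed from a `clade=XX` tag on the description
# line), plus the single-call model report used by the analysis scripts.

#' Read kinetic parameters from CSV
#'
#' Expects a header `label,vmax,km,ki`. Malformed rows are reported with
#' their line numbers; duplicate labels are an error.
#'
#' @param path CSV file path.
#' @return A list of [kinetic_params].
#' @export
read_params_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("label", "vmax", "km", "ki")
  if (!all(need %in% names(df))) {
    stop("parameter CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  if (nrow(df) == 0L) stop("parameter CSV has no rows", call. = FALSE)
  num <- lapply(df[c("vmax", "km", "ki")],
                function(x) suppressWarnings(as.numeric(x)))
  bad <- which(Reduce(`|`, lapply(num, is.na)))
  if (length(bad)) {
    stop("non-numeric parameter value(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)  # +1 for header
  }
  if (anyDuplicated(df$label)) {
    stop("duplicate labels in ", path, call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    kinetic_params(df$label[i], num$vmax[i], num$km[i], num$ki[i])
  })
}

#' Write kinetic parameters to CSV
#'
#' @param params_set List of [kinetic_params].
#' @param path Output path.
#' @return `path`, invisibly. Round-trips through [read_params_csv].
#' @export
write_params_csv <- function(params_set, path) {
  params_set <- check_params_set(params_set)
  df <- data.frame(
    label = vapply(params_set, `[[`, character(1), "label"),
    vmax = vapply(params_set, `[[`, numeric(1), "vmax"),
    km = vapply(params_set, `[[`, numeric(1), "km"),
    ki = vapply(params_set, `[[`, numeric(1), "ki")
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read reactor cycle records from CSV
#'
#' @param path CSV with the [cycle_records] columns.
#' @return A validated [cycle_records] data.frame.
#' @export
read_cycle_records_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cycle_records(df)
}

#' Write reactor cycle records to CSV
#'
#' @param records A [cycle_records] data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cycle_records_csv <- function(records, path) {
  records <- validate_cycle_records(records)
  utils::write.csv(as.data.frame(records)[cycle_record_cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a clone library from FASTA
#'
#' @param path FASTA file of clone sequences.
#' @param run_id Run identifier (default: file name without extension).
#' @return A [clone_library].
#' @export
read_fasta_library <- function(path, run_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  if (is.null(run_id)) run_id <- sub("\\.[^.]*$", "", basename(path))
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  clone_library(run_id, stats::setNames(as.character(ss), ids))
}

#' Write a clone library to FASTA
#'
#' @param library A [clone_library].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_library <- function(library, path) {
  stopifnot(inherits(library, "clone_library"))
  ss <- Biostrings::DNAStringSet(library$sequences)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read a clade reference panel from FASTA
#'
#' Each record's description line must carry a `clade=XX` tag, e.g.
#' `>ref_IIB clade=IIB`.
#'
#' @param path FASTA file path. Defaults to the synthetic panel shipped with
#'   the package.
#' @return A [clade_panel].
#' @export
read_clade_panel <- function(path = system.file(
  "extdata", "ppk1_clade_panel_synthetic.fasta", package = "paokin")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("no such file: ", path, call. = FALSE)
  }
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  m <- regmatches(names(ss), regexpr("clade=[A-Za-z-]+", names(ss)))
  if (length(m) != length(ss)) {
    stop("every panel record needs a 'clade=' tag in its description",
         call. = FALSE)
  }
  clade_panel(sub("^clade=", "", m), as.character(ss))
}

#' Write a clade reference panel to FASTA
#'
#' @param panel A [clade_panel].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clade_panel <- function(panel, path) {
  stopifnot(inherits(panel, "clade_panel"))
  ss <- Biostrings::DNAStringSet(panel$sequence)
  names(ss) <- sprintf("ref_%s clade=%s", panel$clade, panel$clade)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Enrichment-run manifest
#'
#' The run layout of the five-reactor study: aerobic phosphate held at
#' strictly increasing concentrations with a fixed anaerobic COD feed.
#'
#' @param run_ids Run labels.
#' @param aerobic_p Aerobic phosphate concentrations, mg P L^-1, strictly
#'   increasing and positive.
#' @param anaerobic_cod Anaerobic substrate, mg COD L^-1.
#' @return A `data.frame` of class `run_manifest`.
#' @export
run_manifest <- function(run_ids = paste("Run", 1:5),
                         aerobic_p = c(0.05, 0.5, 5, 50, 500),
                         anaerobic_cod = 200) {
  if (any(aerobic_p <= 0) ||
      (length(aerobic_p) > 1 && any(diff(aerobic_p) <= 0))) {
    stop("'aerobic_p' must be positive and strictly increasing",
         call. = FALSE)
  }
  if (length(run_ids) != length(aerobic_p)) {
    stop("one run id per concentration", call. = FALSE)
  }
  df <- data.frame(run_id = run_ids, aerobic_p = aerobic_p,
                   anaerobic_cod = anaerobic_cod, stringsAsFactors = FALSE)
  class(df) <- c("run_manifest", "data.frame")
  df
}

#' One-call dominance model report
#'
#' Runs the whole kinetic argument in one deterministic call: rate curves for
#' all populations over a log grid, the predicted dominant type at each
#' run's held concentration, pairwise crossover concentrations, and a
#' competition trajectory per run.
#'
#' @param params_set List of [kinetic_params].
#' @param manifest A [run_manifest].
#' @param grid_range Concentration range for the rate curve, mg P L^-1.
#' @param grid_n Number of log-spaced grid points.
#' @param n_cycles Cycles for the per-run competition simulations.
#' @param tie_tol Passed to [dominant_label].
#' @return A list: `curve` (rate_curve data.frame), `dominance` (data.frame
#'   run_id, s, dominant), `crossovers` (numeric, empty when fewer than two
#'   populations or no root), `trajectories` (named list of
#'   competition trajectories).
#' @export
reproduce_model_report <- function(params_set, manifest = run_manifest(),
                                   grid_range = c(0.01, 1000),
                                   grid_n = 200, n_cycles = 200,
                                   tie_tol = 1e-3) {
  params_set <- check_params_set(params_set)
  grid <- exp(seq(log(grid_range[1]), log(grid_range[2]),
                  length.out = grid_n))
  curve <- rate_curve(params_set, grid)
  dominance <- data.frame(
    run_id = manifest$run_id, s = manifest$aerobic_p,
    dominant = if (length(params_set) >= 2L) {
      vapply(manifest$aerobic_p, function(s)
        dominant_label(params_set, s, tie_tol = tie_tol), character(1))
    } else {
      rep(params_set[[1]]$label, nrow(manifest))
    },
    stringsAsFactors = FALSE
  )
  crossovers <- if (length(params_set) == 2L) {
    as.numeric(crossover_concentrations(params_set,
                                        s_range = pmax(grid_range, 1e-4)))
  } else numeric(0)
  trajectories <- stats::setNames(lapply(manifest$aerobic_p, function(s) {
    simulate_competition(params_set, reactor_config(aerobic_s = s),
                         n_cycles = n_cycles)
  }), manifest$run_id)
  list(curve = curve, dominance = dominance, crossovers = crossovers,
       trajectories = trajectories)
}
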