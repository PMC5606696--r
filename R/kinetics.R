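# Substrate-inhibition (Haldane) kinetics for Accumulibacter competition:
#   nu(S) = Vmax * S / ((Km + S) * (1 + S/Ki))
# S and Km, Ki in mg P L^-1; Vmax (and nu) per unit time (the time unit is
# carried as opaque T^-1 throughout).

#' Kinetic parameters for one population
#'
#' Bundles the three Haldane parameters of one population's specific
#' substrate-utilization rate curve: the maximum rate `vmax` (per unit time),
#' the half-saturation constant `km` and the inhibition constant `ki`
#' (both mg P L^-1).
#'
#' @param label Population identifier, e.g. `"Type I"`. Must be non-empty.
#' @param vmax Maximum specific substrate-utilization rate, > 0.
#' @param km Half-saturation constant, mg P L^-1, > 0.
#' @param ki Inhibition constant, mg P L^-1, > 0. Large `ki` recovers plain
#'   Michaelis-Menten kinetics.
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params("Type II", vmax = 1.0, km = 0.5, ki = 300)
#' @export
kinetic_params <- function(label, vmax, km, ki) {
  if (!is.character(label) || length(label) != 1L || is.na(label) ||
      !nzchar(label)) {
    stop("'label' must be a single non-empty string", call. = FALSE)
  }
  for (nm in c("vmax", "km", "ki")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("'%s' must be a single finite positive number", nm),
           call. = FALSE)
    }
  }
  structure(
    list(label = label, vmax = as.numeric(vmax), km = as.numeric(km),
         ki = as.numeric(ki)),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf("<kinetic_params> %s: Vmax = %g T^-1, Km = %g, Ki = %g mg P/L\n",
              x$label, x$vmax, x$km, x$ki))
  invisible(x)
}

#' @export
format.kinetic_params <- function(x, ...) {
  sprintf("%s (Vmax=%g, Km=%g, Ki=%g)", x$label, x$vmax, x$km, x$ki)
}

is_kinetic_params <- function(x) inherits(x, "kinetic_params")

# validate a list of kinetic_params; unique_labels = FALSE for operations
# whose degenerate cases (ties, identical curves) are meaningful
check_params_set <- function(params_set, unique_labels = TRUE) {
  if (is_kinetic_params(params_set)) params_set <- list(params_set)
  if (!is.list(params_set) || length(params_set) == 0L ||
      !all(vapply(params_set, is_kinetic_params, logical(1)))) {
    stop("expected a non-empty list of 'kinetic_params' objects",
         call. = FALSE)
  }
  labels <- vapply(params_set, `[[`, character(1), "label")
  if (unique_labels && anyDuplicated(labels)) {
    stop("duplicate population labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  params_set
}

#' Published assumed kinetic parameters for Accumulibacter Types I and II
#'
#' The parameter pair used throughout the dominance analysis: Type I
#' (Vmax 0.95, Km 0.48, Ki 2000) and Type II (Vmax 1.0, Km 0.5, Ki 300).
#' Type II has the slightly higher maximum rate and similar affinity but is
#' far more strongly inhibited by high phosphate, so it wins at low S and
#' loses above the crossover concentration.
#'
#' @return A list of two `kinetic_params` objects, Types I and II.
#' @examples
#' crossover_concentrations(default_accumulibacter_params())
#' @export
default_accumulibacter_params <- function() {
  list(
    kinetic_params("Type I", vmax = 0.95, km = 0.48, ki = 2000),
    kinetic_params("Type II", vmax = 1.0, km = 0.5, ki = 300)
  )
}

#' Specific substrate-utilization rate under substrate inhibition
#'
#' Evaluates the Haldane rate law
#' \deqn{\nu(S) = \frac{V_{max} S}{(K_m + S)(1 + S/K_i)}}
#' at phosphate concentration(s) `s`. The curve rises to a single maximum at
#' \eqn{S = \sqrt{K_m K_i}} and declines beyond it; as \eqn{K_i \to \infty}
#' it reduces to Michaelis-Menten.
#'
#' @param params A [kinetic_params] object.
#' @param s Phosphate concentration(s), mg P L^-1, all >= 0. Vectorized.
#' @return Numeric vector of rates (same length as `s`), per unit time.
#' @examples
#' p2 <- kinetic_params("Type II", 1.0, 0.5, 300)
#' specific_rate(p2, 0.5)   # ~0.4992
#' @export
specific_rate <- function(params, s) {
  if (!is_kinetic_params(params)) {
    stop("'params' must be a 'kinetic_params' object", call. = FALSE)
  }
  if (!is.numeric(s) || any(!is.finite(s))) {
    stop("'s' must be finite numeric", call. = FALSE)
  }
  if (any(s < 0)) stop("negative substrate concentration", call. = FALSE)
  params$vmax * s / ((params$km + s) * (1 + s / params$ki))
}

#' Concentration of maximal rate
#'
#' The unique maximizer of the substrate-inhibition rate curve,
#' \eqn{S^* = \sqrt{K_m K_i}} (mg P L^-1).
#'
#' @inheritParams specific_rate
#' @return The peak concentration, mg P L^-1.
#' @examples
#' peak_concentration(kinetic_params("Type II", 1.0, 0.5, 300))  # ~12.25
#' @export
peak_concentration <- function(params) {
  if (!is_kinetic_params(params)) {
    stop("'params' must be a 'kinetic_params' object", call. = FALSE)
  }
  sqrt(params$km * params$ki)
}

#' Rate curves for a set of populations on a concentration grid
#'
#' @param params_set List of [kinetic_params] with unique labels.
#' @param grid Strictly increasing non-negative concentrations, mg P L^-1.
#' @return A `data.frame` with column `s` and one rate column per population
#'   label, of class `rate_curve`.
#' @examples
#' rate_curve(default_accumulibacter_params(), grid = c(0.5, 5, 50))
#' @export
rate_curve <- function(params_set, grid) {
  params_set <- check_params_set(params_set)
  if (!is.numeric(grid) || length(grid) == 0L) {
    stop("'grid' must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(grid < 0)) stop("grid concentrations must be >= 0", call. = FALSE)
  if (length(grid) > 1L && any(diff(grid) <= 0)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  out <- data.frame(s = grid)
  for (p in params_set) out[[p$label]] <- specific_rate(p, grid)
  class(out) <- c("rate_curve", "data.frame")
  out
}

#' Which population dominates at a given concentration
#'
#' The population with the highest specific substrate-utilization rate at
#' concentration `s` is expected to outgrow the others and dominate the
#' enrichment. When the top two rates differ by less than `tie_tol`
#' relatively, the call is `"tie"` (at very low phosphate the two
#' Accumulibacter types have near-identical affinities and no call is
#' meaningful).
#'
#' @inheritParams rate_curve
#' @param s Single concentration, mg P L^-1, >= 0.
#' @param tie_tol Relative tolerance for declaring a tie between the top two
#'   rates (default 1e-3).
#' @return A single label, or `"tie"`.
#' @examples
#' dominant_label(default_accumulibacter_params(), s = 50)  # "Type I"
#' dominant_label(default_accumulibacter_params(), s = 5)   # "Type II"
#' @export
dominant_label <- function(params_set, s, tie_tol = 1e-3) {
  params_set <- check_params_set(params_set, unique_labels = FALSE)
  if (length(params_set) < 2L) {
    stop("need at least two populations to rank", call. = FALSE)
  }
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s)) {
    stop("'s' must be a single finite number", call. = FALSE)
  }
  if (s < 0) stop("negative substrate concentration", call. = FALSE)
  rates <- vapply(params_set, specific_rate, numeric(1), s = s)
  labels <- vapply(params_set, `[[`, character(1), "label")
  ord <- order(rates, decreasing = TRUE)
  top <- rates[ord[1]]
  second <- rates[ord[2]]
  if (top <= 0 || (top - second) < tie_tol * top) return("tie")
  labels[ord[1]]
}

# positive roots of the rate-equality condition via the exact quadratic:
#   va*kia*(kmb+S)(kib+S) = vb*kib*(kma+S)(kia+S)
# used as a cross-check of the bracketing root-finder.
crossover_quadratic <- function(a, b) {
  A <- a$vmax * a$ki
  B <- b$vmax * b$ki
  c2 <- A - B
  c1 <- A * (b$km + b$ki) - B * (a$km + a$ki)
  c0 <- A * b$km * b$ki - B * a$km * a$ki
  if (abs(c2) < .Machine$double.eps * max(abs(A), abs(B))) {
    if (abs(c1) == 0) return(numeric(0))
    roots <- -c0 / c1
  } else {
    disc <- c1^2 - 4 * c2 * c0
    if (disc < 0) return(numeric(0))
    roots <- (-c1 + c(-1, 1) * sqrt(disc)) / (2 * c2)
  }
  sort(roots[roots > 0 & is.finite(roots)])
}

#' Crossover concentrations of two rate curves
#'
#' Finds all S > 0 in `s_range` where the two populations' specific rates are
#' equal -- the concentration at which predicted competitive dominance
#' switches. Roots are bracketed by a sign-change scan of the rate difference
#' on a log-spaced grid and refined by bisection to 1e-9 relative precision.
#' (The equality condition is also a quadratic in S, which serves as an
#' internal cross-check.)
#'
#' @param params_set List of exactly two [kinetic_params], or the first of
#'   two when `b` is supplied.
#' @param b Optional second [kinetic_params] (alternative calling style).
#' @param s_range Length-2 search interval, within (0, Inf).
#' @param n_scan Number of log-spaced scan points for bracketing.
#' @return Sorted numeric vector of crossover concentrations (possibly
#'   empty). When the two parameter sets are identical the rate difference is
#'   identically zero; an empty vector with attribute `degenerate = TRUE` is
#'   returned.
#' @examples
#' crossover_concentrations(default_accumulibacter_params())  # ~18.35
#' @export
crossover_concentrations <- function(params_set, b = NULL,
                                     s_range = c(1e-4, 1000),
                                     n_scan = 1000) {
  if (is_kinetic_params(params_set) && is_kinetic_params(b)) {
    params_set <- list(params_set, b)
  }
  params_set <- check_params_set(params_set, unique_labels = FALSE)
  if (length(params_set) != 2L) {
    stop("crossover is defined for exactly two populations", call. = FALSE)
  }
  a <- params_set[[1]]; b <- params_set[[2]]
  if (!is.numeric(s_range) || length(s_range) != 2L || any(s_range <= 0) ||
      s_range[1] >= s_range[2]) {
    stop("'s_range' must be an increasing positive interval", call. = FALSE)
  }
  if (isTRUE(all.equal(a[c("vmax", "km", "ki")], b[c("vmax", "km", "ki")]))) {
    return(structure(numeric(0), degenerate = TRUE))
  }
  d <- function(s) specific_rate(a, s) - specific_rate(b, s)
  grid <- exp(seq(log(s_range[1]), log(s_range[2]), length.out = n_scan))
  dv <- d(grid)
  roots <- numeric(0)
  # exact hits on the scan grid
  hit <- which(dv == 0)
  roots <- c(roots, grid[hit])
  sgn <- sign(dv)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  for (i in flip) {
    lo <- grid[i]; hi <- grid[i + 1]
    flo <- dv[i]
    while ((hi - lo) > 1e-9 * hi) {
      mid <- (lo + hi) / 2
      fm <- d(mid)
      if (fm == 0) { lo <- mid; hi <- mid; break }
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    roots <- c(roots, (lo + hi) / 2)
  }
  sort(unique(roots))
}

#' Fit substrate-inhibition parameters to rate observations
#'
#' Least-squares recovery of (Vmax, Km, Ki) from observed (S, rate) pairs via
#' Levenberg-Marquardt. Residuals are absolute by default; `loss = "log"`
#' fits log-rate residuals (multiplicative error), useful when rates span
#' orders of magnitude across the concentration range.
#'
#' Identifiability note: Ki is only weakly identified when the observed
#' concentrations do not reach its magnitude; observations should span both
#' sides of the peak \eqn{\sqrt{K_m K_i}} for a stable fit.
#'
#' @param observations `data.frame` with numeric columns `s` and `rate`
#'   (>= 4 rows, not all at the same concentration).
#' @param init [kinetic_params] starting values; its label is carried to the
#'   estimate.
#' @param lower,upper Length-3 bounds on (vmax, km, ki).
#' @param loss `"absolute"` or `"log"` residuals.
#' @return A list of class `kinetic_fit`: `params` (the estimate as
#'   [kinetic_params]), `residual_norm`, `converged` (logical; non-convergence
#'   is flagged, not an error), `message`, and the underlying `nls.lm` fit.
#' @examples
#' truth <- kinetic_params("Type II", 1.0, 0.5, 300)
#' s <- c(0.05, 0.2, 1, 5, 20, 80, 200, 500)
#' obs <- data.frame(s = s, rate = specific_rate(truth, s))
#' fit_params(obs, init = kinetic_params("Type II", 0.5, 1, 100))$params
#' @export
fit_params <- function(observations, init,
                       lower = c(1e-6, 1e-6, 1e-6),
                       upper = c(Inf, Inf, Inf),
                       loss = c("absolute", "log")) {
  loss <- match.arg(loss)
  if (!is.data.frame(observations) ||
      !all(c("s", "rate") %in% names(observations))) {
    stop("'observations' must be a data.frame with columns 's' and 'rate'",
         call. = FALSE)
  }
  s <- observations$s; r <- observations$rate
  if (length(s) < 4L) {
    stop("need at least 4 observations to fit 3 parameters", call. = FALSE)
  }
  if (length(unique(s)) == 1L) {
    stop("degenerate design: all observations at the same concentration",
         call. = FALSE)
  }
  if (any(s < 0) || any(!is.finite(s)) || any(!is.finite(r))) {
    stop("observations must be finite with s >= 0", call. = FALSE)
  }
  if (!is_kinetic_params(init)) {
    stop("'init' must be a 'kinetic_params' object", call. = FALSE)
  }
  model <- function(th, s) th[1] * s / ((th[2] + s) * (1 + s / th[3]))
  resid_fn <- if (loss == "absolute") {
    function(th) model(th, s) - r
  } else {
    keep <- s > 0 & r > 0
    function(th) log(model(th, s[keep])) - log(r[keep])
  }
  fit <- minpack.lm::nls.lm(
    par = c(init$vmax, init$km, init$ki),
    lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      ftol = 1e-15, ptol = 1e-15, maxiter = 1000)
  )
  th <- fit$par
  converged <- fit$info %in% 1:4  # 1-3 ftol/ptol tests, 4 gradient test
  structure(
    list(
      params = kinetic_params(init$label, th[1], th[2], th[3]),
      residual_norm = sqrt(sum(fit$fvec^2)),
      converged = converged,
      message = fit$message,
      fit = fit
    ),
    class = "kinetic_fit"
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> %s  residual norm %.3g  %s\n",
              format(x$params), x$residual_norm,
              if (x$converged) "converged" else "NOT CONVERGED"))
  invisible(x)
}

#' Exhaustive search for parameter pairs explaining observed dominance
#'
#' The published Type I/II parameter values were chosen by trial and error to
#' reproduce which type dominated at each enrichment concentration. This
#' operation makes that search explicit: every combination of candidate
#' (Vmax, Km, Ki) triples for the two populations is scanned, and a pair is
#' retained iff [dominant_label] reproduces every observation (a tie matches
#' nothing).
#'
#' @param observations `data.frame` with columns `s` (mg P L^-1) and
#'   `dominant` (population label observed dominant at that concentration).
#' @param grid Named list with numeric vectors `vmax`, `km`, `ki`: the
#'   candidate values scanned for each population.
#' @param labels Character vector of length 2: the two population labels.
#' @param tie_tol Passed to [dominant_label].
#' @return A list of retained pairs; each element is a list of two
#'   [kinetic_params]. Empty list when nothing explains the observations.
#' @examples
#' obs <- data.frame(s = c(5, 50), dominant = c("Type II", "Type I"))
#' grid <- list(vmax = c(0.95, 1.0), km = c(0.48, 0.5), ki = c(300, 2000))
#' length(search_explaining_params(obs, grid))
#' @export
search_explaining_params <- function(observations, grid,
                                     labels = c("Type I", "Type II"),
                                     tie_tol = 1e-3) {
  if (!is.data.frame(observations) || nrow(observations) == 0L ||
      !all(c("s", "dominant") %in% names(observations))) {
    stop("'observations' must be a non-empty data.frame with columns ",
         "'s' and 'dominant'", call. = FALSE)
  }
  if (!is.list(grid) || !all(c("vmax", "km", "ki") %in% names(grid)) ||
      !all(vapply(grid[c("vmax", "km", "ki")],
                  function(v) is.numeric(v) && length(v) > 0 &&
                    all(is.finite(v)), logical(1)))) {
    stop("'grid' must contain finite numeric vectors vmax, km, ki",
         call. = FALSE)
  }
  if (length(labels) != 2L || anyDuplicated(labels)) {
    stop("'labels' must be two distinct population labels", call. = FALSE)
  }
  cand <- expand.grid(vmax = grid$vmax, km = grid$km, ki = grid$ki,
                      KEEP.OUT.ATTRS = FALSE)
  make <- function(label, i) {
    kinetic_params(label, cand$vmax[i], cand$km[i], cand$ki[i])
  }
  retained <- list()
  for (i in seq_len(nrow(cand))) {
    pa <- make(labels[1], i)
    for (j in seq_len(nrow(cand))) {
      pb <- make(labels[2], j)
      pair <- list(pa, pb)
      ok <- TRUE
      for (k in seq_len(nrow(observations))) {
        lab <- dominant_label(pair, observations$s[k], tie_tol = tie_tol)
        if (!identical(lab, observations$dominant[k])) { ok <- FALSE; break }
      }
      if (ok) retained[[length(retained) + 1L]] <- pair
    }
  }
  retained
}
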