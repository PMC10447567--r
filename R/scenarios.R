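# Scenario suite: the named simulation cases, parameter sweeps along
# the dose / neutralization / glucose axes, and bisection searches for
# the dose-response thresholds.

.case_names <- c(
  A = "no dosing",
  B = "continuous dosing",
  C = "dosing on/off",
  D = "varying HP dose (continuous)",
  E = "only dead-cell neutralization (k_B_L = 0)",
  F = "only live-cell neutralization (k_B_D = 0)",
  G = "varying influent glucose")

#' Run one of the named simulation cases
#'
#' Cases and their overrides of the standard parameters:
#' \describe{
#'   \item{A}{no dosing (baseline).}
#'   \item{B}{continuous HP from t = 2 d at 500 g/m3 (`dose1 = dose2 = 500`).}
#'   \item{C}{HP at 500 g/m3 on t in \[2, 6\] d, then off (`dose2 = 0`).}
#'   \item{D}{continuous dosing at a supplied concentration (`value`, g/m3).}
#'   \item{E}{`k_B_L = 0`: only dead cells neutralize HP; continuous 500 g/m3.}
#'   \item{F}{`k_B_D = 0`: only live cells neutralize HP; continuous 500 g/m3.}
#'   \item{G}{influent glucose set to `value` (g/m3); continuous 500 g/m3.}
#' }
#' "Continuous" means the second dose equals the first, so treatment
#' never switches off.
#'
#' @param name one of `"A"` to `"G"`.
#' @param p base parameters (overridden per case as above).
#' @param value sweep value required for cases D (dose, g/m3) and G
#'   (influent glucose, g/m3); for E/F it optionally replaces the
#'   default 500 g/m3 dose.
#' @param t_final initial horizon, days (extended automatically when
#'   `steady = TRUE` and the run has not settled).
#' @param steady if `TRUE` (default) run through [run_to_steady_state()];
#'   otherwise a single fixed-horizon integration.
#' @param t_cap horizon cap for steady-state escalation, days.
#' @return list with elements `sim` (the `biofilm_sim`), `metrics`
#'   ([steady_state_metrics()]), `name` and `description`.
#' @examples
#' \donttest{
#' a <- run_case("A", t_final = 50)
#' a$metrics$Lf_ss * 1e6   # about 140 um
#' }
#' @export
run_case <- function(name, p = biofilm_params(), value = NULL,
                     t_final = 100, steady = TRUE, t_cap = 2000) {
  name <- toupper(as.character(name))
  if (!name %in% names(.case_names)) stop("unknown case '", name, "'")
  if (name %in% c("D", "G") && is.null(value))
    stop("case ", name, " needs a sweep value")
  dose <- if (!is.null(value) && name %in% c("D", "E", "F")) value else 500
  sch <- switch(name,
    A = dose_schedule(),
    B = dose_schedule(dose1 = 500, dose2 = 500),
    C = dose_schedule(dose1 = 500, dose2 = 0),
    D = dose_schedule(dose1 = dose, dose2 = dose),
    E = dose_schedule(dose1 = dose, dose2 = dose),
    F = dose_schedule(dose1 = dose, dose2 = dose),
    G = dose_schedule(dose1 = 500, dose2 = 500))
  pc <- switch(name,
    E = do.call(biofilm_params, utils::modifyList(unclass(p), list(k_B_L = 0))),
    F = do.call(biofilm_params, utils::modifyList(unclass(p), list(k_B_D = 0))),
    G = do.call(biofilm_params, utils::modifyList(unclass(p),
                                                  list(S_in_G = value))),
    p)
  sim <- if (steady) {
    run_to_steady_state(pc, sch, t_init = t_final, t_cap = t_cap)
  } else {
    simulate_biofilm(pc, sch, t_final = t_final)
  }
  list(sim = sim, metrics = steady_state_metrics(sim),
       name = name, description = .case_names[[name]])
}

.apply_overrides <- function(p, overrides) {
  if (length(overrides) == 0) return(p)
  do.call(biofilm_params, utils::modifyList(unclass(p), overrides))
}

#' Steady-state response along a continuous-dose axis
#'
#' Runs an independent cold-start simulation to steady state at each
#' dose (`dose2 = dose1`, so treatment never ends) and tabulates the
#' resulting metrics. Dose 0 reproduces the untreated baseline exactly.
#'
#' @param doses HP dose concentrations, g/m3.
#' @param p base parameters.
#' @param overrides named list of parameter overrides applied to every
#'   point (e.g. `list(k_B_D = 0)` for the dead-neutralization knockout).
#' @param t_init,t_cap steady-state horizons, days.
#' @return data.frame (one row per dose): `dose`, `Lf_um`,
#'   `percent_live`, `mean_live_fraction`, `areal_live`, `eradicated`,
#'   `steady`. Solver failures are recorded as `NA` rows, not errors.
#' @export
dose_sweep <- function(doses, p = biofilm_params(), overrides = list(),
                       t_init = 100, t_cap = 2000) {
  if (any(doses < 0)) stop("doses must be non-negative")
  p <- .apply_overrides(p, overrides)
  rows <- lapply(doses, function(d) {
    res <- tryCatch({
      sim <- run_to_steady_state(p, dose_schedule(dose1 = d, dose2 = d),
                                 t_init = t_init, t_cap = t_cap)
      m <- steady_state_metrics(sim)
      data.frame(dose = d, Lf_um = 1e6 * m$Lf_ss,
                 percent_live = m$percent_live,
                 mean_live_fraction = m$mean_live_fraction,
                 areal_live = m$areal_live,
                 eradicated = m$eradicated,
                 steady = isTRUE(sim$steady))
    }, error = function(e) {
      warning("dose ", d, " failed: ", conditionMessage(e))
      data.frame(dose = d, Lf_um = NA_real_, percent_live = NA_real_,
                 mean_live_fraction = NA_real_, areal_live = NA_real_,
                 eradicated = NA, steady = FALSE)
    })
    res
  })
  do.call(rbind, rows)
}

#' Steady-state response along the dead-cell neutralization axis
#'
#' Varies `k_B_D` under continuous dosing and tabulates the steady-state
#' thickness, locating the regime change between a film too small to
#' defend itself and one thicker than the untreated baseline.
#'
#' @param k_values values of `k_B_D` (same units as the standard 10).
#' @param p base parameters.
#' @param dose continuous HP dose, g/m3 (default 500).
#' @param t_init,t_cap steady-state horizons, days.
#' @return data.frame as in [dose_sweep()], with a `k_B_D` column.
#' @export
neutralization_sweep <- function(k_values, p = biofilm_params(), dose = 500,
                                 t_init = 100, t_cap = 2000) {
  if (any(k_values < 0)) stop("k_B_D values must be non-negative")
  rows <- lapply(k_values, function(k) {
    pk <- .apply_overrides(p, list(k_B_D = k))
    res <- tryCatch({
      sim <- run_to_steady_state(pk, dose_schedule(dose1 = dose, dose2 = dose),
                                 t_init = t_init, t_cap = t_cap)
      m <- steady_state_metrics(sim)
      data.frame(k_B_D = k, Lf_um = 1e6 * m$Lf_ss,
                 percent_live = m$percent_live,
                 mean_live_fraction = m$mean_live_fraction,
                 areal_live = m$areal_live,
                 eradicated = m$eradicated,
                 steady = isTRUE(sim$steady))
    }, error = function(e) {
      warning("k_B_D = ", k, " failed: ", conditionMessage(e))
      data.frame(k_B_D = k, Lf_um = NA_real_, percent_live = NA_real_,
                 mean_live_fraction = NA_real_, areal_live = NA_real_,
                 eradicated = NA, steady = FALSE)
    })
    res
  })
  do.call(rbind, rows)
}

#' Bisection search for a dose-response threshold
#'
#' Locates the axis value at which a boolean steady-state property
#' changes, by bisection down to `resolution`. Each candidate is an
#' independent cold-start run to steady state. Built-in predicates:
#' \describe{
#'   \item{`"eradicated"`}{film thickness fell below 1 um.}
#'   \item{`"thicker_than_baseline"`}{steady thickness exceeds the
#'     untreated (dose 0) steady-state thickness.}
#' }
#'
#' @param predicate predicate name, or a function `f(metrics, sim)`
#'   returning `TRUE`/`FALSE`.
#' @param axis which quantity to vary: `"dose"` (continuous HP dose),
#'   `"S_in_G"` (influent glucose at a fixed dose) or `"k_B_D"`.
#' @param lo,hi bracketing axis values; the predicate must differ
#'   between them.
#' @param resolution terminate when the bracket is at most this wide;
#'   the midpoint of the final bracket is returned.
#' @param p base parameters.
#' @param overrides named parameter overrides applied at every point.
#' @param dose fixed HP dose for the `"S_in_G"` and `"k_B_D"` axes, g/m3.
#' @param t_init,t_cap steady-state horizons, days.
#' @return list with `threshold` (midpoint), `bracket` (`c(lo, hi)` of
#'   the final bracket), `n_runs`, and `history` (data.frame of the
#'   evaluated points).
#' @examples
#' \donttest{
#' # continuous dose above which the film no longer out-grows baseline
#' th <- find_threshold("thicker_than_baseline", axis = "dose",
#'                      lo = 0, hi = 20000, resolution = 100)
#' }
#' @export
find_threshold <- function(predicate = c("eradicated", "thicker_than_baseline"),
                           axis = c("dose", "S_in_G", "k_B_D"),
                           lo, hi, resolution = 100,
                           p = biofilm_params(), overrides = list(),
                           dose = 500, t_init = 100, t_cap = 2000) {
  axis <- match.arg(axis)
  if (lo >= hi) stop("need lo < hi")
  p <- .apply_overrides(p, overrides)

  baseline_Lf <- NULL
  if (is.character(predicate)) {
    predicate <- match.arg(predicate)
    if (predicate == "thicker_than_baseline") {
      base <- run_to_steady_state(p, dose_schedule(),
                                  t_init = t_init, t_cap = t_cap)
      baseline_Lf <- steady_state_metrics(base)$Lf_ss
    }
    pred_fun <- switch(predicate,
      eradicated = function(m, sim) isTRUE(m$eradicated),
      thicker_than_baseline = function(m, sim) m$Lf_ss > baseline_Lf)
  } else {
    pred_fun <- predicate
  }

  eval_point <- function(x) {
    if (axis == "dose") {
      sim <- run_to_steady_state(p, dose_schedule(dose1 = x, dose2 = x),
                                 t_init = t_init, t_cap = t_cap)
    } else {
      px <- .apply_overrides(p, stats::setNames(list(x), axis))
      sim <- run_to_steady_state(px, dose_schedule(dose1 = dose, dose2 = dose),
                                 t_init = t_init, t_cap = t_cap)
    }
    m <- steady_state_metrics(sim)
    list(value = pred_fun(m, sim), Lf = m$Lf_ss)
  }

  hist <- data.frame(x = numeric(0), predicate = logical(0), Lf_um = numeric(0))
  note <- function(x, r) {
    hist <<- rbind(hist, data.frame(x = x, predicate = r$value,
                                    Lf_um = 1e6 * r$Lf))
  }
  r_lo <- eval_point(lo); note(lo, r_lo)
  r_hi <- eval_point(hi); note(hi, r_hi)
  if (r_lo$value == r_hi$value)
    stop("predicate does not change sign over [", lo, ", ", hi, "]")
  n <- 2L
  while (hi - lo > resolution) {
    mid <- (lo + hi) / 2
    r <- eval_point(mid); note(mid, r)
    n <- n + 1L
    if (r$value == r_lo$value) {
      lo <- mid; r_lo <- r
    } else {
      hi <- mid; r_hi <- r
    }
  }
  list(threshold = (lo + hi) / 2, bracket = c(lo, hi),
       n_runs = n, history = hist)
}
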