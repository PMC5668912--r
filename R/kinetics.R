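#' Folding records: first-passage or right-censored times
#'
#' One record per simulation: `time` is the first-passage folding time in
#' ns (standard-mass effective time) when `event` is `TRUE`, or the full
#' simulated duration when the run ended without folding (`event = FALSE`,
#' right-censored).
#'
#' @param time positive numeric times (ns).
#' @param event logical (or 0/1) event indicators.
#' @param sim_id optional simulation identifiers.
#' @return a `data.frame` of class `folding_records`.
#' @export
folding_records <- function(time, event, sim_id = seq_along(time)) {
  if (length(time) != length(event))
    stop("time and event must have equal length")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be finite and > 0")
  out <- data.frame(sim_id = sim_id, time = as.numeric(time),
                    event = as.logical(event))
  class(out) <- c("folding_records", "data.frame")
  out
}

#' Individual native-state population of one simulation
#'
#' Number of native frames divided by the number of all saved frames.
#'
#' @param native_flags logical vector of per-frame native classifications.
#' @return fraction in `[0, 1]`.
#' @export
individual_population <- function(native_flags) {
  if (length(native_flags) == 0)
    stop("degenerate input: empty native-flag series")
  mean(as.logical(native_flags))
}

#' Aggregate native-state population over independent simulations
#'
#' Mean, sample standard deviation (N-1 denominator) and standard error
#' `SE = SD/sqrt(N)` of the per-simulation populations, expressed in
#' percent.
#'
#' @param per_sim numeric vector of per-simulation population fractions.
#' @return named numeric vector `c(mean, sd, se)` in percent.
#' @export
aggregate_population <- function(per_sim) {
  n <- length(per_sim)
  if (n < 2) stop("insufficient replicates: need N >= 2 simulations")
  m <- mean(per_sim) * 100
  s <- sd(per_sim) * 100
  c(mean = m, sd = s, se = s / sqrt(n))
}

#' Native-state population time series across simulations
#'
#' Materialises the population-versus-simulation-time layout: at each
#' checkpoint (a step count), the individual population of each simulation
#' is computed from the frames saved up to that step, then aggregated.
#' The aggregated simulation time at a checkpoint is
#' `n_sims * checkpoint * effective_dt`.
#'
#' @param native_flag_matrix logical matrix, frames x simulations, all
#'   simulations saved on the same `save_interval` grid.
#' @param checkpoints increasing step counts, each a multiple of
#'   `save_interval` and within the simulated length.
#' @param save_interval steps between saved frames.
#' @param effective_dt effective time step in fs (standard-mass credit).
#' @return object of class `population_series`: a `data.frame` with columns
#'   `checkpoint`, `aggregated_time_us`, `mean_pct`, `sd_pct`, `se_pct`,
#'   `n_sims`, plus the per-simulation population matrix as attribute
#'   `"per_sim"`.
#' @export
population_time_series <- function(native_flag_matrix, checkpoints,
                                   save_interval, effective_dt) {
  fm <- as.matrix(native_flag_matrix)
  nfr <- nrow(fm); nsim <- ncol(fm)
  if (nsim < 2) stop("insufficient replicates: need N >= 2 simulations")
  checkpoints <- as.numeric(checkpoints)
  if (any(diff(checkpoints) <= 0)) stop("checkpoints must be increasing")
  if (any(checkpoints %% save_interval != 0))
    stop("alignment error: checkpoints must be multiples of save_interval")
  if (max(checkpoints) / save_interval > nfr)
    stop("alignment error: checkpoint beyond simulated length")
  per_sim <- matrix(NA_real_, length(checkpoints), nsim)
  stats <- matrix(NA_real_, length(checkpoints), 3)
  for (k in seq_along(checkpoints)) {
    nf <- checkpoints[k] / save_interval
    per_sim[k, ] <- colMeans(fm[seq_len(nf), , drop = FALSE])
    stats[k, ] <- aggregate_population(per_sim[k, ])
  }
  out <- data.frame(checkpoint = checkpoints,
                    aggregated_time_us =
                      nsim * checkpoints * effective_dt * 1e-9,
                    mean_pct = stats[, 1], sd_pct = stats[, 2],
                    se_pct = stats[, 3], n_sims = nsim)
  attr(out, "per_sim") <- per_sim
  class(out) <- c("population_series", "data.frame")
  out
}

#' First-passage folding record from an RMSD series
#'
#' The folding time is the time of the first saved frame at or below the
#' cutoff: `(frame index, 1-based) * save_interval * effective_dt`.  If no
#' frame crosses, the record is right-censored at
#' `n_steps * effective_dt`.
#'
#' @param rmsd_series per-frame RMSD values (Angstrom) at `save_interval`
#'   spacing.
#' @param cutoff native cutoff (Angstrom).
#' @param save_interval steps between saved frames.
#' @param effective_dt effective time step (fs).
#' @param n_steps total steps simulated.
#' @return one-row `folding_records`.
#' @export
first_passage <- function(rmsd_series, cutoff, save_interval, effective_dt,
                          n_steps) {
  hit <- which(rmsd_series <= cutoff)
  if (length(hit)) {
    folding_records(hit[1] * save_interval * effective_dt * 1e-6, TRUE)
  } else {
    folding_records(n_steps * effective_dt * 1e-6, FALSE)
  }
}

#' Kaplan-Meier estimate of the mean folding time
#'
#' Product-limit survival curve of the not-yet-folded fraction; the mean is
#' the area under the curve restricted to the largest observed time, with a
#' 95\% confidence interval from the Greenwood variance of the restricted
#' mean.
#'
#' @param records a `folding_records` data frame.
#' @return object of class `survival_fit` with fields `tau_f`, `lcl`,
#'   `ucl` (ns), `estimator = "kaplan_meier"`, `n_events`, and the
#'   underlying `survfit` object as `curve`.
#' @export
km_fit <- function(records) {
  if (sum(records$event) < 1) stop("no folding events: cannot estimate")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = records)
  tbl <- summary(fit, rmean = max(records$time))$table
  tau <- unname(tbl["rmean"])
  se <- unname(tbl["se(rmean)"])
  z <- qnorm(0.975)
  new_survival_fit(tau, max(0, tau - z * se), tau + z * se,
                   "kaplan_meier", sum(records$event), curve = fit)
}

#' Exponential (constant-rate) survival fit of the folding time
#'
#' Maximum-likelihood estimate for exponentially distributed folding times
#' with right censoring: `tau = total exposure / number of events`.  The
#' 95\% confidence interval uses the normal approximation on `log(tau)`
#' with standard deviation `1/sqrt(events)`.
#'
#' @param records a `folding_records` data frame.
#' @return a `survival_fit` with `estimator = "exponential"`.
#' @export
exponential_fit <- function(records) {
  d <- sum(records$event)
  if (d < 1) stop("no folding events: cannot estimate")
  tau <- sum(records$time) / d
  z <- qnorm(0.975)
  new_survival_fit(tau, tau * exp(-z / sqrt(d)), tau * exp(z / sqrt(d)),
                   "exponential", d)
}

new_survival_fit <- function(tau, lcl, ucl, estimator, n_events,
                             curve = NULL) {
  structure(list(tau_f = tau, lcl = lcl, ucl = ucl, estimator = estimator,
                 n_events = n_events, curve = curve),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit:%s> tau_f = %.4g ns (95%% CI %.4g-%.4g), %d events\n",
              x$estimator, x$tau_f, x$lcl, x$ucl, x$n_events))
  invisible(x)
}

#' Two-step folding-time estimation
#'
#' The convention for a set of N independent folding simulations:
#' \itemize{
#'   \item full-length set in which every simulation folded: compute both
#'     the Kaplan-Meier and the exponential fit; if their means agree
#'     within 1\% relative, return the exponential fit (the selected
#'     parametric model, `selected = TRUE`); otherwise return the
#'     Kaplan-Meier fit flagged `disagreement = TRUE`;
#'   \item full-length set with censored runs: return the exponential fit;
#'   \item shortened runs (`full_length = FALSE`) in which half or more of
#'     the simulations did not fold: the estimate is discarded (an error),
#'     because its confidence interval would be overly wide.
#' }
#'
#' @param records a `folding_records` data frame (one row per simulation).
#' @param full_length were the simulations run for their full planned
#'   length?
#' @param tolerance relative tolerance for "identical" Kaplan-Meier and
#'   parametric means (default 0.01).
#' @return a `survival_fit` with logical attributes `"selected"` and
#'   `"disagreement"`.
#' @export
estimate_folding_time <- function(records, full_length = TRUE,
                                  tolerance = 0.01) {
  n_cens <- sum(!records$event)
  if (!full_length && n_cens >= length(records$event) / 2)
    stop("estimate discarded: half or more of the shortened simulations ",
         "did not capture a folding event (overly wide confidence interval)")
  if (sum(records$event) < 1) stop("no folding events: cannot estimate")
  ex <- exponential_fit(records)
  if (n_cens > 0) {
    attr(ex, "selected") <- TRUE
    attr(ex, "disagreement") <- FALSE
    return(ex)
  }
  km <- km_fit(records)
  agree <- abs(km$tau_f - ex$tau_f) <= tolerance * abs(ex$tau_f)
  if (agree) {
    attr(ex, "selected") <- TRUE
    attr(ex, "disagreement") <- FALSE
    ex
  } else {
    attr(km, "selected") <- FALSE
    attr(km, "disagreement") <- TRUE
    km
  }
}

#' Log-linear regression of the nonnative fraction (two-state diagnostic)
#'
#' Under two-state folding kinetics D <-> N the nonnative fraction decays
#' exponentially, `ln([D]/[D]0) = -k_f t`, so the natural logarithm of the
#' fraction of simulations not yet folded by `t` is linear in `t` with
#' slope `-k_f = -1/tau_f`.  Ordinary least squares over the grid points
#' with a positive nonnative fraction.
#'
#' @param records a `folding_records` data frame.
#' @param time_grid times (ns) at which to evaluate the nonnative fraction.
#' @return list with `slope` (1/ns), `intercept`, `r_squared`, and the
#'   points used (`time`, `log_fraction`).
#' @export
ln_nonnative_regression <- function(records, time_grid) {
  frac <- vapply(time_grid, function(t)
    1 - mean(records$event & records$time <= t), numeric(1))
  keep <- frac > 0
  if (sum(keep) < 3)
    stop("degenerate regression: fewer than 3 grid points with a positive ",
         "nonnative fraction")
  t <- time_grid[keep]
  y <- log(frac[keep])
  fit <- lm(y ~ t)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1.0 else 1 - ss_res / ss_tot
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2, time = t, log_fraction = y)
}

#' Unpaired pooled-variance t test between two population curves
#'
#' Student's two-sample t test with pooled variance
#' (`df = n_a + n_b - 2`), two-tailed, on two aggregated-population mean
#' curves sampled at matched step-count checkpoints.
#'
#' @param means_a,means_b numeric vectors of aggregated population means
#'   (percent), length >= 2 each.
#' @return list with `t`, `df` and two-tailed `p`.
#' @export
curve_ttest <- function(means_a, means_b) {
  if (length(means_a) < 2 || length(means_b) < 2)
    stop("insufficient data: each curve needs at least 2 checkpoints")
  tt <- t.test(means_a, means_b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
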