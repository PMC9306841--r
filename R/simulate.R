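# Cohort-level simulators: b* trajectories under crowding, physiology
# cohorts with a lactate-linked b*, post-mortem series and mortality
# counts. All are seeded and leave the caller's RNG untouched.

#' Simulate b* trajectories during crowding exposure
#'
#' For each scenario, exposure times are drawn uniformly over
#' \[0, min(duration, samplingWindow)\] and
#' \eqn{b^*_i = b_0 + rate \cdot t_i + \epsilon_i} with independent
#' Normal(0, sigma^2) residuals; sigma may differ between scenarios,
#' so the pooled data are heteroscedastic by design (matching the
#' group-wise variance weights the GLS stage estimates).
#'
#' @param scenarios List of [TrialScenario-class] objects (non-empty).
#' @param nPerScenario Fish sampled per scenario (>= 2).
#' @param samplingWindow Sampling window in minutes.
#' @param seed Integer seed.
#' @return data.frame with columns `fish_id`, `trial` (factor),
#'   `exposure_min`, `b`.
#' @export
#' @examples
#' head(simulateTrajectories(defaultScenarios()[c("Control", "High")], 10))
simulateTrajectories <- function(scenarios, nPerScenario = 40L,
                                 samplingWindow = 15, seed = 1L) {
  if (length(scenarios) == 0L) stop("empty scenario list")
  stopifnot(nPerScenario >= 2L)
  .withSeed(seed, {
    out <- lapply(scenarios, function(sc) {
      validObject(sc)
      tmax <- min(sc@duration, samplingWindow)
      t <- stats::runif(nPerScenario, 0, tmax)
      b <- sc@b0 + sc@rate * t + stats::rnorm(nPerScenario, 0, sc@sigma)
      data.frame(trial = sc@name, exposure_min = t, b = b)
    })
    out <- do.call(rbind, out)
    out$fish_id <- sprintf("F%04d", seq_len(nrow(out)))
    out$trial <- factor(out$trial)
    rownames(out) <- NULL
    out[, c("fish_id", "trial", "exposure_min", "b")]
  })
}

#' Simulate a physiology cohort
#'
#' Generates fish across trials and monitoring periods with
#' \eqn{b^* = f(lactate) + u_{trial} + u_{period(trial)} + \epsilon},
#' where `f` is the monotone-decreasing logistic [lactateLink()] and
#' the `u`s are independent Normal random intercepts with the SDs in
#' the spec. Plasma glucose and cortisol are generated independently
#' of b* (they carry no signal, mirroring their lack of predictive
#' value in the field data); weight and length are plausible adult
#' mackerel values.
#'
#' @param spec A [CohortSpec-class].
#' @param trials Character vector of trial names.
#' @param periods Character vector of monitoring-period names.
#' @return data.frame with one row per fish: identifiers, covariates,
#'   plasma chemistry and `b`.
#' @export
#' @examples
#' head(simulateCohort(cohortSpec(nFish = 3L)))
simulateCohort <- function(spec,
                           trials = c("Control1", "Control2", "Low",
                                      "Moderate", "High"),
                           periods = c("Pre", "Treatment", "Post2h",
                                       "Post24h")) {
  validObject(spec)
  .withSeed(spec@seed, {
    grid <- expand.grid(trial = trials, monitoring_period = periods,
                        fish = seq_len(spec@nFish),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n <- nrow(grid)
    uTrial <- stats::rnorm(length(trials), 0, spec@trialSD)
    names(uTrial) <- trials
    cellNames <- as.vector(outer(trials, periods, paste, sep = ":"))
    uPeriod <- stats::rnorm(length(cellNames), 0, spec@periodSD)
    names(uPeriod) <- cellNames
    lactate <- pmin(stats::rlnorm(n, meanlog = log(5), sdlog = 0.7), 25)
    b <- lactateLink(lactate, spec@lactateLink) +
      uTrial[grid$trial] +
      uPeriod[paste(grid$trial, grid$monitoring_period, sep = ":")] +
      stats::rnorm(n, 0, spec@residualSD)
    data.frame(
      fish_id = sprintf("C%04d", seq_len(n)),
      trial = factor(grid$trial, levels = trials),
      monitoring_period = factor(grid$monitoring_period, levels = periods),
      vitality_assessed = stats::rbinom(n, 1, 0.5) == 1,
      lactate = lactate,
      glucose = stats::rnorm(n, 5, 1),
      cortisol = stats::rlnorm(n, log(120), 0.5),
      weight_g = stats::rnorm(n, 719, 60),
      length_cm = stats::rnorm(n, 38, 1.2),
      b = unname(b))
  })
}

#' Simulate a post-mortem b* series
#'
#' Each fish starts at \eqn{b^*(0) \sim N(b_0, \tau^2)}; at every
#' later time point the fish has shifted towards blue by `drop` b*
#' units (plus `storageEffect` for light-stored fish, default 0) with
#' fresh measurement noise. The blue shift is complete by the first
#' post-mortem hour and stable thereafter.
#'
#' @param nFish Number of fish (>= 2); half stored dark, half light.
#' @param timepoints Hours post-mortem; must start at 0 and contain at
#'   least one later time (default 0, 1, 4, 24).
#' @param drop Size of the post-mortem blue shift, b* units (>= 0).
#' @param storageEffect Additive effect of light storage, b* units.
#' @param b0 Mean baseline b*.
#' @param tau Between-fish SD of the baseline.
#' @param sigma Measurement SD at each time point.
#' @param seed Integer seed.
#' @return Long data.frame: `fish_id`, `time_h` (factor), `storage`
#'   (factor dark/light), `b`.
#' @export
#' @examples
#' head(simulatePostmortem(6, drop = 5))
simulatePostmortem <- function(nFish = 15L, timepoints = c(0, 1, 4, 24),
                               drop = 5, storageEffect = 0, b0 = 17.17,
                               tau = 1.5, sigma = 1, seed = 1L) {
  stopifnot(nFish >= 2L, drop >= 0)
  timepoints <- sort(unique(timepoints))
  if (timepoints[1] != 0 || length(timepoints) < 2L || any(timepoints < 0))
    stop("invalid timepoint set: need 0 plus at least one later time")
  .withSeed(seed, {
    storage <- rep(c("dark", "light"), length.out = nFish)
    base <- stats::rnorm(nFish, b0, tau)
    out <- expand.grid(fish = seq_len(nFish), time_h = timepoints,
                       KEEP.OUT.ATTRS = FALSE)
    shift <- ifelse(out$time_h > 0,
                    -drop + storageEffect * (storage[out$fish] == "light"), 0)
    out$b <- base[out$fish] + shift + stats::rnorm(nrow(out), 0, sigma)
    data.frame(fish_id = factor(sprintf("P%03d", out$fish)),
               time_h = factor(out$time_h, levels = timepoints),
               storage = factor(storage[out$fish], levels = c("dark", "light")),
               b = out$b)
  })
}

#' Simulate a mortality count
#'
#' One Binomial(n, p) draw: deaths among monitored fish.
#'
#' @param nMonitored Number of fish monitored.
#' @param trueP True mortality probability in \[0, 1\].
#' @param seed Integer seed.
#' @return Integer death count.
#' @export
#' @examples
#' simulateMortality(150, 0.31)
simulateMortality <- function(nMonitored, trueP, seed = 1L) {
  stopifnot(trueP >= 0, trueP <= 1, nMonitored >= 0)
  .withSeed(seed, stats::rbinom(1L, nMonitored, trueP))
}
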