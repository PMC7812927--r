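# Bayesian calibration of the nine maximum growth rates: Metropolis-
# Hastings random walk with reflection at the prior bounds, targeting
# pool-stability observations.

#' Packaged calibration observations
#'
#' Pool-stability targets for the packaged pine site: one value per pool
#' with its observation error (10% for predators, 12.5% for litter and SOM,
#' 20% for the other pools), used once per simulated year.
#'
#' @return data.frame: pool, value (g C m^-3), sd (g C m^-3).
#' @export
calibration_observations <- function() {
  path <- system.file("extdata", "calibration_observations.csv",
                      package = "soilfoodweb")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Packaged prior bounds for the nine maximum growth rates
#'
#' Wide uniform priors covering the literature ranges per guild.
#'
#' @return data.frame: guild, lower, upper (g C g C^-1 day^-1).
#' @export
gmax_priors <- function() {
  path <- system.file("extdata", "gmax_priors.csv", package = "soilfoodweb")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Observation days for pool-stability calibration
#'
#' Mid-year snapshots at fixed 365-day spacing (day 180, 545, 910, ...),
#' ignoring leap days. The final simulated year carries no snapshot (for a
#' ten-year run this gives the nine days 180 through 3,100), except that a
#' one-year run keeps its single mid-year day.
#'
#' @param n_days simulation length in days.
#' @return integer vector of observation days.
#' @export
stability_observation_days <- function(n_days) {
  k <- 0:max(floor((n_days - 180) / 365), 0)
  d <- 180 + 365 * k
  d[d <= max(n_days - 365, 180) & d <= n_days]
}

#' Gaussian log-likelihood of a simulated trace
#'
#' Independent Gaussian densities of the simulated pool values at the
#' observation days against the observed values with their stated errors.
#'
#' @param trace an `sfw_trace`.
#' @param obs observation data.frame (pool, value, sd),
#'   see [calibration_observations()].
#' @param days observation days (default: all stability days in the trace).
#' @return log-likelihood (sum over pools x days).
#' @export
log_likelihood <- function(trace, obs, days = NULL) {
  if (is.null(days)) days <- stability_observation_days(nrow(trace))
  if (any(days > nrow(trace))) stop("trace does not cover observation days")
  stopifnot(all(obs$sd > 0))
  ll <- 0
  for (j in seq_len(nrow(obs))) {
    sim <- trace[[obs$pool[j]]][days]
    ll <- ll + sum(dnorm(sim, obs$value[j], obs$sd[j], log = TRUE))
  }
  ll
}

#' Gaussian proposal with reflection at the bounds
#'
#' Adds an independent Gaussian step to each coordinate and reflects at the
#' prior bounds as often as needed, so proposals always stay inside. The
#' reflection keeps the proposal symmetric, preserving detailed balance for
#' the plain Metropolis acceptance rule.
#'
#' @param theta current parameter vector (inside the bounds).
#' @param scale per-coordinate proposal standard deviations.
#' @param lower,upper prior bounds.
#' @return proposed vector, inside the bounds.
#' @export
propose_reflect <- function(theta, scale, lower, upper) {
  stopifnot(length(theta) == length(lower), all(upper > lower))
  x <- theta + rnorm(length(theta), 0, scale)
  span <- upper - lower
  # fold into [lower, lower + 2 span) then mirror the upper half
  y <- (x - lower) %% (2 * span)
  refl <- ifelse(y > span, 2 * span - y, y)
  lower + refl
}

#' Define a calibration problem
#'
#' @param config an `sfw_config` (the basal parameterization).
#' @param climate climate series covering `n_days`.
#' @param n_days simulation length per likelihood evaluation.
#' @param obs observations (default packaged set).
#' @param priors prior bounds (default packaged set).
#' @param n_iter number of MCMC iterations.
#' @param burn_in fraction of iterations discarded as burn-in.
#' @param proposal_frac proposal sd as a fraction of each prior range.
#' @param seed RNG seed.
#' @return list of class `sfw_calibration_problem`.
#' @export
calibration_problem <- function(config, climate, n_days = 3653,
                                obs = calibration_observations(),
                                priors = gmax_priors(), n_iter = 10000,
                                burn_in = 0.5, proposal_frac = 0.05,
                                seed = 1) {
  stopifnot(inherits(config, "sfw_config"), nrow(climate) >= n_days,
            all(priors$upper > priors$lower), all(obs$sd > 0),
            burn_in >= 0, burn_in < 1)
  if (!identical(priors$guild, GUILDS))
    stop("priors must list the nine guilds in canonical order")
  days <- stability_observation_days(n_days)
  if (!length(days)) stop("run too short for any observation day")
  structure(list(config = config, climate = climate, n_days = n_days,
                 obs = obs, priors = priors, n_iter = n_iter,
                 burn_in = burn_in,
                 scale = proposal_frac * (priors$upper - priors$lower),
                 days = days, seed = seed),
            class = "sfw_calibration_problem")
}

#' Metropolis-Hastings random walk with reflection
#'
#' Standard Metropolis accept/reject on the log-likelihood (the prior is
#' uniform on the bounds, and the reflected proposal is symmetric, so the
#' likelihood ratio is the acceptance ratio). The model is run once per
#' iteration with the proposed growth rates; a failed run counts as a
#' rejection with a warning. Accepted states are recorded with their
#' iteration index and log-likelihood. Reproducible given the problem seed.
#'
#' @param problem an `sfw_calibration_problem`.
#' @param loglik_fn optional replacement log-likelihood `function(theta)`
#'   (bypasses the simulation; used e.g. for prior-recovery checks).
#' @param theta0 optional start (default: prior midpoint).
#' @param progress print progress every this many iterations (0 = quiet).
#' @return list of class `sfw_chain`: `accepted` (matrix, one row per
#'   accepted state: nine rates + iteration + loglik), `acceptance_rate`,
#'   `n_iter`, `burn_in`.
#' @export
metropolis_run <- function(problem, loglik_fn = NULL, theta0 = NULL,
                           progress = 0) {
  stopifnot(inherits(problem, "sfw_calibration_problem"))
  pr <- problem$priors
  lower <- pr$lower; upper <- pr$upper
  if (is.null(loglik_fn)) {
    loglik_fn <- function(theta) {
      cfg <- set_gmax(problem$config, theta)
      tr <- run_simulation(cfg, problem$climate, problem$n_days)
      log_likelihood(tr, problem$obs, problem$days)
    }
  }
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(problem$seed)
  theta <- if (is.null(theta0)) (lower + upper) / 2 else theta0
  stopifnot(all(theta >= lower), all(theta <= upper))
  ll <- loglik_fn(theta)
  acc <- matrix(NA_real_, problem$n_iter, 11,
                dimnames = list(NULL, c(GUILDS, "iteration", "loglik")))
  n_acc <- 0L
  for (it in seq_len(problem$n_iter)) {
    cand <- propose_reflect(theta, problem$scale, lower, upper)
    ll_cand <- tryCatch(loglik_fn(cand), error = function(e) {
      warning("model run failed; proposal rejected: ", conditionMessage(e))
      -Inf
    })
    if (is.finite(ll_cand) && log(runif(1)) < ll_cand - ll) {
      theta <- cand
      ll <- ll_cand
      n_acc <- n_acc + 1L
      acc[n_acc, ] <- c(theta, it, ll)
    }
    if (progress > 0 && it %% progress == 0)
      message(sprintf("iteration %d/%d, accepted %d", it, problem$n_iter,
                      n_acc))
  }
  structure(list(accepted = acc[seq_len(n_acc), , drop = FALSE],
                 acceptance_rate = n_acc / problem$n_iter,
                 n_iter = problem$n_iter, burn_in = problem$burn_in),
            class = "sfw_chain")
}

#' Posterior sample: the last n accepted parameter vectors
#'
#' Takes the last `n` accepted states after burn-in (no thinning), in chain
#' order.
#'
#' @param chain an `sfw_chain` from [metropolis_run()].
#' @param n sample size (default 100).
#' @return matrix with `n` rows and one column per guild.
#' @export
posterior_sample <- function(chain, n = 100) {
  stopifnot(inherits(chain, "sfw_chain"))
  keep <- chain$accepted[, "iteration"] > chain$burn_in * chain$n_iter
  post <- chain$accepted[keep, , drop = FALSE]
  if (nrow(post) < n)
    stop(sprintf(paste0("only %d accepted states after burn-in; need %d ",
                        "(increase n_iter)"), nrow(post), n))
  post[seq(nrow(post) - n + 1, nrow(post)), GUILDS, drop = FALSE]
}

#' Summarize a posterior sample as mean and standard deviation per guild
#'
#' @param sample matrix from [posterior_sample()].
#' @return data.frame: guild, mean, sd.
#' @export
summarize_posterior <- function(sample) {
  data.frame(guild = colnames(sample), mean = colMeans(sample),
             sd = apply(sample, 2, sd), row.names = NULL)
}
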