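# Evaluation scenarios: single-parameter overrides of the basal
# configuration, posterior-ensemble propagation, and summary tables.

#' Build the six evaluation scenarios
#'
#' The basal configuration plus five variants, each changing exactly one
#' input: lower litter recalcitrance (0.20), lower litter C:N (40), higher
#' pH (5.9), predator exclusion (initial predator biomass 0), and higher
#' clay content (15%, which regenerates the textural pore-class fractions
#' and the matrix infiltration capacity through the pedotransfer rule).
#'
#' @param basal an `sfw_config`.
#' @return named list of six `sfw_config`s: basal, rec20, cnlit40, ph59,
#'   nopred, clay15.
#' @export
build_scenarios <- function(basal) {
  stopifnot(inherits(basal, "sfw_config"))
  list(basal = basal,
       rec20 = scenario_override(basal, "rec_lit", 0.20),
       cnlit40 = scenario_override(basal, "cn_lit", 40),
       ph59 = scenario_override(basal, "pH", 5.9),
       nopred = scenario_override(basal, "no_predators", TRUE),
       clay15 = scenario_override(basal, "fClay", 0.15))
}

#' Apply a single-parameter scenario override
#'
#' @param basal an `sfw_config`.
#' @param what one of "rec_lit" (initial litter and litterfall
#'   recalcitrance), "cn_lit" (initial litter and litterfall C:N), "pH",
#'   "no_predators", "fClay".
#' @param value the override value.
#' @return a new `sfw_config` differing from basal only in that input.
#' @export
scenario_override <- function(basal, what, value) {
  args <- list(pools0 = basal$pools0, texture = basal$texture,
               quality = basal$quality, inputs = basal$inputs,
               hydro = list(subsoil_imax = basal$hydro$subsoil_imax,
                            SW0 = basal$hydro$SW0),
               dom = basal$dom, bioturb = basal$bioturb,
               guilds = basal$guilds, diet = basal$diet,
               modifiers = basal$modifiers)
  # keep the basal pore geometry unless the texture itself changes
  if (what != "fClay") {
    args$pores <- basal$pores
    args$hydro$I_maxMat <- basal$hydro$I_maxMat
  }
  switch(what,
    rec_lit = {
      args$quality$Rec_lit <- value
      args$quality$Rec_litterfall <- value
    },
    cn_lit = {
      args$quality$CN_lit <- value
      args$quality$CN_litterfall <- value
    },
    pH = args$texture$pH <- value,
    no_predators = args$pools0[["predators"]] <- 0,
    fClay = args$texture$fClay <- value,
    stop("unknown scenario override: ", what)
  )
  do.call(site_config, args)
}

#' Run a posterior ensemble through one scenario
#'
#' One deterministic run per posterior parameter vector; runs are
#' independent, so summaries are invariant to the sample order. Failed runs
#' are recorded and excluded from summaries with a warning.
#'
#' @param config scenario configuration.
#' @param sample posterior sample matrix (rows = parameter vectors,
#'   columns = guilds), see [posterior_sample()].
#' @param climate climate series.
#' @param n_days run length (default 3653: ten years).
#' @param keep_traces also return the full daily traces (memory-heavy).
#' @return list of class `sfw_ensemble`: `runs` (per-run summaries from
#'   [trace_summary()]), `failed` (indices), and optionally `traces`.
#' @export
ensemble_run <- function(config, sample, climate, n_days = 3653,
                         keep_traces = FALSE) {
  stopifnot(nrow(sample) >= 1)
  runs <- vector("list", nrow(sample))
  traces <- if (keep_traces) vector("list", nrow(sample)) else NULL
  failed <- integer(0)
  for (i in seq_len(nrow(sample))) {
    res <- tryCatch({
      tr <- run_simulation(set_gmax(config, sample[i, ]), climate, n_days)
      if (keep_traces) traces[[i]] <- tr
      trace_summary(tr)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("ensemble member %d failed: %s", i,
                      conditionMessage(res)))
      failed <- c(failed, i)
    } else runs[[i]] <- res
  }
  if (length(failed)) runs <- runs[-failed]
  structure(list(runs = runs, failed = failed, traces = traces),
            class = "sfw_ensemble")
}

#' Summarize one daily trace
#'
#' Per-pool time mean, minimum and maximum; cumulative respiration of the
#' microbial guilds; cumulative litter/SOM turnover by bacteria and litter
#' turnover by engineers; mean and sd of soil water content.
#'
#' @param trace an `sfw_trace`.
#' @return list of named summaries.
#' @export
trace_summary <- function(trace) {
  pools <- as.matrix(trace[, POOLS])
  list(pool_mean = colMeans(pools), pool_min = apply(pools, 2, min),
       pool_max = apply(pools, 2, max),
       R_bact = sum(trace$resp_bacteria), R_fun = sum(trace$resp_fungi),
       R_myc = sum(trace$resp_mycorrhiza),
       bact_SOM_turnover = sum(trace$cons_SOM_bacteria),
       bact_litter_turnover = sum(trace$cons_litter_bacteria),
       eng_litter_turnover = sum(trace$cons_litter_engineers),
       SWC_mean = mean(trace$SW), SWC_sd = sd(trace$SW))
}

#' Ensemble pool summary table
#'
#' Time-and-ensemble mean per pool, plus the ensemble-wide minimum and
#' maximum over all days and runs.
#'
#' @param ensemble an `sfw_ensemble` (or list of trace summaries).
#' @return data.frame: pool, mean, min, max (g C m^-3).
#' @export
summarize_pools <- function(ensemble) {
  runs <- if (inherits(ensemble, "sfw_ensemble")) ensemble$runs else ensemble
  stopifnot(length(runs) >= 1)
  means <- sapply(runs, `[[`, "pool_mean")
  mins <- sapply(runs, `[[`, "pool_min")
  maxs <- sapply(runs, `[[`, "pool_max")
  data.frame(pool = POOLS, mean = rowMeans(means),
             min = apply(mins, 1, min), max = apply(maxs, 1, max),
             row.names = NULL)
}

#' Ensemble flux summary table
#'
#' Cumulative microbial respiration, bacterial litter/SOM turnover,
#' engineer litter turnover (mean +/- sd across runs), and soil water
#' content.
#'
#' @param ensemble an `sfw_ensemble` (or list of trace summaries).
#' @return data.frame: quantity, mean, sd.
#' @export
summarize_fluxes <- function(ensemble) {
  runs <- if (inherits(ensemble, "sfw_ensemble")) ensemble$runs else ensemble
  stopifnot(length(runs) >= 1)
  qty <- c("R_bact", "R_fun", "R_myc", "bact_SOM_turnover",
           "bact_litter_turnover", "eng_litter_turnover", "SWC_mean")
  vals <- sapply(qty, function(q) sapply(runs, `[[`, q))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1,
                                         dimnames = list(NULL, qty))
  data.frame(quantity = qty, mean = colMeans(vals),
             sd = apply(vals, 2, sd), row.names = NULL)
}

#' Derived cross-scenario metrics
#'
#' @param pool_table output of [summarize_pools()].
#' @return the fungi:bacteria biomass ratio (ratio of ensemble means; NA if
#'   the bacterial mean is zero).
#' @export
fungi_bacteria_ratio <- function(pool_table) {
  b <- pool_table$mean[pool_table$pool == "bacteria"]
  f <- pool_table$mean[pool_table$pool == "fungi"]
  if (b == 0) return(NA_real_)
  f / b
}

#' Percent change between two scenario values
#'
#' 100 (a - b) / a: the relative decrease from scenario a to scenario b.
#'
#' @param a,b scalar summaries (e.g. mean soil water content).
#' @return percent change (NA if a is zero).
#' @export
percent_change <- function(a, b) {
  if (a == 0) return(NA_real_)
  100 * (a - b) / a
}
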