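#' Environment specification for long-run competition
#'
#' A deterministic environment always imposes the same starvation time
#' \code{T} between food pulses; a stochastic environment draws each
#' starvation time from an exponential distribution with mean
#' \code{lambda_T}. Every pulse has the same magnitude \code{R0}.
#'
#' @param kind "deterministic" or "stochastic".
#' @param T starvation time in hours (deterministic).
#' @param lambda_T mean starvation time in hours (stochastic).
#' @param R0 resource pulse magnitude.
#' @param horizon simulated time in hours after which the winner is read
#'   off (at the first starvation onset at or past this time).
#' @param n_runs number of independent replicates (stochastic
#'   environments).
#' @return an object of class \code{environment_spec}.
#' @export
environment_spec <- function(kind = c("deterministic", "stochastic"),
                             T = NULL, lambda_T = NULL,
                             R0 = 1e8, horizon = 1e6, n_runs = 1L) {
  kind <- match.arg(kind)
  if (kind == "deterministic") {
    if (is.null(T) || T <= 0)
      stop("deterministic environment needs T > 0", call. = FALSE)
    lambda_T <- NULL
  } else {
    if (is.null(lambda_T) || lambda_T <= 0)
      stop("stochastic environment needs lambda_T > 0", call. = FALSE)
    T <- NULL
  }
  if (R0 <= 0 || horizon <= 0 || n_runs < 1)
    stop("environment_spec: R0, horizon must be > 0 and n_runs >= 1",
         call. = FALSE)
  structure(list(kind = kind, T = T, lambda_T = lambda_T, R0 = R0,
                 horizon = horizon, n_runs = as.integer(n_runs)),
            class = "environment_spec")
}

#' @export
print.environment_spec <- function(x, ...) {
  tm <- if (x$kind == "deterministic") sprintf("T = %g h", x$T)
        else sprintf("lambda_T = %g h (%d runs)", x$lambda_T, x$n_runs)
  cat(sprintf("<environment %s: %s, R0 = %g, horizon = %g h>\n",
              x$kind, tm, x$R0, x$horizon))
  invisible(x)
}

#' Draw the next starvation time
#'
#' @param env an [environment_spec()].
#' @param n number of draws.
#' @return \code{n} hours: exactly \code{T} for deterministic
#'   environments, exponential with mean \code{lambda_T} for stochastic
#'   ones (uses the current RNG state).
#' @export
draw_starvation_time <- function(env, n = 1L) {
  stopifnot(inherits(env, "environment_spec"))
  if (env$kind == "deterministic") rep(env$T, n)
  else stats::rexp(n, rate = 1 / env$lambda_T)
}

#' Initialise a competing population on a genotype grid
#'
#' Per-genotype abundances are drawn i.i.d. from a standard log-normal
#' distribution and rescaled so the whole population holds \code{total}
#' cells, all vegetative. Uses the current RNG state; wrap in
#' [with_rng_stream()] for reproducibility.
#'
#' @param grid a [build_genotype_grid()] result.
#' @param total total initial cell count.
#' @return a [population_state()] in growth phase with \code{R = 0} (apply
#'   a pulse before growing).
#' @export
initialize_population <- function(grid, total = 1e8) {
  n <- nrow(grid)
  if (n < 1L) stop("initialize_population: empty grid", call. = FALSE)
  x <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
  population_state(grid, vegetative = x * (total / sum(x)))
}

measure_onset_abundance <- function(state, params) {
  # every cell classified at a starvation onset: solitary + spores
  if (grid_mechanism(state$grid) == "discrete") {
    pd <- partition_discrete(state, params)
    pd$state$solitary + pd$state$spores
  } else {
    state$vegetative + state$spores
  }
}

run_evolution_once <- function(grid, env, params, init_total) {
  state <- initialize_population(grid, init_total)
  cycles <- 0L
  repeat {
    state <- apply_pulse(state, env$R0)
    gw <- grow_with_germination(state, params)
    state <- gw$state
    if (state$clock >= env$horizon) {
      ab <- measure_onset_abundance(state, params)
      break
    }
    T <- draw_starvation_time(env)
    if (grid_mechanism(grid) == "discrete") {
      state <- partition_discrete(state, params)$state
      state <- starve_discrete(state, T, params)
    } else {
      N0 <- state$vegetative
      state$vegetative <- rep(0, length(N0))
      state$solitary_onset <- N0
      cs <- continuous_starvation(N0, grid$gamma, grid$c, T, params)
      state$solitary <- cs$solitary
      state$spores <- state$spores * exp(-params$delta * T) + cs$spores
      state$clock <- state$clock + T
      state$phase <- "starvation"
    }
    cycles <- cycles + 1L
    if (sum(state$solitary) + sum(state$spores) <= 0)
      stop(errorCondition(paste0("all genotypes went extinct after ",
                                 cycles,
                                 " cycles (starvation outlasted every pool)"),
                          class = "sporecycle_extinction"))
  }
  total <- sum(ab)
  list(abundance = ab, relative = ab / total, cycles = cycles,
       measured_at = state$clock)
}

#' Long-run evolutionary competition on a genotype grid
#'
#' Iterates growth-starvation cycles until the simulation clock passes
#' \code{horizon}; genotype abundance for winner determination is measured
#' at the first starvation onset at or after the horizon, counting spores
#' plus solitary cells (a well-defined instant at which every cell is
#' classified). Stochastic environments are repeated \code{n_runs} times
#' under independent labelled RNG streams and the winner is the genotype
#' with the highest mean relative abundance across runs.
#'
#' @param grid a [build_genotype_grid()] result (single mechanism).
#' @param env an [environment_spec()].
#' @param params a [life_history_params()].
#' @param seed master seed controlling the initial abundances and the
#'   starvation-time draws.
#' @param init_total total initial cell count (log-normal across
#'   genotypes).
#' @return an object of class \code{evolution_result}: list with
#'   \code{winner} (one-row data.frame of the winning genotype),
#'   \code{abundance} (grid plus mean relative abundance), \code{per_run}
#'   (per-replicate winners and relative abundances), \code{cycles},
#'   \code{env}, \code{params} and \code{seed}.
#' @export
run_evolution <- function(grid, env, params = life_history_params(),
                          seed = 1L, init_total = 1e8) {
  stopifnot(inherits(env, "environment_spec"))
  n_runs <- if (env$kind == "stochastic") env$n_runs else 1L
  runs <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    runs[[i]] <- with_rng_stream(seed, paste0("run", i),
                                 run_evolution_once(grid, env, params,
                                                    init_total))
  }
  rel <- vapply(runs, `[[`, numeric(nrow(grid)), "relative")
  rel <- matrix(rel, nrow = nrow(grid))
  mean_rel <- rowMeans(rel)
  win <- which.max(mean_rel)
  per_run_win <- vapply(runs, function(r) which.max(r$relative), 0L)
  abundance <- cbind(as.data.frame(grid), mean_relative = mean_rel)
  res <- list(winner = abundance[win, , drop = FALSE],
              winner_index = win,
              abundance = abundance,
              per_run = list(winner_index = per_run_win,
                             relative = rel,
                             cycles = vapply(runs, `[[`, 0L, "cycles")),
              cycles = runs[[1]]$cycles,
              measured_at = runs[[1]]$measured_at,
              env = env, params = params, seed = seed,
              init_total = init_total)
  class(res) <- "evolution_result"
  res
}

#' @export
print.evolution_result <- function(x, ...) {
  tr <- setdiff(names(x$winner), c("c", "mean_relative"))[1]
  cat(sprintf("<evolution_result: winner %s = %g, c = %g (share %.3f) after %d cycles>\n",
              tr, x$winner[[tr]], x$winner$c, x$winner$mean_relative,
              x$cycles))
  invisible(x)
}

#' Winner sweep over a list of environments
#'
#' Runs [run_evolution()] for each environment on a shared grid and
#' parameter set and tabulates the winning genotype per environment. Each
#' environment gets its own labelled RNG stream derived from the master
#' seed, so the sweep is reproducible as a whole and per entry.
#'
#' @param envs list of [environment_spec()] objects.
#' @param grid,params,init_total as in [run_evolution()].
#' @param seed master seed.
#' @return a data.frame of class \code{winner_sweep}, one row per
#'   environment: environment descriptors, winner trait (alpha or gamma),
#'   winner c, its mean relative abundance and the cycle count.
#' @export
winner_sweep <- function(envs, grid, params = life_history_params(),
                         seed = 1L, init_total = 1e8) {
  stopifnot(length(envs) >= 1L)
  tr_name <- if (grid_mechanism(grid) == "discrete") "alpha" else "gamma"
  rows <- lapply(seq_along(envs), function(i) {
    env <- envs[[i]]
    res <- run_evolution(grid, env, params,
                         seed = seeded_rng(seed, paste0("env", i)),
                         init_total = init_total)
    data.frame(env_index = i, kind = env$kind,
               T = if (is.null(env$T)) NA_real_ else env$T,
               lambda_T = if (is.null(env$lambda_T)) NA_real_
                          else env$lambda_T,
               winner_trait = res$winner[[tr_name]],
               winner_c = res$winner$c,
               winner_share = res$winner$mean_relative,
               cycles = res$cycles)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "winner_trait"] <- paste0("winner_", tr_name)
  attr(out, "seed") <- seed
  class(out) <- c("winner_sweep", "data.frame")
  out
}
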