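#' Per-genotype population state of one well-mixed patch
#'
#' Tracks, for every genotype of a grid, the vegetative cell count (growth
#' phase), the solitary (non-aggregated) cell count together with its
#' starvation-onset snapshot, and the dormant spore count, plus the shared
#' resource level, the wall clock and the current phase. Counts are
#' continuous densities (no demographic noise).
#'
#' @param grid a [build_genotype_grid()] result (or compatible data.frame).
#' @param vegetative,spores,solitary,solitary_onset numeric vectors, one
#'   entry per genotype; scalars are recycled. \code{solitary_onset} is the
#'   snapshot of solitary cells taken at starvation onset, from which the
#'   closed-form survivorship decline is evaluated.
#' @param R resource level (>= 0).
#' @param clock simulation time in hours.
#' @param phase "growth" or "starvation".
#' @return an object of class \code{population_state}.
#' @export
population_state <- function(grid, vegetative = 0, spores = 0,
                             solitary = 0, solitary_onset = 0,
                             R = 0, clock = 0,
                             phase = c("growth", "starvation")) {
  phase <- match.arg(phase)
  n <- nrow(grid)
  st <- list(grid = grid,
             vegetative = rep_len(as.numeric(vegetative), n),
             spores = rep_len(as.numeric(spores), n),
             solitary = rep_len(as.numeric(solitary), n),
             solitary_onset = rep_len(as.numeric(solitary_onset), n),
             R = as.numeric(R), clock = as.numeric(clock), phase = phase)
  class(st) <- "population_state"
  validate_population_state(st)
  st
}

validate_population_state <- function(st) {
  pools <- c(st$vegetative, st$spores, st$solitary, st$solitary_onset,
             st$R, st$clock)
  if (any(!is.finite(pools)))
    stop("population_state: non-finite counts", call. = FALSE)
  if (any(pools < 0))
    stop("population_state: negative counts", call. = FALSE)
  if (st$phase == "starvation" && any(st$vegetative > 0))
    stop("population_state: vegetative pool must be empty during starvation",
         call. = FALSE)
  invisible(st)
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state: %d genotypes, phase %s, t = %.4g h>\n",
              nrow(x$grid), x$phase, x$clock))
  cat(sprintf("  vegetative %.4g | solitary %.4g | spores %.4g | R %.4g\n",
              sum(x$vegetative), sum(x$solitary), sum(x$spores), x$R))
  invisible(x)
}

#' Total living cells per genotype
#' @param st a [population_state()].
#' @return numeric vector of vegetative + solitary + spore counts.
#' @export
total_cells <- function(st) st$vegetative + st$solitary + st$spores

#' Apply a food pulse: survivors resume growth
#'
#' Sets the resource level to the pulse magnitude and switches to the
#' growth phase. Solitary survivors of the past starvation become
#' vegetative immediately; dormant spores stay in the spore pool until
#' their germination lag has elapsed (handled by [run_cycle()]).
#'
#' @param st a [population_state()] at the end of a starvation phase (or
#'   freshly initialised).
#' @param R0 resource pulse magnitude.
#' @return the updated \code{population_state} in growth phase.
#' @export
apply_pulse <- function(st, R0) {
  if (R0 <= 0) stop("apply_pulse: R0 must be > 0", call. = FALSE)
  st$vegetative <- st$vegetative + st$solitary
  st$solitary <- rep(0, length(st$solitary))
  st$solitary_onset <- rep(0, length(st$solitary_onset))
  st$R <- as.numeric(R0)
  st$phase <- "growth"
  st
}
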