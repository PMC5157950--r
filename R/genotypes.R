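#' A heritable strategy: aggregation trait plus division rate
#'
#' A genotype couples a division rate \code{c} (per hour) with one
#' aggregation trait, depending on the mechanism:
#' \itemize{
#'   \item \code{"discrete"}: a fraction \code{alpha} in [0, 1] of the
#'     population aggregates instantaneously at starvation onset (stochastic
#'     switch);
#'   \item \code{"continuous"}: starving solitary cells join the aggregate
#'     at a constant per-capita rate \code{gamma} (per hour).
#' }
#'
#' @param mechanism "discrete" or "continuous".
#' @param alpha aggregating fraction (discrete mechanism only).
#' @param gamma aggregation rate per hour (continuous mechanism only).
#' @param c division rate per hour; the population doubling time is
#'   \code{log(2)/c}.
#' @param params optional [life_history_params()] used to range-check
#'   \code{c}.
#' @return an object of class \code{genotype}.
#' @examples
#' genotype("discrete", alpha = 0.5, c = 0.15)
#' genotype("continuous", gamma = 0.1, c = 0.25)
#' @export
genotype <- function(mechanism = c("discrete", "continuous"),
                     alpha = NULL, gamma = NULL, c,
                     params = NULL) {
  mechanism <- match.arg(mechanism)
  if (mechanism == "discrete") {
    if (is.null(alpha) || !is.null(gamma))
      stop("discrete genotype: set alpha (and not gamma)", call. = FALSE)
    if (alpha < 0 || alpha > 1)
      stop("genotype: alpha must lie in [0, 1]", call. = FALSE)
  } else {
    if (is.null(gamma) || !is.null(alpha))
      stop("continuous genotype: set gamma (and not alpha)", call. = FALSE)
    if (gamma < 0) stop("genotype: gamma must be >= 0", call. = FALSE)
  }
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("genotype: c must be a positive finite number", call. = FALSE)
  if (!is.null(params)) check_c_range(c, params)
  g <- list(mechanism = mechanism, alpha = alpha, gamma = gamma, c = c)
  class(g) <- "genotype"
  g
}

#' @export
print.genotype <- function(x, ...) {
  trait <- if (x$mechanism == "discrete") sprintf("alpha = %g", x$alpha)
           else sprintf("gamma = %g /h", x$gamma)
  cat(sprintf("<genotype %s: %s, c = %g /h (T_d = %.3g h)>\n",
              x$mechanism, trait, x$c, log(2) / x$c))
  invisible(x)
}

#' Doubling time of a genotype
#' @param g a [genotype()].
#' @return hours; \code{log(2)/c}.
#' @export
doubling_time <- function(g) log(2) / g$c

seq_grid <- function(seg) {
  # integer-index construction avoids step-accumulation drift
  start <- seg[[1]]; stop <- seg[[2]]; step <- seg[[3]]
  if (step <= 0) stop("grid segment step must be > 0", call. = FALSE)
  if (stop < start) stop("grid segment must have stop >= start",
                         call. = FALSE)
  n <- floor((stop - start) / step + 1e-9)
  vals <- start + step * (0:n)
  # include the stop endpoint when the step sequence lands short of it
  if (stop - vals[length(vals)] > step * 1e-9) vals <- c(vals, stop)
  vals
}

#' Sampling specification for a genotype grid
#'
#' Describes how to discretise the trait space: one or more
#' \code{(start, stop, step)} segments for the aggregation trait (alpha or
#' gamma, matching the mechanism) and one segment for the division rate c.
#' Segments may share endpoints but must not overlap; the generated grid is
#' deduplicated and sorted.
#'
#' @param mechanism "discrete" or "continuous".
#' @param trait_segments list of numeric triplets \code{c(start, stop,
#'   step)} for alpha (discrete) or gamma (continuous); a single triplet may
#'   be passed directly.
#' @param c_range numeric triplet \code{c(start, stop, step)} for the
#'   division rate.
#' @return an object of class \code{genotype_grid_spec}.
#' @examples
#' # the 101 x 41 = 4141 grid used for deterministic environments
#' genotype_grid_spec("discrete", c(0, 1, 0.01), c(0.05, 0.45, 0.01))
#' @export
genotype_grid_spec <- function(mechanism = c("discrete", "continuous"),
                               trait_segments, c_range) {
  mechanism <- match.arg(mechanism)
  if (is.numeric(trait_segments)) trait_segments <- list(trait_segments)
  for (seg in trait_segments) {
    if (length(seg) != 3L || any(!is.finite(seg)))
      stop("each trait segment must be c(start, stop, step)", call. = FALSE)
    if (seg[3] <= 0) stop("trait segment step must be > 0", call. = FALSE)
  }
  if (length(trait_segments) > 1L) {
    o <- order(vapply(trait_segments, `[`, 0, 1L))
    sorted <- trait_segments[o]
    for (i in seq_len(length(sorted) - 1L)) {
      if (sorted[[i]][2] > sorted[[i + 1L]][1] + 1e-12)
        stop("trait segments overlap", call. = FALSE)
    }
  }
  if (length(c_range) != 3L || c_range[3] <= 0)
    stop("c_range must be c(start, stop, step) with step > 0", call. = FALSE)
  structure(list(mechanism = mechanism, trait_segments = trait_segments,
                 c_range = c_range),
            class = "genotype_grid_spec")
}

#' Build the full Cartesian genotype grid
#'
#' Enumerates every (aggregation trait, division rate) combination of a
#' [genotype_grid_spec()]. Trait values arising from several segments are
#' deduplicated (shared endpoints counted once) and sorted.
#'
#' @param spec a [genotype_grid_spec()].
#' @param params optional [life_history_params()]; when given, division
#'   rates are checked against the admissible range.
#' @return a \code{data.frame} of class \code{genotype_grid} with columns
#'   \code{alpha} (or \code{gamma}) and \code{c}, one row per genotype, and
#'   attribute \code{mechanism}.
#' @examples
#' spec <- genotype_grid_spec("discrete", c(0, 1, 0.01), c(0.05, 0.45, 0.01))
#' nrow(build_genotype_grid(spec))  # 4141
#' @export
build_genotype_grid <- function(spec, params = NULL) {
  stopifnot(inherits(spec, "genotype_grid_spec"))
  tvals <- sort(unique(round(
    unlist(lapply(spec$trait_segments, seq_grid)), 12)))
  cvals <- sort(unique(round(seq_grid(spec$c_range), 12)))
  if (length(tvals) == 0L || length(cvals) == 0L)
    stop("empty genotype grid", call. = FALSE)
  if (spec$mechanism == "discrete" &&
      (min(tvals) < 0 || max(tvals) > 1))
    stop("alpha grid must lie in [0, 1]", call. = FALSE)
  if (spec$mechanism == "continuous" && min(tvals) < 0)
    stop("gamma grid must be >= 0", call. = FALSE)
  if (!is.null(params)) check_c_range(cvals, params)
  grid <- expand.grid(trait = tvals, c = cvals, KEEP.OUT.ATTRS = FALSE)
  names(grid)[1] <- if (spec$mechanism == "discrete") "alpha" else "gamma"
  attr(grid, "mechanism") <- spec$mechanism
  class(grid) <- c("genotype_grid", "data.frame")
  grid
}

#' @export
print.genotype_grid <- function(x, ...) {
  tr <- setdiff(names(x), "c")[1]
  cat(sprintf("<genotype_grid: %d genotypes (%s mechanism); %d %s values x %d c values>\n",
              nrow(x), attr(x, "mechanism"),
              length(unique(x[[tr]])), tr, length(unique(x$c))))
  invisible(x)
}

grid_mechanism <- function(grid) {
  m <- attr(grid, "mechanism")
  if (is.null(m)) m <- if ("alpha" %in% names(grid)) "discrete" else "continuous"
  m
}

grid_trait <- function(grid) {
  if (grid_mechanism(grid) == "discrete") grid$alpha else grid$gamma
}
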