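#' One clonal growth phase to starvation onset
#'
#' Emulates the standard laboratory setup: a clonal population of
#' \code{X0} cells completes one growth phase on a pulse of \code{R0}
#' resources; all quantities are read at the onset of starvation, before
#' any starvation mortality. By conservation of cells plus resources the
#' onset population is \code{P = X0 + R0} for every genotype, so the trait
#' readouts reduce to the partitioning: \code{alpha * P} aggregators,
#' \code{(1 - alpha) * P} non-aggregators and \code{s * alpha * P} spores.
#'
#' @param g a discrete-mechanism [genotype()].
#' @param X0 initial clonal cell count (> 0).
#' @param R0 resource pulse (> 0).
#' @param params a [life_history_params()].
#' @return one-row data.frame (class \code{clonal_assay_result}) with
#'   \code{alpha}, \code{c}, \code{P}, \code{aggregators},
#'   \code{non_aggregators}, \code{spores} and the growth duration.
#' @export
clonal_growth_assay <- function(g, X0, R0, params = life_history_params()) {
  if (g$mechanism != "discrete")
    stop("clonal_growth_assay: requires a discrete-mechanism genotype",
         call. = FALSE)
  if (X0 <= 0 || R0 <= 0)
    stop("clonal_growth_assay: X0 and R0 must be > 0", call. = FALSE)
  grid <- data.frame(alpha = g$alpha, c = g$c)
  attr(grid, "mechanism") <- "discrete"
  st <- population_state(grid, vegetative = X0, R = R0)
  gr <- integrate_growth(st, params)
  P <- gr$state$vegetative[1]
  out <- data.frame(alpha = g$alpha, c = g$c, P = P,
                    aggregators = g$alpha * P,
                    non_aggregators = (1 - g$alpha) * P,
                    spores = params$s * g$alpha * P,
                    growth_duration = gr$elapsed)
  class(out) <- c("clonal_assay_result", "data.frame")
  out
}

#' Exponential growth for a fixed time, then abrupt starvation
#'
#' Emulates the alternative laboratory protocol in which strains are
#' plated on abundant resources, grow exponentially (no resource
#' limitation) for \code{t_grow} hours, and are then washed and abruptly
#' starved. The population at starvation is \code{X0 * exp(c * t_grow)}
#' and the spores are \code{s * alpha} of it, so under this protocol spore
#' number correlates positively with the division rate.
#'
#' @param g a discrete-mechanism [genotype()].
#' @param X0 initial cell count.
#' @param t_grow exponential growth duration in hours (>= 0).
#' @param params a [life_history_params()].
#' @return one-row data.frame with \code{population} at abrupt starvation
#'   and \code{spores}.
#' @export
exponential_starve_assay <- function(g, X0, t_grow,
                                     params = life_history_params()) {
  if (g$mechanism != "discrete")
    stop("exponential_starve_assay: requires a discrete-mechanism genotype",
         call. = FALSE)
  if (t_grow < 0) stop("exponential_starve_assay: t_grow must be >= 0",
                       call. = FALSE)
  ex <- g$c * t_grow
  if (ex > 700 || !is.finite(X0 * exp(ex)))
    stop("exponential_starve_assay: growth overflows for this t_grow",
         call. = FALSE)
  pop <- X0 * exp(ex)
  data.frame(alpha = g$alpha, c = g$c, population = pop,
             spores = params$s * g$alpha * pop)
}

pair_spores <- function(gA, gB, XA, XB, params, growth = FALSE, R0 = NULL) {
  # spore output of a 50:50-style pair, per mechanism and setup
  mech <- gA$mechanism
  if (mech != gB$mechanism)
    stop("chimeric mix: both genotypes must use the same mechanism",
         call. = FALSE)
  if (growth) {
    grid <- if (mech == "discrete")
      data.frame(alpha = c(gA$alpha, gB$alpha), c = c(gA$c, gB$c))
    else data.frame(gamma = c(gA$gamma, gB$gamma), c = c(gA$c, gB$c))
    attr(grid, "mechanism") <- mech
    st <- population_state(grid, vegetative = c(XA, XB), R = R0)
    st <- integrate_growth(st, params)$state
    XA <- st$vegetative[1]; XB <- st$vegetative[2]
  }
  if (mech == "discrete") {
    c(params$s * gA$alpha * XA, params$s * gB$alpha * XB)
  } else {
    cs <- continuous_starvation(c(XA, XB), c(gA$gamma, gB$gamma),
                                c(gA$c, gB$c), params$T_sur, params)
    cs$spores
  }
}

cs_from_spores <- function(sp) {
  tot <- sum(sp)
  if (tot <= 0) {
    return(list(cs = c(0.5, 0.5), tie = TRUE))
  }
  list(cs = sp / tot, tie = FALSE)
}

#' Chimeric success of a starving 50:50 mix
#'
#' The classical measure: two genotypes are mixed 50:50 at starvation
#' onset (no shared growth) and each one's chimeric success is its
#' fraction of the total spores once spore formation completes --
#' instantaneously for the discrete mechanism, at the standardised
#' starvation time \code{T_sur} for the continuous one. Mixes in which
#' neither genotype produces spores are scored as a 0.5/0.5 tie by
#' convention (flagged).
#'
#' @param gA,gB [genotype()]s sharing a mechanism.
#' @param X0 total mixed population, split equally.
#' @param params a [life_history_params()].
#' @return list with \code{cs} (the two chimeric successes, summing to 1),
#'   \code{spores} and \code{tie}.
#' @export
chimeric_success_starvation <- function(gA, gB, X0 = 1e8,
                                        params = life_history_params()) {
  if (X0 <= 0) stop("chimeric_success_starvation: X0 must be > 0",
                    call. = FALSE)
  sp <- pair_spores(gA, gB, X0 / 2, X0 / 2, params)
  c(cs_from_spores(sp), list(spores = sp))
}

#' Chimeric success after a shared growth-starvation cycle
#'
#' The ecologically grounded measure: the two genotypes start as a 50:50
#' mix of \code{X0} cells on \code{R0} resources, grow together to
#' exhaustion, then starve naturally; chimeric success is each genotype's
#' fraction of total spores at spore formation. In the limit of high cell
#' density relative to resources (only residual growth) this reduces to
#' the starvation-only measure.
#'
#' @inheritParams chimeric_success_starvation
#' @param R0 shared resource pulse.
#' @return list with \code{cs}, \code{spores} and \code{tie}.
#' @export
chimeric_success_growth_starvation <- function(gA, gB, X0 = 1e3, R0 = 1e8,
                                               params = life_history_params()) {
  if (X0 <= 0 || R0 <= 0)
    stop("chimeric_success_growth_starvation: X0 and R0 must be > 0",
         call. = FALSE)
  sp <- pair_spores(gA, gB, X0 / 2, X0 / 2, params, growth = TRUE, R0 = R0)
  c(cs_from_spores(sp), list(spores = sp))
}

as_genotype_list <- function(genotypes) {
  if (inherits(genotypes, "genotype")) return(list(genotypes))
  if (is.data.frame(genotypes)) {
    mech <- grid_mechanism(genotypes)
    return(lapply(seq_len(nrow(genotypes)), function(i) {
      if (mech == "discrete")
        genotype("discrete", alpha = genotypes$alpha[i], c = genotypes$c[i])
      else
        genotype("continuous", gamma = genotypes$gamma[i],
                 c = genotypes$c[i])
    }))
  }
  genotypes
}

pairwise_spore_matrix <- function(gl, mode, X0, R0, params) {
  n <- length(gl)
  spA <- matrix(NA_real_, n, n)   # spores of i in the (i, j) mix
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sp <- if (mode == "S")
      pair_spores(gl[[i]], gl[[j]], X0 / 2, X0 / 2, params)
    else
      pair_spores(gl[[i]], gl[[j]], X0 / 2, X0 / 2, params,
                  growth = TRUE, R0 = R0)
    spA[i, j] <- sp[1]; spA[j, i] <- sp[2]
  }
  spA
}

#' Average chimeric success over all pairwise mixes
#'
#' For each genotype, the mean of its pairwise chimeric success over the
#' \code{N_st - 1} partners (every other genotype in the set), in either
#' the starvation-only mode (\code{"S"}) or the growth-starvation mode
#' (\code{"GS"}).
#'
#' @param genotypes a list of [genotype()]s or a genotype grid/data.frame.
#' @param mode \code{"S"} or \code{"GS"}.
#' @param X0 total initial mixed population per pair.
#' @param R0 resource pulse (GS mode).
#' @param params a [life_history_params()].
#' @return numeric vector of average chimeric successes in [0, 1].
#' @export
average_chimeric_success <- function(genotypes, mode = c("GS", "S"),
                                     X0 = 1e3, R0 = 1e8,
                                     params = life_history_params()) {
  mode <- match.arg(mode)
  gl <- as_genotype_list(genotypes)
  n <- length(gl)
  if (n < 2L) stop("average_chimeric_success: need at least 2 genotypes",
                   call. = FALSE)
  spA <- pairwise_spore_matrix(gl, mode, X0, R0, params)
  cs <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    tot <- spA[i, j] + spA[j, i]
    cs[i, j] <- if (tot > 0) spA[i, j] / tot else 0.5
  }
  rowMeans(cs, na.rm = TRUE)
}

#' Pairwise dominance matrix of a genotype set
#'
#' Mixes every pair of genotypes 50:50 (starvation-only or
#' growth-starvation setup), measures each one's spores at spore
#' formation, and scores the pair as a win for the genotype with more
#' spores, a loss for the other, or a tie when the relative spore
#' difference is at most \code{tie_tol} (including the both-zero case).
#'
#' @inheritParams average_chimeric_success
#' @param tie_tol relative spore difference treated as "same number of
#'   spores".
#' @return an object of class \code{chimera_result}: list with the
#'   genotype table, the chimeric-success matrix \code{cs}, the
#'   \code{outcome} matrix ("win"/"loss"/"tie"), \code{tie} mask,
#'   \code{average_cs}, per-genotype \code{wins}/\code{losses}/\code{ties},
#'   the ranking with transitivity diagnostics, and the setup descriptor.
#' @export
dominance_matrix <- function(genotypes, mode = c("GS", "S"),
                             X0 = 1e3, R0 = 1e8,
                             params = life_history_params(),
                             tie_tol = 1e-9) {
  mode <- match.arg(mode)
  gl <- as_genotype_list(genotypes)
  n <- length(gl)
  if (n < 2L) stop("dominance_matrix: need at least 2 genotypes",
                   call. = FALSE)
  spA <- pairwise_spore_matrix(gl, mode, X0, R0, params)
  cs <- matrix(0.5, n, n)
  outcome <- matrix("tie", n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- spA[i, j]; b <- spA[j, i]
    tot <- a + b
    cs[i, j] <- if (tot > 0) a / tot else 0.5
    big <- max(a, b)
    if (big == 0 || abs(a - b) <= tie_tol * big) outcome[i, j] <- "tie"
    else outcome[i, j] <- if (a > b) "win" else "loss"
  }
  mech <- gl[[1]]$mechanism
  gt <- do.call(rbind, lapply(gl, function(g)
    data.frame(trait = if (mech == "discrete") g$alpha else g$gamma,
               c = g$c)))
  names(gt)[1] <- if (mech == "discrete") "alpha" else "gamma"
  diag(cs) <- 0.5
  avg <- vapply(seq_len(n), function(i) mean(cs[i, -i]), 0)
  rk <- rank_and_check_linearity(outcome, average_cs = avg)
  res <- list(genotypes = gt, cs = cs, outcome = outcome,
              tie = outcome == "tie" & row(outcome) != col(outcome),
              average_cs = avg,
              wins = rk$wins, losses = rowSums(outcome == "loss"),
              ties = rowSums(outcome == "tie") - 1L,
              ranking = rk$ranking, is_transitive = rk$is_transitive,
              violations = rk$violations,
              setup = list(mode = mode, X0 = X0,
                           R0 = if (mode == "GS") R0 else NA_real_,
                           measurement = if (mech == "discrete")
                             "spore formation (onset)"
                           else sprintf("t = %g h", params$T_sur),
                           tie_tol = tie_tol))
  class(res) <- "chimera_result"
  res
}

#' @export
print.chimera_result <- function(x, ...) {
  cat(sprintf("<chimera_result: %d genotypes, mode %s, %s hierarchy>\n",
              nrow(x$genotypes), x$setup$mode,
              if (x$is_transitive) "transitive" else "NON-transitive"))
  cat("  ranking (best first): ", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}

#' Rank a dominance tournament and check hierarchy linearity
#'
#' Ranks genotypes by their number of strict pairwise wins (ties broken by
#' average chimeric success where supplied, then by input order) and
#' checks whether the strict wins form a transitive tournament -- i.e.
#' whether the genotypes sit in a linear dominance hierarchy, with any
#' cyclic triples reported.
#'
#' @param outcome square character matrix with entries "win"/"loss"/"tie"
#'   (entry \code{[i, j]} read as genotype i versus j).
#' @param average_cs optional numeric tie-break vector.
#' @return list with \code{ranking} (indices, best first), \code{wins},
#'   \code{is_transitive} and \code{violations} (matrix of cyclic triples,
#'   zero rows when transitive).
#' @export
rank_and_check_linearity <- function(outcome, average_cs = NULL) {
  n <- nrow(outcome)
  stopifnot(is.matrix(outcome), n == ncol(outcome))
  win <- outcome == "win"
  wins <- rowSums(win)
  tiebreak <- if (is.null(average_cs)) rep(0, n) else average_cs
  ranking <- order(-wins, -tiebreak, seq_len(n))
  viol <- NULL
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L))
      for (k in (j + 1L):n) {
        trio <- c(i, j, k)
        # a cycle exists iff the three strict-win edges form a rotation
        if ((win[i, j] && win[j, k] && win[k, i]) ||
            (win[j, i] && win[k, j] && win[i, k]))
          viol <- rbind(viol, trio)
      }
  }
  if (is.null(viol)) viol <- matrix(integer(0), 0, 3)
  colnames(viol) <- c("i", "j", "k")
  list(ranking = ranking, wins = wins,
       is_transitive = nrow(viol) == 0L, violations = viol)
}
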