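fmt12 <- function(x) {
  # 12 significant digits for cross-implementation comparison
  if (is.numeric(x)) formatC(x, digits = 12, format = "g") else x
}

write_csv12 <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt12), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write simulation results to an output directory
#'
#' Serialises the supported result objects as CSV tables (12 significant
#' digits) plus a JSON metadata file carrying seeds, parameters (with
#' their provenance tags), durations and the package version. Handles
#' [run_evolution()] results, [winner_sweep()] tables,
#' [dominance_matrix()] results and clonal-assay tables.
#'
#' @param results a single result object or a named list of them.
#' @param out_dir output directory (created if missing).
#' @param params a [life_history_params()] echoed into the metadata.
#' @param seed master seed echoed into the metadata.
#' @return character vector of files written, invisibly.
#' @export
write_results <- function(results, out_dir, params = NULL, seed = NULL) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir))
      stop("write_results: cannot create output directory '", out_dir, "'",
           call. = FALSE)
  }
  if (!is.list(results) || inherits(results, c(
    "evolution_result", "winner_sweep", "chimera_result", "data.frame")))
    results <- list(result = results)
  if (is.null(names(results)))
    names(results) <- paste0("result", seq_along(results))
  written <- character(0)
  for (nm in names(results)) {
    r <- results[[nm]]
    if (inherits(r, "evolution_result")) {
      f <- file.path(out_dir, paste0(nm, "_abundance.csv"))
      write_csv12(r$abundance, f)
      written <- c(written, f)
    } else if (inherits(r, "chimera_result")) {
      f1 <- file.path(out_dir, paste0(nm, "_cs_matrix.csv"))
      lab <- apply(r$genotypes, 1, function(x)
        paste(names(r$genotypes), signif(as.numeric(x), 6), sep = "=",
              collapse = "_"))
      m <- as.data.frame(r$cs)
      names(m) <- lab
      write_csv12(cbind(genotype = lab, m), f1)
      f2 <- file.path(out_dir, paste0(nm, "_ranking.json"))
      jsonlite::write_json(
        list(ranking = r$ranking, wins = r$wins,
             is_transitive = r$is_transitive,
             violations = as.data.frame(r$violations),
             average_cs = r$average_cs, setup = r$setup),
        f2, auto_unbox = TRUE, digits = NA, pretty = TRUE)
      written <- c(written, f1, f2)
    } else if (is.data.frame(r)) {
      f <- file.path(out_dir, paste0(nm, ".csv"))
      write_csv12(r, f)
      written <- c(written, f)
    } else {
      f <- file.path(out_dir, paste0(nm, ".json"))
      jsonlite::write_json(r, f, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
      written <- c(written, f)
    }
  }
  meta <- list(
    package_version = as.character(utils::packageVersion("sporecycle")),
    written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params = if (!is.null(params)) unclass(params) else NULL,
    param_sources = as.list(param_sources()),
    files = basename(written))
  fmeta <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, fmeta, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(written, fmeta))
}
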