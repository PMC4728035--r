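#' The packaged 2008 conservancy survey
#'
#' Loads the worked-example dataset shipped with the package: 423 spoor
#' records (65 lion, 101 leopard, 10 cheetah, 129 wild dog, 12 brown
#' hyaena, 103 + 3 spotted hyaena) across private (2,530 km2, 348 km of
#' transects driven twice, 696 km surveyed), resettlement (960 km2, 149 km)
#' and communal (984 km2, 110 km) land. Counts per species and land-use type are the
#' published survey totals; positions along transects are synthesized
#' uniformly (the original GPS locations are not reproduced).
#'
#' @return A [survey_dataset()].
#' @export
svc_survey <- function() {
  read_survey(system.file("extdata", "svc2008", package = "spoorstats",
                          mustWork = TRUE))
}

#' Configure a pipeline run
#'
#' Exactly one of `input_dir` (read a survey from disk) or `scenario`
#' (simulate one) must be given.
#'
#' @param input_dir directory with `records.csv`, `transects.csv`,
#'   `strata.csv`.
#' @param scenario a [simulation_config()].
#' @param out_dir output directory for tables and the report.
#' @param n_bootstrap bootstrap replicates for CIs and precision curves.
#' @param seed integer seed used by every stochastic stage.
#' @param model a [calibration_model()].
#' @param min_spoor_precision minimum spoor for a precision curve without
#'   an "insufficient sample" flag (default 3).
#' @return An object of class `run_config`.
#' @export
run_config <- function(input_dir = NULL, scenario = NULL, out_dir,
                       n_bootstrap = 1000, seed = 1,
                       model = default_model(), min_spoor_precision = 3L) {
  if (is.null(input_dir) == is.null(scenario)) {
    stop("set exactly one of input_dir / scenario", call. = FALSE)
  }
  structure(list(input_dir = input_dir, scenario = scenario,
                 out_dir = out_dir, n_bootstrap = n_bootstrap,
                 seed = as.integer(seed), model = model,
                 min_spoor_precision = as.integer(min_spoor_precision)),
            class = "run_config")
}

#' Run the full spoor analysis pipeline
#'
#' Ingests (or simulates) a survey, then runs: spoor filtering, effort
#' summary, the species-by-land-use density matrix, per-species bootstrap
#' precision curves (private land, species with at least
#' `min_spoor_precision` spoor are unflagged), the calibrated density and
#' population-size table, and the between-land-use rank test. All tables
#' are written under `out_dir` together with `report.md`; the same config
#' and seed reproduce byte-identical tables.
#'
#' @param config a [run_config()].
#' @return An object of class `run_report`: list with `effort`,
#'   `densities`, `estimates`, `rank_test`, `precision_files`, `files`,
#'   `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  dataset <- stage("ingest", {
    if (!is.null(config$input_dir)) read_survey(config$input_dir)
    else simulate_survey(config$scenario)
  })
  n_raw <- nrow(dataset$records)
  dataset <- stage("filter", filter_spoor(dataset))
  message("filter: ", n_raw, " records in, ", nrow(dataset$records),
          " retained")
  eff <- stage("effort", effort_summary(dataset))
  dm <- stage("density", density_matrix(dataset))

  out <- config$out_dir
  dir.create(file.path(out, "precision"), recursive = TRUE,
             showWarnings = FALSE)
  wr <- function(df, name) {
    p <- file.path(out, name)
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    p
  }

  prec_files <- character()
  for (s in rownames(dm)) {
    for (l in colnames(dm)) {
      rec <- dataset$records
      n <- sum(rec$species == s & rec$lut == l)
      if (n < 2L) next
      iv <- inter_spoor_intervals(dataset, s, l)
      if (length(iv) < 2L) next
      curve <- stage("precision", bootstrap_curve(
        iv, n_bootstrap = max(100, config$n_bootstrap), seed = config$seed))
      flag <- n < config$min_spoor_precision
      df <- as.data.frame(curve)
      df$insufficient_sample <- flag
      p <- wr(df, file.path("precision", paste0(s, "_", l, ".csv")))
      prec_files <- c(prec_files, p)
      message("precision: ", s, "/", l, " n=", n,
              if (flag) " [insufficient sample]" else "")
    }
  }

  est <- stage("estimate", estimate_table(
    dataset, model = config$model, n_bootstrap = config$n_bootstrap,
    seed = config$seed))
  kw <- stage("compare", if (nrow(dataset$records) == 0L) {
    structure(list(H = 0, df = ncol(dm) - 1L, p_value = 1,
                   group_sizes = rep(nrow(dm), ncol(dm)), n_ties = 1L,
                   group_medians = stats::setNames(rep(0, ncol(dm)),
                                                   colnames(dm))),
              class = "rank_test")
  } else {
    compare_lut_densities(dataset)
  })

  dmdf <- data.frame(species = rownames(dm), round(dm, 2),
                     check.names = FALSE)
  files <- c(
    effort = wr(eff, "effort.csv"),
    densities = wr(dmdf, "densities.csv"),
    estimates = wr(local({
      e <- est
      e$spoor_density <- round(e$spoor_density, 2)
      num <- c("pop_density", "pop_density_lo", "pop_density_hi")
      e[num] <- lapply(e[num], round, 2)
      e
    }), "estimates.csv")
  )
  kw_path <- file.path(out, "kw.json")
  jsonlite::write_json(
    list(H = kw$H, df = kw$df, p_value = kw$p_value,
         group_medians = as.list(kw$group_medians)),
    kw_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, kw = kw_path)

  prov <- list(
    seed = config$seed,
    n_bootstrap = config$n_bootstrap,
    package_version = as.character(utils::packageVersion("spoorstats")),
    config_hash = config_hash(config)
  )
  report <- structure(list(effort = eff, densities = dm, estimates = est,
                           rank_test = kw, precision_files = prec_files,
                           files = files, provenance = prov),
                      class = "run_report")
  writeLines(render_report(report), file.path(out, "report.md"))
  report
}

#' @noRd
config_hash <- function(config) {
  # order-stable digest of the config's serialized form
  raw <- serialize(lapply(unclass(config), function(x) {
    if (is.data.frame(x)) as.list(x) else x
  }), NULL, version = 2)
  substr(paste(as.character(raw[seq(1, length(raw), length.out = 64)]),
               collapse = ""), 1, 32)
}

#' @noRd
render_report <- function(report) {
  kw <- report$rank_test
  c("# Spoor survey run report",
    "",
    sprintf("- package: spoorstats %s", report$provenance$package_version),
    sprintf("- seed: %d; bootstrap replicates: %d",
            report$provenance$seed, report$provenance$n_bootstrap),
    sprintf("- config hash: %s", report$provenance$config_hash),
    "",
    "## Effort",
    knit_table(report$effort),
    "",
    "## Spoor densities (per 100 km)",
    knit_table(data.frame(species = rownames(report$densities),
                          round(report$densities, 2),
                          check.names = FALSE)),
    "",
    "## Population estimates",
    knit_table(local({
      e <- report$estimates
      e$spoor_density <- round(e$spoor_density, 2)
      num <- c("pop_density", "pop_density_lo", "pop_density_hi")
      e[num] <- lapply(e[num], round, 2)
      e
    })),
    "",
    "## Land-use comparison",
    sprintf("Kruskal-Wallis H = %.3f, df = %d, p = %.4g", kw$H, kw$df,
            kw$p_value))
}

#' @noRd
knit_table <- function(df) {
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) {
    paste0("| ", paste(trimws(as.character(r)), collapse = " | "), " |")
  })
  c(hdr, sep, rows)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$provenance$seed, "\n")
  cat("  files:", paste(basename(unname(x$files)), collapse = ", "), "\n")
  cat(sprintf("  rank test: H = %.3f, p = %.4g\n", x$rank_test$H,
              x$rank_test$p_value))
  invisible(x)
}
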