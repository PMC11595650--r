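# CSV schemas are versioned so readers can reject unknown layouts loudly
.SCHEMA_VERSION <- "1"

.write_csv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# qseamorph schema ", .SCHEMA_VERSION), con)
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

.read_csv <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "# qseamorph schema")) {
    ver <- trimws(sub("# qseamorph schema", "", first))
    if (ver != .SCHEMA_VERSION)
      stop("unknown schema version '", ver, "' in ", path)
    utils::read.csv(path, skip = 1L, stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Read and write the pipeline's tabular formats
#'
#' Cohort tables (one row per embryo), long-format trajectories
#' (embryo_id, metric, time_hpi, value) and wide standardized-assay tables
#' are stored as RFC-4180 CSV with a one-line schema-version header.
#' Readers validate required columns and name the missing ones.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return The path (writers, invisibly) or a data frame (readers).
#' @export
write_cohort_csv <- function(x, path) .write_csv(x, path)

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- .read_csv(path)
  need <- c("embryo_id", "cycle_id", "ploidy", "tSB", "tB", "tEB",
            "t_biopsy", "transferred", "transfer_order", "live_birth")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("cohort table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' @rdname write_cohort_csv
#' @export
write_trajectories_csv <- function(x, path) .write_csv(x, path)

#' @rdname write_cohort_csv
#' @param metrics Metric names that must be present.
#' @export
read_trajectories_csv <- function(path, metrics = NULL) {
  df <- .read_csv(path)
  need <- c("embryo_id", "metric", "time_hpi", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("trajectory table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (!is.null(metrics)) {
    absent <- setdiff(metrics, unique(df$metric))
    if (length(absent) > 0)
      stop("trajectory table ", path, " has no rows for metric(s): ",
           paste(absent, collapse = ", "))
  }
  df
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages of the analysis graph — generate a
#' calibrated synthetic cohort, resample trajectories on the standardized
#' 30-min assay grid, build group expansion maps with milestone statistics,
#' and run the two intra-cohort ranking simulations — writing versioned CSV
#' and JSON outputs plus a manifest (configuration, seed, package version
#' and an md5 content hash per output file). Identical configurations
#' reproduce identical outputs.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed for the generator.
#' @param n_cycles Number of cycles to simulate.
#' @param steps Subset of `c("generate", "qsea", "stats", "simulate")`.
#' @param config A [cohort_config()]; built from `seed`/`n_cycles` when
#'   `NULL`.
#' @param ranking_metric Assay metric used for the ranking simulations.
#' @param alpha Per-offset significance level for expansion maps.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_cycles = 400,
                         steps = c("generate", "qsea", "stats", "simulate"),
                         config = NULL, ranking_metric = "zp_T",
                         alpha = 0.05) {
  steps <- match.arg(steps, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config)) config <- cohort_config(n_cycles = n_cycles,
                                               seed = seed)
  outputs <- character(0)
  add <- function(p) outputs <<- c(outputs, p)

  cohort <- NULL; qsea <- NULL
  if ("generate" %in% steps) {
    cohort <- sample_cohorts(config)
    add(write_cohort_csv(cohort$embryos, file.path(out_dir, "cohort.csv")))
    add(write_trajectories_csv(cohort$trajectories,
                               file.path(out_dir, "trajectories.csv")))
    message("generate: ", nrow(cohort$embryos), " embryos in ",
            config$n_cycles, " cycles")
  } else {
    cohort <- list(
      embryos = read_cohort_csv(file.path(out_dir, "cohort.csv")),
      trajectories = read_trajectories_csv(
        file.path(out_dir, "trajectories.csv"),
        metrics = ranking_metric),
      config = config)
    class(cohort) <- "cohort_set"
  }

  if ("qsea" %in% steps) {
    for (m in c("zp_A", "emb_A", "zp_T")) {
      qs <- cohort_qsea(cohort, metric = m)
      add(.write_csv(qs, file.path(out_dir, paste0("qsea_", m, ".csv"))))
      if (m == ranking_metric) qsea <- qs
    }
    message("qsea: standardized 0-300 min grid written")
  } else if (any(c("stats", "simulate") %in% steps)) {
    qsea <- .read_csv(file.path(out_dir,
                                paste0("qsea_", ranking_metric, ".csv")))
  }

  if ("stats" %in% steps) {
    emb <- cohort$embryos
    eu <- emb$ploidy == "euploid"
    maps <- list()
    for (m in c("zp_A", "emb_A", "zp_T")) {
      qs <- .read_csv(file.path(out_dir, paste0("qsea_", m, ".csv")))
      rows_eu <- qs$embryo_id %in% emb$embryo_id[eu]
      map <- build_expansion_map(qs[rows_eu, ], qs[!rows_eu, ],
                                 alpha = alpha,
                                 labels = c("euploid", "aneuploid"))
      maps[[m]] <- map
      add(.write_csv(as.data.frame(map),
                     file.path(out_dir, paste0("expansion_map_", m, ".csv"))))
    }
    stats_out <- list(
      alpha = alpha,
      clustering_adjusted = FALSE,
      earliest_significant_offset_min = lapply(maps,
                                               earliest_significant_offset))
    p <- file.path(out_dir, "stats.json")
    jsonlite::write_json(stats_out, p, auto_unbox = TRUE, digits = NA,
                         null = "null")
    add(p)
    message("stats: expansion maps for 3 metrics (euploid vs aneuploid)")
  }

  if ("simulate" %in% steps) {
    emb <- cohort$embryos
    direction <- if (ranking_metric == "zp_T") "ascending" else "descending"
    summaries <- list(ranking_metric = ranking_metric,
                      ranking_offset_min = 300, direction = direction)
    for (ty in c("sim1", "sim2")) {
      elig <- if (ty == "sim1") eligible_sim_one(emb) else
        eligible_sim_two(emb)
      if (length(elig) == 0L) next
      out <- run_simulation(emb, qsea, type = ty, direction = direction)
      add(.write_csv(out, file.path(out_dir, paste0(ty, "_outcomes.csv"))))
      summaries[[ty]] <- unclass(summarize_simulation(out))
      message(ty, ": ", nrow(out), " eligible cycles")
    }
    p <- file.path(out_dir, "simulations.json")
    jsonlite::write_json(summaries, p, auto_unbox = TRUE, digits = NA)
    add(p)
  }

  manifest <- list(
    package = "qseamorph",
    version = as.character(utils::packageVersion("qseamorph")),
    seed = config$seed,
    config = unclass(config),
    steps = steps,
    files = lapply(stats::setNames(nm = basename(outputs)), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
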