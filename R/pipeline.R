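# I/O and orchestration: read cell tables / annotations / clinical data,
# run registration -> regions -> quantification -> Immunoscore -> cohort
# statistics, and write report tables with a run manifest.

#' Pipeline configuration
#'
#' All constants of the analysis with their standard defaults: 0.2
#' micrometre/pixel scan resolution, 1000-pixel tiles (200 micrometres), a
#' 100 micrometre invasive margin, middle-slide registration reference, a
#' 500-pixel registration working scale and the 25-percentile Immunoscore
#' boundary. A config round-trips losslessly through YAML
#' ([write_config()] / [read_config()]).
#'
#' @param resolution micrometres per pixel.
#' @param tile_side tile side in pixels.
#' @param im_width invasive-margin half-width, micrometres.
#' @param im_side sidedness of the IM band (see [in_im_band()]).
#' @param disjoint_regions exclude the inner IM band from TC.
#' @param reference reference slide (name or index; NULL = middle).
#' @param immune_markers,ck_marker marker sets.
#' @param mh_tiling region whose effective tiles carry the Morisita-Horn
#'   proportions (`"TC+IM"` or `"TC"`).
#' @param immunoscore_boundary low/high cut on the averaged percentile.
#' @param percentile_method see [percentile_rank()].
#' @param stage_subset stages retained by the advanced-stage reanalysis.
#' @param welch,fdr,permutation_p statistical options (see
#'   [compare_groups()], [km_logrank()]).
#' @param registration run slide registration (disable only for inputs
#'   already in a common frame).
#' @param working_side,raster_sigma,demons_iter,demons_sigma registration
#'   controls.
#' @param seed seed for any stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(resolution = 0.2, tile_side = 1000, im_width = 100,
                            im_side = "both", disjoint_regions = FALSE,
                            reference = NULL,
                            immune_markers = c("CD3", "CD4", "CD8", "CD19", "CD163"),
                            ck_marker = "CK",
                            mh_tiling = "TC+IM",
                            immunoscore_boundary = 25,
                            percentile_method = "rank",
                            stage_subset = c("IIB", "IIIA", "IIIB", "IIIC"),
                            welch = FALSE, fdr = FALSE, permutation_p = 0,
                            registration = TRUE,
                            working_side = 500, raster_sigma = 2,
                            demons_iter = 30, demons_sigma = 8,
                            seed = 1L) {
  stopifnot(resolution > 0, tile_side >= 1, im_width > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipeline_config, raw[names(raw) %in% names(formals(pipeline_config))])
  cfg
}

#' Read a cell-detection table
#'
#' CSV with columns `slide`, `marker`, `x_um`, `y_um`, `positive` (the shape
#' of a QuPath detection export converted to micrometres). Rows with
#' non-numeric coordinates are rejected and counted; only positive cells are
#' kept.
#'
#' @param path CSV path.
#' @return Named list (per marker) of point tibbles (`x`, `y`), with
#'   attributes `n_rejected` and `slide_order`.
#' @export
read_cell_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           slide = readr::col_integer(),
                           marker = readr::col_character(),
                           x_um = readr::col_character(),
                           y_um = readr::col_character(),
                           positive = readr::col_integer()))
  need <- c("slide", "marker", "x_um", "y_um", "positive")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  x <- suppressWarnings(as.numeric(tab$x_um))
  y <- suppressWarnings(as.numeric(tab$y_um))
  bad <- is.na(x) | is.na(y)
  if (any(bad)) warning(sum(bad), " malformed rows rejected in ", basename(path))
  tab <- dplyr::mutate(tab[!bad, ], x = x[!bad], y = y[!bad])
  tab <- dplyr::filter(tab, .data$positive == 1L)
  if (nrow(tab) == 0) warning("no positive cells in ", basename(path))
  order_tbl <- dplyr::distinct(tab, .data$slide, .data$marker)
  order_tbl <- dplyr::arrange(order_tbl, .data$slide)
  patterns <- lapply(split(tab[c("x", "y")], tab$marker), tibble::as_tibble)
  patterns <- patterns[order_tbl$marker[order_tbl$marker %in% names(patterns)]]
  structure(patterns, n_rejected = sum(bad), slide_order = order_tbl$marker)
}

#' Read the clinical table
#'
#' @param path CSV with columns `patient`, `dfs_months`, `dfs_event`,
#'   `os_months`, `os_event`, `recurrence`, `metastasis`, `stage` and
#'   covariates.
#' @return Tibble.
#' @export
read_clinical <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

quantify_with_config <- function(slides, annotation, config) {
  quantify_patient(slides, annotation,
                   immune_markers = config$immune_markers,
                   ck_marker = config$ck_marker,
                   resolution = config$resolution, tile_side = config$tile_side,
                   side = config$im_side, disjoint = config$disjoint_regions,
                   mh_region = config$mh_tiling)
}

#' Run the full analysis pipeline
#'
#' Stage order: registration (each patient's marker slides aligned to the
#' middle slide) -> region assignment -> per-marker quantification
#' (densities, hotspots, Morisita-Horn indices) -> Immunoscore -> cohort
#' statistics (group comparisons, ROC cutoffs, Kaplan-Meier/log-rank per
#' parameter and endpoint, multivariate Cox). A failing patient is excluded
#' from the cohort statistics and enumerated in the manifest; with fewer
#' than two evaluable patients the statistics are skipped and an error is
#' recorded.
#'
#' @param input a [simulate_cohort()] object or a directory written by
#'   [write_cohort()].
#' @param config a [pipeline_config()].
#' @param outdir optional output directory for the TSV tables and manifest.
#' @param stage_subset_run also rerun the statistics on the advanced-stage
#'   (IIB/III) subset.
#' @return List of class `pipeline_result`: `parameters` (one row per
#'   patient, 47 parameter columns), `clinical`, `stats`, `stats_advanced`,
#'   `manifest`.
#' @export
run_pipeline <- function(input, config = pipeline_config(), outdir = NULL,
                         stage_subset_run = TRUE) {
  set.seed(config$seed)
  t0 <- Sys.time()
  timings <- list(); warnings_log <- character(0)
  log_warn <- function(w) warnings_log <<- c(warnings_log, w)

  if (inherits(input, "synthetic_cohort")) {
    patients <- lapply(input$patients, function(p)
      list(slides = p$slides, annotation = p$annotation))
    clinical <- input$clinical
    checksums <- character(0)
  } else if (is.character(input) && dir.exists(input)) {
    pdirs <- sort(list.dirs(input, recursive = FALSE))
    patients <- lapply(pdirs, function(d) {
      list(slides = read_cell_table(file.path(d, "cells.csv")),
           annotation = read_annotation(file.path(d, "annotation.geojson")))
    })
    clinical <- read_clinical(file.path(input, "clinical.csv"))
    files <- list.files(input, recursive = TRUE, full.names = TRUE)
    checksums <- tools::md5sum(files)
  } else stop("`input` must be a synthetic_cohort or an input directory")

  n <- length(patients)
  failed <- integer(0)
  rows <- vector("list", n)
  t_reg <- Sys.time()
  for (i in seq_len(n)) {
    rows[[i]] <- tryCatch({
      p <- patients[[i]]
      slides <- p$slides
      if (config$registration && length(slides) >= 2) {
        al <- withCallingHandlers(
          align_slides(slides, p$annotation$extent,
                       reference = config$reference,
                       working_side = config$working_side,
                       sigma = config$raster_sigma,
                       max_iter = config$demons_iter,
                       sigma_field = config$demons_sigma),
          warning = function(w) { log_warn(conditionMessage(w)); invokeRestart("muffleWarning") })
        slides <- al$slides
      }
      withCallingHandlers(
        quantify_with_config(slides, p$annotation, config),
        warning = function(w) { log_warn(conditionMessage(w)); invokeRestart("muffleWarning") })
    }, error = function(e) {
      log_warn(sprintf("patient %d failed: %s", i, conditionMessage(e)))
      failed <<- c(failed, i)
      NULL
    })
  }
  timings$quantification <- as.numeric(difftime(Sys.time(), t_reg, units = "secs"))
  ok <- setdiff(seq_len(n), failed)
  params <- dplyr::bind_rows(rows[ok])
  params <- dplyr::bind_cols(tibble::tibble(patient = ok), params)
  stats <- NULL; stats_adv <- NULL
  if (length(ok) >= 2) {
    params <- add_immunoscore(params, boundary = config$immunoscore_boundary,
                              method = config$percentile_method)
    clin <- clinical[match(ok, clinical$patient), ]
    t_st <- Sys.time()
    stats <- cohort_statistics(params, clin, config)
    if (stage_subset_run) {
      adv <- tryCatch(stage_subset(clin, config$stage_subset), error = function(e) NULL)
      if (!is.null(adv) && nrow(adv) >= 10 && sum(adv$dfs_event) >= 3) {
        keep <- params$patient %in% adv$patient
        stats_adv <- tryCatch(cohort_statistics(params[keep, ], adv, config),
                              error = function(e) { log_warn(conditionMessage(e)); NULL })
      } else log_warn("advanced-stage subset too small; subset statistics skipped")
    }
    timings$statistics <- as.numeric(difftime(Sys.time(), t_st, units = "secs"))
  } else {
    log_warn("fewer than 2 evaluable patients: statistics skipped")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("immunoscape")),
    config = unclass(config),
    n_patients = n, failed_patients = failed,
    input_checksums = as.list(checksums),
    timings = timings,
    warnings = warnings_log,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  res <- structure(list(parameters = params, clinical = clinical, stats = stats,
                        stats_advanced = stats_adv, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(outdir)) write_pipeline_result(res, outdir)
  res
}

param_columns <- function(params) {
  setdiff(names(params), c("patient", "Immunoscore_category"))
}

# the statistical layer shared by the full cohort and the stage subset
cohort_statistics <- function(params, clinical, config) {
  cols <- param_columns(params)
  pm <- params[cols]
  group_comparison <- dplyr::bind_rows(
    dplyr::mutate(compare_groups(pm, clinical$recurrence, welch = config$welch,
                                 fdr = config$fdr), split = "ER_vs_LR"),
    dplyr::mutate(compare_groups(pm, clinical$metastasis, welch = config$welch,
                                 fdr = config$fdr), split = "DM_vs_nonDM"))
  surv_univariate <- purrr::map_dfr(cols, function(nm) {
    purrr::map_dfr(c(DFS = "dfs", OS = "os"), function(ep) {
      time <- clinical[[paste0(ep, "_months")]]
      event <- clinical[[paste0(ep, "_event")]]
      v <- pm[[nm]]
      out <- tibble::tibble(parameter = nm, endpoint = toupper(ep),
                            threshold = NA_real_, direction = NA_character_,
                            chisq = NA_real_, p = NA_real_, p_perm = NA_real_)
      okv <- !is.na(v)
      if (sum(okv) < 4 || length(unique(event[okv])) < 2) return(out)
      cut <- tryCatch(roc_cutoff(v[okv], event[okv]), error = function(e) NULL)
      if (is.null(cut)) return(out)
      grp <- dichotomize(v[okv], cut)
      if (nlevels(droplevels(grp)) < 2) return(out)
      km <- tryCatch(km_logrank(time[okv], event[okv], grp,
                                permutation_p = config$permutation_p),
                     error = function(e) NULL)
      if (is.null(km)) return(out)
      dplyr::mutate(out, threshold = cut$threshold, direction = cut$direction,
                    chisq = km$chisq, p = km$p, p_perm = km$p_perm)
    })
  })
  clin2 <- dplyr::mutate(clinical,
    ki67_high = .data$ki67 > 14,
    stage_advanced = .data$stage %in% c("IIB", "IIIA", "IIIB", "IIIC"))
  covars <- c("age_group", "basal_like", "stage_advanced", "tumor_size",
              "grade", "ki67_high", "p53")
  covars <- covars[vapply(covars, function(cv) length(unique(clin2[[cv]])) > 1, logical(1))]
  cox_tables <- purrr::map(c(DFS = "dfs", OS = "os"), function(ep) {
    purrr::map_dfr(cols, function(nm) {
      v <- pm[[nm]]
      okv <- !is.na(v)
      d <- dplyr::mutate(clin2[okv, ], .param = as.integer(
        dichotomize(v[okv], stats::median(v[okv], na.rm = TRUE)) == "high"))
      fit <- tryCatch(
        cox_multivariate(d, time = paste0(ep, "_months"),
                         event = paste0(ep, "_event"),
                         covariates = c(covars, ".param")),
        error = function(e) NULL)
      if (is.null(fit)) return(tibble::tibble())
      dplyr::mutate(tidy.cox_result(fit), parameter = nm,
                    endpoint = toupper(ep), converged = fit$converged)
    })
  })
  list(group_comparison = group_comparison,
       survival_univariate = surv_univariate,
       cox_dfs = cox_tables$DFS, cox_os = cox_tables$OS)
}

#' Write pipeline outputs as TSV tables plus a JSON manifest
#'
#' @param result a `pipeline_result`.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_pipeline_result <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(result$parameters, file.path(outdir, "parameters.tsv"), progress = FALSE)
  if (!is.null(result$stats)) {
    readr::write_tsv(result$stats$group_comparison,
                     file.path(outdir, "group_comparison.tsv"), progress = FALSE)
    readr::write_tsv(result$stats$survival_univariate,
                     file.path(outdir, "survival_univariate.tsv"), progress = FALSE)
    readr::write_tsv(result$stats$cox_dfs, file.path(outdir, "cox_dfs.tsv"), progress = FALSE)
    readr::write_tsv(result$stats$cox_os, file.path(outdir, "cox_os.tsv"), progress = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Human-readable summary of a pipeline run
#'
#' @param result a `pipeline_result`.
#' @return Character vector (one line per statement), invisibly; printed.
#' @export
report_summary <- function(result) {
  lines <- c(sprintf("Patients quantified: %d (of %d; %d failed)",
                     nrow(result$parameters), result$manifest$n_patients,
                     length(result$manifest$failed_patients)),
             sprintf("Parameters per patient: %d",
                     length(param_columns(result$parameters))))
  if (is.null(result$stats)) {
    lines <- c(lines, "No evaluable parameters: statistics skipped.")
  } else {
    gc_ <- result$stats$group_comparison
    su <- result$stats$survival_univariate
    lines <- c(lines,
      sprintf("Group comparisons significant at p < 0.05: %d of %d (ER/LR), %d of %d (DM/non-DM)",
              sum(gc_$significant[gc_$split == "ER_vs_LR"], na.rm = TRUE),
              sum(gc_$split == "ER_vs_LR"),
              sum(gc_$significant[gc_$split == "DM_vs_nonDM"], na.rm = TRUE),
              sum(gc_$split == "DM_vs_nonDM")),
      sprintf("Log-rank significant at p < 0.05: %d (DFS), %d (OS)",
              sum(su$p[su$endpoint == "DFS"] < 0.05, na.rm = TRUE),
              sum(su$p[su$endpoint == "OS"] < 0.05, na.rm = TRUE)))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}

#' @export
print.pipeline_result <- function(x, ...) {
  report_summary(x)
  invisible(x)
}
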