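REQUIRED_COLS <- c("embryo_id", "cell_id", "x", "y", "z", "compartment",
                   "raw_gata6", "raw_nanog")

#' Read a per-nucleus cell table
#'
#' Validates the schema of a comma-separated cell table (one row per
#' segmented nucleus, UTF-8, header required, `.` decimal): required columns
#' `embryo_id`, `cell_id`, `x`, `y`, `z`, `compartment`, `raw_gata6`,
#' `raw_nanog`; any further columns are carried along untouched.
#'
#' @param path Path to a CSV file.
#' @return A validated cell table (data frame).
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(REQUIRED_COLS, names(tab))
  if (length(miss))
    stop("cell table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("x", "y", "z", "raw_gata6", "raw_nanog")) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      stop("non-numeric value in column ", col, " at row ",
           which(is.na(num))[1L], call. = FALSE)
    }
    if (anyNA(v))
      stop("non-numeric value in column ", col, " at row ",
           which(is.na(v))[1L], call. = FALSE)
  }
  for (col in c("raw_gata6", "raw_nanog")) {
    if (any(tab[[col]] < 0))
      stop("negative intensities in column ", col, call. = FALSE)
  }
  bad <- setdiff(unique(tab$compartment), c("TE", "ICM"))
  if (length(bad))
    stop("compartment must be TE or ICM; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  tab
}

#' Write a cell table to CSV
#'
#' @param cohort Cell table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cohort, path) {
  out <- cohort
  num <- vapply(out, is.double, logical(1))
  # full-precision text so that write/read round trips are lossless
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a generator configuration to a YAML sidecar
#' @param cfg A [generator_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_generator_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$stage_bins <- as.list(as.data.frame(x$stage_bins))
  x$emission <- as.list(as.data.frame(x$emission))
  yaml::write_yaml(x, path, precision = 17L)
  invisible(path)
}

#' Read a generator configuration from YAML
#' @param path YAML file written by [write_generator_config()].
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$stage_bins <- as.data.frame(x$stage_bins, stringsAsFactors = FALSE)
  # YAML has no Inf literal guaranteed across emitters; restore open last bin
  x$stage_bins$upper[x$stage_bins$upper == ".inf" |
                       is.na(x$stage_bins$upper)] <- Inf
  x$stage_bins$upper <- as.numeric(x$stage_bins$upper)
  x$emission <- as.data.frame(x$emission, stringsAsFactors = FALSE)
  do.call(generator_config, x[setdiff(names(x), character(0))])
}

#' Serialize a classifier model to YAML
#'
#' Threshold models store their a.u. thresholds; center models store the four
#' cluster centers in log a.u.
#'
#' @param model A `threshold_model` or `center_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "threshold_model")) {
    yaml::write_yaml(list(type = "threshold",
                          theta_gata6 = model$theta_gata6,
                          theta_nanog = model$theta_nanog), path,
                     precision = 17L)
  } else if (inherits(model, "center_model")) {
    ctr <- model$centers
    yaml::write_yaml(list(
      type = "centers",
      reference_bins = model$reference_bins,
      centers = stats::setNames(
        lapply(rownames(ctr), function(l) as.list(ctr[l, ])),
        rownames(ctr))), path, precision = 17L)
  } else stop("unknown model class", call. = FALSE)
  invisible(path)
}

#' Read a classifier model from YAML
#' @param path YAML written by [write_model()].
#' @return A `threshold_model` or `center_model`.
#' @export
read_model <- function(path) {
  x <- yaml::read_yaml(path)
  if (identical(x$type, "threshold"))
    return(threshold_model(x$theta_gata6, x$theta_nanog))
  if (identical(x$type, "centers")) {
    ctr <- do.call(rbind, lapply(x$centers, function(c_) unlist(c_)))
    rownames(ctr) <- names(x$centers)
    return(structure(list(centers = ctr[LINEAGES, , drop = FALSE],
                          reference_bins = unlist(x$reference_bins),
                          k = 3, seed = NA_integer_),
                     class = "center_model"))
  }
  stop("unknown model type in ", path, call. = FALSE)
}

#' Run the full census pipeline
#'
#' Generate (or read) a cohort, fit and shrink the depth-decay slopes,
#' correct intensities, classify ICM cells, and summarise composition by
#' embryo and stage bin, writing every artifact plus a manifest to `out_dir`.
#' Given the same configuration and seed the outputs are identical run to
#' run.
#'
#' @param config A `generator_config`, a list with optional sections
#'   `generator` (arguments to [generator_config()]), `classifier`
#'   (`method`, `reference_bins`) and `smooth` (`span`), or a path to a YAML
#'   file holding such a list.
#' @param out_dir Output directory, created if needed.
#' @param classifier `"kmeans"` (reference-anchored centers) or
#'   `"threshold"` (50 a.u. quadrants); overrides the config section.
#' @param seed Overrides the generator seed.
#' @param input Optional path to an existing cell-table CSV; skips
#'   generation.
#' @return Invisibly, a list with the cohort, fits, model, composition
#'   tables and output paths.
#' @export
run_pipeline <- function(config = generator_config(), out_dir = ".",
                         classifier = NULL, seed = NULL, input = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (inherits(config, "generator_config")) {
    cfg <- config
    config <- list()
  } else {
    cfg <- do.call(generator_config, config$generator %||% list())
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  method <- classifier %||% config$classifier$method %||% "kmeans"
  method <- match.arg(method, c("kmeans", "threshold"))
  ref_bins <- config$classifier$reference_bins %||% c("32-64", "120-150")
  span <- config$smooth$span %||% 0.75

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)

  cohort <- if (is.null(input)) generate_cohort(cfg) else
    read_cell_table(input)
  shr <- eb_shrink(fit_decay_cohort(cohort, floor = cfg$intensity_floor))
  cohort <- correct_z(cohort, shr, floor = cfg$intensity_floor)
  if (method == "kmeans") {
    model <- fit_centers(cohort, reference_bins = ref_bins, seed = cfg$seed)
    cohort <- assign_by_centers(cohort, model)
  } else {
    model <- threshold_model()
    cohort <- classify_threshold(cohort, model)
  }
  comp <- composition(cohort)
  bins <- bin_composition(comp)
  smoothed <- tryCatch(smooth_composition(comp, span = span),
                       error = function(e) NULL)

  write_cell_table(cohort, p("cells.csv"))
  utils::write.csv(shr$fits, p("decay_fits.csv"), row.names = FALSE)
  utils::write.csv(comp, p("composition.csv"), row.names = FALSE)
  utils::write.csv(bins, p("bin_summary.csv"), row.names = FALSE)
  if (!is.null(smoothed))
    utils::write.csv(smoothed, p("smoothed.csv"), row.names = FALSE)
  write_model(model, p("classifier.yaml"))
  write_generator_config(cfg, p("generator.yaml"))
  manifest <- list(
    seed = cfg$seed, classifier = method,
    package_version = as.character(utils::packageVersion("icmcensus")),
    n_embryos = length(unique(cohort$embryo_id)),
    n_cells = nrow(cohort),
    embryos_per_stage = as.list(table(comp$stage)))
  yaml::write_yaml(manifest, p("manifest.yaml"))

  message(sprintf("pipeline: %d embryos, %d cells, classifier=%s -> %s",
                  manifest$n_embryos, manifest$n_cells, method, out_dir))
  invisible(list(cohort = cohort, shrinkage = shr, model = model,
                 composition = comp, bin_summary = bins,
                 smoothed = smoothed, out_dir = out_dir))
}
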