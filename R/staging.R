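#' Developmental stage bins
#'
#' Default total-cell-count bins covering blastocyst development from early
#' cavitation (32 cells) to peri-implantation (>150 cells). Bins are
#' half-open `[lower, upper)`, so a 64-cell embryo falls in "64-90".
#'
#' @return Data frame with columns `label`, `lower`, `upper` (last bin open).
#' @export
stage_bins <- function() {
  data.frame(label = c("32-64", "64-90", "90-120", "120-150", ">150"),
             lower = c(32, 64, 90, 120, 150),
             upper = c(64, 90, 120, 150, Inf),
             stringsAsFactors = FALSE)
}

#' Stage an embryo by its total cell count
#'
#' @param total Total cell count(s); embryos under the first bin edge are
#'   rejected as pre-blastocyst.
#' @param bins Stage-bin table, see [stage_bins()].
#' @return Character vector of bin labels.
#' @export
stage_bin <- function(total, bins = stage_bins()) {
  if (any(total < bins$lower[1L]))
    stop("total cell count below ", bins$lower[1L],
         ": pre-blastocyst embryos are out of range", call. = FALSE)
  idx <- findInterval(total, c(bins$lower, Inf), rightmost.closed = FALSE)
  bins$label[idx]
}

lineage_counts <- function(labels) {
  vapply(LINEAGES, function(l) sum(labels == l, na.rm = TRUE), integer(1))
}

#' Per-embryo lineage composition
#'
#' Counts and ICM fractions of the four lineages per embryo, plus TE/ICM
#' totals and the stage bin. Fractions are of the ICM and sum to one;
#' embryos with an empty ICM are flagged (`icm_empty`) and their fractions
#' left `NA`.
#'
#' @param cohort Cell table with lineage labels.
#' @param labels Which labels to summarise: classifier output
#'   (`"called_lineage"`) or generator truth (`"true_lineage"`).
#' @param bins Stage-bin table.
#' @return Data frame, one row per embryo.
#' @export
composition <- function(cohort, labels = c("called_lineage", "true_lineage"),
                        bins = stage_bins()) {
  labels <- match.arg(labels)
  if (!labels %in% names(cohort))
    stop("cohort has no ", labels, " column", call. = FALSE)
  per <- lapply(split(cohort, cohort$embryo_id), function(emb) {
    total <- nrow(emb)
    icm <- emb$compartment == "ICM"
    cnt <- lineage_counts(emb[[labels]][icm])
    n_icm <- sum(icm)
    frac <- if (n_icm > 0) cnt / n_icm else rep(NA_real_, 4)
    committed <- cnt[["PrE"]] + cnt[["EPI"]] + cnt[["DN"]]
    data.frame(embryo_id = emb$embryo_id[1L],
               condition = if ("condition" %in% names(emb)) emb$condition[1L] else NA,
               regime = if ("regime" %in% names(emb)) emb$regime[1L] else NA,
               total = total, n_te = sum(!icm), n_icm = n_icm,
               stage = stage_bin(total, bins),
               n_epi = cnt[["EPI"]], n_pre = cnt[["PrE"]],
               n_dp = cnt[["DP"]], n_dn = cnt[["DN"]],
               frac_epi = frac[1L], frac_pre = frac[2L],
               frac_dp = frac[3L], frac_dn = frac[4L],
               frac_epi_dn = frac[1L] + frac[4L],
               pre_share_committed =
                 if (committed > 0) cnt[["PrE"]] / committed else NA_real_,
               icm_empty = n_icm == 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per)
  out <- out[order(out$total), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stage-binned average composition
#'
#' Unweighted means across member embryos (each embryo counts once,
#' regardless of its cell number), matching per-embryo composition plots.
#'
#' @param comp Per-embryo table from [composition()].
#' @param bins Stage-bin table.
#' @return Data frame, one row per occupied bin.
#' @export
bin_composition <- function(comp, bins = stage_bins()) {
  comp <- comp[!comp$icm_empty, , drop = FALSE]
  num <- c("total", "n_te", "n_icm", "frac_epi", "frac_pre", "frac_dp",
           "frac_dn", "frac_epi_dn", "pre_share_committed")
  per <- lapply(split(comp, factor(comp$stage, levels = bins$label)),
                function(d) {
    if (!nrow(d)) return(NULL)
    cbind(data.frame(stage = d$stage[1L], n_embryos = nrow(d),
                     te_fraction = mean(d$n_te / d$total),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(colMeans(d[num], na.rm = TRUE))))
  })
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  out
}

#' Smoothed lineage-fraction trends against embryo size
#'
#' Local (tricube-weighted, degree-1) regression of each ICM fraction on the
#' total cell count, evaluated on a grid and clipped to `[0, 1]`.
#'
#' @param comp Per-embryo table from [composition()].
#' @param fractions Fraction columns to smooth.
#' @param span Local-regression span.
#' @param grid Evaluation grid of total cell counts; defaults to the
#'   observed range.
#' @return Data frame with `total`, one column per smoothed fraction.
#' @export
smooth_composition <- function(comp,
                               fractions = c("frac_pre", "frac_dp",
                                             "frac_epi_dn"),
                               span = 0.75, grid = NULL) {
  comp <- comp[!comp$icm_empty, , drop = FALSE]
  if (nrow(comp) < 10L || length(unique(comp$stage)) < 2L)
    stop("need at least 10 embryos spanning at least 2 stage bins",
         call. = FALSE)
  grid <- grid %||% seq(min(comp$total), max(comp$total), by = 2)
  out <- data.frame(total = grid)
  dat <- data.frame(total = comp$total)
  for (fc in fractions) {
    dat$y <- comp[[fc]]
    fit <- stats::loess(y ~ total, data = dat, span = span, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    out[[fc]] <- pmin(pmax(
      stats::predict(fit, newdata = data.frame(total = grid)), 0), 1)
  }
  out
}

#' Half / single / double embryo scaling experiment
#'
#' Builds cohorts of embryos whose every compartment is scaled by 0.5, 1 or
#' 2 relative to the control terminal stage, runs the full measurement
#' pipeline (decay fitting, shrinkage, correction, classification with
#' centers anchored on the single-sized group), and summarises sizes and ICM
#' composition per group.
#'
#' @param cfg A [generator_config()].
#' @param n_per_group Embryos per scale group.
#' @param classifier `"kmeans"` or `"threshold"`.
#' @param seed Seed for generation and classification.
#' @return List with `cells`, per-embryo `composition` (plus `scale`
#'   column) and per-group `summary`.
#' @export
scaling_experiment <- function(cfg = generator_config(), n_per_group = 10L,
                               classifier = c("kmeans", "threshold"),
                               seed = cfg$seed) {
  classifier <- match.arg(classifier)
  scales <- c(0.5, 1, 2)
  # paired design: the three scale groups share per-index seeds, emulating
  # half/single/double embryos derived from the same litters
  seeds <- derive_seeds(seed, n_per_group)
  k <- 0L
  cells <- list()
  for (s in scales) {
    for (i in seq_len(n_per_group)) {
      k <- k + 1L
      emb <- make_scaled_embryo(cfg, scale = s,
                                embryo_id = sprintf("S%s_%02d", s, i),
                                litter_id = sprintf("L%s", s),
                                seed = seeds[i])
      emb$condition <- ifelse(s == 1, "Control", paste0("scale_", s))
      cells[[k]] <- emb
    }
  }
  cohort <- do.call(rbind, cells)
  rownames(cohort) <- NULL
  shr <- eb_shrink(fit_decay_cohort(cohort))
  cohort <- correct_z(cohort, shr)
  cohort <- if (classifier == "kmeans") {
    assign_by_centers(cohort, refit_for_batch(cohort, seed = seed))
  } else {
    classify_threshold(cohort)
  }
  # scaled groups fall outside the standard bins; stage on a single open bin
  open_bins <- data.frame(label = "all", lower = 1, upper = Inf)
  comp <- composition(cohort, bins = open_bins)
  comp$scale <- as.numeric(sub("scale_", "", comp$regime))
  grp <- lapply(split(comp, comp$scale), function(d) {
    data.frame(scale = d$scale[1L], n_embryos = nrow(d),
               mean_total = mean(d$total), mean_te = mean(d$n_te),
               mean_icm = mean(d$n_icm),
               frac_epi = mean(d$frac_epi), frac_pre = mean(d$frac_pre),
               frac_dp = mean(d$frac_dp), frac_dn = mean(d$frac_dn),
               pre_share_committed = mean(d$pre_share_committed),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, grp)
  rownames(summary) <- NULL
  list(cells = cohort, composition = comp, summary = summary)
}
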