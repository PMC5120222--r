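#' Default per-lineage fluorescence emission model
#'
#' Mean and standard deviation of log fluorescence (natural log of arbitrary
#' units on the 8-bit 0-255 scale) for each (lineage, channel) pair.
#' Defaults place marker-positive populations near 150 a.u., negative
#' populations near 15 a.u., and double-positive progenitors near 120 a.u. on
#' both channels, so that on the linear scale the four populations fall in the
#' quadrants delimited by the 50 a.u. thresholds. Trophectoderm cells carry a
#' low-expression profile on both ICM markers.
#'
#' @param positive_au,negative_au,dp_au,te_au Linear-scale (a.u.) means for
#'   marker-positive, marker-negative, double-positive and trophectoderm
#'   expression.
#' @param sd_log Biological spread of log intensity within a lineage
#'   (log a.u.), shared across lineages and channels.
#' @return A data frame with columns `lineage`, `channel`, `mean_log`,
#'   `sd_log`.
#' @export
default_emission <- function(positive_au = 150, negative_au = 15,
                             dp_au = 120, te_au = 12, sd_log = 0.25) {
  grid <- expand.grid(lineage = c(LINEAGES, "TE"), channel = CHANNELS,
                      stringsAsFactors = FALSE)
  attr(grid, "out.attrs") <- NULL
  mean_au <- function(lineage, channel) {
    switch(lineage,
      EPI = if (channel == "nanog") positive_au else negative_au,
      PrE = if (channel == "gata6") positive_au else negative_au,
      DP  = dp_au,
      DN  = negative_au,
      TE  = te_au)
  }
  grid$mean_log <- log(mapply(mean_au, grid$lineage, grid$channel))
  grid$sd_log <- sd_log
  grid
}

#' Configuration of the synthetic blastocyst generator
#'
#' Bundles every parameter of the forward model: stage structure (total cell
#' counts per developmental stage bin), the constant TE:ICM split, the
#' incremental-allocation law of the progenitor (DP) pool, late NANOG
#' downregulation, the lineage-conditional log-normal fluorescence emission,
#' multiplicative depth (Z) decay, measurement noise, and 8-bit clipping.
#'
#' @param seed Integer seed; the whole cohort is reproducible given this seed.
#' @param n_per_bin Embryos generated per stage bin.
#' @param stage_bins Data frame with `label`, `lower`, `upper` total-cell-count
#'   edges (half-open bins); defaults to [stage_bins()].
#' @param max_total Upper cell count used when sampling totals in the open
#'   last bin.
#' @param te_icm_ratio Fraction of total cells that are trophectoderm,
#'   constant across stages.
#' @param allocation_ratio Target terminal PrE share of allocated
#'   (committed) ICM cells; the 3:2 PrE:EPI ratio corresponds to 0.6.
#' @param allocation_completion_size Total cell count at which the expected
#'   DP fraction reaches its floor.
#' @param dp_floor Residual expected DP fraction after completion.
#' @param dn_late_fraction Probability that an EPI cell has downregulated
#'   NANOG (scored DN) in embryos beyond `dn_late_threshold` cells.
#' @param dn_late_threshold Total cell count beyond which NANOG
#'   downregulation applies.
#' @param emission Emission table as produced by [default_emission()].
#' @param noise_sd Additive measurement noise on log intensity (log a.u.).
#' @param decay_mean,decay_sd Mean and between-embryo standard deviation of
#'   the true Z-decay slope (log a.u. per micron; negative means decay).
#' @param decay_channel_jitter_sd Small per-channel jitter around the
#'   embryo-level slope.
#' @param z_range Nuclear depth span in microns (z measured from the first
#'   optical section).
#' @param intensity_cap Saturation level of the detector (255 a.u.).
#' @param intensity_floor Floor applied to raw values before taking logs.
#' @return An object of class `generator_config` (a validated list).
#' @export
generator_config <- function(seed = 1L,
                             n_per_bin = 10L,
                             stage_bins = NULL,
                             max_total = 200L,
                             te_icm_ratio = 0.66,
                             allocation_ratio = 0.6,
                             allocation_completion_size = 100,
                             dp_floor = 0.05,
                             dn_late_fraction = 0.25,
                             dn_late_threshold = 150,
                             emission = default_emission(),
                             noise_sd = 0.15,
                             decay_mean = -0.0125,
                             decay_sd = 0.003,
                             decay_channel_jitter_sd = 0.001,
                             z_range = 60,
                             intensity_cap = 255,
                             intensity_floor = 1) {
  bins <- stage_bins %||% stage_bins()
  cfg <- list(seed = as.integer(seed), n_per_bin = as.integer(n_per_bin),
              stage_bins = bins, max_total = max_total,
              te_icm_ratio = te_icm_ratio, allocation_ratio = allocation_ratio,
              allocation_completion_size = allocation_completion_size,
              dp_floor = dp_floor, dn_late_fraction = dn_late_fraction,
              dn_late_threshold = dn_late_threshold, emission = emission,
              noise_sd = noise_sd, decay_mean = decay_mean,
              decay_sd = decay_sd,
              decay_channel_jitter_sd = decay_channel_jitter_sd,
              z_range = z_range, intensity_cap = intensity_cap,
              intensity_floor = intensity_floor)
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$allocation_ratio <= 0 || cfg$allocation_ratio >= 1)
    stop("allocation_ratio must lie in (0, 1)", call. = FALSE)
  if (cfg$dp_floor < 0 || cfg$dp_floor > 1)
    stop("dp_floor must lie in [0, 1]", call. = FALSE)
  if (cfg$te_icm_ratio <= 0 || cfg$te_icm_ratio >= 1)
    stop("te_icm_ratio must lie in (0, 1)", call. = FALSE)
  if (cfg$intensity_cap <= 0) stop("intensity_cap must be positive", call. = FALSE)
  bins <- cfg$stage_bins
  if (!is.data.frame(bins) || nrow(bins) == 0L)
    stop("stage_bins must be a non-empty data frame", call. = FALSE)
  if (is.unsorted(bins$lower, strictly = TRUE) ||
      any(bins$upper[-nrow(bins)] != bins$lower[-1L]))
    stop("stage bins must be ordered and non-overlapping", call. = FALSE)
  em <- cfg$emission
  need <- expand.grid(lineage = c(LINEAGES, "TE"), channel = CHANNELS,
                      stringsAsFactors = FALSE)
  have <- paste(em$lineage, em$channel)
  miss <- setdiff(paste(need$lineage, need$channel), have)
  if (length(miss))
    stop("emission table is missing entries for: ",
         paste(miss, collapse = "; "), call. = FALSE)
  # DP must co-express both markers: its mean sits between the negative and
  # positive means on each channel
  for (ch in CHANNELS) {
    m <- function(l) em$mean_log[em$lineage == l & em$channel == ch][1L]
    lo <- min(m("EPI"), m("PrE")); hi <- max(m("EPI"), m("PrE"))
    if (m("DP") <= lo || m("DP") > hi + 1e-9)
      stop("emission means must place DP between the negative and positive ",
           "levels on channel ", ch, call. = FALSE)
  }
  cfg
}

#' Expected progenitor (DP) fraction at a given embryo size
#'
#' Linear interpolation of the expected double-positive fraction of the ICM:
#' 1 at 32 total cells, declining to `floor` at
#' `cfg$allocation_completion_size`, constant thereafter.
#'
#' @param total Total cell count(s).
#' @param cfg A [generator_config()].
#' @param floor Residual fraction after completion; defaults to
#'   `cfg$dp_floor`. Pass 0 for the in-culture commitment schedule.
#' @return Expected DP fraction(s) in `[floor, 1]`.
#' @export
dp_fraction_expected <- function(total, cfg, floor = cfg$dp_floor) {
  span <- cfg$allocation_completion_size - 32
  p <- 1 - (1 - floor) * (total - 32) / span
  pmin(pmax(p, floor), 1)
}

#' Incremental allocation of ICM cells to lineages
#'
#' Draws one lineage label per ICM cell under the incremental-allocation
#' model: each cell remains an uncommitted double-positive (DP) progenitor
#' with the stage-dependent probability given by [dp_fraction_expected()];
#' committed cells are PrE with probability `allocation_ratio` and EPI
#' otherwise. In embryos beyond `dn_late_threshold` total cells, each EPI
#' cell independently downregulates NANOG (label DN) with probability
#' `dn_late_fraction`. Commitment is irreversible: labels are drawn once and
#' never revised by the generator.
#'
#' @param n_icm Number of ICM cells to label.
#' @param target_total Total cell count of the embryo (sets the stage).
#' @param cfg A [generator_config()].
#' @param seed Optional seed for reproducibility.
#' @return Character vector of length `n_icm` with values in
#'   `EPI`, `PrE`, `DP`, `DN`.
#' @export
simulate_allocation <- function(n_icm, target_total, cfg, seed = NULL) {
  if (!is.numeric(n_icm) || n_icm < 1)
    stop("n_icm must be a positive integer", call. = FALSE)
  if (!is.numeric(target_total) || target_total < 1)
    stop("target_total must be a positive integer", call. = FALSE)
  validate_generator_config(cfg)
  with_seed(seed, {
    p_dp <- dp_fraction_expected(target_total, cfg)
    labels <- ifelse(stats::runif(n_icm) < p_dp, "DP",
                     ifelse(stats::runif(n_icm) < cfg$allocation_ratio,
                            "PrE", "EPI"))
    if (target_total > cfg$dn_late_threshold) {
      epi <- which(labels == "EPI")
      labels[epi[stats::runif(length(epi)) < cfg$dn_late_fraction]] <- "DN"
    }
    labels
  })
}

emission_lookup <- function(cfg, lineage, channel) {
  em <- cfg$emission
  idx <- match(paste(lineage, channel), paste(em$lineage, em$channel))
  if (anyNA(idx))
    stop("emission table has no entry for (",
         paste(unique(lineage[is.na(idx)]), collapse = ","), ", ", channel,
         ")", call. = FALSE)
  list(mean = em$mean_log[idx], sd = em$sd_log[idx])
}

#' Emit fluorescence measurements for one synthetic embryo
#'
#' Forward model of the confocal measurement: each cell receives a depth `z`
#' uniform on the nuclear span; its log intensity on each channel is the
#' lineage emission mean plus a biological deviate, plus the embryo's true
#' depth-decay slope times `z`, plus measurement noise; the linear-scale
#' value is exponentiated and clipped to the 8-bit range. Cells clipped at
#' saturation on either channel are flagged in the `clipped` column.
#'
#' @param icm_labels Character vector of ICM lineage labels (from
#'   [simulate_allocation()]).
#' @param n_te Number of trophectoderm cells to add.
#' @param cfg A [generator_config()].
#' @param embryo_id,litter_id Identifiers stored on every row.
#' @param condition,regime,culture_h Embryo-level metadata.
#' @param seed Optional seed.
#' @return A cell table (data frame, one row per cell) with positions,
#'   compartment, raw intensities, the generator-true lineage and the
#'   generator-true per-channel decay slopes.
#' @export
emit_fluorescence <- function(icm_labels, n_te, cfg, embryo_id = "E1",
                              litter_id = "L1", condition = "none",
                              regime = "none", culture_h = 0, seed = NULL) {
  validate_generator_config(cfg)
  with_seed(seed, {
    n <- length(icm_labels) + n_te
    lineage <- c(icm_labels, rep(NA_character_, n_te))
    profile <- c(icm_labels, rep("TE", n_te))
    slope_embryo <- stats::rnorm(1, cfg$decay_mean, cfg$decay_sd)
    z <- stats::runif(n, 0, cfg$z_range)
    cells <- data.frame(
      embryo_id = embryo_id, cell_id = paste0(embryo_id, "_c", seq_len(n)),
      litter_id = litter_id,
      x = stats::runif(n, 0, 80), y = stats::runif(n, 0, 80), z = z,
      compartment = c(rep("ICM", length(icm_labels)), rep("TE", n_te)),
      true_lineage = lineage, condition = condition, regime = regime,
      culture_h = culture_h, stringsAsFactors = FALSE)
    clipped <- rep(FALSE, n)
    for (ch in CHANNELS) {
      em <- emission_lookup(cfg, profile, ch)
      slope_ch <- slope_embryo +
        stats::rnorm(1, 0, cfg$decay_channel_jitter_sd)
      log_i <- em$mean + stats::rnorm(n, 0, em$sd) + slope_ch * z +
        stats::rnorm(n, 0, cfg$noise_sd)
      lin <- exp(log_i)
      clipped <- clipped | lin > cfg$intensity_cap
      cells[[paste0("raw_", ch)]] <- pmin(pmax(lin, 0), cfg$intensity_cap)
      cells[[paste0("true_slope_", ch)]] <- slope_ch
    }
    cells$clipped <- clipped
    cells
  })
}

# sample an embryo total within half-open bin [lower, upper)
sample_total <- function(lower, upper, cfg) {
  hi <- min(upper, cfg$max_total)
  sample(seq.int(lower, hi - 1L), 1L)
}

make_embryo <- function(total, cfg, embryo_id, litter_id, regime,
                        target_total = total, condition = "none",
                        culture_h = 0) {
  n_te <- round(cfg$te_icm_ratio * total)
  n_icm <- total - n_te
  labels <- simulate_allocation(n_icm, target_total, cfg)
  emit_fluorescence(labels, n_te, cfg, embryo_id = embryo_id,
                    litter_id = litter_id, condition = condition,
                    regime = regime, culture_h = culture_h)
}

#' Generate a cohort of synthetic blastocysts
#'
#' Draws `n_per_bin` embryos per stage bin with total cell counts uniform
#' within the bin edges, a constant TE:ICM ratio, stage-appropriate
#' incremental lineage allocation and the full fluorescence forward model.
#' The result is byte-identical for a given `cfg$seed`.
#'
#' @param cfg A [generator_config()].
#' @return A cell table (data frame, one row per cell) covering all embryos,
#'   with the configuration attached as attribute `config`.
#' @export
generate_cohort <- function(cfg = generator_config()) {
  validate_generator_config(cfg)
  bins <- cfg$stage_bins
  if (nrow(bins) == 0L) stop("stage bin list is empty", call. = FALSE)
  n_embryos <- nrow(bins) * cfg$n_per_bin
  seeds <- derive_seeds(cfg$seed, n_embryos)
  out <- vector("list", n_embryos)
  k <- 0L
  for (b in seq_len(nrow(bins))) {
    for (i in seq_len(cfg$n_per_bin)) {
      k <- k + 1L
      out[[k]] <- with_seed(seeds[k], {
        total <- sample_total(bins$lower[b], bins$upper[b], cfg)
        make_embryo(total, cfg, embryo_id = sprintf("E%03d", k),
                    litter_id = sprintf("L%d_%d", b, ceiling(i / 7)),
                    regime = bins$label[b])
      })
    }
  }
  cohort <- do.call(rbind, out)
  rownames(cohort) <- NULL
  attr(cohort, "config") <- cfg
  cohort
}

#' Generate a half-, single- or double-sized embryo
#'
#' Emulates embryos aggregated from two 8-cell embryos (double) or single
#' blastomere-derived embryos (half): the cell number of every compartment is
#' scaled by `scale` relative to a control embryo at the terminal stage, while
#' lineage allocation follows the control embryo's developmental stage, so ICM
#' composition is scale-invariant by construction.
#'
#' @param cfg A [generator_config()].
#' @param scale One of 0.5, 1 or 2.
#' @param embryo_id,litter_id Identifiers.
#' @param seed Optional seed.
#' @return A single-embryo cell table.
#' @export
make_scaled_embryo <- function(cfg, scale = 1, embryo_id = "S1",
                               litter_id = "L1", seed = NULL) {
  if (!scale %in% c(0.5, 1, 2))
    stop("scale must be one of 0.5, 1, 2", call. = FALSE)
  validate_generator_config(cfg)
  with_seed(seed, {
    dev_total <- sample(120:170, 1L)
    total <- round(scale * dev_total)
    make_embryo(total, cfg, embryo_id = embryo_id, litter_id = litter_id,
                regime = paste0("scale_", scale), target_total = dev_total,
                condition = "none")
  })
}
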