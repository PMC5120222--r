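CONDITIONS <- c("Control", "FGF4", "MEKi", "FGFRi")

#' Specification of a treatment regime
#'
#' A regime is a condition applied from a collection stage for a number of
#' hours in culture, optionally followed by a second condition (release
#' experiments).
#'
#' @param condition One of `Control`, `FGF4`, `MEKi`, `FGFRi`.
#' @param start_stage Collection stage: a stage-bin label or `"8-cell"`.
#' @param duration_h Hours in culture under `condition`.
#' @param sequence Optional second phase: a list with `condition` and
#'   `duration_h`.
#' @return Object of class `treatment_spec`.
#' @export
treatment_spec <- function(condition, start_stage = "32-64",
                           duration_h = 30, sequence = NULL) {
  condition <- match.arg(condition, CONDITIONS)
  if (duration_h <= 0) stop("duration_h must be positive", call. = FALSE)
  if (!is.null(sequence)) {
    sequence$condition <- match.arg(sequence$condition, CONDITIONS)
    if (is.null(sequence$duration_h) || sequence$duration_h <= 0)
      stop("sequence duration_h must be positive", call. = FALSE)
  }
  structure(list(condition = condition, start_stage = start_stage,
                 duration_h = duration_h, sequence = sequence),
            class = "treatment_spec")
}

# commitment schedule during culture: same linear law as the generator but
# with floor 0 -- extended culture completes allocation, the residual DP
# floor models developmental delay in freshly collected embryos only
culture_retention <- function(n_start, n_end, cfg) {
  p0 <- dp_fraction_expected(max(n_start, 32), cfg, floor = 0)
  p1 <- dp_fraction_expected(n_end, cfg, floor = 0)
  if (p0 <= 0) return(0)
  min(1, p1 / p0)
}

grow_size <- function(n0, hours, doubling_h, cap) {
  max(n0, min(round(n0 * 2^(hours / doubling_h)), cap))
}

resolve_lineages <- function(labels, condition, retention, cfg,
                             fgf4_dn_prob) {
  n <- length(labels)
  dp <- which(labels == "DP")
  if (length(dp)) {
    if (condition == "FGF4") {
      labels[dp] <- "PrE"  # saturating signal converts every progenitor
    } else {
      stays <- stats::runif(length(dp)) < retention
      commit <- dp[!stays]
      if (length(commit)) {
        labels[commit] <- switch(condition,
          Control = ifelse(stats::runif(length(commit)) <
                             cfg$allocation_ratio, "PrE", "EPI"),
          MEKi = "EPI", FGFRi = "EPI")
      }
    }
  }
  if (condition == "FGF4") {
    epi <- which(labels == "EPI")
    if (length(epi) && fgf4_dn_prob > 0)
      labels[epi[stats::runif(length(epi)) < fgf4_dn_prob]] <- "DN"
  }
  if (condition %in% c("MEKi", "FGFRi"))
    labels[labels == "DN"] <- "EPI"  # NANOG maintained / restored
  labels
}

apply_treatment_embryo <- function(emb, spec, cfg, doubling_h, cap,
                                   fgf4_dn_prob) {
  id <- emb$embryo_id[1L]
  n0 <- nrow(emb)
  n_end <- grow_size(n0, spec$duration_h, doubling_h, cap)
  # divisions uniformly at random: each new cell inherits the compartment
  # and current lineage of a random existing cell
  if (n_end > n0) {
    parents <- sample.int(n0, n_end - n0, replace = TRUE)
    add <- emb[parents, , drop = FALSE]
    emb <- rbind(emb, add)
  }
  icm <- emb$compartment == "ICM"
  retention <- culture_retention(n0, n_end, cfg)
  labels <- resolve_lineages(emb$true_lineage[icm], spec$condition,
                             retention, cfg, fgf4_dn_prob)
  # committed single-positive labels are never flipped between EPI and PrE
  emit_fluorescence(labels, sum(!icm), cfg, embryo_id = id,
                    litter_id = emb$litter_id[1L],
                    condition = spec$condition,
                    regime = spec$start_stage,
                    culture_h = emb$culture_h[1L] + spec$duration_h)
}

make_morula_embryo <- function(cfg, embryo_id, litter_id = "L8c") {
  # an 8-cell embryo has no blastocyst lineages yet; represent its future
  # ICM as an all-progenitor pool seeded at the 32-cell allocation start
  n <- 8L
  n_te <- round(cfg$te_icm_ratio * n)
  emit_fluorescence(rep("DP", n - n_te), n_te, cfg, embryo_id = embryo_id,
                    litter_id = litter_id, condition = "none",
                    regime = "8-cell")
}

#' Simulate an FGF-pathway modulation experiment on a cohort
#'
#' Grows each embryo in culture towards the 120-170-cell terminal range
#' (exponential growth, per-embryo terminal size drawn uniformly) and applies
#' the condition's commitment rules: only uncommitted double-positive
#' progenitors change fate. Under FGF4 every progenitor becomes PrE and EPI
#' cells downregulate NANOG (DN) with probability `fgf4_dn_prob`; under
#' MEKi/FGFRi committing progenitors become EPI and NANOG is maintained
#' (DN reverts to EPI); under Control progenitors commit on the normal
#' schedule, splitting `allocation_ratio : 1 - allocation_ratio` between PrE
#' and EPI. Committed EPI and PrE labels are never changed. Fluorescence is
#' re-emitted for the post-treatment expression state.
#'
#' @param cohort Cell table with generator-true lineages, or `NULL` with
#'   `spec$start_stage = "8-cell"` to start `n_embryos` embryos before
#'   lineage allocation.
#' @param spec A [treatment_spec()].
#' @param cfg A [generator_config()].
#' @param n_embryos Number of embryos when starting from the 8-cell stage.
#' @param fgf4_dn_prob Probability that an EPI cell downregulates NANOG
#'   under FGF4.
#' @param doubling_h Cell-cycle doubling time in culture (hours).
#' @param terminal_range Range the per-embryo terminal size is drawn from.
#' @param seed Optional seed.
#' @return A cell table of the treated cohort.
#' @export
apply_treatment <- function(cohort, spec, cfg = generator_config(),
                            n_embryos = 10L, fgf4_dn_prob = 0.3,
                            doubling_h = 10, terminal_range = c(120, 170),
                            seed = NULL) {
  stopifnot(inherits(spec, "treatment_spec"))
  validate_generator_config(cfg)
  with_seed(seed, {
    if (is.null(cohort)) {
      if (!identical(spec$start_stage, "8-cell"))
        stop("a cohort is required unless start_stage is \"8-cell\"",
             call. = FALSE)
      cohort <- do.call(rbind, lapply(seq_len(n_embryos), function(i) {
        make_morula_embryo(cfg, embryo_id = sprintf("T%03d", i))
      }))
    }
    if (!"true_lineage" %in% names(cohort))
      stop("cohort lacks generator-true lineages", call. = FALSE)
    out <- lapply(split(cohort, cohort$embryo_id), function(emb) {
      cap <- round(stats::runif(1, terminal_range[1], terminal_range[2]))
      apply_treatment_embryo(emb, spec, cfg, doubling_h, cap, fgf4_dn_prob)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Progenitor-pool predictor of treatment outcome
#'
#' Deterministic bookkeeping on the ICM fractions at the beginning of
#' treatment: the proportion of committed single-positive cells is preserved
#' and only the progenitor (DP) pool is redistributed. FGF4 sends all DP to
#' PrE (and, with probability `fgf4_dn_prob`, EPI to DN); MEKi/FGFRi send DP
#' and DN to EPI; Control splits DP `rho : 1 - rho` between PrE and EPI.
#'
#' @param initial Named fractions `c(EPI=, PrE=, DP=, DN=)` summing to 1.
#' @param condition Treatment condition.
#' @param rho Terminal PrE share of allocated cells.
#' @param fgf4_dn_prob NANOG-downregulation probability under FGF4.
#' @return Object of class `outcome_prediction`: predicted fractions and the
#'   rule applied.
#' @export
predict_outcome <- function(initial, condition, rho = 0.6,
                            fgf4_dn_prob = 0) {
  condition <- match.arg(condition, CONDITIONS)
  if (!all(LINEAGES %in% names(initial)))
    stop("initial fractions must be named EPI, PrE, DP, DN", call. = FALSE)
  f <- initial[LINEAGES]
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
    stop("initial fractions must be non-negative and sum to 1", call. = FALSE)
  out <- switch(condition,
    Control = c(EPI = unname(f["EPI"] + (1 - rho) * f["DP"]),
                PrE = unname(f["PrE"] + rho * f["DP"]),
                DP = 0, DN = unname(f["DN"])),
    FGF4 = c(EPI = unname(f["EPI"] * (1 - fgf4_dn_prob)),
             PrE = unname(f["PrE"] + f["DP"]),
             DP = 0,
             DN = unname(f["DN"] + f["EPI"] * fgf4_dn_prob)),
    c(EPI = unname(f["EPI"] + f["DP"] + f["DN"]),
      PrE = unname(f["PrE"]), DP = 0, DN = 0))  # MEKi / FGFRi
  structure(list(fractions = out, condition = condition, rho = rho,
                 fgf4_dn_prob = fgf4_dn_prob),
            class = "outcome_prediction")
}

#' @export
print.outcome_prediction <- function(x, ...) {
  cat("Predicted ICM composition after", x$condition, "treatment:\n")
  print(round(x$fractions, 3))
  invisible(x)
}

#' Two-phase (release) treatment experiment
#'
#' Runs the first phase of `spec`, then releases the cohort into the
#' sequence condition for its duration, and summarises the generator-true
#' composition after each phase.
#'
#' @param cohort Starting cohort, or `NULL` with `start_stage = "8-cell"`.
#' @param spec A [treatment_spec()] with a non-`NULL` `sequence`.
#' @param cfg A [generator_config()].
#' @param ... Passed on to [apply_treatment()].
#' @param seed Optional seed.
#' @return List with `phase1`, `phase2` cell tables and per-phase
#'   composition summaries (generator truth).
#' @export
release_experiment <- function(cohort, spec, cfg = generator_config(), ...,
                               seed = NULL) {
  stopifnot(inherits(spec, "treatment_spec"))
  if (is.null(spec$sequence))
    stop("release_experiment needs a spec with a sequence phase",
         call. = FALSE)
  with_seed(seed, {
    phase1 <- apply_treatment(cohort, spec, cfg, ...)
    spec2 <- treatment_spec(spec$sequence$condition,
                            start_stage = "release",
                            duration_h = spec$sequence$duration_h)
    phase2 <- apply_treatment(phase1, spec2, cfg, ...)
    open_bins <- data.frame(label = "all", lower = 1, upper = Inf)
    list(phase1 = phase1, phase2 = phase2,
         composition_phase1 = composition(phase1, "true_lineage", open_bins),
         composition_phase2 = composition(phase2, "true_lineage", open_bins))
  })
}
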