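true_fractions <- function(cohort) {
  lab <- cohort$true_lineage[cohort$compartment == "ICM"]
  c(EPI = mean(lab == "EPI"), PrE = mean(lab == "PrE"),
    DP = mean(lab == "DP"), DN = mean(lab == "DN"))
}

test_that("predict_outcome implements the progenitor-pool bookkeeping", {
  init <- c(EPI = 0.3, PrE = 0.5, DP = 0.2, DN = 0)
  fgf <- predict_outcome(init, "FGF4")
  expect_equal(fgf$fractions,
               c(EPI = 0.3, PrE = 0.7, DP = 0, DN = 0))
  meki <- predict_outcome(c(EPI = 0.3, PrE = 0.5, DP = 0.15, DN = 0.05),
                          "MEKi")
  expect_equal(meki$fractions, c(EPI = 0.5, PrE = 0.5, DP = 0, DN = 0))
  ctl <- predict_outcome(init, "Control", rho = 0.6)
  expect_equal(ctl$fractions,
               c(EPI = 0.3 + 0.4 * 0.2, PrE = 0.5 + 0.6 * 0.2, DP = 0,
                 DN = 0))
  # mass conservation
  for (cond in c("Control", "FGF4", "MEKi", "FGFRi"))
    expect_equal(sum(predict_outcome(init, cond)$fractions), 1)

  # no progenitors: committed cells cannot change fate
  committed <- c(EPI = 0.4, PrE = 0.6, DP = 0, DN = 0)
  for (cond in c("Control", "FGF4", "MEKi", "FGFRi"))
    expect_equal(predict_outcome(committed, cond)$fractions, committed)

  expect_error(predict_outcome(c(EPI = 0.5, PrE = 0.5, DP = 0.5, DN = 0),
                               "FGF4"), "sum to 1")
})

test_that("FGF4 from the 8-cell stage yields an all-PrE ICM; MEKi an all-EPI ICM", {
  cfg <- small_cfg()
  fgf <- apply_treatment(NULL, treatment_spec("FGF4", "8-cell", 48),
                         cfg, n_embryos = 6, seed = 51)
  expect_equal(unname(true_fractions(fgf)["PrE"]), 1)
  expect_true(all(table(fgf$embryo_id) >= 120))

  meki <- apply_treatment(NULL, treatment_spec("MEKi", "8-cell", 48),
                          cfg, n_embryos = 6, seed = 52)
  expect_equal(unname(true_fractions(meki)["EPI"]), 1)
})

test_that("late treatment is indistinguishable from control", {
  cfg <- small_cfg(n_per_bin = 12L,
                   stage_bins = data.frame(label = "120-150", lower = 120,
                                           upper = 150))
  coh <- generate_cohort(cfg)
  late <- apply_treatment(coh, treatment_spec("MEKi", "120-150", 15),
                          cfg, seed = 53)
  ctl <- apply_treatment(coh, treatment_spec("Control", "120-150", 15),
                         cfg, seed = 54)
  f_late <- true_fractions(late)
  f_ctl <- true_fractions(ctl)
  expect_lt(max(abs(f_late[c("EPI", "PrE")] - f_ctl[c("EPI", "PrE")])),
            0.06)
})

test_that("the progenitor-pool predictor matches the simulated outcome", {
  cfg <- small_cfg(n_per_bin = 200L,
                   stage_bins = data.frame(label = "64-90", lower = 64,
                                           upper = 90))
  coh <- generate_cohort(cfg)
  init <- true_fractions(coh)
  for (cond in c("Control", "FGF4", "MEKi")) {
    trt <- apply_treatment(coh, treatment_spec(cond, "64-90", 30), cfg,
                           fgf4_dn_prob = 0.3, seed = 55)
    pred <- predict_outcome(init, cond, rho = cfg$allocation_ratio,
                            fgf4_dn_prob = if (cond == "FGF4") 0.3 else 0)
    expect_lt(max(abs(true_fractions(trt) - pred$fractions)), 0.05)
  }
})

test_that("committed cells never flip lineage under any condition sequence", {
  cfg <- small_cfg(n_per_bin = 4L,
                   stage_bins = data.frame(label = "64-90", lower = 64,
                                           upper = 90))
  coh <- generate_cohort(cfg)
  seqs <- list(c("FGF4", "Control"), c("MEKi", "Control"),
               c("FGF4", "MEKi"), c("Control", "FGF4"))
  for (s in seqs) {
    spec <- treatment_spec(s[1], "64-90", 24,
                           sequence = list(condition = s[2],
                                           duration_h = 18))
    out <- release_experiment(coh, spec, cfg, seed = 56)
    for (ph in list(out$phase1, out$phase2)) {
      before <- coh$true_lineage[match(ph$cell_id, coh$cell_id)]
      after <- ph$true_lineage
      committed <- !is.na(before) & before %in% c("EPI", "PrE")
      # EPI may later downregulate NANOG (DN) but never becomes PrE,
      # and PrE never becomes EPI
      expect_false(any(before[committed] == "EPI" &
                         after[committed] == "PrE"))
      expect_false(any(before[committed] == "PrE" &
                         after[committed] %in% c("EPI", "DN")))
    }
  }
})

test_that("release regimes reproduce the published sequences", {
  cfg <- small_cfg()
  # FGF4 for 30 h exhausts progenitors; release into control medium leaves
  # an ICM of only PrE cells
  spec <- treatment_spec("FGF4", "8-cell", 30,
                         sequence = list(condition = "Control",
                                         duration_h = 18))
  out <- release_experiment(NULL, spec, cfg, n_embryos = 8, seed = 57)
  expect_equal(mean(out$composition_phase2$frac_pre), 1)

  # MEKi for 30 h retains roughly half the ICM as progenitors; release
  # regenerates a PrE compartment alongside EPI
  spec2 <- treatment_spec("MEKi", "8-cell", 30,
                          sequence = list(condition = "Control",
                                          duration_h = 18))
  out2 <- release_experiment(NULL, spec2, cfg, n_embryos = 8, seed = 58)
  expect_gt(mean(out2$composition_phase1$frac_dp), 0.3)
  expect_gt(mean(out2$composition_phase2$frac_pre), 0.1)
  expect_gt(mean(out2$composition_phase2$frac_epi), 0.1)
  expect_equal(mean(out2$composition_phase2$frac_dp), 0)

  # a control phase after a control phase is still a control outcome
  spec3 <- treatment_spec("Control", "64-90", 20,
                          sequence = list(condition = "Control",
                                          duration_h = 20))
  coh <- generate_cohort(small_cfg(
    n_per_bin = 10L,
    stage_bins = data.frame(label = "64-90", lower = 64, upper = 90)))
  out3 <- release_experiment(coh, spec3, cfg, seed = 59)
  one <- apply_treatment(coh, treatment_spec("Control", "64-90", 40), cfg,
                         seed = 60)
  f2 <- colMeans(out3$composition_phase2[c("frac_epi", "frac_pre",
                                           "frac_dp")])
  f1 <- colMeans(composition(one, "true_lineage",
                             data.frame(label = "all", lower = 1,
                                        upper = Inf))[c("frac_epi",
                                                        "frac_pre",
                                                        "frac_dp")])
  expect_lt(max(abs(f2 - f1)), 0.06)
})

test_that("predicted deviation from control grows with the progenitor pool", {
  # stage dose: more progenitors at treatment onset, larger deviation
  dp_levels <- c(0, 0.2, 0.4, 0.6)
  tv <- vapply(dp_levels, function(dp) {
    init <- c(EPI = (1 - dp) * 0.4, PrE = (1 - dp) * 0.6, DP = dp, DN = 0)
    fgf <- predict_outcome(init, "FGF4")$fractions
    ctl <- predict_outcome(init, "Control")$fractions
    sum(abs(fgf - ctl)) / 2
  }, numeric(1))
  expect_true(all(diff(tv) >= 0))
})

test_that("treatment specs validate their arguments", {
  expect_error(treatment_spec("Heat"), "arg")
  expect_error(treatment_spec("FGF4", duration_h = 0), "positive")
  expect_error(treatment_spec("FGF4", sequence = list(condition = "MEKi")),
               "duration")
  expect_error(apply_treatment(NULL, treatment_spec("FGF4", "64-90", 10)),
               "8-cell")
  coh <- generate_cohort(small_cfg(n_per_bin = 1L))
  coh$true_lineage <- NULL
  expect_error(apply_treatment(coh, treatment_spec("FGF4"),
                               small_cfg()), "true lineages")
  expect_error(release_experiment(coh, treatment_spec("FGF4")), "sequence")
})
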