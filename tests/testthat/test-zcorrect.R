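make_line_embryo <- function(intercept = 5, slope = -0.02, n = 20,
                             id = "E1") {
  z <- seq(0, 57, length.out = n)
  data.frame(embryo_id = id, cell_id = paste0(id, "_c", seq_len(n)),
             x = 0, y = 0, z = z, compartment = "ICM",
             raw_gata6 = exp(intercept + slope * z),
             raw_nanog = exp(intercept + slope * z),
             stringsAsFactors = FALSE)
}

test_that("OLS decay fit is exact on noiseless data and flat data", {
  emb <- make_line_embryo(intercept = 5, slope = -0.02)
  f <- suppressWarnings(fit_decay(emb, "gata6"))  # perfect fit
  expect_equal(f$slope, -0.02, tolerance = 1e-10)
  expect_equal(f$intercept, 5, tolerance = 1e-10)
  expect_lt(f$se, 1e-10)

  flat <- make_line_embryo(intercept = 4, slope = 0)
  f0 <- suppressWarnings(fit_decay(flat, "nanog"))
  expect_equal(f0$slope, 0, tolerance = 1e-12)
  expect_equal(f0$se, 0, tolerance = 1e-12)
})

test_that("decay fitting rejects embryos with fewer than 3 usable cells", {
  tiny <- make_line_embryo(n = 2)
  expect_error(fit_decay(tiny, "gata6"), "fewer than 3")
  # cohort-level fitting downgrades the error to a warning and drops the embryo
  coh <- rbind(make_line_embryo(n = 10, id = "A"),
               make_line_embryo(n = 2, id = "B"))
  w <- capture_warnings(fits <- fit_decay_cohort(coh))
  expect_true(any(grepl("fewer than 3", w)))
  expect_setequal(unique(fits$embryo_id), "A")
})

test_that("empirical-Bayes shrinkage follows the precision-weighted formula", {
  # two embryos, slopes -0.03 and -0.01, equal standard errors 0.002:
  # tau2 = var(b) - mean(se^2) = 2e-4 - 4e-6 = 1.96e-4
  # w = 1.96e-4 / 2e-4 = 0.98
  # b*_1 = 0.98(-0.03) + 0.02(-0.02) = -0.02980
  # b*_2 = 0.98(-0.01) + 0.02(-0.02) = -0.01020
  fits <- data.frame(embryo_id = c("A", "B"), channel = "gata6",
                     intercept = 5, slope = c(-0.03, -0.01), se = 0.002,
                     n = 50)
  shr <- eb_shrink(fits)
  expect_equal(shr$model$mean_slope, -0.02)
  expect_equal(shr$model$tau2, 1.96e-4)
  expect_equal(shr$fits$shrunk_slope, c(-0.0298, -0.0102))
})

test_that("shrinkage limits behave: identical slopes, dominant noise, single embryo", {
  # identical slopes: b* = b = mean for everyone
  same <- data.frame(embryo_id = c("A", "B", "C"), channel = "nanog",
                     intercept = 5, slope = -0.015, se = 0.001, n = 40)
  expect_equal(eb_shrink(same)$fits$shrunk_slope, rep(-0.015, 3))

  # measurement noise swamps the spread: tau2 truncates at 0, all b* = mean
  noisy <- data.frame(embryo_id = c("A", "B"), channel = "nanog",
                      intercept = 5, slope = c(-0.016, -0.014), se = 0.05,
                      n = 40)
  shr <- eb_shrink(noisy)
  expect_equal(shr$model$tau2, 0)
  expect_equal(shr$fits$shrunk_slope, rep(-0.015, 2))

  single <- data.frame(embryo_id = "A", channel = "gata6", intercept = 5,
                       slope = -0.02, se = 0.002, n = 40)
  expect_warning(s1 <- eb_shrink(single), "single embryo")
  expect_equal(s1$fits$shrunk_slope, -0.02)
})

test_that("shrunk slopes lie between raw slope and cohort mean, with reduced variance", {
  cfg <- small_cfg(seed = 21)
  coh <- generate_cohort(cfg)
  shr <- eb_shrink(fit_decay_cohort(coh))
  for (ch in unique(shr$fits$channel)) {
    f <- shr$fits[shr$fits$channel == ch, ]
    b_bar <- shr$model$mean_slope[shr$model$channel == ch]
    lo <- pmin(f$slope, b_bar) - 1e-12
    hi <- pmax(f$slope, b_bar) + 1e-12
    expect_true(all(f$shrunk_slope >= lo & f$shrunk_slope <= hi))
    expect_lte(var(f$shrunk_slope), var(f$slope))
  }
})

test_that("slope estimation is unbiased over many synthetic embryos", {
  cfg <- small_cfg()
  set.seed(22)
  diffs <- replicate(500, {
    lab <- simulate_allocation(12, 60, cfg)
    emb <- emit_fluorescence(lab, 24, cfg)
    fit_decay(emb, "gata6")$slope - emb$true_slope_gata6[1]
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(length(diffs)))
})

test_that("correction inverts the generator and is the identity when slope is zero", {
  # noiseless decayed single-lineage embryos: correction inverts the
  # generator exactly, leaving log intensity constant
  cfg <- degenerate_cfg(decay_mean = -0.02)
  coh <- do.call(rbind, lapply(1:3, function(i) {
    emit_fluorescence(rep("PrE", 30), n_te = 0, cfg,
                      embryo_id = paste0("P", i), seed = 30 + i)
  }))
  shr <- suppressWarnings(eb_shrink(fit_decay_cohort(coh)))  # perfect fits
  cor <- correct_z(coh, shr)
  spread <- tapply(cor$corrected_log_gata6, cor$embryo_id,
                   function(x) diff(range(x)))
  expect_lt(max(spread), 1e-9)

  # zero shrunk slope: corrected equals log(raw)
  emb <- make_line_embryo(slope = -0.015)
  fits <- data.frame(embryo_id = "E1", channel = c("gata6", "nanog"),
                     intercept = 5, slope = -0.015, se = 0.001, n = 20,
                     shrunk_slope = 0, weight = 1)
  out <- correct_z(emb, fits)
  expect_equal(out$corrected_log_gata6, log(emb$raw_gata6))
})

test_that("correction flattens the depth trend and improves slope estimates", {
  # Per-embryo raw slope estimates carry a large standard error (the lineage
  # mixture makes log intensity bimodal), so in embryos whose raw estimate
  # fluctuates towards zero the corrected trend can exceed the raw estimate
  # even though it is closer to the true decay. The strong majority of
  # embryos flattens, the spread of depth trends shrinks, and shrinkage
  # brings slopes closer to the generating truth on average.
  cfg <- small_cfg(seed = 23, n_per_bin = 40L,
                   stage_bins = data.frame(label = "90-120", lower = 90,
                                           upper = 120))
  coh <- generate_cohort(cfg)
  shr <- eb_shrink(fit_decay_cohort(coh))
  cor <- correct_z(coh, shr)
  per <- t(vapply(split(cor, cor$embryo_id), function(emb) {
    raw <- fit_decay(emb, "gata6")$slope
    res <- unname(coef(lm(corrected_log_gata6 ~ z, data = emb))[2])
    c(raw = raw, res = res, truth = emb$true_slope_gata6[1])
  }, numeric(3)))
  expect_gte(mean(abs(per[, "res"]) < abs(per[, "raw"])), 0.85)
  expect_lt(median(abs(per[, "res"])), 0.5 * median(abs(per[, "raw"])))

  f <- shr$fits[shr$fits$channel == "gata6", ]
  truth <- per[match(f$embryo_id, rownames(per)), "truth"]
  expect_lt(mean(abs(f$shrunk_slope - truth)), mean(abs(f$slope - truth)))
})

test_that("missing fits exclude the embryo from correction with a warning", {
  coh <- rbind(make_line_embryo(id = "A"), make_line_embryo(id = "B"))
  fits <- data.frame(embryo_id = "A", channel = c("gata6", "nanog"),
                     intercept = 5, slope = -0.02, se = 1e-3, n = 20,
                     shrunk_slope = -0.02, weight = 1)
  suppressWarnings(expect_warning(out <- correct_z(coh, fits), "excluded"))
  expect_setequal(unique(out$embryo_id), "A")
})
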