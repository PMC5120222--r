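#' Fit the depth-decay model for one embryo and channel
#'
#' Fluorescence decays multiplicatively with imaging depth; the decay is
#' modelled per embryo and channel by ordinary least squares of log raw
#' intensity on the Z coordinate, over all cells of the embryo. Raw values
#' are floored at `floor` a.u. before the log so 8-bit zeros stay finite.
#'
#' @param cells Cell table rows of a single embryo.
#' @param channel `"gata6"` or `"nanog"`.
#' @param floor Intensity floor applied before the log (a.u.).
#' @return A one-row data frame: `embryo_id`, `channel`, `intercept`,
#'   `slope`, `se`, `n`.
#' @export
fit_decay <- function(cells, channel, floor = 1) {
  assert_cells(cells, paste0("raw_", channel))
  id <- unique(cells$embryo_id)
  if (length(id) != 1L)
    stop("fit_decay expects cells of a single embryo", call. = FALSE)
  y <- log(pmax(cells[[paste0("raw_", channel)]], floor))
  z <- cells$z
  ok <- is.finite(y) & is.finite(z)
  if (sum(ok) < 3L)
    stop("degenerate decay fit for embryo ", id, " channel ", channel,
         ": fewer than 3 usable cells", call. = FALSE)
  fit <- stats::lm(y[ok] ~ z[ok])
  cf <- summary(fit)$coefficients
  data.frame(embryo_id = id, channel = channel,
             intercept = cf[1L, 1L], slope = cf[2L, 1L], se = cf[2L, 2L],
             n = sum(ok), stringsAsFactors = FALSE)
}

#' Fit depth-decay models for every embryo and channel in a cohort
#'
#' Embryos with fewer than 3 usable cells on a channel are excluded with a
#' warning rather than aborting the batch.
#'
#' @param cohort A cell table covering one or more embryos.
#' @param channels Channels to fit.
#' @param floor Intensity floor (a.u.).
#' @return Data frame of per-(embryo, channel) fits.
#' @export
fit_decay_cohort <- function(cohort, channels = CHANNELS, floor = 1) {
  pieces <- split(cohort, cohort$embryo_id)
  out <- list()
  for (ch in channels) {
    for (emb in pieces) {
      fit <- tryCatch(fit_decay(emb, ch, floor = floor),
                      error = function(e) {
                        warning(conditionMessage(e), call. = FALSE)
                        NULL
                      })
      if (!is.null(fit)) out[[length(out) + 1L]] <- fit
    }
  }
  if (!length(out)) stop("no embryo could be fitted", call. = FALSE)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Empirical-Bayes shrinkage of decay slopes towards the cohort mean
#'
#' Per-embryo slopes rest on a moderate number of cells and are unstable, so
#' they are shrunk towards the cohort (per-channel) average under the
#' standard normal-normal model: with `b_e` the raw slope and `se_e` its
#' standard error, the between-embryo variance is estimated by method of
#' moments, `tau2 = max(0, var(b) - mean(se^2))`, and the shrunk slope is
#' `b* = w_e b_e + (1 - w_e) mean(b)` with precision weight
#' `w_e = tau2 / (tau2 + se_e^2)`. With a single embryo on a channel,
#' shrinkage is skipped (`b* = b`) with a warning.
#'
#' @param fits Fit table from [fit_decay_cohort()].
#' @return A list of class `eb_shrinkage`: `fits` (the input with
#'   `shrunk_slope` and `weight` columns) and `model` (per-channel
#'   `mean_slope` and `tau2`).
#' @export
eb_shrink <- function(fits) {
  stopifnot(is.data.frame(fits),
            all(c("embryo_id", "channel", "slope", "se") %in% names(fits)))
  fits$shrunk_slope <- NA_real_
  fits$weight <- NA_real_
  model <- list()
  for (ch in unique(fits$channel)) {
    i <- which(fits$channel == ch)
    b <- fits$slope[i]
    se2 <- fits$se[i]^2
    b_bar <- mean(b)
    if (length(i) < 2L) {
      warning("single embryo on channel ", ch, ": shrinkage skipped",
              call. = FALSE)
      tau2 <- NA_real_
      fits$shrunk_slope[i] <- b
      fits$weight[i] <- 1
    } else {
      tau2 <- max(0, stats::var(b) - mean(se2))
      w <- if (tau2 == 0) rep(0, length(i)) else tau2 / (tau2 + se2)
      fits$shrunk_slope[i] <- w * b + (1 - w) * b_bar
      fits$weight[i] <- w
    }
    model[[ch]] <- data.frame(channel = ch, mean_slope = b_bar, tau2 = tau2,
                              stringsAsFactors = FALSE)
  }
  out <- list(fits = fits, model = do.call(rbind, c(model, list(make.row.names = FALSE))))
  class(out) <- "eb_shrinkage"
  out
}

#' @export
print.eb_shrinkage <- function(x, ...) {
  cat("Empirical-Bayes depth-decay shrinkage\n")
  print(x$model, row.names = FALSE)
  cat(nrow(x$fits), "embryo/channel fits\n")
  invisible(x)
}

#' Remove depth decay from a cohort's fluorescence values
#'
#' Subtracts the embryo- and channel-specific shrunk slope times `z` from the
#' log raw intensity, referencing every cell to the first optical section
#' (z = 0): `corrected_log = log(max(raw, floor)) - b* z`. Embryos lacking a
#' fit on any requested channel are excluded with a warning. Linear-scale
#' corrected values (`exp(corrected_log)`) are what the quadrant thresholds
#' operate on.
#'
#' @param cohort Cell table.
#' @param shrinkage An `eb_shrinkage` object (or a fit table with a
#'   `shrunk_slope` column).
#' @param channels Channels to correct.
#' @param floor Intensity floor (a.u.), matching the fit.
#' @return The cohort with `corrected_log_<channel>` columns added.
#' @export
correct_z <- function(cohort, shrinkage, channels = CHANNELS, floor = 1) {
  fits <- if (inherits(shrinkage, "eb_shrinkage")) shrinkage$fits else shrinkage
  stopifnot("shrunk_slope" %in% names(fits))
  keep <- rep(TRUE, nrow(cohort))
  for (ch in channels) {
    f <- fits[fits$channel == ch, ]
    idx <- match(cohort$embryo_id, f$embryo_id)
    missing_fit <- is.na(idx)
    if (any(missing_fit)) {
      warning("no ", ch, " decay fit for embryo(s) ",
              paste(unique(cohort$embryo_id[missing_fit]), collapse = ", "),
              "; excluded", call. = FALSE)
      keep <- keep & !missing_fit
    }
    b <- f$shrunk_slope[idx]
    cohort[[paste0("corrected_log_", ch)]] <-
      log(pmax(cohort[[paste0("raw_", ch)]], floor)) - b * cohort$z
  }
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
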