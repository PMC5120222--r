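#' Fixed-threshold quadrant classifier
#'
#' Thresholds on corrected linear-scale intensities (a.u. on the 8-bit
#' scale). A marker is scored positive when its value is greater than or
#' equal to the threshold, so cells sitting exactly on a threshold count as
#' positive.
#'
#' @param theta_gata6,theta_nanog GATA6 and NANOG thresholds in a.u.
#'   (default 50, established on late embryos where the committed
#'   populations are fully segregated).
#' @return Object of class `threshold_model`.
#' @export
threshold_model <- function(theta_gata6 = 50, theta_nanog = 50) {
  if (theta_gata6 <= 0 || theta_gata6 >= 255 ||
      theta_nanog <= 0 || theta_nanog >= 255)
    stop("thresholds must lie in (0, 255) a.u.", call. = FALSE)
  structure(list(theta_gata6 = theta_gata6, theta_nanog = theta_nanog,
                 scale = "linear"),
            class = "threshold_model")
}

#' Classify ICM cells by quadrant thresholding
#'
#' EPI: NANOG positive, GATA6 negative; PrE: GATA6 positive, NANOG negative;
#' DP: both positive; DN: both negative. Operates on the linear scale
#' obtained by inverting the corrected log intensities. Trophectoderm cells
#' are never classified (their `called_lineage` stays `NA`).
#'
#' @param cohort Cell table with `corrected_log_gata6` and
#'   `corrected_log_nanog` columns (see [correct_z()]).
#' @param model A [threshold_model()].
#' @return The cohort with a `called_lineage` column filled for ICM cells.
#' @export
classify_threshold <- function(cohort, model = threshold_model()) {
  stopifnot(inherits(model, "threshold_model"))
  need <- paste0("corrected_log_", CHANNELS)
  if (!all(need %in% names(cohort)))
    stop("corrected log intensities missing; run correct_z() first",
         call. = FALSE)
  g <- exp(cohort$corrected_log_gata6)
  n <- exp(cohort$corrected_log_nanog)
  icm <- cohort$compartment == "ICM"
  if (any(!is.finite(g[icm])) || any(!is.finite(n[icm])))
    stop("non-finite corrected intensities", call. = FALSE)
  if (any(g[icm] < 0) || any(n[icm] < 0))
    stop("negative intensities are not valid fluorescence values",
         call. = FALSE)
  # compare in the log domain (monotone, so equivalent to the linear rule)
  # to keep exact-threshold ties exact under the log/exp round trip
  gp <- cohort$corrected_log_gata6 >= log(model$theta_gata6)
  np <- cohort$corrected_log_nanog >= log(model$theta_nanog)
  lab <- ifelse(np & !gp, "EPI",
         ifelse(gp & !np, "PrE",
         ifelse(gp & np, "DP", "DN")))
  cohort$called_lineage <- ifelse(icm, lab, NA_character_)
  cohort
}

#' Reference-anchored k-means cluster centers
#'
#' Pools ICM cells of the early (progenitor-dominated) and late (fully
#' segregated) reference stages in (log GATA6, log NANOG) space and fits
#' k = 3 clusters (EPI, PrE, DP) by k-means with multiple restarts under a
#' fixed seed. Fitted centers are labelled by their coordinates (highest
#' NANOG is EPI, highest GATA6 is PrE, the remaining one is DP) and a fourth,
#' double-negative center is synthesized at (GATA6 of EPI, NANOG of PrE).
#'
#' @param cohort Corrected cell table.
#' @param reference_bins Stage-bin labels pooled as the reference
#'   distribution; `NULL` uses every ICM cell supplied (used when anchoring
#'   on control embryos of a cultured batch).
#' @param bins Stage-bin table used to stage embryos, see [stage_bins()].
#' @param k Number of fitted clusters.
#' @param seed Seed for the k-means restarts.
#' @param nstart Number of random restarts; the best inertia is kept.
#' @return Object of class `center_model` with a 4 x 2 `centers` matrix
#'   (rows EPI, PrE, DP, DN; columns gata6, nanog; log a.u.).
#' @export
fit_centers <- function(cohort, reference_bins = c("32-64", "120-150"),
                        bins = stage_bins(), k = 3, seed = 1L,
                        nstart = 10L) {
  need <- paste0("corrected_log_", CHANNELS)
  if (!all(need %in% names(cohort)))
    stop("corrected log intensities missing; run correct_z() first",
         call. = FALSE)
  cells <- cohort[cohort$compartment == "ICM", , drop = FALSE]
  if (!is.null(reference_bins)) {
    totals <- tapply(rep(1L, nrow(cohort)), cohort$embryo_id, sum)
    stage <- stage_bin(as.integer(totals), bins)
    ref_ids <- names(totals)[stage %in% reference_bins]
    if (!length(ref_ids))
      stop("no embryos fall in the reference bins ",
           paste(reference_bins, collapse = " + "), call. = FALSE)
    cells <- cells[cells$embryo_id %in% ref_ids, , drop = FALSE]
  }
  x <- cbind(gata6 = cells$corrected_log_gata6,
             nanog = cells$corrected_log_nanog)
  if (any(!is.finite(x))) stop("non-finite reference coordinates", call. = FALSE)
  if (nrow(unique(x)) < k)
    stop("fewer than k distinct reference points", call. = FALSE)
  km <- with_seed(seed, stats::kmeans(x, centers = k, nstart = nstart,
                                      iter.max = 100L))
  ctr <- km$centers
  i_epi <- which.max(ctr[, "nanog"])
  i_pre <- which.max(ctr[, "gata6"])
  if (i_epi == i_pre)
    stop("ambiguous center labelling: one cluster maximizes both markers",
         call. = FALSE)
  i_dp <- setdiff(seq_len(k), c(i_epi, i_pre))[1L]
  centers <- rbind(EPI = ctr[i_epi, ], PrE = ctr[i_pre, ], DP = ctr[i_dp, ],
                   DN = c(gata6 = unname(ctr[i_epi, "gata6"]),
                          nanog = unname(ctr[i_pre, "nanog"])))
  structure(list(centers = centers, reference_bins = reference_bins,
                 k = k, seed = seed),
            class = "center_model")
}

#' @export
print.center_model <- function(x, ...) {
  cat("k-means lineage centers (log a.u.), reference:",
      if (is.null(x$reference_bins)) "all supplied cells"
      else paste(x$reference_bins, collapse = " + "), "\n")
  print(round(x$centers, 3))
  invisible(x)
}

#' Assign ICM cells to the nearest lineage center
#'
#' Euclidean distance in (log GATA6, log NANOG) space; ties are broken by the
#' fixed priority EPI > PrE > DP > DN. Trophectoderm cells are never
#' classified.
#'
#' @param cohort Corrected cell table.
#' @param model A [fit_centers()] model.
#' @return The cohort with a `called_lineage` column filled for ICM cells.
#' @export
assign_by_centers <- function(cohort, model) {
  stopifnot(inherits(model, "center_model"))
  need <- paste0("corrected_log_", CHANNELS)
  if (!all(need %in% names(cohort)))
    stop("corrected log intensities missing; run correct_z() first",
         call. = FALSE)
  icm <- cohort$compartment == "ICM"
  x <- cbind(cohort$corrected_log_gata6, cohort$corrected_log_nanog)
  if (any(!is.finite(x[icm, ])))
    stop("non-finite corrected coordinates", call. = FALSE)
  ctr <- model$centers[LINEAGES, , drop = FALSE]  # priority order
  d2 <- do.call(cbind, lapply(seq_len(nrow(ctr)), function(j) {
    (x[, 1] - ctr[j, "gata6"])^2 + (x[, 2] - ctr[j, "nanog"])^2
  }))
  lab <- LINEAGES[apply(d2, 1L, which.min)]  # which.min takes first on ties
  cohort$called_lineage <- ifelse(icm, lab, NA_character_)
  cohort
}

#' Re-anchor cluster centers on the control embryos of a batch
#'
#' Cultured or treated batches are acquired with their own imaging
#' parameters, so centers are re-fit on the pooled ICM cells of that batch's
#' control embryos and then applied to every condition of the batch.
#'
#' @param cohort Corrected cell table of the batch, with a `condition`
#'   column.
#' @param control Value of `condition` identifying control embryos.
#' @param seed,nstart Passed to [fit_centers()].
#' @return A `center_model` fitted on the controls.
#' @export
refit_for_batch <- function(cohort, control = "Control", seed = 1L,
                            nstart = 10L) {
  if (!"condition" %in% names(cohort))
    stop("cohort has no condition column", call. = FALSE)
  ctl <- cohort[cohort$condition == control, , drop = FALSE]
  if (!nrow(ctl))
    stop("no control embryos in this batch", call. = FALSE)
  fit_centers(ctl, reference_bins = NULL, seed = seed, nstart = nstart)
}
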