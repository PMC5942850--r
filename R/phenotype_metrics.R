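# Fitness and stress-phenotype metrics: logistic growth-curve fitting,
# relative fitness, AUC, Biolog-style endpoint scoring with a data-driven
# noise threshold, and control-normalised stress fold changes.

#' Construct a growth curve
#'
#' @param times sampling times in hours (strictly increasing).
#' @param od absorbance readings at 600 nm.
#' @param sample_id,plate_id optional labels.
#' @return object of class `growth_curve` (a data.frame `time_h`, `od600`).
#' @export
growth_curve <- function(times, od, sample_id = NA_character_,
                         plate_id = NA_character_) {
  stopifnot(length(times) == length(od), all(diff(times) > 0),
            all(is.finite(od)))
  structure(data.frame(time_h = times, od600 = od),
            sample_id = sample_id, plate_id = plate_id,
            class = c("growth_curve", "data.frame"))
}

#' Logistic population-growth model
#'
#' `N(t) = K / (1 + ((K - n0) / n0) * exp(-r t))`.
#'
#' @param t time in hours.
#' @param r growth rate (divisions/hour).
#' @param K carrying-capacity absorbance.
#' @param n0 initial absorbance.
#' @export
logistic_model <- function(t, r, K, n0) {
  K / (1 + ((K - n0) / n0) * exp(-r * t))
}

#' Fit the logistic growth equation to a curve
#'
#' Nonlinear least squares with multi-start initialisation: a grid of
#' candidate growth rates seeds `nls` (port algorithm, positivity bounds),
#' with K started at the maximum reading and n0 at the first positive
#' reading. Wells whose dynamic range (max - min reading) is below
#' `noise_floor` are flagged as non-growing and return `r = NA` rather than
#' a spurious rate. Readings are used as-is; subtract a blank first if the
#' plate has a media baseline (see `blank`).
#'
#' @param curve a [growth_curve()] (or data.frame with `time_h`, `od600`).
#' @param blank absorbance blank subtracted from all readings (default 0).
#' @param noise_floor minimal dynamic range considered growth.
#' @return list of class `logistic_fit` with `r`, `K`, `n0`,
#'   `residual_sse`, `converged`, `flag` (`"ok"` or `"non_growing"`).
#' @export
fit_logistic <- function(curve, blank = 0, noise_floor = 0.02) {
  stopifnot(nrow(curve) >= 10)
  t <- curve$time_h
  y <- curve$od600 - blank
  if (max(y) - min(y) < noise_floor) {
    return(structure(list(r = NA_real_, K = NA_real_, n0 = NA_real_,
                          residual_sse = NA_real_, converged = FALSE,
                          flag = "non_growing"),
                     class = "logistic_fit"))
  }
  K0 <- max(y)
  n00 <- max(min(y[y > 0], K0 / 2), 1e-6)
  best <- NULL
  for (r0 in c(0.1, 0.25, 0.5, 1, 2)) {
    fit <- tryCatch(
      suppressWarnings(
        stats::nls(y ~ K / (1 + ((K - n0) / n0) * exp(-r * t)),
                   start = list(r = r0, K = K0, n0 = n00),
                   lower = c(r = 1e-6, K = 1e-6, n0 = 1e-9),
                   algorithm = "port",
                   control = stats::nls.control(maxiter = 200,
                                                warnOnly = TRUE))),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(fit = fit, sse = sse)
    }
  }
  if (is.null(best)) {
    return(structure(list(r = NA_real_, K = NA_real_, n0 = NA_real_,
                          residual_sse = NA_real_, converged = FALSE,
                          flag = "fit_failed"),
                     class = "logistic_fit"))
  }
  cf <- stats::coef(best$fit)
  structure(list(r = unname(cf["r"]), K = unname(cf["K"]),
                 n0 = unname(cf["n0"]), residual_sse = best$sse,
                 converged = best$fit$convInfo$isConv, flag = "ok"),
            class = "logistic_fit")
}

#' Relative fitness as a growth-rate difference
#'
#' `r_focal - mean(r_reference)`, in divisions/hour; the reference mean is
#' conventionally taken over same-plate reference replicates (ancestor
#' replicates for evolved populations, or the K12 reference for the
#' ancestors themselves).
#'
#' @param r_focal growth rate of the focal population.
#' @param r_reference growth rate(s) of the reference; averaged.
#' @export
relative_fitness <- function(r_focal, r_reference) {
  stopifnot(length(r_focal) == 1, length(r_reference) >= 1)
  r_focal - mean(r_reference)
}

#' Area under the growth curve above baseline
#'
#' Trapezoidal area of the readings above the initial (first) reading, in
#' absorbance-hours: a complementary fitness metric that integrates lag,
#' growth rate and carrying capacity.
#'
#' @param curve a [growth_curve()].
#' @export
curve_auc <- function(curve) {
  t <- curve$time_h
  y <- curve$od600 - curve$od600[1]
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Construct endpoint plate data
#'
#' Long-format Biolog-style endpoint readings: one row per
#' (sample, compound, well, time point), with `time_label` either `"10m"`
#' (pre-growth baseline) or `"24h"` (endpoint).
#'
#' @param df data.frame with columns `sample_id`, `compound`, `well`,
#'   `time_label`, `absorbance`.
#' @return data.frame of class `plate_data`.
#' @export
plate_data <- function(df) {
  stopifnot(all(c("sample_id", "compound", "well", "time_label",
                  "absorbance") %in% names(df)),
            all(df$time_label %in% c("10m", "24h")))
  class(df) <- unique(c("plate_data", class(df)))
  df
}

#' Biolog phenotype score B = A_24h - A_10m
#'
#' Growth/respiration signal per (sample, compound, well): the endpoint
#' absorbance minus the 10-minute pre-growth reading. May be negative.
#'
#' @param plate a [plate_data()].
#' @return data.frame with `sample_id`, `compound`, `well`, `B`.
#' @export
biolog_score <- function(plate) {
  stopifnot(inherits(plate, "plate_data"))
  a10 <- plate[plate$time_label == "10m", ]
  a24 <- plate[plate$time_label == "24h", ]
  key <- function(d) paste(d$sample_id, d$compound, d$well, sep = "\r")
  idx <- match(key(a10), key(a24))
  if (anyNA(idx)) stop("unpaired 10m/24h readings in plate data")
  data.frame(sample_id = a10$sample_id, compound = a10$compound,
             well = a10$well, B = a24$absorbance[idx] - a10$absorbance)
}

#' Data-driven noise threshold from pre-growth readings
#'
#' The given quantile of the absolute pairwise differences
#' `|A_i,C,10m - A_j,C,10m|` between samples within each condition
#' (compound x well), pooled across conditions: the level below which an
#' endpoint difference is indistinguishable from plating noise. The fixed
#' conventional value 0.097 may be used instead wherever a threshold is
#' accepted.
#'
#' @param plate a [plate_data()].
#' @param quantile quantile of the pooled pairwise differences (default
#'   0.99).
#' @export
noise_threshold <- function(plate, quantile = 0.99) {
  stopifnot(inherits(plate, "plate_data"), quantile > 0, quantile <= 1)
  a10 <- plate[plate$time_label == "10m", ]
  diffs <- unlist(lapply(split(a10$absorbance,
                               paste(a10$compound, a10$well)), function(a) {
    if (length(a) < 2) return(numeric(0))
    as.numeric(stats::dist(a))
  }), use.names = FALSE)
  if (length(diffs) == 0) stop("need at least two samples per condition")
  as.numeric(stats::quantile(diffs, quantile, names = FALSE))
}

#' Select the assay well (concentration) per compound
#'
#' Among the four concentration wells of each compound, picks the well with
#' the highest variance of the matched evolved-minus-ancestor difference in
#' the B score across sample pairs. Ties go to the lowest well index (with
#' a message).
#'
#' @param b_evolved,b_ancestor data.frames from [biolog_score()] for the
#'   matched evolved and ancestor samples, with equal row order of
#'   (pair, compound, well).
#' @return data.frame with `compound`, `well`.
#' @export
select_concentration_well <- function(b_evolved, b_ancestor) {
  stopifnot(nrow(b_evolved) == nrow(b_ancestor),
            all(b_evolved$compound == b_ancestor$compound),
            all(b_evolved$well == b_ancestor$well))
  d <- data.frame(compound = b_evolved$compound, well = b_evolved$well,
                  diff = b_evolved$B - b_ancestor$B)
  rows <- lapply(split(d, d$compound), function(sub) {
    v <- vapply(split(sub$diff, sub$well), stats::var, numeric(1))
    wells <- as.integer(names(v))
    best <- wells[v == max(v, na.rm = TRUE) & !is.na(v)]
    if (length(best) > 1) {
      message("variance tie for compound ", sub$compound[1],
              "; choosing lowest well index")
    }
    data.frame(compound = sub$compound[1], well = min(best))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tolerance gain/loss call from endpoint scores
#'
#' `"gained"` if `B_evolved - B_ancestor > A_thresh`, `"lost"` if
#' `B_ancestor - B_evolved > A_thresh`, else `"none"` (strict
#' inequalities; a difference exactly at the threshold is noise).
#'
#' @param B_evolved,B_ancestor endpoint B scores (vectors of equal length).
#' @param A_thresh noise threshold (conventional default 0.097 absorbance).
#' @export
call_tolerance <- function(B_evolved, B_ancestor, A_thresh = 0.097) {
  stopifnot(length(B_evolved) == length(B_ancestor), A_thresh > 0)
  d <- B_evolved - B_ancestor
  ifelse(d > A_thresh, "gained", ifelse(-d > A_thresh, "lost", "none"))
}

#' Control-normalised stress fold change G
#'
#' `G = (A_X,E / A_X,A) / (A_ctrl,E / A_ctrl,A)`: the evolved/ancestor
#' density ratio in the stress condition X divided by the same ratio in the
#' control medium, which removes the effect of evolved changes in carrying
#' capacity. `G > 1` means the evolved population grew relatively better
#' under stress. The natural-log fold change is attached as attribute
#' `log_G`.
#'
#' @param A_X_evolved,A_X_ancestor 24 h densities in the stress condition.
#' @param A_ctrl_evolved,A_ctrl_ancestor 24 h densities in control medium.
#' @export
stress_fold_change <- function(A_X_evolved, A_X_ancestor,
                               A_ctrl_evolved, A_ctrl_ancestor) {
  vals <- c(A_X_evolved, A_X_ancestor, A_ctrl_evolved, A_ctrl_ancestor)
  if (any(vals <= 0)) {
    bad <- c("A_X_evolved", "A_X_ancestor", "A_ctrl_evolved",
             "A_ctrl_ancestor")[c(any(A_X_evolved <= 0),
                                  any(A_X_ancestor <= 0),
                                  any(A_ctrl_evolved <= 0),
                                  any(A_ctrl_ancestor <= 0))]
    stop("non-positive absorbance reading(s) in: ",
         paste(bad, collapse = ", "))
  }
  g <- (A_X_evolved / A_X_ancestor) / (A_ctrl_evolved / A_ctrl_ancestor)
  attr(g, "log_G") <- log(g)
  g
}
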