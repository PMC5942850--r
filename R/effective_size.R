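# Nominal effective population size for serial growth-dilution regimes.
#
# Within each daily cycle the census runs up a deterministic ladder: from
# the bottleneck size n_min = n_max / dilution through floor(log2(dilution))
# doublings, plus the final stationary-phase census n_max itself (the
# fractional last generation). N_e is the harmonic mean of every size on
# every sampled day's ladder.

#' Within-cycle population-size ladder
#'
#' `[n_min, 2 n_min, ..., 2^k n_min, n_max]` with
#' `k = floor(log2(dilution))` and `n_min = n_max / dilution`; length
#' `k + 2` (18 entries for a 100,000-fold dilution). `dilution = 1` gives
#' the degenerate single-entry ladder `[n_max]`.
#'
#' @param n_max stationary-phase census size (cells).
#' @param dilution daily dilution fold.
#' @export
size_ladder <- function(n_max, dilution = 1e5) {
  stopifnot(n_max > 0, dilution >= 1, n_max >= dilution)
  if (dilution == 1) return(n_max)
  k <- complete_doublings(dilution)
  n_min <- n_max / dilution
  c(n_min * 2^(0:k), n_max)
}

#' Construct a census count series
#'
#' Daily stationary-phase census sizes for one population. Days whose
#' colony counts failed plate quality control (fewer than `min_colonies` or
#' more than `max_colonies` colonies) are dropped and the day count
#' adjusted; pass `colonies` to apply this filter.
#'
#' @param day integer vector of sampled days.
#' @param n_max stationary-phase census size per day (cells).
#' @param dilution daily dilution fold.
#' @param colonies optional colony counts backing each census, used for QC.
#' @param min_colonies,max_colonies QC bounds on countable plates.
#' @return object of class `count_series`.
#' @export
count_series <- function(day, n_max, dilution = 1e5, colonies = NULL,
                         min_colonies = 20, max_colonies = 700) {
  stopifnot(length(day) == length(n_max), all(n_max > 0), dilution >= 1)
  keep <- rep(TRUE, length(day))
  if (!is.null(colonies)) {
    stopifnot(length(colonies) == length(day))
    keep <- colonies >= min_colonies & colonies <= max_colonies
  }
  structure(list(day = day[keep], n_max = n_max[keep], dilution = dilution,
                 days_dropped = sum(!keep)),
            class = "count_series")
}

#' Nominal effective population size
#'
#' The harmonic mean of all within-cycle population sizes over all sampled
#' days: `N_e = (D * G) / sum over days and generations of 1/N`, with `D`
#' sampled days and `G` the ladder length (18 for a 100,000-fold dilution:
#' generations 0..16 plus the final stationary census).
#'
#' @param series a [count_series()], or a numeric vector of daily `n_max`
#'   values (then `dilution` is used).
#' @param dilution dilution fold when `series` is a bare numeric vector.
#' @return N_e (cells), with attribute `days_used`.
#' @export
nominal_ne <- function(series, dilution = 1e5) {
  if (!inherits(series, "count_series")) {
    series <- count_series(day = seq_along(series), n_max = series,
                           dilution = dilution)
  }
  if (length(series$n_max) < 1) stop("no sampled days in count series")
  if (any(series$n_max <= 0)) {
    stop("non-positive census size on day ",
         series$day[which(series$n_max <= 0)[1]])
  }
  ladders <- lapply(series$n_max, size_ladder, dilution = series$dilution)
  len <- length(ladders[[1]])
  recip <- sum(vapply(ladders, function(l) sum(1 / l), numeric(1)))
  ne <- (length(series$n_max) * len) / recip
  attr(ne, "days_used") <- length(series$n_max)
  ne
}

#' Hook for linkage-corrected effective-size estimators
#'
#' The reduction of N_e by background selection or interference in fully
#' linked genomes is estimated by external published methods that are not
#' re-implemented here. By default this hook records its parameters and
#' returns an explicit "not computed" marker; supply `method` (a function
#' `f(series, s, U_d)`) to plug in an external estimator, whose value is
#' returned unchanged.
#'
#' @param series a [count_series()].
#' @param s deleterious selection coefficient (conventionally 0.03).
#' @param U_d deleterious genomic mutation rate (the genomic rate U is an
#'   upper bound).
#' @param method optional external estimator function.
#' @return list with `value` (NA unless `method` is given), `status`, and
#'   `params` echoing the inputs.
#' @export
linkage_ne_hook <- function(series, s = 0.03, U_d, method = NULL) {
  params <- list(s = s, U_d = U_d,
                 days = if (inherits(series, "count_series"))
                   length(series$n_max) else length(series))
  if (is.null(method)) {
    return(list(value = NA_real_,
                status = "external method; not implemented",
                params = params))
  }
  stopifnot(is.function(method))
  list(value = method(series, s, U_d), status = "computed by user method",
       params = params)
}
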