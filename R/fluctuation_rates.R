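# Mutation-rate estimation from parallel-culture fluctuation assays.
#
# Model class: Lea-Coulson / MSS formulation with deterministic exponential
# growth, full plating, no phenotypic lag and no differential mutant
# fitness. The number of mutational events per culture is Poisson(m) and
# the resulting mutant-count distribution follows the classical
# Luria-Delbruck recursion. Rates are converted to per-bp and per-genome
# (Drake-style) via the count C of resistance-conferring single-nucleotide
# changes in the reporter gene.

#' Construct a fluctuation-assay experiment
#'
#' @param df data.frame with columns `culture_id`, `mutant_count`,
#'   `n_final` (cells per culture at plating).
#' @param plating_fraction fraction of each culture plated. Only full
#'   plating (1) is currently supported; the field is validated and kept as
#'   the designated extension point.
#' @return data.frame of class `fluctuation_experiment`.
#' @export
fluctuation_experiment <- function(df, plating_fraction = 1) {
  stopifnot(all(c("culture_id", "mutant_count", "n_final") %in% names(df)),
            all(df$mutant_count >= 0), all(df$n_final > 0),
            plating_fraction > 0, plating_fraction <= 1)
  if (plating_fraction < 1) {
    stop("plating_fraction < 1 is not supported by the current model class")
  }
  attr(df, "plating_fraction") <- plating_fraction
  class(df) <- unique(c("fluctuation_experiment", class(df)))
  df
}

#' Luria-Delbruck probability mass function
#'
#' Classical recursion for the Lea-Coulson distribution of mutant counts:
#' `p_0 = exp(-m)`, `p_k = (m/k) * sum_{i=0}^{k-1} p_i / (k - i + 1)`,
#' where `m` is the expected number of mutational events per culture.
#'
#' @param m expected mutational events per culture (>= 0).
#' @param k_max largest mutant count to evaluate.
#' @return numeric vector of probabilities for counts `0..k_max`.
#' @export
ld_pmf <- function(m, k_max) {
  stopifnot(m >= 0, k_max >= 0)
  p <- numeric(k_max + 1)
  p[1] <- exp(-m)
  if (k_max >= 1 && m > 0) {
    for (k in seq_len(k_max)) {
      i <- 0:(k - 1)
      p[k + 1] <- (m / k) * sum(p[i + 1] / (k - i + 1))
    }
  }
  p
}

#' Log-likelihood of fluctuation counts under the Luria-Delbruck model
#'
#' Counts at or above `cap` are treated as right-censored ("jackpot"
#' cultures whose plates are not countable): they contribute the tail mass
#' `P(K >= cap)`. This keeps the quadratic pmf recursion tractable without
#' discarding jackpots.
#'
#' @param m expected mutational events per culture.
#' @param counts observed mutant counts (i.i.d. across cultures).
#' @param cap censoring threshold (default `Inf`, no censoring).
#' @export
ld_loglik <- function(m, counts, cap = Inf) {
  stopifnot(m >= 0, all(counts >= 0))
  if (m == 0) return(if (all(counts == 0)) 0 else -Inf)
  censored <- counts >= cap
  kmax <- if (any(!censored)) max(counts[!censored]) else 0
  if (is.finite(cap)) kmax <- max(kmax, cap - 1)
  p <- ld_pmf(m, kmax)
  ll <- sum(log(pmax(p[counts[!censored] + 1], 1e-300)))
  if (any(censored)) {
    tail_mass <- max(1 - sum(p[seq_len(cap)]), 1e-300)
    ll <- ll + sum(censored) * log(tail_mass)
  }
  ll
}

#' Maximum-likelihood mutation-rate estimate from a fluctuation assay
#'
#' Maximises the Luria-Delbruck likelihood of the observed mutant counts in
#' `m` (expected mutational events per culture), converts to the
#' per-cell-division rate `mu = m_hat / mean(n_final)`, and attaches a 95%
#' profile-likelihood confidence interval (log-likelihood drop of
#' `qchisq(0.95, 1)/2 = 1.92`). All-zero counts give `m_hat = 0` with a
#' one-sided upper bound.
#'
#' @param experiment a [fluctuation_experiment()].
#' @param C correction factor: number of resistance-conferring
#'   single-nucleotide changes in the reporter gene (71 for rpoB and
#'   rifampicin).
#' @param L genome length in bp (E. coli K12: 4,641,652).
#' @param count_cap right-censoring threshold passed to [ld_loglik()];
#'   counts at or above it are treated as ">= cap" jackpots.
#' @return list of class `mutation_rate_estimate` with `m_hat`, `mu`
#'   (per cell per division), `ci_low`, `ci_high`, `mu_bp`, `U`, `C`, `L`,
#'   `n_cultures`, `mean_n_final`.
#' @export
estimate_mu <- function(experiment, C = 71, L = 4641652, count_cap = 512) {
  stopifnot(inherits(experiment, "fluctuation_experiment"),
            nrow(experiment) >= 2)
  counts <- experiment$mutant_count
  if (any(counts != floor(counts)) || any(!is.finite(counts))) {
    stop("mutant counts must be finite non-negative integers")
  }
  nbar <- mean(experiment$n_final)
  drop <- stats::qchisq(0.95, 1) / 2
  if (all(counts == 0)) {
    # boundary MLE: for all-zero data ll(0) - ll(m) = n*m, so the one-sided
    # upper bound solves n*m = 1.92
    m_hi <- stats::uniroot(function(m) length(counts) * m - drop,
                           c(0, 100))$root
    est <- list(m_hat = 0, m_low = 0, m_high = m_hi)
  } else {
    nll <- function(m) -ld_loglik(m, counts, cap = count_cap)
    upper <- max(2 * mean(pmin(counts, count_cap)), 10)
    opt <- stats::optimize(nll, interval = c(1e-8, upper), tol = 1e-8)
    while (opt$minimum > 0.95 * upper && upper < 1e6) {
      upper <- upper * 10
      opt <- stats::optimize(nll, interval = c(1e-8, upper), tol = 1e-8)
    }
    m_hat <- opt$minimum
    ll_hat <- -opt$objective
    prof <- function(m) ll_hat - ld_loglik(m, counts, cap = count_cap) - drop
    m_lo <- if (prof(1e-10) < 0) 0 else
      stats::uniroot(prof, c(1e-10, m_hat), tol = 1e-8)$root
    hi_bracket <- m_hat * 2
    while (prof(hi_bracket) < 0 && hi_bracket < 1e7) hi_bracket <- hi_bracket * 2
    m_hi <- stats::uniroot(prof, c(m_hat, hi_bracket), tol = 1e-8)$root
    est <- list(m_hat = m_hat, m_low = m_lo, m_high = m_hi)
  }
  mu <- est$m_hat / nbar
  rates <- drake_genomic_rate(mu, C = C, L = L)
  structure(list(m_hat = est$m_hat, mu = mu,
                 ci_low = est$m_low / nbar, ci_high = est$m_high / nbar,
                 mu_bp = rates[["mu_bp"]], U = rates[["U"]],
                 C = C, L = L, n_cultures = length(counts),
                 mean_n_final = nbar),
            class = "mutation_rate_estimate")
}

#' Convert a reporter-locus rate to per-bp and genomic mutation rates
#'
#' Drake-style conversion: `mu_bp = mu_rif / C` and `U = L * mu_rif / C`,
#' where `C` counts the single-nucleotide changes in the reporter gene
#' (rpoB) known to confer the selectable phenotype (rifampicin resistance)
#' and `L` is the genome length.
#'
#' @param mu_rif rate of mutation to the selectable phenotype, per cell per
#'   division.
#' @param C correction factor (default 71).
#' @param L genome length in bp (default 4,641,652).
#' @return named numeric vector `c(mu_bp =, U =)`.
#' @export
drake_genomic_rate <- function(mu_rif, C = 71, L = 4641652) {
  stopifnot(mu_rif >= 0, C > 0, L > 0)
  c(mu_bp = mu_rif / C, U = L * mu_rif / C)
}

#' Evolved mutation rate as a percentage of the ancestral rate
#'
#' `100 * mu_evolved / mu_ancestor`: the reporting convention for
#' mutation-rate evolution (e.g. 18 means the evolved rate is 18% of the
#' ancestor's).
#'
#' @param evolved,ancestor `mutation_rate_estimate` objects (or numbers,
#'   taken as rates directly).
#' @export
fold_change_summary <- function(evolved, ancestor) {
  mu_e <- if (inherits(evolved, "mutation_rate_estimate")) evolved$mu
          else evolved
  mu_a <- if (inherits(ancestor, "mutation_rate_estimate")) ancestor$mu
          else ancestor
  if (mu_a <= 0) stop("ancestral mutation rate must be positive")
  100 * mu_e / mu_a
}
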