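# Mutant-cloud and diversity metrics from pooled-sequencing allele
# frequencies.
#
# A population is viewed as a cloud of genotypes around its consensus
# sequence (the per-site majority allele). The spread C is the mean per-site
# fraction of reads not carrying the majority allele; the consensus distance
# D counts sites whose majority allele differs from the ancestral allele;
# and pi is the mean per-site fraction of mismatching read pairs.

#' Construct and validate a variant table
#'
#' One row per (population, generation, position, derived base): the
#' pooled-sequencing record of a derived allele, with its frequency, read
#' depth and majority-allele read count. Positions are 1-based.
#'
#' @param df data.frame with columns `population_id`, `generation`,
#'   `position`, `ref_base`, `derived_base`, `frequency`, `depth`,
#'   `majority_reads`, `gene_id`, `effect_class`.
#' @return the validated data.frame with class `variant_table`.
#' @export
variant_table <- function(df) {
  required <- c("population_id", "generation", "position", "ref_base",
                "derived_base", "frequency", "depth", "majority_reads",
                "gene_id", "effect_class")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("variant table is missing columns: ", paste(missing, collapse = ", "))
  }
  stopifnot(all(df$frequency >= 0 & df$frequency <= 1),
            all(df$depth >= 0),
            all(df$majority_reads >= 0 & df$majority_reads <= df$depth),
            all(df$position >= 1),
            all(df$ref_base != df$derived_base))
  dup <- duplicated(df[, c("population_id", "generation", "position",
                           "derived_base")])
  if (any(dup)) stop("duplicate variant records at rows: ",
                     paste(utils::head(which(dup)), collapse = ", "))
  class(df) <- unique(c("variant_table", class(df)))
  df
}

#' Per-site cloud spread C_n
#'
#' The fraction of the population not carrying the majority allele:
#' `C_n = 1 - p` for majority-allele frequency `p > 0.5`. A site with
#' `p = 0.5` exactly has no majority allele and is not admissible here;
#' callers exclude such sites (see [cloud_spread()]).
#'
#' @param p_majority majority-allele frequency, in (0.5, 1].
#' @export
site_spread <- function(p_majority) {
  stopifnot(all(p_majority > 0.5), all(p_majority <= 1))
  1 - p_majority
}

# Per-position majority-allele frequency from (possibly multi-allelic)
# derived records of one population sample. Returns NA where no single
# majority allele exists (exact tie or no allele > 0.5).
.majority_by_position <- function(positions, frequencies) {
  out <- vapply(split(frequencies, positions), function(p) {
    ref_share <- max(0, 1 - sum(p))
    shares <- c(ref_share, p)
    mx <- max(shares)
    # a majority allele must strictly exceed 0.5 and be unique
    if (mx <= 0.5 || sum(shares == mx) > 1L) return(NA_real_)
    mx
  }, numeric(1))
  names(out) <- names(split(frequencies, positions))
  out
}

#' Population spread C: mean per-site cloud spread
#'
#' Averages `C_n = 1 - p_majority` over all sites in the genome: variant
#' sites contribute their spread, invariant sites contribute zero, so the
#' sum over variant sites is divided by the full site denominator
#' (default: the E. coli K12 genome length). Sites with no majority allele
#' (exact frequency ties at 0.5) are excluded with a warning.
#'
#' @param table a [variant_table()] restricted to one population sample.
#' @param denominator_sites number of sites in the genome.
#' @export
cloud_spread <- function(table, denominator_sites = 4641652) {
  maj <- .majority_by_position(table$position, table$frequency)
  stopifnot(denominator_sites >= sum(!is.na(maj)))
  if (anyNA(maj)) {
    warning(sum(is.na(maj)), " site(s) with no majority allele excluded",
            " from cloud spread")
    maj <- maj[!is.na(maj)]
  }
  if (length(maj) == 0) return(0)
  sum(site_spread(maj)) / denominator_sites
}

#' Consensus distance D
#'
#' The number of sites at which the majority allele differs from the
#' ancestral allele, i.e. positions where a derived allele exceeds
#' frequency 0.5 (strictly). Frequency ties at 0.5 leave no majority and
#' are excluded with a warning.
#'
#' @param table a [variant_table()] restricted to one population sample.
#' @export
consensus_distance <- function(table) {
  by_pos <- split(table$frequency, table$position)
  tied <- vapply(by_pos, function(p) {
    shares <- c(max(0, 1 - sum(p)), p)
    sum(shares == max(shares)) > 1L
  }, logical(1))
  if (any(tied)) {
    warning(sum(tied), " site(s) with no majority allele excluded from D")
  }
  moved <- vapply(by_pos[!tied], function(p) max(p) > 0.5, logical(1))
  sum(moved)
}

#' Per-site nucleotide diversity from read counts
#'
#' The fraction of mismatching read pairs at a site:
#' `pi_n = m_p * (m - m_p) / (m * (m - 1) / 2)`, where `m_p` is the
#' majority-allele read count and `m` the total read depth. Sites with
#' `m < 2` have no read pairs and return `NA`; [mean_diversity()] excludes
#' and reports them.
#'
#' @param m_p majority-allele read count.
#' @param m total read depth.
#' @export
site_diversity <- function(m_p, m) {
  stopifnot(all(m_p >= 0), all(m_p <= m))
  n <- max(length(m_p), length(m))
  m_p <- rep_len(m_p, n)
  m <- rep_len(m, n)
  ifelse(m >= 2, m_p * (m - m_p) / (m * (m - 1) / 2), NA_real_)
}

#' Mean nucleotide site diversity pi
#'
#' Sum of per-site diversities over variant sites divided by the number of
#' genome positions with non-zero coverage; covered invariant sites
#' contribute zero diversity.
#'
#' @param table a [variant_table()] restricted to one population sample.
#' @param L_covered number of positions with non-zero coverage.
#' @return mean diversity, with attribute `excluded_sites` counting variant
#'   records dropped for depth < 2.
#' @export
mean_diversity <- function(table, L_covered) {
  stopifnot(L_covered >= 1)
  pin <- site_diversity(table$majority_reads, table$depth)
  excluded <- sum(is.na(pin))
  pi <- sum(pin, na.rm = TRUE) / L_covered
  attr(pi, "excluded_sites") <- excluded
  pi
}

#' Count high-frequency derived alleles
#'
#' Sites carrying a derived allele at frequency strictly greater than
#' `threshold` (default 50% of the population).
#'
#' @param table a [variant_table()] restricted to one population sample.
#' @param threshold frequency threshold (strict inequality).
#' @export
high_frequency_derived <- function(table, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold < 1)
  sum(table$frequency > threshold)
}

.spectrum_classes <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T")

.fold_change <- function(ref, derived) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  raw <- paste0(ref, ">", derived)
  folded <- ifelse(ref %in% c("A", "C"), raw,
                   paste0(comp[ref], ">", comp[derived]))
  folded
}

#' Folded mutational spectrum over six substitution classes
#'
#' Because DNA is double-stranded, the twelve raw single-nucleotide changes
#' fold into six classes anchored on A or C: A>C, A>G, A>T, C>A, C>G, C>T
#' (e.g. T>G is counted as its reverse complement A>C). Typically applied
#' to variants at four-fold degenerate sites; the caller supplies the
#' eligible records.
#'
#' @param ref,derived character vectors of reference and derived bases in
#'   `{A,C,G,T}` (equal length), e.g. the `ref_base`/`derived_base` columns
#'   of a [variant_table()] subset to eligible sites.
#' @return a `spectrum_profile` data.frame with one row per class and
#'   columns `class`, `count`, `frequency` (frequencies sum to 1 when any
#'   mutations are counted, and are 0 otherwise).
#' @export
mutational_spectrum <- function(ref, derived) {
  stopifnot(length(ref) == length(derived),
            all(ref %in% c("A", "C", "G", "T")),
            all(derived %in% c("A", "C", "G", "T")),
            all(ref != derived))
  folded <- .fold_change(ref, derived)
  counts <- vapply(.spectrum_classes, function(cl) sum(folded == cl),
                   numeric(1))
  total <- sum(counts)
  freq <- if (total > 0) counts / total else rep(0, length(counts))
  structure(data.frame(class = .spectrum_classes, count = as.integer(counts),
                       frequency = freq, row.names = NULL),
            class = c("spectrum_profile", "data.frame"))
}

#' Summarise the mutant cloud of each population sample
#'
#' Computes, per (population, generation): the cloud spread C, the
#' consensus distance D, mean nucleotide diversity pi, the number of
#' high-frequency derived alleles, and the covered-site count used as the
#' pi denominator.
#'
#' @param table a [variant_table()] (may span populations and generations).
#' @param genome_length site denominator for C (defaults to the E. coli
#'   K12 genome length).
#' @param L_covered positions with non-zero coverage used for pi; defaults
#'   to `genome_length` (appropriate when virtually the whole genome is
#'   covered).
#' @param hf_threshold threshold for [high_frequency_derived()].
#' @param populations optional character vector of population ids expected
#'   in the output; populations with no variant records (monomorphic at
#'   the detection limit) then appear with all metrics zero, once per
#'   generation observed in the table (or generation 0 if none).
#' @return a tidy data.frame with one row per (population_id, generation).
#' @export
cloud_summary <- function(table, genome_length = 4641652,
                          L_covered = genome_length, hf_threshold = 0.5,
                          populations = NULL) {
  stopifnot(inherits(table, "data.frame"))
  groups <- unique(table[, c("population_id", "generation")])
  if (!is.null(populations)) {
    absent <- setdiff(populations, groups$population_id)
    gens <- if (nrow(groups) > 0) unique(groups$generation) else 0L
    if (length(absent) > 0) {
      groups <- rbind(groups,
                      expand.grid(population_id = absent, generation = gens,
                                  stringsAsFactors = FALSE))
    }
  }
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sub <- table[table$population_id == groups$population_id[i] &
                   table$generation == groups$generation[i], ]
    data.frame(population_id = groups$population_id[i],
               generation = groups$generation[i],
               C = cloud_spread(sub, genome_length),
               D = consensus_distance(sub),
               pi = as.numeric(mean_diversity(sub, L_covered)),
               hf_count = high_frequency_derived(sub, hf_threshold),
               L_covered = L_covered)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
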