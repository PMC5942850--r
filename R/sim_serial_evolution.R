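# Serial-transfer Wright-Fisher simulator for asexual microbial evolution.
#
# The population is represented as a set of haplotype classes (count, fitness
# multiplier, per-genome mutation rate, vector of mutated sites), so linkage
# is exact: the populations modelled here are fully asexual and every mutation
# stays tied to the genome it arose on. Each 24 h cycle consists of
# floor(log2(dilution)) synchronous doublings under multinomial selection,
# one final partial growth step up to carrying capacity, and a multinomial
# bottleneck of n_max/dilution cells.

#' Distribution of fitness effects, point-mass per class
#'
#' Each new mutation is beneficial with probability `fraction_beneficial`
#' (fitness multiplier `1 + s_beneficial`), deleterious with probability
#' `fraction_deleterious` (multiplier `1 - s_deleterious`), and neutral
#' otherwise. With `kind = "exponential"` the effect sizes are drawn from
#' exponential distributions with the given means instead of point masses.
#'
#' @param fraction_beneficial probability a new mutation is beneficial.
#' @param s_beneficial selection coefficient of beneficial mutations.
#' @param fraction_deleterious probability a new mutation is deleterious.
#' @param s_deleterious selection coefficient (cost) of deleterious mutations.
#' @param kind `"pointmass"` (default) or `"exponential"`.
#' @return an object of class `mutcloud_dfe`.
#' @export
dfe_spec <- function(fraction_beneficial = 0.001, s_beneficial = 0.1,
                     fraction_deleterious = 0.3, s_deleterious = 0.03,
                     kind = c("pointmass", "exponential")) {
  kind <- match.arg(kind)
  stopifnot(fraction_beneficial >= 0, fraction_deleterious >= 0,
            fraction_beneficial + fraction_deleterious <= 1,
            s_beneficial > 0 || fraction_beneficial == 0,
            s_deleterious > 0 || fraction_deleterious == 0,
            s_deleterious < 1)
  structure(list(fraction_beneficial = fraction_beneficial,
                 s_beneficial = s_beneficial,
                 fraction_deleterious = fraction_deleterious,
                 s_deleterious = s_deleterious,
                 kind = kind),
            class = "mutcloud_dfe")
}

#' Configuration for a serial-transfer evolution simulation
#'
#' Defaults mirror the experimental design the package targets: daily
#' 100,000-fold dilution (16.61 generations per cycle, 16 complete
#' doublings) and pooled sequencing at a few hundred-fold depth with a 5%
#' reporting threshold.
#'
#' @param genome_length genome size in bp (positions are 1-based).
#' @param gene_table optional [gene_table()] used to annotate variants.
#' @param U genomic mutation rate, mutations per genome per generation.
#' @param dfe a [dfe_spec()].
#' @param n_max carrying capacity in cells (must be < 2^31).
#' @param dilution daily dilution fold (>= 1).
#' @param days number of growth-dilution cycles.
#' @param replicates number of replicate populations.
#' @param seed root seed; per-replicate child seeds are derived from it.
#' @param seq_depth mean sequencing reads per site.
#' @param detection_threshold minimum reportable allele frequency.
#' @param mutator_locus optional `list(position =, rate_multiplier =)`;
#'   `position` may be a scalar or a `c(start, end)` range. A mutation
#'   landing there multiplies the lineage's genomic mutation rate, enabling
#'   mutation-rate evolution.
#' @param beneficial_gene optional gene_id: mutations inside this gene are
#'   always beneficial (effect `dfe$s_beneficial`), which plants a known
#'   target of selection for power tests of the convergence scan.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 50000L, gene_table = NULL,
                       U = 0.0034, dfe = dfe_spec(),
                       n_max = 1e5, dilution = 1e3, days = 50L,
                       replicates = 8L, seed = 1L,
                       seq_depth = 200, detection_threshold = 0.05,
                       mutator_locus = NULL, beneficial_gene = NULL) {
  stopifnot(genome_length >= 1, U >= 0, n_max > 0, n_max < 2^31,
            dilution >= 1, n_max / dilution >= 1, days >= 1,
            replicates >= 1, seq_depth > 0,
            detection_threshold >= 0, detection_threshold < 1)
  if (!is.null(gene_table)) stopifnot(inherits(gene_table, "gene_table"))
  if (!is.null(mutator_locus)) {
    stopifnot(is.list(mutator_locus),
              all(c("position", "rate_multiplier") %in% names(mutator_locus)),
              mutator_locus$rate_multiplier > 0)
  }
  if (!is.null(beneficial_gene)) {
    stopifnot(!is.null(gene_table),
              beneficial_gene %in% gene_table$gene_id)
  }
  structure(list(genome_length = as.integer(genome_length),
                 gene_table = gene_table, U = U, dfe = dfe,
                 n_max = n_max, dilution = dilution,
                 days = as.integer(days), replicates = as.integer(replicates),
                 seed = as.integer(seed), seq_depth = seq_depth,
                 detection_threshold = detection_threshold,
                 mutator_locus = mutator_locus,
                 beneficial_gene = beneficial_gene),
            class = "sim_config")
}

#' Generations per growth-dilution cycle
#'
#' A `dilution`-fold daily dilution allows log2(dilution) generations of
#' regrowth per cycle: 16.61 for the canonical 100,000-fold dilution.
#'
#' @param dilution dilution fold (> 1; `dilution = 1` gives 0).
#' @export
generations_per_cycle <- function(dilution = 1e5) {
  stopifnot(dilution >= 1)
  log2(dilution)
}

#' Complete doublings per growth-dilution cycle
#'
#' `floor(log2(dilution))`: 16 complete cell generations for a 100,000-fold
#' dilution; the remaining fractional generation brings the culture to its
#' stationary-phase census.
#'
#' @inheritParams generations_per_cycle
#' @export
complete_doublings <- function(dilution = 1e5) {
  stopifnot(dilution >= 1)
  as.integer(floor(log2(dilution)))
}

#' Convert an experiment day to a generation count
#'
#' `round(day * log2(dilution))`: day 28 corresponds to generation 465 and
#' day 175 to generation 2907 under 100,000-fold daily dilution.
#'
#' @param day day index (days of serial transfer completed).
#' @inheritParams generations_per_cycle
#' @export
generations_at_day <- function(day, dilution = 1e5) {
  stopifnot(all(day >= 0))
  round(day * generations_per_cycle(dilution))
}

#' Derive a per-replicate child seed from a root seed
#'
#' Deterministic in (seed, index) and kept below 2^31.
#' @param seed root integer seed.
#' @param index replicate index (1-based).
#' @export
child_seed <- function(seed, index) {
  stopifnot(index >= 1)
  as.integer((as.numeric(seed) %% 2147483629 + 1000003 * as.numeric(index)) %%
               2147483629)
}

# Evaluate expr with a local RNG seeded at `seed`, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483629))
  force(expr)
}

condition_extinction <- function(msg) {
  structure(class = c("mutcloud_extinction", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

# Draw fitness multipliers and mutation-rate multipliers for `n` new
# mutations at `positions`.
.draw_effects <- function(n, positions, config) {
  dfe <- config$dfe
  class <- character(n)
  mult <- rep(1, n)
  u <- stats::runif(n)
  ben <- u < dfe$fraction_beneficial
  del <- !ben & u < dfe$fraction_beneficial + dfe$fraction_deleterious
  if (!is.null(config$beneficial_gene)) {
    gt <- config$gene_table
    g <- gt[gt$gene_id == config$beneficial_gene, ]
    inside <- positions >= g$start & positions <= g$end
    ben <- ben | inside
    del <- del & !inside
  }
  if (dfe$kind == "pointmass") {
    mult[ben] <- 1 + dfe$s_beneficial
    mult[del] <- 1 - dfe$s_deleterious
  } else {
    mult[ben] <- 1 + stats::rexp(sum(ben), 1 / dfe$s_beneficial)
    mult[del] <- pmax(1e-6, 1 - stats::rexp(sum(del), 1 / dfe$s_deleterious))
  }
  class[ben] <- "beneficial"
  class[del] <- "deleterious"
  class[!ben & !del] <- "neutral"
  rate_mult <- rep(1, n)
  ml <- config$mutator_locus
  if (!is.null(ml)) {
    lo <- min(ml$position); hi <- max(ml$position)
    at_locus <- positions >= lo & positions <= hi
    rate_mult[at_locus] <- ml$rate_multiplier
  }
  list(class = class, fitness_mult = mult, rate_mult = rate_mult)
}

# One selection + resampling step to total size `target`; then mutation of
# `divisions` genome replications. Returns the updated population.
.grow_step <- function(pop, target, divisions, config) {
  w <- pop$counts * pop$fitness
  if (sum(w) <= 0 || sum(pop$counts) <= 0) {
    stop(condition_extinction("population extinct: no viable cells remain"))
  }
  counts <- as.numeric(stats::rmultinom(1, size = target, prob = w))
  # mutation: Poisson(U) new mutations per genome replication, allocated to
  # haplotypes in proportion to their post-growth counts
  n_events <- stats::rpois(length(counts),
                           counts * (divisions / target) * pop$mutrate)
  n_events <- pmin(n_events, counts)
  tot <- sum(n_events)
  if (tot > 0) {
    parent <- rep.int(seq_along(counts), n_events)
    pos <- sample.int(config$genome_length, tot, replace = TRUE)
    eff <- .draw_effects(tot, pos, config)
    new_muts <- vector("list", tot)
    for (e in seq_len(tot)) {
      pm <- pop$muts[[parent[e]]]
      while (pos[e] %in% pm) {  # infinite-sites: re-draw on collision
        pos[e] <- sample.int(config$genome_length, 1L)
      }
      new_muts[[e]] <- c(pm, pos[e])
    }
    counts <- counts - tabulate(parent, nbins = length(counts))
    pop$counts <- c(counts, rep(1, tot))
    pop$fitness <- c(pop$fitness, pop$fitness[parent] * eff$fitness_mult)
    pop$mutrate <- c(pop$mutrate, pop$mutrate[parent] * eff$rate_mult)
    pop$muts <- c(pop$muts, new_muts)
    unseen <- pop$site_class[pos] == ""
    if (any(unseen)) {
      first <- unseen & !duplicated(pos)
      pop$site_class[pos[first]] <- eff$class[first]
    }
  } else {
    pop$counts <- counts
  }
  keep <- pop$counts > 0
  pop$counts <- pop$counts[keep]
  pop$fitness <- pop$fitness[keep]
  pop$mutrate <- pop$mutrate[keep]
  pop$muts <- pop$muts[keep]
  pop
}

.bottleneck <- function(pop, size) {
  if (sum(pop$counts) <= 0) {
    stop(condition_extinction("population extinct at transfer"))
  }
  counts <- as.numeric(stats::rmultinom(1, size = size, prob = pop$counts))
  keep <- counts > 0
  pop$counts <- counts[keep]
  pop$fitness <- pop$fitness[keep]
  pop$mutrate <- pop$mutrate[keep]
  pop$muts <- pop$muts[keep]
  pop
}

# True derived-allele frequencies across the population.
.snapshot_freqs <- function(pop) {
  total <- sum(pop$counts)
  if (length(pop$muts) == 0 || all(lengths(pop$muts) == 0)) {
    return(data.frame(position = integer(0), frequency = numeric(0),
                      effect_class = character(0)))
  }
  allpos <- unlist(pop$muts, use.names = FALSE)
  wt <- rep.int(pop$counts, lengths(pop$muts))
  agg <- rowsum(wt, group = allpos)
  pos <- as.integer(rownames(agg))
  data.frame(position = pos, frequency = as.numeric(agg) / total,
             effect_class = pop$site_class[pos], row.names = NULL)
}

#' Simulate one replicate population through serial growth-dilution cycles
#'
#' Growth within a cycle is modelled as `floor(log2(dilution))` synchronous
#' doublings with selection (expected offspring proportional to the fitness
#' multiplier; multinomial resampling at the doubled size), followed by one
#' partial generation up to the carrying capacity `n_max`. Each genome
#' replication acquires Poisson(U) new mutations placed uniformly over the
#' genome (infinite-sites collisions within a haplotype are re-drawn). The
#' cycle ends with a multinomial bottleneck of `round(n_max / dilution)`
#' cells. Snapshots report the true derived-allele frequency at every
#' segregating site.
#'
#' @param config a [sim_config()].
#' @param replicate_seed integer seed for this replicate.
#' @param snapshot_cycles cycles (days) after which to record a snapshot;
#'   defaults to the final cycle only. Snapshots are taken at stationary
#'   phase, before the bottleneck.
#' @return an object of class `evo_trajectory`: a list with `snapshots`
#'   (one per requested cycle, each holding `cycle`, `generation`, `freqs`,
#'   `mean_fitness`, `mean_mutrate`, `n_cells`, `n_haplotypes`), the
#'   deterministic within-cycle `size_ladder`, and the `census` of daily
#'   stationary-phase sizes.
#' @seealso [sample_reads()] to turn a snapshot into a pooled-sequencing
#'   variant table.
#' @export
simulate_replicate <- function(config, replicate_seed = config$seed,
                               snapshot_cycles = config$days) {
  stopifnot(inherits(config, "sim_config"))
  snapshot_cycles <- sort(unique(as.integer(snapshot_cycles)))
  stopifnot(all(snapshot_cycles >= 1), all(snapshot_cycles <= config$days))
  n0 <- round(config$n_max / config$dilution)
  k <- complete_doublings(config$dilution)
  ladder <- size_ladder(config$n_max, config$dilution)
  with_seed(replicate_seed, {
    pop <- list(counts = n0, fitness = 1, mutrate = config$U,
                muts = list(integer(0)),
                site_class = character(config$genome_length))
    snapshots <- vector("list", length(snapshot_cycles))
    names(snapshots) <- as.character(snapshot_cycles)
    for (day in seq_len(config$days)) {
      size <- n0
      for (g in seq_len(k)) {
        divisions <- size            # every cell divides once
        size <- 2 * size
        pop <- .grow_step(pop, target = size, divisions = divisions,
                          config = config)
      }
      if (size < config$n_max) {     # fractional final generation
        divisions <- config$n_max - size
        pop <- .grow_step(pop, target = config$n_max, divisions = divisions,
                          config = config)
        size <- config$n_max
      }
      if (day %in% snapshot_cycles) {
        total <- sum(pop$counts)
        snapshots[[as.character(day)]] <- list(
          cycle = day,
          generation = generations_at_day(day, config$dilution),
          freqs = .snapshot_freqs(pop),
          mean_fitness = sum(pop$counts * pop$fitness) / total,
          mean_mutrate = sum(pop$counts * pop$mutrate) / total,
          n_cells = total,
          n_haplotypes = length(pop$counts))
      }
      pop <- .bottleneck(pop, n0)
    }
    structure(list(snapshots = snapshots,
                   size_ladder = ladder,
                   census = data.frame(day = seq_len(config$days),
                                       n_max = config$n_max),
                   replicate_seed = replicate_seed,
                   config = config),
              class = "evo_trajectory")
  })
}

#' Simulate a pooled-sequencing readout of true allele frequencies
#'
#' Per site, the read depth is Poisson(`depth`) and the derived-read count
#' binomial(depth, frequency). The reported frequency is count/depth; sites
#' whose reported frequency falls below `detection_threshold`, or with zero
#' depth, are omitted (zero-depth sites are tallied in the coverage report).
#'
#' @param true_freqs data.frame with `position` and `frequency` columns
#'   (e.g. a snapshot's `freqs`), optionally `effect_class`.
#' @param depth mean reads per site.
#' @param detection_threshold minimum reportable frequency.
#' @param seed integer seed.
#' @param population_id,generation labels stamped on the output rows.
#' @param gene_table optional [gene_table()] for gene annotation.
#' @param genome_length genome size, used for the coverage report.
#' @return a [variant_table()] data.frame, with attributes
#'   `coverage_report` (`list(sites_zero_depth, L_covered)`).
#' @export
sample_reads <- function(true_freqs, depth = 200, detection_threshold = 0.05,
                         seed = 1L, population_id = "pop1", generation = 0L,
                         gene_table = NULL, genome_length = NULL) {
  stopifnot(all(true_freqs$frequency >= 0), all(true_freqs$frequency <= 1))
  with_seed(seed, {
    n <- nrow(true_freqs)
    m <- stats::rpois(n, depth)
    kreads <- stats::rbinom(n, m, true_freqs$frequency)
    freq <- ifelse(m > 0, kreads / m, NA_real_)
    zero_depth <- sum(m == 0)
    keep <- m > 0 & freq >= detection_threshold & freq > 0
    pos <- true_freqs$position[keep]
    ref <- .ref_base_at(pos)
    der <- .derived_base_at(pos, ref)
    gene <- rep("intergenic", sum(keep))
    if (!is.null(gene_table) && sum(keep) > 0) {
      gene <- assign_gene(pos, gene_table)
    }
    eff <- if ("effect_class" %in% names(true_freqs)) {
      true_freqs$effect_class[keep]
    } else rep("noncoding", sum(keep))
    tab <- data.frame(
      population_id = rep(population_id, sum(keep)),
      generation = rep(as.integer(generation), sum(keep)),
      position = pos, ref_base = ref, derived_base = der,
      frequency = freq[keep], depth = m[keep],
      majority_reads = pmax(kreads[keep], m[keep] - kreads[keep]),
      gene_id = gene, effect_class = eff)
    tab <- variant_table(tab)
    L <- if (is.null(genome_length)) NA_integer_ else as.integer(genome_length)
    attr(tab, "coverage_report") <-
      list(sites_zero_depth = zero_depth,
           L_covered = if (is.na(L)) NA_integer_ else L - zero_depth)
    tab
  })
}

# Deterministic pseudo-random reference base per position (plumbing only:
# spectra of simulated data are uniform by construction).
.ref_base_at <- function(pos) {
  c("A", "C", "G", "T")[(pos * 2654435761) %% 4 + 1]
}

.derived_base_at <- function(pos, ref) {
  bases <- c("A", "C", "G", "T")
  idx <- (pos * 40503) %% 3 + 1  # 1..3, deterministic
  vapply(seq_along(pos), function(i) setdiff(bases, ref[i])[idx[i]], "")
}

#' Map positions to gene identifiers
#'
#' Positions not covered by any gene are labelled `"intergenic"`. With
#' overlapping genes the first matching gene (in table order) wins.
#'
#' @param positions integer vector of 1-based positions.
#' @param genes a [gene_table()].
#' @export
assign_gene <- function(positions, genes) {
  out <- rep("intergenic", length(positions))
  for (i in seq_len(nrow(genes))) {
    hit <- positions >= genes$start[i] & positions <= genes$end[i] &
      out == "intergenic"
    out[hit] <- genes$gene_id[i]
  }
  out
}

#' Simulate a Luria-Delbruck fluctuation assay
#'
#' Mutant counts per culture are compound-Poisson draws from the
#' Lea-Coulson model: the number of mutational events is Poisson with mean
#' `m = mu * n_final`, and each event founds a clone whose final size is
#' `floor(1/u)`, `u ~ Uniform(0,1)` (the classical single-clone size law
#' `P(size = j) = 1/(j(j+1))` under deterministic exponential growth),
#' truncated at `n_final`. This stochastic variant reproduces exactly the
#' probability mass function computed by [ld_pmf()].
#'
#' @param mu per-cell-division mutation rate to the selected marker.
#' @param n_final cells per culture at plating.
#' @param cultures number of parallel cultures.
#' @param seed integer seed.
#' @return a `fluctuation_experiment` data.frame with columns `culture_id`,
#'   `mutant_count`, `n_final`.
#' @export
simulate_fluctuation <- function(mu, n_final, cultures, seed = 1L) {
  stopifnot(mu >= 0, n_final > 0, cultures >= 1, is.finite(mu * n_final))
  m <- mu * n_final
  with_seed(seed, {
    counts <- vapply(seq_len(cultures), function(i) {
      n_events <- stats::rpois(1, m)
      if (n_events == 0) return(0)
      clone <- pmin(floor(1 / stats::runif(n_events)), n_final)
      sum(clone)
    }, numeric(1))
    fluctuation_experiment(data.frame(
      culture_id = paste0("c", seq_len(cultures)),
      mutant_count = counts,
      n_final = rep(n_final, cultures)))
  })
}

#' Simulate a logistic growth curve with Gaussian read noise
#'
#' @param r growth rate, divisions per hour.
#' @param K carrying-capacity absorbance.
#' @param n0 initial absorbance (0 < n0 < K).
#' @param times sampling times in hours.
#' @param noise_sd standard deviation of i.i.d. Gaussian measurement noise.
#' @param seed integer seed.
#' @return a [growth_curve()] object.
#' @export
simulate_growth_curve <- function(r, K, n0, times = seq(0, 18, by = 1 / 6),
                                  noise_sd = 0.005, seed = 1L) {
  stopifnot(r > 0, K > n0, n0 > 0, noise_sd >= 0)
  mean_od <- logistic_model(times, r = r, K = K, n0 = n0)
  with_seed(seed, {
    od <- mean_od + stats::rnorm(length(times), 0, noise_sd)
    growth_curve(times, od)
  })
}

#' Simulate endpoint plate readings (Biolog-style)
#'
#' Produces long-format plate data with a 10-minute near-baseline reading
#' and a 24-hour reading equal to baseline plus the planted growth effect,
#' both with Gaussian noise; four concentration wells per compound.
#'
#' @param effects data.frame with columns `sample_id`, `compound`, `well`
#'   (1..4) and `effect` (true absorbance gain over 24 h; 0 = no growth).
#' @param baseline 10-minute baseline absorbance.
#' @param noise_sd Gaussian noise s.d. applied to every reading.
#' @param seed integer seed.
#' @return a `plate_data` long data.frame with columns `sample_id`,
#'   `compound`, `well`, `time_label` (`"10m"`/`"24h"`), `absorbance`.
#' @export
simulate_plate <- function(effects, baseline = 0.1, noise_sd = 0.01,
                           seed = 1L) {
  stopifnot(all(c("sample_id", "compound", "well", "effect") %in%
                  names(effects)), noise_sd >= 0, baseline >= 0)
  with_seed(seed, {
    n <- nrow(effects)
    a10 <- baseline + stats::rnorm(n, 0, noise_sd)
    a24 <- baseline + effects$effect + stats::rnorm(n, 0, noise_sd)
    long <- rbind(
      data.frame(sample_id = effects$sample_id, compound = effects$compound,
                 well = effects$well, time_label = "10m", absorbance = a10),
      data.frame(sample_id = effects$sample_id, compound = effects$compound,
                 well = effects$well, time_label = "24h", absorbance = a24))
    plate_data(long)
  })
}

#' Simulate a full multi-strain serial-transfer experiment
#'
#' Runs [simulate_replicate()] for each (strain, replicate) combination and
#' samples pooled-sequencing reads at the requested snapshot cycles.
#' Per-replicate seeds are derived deterministically from the root seed with
#' [child_seed()], so the same configuration and seed give bit-identical
#' output.
#'
#' @param strains named numeric vector of genomic mutation rates, one per
#'   ancestral strain (e.g. `c(MRS = 0.00034, ...)`).
#' @param config a [sim_config()]; its `U` is overridden per strain.
#' @param snapshot_cycles cycles at which to sequence.
#' @return list with `variants` (one pooled [variant_table()] across all
#'   populations; population ids are `<strain>_<replicate>`),
#'   `trajectories` (nested list by strain then replicate), and `census`
#'   (a `count_series`-style data.frame across populations).
#' @export
simulate_experiment <- function(strains, config,
                                snapshot_cycles = config$days) {
  stopifnot(length(strains) >= 1, !is.null(names(strains)))
  all_variants <- list()
  trajectories <- list()
  census <- list()
  idx <- 0L
  for (s in names(strains)) {
    cfg <- config
    cfg$U <- strains[[s]]
    trajectories[[s]] <- vector("list", cfg$replicates)
    for (r in seq_len(cfg$replicates)) {
      idx <- idx + 1L
      pid <- paste0(s, "_", r)
      traj <- simulate_replicate(cfg, child_seed(cfg$seed, idx),
                                 snapshot_cycles = snapshot_cycles)
      trajectories[[s]][[r]] <- traj
      for (snap in traj$snapshots) {
        vt <- sample_reads(snap$freqs, depth = cfg$seq_depth,
                           detection_threshold = cfg$detection_threshold,
                           seed = child_seed(cfg$seed, idx) + snap$cycle,
                           population_id = pid,
                           generation = snap$generation,
                           gene_table = cfg$gene_table,
                           genome_length = cfg$genome_length)
        all_variants[[length(all_variants) + 1L]] <- vt
      }
      census[[length(census) + 1L]] <-
        data.frame(day = traj$census$day, population_id = pid,
                   n_max = traj$census$n_max)
    }
  }
  variants <- do.call(rbind, all_variants)
  rownames(variants) <- NULL
  list(variants = variant_table(variants),
       trajectories = trajectories,
       census = do.call(rbind, census))
}
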