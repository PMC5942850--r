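# Programmatic fixtures shared across test files.

# Minimal valid variant-table rows for one population sample. Depth-derived
# fields are consistent by construction: majority reads = max(derived, ref).
make_variants <- function(frequency, depth = 200, position = seq_along(frequency),
                          population_id = "pop1", generation = 0L,
                          gene_id = "intergenic", ref_base = "A",
                          derived_base = "G", effect_class = "noncoding") {
  n <- length(frequency)
  depth <- rep_len(depth, n)
  k <- round(frequency * depth)
  variant_table(data.frame(
    population_id = rep_len(population_id, n),
    generation = rep_len(generation, n),
    position = position, ref_base = rep_len(ref_base, n),
    derived_base = rep_len(derived_base, n),
    frequency = frequency, depth = depth,
    majority_reads = pmax(k, depth - k),
    gene_id = rep_len(gene_id, n),
    effect_class = rep_len(effect_class, n)))
}

# Random but valid single-population variant table.
random_variants <- function(n_sites, seed, max_depth = 30) {
  set.seed(seed)
  depth <- sample(2:max_depth, n_sites, replace = TRUE)
  derived_reads <- vapply(depth, function(m) sample(0:m, 1), integer(1))
  # drop invariant (0-frequency) records and exact half-splits (sites with
  # no majority allele warn by design and are tested separately)
  keep <- derived_reads > 0 & 2 * derived_reads != depth
  depth <- depth[keep]; derived_reads <- derived_reads[keep]
  make_variants(frequency = derived_reads / depth, depth = depth,
                position = seq_len(sum(keep)))
}

# Regular gene grid over a small genome.
demo_genes <- function(n_genes = 20, gene_len = 500, gap = 500) {
  starts <- 1 + (seq_len(n_genes) - 1) * (gene_len + gap)
  gene_table(data.frame(gene_id = sprintf("g%02d", seq_len(n_genes)),
                        start = starts, end = starts + gene_len - 1))
}

# Brute-force per-site pair-enumeration oracle for nucleotide diversity:
# label each read, count mismatching pairs / all pairs.
pi_pair_oracle <- function(m_p, m) {
  reads <- c(rep(1L, m_p), rep(0L, m - m_p))
  mism <- 0L; pairs <- 0L
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      pairs <- pairs + 1L
      if (reads[i] != reads[j]) mism <- mism + 1L
    }
  }
  mism / pairs
}
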