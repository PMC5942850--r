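# Replicate-convergence test for putatively beneficial genes.
#
# Under the null, mutations land on genes in proportion to gene length
# alone. For a gene g hit at high frequency in n_g of R replicate
# populations, the null point probability is
#
#   P_g = p_g^{n_g} * sum over size-n_g replicate subsets S of
#         [ prod_{r in S} n_r ] * (1 - p_g)^{n_tot - sum_{r in S} n_r}
#
# where n_r is the number of distinct mutant genes observed in replicate r,
# n_tot their sum, and p_g = l_g / sum(l). This is a point probability
# ("exactly n_g replicates"), not a tail. It is computed exactly, either by
# subset enumeration or by a dynamic program over (replicates processed,
# subset size, chosen-sum), which agree wherever both are feasible.

#' Construct and validate a gene table
#'
#' Coordinates are 1-based and inclusive (GFF3 convention); gene length is
#' `end - start + 1`.
#'
#' @param df data.frame with columns `gene_id`, `start`, `end` and
#'   optionally `strand`.
#' @return data.frame of class `gene_table` with a `length` column added.
#' @export
gene_table <- function(df) {
  stopifnot(all(c("gene_id", "start", "end") %in% names(df)),
            all(df$start >= 1), all(df$end >= df$start))
  if (anyDuplicated(df$gene_id)) stop("gene_ids must be unique")
  if (!"strand" %in% names(df)) df$strand <- "+"
  df$length <- df$end - df$start + 1
  class(df) <- unique(c("gene_table", class(df)))
  df
}

#' Length-proportional null hit probability of a gene
#'
#' `p_g = l_g / sum over genes in scope of l`, the probability that a
#' random mutation falling somewhere in the gene set lands in gene `g`.
#'
#' @param genes a [gene_table()] defining the scope set.
#' @param gene_id gene(s) to report; default all genes.
#' @return named numeric vector of probabilities (sums to 1 over the scope).
#' @export
gene_hit_probability <- function(genes, gene_id = genes$gene_id) {
  stopifnot(inherits(genes, "gene_table"), all(gene_id %in% genes$gene_id))
  p <- genes$length / sum(genes$length)
  names(p) <- genes$gene_id
  p[gene_id]
}

#' Number of ways to choose the hit replicates
#'
#' `choose(R_size, n_g)`: e.g. 2 hit replicates among 32 can be placed in
#' 496 ways.
#'
#' @param R_size number of replicate populations.
#' @param n_g number of replicates carrying a hit.
#' @export
count_replicate_subsets <- function(R_size, n_g) {
  stopifnot(R_size >= 0, n_g >= 0, n_g <= R_size)
  choose(R_size, n_g)
}

#' Build the replicate-by-gene hit matrix
#'
#' For each replicate population, the set of genes carrying at least one
#' derived allele above the frequency threshold at the focal generation.
#' A gene with several qualifying mutations in one replicate counts once
#' (n_r counts distinct mutant genes). Intergenic high-frequency alleles
#' are reported separately and excluded from the test.
#'
#' @param variants a [variant_table()] spanning the replicate populations.
#' @param genes a [gene_table()]; the scope set of the test.
#' @param threshold hit threshold on derived-allele frequency (strict).
#' @param generation focal generation; default the latest in the table.
#' @param ancestral_mask optional data.frame with `position` (and
#'   optionally `derived_base`) of ancestral standing variants to exclude
#'   before counting, for experiments whose replicates share pre-existing
#'   mutations.
#' @return an object of class `hit_matrix`: list with `hits` (named list of
#'   per-replicate gene-id vectors), `n_r`, `n_tot`, `n_g` (named count per
#'   gene with at least one hit), `intergenic` (per-replicate counts of
#'   excluded intergenic high-frequency alleles), and `generation`.
#' @export
hit_matrix <- function(variants, genes, threshold = 0.5, generation = NULL,
                       ancestral_mask = NULL) {
  stopifnot(inherits(genes, "gene_table"))
  if (is.null(generation)) {
    generation <- if (nrow(variants) > 0) max(variants$generation)
                  else NA_integer_
  }
  v <- variants[!is.na(generation) & variants$generation == generation &
                  variants$frequency > threshold, ]
  if (!is.null(ancestral_mask)) {
    if ("derived_base" %in% names(ancestral_mask)) {
      key <- paste(v$position, v$derived_base)
      mkey <- paste(ancestral_mask$position, ancestral_mask$derived_base)
      v <- v[!(key %in% mkey), ]
    } else {
      v <- v[!(v$position %in% ancestral_mask$position), ]
    }
  }
  pops <- sort(unique(variants$population_id))
  gid <- assign_gene(v$position, genes)
  in_gene <- gid != "intergenic"
  hits <- lapply(pops, function(p) {
    sort(unique(gid[in_gene & v$population_id == p]))
  })
  names(hits) <- pops
  intergenic <- vapply(pops, function(p) {
    sum(!in_gene & v$population_id == p)
  }, numeric(1))
  n_r <- vapply(hits, length, integer(1))
  all_genes <- unlist(hits, use.names = FALSE)
  n_g <- if (length(all_genes)) table(all_genes) else integer(0)
  structure(list(hits = hits, n_r = n_r, n_tot = sum(n_r),
                 n_g = n_g, intergenic = intergenic,
                 generation = generation),
            class = "hit_matrix")
}

.enrichment_enumerate <- function(n_r, n_g, p_g) {
  n_tot <- sum(n_r)
  subsets <- utils::combn(length(n_r), n_g)
  total <- sum(apply(subsets, 2, function(S) {
    prod(n_r[S]) * (1 - p_g)^(n_tot - sum(n_r[S]))
  }))
  p_g^n_g * total
}

.enrichment_dp <- function(n_r, n_g, p_g) {
  n_r <- as.integer(round(n_r))
  n_tot <- sum(n_r)
  # f[j+1, s+1] = sum over size-j subsets with chosen-sum s of prod n_r
  f <- matrix(0, nrow = n_g + 1L, ncol = n_tot + 1L)
  f[1L, 1L] <- 1
  for (r in seq_along(n_r)) {
    nr <- n_r[r]
    if (nr == 0L) next  # factor 0: subsets containing r contribute nothing
    jmax <- min(r, n_g)
    for (j in jmax:1L) {
      src <- f[j, seq_len(n_tot + 1L - nr)]
      nz <- which(src != 0)
      if (length(nz)) {
        f[j + 1L, nz + nr] <- f[j + 1L, nz + nr] + src[nz] * nr
      }
    }
  }
  s <- 0:n_tot
  p_g^n_g * sum(f[n_g + 1L, ] * (1 - p_g)^(n_tot - s))
}

#' Null point probability of the observed replicate convergence
#'
#' Probability, under length-proportional random placement of each
#' replicate's observed mutant genes, that exactly the observed number
#' `n_g` of replicates carry a hit in the focal gene. Exact computation by
#' subset enumeration when `choose(R, n_g)` is small, otherwise by an
#' equivalent dynamic program.
#'
#' @param n_r integer vector: number of distinct mutant genes per replicate.
#' @param n_g number of replicates with a hit in the focal gene (>= 1).
#' @param p_g the gene's null hit probability, in (0, 1); `p_g = 0` returns 0.
#' @param method `"auto"` (default), `"enumerate"` or `"dp"`.
#' @param enum_limit maximum subset count for enumeration under `"auto"`.
#' @export
enrichment_probability <- function(n_r, n_g, p_g,
                                   method = c("auto", "enumerate", "dp"),
                                   enum_limit = 20000) {
  method <- match.arg(method)
  stopifnot(n_g >= 1, n_g <= length(n_r), all(n_r >= 0),
            p_g >= 0, p_g < 1)
  if (p_g == 0) return(0)
  if (method == "auto") {
    method <- if (count_replicate_subsets(length(n_r), n_g) <= enum_limit)
      "enumerate" else "dp"
  }
  switch(method,
         enumerate = .enrichment_enumerate(n_r, n_g, p_g),
         dp = .enrichment_dp(n_r, n_g, p_g))
}

#' Scan all hit genes for improbable replicate convergence
#'
#' Computes `p_g` and `P_g` for every gene with at least one hit replicate
#' and flags genes whose null point probability falls below `alpha`.
#'
#' @param hits a [hit_matrix()].
#' @param genes a [gene_table()] (the same scope set used to build `hits`).
#' @param alpha significance threshold on `P_g` (strict `<`); the default
#'   0.005% = 5e-5 applies no further multiple-testing correction.
#' @return data.frame of class `enrichment_result` with columns `gene_id`,
#'   `length`, `n_g`, `p_g`, `P_g`, `significant`, sorted by `P_g`.
#' @export
beneficial_scan <- function(hits, genes, alpha = 5e-5) {
  stopifnot(inherits(hits, "hit_matrix"), inherits(genes, "gene_table"))
  gene_ids <- names(hits$n_g)
  if (length(gene_ids) == 0) {
    out <- data.frame(gene_id = character(0), length = integer(0),
                      n_g = integer(0), p_g = numeric(0), P_g = numeric(0),
                      significant = logical(0))
    class(out) <- c("enrichment_result", class(out))
    return(out)
  }
  p_all <- gene_hit_probability(genes)
  rows <- lapply(gene_ids, function(g) {
    ng <- as.integer(hits$n_g[[g]])
    pg <- unname(p_all[[g]])
    Pg <- enrichment_probability(hits$n_r, ng, pg)
    data.frame(gene_id = g,
               length = genes$length[genes$gene_id == g],
               n_g = ng, p_g = pg, P_g = Pg)
  })
  out <- do.call(rbind, rows)
  out <- call_significant(out, alpha)
  out <- out[order(out$P_g, -out$n_g), ]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Flag significant convergence results
#'
#' `significant` is `P_g < alpha` (strict), with the default threshold
#' 0.005% = 5e-5.
#'
#' @param results data.frame with a `P_g` column.
#' @param alpha significance threshold.
#' @export
call_significant <- function(results, alpha = 5e-5) {
  stopifnot("P_g" %in% names(results), alpha > 0)
  results$significant <- results$P_g < alpha
  results
}

#' Monte-Carlo oracle for the convergence null
#'
#' Each simulation assigns, per replicate r, its `n_r` observed mutant
#' genes independently: each lands in the focal gene with probability
#' `p_g` (one Bernoulli trial per observed mutant gene), and a replicate
#' counts as hit if at least one lands there. Returns the fraction of
#' simulations with exactly (and at least) `n_g` hit replicates, with
#' binomial standard errors.
#'
#' @param n_r integer vector of observed mutant-gene counts per replicate.
#' @param n_g observed number of hit replicates.
#' @param p_g null hit probability of the gene.
#' @param n_sims number of simulations.
#' @param seed integer seed.
#' @return list with `p_exact`, `se_exact`, `p_tail` (>= n_g), `se_tail`,
#'   and `n_sims`.
#' @export
monte_carlo_null <- function(n_r, n_g, p_g, n_sims = 1e5, seed = 1L) {
  stopifnot(all(n_r >= 0), n_g >= 0, n_g <= length(n_r),
            p_g >= 0, p_g <= 1, n_sims >= 1)
  with_seed(seed, {
    R <- length(n_r)
    hit_counts <- vapply(seq_len(n_sims), function(i) {
      sum(stats::rbinom(R, n_r, p_g) >= 1L)
    }, numeric(1))
    p_exact <- mean(hit_counts == n_g)
    p_tail <- mean(hit_counts >= n_g)
    list(p_exact = p_exact,
         se_exact = sqrt(p_exact * (1 - p_exact) / n_sims),
         p_tail = p_tail,
         se_tail = sqrt(p_tail * (1 - p_tail) / n_sims),
         n_sims = n_sims)
  })
}
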