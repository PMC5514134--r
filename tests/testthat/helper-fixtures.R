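# Shared fixtures: all built in code, deterministic under fixed seeds.

quiet <- function(expr) suppressMessages(expr)

# free_matrix is internal; tests reach it through the namespace
free_matrix_of <- function(p) motifnet:::free_matrix(p)

# an unmasked promoter set of hand-written sequences
hand_promoters <- function(seqs, upstream, downstream, genes = NULL) {
  if (is.null(genes)) genes <- sprintf("p%02d", seq_along(seqs))
  promoter_set(genes, seqs, upstream, downstream)
}

ccaat_pwm <- function() pwm_from_consensus("CCAAT")

# a small informative PWM with all cells positive (finite log-odds)
toy_pwm <- function(width = 4, seed = 7) {
  withr::with_seed(seed, {
    counts <- matrix(stats::rpois(4 * width, 5) + 1, 4, width)
  })
  pwm_from_counts(counts, pseudocount = 0.5)
}

# edge list for k cliques of size s, optionally bridged in a chain
clique_network <- function(k, s, bridge = FALSE, weight = 0.5) {
  edges <- purrr::map_dfr(seq_len(k), function(ci) {
    genes <- sprintf("c%d_%02d", ci, seq_len(s))
    pairs <- utils::combn(genes, 2)
    tibble::tibble(gene_a = pairs[1, ], gene_b = pairs[2, ], pcor = weight)
  })
  if (bridge && k > 1) {
    for (ci in seq_len(k - 1)) {
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        gene_a = sprintf("c%d_%02d", ci, s),
        gene_b = sprintf("c%d_%02d", ci + 1, 1),
        pcor = weight))
    }
  }
  build_network(edges, cutoff = weight, absolute = FALSE)
}

# brute-force hypergeometric tails by direct pmf summation
brute_hyper <- function(k, m, Kpop, Npop) {
  ks <- max(0, m - (Npop - Kpop)):min(m, Kpop)
  pmf <- choose(Kpop, ks) * choose(Npop - Kpop, m - ks) / choose(Npop, m)
  list(p_enrich = sum(pmf[ks >= k]), p_deplete = sum(pmf[ks <= k]))
}

# planted end-to-end fixture: co-expression modules whose genes carry a
# TSS-biased CCAAT, over masked promoters, plus independent background
planted_study <- function(n_genes = 200, n_modules = 4, module_size = 10,
                          n_samples = 5000, within_pcor = 0.09,
                          mask_fraction = 0.2, scale = 50,
                          per_gene_count = 2, seed = 42) {
  prom <- quiet(generate_promoters(n_genes, upstream = 1000, downstream = 0,
                                   mask_fraction = mask_fraction, seed = seed))
  expr <- quiet(generate_expression(module_sizes = rep(module_size, n_modules),
                                    n_background_genes = n_genes - n_modules * module_size,
                                    n_samples = n_samples,
                                    within_pcor = within_pcor, seed = seed + 1))
  planted_genes <- names(expr$truth$module_labels)
  planted <- quiet(plant_motif(prom, ccaat_pwm(), genes = planted_genes,
                               placement = "tss_biased", scale = scale,
                               per_gene_count = per_gene_count, seed = seed + 2))
  list(promoters = planted$promoters, expression = expr$expression,
       module_truth = expr$truth, plant_truth = planted$truth,
       planted_genes = planted_genes)
}
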