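test_that("bias background matches hand evaluation and the unmasked closed form", {
  # two unmasked promoters over -4..0: K = 10, E(d) = 2, V(d) = 2
  p <- hand_promoters(c("ACGTA", "GGGGG"), upstream = 4, downstream = 0)
  bg <- bias_background(p)
  expect_equal(bg$K, 10)
  expect_equal(bg$E_d, 2)
  expect_equal(bg$V_d, 2)

  # promoter B masked at -4, -3: k_i = (1,1,2,2,2), K = 8
  pm <- hand_promoters(c("ACGTA", "ggGGG"), upstream = 4, downstream = 0)
  bgm <- bias_background(pm)
  expect_equal(unname(bgm$k_i), c(1, 1, 2, 2, 2))
  expect_equal(bgm$K, 8)
  expect_equal(bgm$E_d, 13 / 8)
  expect_equal(bgm$V_d, 35 / 8 - (13 / 8)^2)

  # degenerate single-position promoter set
  p1 <- promoter_set("g1", "AC", 1, 0)
  expect_equal(bias_background(p1)$E_d, 0.5)

  # all-masked group errors
  expect_error(bias_background(hand_promoters("acgt", 3, 0)), "K = 0")

  # closed form with no masking, 20 random geometries
  withr::with_seed(201, {
    for (rep in 1:20) {
      M <- sample(0:300, 1); N <- sample(0:300, 1)
      if (M + N == 0) M <- 1
      pr <- quiet(generate_promoters(3, M, N, 0, seed = rep))
      expect_equal(bias_background(pr)$E_d,
                   (M * (M + 1) + N * (N + 1)) / (2 * (M + N + 1)))
    }
  })
})

test_that("uniform placement over free positions reproduces E(d) and V(d)", {
  p <- quiet(generate_promoters(30, 800, 100, mask_fraction = 0.35, seed = 211))
  bg <- bias_background(p)
  pos <- promoter_positions(p)
  withr::with_seed(212, {
    draw <- sample(pos, 1e5, replace = TRUE, prob = bg$k_i / bg$K)
  })
  expect_lt(abs(mean(abs(draw)) - bg$E_d) / bg$E_d, 0.01)
  expect_lt(abs(stats::var(abs(draw)) - bg$V_d) / bg$V_d, 0.02)

  p0 <- quiet(generate_promoters(30, 800, 100, mask_fraction = 0, seed = 213))
  bg0 <- bias_background(p0)
  withr::with_seed(214, draw0 <- sample(promoter_positions(p0), 1e5, replace = TRUE,
                                        prob = bg0$k_i / bg0$K))
  expect_lt(abs(mean(abs(draw0)) - bg0$E_d) / bg0$E_d, 0.01)
})

test_that("the Z statistic matches hand cases and is calibrated under the null", {
  bg <- bias_background(hand_promoters(c("ACGTA", "GGGGG"), 4, 0))
  z <- bias_z(bg, rep(0, 8))
  expect_equal(z$z, 4)                           # (2 - 0)/sqrt(2/8)
  expect_equal(z$n, 8)

  # occurrences at the background mean give Z = 0
  z0 <- suppressWarnings(bias_z(bg, c(-1, -3)))
  expect_equal(z0$z, 0)

  expect_error(bias_z(bg, numeric(0)), "undefined")
  bg0 <- bias_background(promoter_set("g1", "AC", 1, 0))
  bg0$V_d <- 0
  expect_error(bias_z(bg0, c(0, 0, 0, 0, 0)), "V\\(d\\)")
  expect_warning(bias_z(bg, c(0, 0)), "unreliable")

  # null calibration: uniform placement gives standard-normal Z (small run;
  # the full 10,000-group calibration lives in the acceptance suite)
  p <- quiet(generate_promoters(20, 1000, 0, 0, seed = 221))
  bgn <- bias_background(p)
  pos <- promoter_positions(p)
  withr::with_seed(222, {
    zs <- vapply(1:2000, function(k) {
      bias_z(bgn, sample(pos, 20, replace = TRUE, prob = bgn$k_i / bgn$K))$z
    }, numeric(1))
  })
  expect_lt(abs(mean(zs)), 0.1)
  expect_gt(stats::sd(zs), 0.85)
  expect_lt(stats::sd(zs), 1.15)
})

test_that("neighborhood enrichment equals exact hypergeometric tails", {
  # 5 of 10 genes carry the motif; a group of all 5 carriers: p = 1/C(10,5)
  pop <- sprintf("g%02d", 1:10)
  expect_equal(neighborhood_enrichment(pop[1:5], pop[1:5], pop), 1 / choose(10, 5))
  expect_equal(neighborhood_enrichment(pop[6:10], pop[1:5], pop), 1)

  withr::with_seed(231, {
    for (rep in 1:25) {
      N <- sample(5:30, 1)
      pop <- sprintf("g%02d", seq_len(N))
      K <- sample(0:N, 1); m <- sample(1:N, 1)
      group <- sample(pop, m); motif <- sample(pop, K)
      k <- length(intersect(group, motif))
      expect_equal(neighborhood_enrichment(group, motif, pop),
                   brute_hyper(k, m, K, N)$p_enrich)
    }
  })
  expect_error(neighborhood_enrichment("a", "a", character(0)), "population")
  expect_error(neighborhood_enrichment("zz", "a", c("a", "b")), "subset")
})

test_that("target calling follows the seeded-group rule", {
  pwm <- ccaat_pwm()
  # star network: seed S with 6 neighbors, all promoters carrying a planted
  # TSS-proximal motif; plus unconnected background genes without hits
  genes <- c("S", sprintf("nb%d", 1:6), sprintf("bg%d", 1:13))
  prom <- quiet(generate_promoters(20, 1000, 0, 0, seed = 241))
  prom$gene <- genes
  planted <- quiet(plant_motif(prom, pwm, genes = genes[1:7], placement = "tss_biased",
                               scale = 30, per_gene_count = 3, seed = 242))
  edges <- tibble::tibble(gene_a = "S", gene_b = sprintf("nb%d", 1:6), pcor = 0.1)
  bg_edges <- tibble::tibble(gene_a = sprintf("bg%d", 1:12),
                             gene_b = sprintf("bg%d", 2:13), pcor = 0.1)
  net <- build_network(dplyr::bind_rows(edges, bg_edges), cutoff = 0.04)
  hits <- scan_promoters(planted$promoters, pwm, threshold = 9.9)
  calls <- call_targets(net, planted$promoters, hits, z_cutoff = 3.5, p_cutoff = 1e-5)
  expect_setequal(calls$targets$gene, genes[1:7])
  expect_true(all(calls$targets$by_bias | calls$targets$by_enrichment))
  # every called target carries at least one hit
  expect_true(all(calls$targets$gene %in% hits$gene))

  # a seed without the motif contributes nothing, however strong its group
  hits_no_seed <- hits[hits$gene != "S", ]
  calls2 <- call_targets(net, planted$promoters, hits_no_seed,
                         z_cutoff = 3.5, p_cutoff = 1e-5)
  seed_row <- calls2$seeds[calls2$seeds$seed == "S", ]
  expect_false(seed_row$called)
  expect_false("S" %in% calls2$targets$gene)

  # node order does not change the target set
  all_edges <- dplyr::bind_rows(bg_edges, edges)
  net_rev <- build_network(all_edges[rev(seq_len(nrow(all_edges))), ], cutoff = 0.04)
  calls3 <- call_targets(net_rev, planted$promoters, hits, z_cutoff = 3.5, p_cutoff = 1e-5)
  expect_identical(calls3$targets, calls$targets)

  expect_error(call_targets(net, planted$promoters[1:5, ], hits),
               "without promoter")
})

test_that("promoter shuffling preserves masks and composition", {
  p <- quiet(generate_promoters(15, 300, 50, mask_fraction = 0.3, seed = 251))
  s <- shuffle_promoters(p, seed = 9)
  expect_identical(free_matrix_of(s), free_matrix_of(p))   # mask geometry kept
  comp <- function(x) lapply(strsplit(x, ""), function(ch) sort(ch[ch %in% c("A", "C", "G", "T")]))
  expect_identical(comp(s$sequence), comp(p$sequence))     # free bases permuted
  expect_identical(shuffle_promoters(p, seed = 9)$sequence, s$sequence)
  sd <- shuffle_promoters(p, seed = 9, dinucleotide = TRUE)
  expect_identical(free_matrix_of(sd), free_matrix_of(p))
})

test_that("permutation FDR is small for planted signal and near 1 for a null input", {
  pwm <- ccaat_pwm()
  study <- planted_study(n_genes = 60, n_modules = 3, module_size = 6,
                         n_samples = 3000, within_pcor = 0.15, seed = 261)
  net <- build_network(estimate_pcor(study$expression), cutoff = 0.08)
  hits <- scan_promoters(study$promoters, pwm, threshold = 9.9)
  calls <- call_targets(net, study$promoters, hits, z_cutoff = 3.5, p_cutoff = 1e-5)
  expect_gt(nrow(calls$targets), 0)
  f <- permutation_fdr(net, study$promoters, pwm, threshold = 9.9,
                       n_perm = 5, seed = 10, observed = nrow(calls$targets))
  expect_lte(f$fdr, 0.05)

  # feeding an already-shuffled promoter set back in: observed is itself null
  shuf <- shuffle_promoters(study$promoters, seed = 11)
  null_hits <- scan_promoters(shuf, pwm, threshold = 9.9)
  null_calls <- call_targets(net, shuf, null_hits, z_cutoff = 3.5, p_cutoff = 1e-5)
  if (nrow(null_calls$targets) > 0) {
    fn <- permutation_fdr(net, shuf, pwm, threshold = 9.9, n_perm = 10, seed = 12,
                          observed = nrow(null_calls$targets))
    expect_gt(fn$fdr, 0.2)       # same order as the observed count
  }
  expect_error(permutation_fdr(net, study$promoters, pwm, threshold = 9.9,
                               n_perm = 0), "n_perm")
})
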