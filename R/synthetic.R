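#' Ground truth carried by the synthetic generators
#'
#' Each generator returns, alongside its data, a `synthetic_truth` list
#' recording what was planted: `target_genes` (genes given motif
#' occurrences), `positions` (named list gene -> TSS-relative anchors),
#' `module_labels` (named integer vector gene -> module id), `bound_genes`.
#' Downstream tests compare recovered structure against these fields.
#'
#' @param target_genes,positions,module_labels,bound_genes See description.
#' @return A list of class `synthetic_truth`.
#' @keywords internal
synthetic_truth <- function(target_genes = character(0), positions = list(),
                            module_labels = integer(0), bound_genes = character(0)) {
  stopifnot(all(names(positions) %in% target_genes))
  if (length(module_labels)) {
    sizes <- table(module_labels)
    stopifnot(all(sizes >= 2))
  }
  structure(list(target_genes = target_genes, positions = positions,
                 module_labels = module_labels, bound_genes = bound_genes),
            class = "synthetic_truth")
}

#' Generate random promoters with repeat-like masked blocks
#'
#' Sequences are i.i.d. uniform over A/C/G/T spanning `-upstream..+downstream`
#' around a notional TSS. Masking emulates RepeatMasker output: runs with
#' geometric lengths (mean 150 bp, the scale of common repeat/transposon
#' blocks) are dropped at random starts until about `mask_fraction` of all
#' positions are covered; masked positions are lowercased.
#'
#' @param n_genes Number of promoters; genes are named `g0001`, `g0002`, ...
#' @param upstream,downstream Geometry in bp (defaults 2500/200, the
#'   genome-wide scan configuration; the CCAAT/NF-Y configuration is
#'   1000/0).
#' @param mask_fraction Target fraction of masked positions, in \[0, 1\].
#' @param mean_block Mean masked-block length in bp.
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return A [promoter_set()].
#' @export
generate_promoters <- function(n_genes, upstream = 2500, downstream = 200,
                               mask_fraction = 0, mean_block = 150, seed = 1) {
  check_geometry(upstream, downstream)
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (mask_fraction < 0 || mask_fraction > 1) stop("mask_fraction must be in [0, 1]")
  withr::local_seed(seed)
  message("generate_promoters: seed ", seed)
  len <- upstream + downstream + 1L
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n_genes), function(i) {
    ch <- sample(bases, len, replace = TRUE)
    if (mask_fraction > 0) {
      masked <- logical(len)
      target <- mask_fraction * len
      guard <- 0
      while (sum(masked) < target && guard < 10 * len) {
        run <- if (mask_fraction >= 1) len else 1 + stats::rgeom(1, 1 / mean_block)
        run <- min(run, ceiling(target - sum(masked)))   # do not overshoot
        start <- sample.int(len, 1)
        masked[start:min(len, start + run - 1)] <- TRUE
        guard <- guard + 1
      }
      ch[masked] <- tolower(ch[masked])
    }
    paste(ch, collapse = "")
  }, character(1))
  promoter_set(sprintf("g%04d", seq_len(n_genes)), seqs, upstream, downstream)
}

#' Plant motif occurrences into promoters
#'
#' Writes the PWM's maximum-scoring word (its consensus) into selected
#' promoters at sampled anchors, either uniformly over eligible positions
#' or biased toward the TSS. Eligible anchors are those whose whole
#' `w`-length window is unmasked and inside the promoter; planted
#' occurrences never overwrite masked blocks and never overlap each other
#' within a promoter. TSS-biased placement weights eligible anchors by a
#' truncated geometric law on the distance, `P(i) proportional to
#' (1 - 1/scale)^|i|`, a one-parameter monotone decay toward the TSS.
#'
#' @param promoters A [promoter_set()].
#' @param pwm A [pwm_from_counts()] object (its consensus word is planted).
#' @param genes Genes to receive occurrences (subset of the promoter set).
#' @param placement `"uniform"` or `"tss_biased"`.
#' @param scale Decay scale in bp for `"tss_biased"`.
#' @param per_gene_count Occurrences planted per listed gene.
#' @param seed RNG seed.
#' @return List with `promoters` (modified set) and `truth`
#'   (a `synthetic_truth` with planted genes and anchor positions).
#' @export
plant_motif <- function(promoters, pwm, genes, placement = c("uniform", "tss_biased"),
                        scale = 50, per_gene_count = 1, seed = 1) {
  placement <- match.arg(placement)
  missing <- setdiff(genes, promoters$gene)
  if (length(missing)) stop("genes not in promoter set: ", paste(missing, collapse = ", "))
  w <- pwm$width
  L <- promoter_upstream(promoters) + promoter_downstream(promoters) + 1L
  if (w > L) stop("motif wider than the promoters")
  withr::local_seed(seed)
  message("plant_motif: seed ", seed)
  word <- strsplit(pwm$consensus, "", fixed = TRUE)[[1]]
  M <- promoter_upstream(promoters)
  seqs <- promoters$sequence
  names(seqs) <- promoters$gene
  positions <- list()
  for (g in genes) {
    ch <- strsplit(seqs[[g]], "", fixed = TRUE)[[1]]
    free <- ch %in% c("A", "C", "G", "T")
    ok <- vapply(seq_len(L - w + 1), function(j) all(free[j:(j + w - 1)]), logical(1))
    anchors_here <- integer(0)
    for (k in seq_len(per_gene_count)) {
      cand <- which(ok)
      if (length(cand) == 0) {
        stop("no free window of width ", w, " available in promoter of gene ", g)
      }
      prob <- if (placement == "uniform") rep(1, length(cand)) else
        (1 - 1 / scale)^abs(cand - 1L - M)
      j <- if (length(cand) == 1) cand else sample(cand, 1, prob = prob)
      ch[j:(j + w - 1)] <- word
      anchors_here <- c(anchors_here, j - 1L - M)
      # block overlaps with the fresh occurrence
      ok[max(1, j - w + 1):min(L - w + 1, j + w - 1)] <- FALSE
    }
    seqs[[g]] <- paste(ch, collapse = "")
    positions[[g]] <- sort(anchors_here)
  }
  list(
    promoters = promoter_set(promoters$gene, unname(seqs[promoters$gene]),
                             M, promoter_downstream(promoters)),
    truth = synthetic_truth(target_genes = genes, positions = positions)
  )
}

#' Sample expression from a block-structured graphical Gaussian model
#'
#' Draws samples from a zero-mean multivariate normal whose precision
#' matrix is block-diagonal: within each planted module the off-diagonal
#' precision entries are set so that the implied partial correlation of
#' every within-module pair equals `within_pcor`
#' (`omega_ij = -within_pcor` with unit diagonal); background genes are
#' independent. A module of size `s` admits `within_pcor < 1/(s-1)`;
#' anything larger makes the precision matrix non-positive-definite and is
#' rejected before sampling. Sampling is exact (Cholesky of the implied
#' covariance) with no additional noise model: the generator tests the
#' estimator, not expression preprocessing.
#'
#' @param module_sizes Integer vector of planted module sizes (each >= 2);
#'   may be empty for a fully independent matrix.
#' @param n_background_genes Independent genes appended after the modules.
#' @param n_samples Number of samples (columns); must be >= 1.
#' @param within_pcor Within-module partial correlation, in (0, 1).
#' @param seed RNG seed.
#' @return List with `expression` (tibble: `gene`, sample columns `s1`...)
#'   and `truth` (module labels for module genes).
#' @export
generate_expression <- function(module_sizes, n_background_genes, n_samples,
                                within_pcor = 0.3, seed = 1) {
  if (length(module_sizes) && any(module_sizes < 2)) stop("module sizes must be >= 2")
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (within_pcor <= 0 || within_pcor >= 1) stop("within_pcor must be in (0, 1)")
  p <- sum(module_sizes) + n_background_genes
  if (p < 1) stop("no genes requested")
  omega <- diag(p)
  start <- 0
  labels <- integer(0)
  for (mi in seq_along(module_sizes)) {
    s <- module_sizes[mi]
    if (within_pcor >= 1 / (s - 1)) {
      stop("within_pcor = ", within_pcor, " makes a module of size ", s,
           " non-positive-definite (needs < 1/(size-1) = ", signif(1 / (s - 1), 3), ")")
    }
    idx <- start + seq_len(s)
    omega[idx, idx] <- -within_pcor
    diag(omega)[idx] <- 1
    labels <- c(labels, rep(mi, s))
    start <- start + s
  }
  withr::local_seed(seed)
  message("generate_expression: seed ", seed)
  sigma <- solve(omega)
  ch <- chol(sigma)
  z <- matrix(stats::rnorm(p * n_samples), n_samples, p)
  m <- t(z %*% ch)                                   # p x n_samples
  genes <- sprintf("g%04d", seq_len(p))
  rownames(m) <- genes
  colnames(m) <- sprintf("s%d", seq_len(n_samples))
  truth <- synthetic_truth(
    module_labels = stats::setNames(labels, genes[seq_along(labels)])
  )
  list(expression = as_expression_tibble(m), truth = truth)
}

#' Simulate a TF-binding table
#'
#' Flags each gene as bound independently, with a per-group probability —
#' emulating ChIP-seq-derived bound/unbound promoter tables where, e.g.,
#' a motif's genome-wide bound fraction differs from the bound fraction
#' inside regulated modules.
#'
#' @param genes Data frame with columns `gene` and `group`, or a character
#'   vector of gene ids (then a single group `"all"` is assumed).
#' @param bound_fraction_by_group Named numeric vector mapping every group
#'   present in `genes` to a bound probability in \[0, 1\].
#' @param seed RNG seed.
#' @return Tibble: `gene`, `group`, `bound` (logical).
#' @export
generate_binding_table <- function(genes, bound_fraction_by_group, seed = 1) {
  if (is.character(genes)) genes <- tibble::tibble(gene = genes, group = "all")
  genes <- tibble::as_tibble(genes)
  stopifnot(all(c("gene", "group") %in% names(genes)))
  unknown <- setdiff(unique(genes$group), names(bound_fraction_by_group))
  if (length(unknown)) {
    stop("groups without a bound fraction: ", paste(unknown, collapse = ", "))
  }
  pr <- bound_fraction_by_group[genes$group]
  if (any(pr < 0 | pr > 1)) stop("bound fractions must be in [0, 1]")
  withr::local_seed(seed)
  message("generate_binding_table: seed ", seed)
  tibble::tibble(gene = genes$gene, group = genes$group,
                 bound = stats::runif(nrow(genes)) < unname(pr))
}
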