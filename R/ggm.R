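#' Expression matrices as tibbles
#'
#' Throughout the package an expression matrix is a tibble whose first
#' column `gene` holds gene ids and whose remaining columns are samples.
#' These helpers convert to and from the genes-by-samples numeric matrix
#' used internally, and read/write the gene x sample TSV interchange format
#' (header row of sample ids).
#'
#' @param x Expression tibble (or numeric matrix with gene rownames).
#' @return `expression_matrix()` returns the numeric matrix;
#'   `as_expression_tibble()` the tibble form.
#' @export
expression_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  m <- as.matrix(x[, setdiff(names(x), "gene"), drop = FALSE])
  rownames(m) <- x$gene
  storage.mode(m) <- "double"
  m
}

#' @rdname expression_matrix
#' @export
as_expression_tibble <- function(x) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  dplyr::bind_cols(tibble::tibble(gene = rownames(x)), tibble::as_tibble(x))
}

#' @rdname expression_matrix
#' @param path TSV file path.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1] <- "gene"
  tibble::as_tibble(df)
}

#' @rdname expression_matrix
#' @export
write_expression_tsv <- function(x, path) {
  if (is.matrix(x)) x <- as_expression_tibble(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Shrinkage estimate of partial correlations
#'
#' Estimates the partial correlation (pcor) between every gene pair — the
#' correlation of two genes' expression after removing the linear effects
#' of all other genes — under a graphical Gaussian model. The sample
#' correlation matrix is shrunk toward the identity with the analytic
#' (Schafer–Strimmer) intensity
#' \deqn{\lambda^* = \sum_{i \ne j} \widehat{Var}(r_{ij}) \Big/ \sum_{i \ne j} r_{ij}^2,}
#' clipped to \[0, 1\], which keeps the estimate well-conditioned when genes
#' outnumber samples; the shrunk matrix is inverted and standardised,
#' `pcor_ij = -omega_ij / sqrt(omega_ii * omega_jj)`. Deterministic.
#'
#' @param x Expression tibble (first column `gene`, then samples) or a
#'   genes-by-samples numeric matrix; at least 3 samples, no missing
#'   values, no constant gene.
#' @return A tibble of class `pcor_result` with columns `gene_a`, `gene_b`
#'   (each unordered pair once, `gene_a < gene_b`), `pcor`; attributes
#'   `lambda` (shrinkage intensity), `n_samples`, `genes`.
#' @examples
#' sim <- generate_expression(module_sizes = c(3), n_background_genes = 2,
#'                            n_samples = 200, within_pcor = 0.3, seed = 1)
#' estimate_pcor(sim$expression)
#' @export
estimate_pcor <- function(x) {
  m <- expression_matrix(x)
  n <- ncol(m)
  p <- nrow(m)
  if (n < 3) stop("at least 3 samples are required to estimate partial correlations")
  if (anyNA(m)) stop("missing values in the expression matrix; handle them upstream")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant (zero-variance) genes: ", paste(rownames(m)[sds == 0], collapse = ", "))
  }
  xs <- t((m - rowMeans(m)) / sds)                  # n x p, columns standardised
  r <- crossprod(xs) / (n - 1)                      # sample correlation
  # unbiased variance of each r_ij from the products w_k = x_ki x_kj:
  # Var(r_ij) = n / (n-1)^3 * sum_k (w_k - mean(w))^2
  sw <- crossprod(xs)                               # sum_k w_k
  sw2 <- crossprod(xs^2)                            # sum_k w_k^2
  var_r <- n / (n - 1)^3 * (sw2 - sw^2 / n)
  off <- upper.tri(r)
  lambda <- sum(var_r[off]) / sum(r[off]^2)
  lambda <- min(1, max(0, ifelse(is.finite(lambda), lambda, 1)))
  r_shrunk <- (1 - lambda) * r
  diag(r_shrunk) <- 1
  omega <- solve(r_shrunk)
  d <- 1 / sqrt(diag(omega))
  pc <- -omega * tcrossprod(d)
  idx <- which(off, arr.ind = TRUE)
  out <- tibble::tibble(gene_a = rownames(m)[idx[, 1]],
                        gene_b = rownames(m)[idx[, 2]],
                        pcor = pc[off])
  attr(out, "lambda") <- lambda
  attr(out, "n_samples") <- n
  attr(out, "genes") <- rownames(m)
  class(out) <- c("pcor_result", class(out))
  out
}

#' Partial correlations by repeated gene subsampling
#'
#' For gene sets too large to invert at once, repeatedly draws random gene
#' subsets, runs [estimate_pcor()] on each, and averages each pair's pcor
#' over the iterations in which both genes co-occurred. Pairs covered fewer
#' than `min_pair_coverage` times are dropped (reported via the `coverage`
#' attribute).
#'
#' @inheritParams estimate_pcor
#' @param subset_size Genes per draw (<= number of genes).
#' @param iterations Number of draws.
#' @param min_pair_coverage Minimum co-occurrence count for a pair to be
#'   reported.
#' @param seed RNG seed.
#' @return A `pcor_result` tibble with an extra `coverage` column.
#' @export
estimate_pcor_subsampled <- function(x, subset_size, iterations = 100,
                                     min_pair_coverage = 1, seed = 1) {
  m <- expression_matrix(x)
  p <- nrow(m)
  if (subset_size > p) stop("subset_size exceeds the number of genes")
  if (subset_size == p && iterations == 1) return(estimate_pcor(m))
  withr::local_seed(seed)
  sum_pc <- matrix(0, p, p, dimnames = list(rownames(m), rownames(m)))
  cnt <- matrix(0L, p, p)
  for (it in seq_len(iterations)) {
    pick <- sort(sample.int(p, subset_size))
    pc <- estimate_pcor(m[pick, , drop = FALSE])
    ia <- match(pc$gene_a, rownames(m))
    ib <- match(pc$gene_b, rownames(m))
    sum_pc[cbind(ia, ib)] <- sum_pc[cbind(ia, ib)] + pc$pcor
    cnt[cbind(ia, ib)] <- cnt[cbind(ia, ib)] + 1L
  }
  off <- upper.tri(sum_pc)
  keep <- off & cnt >= min_pair_coverage
  idx <- which(keep, arr.ind = TRUE)
  out <- tibble::tibble(gene_a = rownames(m)[idx[, 1]],
                        gene_b = rownames(m)[idx[, 2]],
                        pcor = sum_pc[keep] / cnt[keep],
                        coverage = cnt[keep])
  out <- dplyr::arrange(out, .data$gene_a, .data$gene_b)
  attr(out, "lambda") <- NA_real_
  attr(out, "n_samples") <- ncol(m)
  attr(out, "genes") <- rownames(m)
  attr(out, "coverage_summary") <- summary(cnt[off])
  class(out) <- c("pcor_result", class(out))
  out
}

#' Threshold partial correlations into a co-expression network
#'
#' Keeps gene pairs whose pcor reaches the cutoff (signed by default —
#' `pcor >= cutoff` — since negative partial correlations are not evidence
#' of co-expression; set `absolute = TRUE` to keep `|pcor| >= cutoff`).
#' Nodes with at least one retained edge form the network.
#'
#' @param pcor A `pcor_result` tibble (or any tibble with `gene_a`,
#'   `gene_b`, `pcor`).
#' @param cutoff Partial-correlation cutoff (default 0.04).
#' @param absolute Threshold on `|pcor|` instead.
#' @return Tibble of class `coexpression_network`: edge list `gene_a`,
#'   `gene_b`, `pcor`; attributes `nodes`, `cutoff`, `absolute`.
#' @export
build_network <- function(pcor, cutoff = 0.04, absolute = FALSE) {
  w <- if (absolute) abs(pcor$pcor) else pcor$pcor
  keep <- !is.na(w) & w >= cutoff
  edges <- tibble::tibble(gene_a = pcor$gene_a[keep], gene_b = pcor$gene_b[keep],
                          pcor = pcor$pcor[keep])
  attr(edges, "nodes") <- sort(unique(c(edges$gene_a, edges$gene_b)))
  attr(edges, "cutoff") <- cutoff
  attr(edges, "absolute") <- absolute
  class(edges) <- c("coexpression_network", class(edges))
  edges
}

#' Network accessors
#'
#' @param network A [build_network()] network.
#' @return `network_nodes()`: character vector of genes with >= 1 edge.
#'   `network_adjacency()`: named list mapping each gene to its direct
#'   neighbours. `network_neighbors()`: neighbours of one gene.
#' @export
network_nodes <- function(network) attr(network, "nodes")

#' @rdname network_nodes
#' @export
network_adjacency <- function(network) {
  nodes <- network_nodes(network)
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  nb <- split(c(network$gene_b, network$gene_a), c(network$gene_a, network$gene_b))
  adj[names(nb)] <- lapply(nb, unique)
  adj
}

#' @rdname network_nodes
#' @param gene A single gene id.
#' @export
network_neighbors <- function(network, gene) {
  unique(c(network$gene_b[network$gene_a == gene],
           network$gene_a[network$gene_b == gene]))
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("# A co-expression network: %d nodes, %d edges (pcor%s >= %g)\n",
              length(network_nodes(x)), nrow(x),
              if (isTRUE(attr(x, "absolute"))) " (absolute)" else "",
              attr(x, "cutoff")))
  NextMethod()
}

#' Empirical FDR for a pcor edge cutoff by sample permutation
#'
#' Permutes each gene's sample labels independently (destroying all
#' between-gene dependence while keeping marginals), re-estimates partial
#' correlations, and counts null pairs reaching the cutoff. FDR is the mean
#' null edge count over permutations divided by the observed edge count.
#'
#' @inheritParams estimate_pcor
#' @param cutoff Edge cutoff (as in [build_network()]).
#' @param n_perm Number of permutations (>= 1).
#' @param seed RNG seed.
#' @param absolute Count `|pcor| >= cutoff` instead.
#' @return Tibble: `fdr`, `observed`, `mean_null`; attribute `perm_counts`.
#' @export
edge_fdr <- function(x, cutoff = 0.04, n_perm = 10, seed = 1, absolute = FALSE) {
  if (!is.numeric(n_perm) || n_perm < 1) stop("n_perm must be >= 1")
  m <- expression_matrix(x)
  count_edges <- function(mat) {
    pc <- estimate_pcor(mat)
    w <- if (absolute) abs(pc$pcor) else pc$pcor
    sum(w >= cutoff)
  }
  observed <- count_edges(m)
  withr::local_seed(seed)
  perm_counts <- vapply(seq_len(n_perm), function(k) {
    perm <- t(apply(m, 1, sample))
    rownames(perm) <- rownames(m)
    count_edges(perm)
  }, numeric(1))
  mean_null <- mean(perm_counts)
  fdr <- if (observed == 0) {
    if (mean_null == 0) 0 else {
      warning("no observed edges at cutoff but null edges present; FDR infinite")
      Inf
    }
  } else mean_null / observed
  out <- tibble::tibble(fdr = fdr, observed = observed, mean_null = mean_null)
  attr(out, "perm_counts") <- perm_counts
  out
}

#' Read and write networks as 3-column edge-list TSV
#'
#' @param network A [build_network()] network.
#' @param path File path (`gene_a`, `gene_b`, `pcor`).
#' @param cutoff,absolute Recorded on the re-read network.
#' @export
write_network_tsv <- function(network, path) {
  utils::write.table(network, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
read_network_tsv <- function(path, cutoff = NA_real_, absolute = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("gene_a", "gene_b", "pcor")
  build_network(tibble::as_tibble(df), cutoff = min(df$pcor, cutoff, na.rm = TRUE),
                absolute = absolute)
}
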