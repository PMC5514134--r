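#' Induced sub-network on a gene set
#'
#' Keeps the edges whose both endpoints are in `genes`, preserving weights —
#' the step that carves the target-gene sub-network out of the full
#' co-expression network before module detection.
#'
#' @param network A [build_network()] network.
#' @param genes Character vector of genes.
#' @return A `coexpression_network` on `genes` intersected with the nodes.
#' @export
extract_subnetwork <- function(network, genes) {
  keep <- network$gene_a %in% genes & network$gene_b %in% genes
  out <- tibble::tibble(gene_a = network$gene_a[keep],
                        gene_b = network$gene_b[keep],
                        pcor = network$pcor[keep])
  attr(out, "nodes") <- sort(unique(c(out$gene_a, out$gene_b)))
  attr(out, "cutoff") <- attr(network, "cutoff")
  attr(out, "absolute") <- attr(network, "absolute")
  class(out) <- c("coexpression_network", class(out))
  if (nrow(out) == 0) warning("no edges between the requested genes; empty sub-network")
  out
}

#' Markov clustering (MCL) of a weighted network
#'
#' Partitions a co-expression (sub-)network into modules by Markov
#' clustering: edge weights become a column-stochastic flow matrix with
#' self-loops (each node's loop weight set to its maximum incident edge
#' weight), then expansion (matrix power) and inflation (entrywise power
#' followed by column renormalisation) alternate, pruning entries below
#' `prune_below`, until the matrix change falls under `tol` or `max_iter`
#' is reached. Clusters are read off the attractor rows of the limit
#' matrix. Nodes are canonically ordered (sorted ids) before iteration, so
#' the partition is invariant to input order; a node attracted to several
#' clusters goes to the larger one (ties to the lower module id). Modules
#' are numbered 1, 2, ... by descending size, so module 1 is always the
#' largest.
#'
#' @param network A [build_network()] / [extract_subnetwork()] network with
#'   non-negative edge weights.
#' @param inflation Inflation exponent (> 1, default 2).
#' @param expansion Expansion power (integer >= 2, default 2).
#' @param prune_below Entries below this are zeroed each iteration.
#' @param max_iter Iteration cap; non-convergence returns the current
#'   interpretation with a warning and `converged = FALSE`.
#' @param tol Convergence tolerance on the max absolute entry change.
#' @return Tibble of class `module_partition`: `gene`, `module` (1-based);
#'   attributes `unassigned` (singleton genes), `converged`, `n_iter`,
#'   `module_sizes`.
#' @export
mcl_cluster <- function(network, inflation = 2, expansion = 2,
                        prune_below = 1e-5, max_iter = 100, tol = 1e-6) {
  if (inflation <= 1) stop("inflation must be > 1")
  if (expansion < 2) stop("expansion must be >= 2")
  nodes <- sort(network_nodes(network))
  p <- length(nodes)
  if (p == 0) {
    out <- tibble::tibble(gene = character(0), module = integer(0))
    class(out) <- c("module_partition", class(out))
    attr(out, "unassigned") <- character(0)
    attr(out, "converged") <- TRUE
    return(out)
  }
  A <- matrix(0, p, p, dimnames = list(nodes, nodes))
  ia <- match(network$gene_a, nodes)
  ib <- match(network$gene_b, nodes)
  A[cbind(ia, ib)] <- network$pcor
  A[cbind(ib, ia)] <- network$pcor
  if (any(A < 0)) stop("MCL needs non-negative edge weights")
  loops <- apply(A, 2, max)
  loops[loops == 0] <- 1
  diag(A) <- loops
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    Mexp <- M
    for (e in seq_len(expansion - 1)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf[Minf < prune_below] <- 0
    cs <- colSums(Minf)
    cs[cs == 0] <- 1
    Minf <- sweep(Minf, 2, cs, "/")
    if (max(abs(Minf - M)) < tol) {
      M <- Minf
      converged <- TRUE
      break
    }
    M <- Minf
  }
  if (!converged) warning("MCL did not converge in ", max_iter, " iterations")
  interpret_mcl(M, nodes, converged, it)
}

# read clusters off the limit matrix: attractors are rows with positive
# diagonal; overlapping attractor rows merge; nodes claimed by several
# clusters go to the larger (ties: lower id after size ordering).
interpret_mcl <- function(M, nodes, converged, n_iter, eps = 1e-9) {
  p <- length(nodes)
  attractors <- which(diag(M) > eps)
  clusters <- list()
  for (a in attractors) {
    members <- which(M[a, ] > eps)
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      if (length(intersect(clusters[[ci]], members))) {
        clusters[[ci]] <- union(clusters[[ci]], members)
        placed <- TRUE
        break
      }
    }
    if (!placed) clusters[[length(clusters) + 1]] <- members
  }
  # merge any chains created by late unions
  repeat {
    merged <- FALSE
    if (length(clusters) > 1) {
      for (i in seq_len(length(clusters) - 1)) {
        for (j in seq(i + 1, length(clusters))) {
          if (length(intersect(clusters[[i]], clusters[[j]]))) {
            clusters[[i]] <- union(clusters[[i]], clusters[[j]])
            clusters[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  sizes <- lengths(clusters)
  ord <- order(-sizes, vapply(clusters, min, integer(1)))
  clusters <- clusters[ord]
  assignment <- rep(NA_integer_, p)
  for (ci in seq_along(clusters)) {
    free <- clusters[[ci]][is.na(assignment[clusters[[ci]]])]
    assignment[free] <- ci
  }
  unassigned <- nodes[is.na(assignment)]
  keep <- !is.na(assignment)
  # renumber by final (post-assignment) descending size
  final_sizes <- table(assignment[keep])
  size_ord <- order(-as.integer(final_sizes), as.integer(names(final_sizes)))
  relabel <- stats::setNames(seq_along(final_sizes), names(final_sizes)[size_ord])
  out <- tibble::tibble(gene = nodes[keep],
                        module = unname(relabel[as.character(assignment[keep])]))
  out <- dplyr::arrange(out, .data$module, .data$gene)
  attr(out, "unassigned") <- unassigned
  attr(out, "converged") <- converged
  attr(out, "n_iter") <- n_iter
  attr(out, "module_sizes") <- as.integer(sort(final_sizes, decreasing = TRUE))
  class(out) <- c("module_partition", class(out))
  out
}

#' @export
print.module_partition <- function(x, ...) {
  sizes <- attr(x, "module_sizes")
  cat(sprintf("# A module partition: %d modules over %d genes (largest %s)\n",
              length(sizes), nrow(x),
              if (length(sizes)) sizes[1] else 0))
  NextMethod()
}

#' Write a module partition and its size summary as TSV
#'
#' @param partition A [mcl_cluster()] partition.
#' @param path Gene-to-module TSV.
#' @param summary_path Optional module-size summary TSV.
#' @export
write_partition_tsv <- function(partition, path, summary_path = NULL) {
  utils::write.table(partition, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(summary_path)) {
    sizes <- dplyr::count(partition, .data$module, name = "size")
    utils::write.table(sizes, summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
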