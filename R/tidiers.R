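#' Broom-style tidiers for motifnet result objects
#'
#' `tidy()` returns the per-unit table of a result (gene pairs, seeds,
#' module assignments); `glance()` returns a one-row summary.
#'
#' @param x A `pcor_result`, `target_calls`, `module_partition`,
#'   `permutation_fdr`, or `pipeline_run` object.
#' @param ... Unused.
#' @return A tibble.
#' @name motifnet-tidiers
NULL

#' @rdname motifnet-tidiers
#' @export
tidy.pcor_result <- function(x, ...) tibble::as_tibble(unclass_keep_cols(x))

#' @rdname motifnet-tidiers
#' @export
glance.pcor_result <- function(x, ...) {
  tibble::tibble(n_genes = length(attr(x, "genes")),
                 n_pairs = nrow(x),
                 n_samples = attr(x, "n_samples"),
                 lambda = attr(x, "lambda"))
}

#' @rdname motifnet-tidiers
#' @export
tidy.coexpression_network <- function(x, ...) tibble::as_tibble(unclass_keep_cols(x))

#' @rdname motifnet-tidiers
#' @export
glance.coexpression_network <- function(x, ...) {
  tibble::tibble(n_nodes = length(network_nodes(x)), n_edges = nrow(x),
                 cutoff = attr(x, "cutoff"),
                 absolute = isTRUE(attr(x, "absolute")))
}

#' @rdname motifnet-tidiers
#' @export
tidy.target_calls <- function(x, ...) x$targets

#' @rdname motifnet-tidiers
#' @export
glance.target_calls <- function(x, ...) {
  tibble::tibble(n_targets = nrow(x$targets),
                 n_by_bias = sum(x$targets$by_bias),
                 n_by_enrichment = sum(x$targets$by_enrichment),
                 n_by_both = sum(x$targets$by_bias & x$targets$by_enrichment),
                 n_seeds_called = sum(x$seeds$called),
                 z_cutoff = x$params$z_cutoff,
                 p_cutoff = x$params$p_cutoff)
}

#' @rdname motifnet-tidiers
#' @export
tidy.module_partition <- function(x, ...) tibble::as_tibble(unclass_keep_cols(x))

#' @rdname motifnet-tidiers
#' @export
glance.module_partition <- function(x, ...) {
  sizes <- attr(x, "module_sizes")
  tibble::tibble(n_modules = length(sizes), n_genes = nrow(x),
                 largest = if (length(sizes)) sizes[1] else 0L,
                 n_unassigned = length(attr(x, "unassigned")),
                 converged = isTRUE(attr(x, "converged")))
}

#' @rdname motifnet-tidiers
#' @export
tidy.permutation_fdr <- function(x, ...) {
  tibble::tibble(perm = seq_along(attr(x, "perm_counts")),
                 null_targets = attr(x, "perm_counts"))
}

#' @rdname motifnet-tidiers
#' @export
glance.permutation_fdr <- function(x, ...) tibble::as_tibble(unclass_keep_cols(x))

#' @rdname motifnet-tidiers
#' @export
glance.pipeline_run <- function(x, ...) tibble::as_tibble(x$summary)

unclass_keep_cols <- function(x) {
  out <- x
  class(out) <- c("tbl_df", "tbl", "data.frame")
  attr(out, "perm_counts") <- NULL
  attr(out, "nodes") <- NULL
  attr(out, "genes") <- NULL
  out
}
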