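#' Hypergeometric over-representation of a gene set in a module
#'
#' Exact hypergeometric tails for the number of annotated genes observed in
#' a module drawn from a finite population, plus the fold change
#' `(k/m) / (Kpop/Npop)` — a module's annotated proportion over the
#' population (e.g. genome-wide) proportion. Both tails include the
#' observed count, so `p_enrich + p_deplete >= 1`.
#'
#' @param module Character vector of module genes (subset of `population`),
#'   or a single integer count `k` when `annotated`/`population` are also
#'   counts.
#' @param annotated Character vector of annotated (e.g. term or bound)
#'   genes, or the count annotated in the module/population (see Details).
#' @param population Character vector of all analysed genes, or its size.
#' @param set_id Label carried into the result.
#' @details Count form: `hypergeom_ora(k = c(k, m), c(Kpop), c(Npop))` is
#'   not supported; pass gene vectors, or use
#'   `hypergeom_ora_counts(k, m, Kpop, Npop)` for pre-tabulated counts.
#' @return Tibble of class `enrichment_result`: `set_id`, `module_size` m,
#'   `population_size` Npop, `annotated_population` Kpop,
#'   `annotated_module` k, `fold`, `p_enrich`, `p_deplete`.
#' @export
hypergeom_ora <- function(module, annotated, population, set_id = "set") {
  if (!all(module %in% population)) {
    stop("module genes outside the population: ",
         paste(setdiff(module, population), collapse = ", "))
  }
  if (length(population) == 0) stop("empty population")
  annotated <- intersect(annotated, population)
  hypergeom_ora_counts(k = length(intersect(module, annotated)),
                       m = length(unique(module)),
                       Kpop = length(unique(annotated)),
                       Npop = length(unique(population)),
                       set_id = set_id)
}

#' @rdname hypergeom_ora
#' @param k,m,Kpop,Npop Annotated-in-module, module size, annotated-in-
#'   population, population size.
#' @export
hypergeom_ora_counts <- function(k, m, Kpop, Npop, set_id = "set") {
  stopifnot(k >= 0, k <= m, Kpop <= Npop, k <= Kpop, m <= Npop)
  tails <- hyper_tails(k, m, Kpop, Npop)
  fold <- if (Kpop == 0 || m == 0) NA_real_ else (k / m) / (Kpop / Npop)
  out <- tibble::tibble(set_id = set_id, module_size = as.integer(m),
                        population_size = as.integer(Npop),
                        annotated_population = as.integer(Kpop),
                        annotated_module = as.integer(k),
                        fold = fold, p_enrich = tails$p_enrich,
                        p_deplete = tails$p_deplete)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' TF-binding fold enrichment of a module
#'
#' The binding analogue of [hypergeom_ora()]: `annotated` is the set of
#' genes whose promoter carries a protein-bound motif site, so `fold` is
#' the module's bound proportion over the genome-wide bound proportion
#' (e.g. 49% bound among targets over 28% genome-wide = 1.75) with exact
#' hypergeometric enrichment and depletion tails.
#'
#' @inheritParams hypergeom_ora
#' @param bound Character vector of bound genes (or a binding table from
#'   [generate_binding_table()] / [read_binding_table()], in which case the
#'   `bound` flags are used).
#' @export
binding_fold_enrichment <- function(module, bound, population, set_id = "binding") {
  if (is.data.frame(bound)) bound <- bound$gene[bound$bound]
  hypergeom_ora(module, bound, population, set_id = set_id)
}

#' Enrichment of every module against a term collection
#'
#' Runs [hypergeom_ora()] for each module x term pair and optionally adds a
#' Benjamini-Hochberg adjusted column over all pairs.
#'
#' @param partition A [mcl_cluster()] partition.
#' @param terms Named list term -> gene vector (e.g. from [read_gmt()]).
#' @param population All analysed genes.
#' @param adjust Add `p_adjust` (BH over `p_enrich`).
#' @return Tibble: `module`, then the [hypergeom_ora()] columns.
#' @export
module_enrichment <- function(partition, terms, population, adjust = FALSE) {
  mods <- split(partition$gene, partition$module)
  out <- purrr::map_dfr(names(mods), function(mid) {
    genes <- intersect(mods[[mid]], population)
    if (length(genes) == 0) return(NULL)
    purrr::map_dfr(names(terms), function(tid) {
      res <- hypergeom_ora(genes, terms[[tid]], population, set_id = tid)
      dplyr::bind_cols(tibble::tibble(module = as.integer(mid)), res)
    })
  })
  if (adjust && nrow(out)) out$p_adjust <- stats::p.adjust(out$p_enrich, method = "BH")
  out
}

#' Per-module summary of per-gene genomic values
#'
#' Aggregates a per-gene value (expression level, H3K4me3 signal, promoter
#' methylation, ...) to one number per module. Genes without a value are
#' dropped; modules with no valued genes are reported as `NA` and flagged.
#'
#' @param partition A [mcl_cluster()] partition.
#' @param values Named numeric vector gene -> value, or a data frame with
#'   columns `gene`, `value`.
#' @param statistic `"median"` or `"mean"`.
#' @return Tibble: `module`, `n_genes` (with values), `value`.
#' @export
module_value_summary <- function(partition, values, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  if (is.data.frame(values)) values <- stats::setNames(values$value, values$gene)
  fn <- if (statistic == "median") stats::median else mean
  out <- partition |>
    dplyr::mutate(value = unname(values[.data$gene])) |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(n_genes = sum(!is.na(.data$value)),
                     value = if (any(!is.na(.data$value)))
                       fn(.data$value[!is.na(.data$value)]) else NA_real_,
                     .groups = "drop")
  if (any(is.na(out$value))) {
    warning("modules with no values: ",
            paste(out$module[is.na(out$value)], collapse = ", "))
  }
  out
}

#' Read a GMT term-to-genes file
#'
#' Standard GMT: one term per line, tab-separated
#' `term <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param path GMT file.
#' @return Named list term -> character vector of genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(x) unique(x[-(1:2)])),
                  vapply(parts, `[[`, "", 1))
}

#' Read a two-column bound-gene table
#'
#' TSV with a header and columns `gene` and `bound` (logical or 0/1).
#'
#' @param path TSV file.
#' @return Tibble: `gene`, `bound`.
#' @export
read_binding_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "bound") %in% names(df)))
  tibble::tibble(gene = as.character(df$gene), bound = as.logical(df$bound))
}
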