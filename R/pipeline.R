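#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run in one named list. The
#' default is the genome-wide scan configuration (promoters -2500..+200,
#' per-window PWM p-value 4^-8, pcor edge cutoff 0.04, bias cutoff
#' Z >= 3.5, enrichment cutoff p <= 1e-5, at least 5 pooled occurrences for
#' the bias test). [nfy_config()] switches to the CCAAT/NF-Y geometry
#' (-1000..0, the motif being too frequent for the wide window), and
#' [sp1_config()] to the Sp1 settings (Z >= 4, p <= 1e-4, -2500..+200).
#'
#' @param ... Overrides of the defaults, by name.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    upstream = 2500, downstream = 200,
    pwm_pvalue = 4^-8,
    pcor_cutoff = 0.04, absolute = FALSE,
    z_cutoff = 3.5, p_cutoff = 1e-5, min_occurrences = 5,
    inflation = 2, n_perm = 10, seed = 1,
    dinucleotide = FALSE
  )
  over <- list(...)
  unknown <- setdiff(names(over), c(names(cfg), "pwm", "promoters", "expression", "network"))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$pwm_pvalue > 0, cfg$pwm_pvalue <= 1,
            cfg$p_cutoff > 0, cfg$p_cutoff <= 1,
            cfg$inflation > 1, cfg$n_perm >= 1, cfg$min_occurrences >= 1)
  check_geometry(cfg$upstream, cfg$downstream)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @rdname pipeline_config
#' @export
nfy_config <- function(...) pipeline_config(upstream = 1000, downstream = 0,
                                            z_cutoff = 3.5, p_cutoff = 1e-5, ...)

#' @rdname pipeline_config
#' @export
sp1_config <- function(...) pipeline_config(upstream = 2500, downstream = 200,
                                            z_cutoff = 4, p_cutoff = 1e-4, ...)

#' Run the full motif-module discovery pipeline
#'
#' Executes scan -> network -> target calling -> permutation FDR ->
#' sub-network extraction -> Markov clustering -> (optional) binding/term
#' enrichment, writing every stage's table plus a machine-readable summary
#' into `out_dir`. Stage outputs are pure functions of the inputs, the
#' configuration, and the seed; rerunning with the same seed reproduces
#' them byte for byte. The resolved configuration is written beside the
#' outputs.
#'
#' @param config A [pipeline_config()].
#' @param promoters A [promoter_set()] (or path to a masked FASTA).
#' @param pwm A [pwm_from_counts()] object (or path to a JASPAR PFM).
#' @param expression Expression tibble / TSV path; ignored when `network`
#'   is given.
#' @param network Optional prebuilt [build_network()] network or edge-list
#'   TSV path; skips pcor estimation.
#' @param binding Optional bound-gene table (tibble or TSV path) for module
#'   binding enrichment.
#' @param terms Optional named list (or GMT path) for module term
#'   enrichment.
#' @param out_dir Output directory (created). `NULL` skips file output.
#' @return List of class `pipeline_run`: `hits`, `network`, `calls`,
#'   `fdr`, `subnetwork`, `partition`, `binding_enrichment`,
#'   `term_enrichment`, `summary` (named list of counts), `config`.
#' @export
run_pipeline <- function(config, promoters, pwm, expression = NULL,
                         network = NULL, binding = NULL, terms = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  if (is.character(promoters)) promoters <- stage("load promoters", read_promoters_fasta(promoters))
  if (is.character(pwm)) pwm <- stage("load pwm", load_jaspar_pwm(pwm))
  if (is.character(expression)) expression <- stage("load expression", read_expression_tsv(expression))
  if (is.character(network)) network <- stage("load network", read_network_tsv(network))
  if (is.character(binding)) binding <- stage("load binding", read_binding_table(binding))
  if (is.character(terms)) terms <- stage("load terms", read_gmt(terms))

  threshold <- stage("threshold", pwm_score_threshold(pwm, config$pwm_pvalue))
  hits <- stage("scan", scan_promoters(promoters, pwm, threshold))
  if (is.null(network)) {
    if (is.null(expression)) stop("pipeline stage 'network' failed: neither an expression matrix nor a prebuilt network was given")
    pc <- stage("pcor", estimate_pcor(expression))
    network <- stage("network", build_network(pc, config$pcor_cutoff, config$absolute))
  }
  # restrict to genes that have both an edge and a promoter sequence
  common <- intersect(network_nodes(network), promoters$gene)
  network <- stage("network", extract_subnetwork(network, common))
  calls <- stage("targets", call_targets(network, promoters, hits,
                                         z_cutoff = config$z_cutoff,
                                         p_cutoff = config$p_cutoff,
                                         min_occurrences = config$min_occurrences))
  fdr <- NULL
  if (config$n_perm >= 1 && nrow(calls$targets) >= 1) {
    fdr <- stage("fdr", permutation_fdr(
      network, promoters, pwm, threshold,
      z_cutoff = config$z_cutoff, p_cutoff = config$p_cutoff,
      min_occurrences = config$min_occurrences, n_perm = config$n_perm,
      seed = config$seed, dinucleotide = config$dinucleotide,
      observed = nrow(calls$targets)))
  }
  sub <- stage("subnetwork", extract_subnetwork(network, calls$targets$gene))
  partition <- stage("modules", mcl_cluster(sub, inflation = config$inflation))
  population <- network_nodes(network)
  binding_enrichment <- NULL
  if (!is.null(binding)) {
    binding_enrichment <- stage("binding enrichment", {
      mods <- split(partition$gene, partition$module)
      purrr::map_dfr(names(mods), function(mid) {
        dplyr::bind_cols(tibble::tibble(module = as.integer(mid)),
                         binding_fold_enrichment(mods[[mid]], binding, population))
      })
    })
  }
  term_enrichment <- NULL
  if (!is.null(terms)) {
    term_enrichment <- stage("term enrichment",
                             module_enrichment(partition, terms, population))
  }
  summary <- list(
    n_promoters = nrow(promoters),
    n_network_genes = length(population),
    n_network_edges = nrow(network),
    n_motif_genes = length(unique(hits$gene)),
    n_hits = nrow(hits),
    n_targets = nrow(calls$targets),
    n_targets_by_bias = sum(calls$targets$by_bias),
    n_targets_by_enrichment = sum(calls$targets$by_enrichment),
    n_targets_by_both = sum(calls$targets$by_bias & calls$targets$by_enrichment),
    fdr = if (is.null(fdr)) NA_real_ else fdr$fdr,
    n_modules = length(attr(partition, "module_sizes")),
    largest_module = if (length(attr(partition, "module_sizes")))
      attr(partition, "module_sizes")[1] else 0L
  )
  run <- structure(list(hits = hits, network = network, calls = calls, fdr = fdr,
                        subnetwork = sub, partition = partition,
                        binding_enrichment = binding_enrichment,
                        term_enrichment = term_enrichment,
                        summary = summary, config = config),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline_run(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "<pipeline run>\n",
    "  network: %d genes, %d edges; motif in %d promoters (%d hits)\n",
    "  targets: %d (bias %d, enrichment %d, both %d); permutation FDR %s\n",
    "  modules: %d (largest %d)\n"),
    s$n_network_genes, s$n_network_edges, s$n_motif_genes, s$n_hits,
    s$n_targets, s$n_targets_by_bias, s$n_targets_by_enrichment,
    s$n_targets_by_both,
    if (is.na(s$fdr)) "not run" else sprintf("%.2f%%", 100 * s$fdr),
    s$n_modules, s$largest_module))
  invisible(x)
}

write_pipeline_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_hits_tsv(run$hits, p("hits.tsv"))
  write_network_tsv(run$network, p("network.tsv"))
  write_target_calls_tsv(run$calls, p("seeds.tsv"), p("targets.tsv"))
  write_partition_tsv(run$partition, p("modules.tsv"), p("module_sizes.tsv"))
  if (!is.null(run$binding_enrichment)) {
    utils::write.table(run$binding_enrichment, p("binding_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$term_enrichment)) {
    utils::write.table(run$term_enrichment, p("term_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$fdr)) {
    utils::write.table(run$fdr, p("fdr.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(run$summary, p("summary.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(unclass(run$config), p("config.yaml"))
  invisible(out_dir)
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file of `key: value` pairs understood by
#'   [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}
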