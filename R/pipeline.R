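# End-to-end orchestration: origin analysis (classify -> detect -> tree) and
# mapping analysis (phenotypes -> segregation chi-square -> genetic map),
# with machine-readable summaries and a resolved-config copy next to every
# output set.

RUN_CONFIG_KEYS <- c("seed", "out_dir", "panel", "classification",
                     "detection", "tree", "mapping", "enzymes")

#' Assemble a run configuration
#'
#' Unknown keys are rejected; every run writes a resolved copy of the
#' configuration alongside its outputs.
#'
#' @param seed integer seed applied to every stochastic stage.
#' @param out_dir output directory (created if absent).
#' @param panel list: either `simulate = list(...)` with
#'   [panel_sim_config()] arguments, or `genotypes = <path>` (VCF/TSV) plus
#'   `metadata = <path>` (panel TSV).
#' @param classification list of [classification_policy()] arguments.
#' @param detection list of [detection_params()] arguments.
#' @param tree list: `min_overlap`, `het_weight` for
#'   [p_distance_matrix()].
#' @param mapping list: either `simulate = list(...)` with
#'   [pop_sim_config()] arguments or `table = <path>` (population TSV);
#'   plus `loci`, optional `anchor`, `ratio` (default `c(3, 1)`),
#'   `threshold` (default 2), `it_column` (default `"it"`).
#' @param enzymes optional path to a restriction-enzyme TSV.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("introscan_"),
                       panel = NULL, classification = list(),
                       detection = list(), tree = list(), mapping = NULL,
                       enzymes = NULL) {
  cfg <- list(seed = seed, out_dir = out_dir, panel = panel,
              classification = classification, detection = detection,
              tree = tree, mapping = mapping, enzymes = enzymes)
  stopifnot(is_count(seed))
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose top-level keys are [run_config()] arguments;
#'   unknown keys are an error.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, y)
}

write_resolved_config <- function(config, out_dir) {
  resolved <- unclass(config)
  resolved$out_dir <- out_dir
  yaml::write_yaml(resolved, file.path(out_dir, "resolved_config.yaml"))
}

resolve_panel_inputs <- function(config) {
  p <- config$panel
  if (is.null(p)) stop("origin analysis: config$panel is required")
  if (!is.null(p$simulate)) {
    args <- p$simulate
    if (is.null(args$seed)) args$seed <- config$seed
    sim <- simulate_species_panel(do.call(panel_sim_config, args))
    list(geno = sim$geno, panel = sim$panel,
         chrom_length = sim$config$chrom_length, sim = sim)
  } else {
    if (is.null(p$genotypes) || is.null(p$metadata)) {
      stop("origin analysis: panel needs 'simulate' or 'genotypes' + 'metadata'")
    }
    list(geno = read_genotype_table(p$genotypes),
         panel = read_panel_metadata(p$metadata),
         chrom_length = p$chrom_length, sim = NULL)
  }
}

#' Run the origin analysis end to end
#'
#' Classifies sites, detects the introgressed segment and its breakpoint
#' bracket, and (when a segment is called) builds a neighbor-joining tree
#' from p-distances restricted to the called segment to place the query
#' relative to the donor candidates. Writes `classification.tsv`,
#' `segment.bed`, `density_profile.tsv`, `tree.nwk`, `summary.json` and
#' `resolved_config.yaml` under `config$out_dir`.
#'
#' @param config a [run_config()] with a `panel` entry.
#' @return The summary list (status `"ok"` or `"no_call"`, per-category
#'   site counts, segment interval, breakpoint bracket, tree placement),
#'   invisibly.
#' @export
run_origin_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- resolve_panel_inputs(config)
  policy <- do.call(classification_policy, config$classification %||% list())
  params <- do.call(detection_params, config$detection %||% list())

  classified <- classify_sites(inputs$geno, inputs$panel, policy)
  utils::write.table(classified, file.path(out_dir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  chrom <- unique(classified$chrom)[1]
  call <- detect_segment(classified[classified$chrom == chrom, ], params,
                         chrom_length = inputs$chrom_length)
  write_segment_bed(call, file.path(out_dir, "segment.bed"))

  category_counts <- as.list(table(classified$category))
  summary <- list(status = if (is.null(call)) "no_call" else "ok",
                  chrom = chrom,
                  n_sites = nrow(classified),
                  category_counts = category_counts,
                  parameters = list(policy = unclass(policy),
                                    detection = unclass(params)))

  if (!is.null(call)) {
    utils::write.table(call$density_profile,
                       file.path(out_dir, "density_profile.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    tree_opts <- config$tree %||% list()
    region <- restrict_to_region(inputs$geno, chrom,
                                 call$segment_start, call$segment_end)
    dmat <- p_distance_matrix(region,
                              min_overlap = tree_opts$min_overlap %||% 50,
                              het_weight = tree_opts$het_weight %||% 0.5)
    tree <- neighbor_joining(dmat)
    write_newick(tree, file.path(out_dir, "tree.nwk"))
    donors <- inputs$panel$id[inputs$panel$group == "DONOR_CANDIDATE"]
    query <- inputs$panel$id[inputs$panel$group == "QUERY"]
    coph <- ape::cophenetic.phylo(tree)[query, ]
    coph <- coph[names(coph) != query]
    summary$segment <- list(start = call$segment_start,
                            end = call$segment_end,
                            end_mb = round_half_out(call$segment_end / 1e6, 2),
                            n_support = call$n_support)
    summary$breakpoint <- list(lo = call$breakpoint_lo,
                               hi = call$breakpoint_hi)
    summary$tree <- list(
      query = query,
      nearest_neighbor = names(coph)[which.min(coph)],
      query_in_donor_clade = ape::is.monophyletic(tree, c(donors, query)))
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_resolved_config(config, out_dir)
  invisible(summary)
}

resolve_population_inputs <- function(config) {
  m <- config$mapping
  if (is.null(m)) stop("mapping analysis: config$mapping is required")
  if (!is.null(m$simulate)) {
    args <- m$simulate
    if (is.null(args$seed)) args$seed <- config$seed
    sim <- simulate_mapping_population(do.call(pop_sim_config, args))
    list(population = sim$population,
         loci = m$loci %||% sim$config$loci, sim = sim)
  } else {
    if (is.null(m$table)) {
      stop("mapping analysis: mapping needs 'simulate' or 'table'")
    }
    pop <- utils::read.delim(m$table, stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (is.null(m$loci)) stop("mapping analysis: 'loci' is required with a table")
    list(population = pop, loci = m$loci, sim = NULL)
  }
}

#' Run the mapping analysis end to end
#'
#' Classifies infection-type phenotypes, tests the observed
#' resistant/susceptible split against the expected ratio, and builds the
#' genetic map from minimal recombinant-gamete counts. Writes `map.tsv`,
#' `map_chart.txt`, `segregation.json`, `summary.json` and
#' `resolved_config.yaml` under `config$out_dir`.
#'
#' @param config a [run_config()] with a `mapping` entry.
#' @return The summary list (segregation test, interval table,
#'   co-segregation groups), invisibly.
#' @export
run_mapping_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- resolve_population_inputs(config)
  m <- config$mapping
  pop <- inputs$population
  it_column <- m$it_column %||% "it"
  ratio <- m$ratio %||% c(3, 1)
  threshold <- m$threshold %||% 2

  summary <- list(status = "ok", n_plants = nrow(pop))
  if (it_column %in% names(pop)) {
    ph <- classify_phenotype(pop[[it_column]], threshold = threshold)
    n_r <- sum(ph$binary == "R")
    n_s <- sum(ph$binary == "S")
    seg <- tryCatch(chi2_segregation(n_r, n_s, ratio), error = identity)
    if (inherits(seg, "error")) {
      summary$segregation <- list(n_r = n_r, n_s = n_s,
                                  note = paste("ratio-fit failure:",
                                               conditionMessage(seg)))
    } else {
      if (n_r == 0 || n_s == 0) {
        summary$segregation_note <-
          "one phenotype class is empty; ratio fit is degenerate"
      }
      summary$segregation <- list(n_r = n_r, n_s = n_s, ratio = ratio,
                                  chi2 = round_half_out(seg$chi2, 2),
                                  df = seg$df, p = seg$p)
      jsonlite::write_json(summary$segregation,
                           file.path(out_dir, "segregation.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }

  gmap <- build_genetic_map(pop, inputs$loci, anchor = m$anchor)
  utils::write.table(gmap$intervals, file.path(out_dir, "map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_genetic_map(gmap, file.path(out_dir, "map_chart.txt"))
  summary$map <- list(loci = gmap$map$locus, pos_cM = gmap$map$pos_cM,
                      groups = gmap$map$group,
                      intervals = gmap$intervals)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_resolved_config(config, out_dir)
  invisible(summary)
}
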