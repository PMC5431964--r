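#' Assemble a validated end-to-end run configuration
#'
#' Defaults reproduce the conventional analysis parameters: 1,250 km²
#' minimum cell land area, hotspot thresholds of 5% and 10% of cells, and a
#' 10% reserve-coverage gap threshold, so an un-tuned run is the standard
#' analysis.
#'
#' @param occurrences,tree,cells paths to the occurrence CSV, Newick tree
#'   and cell-table CSV. All three may be omitted when `simulate` is given.
#' @param taxonomy optional path to a species/genus/family CSV.
#' @param simulate optional [synthetic_config()]; when given, inputs are
#'   generated instead of read and the file paths are ignored.
#' @param out_dir directory for the run's artifacts.
#' @param min_land_area exclusion threshold, km² (default 1250).
#' @param p hotspot threshold fractions (default `c(0.05, 0.10)`).
#' @param gap_threshold reserve-coverage fraction separating gaps from
#'   protected hotspot cells (default 0.10).
#' @param threshold_mode hotspot selection mode, `"cells"` or `"range"`.
#' @param adjacency region adjacency rule, `"queen"` or `"rook"`.
#' @param rooted PD rooting convention (see [faith_pd()]).
#' @param pdrel_s1 single-species-cell handling for PD_rel.
#' @param seed seed recorded in the manifest (and used by `simulate`).
#' @return a list of class `run_config`.
#' @export
run_config <- function(occurrences = NULL, tree = NULL, cells = NULL,
                       taxonomy = NULL, simulate = NULL, out_dir = "run_out",
                       min_land_area = 1250, p = c(0.05, 0.10),
                       gap_threshold = 0.10,
                       threshold_mode = c("cells", "range"),
                       adjacency = c("queen", "rook"),
                       rooted = TRUE,
                       pdrel_s1 = c("undefined", "zero"),
                       seed = 1) {
  threshold_mode <- match.arg(threshold_mode)
  adjacency <- match.arg(adjacency)
  pdrel_s1 <- match.arg(pdrel_s1)
  stopifnot(min_land_area >= 0, all(p > 0 & p < 1),
            gap_threshold > 0, gap_threshold < 1)
  if (is.null(simulate) && (is.null(occurrences) || is.null(tree) || is.null(cells))) {
    stop("either provide occurrences/tree/cells paths or a simulate config",
         call. = FALSE)
  }
  structure(list(occurrences = occurrences, tree = tree, cells = cells,
                 taxonomy = taxonomy, simulate = simulate, out_dir = out_dir,
                 min_land_area = min_land_area, p = sort(p),
                 gap_threshold = gap_threshold,
                 threshold_mode = threshold_mode, adjacency = adjacency,
                 rooted = rooted, pdrel_s1 = pdrel_s1,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; a `simulate:` mapping is
#' passed to [synthetic_config()]. Unset keys take the standard defaults.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(synthetic_config, y$simulate)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, y)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full hotspot and gap analysis pipeline
#'
#' Orchestrates input loading (or simulation), cell filtering, taxon
#' alignment, the per-cell diversity table, per-metric hotspot selection at
#' each threshold, multi-metric overlap accounting, contiguous-region
#' labeling, and gap classification. All tabular artifacts are written as
#' CSV, summaries as JSON, plus a manifest echoing the configuration with
#' input hashes and the log of every drop/flag decision. Re-running on
#' identical inputs and configuration produces byte-identical files.
#'
#' @param config a [run_config()] or path to a YAML file for
#'   [read_run_config()].
#' @return invisibly, a list with the in-memory results: `cells`, `matrix`,
#'   `tree`, `diversity`, `hotspots` (per p, per metric), `union` (per p),
#'   `overlap` (per p), `regions`, `gaps`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log <- character(0)
  note <- function(...) log <<- c(log, paste0(...))
  capture_messages <- function(expr) {
    withCallingHandlers(expr, message = function(m) {
      note(sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  }

  hashes <- list()
  if (!is.null(config$simulate)) {
    sim <- pipeline_stage("simulate",
                          simulate_dataset(config$simulate, dir = file.path(out, "inputs")))
    cells <- sim$cells
    tree <- sim$tree
    mat <- sim$matrix
    note("simulated inputs with seed ", config$simulate$seed)
    for (f in c("cells.csv", "tree.nwk", "occurrences.csv")) {
      hashes[[f]] <- unname(tools::md5sum(file.path(out, "inputs", f)))
    }
  } else {
    for (f in c(config$cells, config$tree, config$occurrences, config$taxonomy)) {
      if (!file.exists(f)) {
        stop("[stage: inputs] input file not found: ", f, call. = FALSE)
      }
      hashes[[basename(f)]] <- unname(tools::md5sum(f))
    }
    cells <- pipeline_stage("cells", read_cells(config$cells))
    tree <- pipeline_stage("phylogeny", read_newick(config$tree))
    mat <- capture_messages(
      pipeline_stage("occurrences", load_occurrences(config$occurrences, cells)))
  }

  filtered <- capture_messages(
    pipeline_stage("filter", filter_cells(cells, mat, config$min_land_area)))
  cells <- filtered$cells
  mat <- filtered$matrix
  aligned <- capture_messages(pipeline_stage("align", align_taxa(mat, tree)))
  mat <- aligned$matrix
  tree <- aligned$tree
  note("analysis grid: ", nrow(cells), " cells, ", nrow(mat), " species")

  div <- pipeline_stage("diversity",
                        diversity_table(tree, mat, pdrel_s1 = config$pdrel_s1,
                                        rooted = config$rooted))
  utils::write.csv(div, file.path(out, "diversity.csv"), row.names = FALSE)

  metrics <- c("SR", "CWE_pct", "PD_rel", "PE")
  hotspots <- list()
  unions <- list()
  overlaps <- list()
  for (p in config$p) {
    tag <- sprintf("p%02.0f", 100 * p)
    sets <- lapply(metrics, function(m) {
      pipeline_stage("hotspots",
                     select_hotspots(div, m, p, mode = config$threshold_mode))
    })
    names(sets) <- metrics
    uni <- hotspot_union(sets)
    sel <- do.call(rbind, lapply(sets, function(s) {
      data.frame(cell_id = s$cells, metric = s$metric, p = s$p)
    }))
    sel$n_metrics <- uni$n_metrics[match(sel$cell_id, uni$cell_id)]
    rownames(sel) <- NULL
    utils::write.csv(sel[order(sel$metric, sel$cell_id), ],
                     file.path(out, paste0("hotspots_", tag, ".csv")),
                     row.names = FALSE)
    ov <- pipeline_stage("overlap", overlap_summary(sets, cells, mat))
    hotspots[[tag]] <- sets
    unions[[tag]] <- uni
    overlaps[[tag]] <- ov
  }

  # regions and gaps on the union of the largest threshold (the main map)
  main_tag <- sprintf("p%02.0f", 100 * max(config$p))
  main_union <- unions[[main_tag]]
  regions <- pipeline_stage("regions",
                            label_regions(main_union$cell_id, cells,
                                          adjacency = config$adjacency))
  if (!is.null(config$taxonomy)) {
    taxonomy <- utils::read.csv(config$taxonomy, stringsAsFactors = FALSE)
    ratios <- lapply(regions$regions$region_id, function(rid) {
      ids <- regions$membership$cell_id[regions$membership$region_id == rid]
      pipeline_stage("regions", region_taxon_ratios(ids, mat, taxonomy))
    })
    regions$regions$n_species <- vapply(ratios, `[[`, numeric(1L), "n_species")
    regions$regions$species_genus_ratio <-
      vapply(ratios, `[[`, numeric(1L), "species_genus_ratio")
    regions$regions$species_family_ratio <-
      vapply(ratios, `[[`, numeric(1L), "species_family_ratio")
  }
  utils::write.csv(merge(regions$membership, main_union, by = "cell_id"),
                   file.path(out, "regions.csv"), row.names = FALSE)
  gaps <- pipeline_stage("gaps",
                         classify_gaps(main_union, cells,
                                       threshold = config$gap_threshold))
  utils::write.csv(gaps$cells, file.path(out, "gaps.csv"), row.names = FALSE)

  summary <- list(
    thresholds = config$p,
    overlap = lapply(overlaps, function(ov) {
      list(union_cells = ov$union$n_cells,
           union_land_area = ov$union$land_area,
           union_land_fraction = ov$union$land_fraction,
           union_species = ov$species$union_count,
           union_species_fraction = ov$species$union_fraction,
           per_n = ov$per_n,
           pairwise = ov$pairwise)
    }),
    regions = regions$regions,
    gap_summary = as.list(gaps$summary),
    gap_per_n = gaps$per_n
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package = "phylohotspot",
    version = as.character(utils::packageVersion("phylohotspot")),
    config = config_echo(config),
    input_md5 = hashes,
    log = log
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cells = cells, matrix = mat, tree = tree, diversity = div,
                 hotspots = hotspots, union = unions, overlap = overlaps,
                 regions = regions, gaps = gaps, manifest = manifest))
}

config_echo <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$simulate)) cfg$simulate <- unclass(cfg$simulate)
  cfg[!vapply(cfg, is.null, logical(1L))]
}
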