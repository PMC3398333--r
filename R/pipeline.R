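#' Pipeline configuration
#'
#' Collects the paths, thresholds and seeds that drive [run_pipeline()].
#' When `simulate` is `TRUE` the synthetic-data module generates catalog,
#' counts and colorimetry under `sim_config`; otherwise `catalog_path`,
#' `counts_stem` and (optionally) `colorimetry_path` must point at existing
#' TSV inputs.
#'
#' @param output_dir Directory for all outputs (created if missing).
#' @param simulate Generate synthetic inputs instead of reading files.
#' @param sim_config A [simulation_config()] used when `simulate = TRUE`.
#' @param catalog_path,counts_stem,colorimetry_path Input locations used when
#'   `simulate = FALSE` (`counts_stem` as in [read_counts()]).
#' @param fdr,lfc,rpkm_floor DE screen thresholds.
#' @param top_k Neighbors kept per gene in the co-expression network.
#' @param k_clusters Trajectory clusters for k-means.
#' @param max_fold Visualization fold-change bound.
#' @param seed Seed for the clustering restarts (simulation has its own seed
#'   inside `sim_config`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir,
                            simulate = TRUE,
                            sim_config = simulation_config(),
                            catalog_path = NULL,
                            counts_stem = NULL,
                            colorimetry_path = NULL,
                            fdr = 0.001, lfc = 1, rpkm_floor = 0.01,
                            top_k = 12, k_clusters = 10, max_fold = 32,
                            seed = 1) {
  stopifnot(fdr > 0, lfc > 0, rpkm_floor > 0, top_k >= 1, k_clusters >= 1,
            max_fold > 1)
  structure(list(output_dir = output_dir, simulate = simulate,
                 sim_config = sim_config, catalog_path = catalog_path,
                 counts_stem = counts_stem,
                 colorimetry_path = colorimetry_path,
                 fdr = fdr, lfc = lfc, rpkm_floor = rpkm_floor,
                 top_k = top_k, k_clusters = k_clusters,
                 max_fold = max_fold, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage_log <- function(quiet, stage, ...) {
  if (!quiet) message(sprintf("[%s] ", stage), ...)
}

.run_stage <- function(stage, quiet, expr) {
  .stage_log(quiet, stage, "running")
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full expression-analysis pipeline
#'
#' Executes simulate (optional) -> quantify -> DE test -> profiles ->
#' co-expression -> KO aggregation -> colorimetry, writing every intermediate
#' as TSV under the configured output directory plus a YAML manifest
#' recording the configuration, seeds, package version and row counts per
#' output. Reruns with an identical configuration are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress stage-tagged progress messages.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  outputs <- list()
  note <- function(name, file, rows) {
    outputs[[name]] <<- list(file = basename(file), rows = rows)
  }

  colorimetry <- NULL
  if (config$simulate) {
    sim <- .run_stage("simulate", quiet, {
      catalog <- generate_catalog(config$sim_config)
      res <- simulate_counts(catalog, config$sim_config)
      colorimetry <- simulate_colorimetry(
        stages = length(res$counts$stage_libraries),
        seed = config$sim_config$seed)
      write_tsv(catalog, out("catalog.tsv"))
      write_counts(res$counts, out("counts"))
      truth <- data.frame(gene_id = res$truth$de_genes,
                          direction = unname(res$truth$direction),
                          effect_log2 = unname(res$truth$effect_log2))
      write_tsv(truth, out("truth.tsv"))
      write_tsv(colorimetry, out("colorimetry.tsv"))
      yaml::write_yaml(unclass(config$sim_config), out("sim_config.yaml"))
      note("catalog", out("catalog.tsv"), nrow(catalog))
      note("counts", out("counts.tsv"), nrow(res$counts$counts))
      note("truth", out("truth.tsv"), nrow(truth))
      note("colorimetry", out("colorimetry.tsv"), nrow(colorimetry))
      list(catalog = catalog, counts = res$counts,
           colorimetry = colorimetry)
    })
    catalog <- sim$catalog; counts <- sim$counts
    colorimetry <- sim$colorimetry
  } else {
    loaded <- .run_stage("load", quiet, {
      catalog <- read_tsv(config$catalog_path)
      counts <- read_counts(config$counts_stem)
      colorimetry <- if (!is.null(config$colorimetry_path)) {
        read_tsv(config$colorimetry_path)
      }
      list(catalog = catalog, counts = counts, colorimetry = colorimetry)
    })
    catalog <- loaded$catalog; counts <- loaded$counts
    colorimetry <- loaded$colorimetry
  }
  stages <- counts$stage_libraries

  rpkm <- .run_stage("quantify", quiet, {
    rpkm <- compute_rpkm(counts, catalog)
    expr <- data.frame(gene_id = rownames(rpkm), rpkm, check.names = FALSE)
    for (s in stages) expr[[paste0("bin_", s)]] <-
      assign_expression_bin(rpkm[, s])
    write_tsv(expr, out("expression.tsv"))
    note("expression", out("expression.tsv"), nrow(expr))
    rpkm
  })

  de <- .run_stage("detest", quiet, {
    de <- de_all_pairs(counts, catalog, config$fdr, config$lfc,
                       config$rpkm_floor)
    for (nm in names(de)) {
      write_tsv(de[[nm]], out(paste0("de_", nm, ".tsv")))
      note(paste0("de_", nm), out(paste0("de_", nm, ".tsv")), nrow(de[[nm]]))
    }
    union <- union_pairwise(de)
    writeLines(union, out("de_union.txt"))
    note("de_union", out("de_union.txt"), length(union))
    de
  })
  de_genes <- union_pairwise(de)

  .run_stage("classify", quiet, {
    prof <- profile_assignments(rpkm, genes = de_genes, stages = stages,
                                rpkm_floor = config$rpkm_floor)
    prof$visualized <- prof$gene_id %in%
      filter_for_visualization(prof, config$max_fold)
    if (length(de_genes) >= config$k_clusters) {
      cl <- kmeans_profiles(rpkm[de_genes, , drop = FALSE],
                            k = config$k_clusters, seed = config$seed,
                            stages = stages)
      prof$cluster <- unname(cl[prof$gene_id])
    }
    write_tsv(prof, out("profiles.tsv"))
    note("profiles", out("profiles.tsv"), nrow(prof))
  })

  .run_stage("coexpress", quiet, {
    el_empty <- data.frame(gene_a = character(0), gene_b = character(0),
                           pcc = numeric(0), mr = numeric(0))
    el <- el_empty
    net <- NULL
    if (length(de_genes) >= 2) {
      cc <- pairwise_pcc(rpkm[de_genes, , drop = FALSE], stages = stages)
      if (nrow(cc) >= 2) {
        net <- build_topk_network(mutual_rank(cc), k = config$top_k)
        el <- network_edge_table(net)
      }
    }
    write_tsv(el, out("network_edges.tsv"))
    if (!is.null(net)) {
      igraph::write_graph(net, out("network.graphml"), format = "graphml")
    }
    note("network_edges", out("network_edges.tsv"), nrow(el))
  })

  .run_stage("aggregate", quiet, {
    fam <- aggregate_by_ko(rpkm, counts, catalog)
    fam <- classify_family_regulation(fam, counts, config$fdr, config$lfc,
                                      config$rpkm_floor)
    write_tsv(fam, out("ko_families.tsv"))
    export_pathway_selection(fam, out("pathway_magnitude.txt"),
                             mode = "magnitude", stage = stages[1])
    export_pathway_selection(fam, out("pathway_change.txt"), mode = "change")
    note("ko_families", out("ko_families.tsv"), nrow(fam))
  })

  if (!is.null(colorimetry)) {
    .run_stage("cirg", quiet, {
      cs <- summarize_color(colorimetry)
      write_tsv(cs, out("cirg_summary.tsv"))
      note("cirg_summary", out("cirg_summary.tsv"), nrow(cs))
    })
  }

  manifest <- list(
    package = "dgexact",
    version = as.character(utils::packageVersion("dgexact")),
    seed = config$seed,
    sim_seed = if (config$simulate) config$sim_config$seed,
    thresholds = list(fdr = config$fdr, lfc = config$lfc,
                      rpkm_floor = config$rpkm_floor,
                      top_k = config$top_k, k_clusters = config$k_clusters,
                      max_fold = config$max_fold),
    outputs = outputs)
  yaml::write_yaml(manifest, out("manifest.yaml"))
  .stage_log(quiet, "done", length(outputs), " outputs written to ",
             config$output_dir)
  invisible(manifest)
}
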