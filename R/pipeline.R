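# End-to-end orchestration: inputs (files or simulation) -> swarm catalog ->
# spectra -> CCSV clusterings -> PSAs, microRNA clusters, association map,
# enrichment tables, run manifest.

#' Assemble a pipeline configuration
#'
#' Either `simulate` (a [syntheticConfig()]) or all of `tissues`,
#' `processes`, `corpus` (file paths; `universe` defaults to the union of
#' all gene-set members) must be provided. Thresholds default to the CCSV
#' cuts used throughout the analysis: 0.897 on the swarm side, 0.92 on the
#' disease side, 0.67 on the microRNA side.
#'
#' @param simulate optional [syntheticConfig()]; when given, all inputs are
#'   generated.
#' @param tissues,processes,corpus,interactions,universe input file paths
#'   (GMT, GMT, JSONL, TSV edge list, one-symbol-per-line text).
#' @param q_threshold module admission FDR for [buildSwarmCatalog()].
#' @param swarm_ccsv,disease_ccsv,mirna_ccsv CCSV cut thresholds.
#' @param metric,linkage,mode clustering metric/linkage and co-citation
#'   counting mode.
#' @param transform spectrum conditioning (`"log1p"` or `"none"`).
#' @param link_factor PSA-microRNA linkage factor.
#' @param seed integer seed (overrides the simulate block's seed).
#' @return a list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(simulate = NULL, tissues = NULL, processes = NULL,
                           corpus = NULL, interactions = NULL,
                           universe = NULL, q_threshold = 0.05,
                           swarm_ccsv = 0.897, disease_ccsv = 0.92,
                           mirna_ccsv = 0.67, metric = "pearson",
                           linkage = "average", mode = "any-member",
                           transform = "log1p", link_factor = 2.0,
                           seed = 1L) {
  if (is.null(simulate) &&
      (is.null(tissues) || is.null(processes) || is.null(corpus))) {
    .err("either a simulate block or tissues/processes/corpus paths are required")
  }
  if (!is.null(simulate)) {
    if (!inherits(simulate, "SyntheticConfig")) {
      simulate <- do.call(syntheticConfig, simulate)
    }
    simulate$seed <- as.integer(seed)
  }
  cfg <- list(
    simulate = simulate, tissues = tissues, processes = processes,
    corpus = corpus, interactions = interactions, universe = universe,
    q_threshold = q_threshold, swarm_ccsv = swarm_ccsv,
    disease_ccsv = disease_ccsv, mirna_ccsv = mirna_ccsv, metric = metric,
    linkage = linkage, mode = mode, transform = transform,
    link_factor = link_factor, seed = as.integer(seed)
  )
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path path to a YAML file whose keys mirror the arguments of
#'   [pipelineConfig()].
#' @return a `"PipelineConfig"` list.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, raw)
}

# canonical JSON of the config (stable key order) for hashing
.configJson <- function(config) {
  cfg <- config
  class(cfg) <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    class(sim) <- NULL
    cfg$simulate <- sim[order(names(sim))]
  }
  cfg <- cfg[order(names(cfg))]
  jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null")
}

.md5String <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeChar(x, tf, eos = NULL)
  unname(tools::md5sum(tf))
}

#' Run the full swarm association analysis
#'
#' Loads (or simulates) the inputs, builds the swarm catalog, counts the
#' swarm x disease and swarm x microRNA spectra, clusters both with CCSV
#' cuts, extracts PSAs and microRNA clusters, links them, enriches each
#' PSA's protein union against the process collection, and writes every
#' table plus a JSON run manifest (config hash, seed, md5 of each output).
#' Outputs are bitwise-identical for identical config and seed.
#'
#' @param config a `"PipelineConfig"` (or arguments for [pipelineConfig()]).
#' @param out_dir output directory; created if missing. `NULL` skips all
#'   file output.
#' @return (invisibly) a list bundle: catalog, spectra, trees, partitions,
#'   `psas`, `mirna_clusters`, `association_map`, `enrichment`, `manifest`,
#'   and (simulate mode) `truth`.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "PipelineConfig")) {
    config <- do.call(pipelineConfig, config)
  }
  truth <- NULL
  if (!is.null(config$simulate)) {
    uni <- makeUniverse(config$simulate)
    cc <- makeCorpus(uni, config$simulate)
    graph <- makeInteractions(uni, config$simulate)
    vocab <- uni$vocabulary
    tissues <- uni$tissues
    processes <- uni$processes
    corp <- cc$corpus
    universe <- vocab@proteins
    truth <- uni$truth
  } else {
    for (f in c(config$tissues, config$processes, config$corpus,
                config$interactions, config$universe)) {
      if (!is.null(f) && !file.exists(f)) .err("missing input: %s", f)
    }
    tissues <- readGeneSets(config$tissues)
    processes <- readGeneSets(config$processes)
    universe <- if (!is.null(config$universe)) {
      normalizeProtein(readLines(config$universe, warn = FALSE))
    } else {
      unique(c(unlist(tissues@sets, use.names = FALSE),
               unlist(processes@sets, use.names = FALSE)))
    }
    corp <- readCorpus(config$corpus)
    graph <- if (!is.null(config$interactions)) {
      readEdgeList(config$interactions, header = TRUE)
    } else NULL
    men <- mentions(corp)
    vocab <- entityVocabulary(
      proteins = universe,
      diseases = unique(unlist(lapply(men, `[[`, "diseases"))),
      functions = unique(unlist(lapply(men, `[[`, "functions"))),
      microRNAs = unique(unlist(lapply(men, `[[`, "microRNAs")))
    )
  }

  catalog <- buildSwarmCatalog(tissues, processes, universe,
                               q_threshold = config$q_threshold)
  if (!length(catalog@swarm_id)) .err("empty swarm catalog")

  diseases <- sort(vocab@diseases)
  mirnas <- sort(vocab@microRNAs)
  spec_dis <- buildSpectrumMatrix(corp, catalog, diseases, mode = config$mode)
  spec_mir <- buildSpectrumMatrix(corp, catalog, mirnas, mode = config$mode)

  dis_vals <- transformSpectrum(spec_dis, method = config$transform)$values
  swarm_tree <- hierarchicalMergeTree(
    similarityMatrix(dis_vals, config$metric, "rows"), config$linkage)
  disease_tree <- hierarchicalMergeTree(
    similarityMatrix(dis_vals, config$metric, "cols"), config$linkage)
  swarm_part <- ccsvCut(swarm_tree, config$swarm_ccsv)
  disease_part <- ccsvCut(disease_tree, config$disease_ccsv)

  psas <- extractPsas(swarm_part, catalog)
  mir <- clusterMirnas(spec_mir, threshold = config$mirna_ccsv,
                       metric = config$metric, linkage = config$linkage,
                       transform = config$transform)
  assoc <- mapMirnaClusters(spec_mir, psas, mir$clusters,
                            factor = config$link_factor)

  enrichment <- do.call(rbind, lapply(seq_len(nrow(psas)), function(i) {
    df <- enrichProteinSet(psas$proteins[[i]], processes, universe)
    if (nrow(df)) df$psa_id <- psas$psa_id[i]
    df
  }))

  subgraph <- if (!is.null(graph)) {
    inducedSubgraphStats(graph,
                         unique(unlist(psas$proteins, use.names = FALSE)))
  } else NULL

  result <- list(
    config = config, catalog = catalog,
    disease_spectrum = spec_dis, mirna_spectrum = spec_mir,
    swarm_tree = swarm_tree, disease_tree = disease_tree,
    mirna_tree = mir$tree,
    swarm_partition = swarm_part, disease_partition = disease_part,
    mirna_partition = mir$partition,
    psas = psas, mirna_clusters = mir$clusters, association_map = assoc,
    enrichment = enrichment, subgraph = subgraph, truth = truth
  )
  result$manifest <- .writeOutputs(result, out_dir)
  invisible(result)
}

# write TSV/Newick outputs and assemble the manifest (config hash + seed +
# md5 per file); with out_dir = NULL only the config hash is produced
.writeOutputs <- function(result, out_dir) {
  cfg_json <- .configJson(result$config)
  manifest <- list(
    config_hash = .md5String(cfg_json),
    seed = result$config$seed,
    files = list()
  )
  if (is.null(out_dir)) return(manifest)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character()

  wr <- function(name, fun) {
    p <- file.path(out_dir, name)
    fun(p)
    paths[[name]] <<- p
  }
  flat <- function(df) {
    for (cl in names(df)) {
      if (is.list(df[[cl]])) {
        df[[cl]] <- vapply(df[[cl]], paste, "", collapse = ",")
      }
      if (is.numeric(df[[cl]])) {
        df[[cl]] <- format(df[[cl]], digits = 12, trim = TRUE,
                           scientific = FALSE)
      }
    }
    df
  }
  partTsv <- function(part, p) {
    mem <- membership(part)
    ids <- names(part@clusters)[mem]
    utils::write.table(
      data.frame(label = names(mem), cluster = ids,
                 ccsv = format(unname(part@ccsv[ids]), digits = 12,
                               trim = TRUE, scientific = FALSE)),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  wr("swarms.tsv", function(p) writeSwarmCatalog(result$catalog, p))
  wr("spectrum_diseases.tsv",
     function(p) writeMatrixTsv(result$disease_spectrum@counts, p))
  wr("spectrum_mirnas.tsv",
     function(p) writeMatrixTsv(result$mirna_spectrum@counts, p))
  wr("swarm_tree.nwk", function(p) writeNewick(result$swarm_tree, p))
  wr("mirna_tree.nwk", function(p) writeNewick(result$mirna_tree, p))
  wr("swarm_partition.tsv", function(p) partTsv(result$swarm_partition, p))
  wr("disease_partition.tsv", function(p) partTsv(result$disease_partition, p))
  wr("psas.tsv", function(p) {
    utils::write.table(flat(result$psas), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  wr("mirna_clusters.tsv", function(p) {
    utils::write.table(flat(result$mirna_clusters), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
  wr("association_map.tsv", function(p) {
    utils::write.table(flat(result$association_map), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
  if (!is.null(result$enrichment) && nrow(result$enrichment)) {
    wr("enrichment.tsv", function(p) {
      utils::write.table(flat(result$enrichment), p, sep = "\t",
                         quote = FALSE, row.names = FALSE)
    })
  }

  manifest$files <- lapply(paths, function(p) unname(tools::md5sum(p)))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  manifest
}

#' Score a pipeline run against planted truth
#'
#' Compares the swarm-side partition with the planted block labels and the
#' microRNA partition with the planted cluster labels (adjusted Rand index),
#' and scores the predicted PSA-microRNA-cluster links against the planted
#' links: each predicted link is mapped to (majority planted block of the
#' PSA's swarms, majority planted cluster of the microRNA cluster) and
#' precision/recall are computed over these planted pairs.
#'
#' @param result bundle returned by [runPipeline()] (simulate mode), or any
#'   list with `swarm_partition`, `mirna_partition`, `psas`,
#'   `mirna_clusters`, `association_map`.
#' @param truth a [PlantedTruth-class] (defaults to `result$truth`).
#' @return list with `swarm_ari`, `mirna_ari`, `link_precision`,
#'   `link_recall`.
#' @export
evaluateRecovery <- function(result, truth = result$truth) {
  if (is.null(truth)) .err("no planted truth available")
  swarm_ids <- unlist(result$swarm_partition@clusters, use.names = FALSE)
  swarm_ari <- adjustedRand(result$swarm_partition,
                            truth@block_of_swarm[swarm_ids])
  mirna_ids <- unlist(result$mirna_partition@clusters, use.names = FALSE)
  mirna_ari <- adjustedRand(result$mirna_partition,
                            truth@mirna_cluster[mirna_ids])

  majority <- function(x) names(sort(table(x), decreasing = TRUE))[1]
  psa_block <- vapply(result$psas$swarms, function(s) {
    majority(truth@block_of_swarm[s])
  }, character(1))
  names(psa_block) <- result$psas$psa_id
  mc_truth <- vapply(result$mirna_clusters$members, function(s) {
    majority(truth@mirna_cluster[s])
  }, character(1))
  names(mc_truth) <- result$mirna_clusters$cluster_id

  linked <- result$association_map[result$association_map$linked, ,
                                   drop = FALSE]
  pred <- unique(paste(psa_block[linked$psa_id],
                       mc_truth[linked$mirna_cluster], sep = "\r"))
  want <- unique(paste(truth@links$block, truth@links$mirna_cluster,
                       sep = "\r"))
  tp <- length(intersect(pred, want))
  list(
    swarm_ari = swarm_ari,
    mirna_ari = mirna_ari,
    link_precision = if (length(pred)) tp / length(pred) else 0,
    link_recall = if (length(want)) tp / length(want) else 1
  )
}
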