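# Synthetic universe / corpus / interaction-graph generators with planted
# block structure and ground-truth labels. These define the benchmark
# conditions under which the whole pipeline is validated.

#' Configuration for the synthetic benchmark generator
#'
#' The generator emulates the measurement design of the real study at desk
#' scale: tissue proteomes and biological-process sets whose intersections
#' form overlap modules, a planted assignment of modules (hence swarms),
#' concepts and microRNA clusters to co-citation blocks, and an annotated
#' abstract corpus in which within-block co-mentions are elevated over
#' background.
#'
#' Geometry: each block `b` owns one tissue; its modules are the
#' intersections of that tissue with each of the `n_processes` process sets,
#' each of exactly `module_size` proteins. The planted protein count is
#' therefore `n_blocks * n_processes * module_size`, and must not exceed
#' `n_proteins`; remaining proteins form a background pool (set filler and
#' enrichment universe padding) that never appears in the corpus.
#'
#' @param n_proteins total protein universe size (default 3000).
#' @param n_tissues number of tissue proteome sets (>= `n_blocks`).
#' @param n_processes number of biological-process sets; also the number of
#'   overlap modules per block.
#' @param n_diseases,n_functions concept vocabulary sizes; concepts are dealt
#'   round-robin to blocks, leaving any remainder as unassigned background.
#' @param n_mirnas number of mature microRNAs; split into `n_blocks` planted
#'   clusters, cluster `b` attached to block `b`.
#' @param n_blocks number of planted co-citation blocks.
#' @param p_in within-block per-entity mention probability per abstract.
#' @param p_out background per-entity mention probability per abstract.
#' @param n_abstracts corpus size.
#' @param mean_mentions intended expected number of entity mentions per
#'   abstract; checked against the expectation implied by the other
#'   parameters (a gross mismatch triggers a warning), see the vignette.
#' @param module_size proteins per overlap module (chunked into
#'   `ceiling(module_size / 5)` swarms).
#' @param filler background-pool proteins added to each tissue/process set
#'   (drawn from disjoint slices, so intersections stay exactly the planted
#'   modules); keeps set sizes realistic while leaving planted overlaps
#'   enriched.
#' @param seed integer seed; all generators are pure functions of the config.
#' @return a list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(n_proteins = 3000L, n_tissues = 6L,
                            n_processes = 4L, n_diseases = 40L,
                            n_functions = 30L, n_mirnas = 24L,
                            n_blocks = 6L, p_in = 0.6, p_out = 0.02,
                            n_abstracts = 2000L, mean_mentions = NULL,
                            module_size = 25L, filler = 50L, seed = 1L) {
  cfg <- list(
    n_proteins = as.integer(n_proteins), n_tissues = as.integer(n_tissues),
    n_processes = as.integer(n_processes), n_diseases = as.integer(n_diseases),
    n_functions = as.integer(n_functions), n_mirnas = as.integer(n_mirnas),
    n_blocks = as.integer(n_blocks), p_in = p_in, p_out = p_out,
    n_abstracts = as.integer(n_abstracts), mean_mentions = mean_mentions,
    module_size = as.integer(module_size), filler = as.integer(filler),
    seed = as.integer(seed)
  )
  counts <- cfg[c("n_proteins", "n_tissues", "n_processes", "n_diseases",
                  "n_functions", "n_mirnas", "n_blocks", "module_size")]
  if (any(unlist(counts) < 1L)) .err("all counts must be >= 1")
  if (cfg$n_abstracts < 0L) .err("n_abstracts must be >= 0")
  if (cfg$filler < 0L) .err("filler must be >= 0")
  if (!(p_in > 0 && p_in <= 1)) .err("p_in must be in (0, 1]")
  if (!(p_out >= 0 && p_out < 1)) .err("p_out must be in [0, 1)")
  if (p_in <= p_out) .err("p_in must exceed p_out")
  if (cfg$n_blocks > cfg$n_diseases) {
    .err("n_blocks (%d) exceeds n_diseases (%d)", cfg$n_blocks, cfg$n_diseases)
  }
  if (cfg$n_blocks > cfg$n_mirnas) {
    .err("n_blocks (%d) exceeds n_mirnas (%d)", cfg$n_blocks, cfg$n_mirnas)
  }
  if (cfg$n_tissues < cfg$n_blocks) {
    .err("need n_tissues >= n_blocks to place every block")
  }
  planted <- cfg$n_blocks * cfg$n_processes * cfg$module_size
  if (planted > cfg$n_proteins) {
    .err("cannot place %d blocks: %d planted proteins > n_proteins = %d",
         cfg$n_blocks, planted, cfg$n_proteins)
  }
  class(cfg) <- "SyntheticConfig"
  cfg
}

# expected mentions per abstract implied by the config (block entities at
# p_in, everything else corpus-active at p_out)
.expectedMentions <- function(cfg) {
  planted <- cfg$n_blocks * cfg$n_processes * cfg$module_size
  n_active <- planted + cfg$n_diseases + cfg$n_functions + cfg$n_mirnas
  block_prot <- cfg$n_processes * cfg$module_size
  block_conc <- floor(cfg$n_diseases / cfg$n_blocks) +
    floor(cfg$n_functions / cfg$n_blocks) +
    ceiling(cfg$n_mirnas / cfg$n_blocks)
  block_sz <- block_prot + block_conc
  block_sz * cfg$p_in + (n_active - block_sz) * cfg$p_out
}

#' Planted ground truth of a synthetic universe
#'
#' @slot block_of_swarm named character: swarm id -> block label.
#' @slot block_of_concept named character: concept id -> block label
#'   (`"background"` for unassigned concepts).
#' @slot mirna_cluster named character: microRNA id -> planted cluster label.
#' @slot links data.frame with columns `block`, `mirna_cluster`: the planted
#'   PSA-to-microRNA-cluster associations.
#' @export
setClass("PlantedTruth",
  representation(
    block_of_swarm = "character", block_of_concept = "character",
    mirna_cluster = "character", links = "data.frame"
  )
)

setMethod("show", "PlantedTruth", function(object) {
  cat("PlantedTruth:", length(unique(object@block_of_swarm)), "blocks,",
      length(object@block_of_swarm), "swarm labels,",
      nrow(object@links), "planted links\n")
})

.blockLabel <- function(b) sprintf("block%02d", b)

# round-robin assignment of concept ids to blocks; remainder -> background
.assignConcepts <- function(ids, n_blocks) {
  per <- floor(length(ids) / n_blocks)
  lab <- rep("background", length(ids))
  if (per > 0L) {
    assigned <- seq_len(per * n_blocks)
    lab[assigned] <- .blockLabel(rep(seq_len(n_blocks), each = per))
  }
  setNames(lab, ids)
}

#' Generate the synthetic universe
#'
#' Builds the entity vocabulary, tissue and process gene-set collections and
#' the planted truth labels. Tissue/process intersections equal the planted
#' modules exactly: filler members of each set are drawn from disjoint
#' background pools, so the module structure is recoverable and every module
#' is hypergeometrically enriched against the full protein universe.
#'
#' @param config a [syntheticConfig()].
#' @return list with elements `vocabulary`, `tissues`, `processes`, `truth`,
#'   plus `modules` (data.frame of planted module geometry, used by the
#'   corpus and interaction generators).
#' @export
makeUniverse <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed)
  cfg <- config
  proteins <- sprintf("P%05d", seq_len(cfg$n_proteins))
  tissues_nm <- sprintf("tissue_%02d", seq_len(cfg$n_tissues))
  process_nm <- sprintf("process_%02d", seq_len(cfg$n_processes))
  diseases <- sprintf("disease_%03d", seq_len(cfg$n_diseases))
  functions <- sprintf("immune_function_%03d", seq_len(cfg$n_functions))
  mirnas <- normalizeMirna(sprintf("mir-%d", 100L + seq_len(cfg$n_mirnas)))

  planted_n <- cfg$n_blocks * cfg$n_processes * cfg$module_size
  planted <- proteins[seq_len(planted_n)]
  pool <- proteins[-seq_len(planted_n)]

  # module geometry: block b x process j -> module_size planted proteins
  modules <- expand.grid(
    process = seq_len(cfg$n_processes), block = seq_len(cfg$n_blocks),
    KEEP.OUT.ATTRS = FALSE
  )[, c("block", "process")]
  modules$tissue <- tissues_nm[modules$block]
  modules$process_name <- process_nm[modules$process]
  member_list <- split(
    planted,
    rep(seq_len(nrow(modules)), each = cfg$module_size)
  )
  modules$members <- unname(member_list)

  # filler: disjoint slices of the background pool per set, so that
  # tissue-by-process intersections contain planted members only
  n_sets <- cfg$n_tissues + cfg$n_processes
  filler_per <- min(cfg$filler, floor(length(pool) / max(1L, n_sets)))
  filler <- if (filler_per > 0L) {
    split(sample(pool, filler_per * n_sets),
          rep(seq_len(n_sets), each = filler_per))
  } else {
    rep(list(character()), n_sets)
  }

  tissue_sets <- lapply(seq_len(cfg$n_tissues), function(i) {
    own <- if (i <= cfg$n_blocks) {
      unlist(modules$members[modules$block == i], use.names = FALSE)
    } else character()
    sort(c(own, filler[[i]]))
  })
  process_sets <- lapply(seq_len(cfg$n_processes), function(j) {
    own <- unlist(modules$members[modules$process == j], use.names = FALSE)
    sort(c(own, filler[[cfg$n_tissues + j]]))
  })

  # swarm-id level truth: module (b, j) chunks into ceil(module_size/5)
  # swarms named "<tissue>|<process>|<k>"
  n_chunks <- ceiling(cfg$module_size / 5L)
  swarm_ids <- unlist(lapply(seq_len(nrow(modules)), function(m) {
    sprintf("%s|%s|%d", modules$tissue[m], modules$process_name[m],
            seq_len(n_chunks))
  }), use.names = FALSE)
  swarm_blocks <- rep(.blockLabel(modules$block), each = n_chunks)

  cluster_of <- .blockLabel(
    ((seq_len(cfg$n_mirnas) - 1L) %% cfg$n_blocks) + 1L
  )
  mirna_cluster <- setNames(paste0("mc_", cluster_of), mirnas)

  truth <- new("PlantedTruth",
    block_of_swarm = setNames(swarm_blocks, swarm_ids),
    block_of_concept = c(
      .assignConcepts(diseases, cfg$n_blocks),
      .assignConcepts(functions, cfg$n_blocks)
    ),
    mirna_cluster = mirna_cluster,
    links = data.frame(
      block = .blockLabel(seq_len(cfg$n_blocks)),
      mirna_cluster = paste0("mc_", .blockLabel(seq_len(cfg$n_blocks))),
      stringsAsFactors = FALSE
    )
  )

  list(
    vocabulary = entityVocabulary(proteins, diseases, functions, mirnas),
    tissues = geneSetCollection(setNames(tissue_sets, tissues_nm)),
    processes = geneSetCollection(setNames(process_sets, process_nm)),
    truth = truth,
    modules = modules
  )
}

# sample a class of mentions for all abstracts at once: probability matrix
# is p_in where (abstract block == entity block), p_out elsewhere
.sampleMentions <- function(block_of_abstract, entity_block, entities,
                            p_in, p_out) {
  n_abs <- length(block_of_abstract)
  n_ent <- length(entities)
  if (n_ent == 0L || n_abs == 0L) {
    return(rep(list(character()), n_abs))
  }
  p <- matrix(p_out, n_abs, n_ent)
  match_mat <- outer(block_of_abstract, entity_block, `==`)
  p[match_mat] <- p_in
  hits <- matrix(runif(n_abs * n_ent) < p, n_abs, n_ent)
  lapply(seq_len(n_abs), function(i) entities[hits[i, ]])
}

#' Generate a synthetic annotated corpus
#'
#' Each abstract picks one planted block uniformly at random, then mentions
#' each of that block's entities (module proteins, assigned diseases and
#' functions, attached microRNA cluster members) independently with
#' probability `p_in`, and every other corpus-active entity with probability
#' `p_out`. Background-pool proteins (those outside every module) never
#' appear. The expected within-block co-citation count therefore strictly
#' exceeds the background expectation.
#'
#' @param universe output of [makeUniverse()].
#' @param config the same [syntheticConfig()].
#' @return list with `corpus` (a [Corpus-class]) and `block_of_abstract`
#'   (character vector of the block sampled for each abstract).
#' @export
makeCorpus <- function(universe, config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  cfg <- config
  if (cfg$p_in <= cfg$p_out) .err("p_in must exceed p_out")
  if (!is.null(cfg$mean_mentions)) {
    implied <- .expectedMentions(cfg)
    if (abs(implied - cfg$mean_mentions) > 0.5 * implied) {
      warning(sprintf(
        "mean_mentions = %.1f but the configured rates imply ~%.1f mentions per abstract",
        cfg$mean_mentions, implied), call. = FALSE)
    }
  }
  set.seed(cfg$seed + 1L)
  n_abs <- cfg$n_abstracts
  if (n_abs == 0L) {
    return(list(corpus = new("Corpus", ids = character(), mentions = list()),
                block_of_abstract = character()))
  }
  blocks <- .blockLabel(sample.int(cfg$n_blocks, n_abs, replace = TRUE))

  modules <- universe$modules
  prot <- unlist(modules$members, use.names = FALSE)
  prot_block <- rep(.blockLabel(modules$block), lengths(modules$members))

  truth <- universe$truth
  conc_block <- truth@block_of_concept
  diseases <- universe$vocabulary@diseases
  functions <- universe$vocabulary@functions
  mirnas <- universe$vocabulary@microRNAs
  mirna_block <- sub("^mc_", "", truth@mirna_cluster[mirnas])

  men_p <- .sampleMentions(blocks, prot_block, prot, cfg$p_in, cfg$p_out)
  men_d <- .sampleMentions(blocks, unname(conc_block[diseases]), diseases,
                           cfg$p_in, cfg$p_out)
  men_f <- .sampleMentions(blocks, unname(conc_block[functions]), functions,
                           cfg$p_in, cfg$p_out)
  men_m <- .sampleMentions(blocks, mirna_block, mirnas, cfg$p_in, cfg$p_out)

  men <- lapply(seq_len(n_abs), function(i) {
    list(proteins = men_p[[i]], diseases = men_d[[i]],
         functions = men_f[[i]], microRNAs = men_m[[i]])
  })
  ids <- sprintf("abs%06d", seq_len(n_abs))
  list(
    corpus = new("Corpus", ids = ids, mentions = men),
    block_of_abstract = setNames(blocks, ids)
  )
}

#' Generate a synthetic protein interaction graph
#'
#' Planted-partition graph over the module proteins: within-module edges
#' appear with probability `q_in`, cross-module edges with `q_out`
#' (defaults 0.8 / 0.02).
#'
#' @param universe output of [makeUniverse()].
#' @param config the same [syntheticConfig()].
#' @param q_in,q_out edge probabilities within / across modules.
#' @return an [InteractionGraph-class].
#' @export
makeInteractions <- function(universe, config, q_in = 0.8, q_out = 0.02) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed + 2L)
  modules <- universe$modules
  prot <- unlist(modules$members, use.names = FALSE)
  mod_of <- rep(seq_len(nrow(modules)), lengths(modules$members))
  n <- length(prot)
  if (n < 2L) return(interactionGraph(prot, NULL))
  idx <- combn(n, 2L)
  same <- mod_of[idx[1, ]] == mod_of[idx[2, ]]
  p <- ifelse(same, q_in, q_out)
  keep <- runif(ncol(idx)) < p
  interactionGraph(prot, cbind(prot[idx[1, keep]], prot[idx[2, keep]]))
}

#' Run all generators and write their outputs to disk
#'
#' Writes the tissue/process GMTs, the JSONL corpus, the TSV edge list and
#' the truth labels, using the same formats the readers consume.
#'
#' @param config a [syntheticConfig()].
#' @param dir output directory (created if missing).
#' @return (invisibly) list of generated objects.
#' @export
simulateStudy <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  uni <- makeUniverse(config)
  cc <- makeCorpus(uni, config)
  graph <- makeInteractions(uni, config)
  writeGeneSets(uni$tissues, file.path(dir, "tissues.gmt"))
  writeLines(uni$vocabulary@proteins, file.path(dir, "universe.txt"))
  writeGeneSets(uni$processes, file.path(dir, "processes.gmt"))
  writeCorpus(cc$corpus, file.path(dir, "corpus.jsonl"))
  writeLines(
    c("protein1\tprotein2",
      apply(graph@edges, 1L, paste, collapse = "\t")),
    file.path(dir, "interactions.tsv")
  )
  truth <- uni$truth
  tdf <- rbind(
    data.frame(entity = names(truth@block_of_swarm), kind = "swarm",
               label = unname(truth@block_of_swarm)),
    data.frame(entity = names(truth@block_of_concept), kind = "concept",
               label = unname(truth@block_of_concept)),
    data.frame(entity = names(truth@mirna_cluster), kind = "microRNA",
               label = unname(truth@mirna_cluster))
  )
  utils::write.table(tdf, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(universe = uni, corpus = cc$corpus,
                 block_of_abstract = cc$block_of_abstract, graph = graph))
}
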