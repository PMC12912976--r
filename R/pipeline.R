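#' Pipeline run configuration
#'
#' Assembles and validates the parameters of a full [run_pipeline()] run.
#' Unknown parameter names are rejected. When `simulate = FALSE`, `inputs`
#' must name the on-disk files: `outgroup` (BED), `species` (named character
#' vector of BEDs) and `anchors` (named `"query:target"` TSV paths).
#'
#' @param simulate generate the inputs with [simulate_clade()] (default
#'   `TRUE`).
#' @param sim a [sim_config()] (used when `simulate = TRUE`).
#' @param chain a [chain_params()].
#' @param ploidy descendant:reference copy-number ratio (default 3).
#' @param n_regions homoeologous-set regions for [define_regions()]
#'   (default 16).
#' @param min_species cluster species filter (default 2).
#' @param window,step retention window and step in genes (defaults 100/50).
#' @param species_fraction RTG calling threshold (default 0.8).
#' @param hotspot_window,hotspot_nperm hotspot scan parameters.
#' @param ingroup species used to build the model genome (default
#'   `"auto"`: the descendant with the fewest inferred fusion junctions,
#'   i.e. the least rearranged genome).
#' @param inputs input file list when `simulate = FALSE`.
#' @param seed seed for every stochastic stage.
#' @return list of class `run_config`.
#' @export
run_config <- function(simulate = TRUE, sim = sim_config(), chain = chain_params(),
                       ploidy = 3L, n_regions = 16L, min_species = 2L,
                       window = 100L, step = 50L, species_fraction = 0.8,
                       hotspot_window = 50L, hotspot_nperm = 1000L,
                       ingroup = "auto", inputs = NULL, seed = 1L) {
  cfg <- list(simulate = simulate, sim = sim, chain = chain,
              ploidy = as.integer(ploidy), n_regions = n_regions,
              min_species = as.integer(min_species),
              window = as.integer(window), step = as.integer(step),
              species_fraction = species_fraction,
              hotspot_window = as.integer(hotspot_window),
              hotspot_nperm = as.integer(hotspot_nperm),
              ingroup = ingroup, inputs = inputs, seed = as.integer(seed))
  if (cfg$simulate) cfg$sim$seed <- cfg$seed
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' Top-level keys mirror the [run_config()] arguments, with `sim` and
#' `chain` as nested objects; unknown keys raise an error.
#'
#' @param path JSON file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(js), known)
  if (length(bad) > 0) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  if (!is.null(js$sim)) {
    sim_known <- names(formals(sim_config))
    bad <- setdiff(names(js$sim), sim_known)
    if (length(bad) > 0) stop("unknown sim key(s): ", paste(bad, collapse = ", "))
    js$sim <- do.call(sim_config, js$sim)
  }
  if (!is.null(js$chain)) js$chain <- do.call(chain_params, as.list(js$chain))
  do.call(run_config, js)
}

load_inputs <- function(cfg) {
  inp <- cfg$inputs
  for (need in c("outgroup", "species", "anchors")) {
    if (is.null(inp[[need]])) stop("missing input: ", need)
  }
  genomes <- list(outgroup = read_bed(inp$outgroup, species = "outgroup"))
  for (sp in names(inp$species)) {
    genomes[[sp]] <- read_bed(inp$species[[sp]], species = sp)
  }
  anchors <- list()
  for (nm in names(inp$anchors)) {
    qt <- strsplit(nm, ":")[[1]]
    anchors[[nm]] <- read_anchors(inp$anchors[[nm]],
                                  genomes[[qt[1]]], genomes[[qt[2]]])
  }
  list(genomes = genomes, anchors = anchors, truth = NULL, expression = NULL)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input simulation (or loading), anchor chaining for
#' every genome pair, syntenic depth against the outgroup, microsynteny
#' clustering and phylogenomic profiling, fission/fusion counting,
#' ancestral-block reconstruction (level 1-4 and model genome) on the least
#' rearranged descendant, mapping of all descendants onto the model genome,
#' retention/reciprocity profiling, and RTG calling with hotspot and
#' expression-specificity analyses (simulation mode). All stage outputs are
#' written under `out_dir` as TSV/BED/JSON and the run manifest records
#' parameters, seed and an MD5 checksum per artifact. A stage failure aborts
#' the run with the failing stage named; completed outputs are retained.
#'
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @return the manifest (list), invisibly written to
#'   `out_dir/run_manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages[[name]] <<- "ok"
    res
  }

  dat <- stage("inputs", function() {
    if (config$simulate) {
      sim <- simulate_clade(config$sim)
      write_simulation(sim, file.path(out_dir, "sim"))
      list(genomes = sim$genomes, anchors = sim$anchors,
           truth = sim$truth, expression = sim$expression)
    } else {
      load_inputs(config)
    }
  })
  genomes <- dat$genomes
  outgroup <- genomes$outgroup
  sps <- setdiff(names(genomes), "outgroup")

  blocks <- stage("chain", function() {
    out <- list()
    for (nm in names(dat$anchors)) {
      qt <- strsplit(nm, ":")[[1]]
      bl <- chain_anchors(dat$anchors[[nm]], genomes[[qt[1]]], genomes[[qt[2]]],
                          config$chain)
      write_blocks(bl, file.path(out_dir, paste0("blocks_", gsub(":", "_", nm), ".tsv")))
      out[[nm]] <- bl
      # reversed polarity for painting the descendant by the outgroup
      if (qt[1] == "outgroup") {
        rev_anch <- anchor_pairs(dat$anchors[[nm]]$gene_b,
                                 dat$anchors[[nm]]$gene_a,
                                 dat$anchors[[nm]]$score)
        out[[paste(qt[2], qt[1], sep = ":")]] <-
          chain_anchors(rev_anch, genomes[[qt[2]]], outgroup, config$chain)
      }
    }
    out
  })

  depth <- stage("depth", function() {
    out <- list()
    for (sp in sps) {
      d <- syntenic_depth(blocks[[paste("outgroup", sp, sep = ":")]], outgroup)
      out[[sp]] <- d
      write_tsv(data.frame(gene_id = names(d), depth = unname(d)),
                file.path(out_dir, paste0("depth_outgroup_vs_", sp, ".tsv")))
    }
    out
  })

  clusters <- stage("clusters", function() {
    pairs <- do.call(rbind, lapply(names(dat$anchors), function(nm) {
      syntenic_gene_pairs(blocks[[nm]])
    }))
    cl <- build_clusters(anchor_pairs(pairs$gene_a, pairs$gene_b),
                         species_map(genomes), config$min_species)
    write_tsv(cl$members, file.path(out_dir, "clusters.tsv"))
    prof <- phylogenomic_profile(cl)
    write_tsv(data.frame(species = rownames(prof$matrix), prof$matrix,
                         check.names = FALSE),
              file.path(out_dir, "profile.tsv"))
    cl
  })

  rearr <- stage("rearrange", function() {
    out <- list()
    rows <- list()
    for (sp in sps) {
      painting <- paint_genome(blocks[[paste(sp, "outgroup", sep = ":")]],
                               genomes[[sp]])
      ff <- count_fissions_fusions(painting, outgroup, ploidy = config$ploidy)
      out[[sp]] <- ff
      rows[[sp]] <- data.frame(species = sp, fissions = ff$fissions,
                               fusions = ff$fusions, c_desc = ff$c_desc,
                               c_ref = ff$c_ref)
    }
    write_tsv(do.call(rbind, rows), file.path(out_dir, "rearrangements.tsv"))
    out
  })

  agb <- stage("agb_build", function() {
    ingroup_sp <- config$ingroup
    if (identical(ingroup_sp, "auto")) {
      fus <- vapply(sps, function(sp) rearr[[sp]]$fusions +
                      rearr[[sp]]$fissions, 0L)
      ingroup_sp <- sps[order(fus, sps)][1]
    }
    ing <- genomes[[ingroup_sp]]
    l1 <- blocks[[paste(ingroup_sp, "outgroup", sep = ":")]]
    l2 <- merge_level2(l1, ing, outgroup)
    regions <- define_regions(outgroup, l2, n_regions = config$n_regions)
    sets <- assign_homoeologs(l2, regions, ing)
    sets <- order_level4(sets)
    model <- build_model_genome(sets, ing)
    write_bed(model$annotation, file.path(out_dir, "model_genome.bed"))
    write_tsv(model$provenance, file.path(out_dir, "model_provenance.tsv"))
    jsonlite::write_json(
      list(ingroup = ingroup_sp,
           regions = regions,
           agb_chroms = model$agb_chroms,
           slot_totals = as.list(model$slot_totals)),
      file.path(out_dir, "model_manifest.json"), auto_unbox = TRUE, digits = NA)
    list(ingroup = ingroup_sp, level2 = l2, regions = regions, sets = sets,
         model = model)
  })

  stage("agb_map", function() {
    model_ann <- agb$model$annotation
    for (sp in sps) {
      ra <- dat$anchors[[paste("outgroup", sp, sep = ":")]]
      # anchors to the model: descendant gene -> ingroup gene sharing its
      # outgroup anchor, restricted to genes placed on the model
      placed <- agb$model$annotation$genes$gene_id
      ia <- agb$sets$anchors
      ref2model <- ia[ia$gene_a %in% placed, c("gene_b", "gene_a")]
      mm <- merge(data.frame(ref = ra$gene_a, qg = ra$gene_b),
                  data.frame(ref = ref2model$gene_b, mg = ref2model$gene_a))
      bl <- chain_anchors(anchor_pairs(mm$qg, mm$mg), genomes[[sp]], model_ann,
                          config$chain)
      mp <- map_to_agbs(genomes[[sp]], bl, agb$model,
                        window = config$hotspot_window)
      write_tsv(mp$genes, file.path(out_dir, paste0("agb_map_", sp, ".tsv")))
    }
    NULL
  })

  retention <- stage("fractionation", function() {
    pres <- presence_from_agb(agb$sets, outgroup)
    prof <- retention_windows(outgroup, pres, window = config$window,
                              step = config$step)
    write_retention(prof, file.path(out_dir, "retention.tsv"))
    rec <- reciprocity(prof)
    write_tsv(data.frame(pair = names(rec$pairwise),
                         correlation = round(unname(rec$pairwise), 6)),
              file.path(out_dir, "reciprocity.tsv"))
    list(profile = prof, reciprocity = rec)
  })

  stage("rtg", function() {
    if (is.null(dat$truth)) return(NULL)  # truth-anchored calls: sim mode
    pres <- lapply(stats::setNames(sps, sps), function(sp) {
      presence_from_truth(dat$truth$genes, sp, outgroup)
    })
    cm <- build_copy_matrix(pres, outgroup)
    calls <- call_rtgs(cm, config$species_fraction)
    write_tsv(calls, file.path(out_dir, "rtg_calls.tsv"))
    rtg_ref <- calls$gene_id[calls$rtg]
    # place RTG paleoparalogs on the model genome via the truth table
    anc <- sub("^outgroup_", "", rtg_ref)
    tg <- dat$truth$genes
    paralogs <- tg$gene_id[tg$species == agb$ingroup & tg$ancestral_gene %in% anc]
    hs <- rtg_hotspots(paralogs, agb$model$annotation,
                       window = config$hotspot_window,
                       nperm = config$hotspot_nperm, seed = config$seed)
    write_tsv(hs, file.path(out_dir, "rtg_hotspots.tsv"))
    if (!is.null(dat$expression)) {
      tg1 <- tg[tg$species == sps[1], ]
      rtg_genes <- tg1$gene_id[tg1$ancestral_gene %in% anc]
      counts <- table(tg1$ancestral_gene)
      single <- tg1$gene_id[tg1$ancestral_gene %in%
                              names(counts)[counts == 1] &
                              !tg1$ancestral_gene %in% anc]
      tc <- tau_contrast(rtg_genes, single, dat$expression)
      write_tsv(data.frame(group = c(rep("rtg", length(tc$tau1)),
                                     rep("single_copy", length(tc$tau2))),
                           gene_id = c(names(tc$tau1), names(tc$tau2)),
                           tau = round(c(tc$tau1, tc$tau2), 6)),
                file.path(out_dir, "tau.tsv"))
    }
    NULL
  })

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = FALSE))
  files <- files[files != "run_manifest.json"]
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    package = "paleosynteny",
    version = as.character(utils::packageVersion("paleosynteny")),
    seed = config$seed,
    parameters = list(
      chain = unclass(config$chain), ploidy = config$ploidy,
      n_regions = config$n_regions, min_species = config$min_species,
      window = config$window, step = config$step,
      species_fraction = config$species_fraction,
      hotspot_window = config$hotspot_window,
      simulate = config$simulate),
    stages = stages,
    checksums = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
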