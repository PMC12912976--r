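# shared fixtures: reduced-scale simulation configs and the standard
# ancestral-block reconstruction run with truth-based recovery metrics

tiny_config <- function(seed = 1, ...) {
  sim_config(n_chrom = 2, genes_per_chrom = 120, n_species = 2,
             n_fissions = 1, n_fusions = 1, n_inversions = 1,
             n_translocations = 0, outgroup_inversions = 0, seed = seed, ...)
}

# full ancestral-block reconstruction for one descendant of a simulation,
# returning the model genome plus truth-recovery metrics:
#  - set_correct: fraction of placed genes whose inferred region contains the
#    outgroup position of their ancestral gene
#  - slot_ari: gene-weighted mean, over homoeologous sets, of the adjusted
#    Rand index between slot labels and true subgenome labels
agb_recovery <- function(sim, species = "sp1", n_regions = 16) {
  ing <- sim$genomes[[species]]
  og <- sim$genomes$outgroup
  an <- sim$anchors[[paste0("outgroup:", species)]]
  l1 <- chain_anchors(anchor_pairs(an$gene_b, an$gene_a), ing, og)
  l2 <- merge_level2(l1, ing, og)
  regions <- define_regions(og, l2, n_regions)
  sets <- order_level4(assign_homoeologs(l2, regions, ing))
  model <- suppressWarnings(build_model_genome(sets, ing))
  prov <- model$provenance
  tg <- sim$truth$genes
  anc <- tg$ancestral_gene[match(prov$gene_id, tg$gene_id)]
  ogr <- stats::setNames(og$genes$rank, og$genes$gene_id)
  ogc <- stats::setNames(og$genes$chrom, og$genes$gene_id)
  ogid <- paste0("outgroup_", anc)
  reg <- regions[match(prov$set_index, regions$set_index), ]
  set_correct <- mean(ogc[ogid] == reg$chrom &
                        ogr[ogid] >= reg$start & ogr[ogid] <= reg$end)
  sub <- tg$subgenome[match(prov$gene_id, tg$gene_id)]
  groups <- split(seq_len(nrow(prov)), prov$set_index)
  aris <- vapply(groups, function(i) ari(prov$slot[i], sub[i]), numeric(1))
  w <- vapply(groups, length, integer(1))
  list(model = model, sets = sets, regions = regions, level2 = l2, level1 = l1,
       set_correct = set_correct, slot_ari = sum(aris * w) / sum(w),
       placed_fraction = nrow(prov) / n_genes(ing))
}

# loss-free, rearrangement-free clade (triplication only)
lossfree_config <- function(seed = 1, n_species = 1) {
  sim_config(n_species = n_species, retention_mean = 1, rtg_fraction = 0,
             n_fissions = 0, n_fusions = 0, n_inversions = 0,
             n_translocations = 0, outgroup_inversions = 0, seed = seed)
}
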