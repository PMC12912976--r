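test_that("two-step triplication gives three copies of everything", {
  cfg <- sim_config(seed = 2)
  anc <- simulate_ancestor(cfg)
  expect_equal(length(anc$chromosomes), 8)
  expect_equal(n_genes(anc), 4000)
  wgt <- apply_wgt(anc)
  expect_equal(length(wgt$genome$chromosomes), 24)
  expect_equal(n_genes(wgt$genome), 12000)
  copies <- table(wgt$truth$ancestral_gene)
  expect_true(all(copies == 3))
  per_sub <- table(wgt$truth$subgenome,
                   sub("_.*$", "", wgt$genome$genes$chrom[
                     match(wgt$truth$gene_id, wgt$genome$genes$gene_id)]))
  expect_equal(unname(table(sub("^.*_", "", wgt$genome$chromosomes))),
               as.integer(c(8, 8, 8)), ignore_attr = TRUE)
  expect_setequal(unique(wgt$truth$subgenome), c("a", "b", "c"))
})

test_that("simulation is reproducible from its seed", {
  s1 <- simulate_clade(tiny_config(seed = 7))
  s2 <- simulate_clade(tiny_config(seed = 7))
  expect_identical(s1$genomes$sp1$genes, s2$genomes$sp1$genes)
  expect_identical(s1$truth$event_log, s2$truth$event_log)
  expect_identical(s1$expression, s2$expression)
  a <- simulate_ancestor(sim_config(n_chrom = 1, genes_per_chrom = 10, seed = 3))
  b <- simulate_ancestor(sim_config(n_chrom = 1, genes_per_chrom = 10, seed = 3))
  expect_identical(a$genes, b$genes)
  expect_equal(a$genes$rank, 0:9)
})

test_that("fractionation respects retention boundaries and immunity", {
  cfg <- sim_config(seed = 11)
  wgt <- apply_wgt(simulate_ancestor(cfg))

  # retention_mean = 1: nothing is deleted (300% combined ceiling)
  cfg1 <- sim_config(retention_mean = 1, seed = 11)
  fr <- apply_fractionation(wgt$genome, wgt$truth, cfg1)
  expect_equal(n_genes(fr$genome), 12000)
  expect_equal(fr$n_deleted, 0)

  # all genes immune: no deletions regardless of retention_mean
  all_anc <- unique(wgt$truth$ancestral_gene)
  cfg2 <- sim_config(retention_mean = 0.3, rtg_fraction = 1, seed = 11)
  fr2 <- apply_fractionation(wgt$genome, wgt$truth, cfg2, rtg_set = all_anc)
  expect_equal(fr2$n_deleted, 0)

  # survivor count within 3 binomial SDs of p * n
  cfg3 <- sim_config(retention_mean = 0.4, rtg_fraction = 0, seed = 11)
  fr3 <- apply_fractionation(wgt$genome, wgt$truth, cfg3)
  expect_lt(abs(n_genes(fr3$genome) - 0.4 * 12000),
            3 * sqrt(12000 * 0.4 * 0.6) + 1)
  # conservation: survivors + recorded deletions = 3 x ancestral count
  expect_equal(n_genes(fr3$genome) + fr3$n_deleted, 12000)
})

test_that("rearrangement events do what the log says", {
  g <- rank_annotation("g", 10)

  # fission at a sampled gap splits into two chromosomes of total 10
  set.seed(1)
  re <- apply_rearrangements(g, n_fissions = 1, lineage = "L")
  expect_equal(length(re$genome$chromosomes), 2)
  sizes <- table(re$genome$genes$chrom)
  expect_equal(sum(sizes), 10)
  expect_equal(re$events$event, "fission")
  expect_equal(sort(as.integer(sizes)),
               sort(c(re$events$position, 10 - re$events$position)))

  # fusion decreases the chromosome count by one
  two <- genome_annotation(rbind(
    data.frame(gene_id = sprintf("x%02d", 1:6), chrom = "c1",
               start = (1:6) * 100L, end = (1:6) * 100L + 50L, strand = "+"),
    data.frame(gene_id = sprintf("y%02d", 1:6), chrom = "c2",
               start = (1:6) * 100L, end = (1:6) * 100L + 50L, strand = "+")),
    "two")
  set.seed(2)
  re2 <- apply_rearrangements(two, n_fusions = 1, lineage = "L")
  expect_equal(length(re2$genome$chromosomes), 1)
  expect_equal(n_genes(re2$genome), 12)

  # zero events: identity up to re-synthesised bp coordinates
  re0 <- apply_rearrangements(g, lineage = "L")
  expect_equal(nrow(re0$events), 0)
  expect_equal(re0$genome$genes$gene_id, g$genes$gene_id)
  expect_equal(re0$genome$genes$rank, g$genes$rank)

  # inversion reverses a contiguous interval and flips strands
  set.seed(3)
  re3 <- apply_rearrangements(g, n_inversions = 1, lineage = "L")
  ev <- re3$events
  s <- ev$position; e <- ev$position2
  before <- g$genes[order(g$genes$rank), ]
  after <- re3$genome$genes[order(re3$genome$genes$rank), ]
  expect_equal(after$gene_id[s:e], rev(before$gene_id[s:e]))
  expect_true(all(after$strand[s:e] != rev(before$strand[s:e])))
  outside <- setdiff(seq_len(10), s:e)
  expect_equal(after$gene_id[outside], before$gene_id[outside])
})

test_that("chromosome count obeys the event ledger", {
  for (seed in 1:5) {
    cfg <- sim_config(n_species = 1, n_fissions = 4, n_fusions = 2,
                      n_inversions = 2, n_translocations = 1,
                      retention_mean = 1, rtg_fraction = 0,
                      outgroup_inversions = 0, seed = seed)
    sim <- simulate_clade(cfg)
    ev <- sim$truth$event_log
    ev <- ev[ev$lineage == "sp1", ]
    expect_equal(length(sim$genomes$sp1$chromosomes),
                 24 + sum(ev$event == "fission") - sum(ev$event == "fusion"))
    expect_equal(sum(ev$event == "fission"), 4)
    expect_equal(sum(ev$event == "fusion"), 2)
  }
})

test_that("fractionation is globally unbiased with reciprocal local bias", {
  sim <- simulate_clade(sim_config(seed = 21, n_species = 1))
  wp <- sim$truth$window_probs
  probs <- as.matrix(wp[, c("p_a", "p_b", "p_c")])
  # per-window probabilities sum to 3 * retention_mean exactly
  expect_equal(unname(rowSums(probs)), rep(3 * 0.41, nrow(probs)),
               tolerance = 1e-12)
  # global unbiasedness: slot means within 3 SE of each other
  se <- apply(probs, 2, stats::sd) / sqrt(nrow(probs))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_lt(abs(mean(probs[, i]) - mean(probs[, j])),
              3 * sqrt(se[i]^2 + se[j]^2))
  }
  # reciprocity in the probabilities themselves (compositional constraint)
  cors <- stats::cor(probs)
  expect_true(all(cors[upper.tri(cors)] < 0))

  # degenerate concentration: identical probabilities in every window
  sim2 <- simulate_clade(sim_config(seed = 21, n_species = 1,
                                    bias_concentration = Inf))
  wp2 <- sim2$truth$window_probs
  expect_true(all(abs(as.matrix(wp2[, c("p_a", "p_b", "p_c")]) - 0.41) < 1e-12))
})

test_that("truth anchors connect each outgroup gene to at most three copies", {
  sim <- simulate_clade(tiny_config(seed = 9))
  expect_equal(n_genes(sim$genomes$outgroup), 240)
  an <- sim$anchors[["outgroup:sp1"]]
  expect_true(all(table(an$gene_a) <= 3))
  # descendant-descendant anchors pair same subgenome, same ancestral gene
  cross <- sim$anchors[["sp1:sp2"]]
  tg <- sim$truth$genes
  key <- function(id) paste(tg$subgenome[match(id, tg$gene_id)],
                            tg$ancestral_gene[match(id, tg$gene_id)])
  expect_true(all(key(cross$gene_a) == key(cross$gene_b)))
})

test_that("simulation output files round-trip", {
  sim <- simulate_clade(tiny_config(seed = 2))
  dir <- file.path(tempdir(), "simout")
  write_simulation(sim, dir)
  expect_true(file.exists(file.path(dir, "outgroup.bed")))
  expect_true(file.exists(file.path(dir, "config.json")))
  back <- read_bed(file.path(dir, "sp1.bed"), species = "sp1")
  expect_equal(n_genes(back), n_genes(sim$genomes$sp1))
})
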