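make_blocks <- function(rows) {
  # minimal synteny_blocks stub for merge tests: rows give q/t spans; anchors
  # are the dense diagonal of each span
  blocks <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(block_id = sprintf("blk%05d", i), q_chrom = r$qc,
               q_start = r$qs, q_end = r$qe, t_chrom = r$tc,
               t_start = r$ts, t_end = r$te, orientation = r$o,
               n_anchors = r$qe - r$qs + 1L, stringsAsFactors = FALSE)
  }))
  anchors <- do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    q <- r$qs:r$qe
    t <- if (r$o == "+") r$ts:r$te else r$te:r$ts
    data.frame(block_id = sprintf("blk%05d", i),
               gene_a = sprintf("%s_g%03d", r$qc, q),
               gene_b = sprintf("%s_g%03d", r$tc, t),
               q_rank = q, t_rank = t, stringsAsFactors = FALSE)
  }))
  structure(list(blocks = blocks, anchors = anchors), class = "synteny_blocks")
}

test_that("level-2 merging joins outgroup-adjacent segments only", {
  ing <- rank_annotation("i", 40)
  og <- rank_annotation("o", 40)
  bl <- make_blocks(list(
    list(qc = "ichr", qs = 0, qe = 9, tc = "ochr", ts = 0, te = 9, o = "+"),
    list(qc = "ichr", qs = 10, qe = 19, tc = "ochr", ts = 10, te = 19, o = "+")))
  l2 <- merge_level2(bl, ing, og)
  expect_equal(nrow(l2$blocks), 1)
  expect_equal(c(l2$blocks$out_start, l2$blocks$out_end), c(0L, 19L))

  # different outgroup chromosomes: no merge
  bl2 <- make_blocks(list(
    list(qc = "ichr", qs = 0, qe = 9, tc = "ochr", ts = 0, te = 9, o = "+"),
    list(qc = "ichr", qs = 10, qe = 19, tc = "xchr", ts = 10, te = 19, o = "+")))
  expect_equal(nrow(merge_level2(bl2, ing, og)$blocks), 2)

  # outgroup gap beyond the tolerance: no merge
  bl3 <- make_blocks(list(
    list(qc = "ichr", qs = 0, qe = 9, tc = "ochr", ts = 0, te = 9, o = "+"),
    list(qc = "ichr", qs = 10, qe = 19, tc = "ochr", ts = 20, te = 29, o = "+")))
  expect_equal(nrow(merge_level2(bl3, ing, og, adjacency_tol = 5)$blocks), 2)
  expect_equal(nrow(merge_level2(bl3, ing, og, adjacency_tol = 15)$blocks), 1)
})

test_that("level-2 merging conserves outgroup coverage on simulations", {
  sim <- simulate_clade(sim_config(seed = 71, n_species = 1))
  an <- sim$anchors[["outgroup:sp1"]]
  l1 <- chain_anchors(anchor_pairs(an$gene_b, an$gene_a),
                      sim$genomes$sp1, sim$genomes$outgroup)
  l2 <- merge_level2(l1, sim$genomes$sp1, sim$genomes$outgroup)
  expect_lte(nrow(l2$blocks), nrow(l1$blocks))
  cover <- function(df, s, e) {
    covered <- logical(4000)
    for (i in seq_len(nrow(df))) {
      covered[(df[[s]][i]:df[[e]][i]) + 1] <- TRUE
    }
    sum(covered)
  }
  expect_equal(cover(l2$blocks, "out_start", "out_end"),
               cover(l1$blocks, "t_start", "t_end"))
  expect_equal(nrow(l2$anchors), nrow(l1$anchors))
})

test_that("region definition respects counts, falls back to midpoints", {
  sim <- simulate_clade(sim_config(seed = 72, n_species = 1))
  an <- sim$anchors[["outgroup:sp1"]]
  l1 <- chain_anchors(anchor_pairs(an$gene_b, an$gene_a),
                      sim$genomes$sp1, sim$genomes$outgroup)
  l2 <- merge_level2(l1, sim$genomes$sp1, sim$genomes$outgroup)
  og <- sim$genomes$outgroup

  r8 <- define_regions(og, l2, 8)
  expect_equal(nrow(r8), 8)
  expect_true(all(r8$start == 0 & r8$end == 499))

  r16 <- define_regions(og, l2, 16)
  expect_equal(nrow(r16), 16)
  expect_equal(unname(table(r16$chrom)), rep(2L, 8), ignore_attr = TRUE)

  # no block boundaries at all: cuts at chromosome midpoints
  empty_l2 <- merge_level2(
    chain_anchors(anchor_pairs(character(), character()),
                  sim$genomes$sp1, og), sim$genomes$sp1, og)
  rmid <- define_regions(og, empty_l2, 16)
  expect_true(all(rmid$end[seq(1, 15, 2)] == 249))

  expect_error(define_regions(og, l2, 4), "at least")
})

test_that("three full-region copies occupy three clean slots", {
  ing <- genome_annotation(do.call(rbind, lapply(c("ic1", "ic2", "ic3"),
    function(ch) data.frame(gene_id = sprintf("%s_g%03d", ch, 0:19),
                            chrom = ch, start = (0:19) * 100L,
                            end = (0:19) * 100L + 50L, strand = "+"))), "ing")
  og <- rank_annotation("o", 20)
  bl <- make_blocks(lapply(c("ic1", "ic2", "ic3"), function(ch)
    list(qc = ch, qs = 0, qe = 19, tc = "ochr", ts = 0, te = 19, o = "+")))
  l2 <- merge_level2(bl, ing, og)
  regions <- define_regions(og, l2, 1)
  sets <- assign_homoeologs(l2, regions, ing)
  expect_equal(nrow(sets$conflicts), 0)
  expect_equal(sort(unique(sets$assignments$slot)), c("a", "b", "c"))
  expect_equal(unname(table(sets$assignments$slot)), rep(1L, 3),
               ignore_attr = TRUE)
})

test_that("loss-free triplication is recovered perfectly up to relabelling", {
  sim <- simulate_clade(lossfree_config(seed = 73))
  rec <- agb_recovery(sim, n_regions = 16)
  expect_equal(rec$set_correct, 1)
  expect_equal(rec$slot_ari, 1)
  expect_equal(unname(rec$model$slot_totals), rep(4000L, 3),
               ignore_attr = TRUE)
})

test_that("no two blocks in one slot overlap on outgroup ranks", {
  sim <- simulate_clade(sim_config(seed = 74, n_species = 1))
  rec <- agb_recovery(sim)
  a <- rec$sets$assignments
  conflicted <- rec$sets$conflicts$piece_id
  for (key in unique(paste(a$set_index, a$slot))) {
    rows <- a[paste(a$set_index, a$slot) == key & !a$piece_id %in% conflicted, ]
    if (nrow(rows) < 2) next
    rows <- rows[order(rows$out_start), ]
    expect_true(all(diff_ok <- rows$out_start[-1] > rows$out_end[-nrow(rows)]))
  }
})

test_that("level-4 ordering improves collinearity with the outgroup", {
  sim <- simulate_clade(sim_config(seed = 75, n_species = 1))
  rec <- agb_recovery(sim)
  anch <- rec$sets$anchors
  a <- rec$sets$assignments
  ktau <- function(assign_tab) {
    out <- c()
    for (key in unique(paste(assign_tab$set_index, assign_tab$slot))) {
      rows <- assign_tab[paste(assign_tab$set_index, assign_tab$slot) == key, ]
      rows <- rows[order(rows$order_index), ]
      tt <- unlist(lapply(seq_len(nrow(rows)), function(i) {
        x <- anch[anch$piece_id == rows$piece_id[i], ]
        x <- x[order(x$q_rank), ]
        if (rows$flipped[i]) rev(x$t_rank) else x$t_rank
      }))
      if (length(tt) > 2) out <- c(out, stats::cor(seq_along(tt), tt,
                                                   method = "kendall"))
    }
    mean(out)
  }
  ordered <- ktau(a)
  shuffled <- a
  set.seed(1)
  shuffled$order_index <- sample(shuffled$order_index)
  shuffled$flipped <- FALSE
  expect_gte(ordered, ktau(shuffled))
  expect_gt(ordered, 0.9)
})

test_that("the model genome has 3 x n_sets pseudo-chromosomes and no double placement", {
  sim <- simulate_clade(sim_config(seed = 76, n_species = 1))
  rec <- agb_recovery(sim)
  expect_equal(nrow(rec$model$agb_chroms), 48)
  expect_equal(anyDuplicated(rec$model$provenance$gene_id), 0)
  expect_lte(nrow(rec$model$provenance), n_genes(sim$genomes$sp1))
})

test_that("mapping genomes onto the model genome recovers their ancestry", {
  sim <- simulate_clade(sim_config(seed = 77, n_species = 2))
  rec <- agb_recovery(sim, species = "sp1")
  model <- rec$model
  tg <- sim$truth$genes

  # self-consistency: map the genome the model was built from
  ing <- sim$genomes$sp1
  prov <- model$provenance
  self_pairs <- anchor_pairs(prov$gene_id, prov$gene_id)
  bl_self <- chain_anchors(self_pairs, ing, model$annotation)
  mp_self <- map_to_agbs(ing, bl_self, model)
  ok <- !is.na(mp_self$genes$agb) & mp_self$genes$gene_id %in% prov$gene_id
  agree <- mp_self$genes$agb[ok] == prov$agb[match(mp_self$genes$gene_id[ok],
                                                   prov$gene_id)]
  expect_gte(mean(agree), 0.99)

  # sibling species: anchors via shared ancestral gene and subgenome
  t1 <- tg[tg$species == "sp1" & tg$gene_id %in% prov$gene_id, ]
  t2 <- tg[tg$species == "sp2", ]
  key1 <- paste(t1$subgenome, t1$ancestral_gene)
  key2 <- paste(t2$subgenome, t2$ancestral_gene)
  m <- match(key2, key1)
  pairs <- anchor_pairs(t2$gene_id[!is.na(m)], t1$gene_id[m[!is.na(m)]])
  bl_sib <- chain_anchors(pairs, sim$genomes$sp2, model$annotation)
  mp <- map_to_agbs(sim$genomes$sp2, bl_sib, model)
  lab <- mp$genes[!is.na(mp$genes$set_index), ]
  # truth: the sibling gene's ancestral position must fall in the set's region
  anc <- t2$ancestral_gene[match(lab$gene_id, t2$gene_id)]
  og <- sim$genomes$outgroup
  ogr <- stats::setNames(og$genes$rank, og$genes$gene_id)
  ogc <- stats::setNames(og$genes$chrom, og$genes$gene_id)
  reg <- rec$regions[match(lab$set_index, rec$regions$set_index), ]
  ogid <- paste0("outgroup_", anc)
  hit <- ogc[ogid] == reg$chrom & ogr[ogid] >= reg$start & ogr[ogid] <= reg$end
  expect_gte(mean(hit), 0.95)

  # zero anchors: empty mapping
  mp0 <- map_to_agbs(sim$genomes$sp2,
                     chain_anchors(anchor_pairs(character(), character()),
                                   sim$genomes$sp2, model$annotation), model)
  expect_true(all(is.na(mp0$genes$agb)))
})
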