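test_that("a perfect five-anchor diagonal is one block; four anchors are not", {
  q <- rank_annotation("q")
  t <- rank_annotation("t")
  an5 <- anchor_pairs(sprintf("q%02d", 0:4), sprintf("t%02d", 10:14 - 10))
  bl <- chain_anchors(an5, q, t)
  expect_equal(nrow(bl$blocks), 1)
  expect_equal(bl$blocks$orientation, "+")
  expect_equal(bl$blocks$n_anchors, 5)

  an4 <- anchor_pairs(sprintf("q%02d", 0:3), sprintf("t%02d", 0:3))
  expect_equal(nrow(chain_anchors(an4, q, t)$blocks), 0)
})

test_that("reversing a target segment flips block orientation, not content", {
  sim <- simulate_clade(lossfree_config(seed = 31))
  og <- sim$genomes$outgroup
  sp <- sim$genomes$sp1
  an <- sim$anchors[["outgroup:sp1"]]
  base <- chain_anchors(an, og, sp)
  # invert one descendant segment and re-chain
  set.seed(99)
  inv <- apply_rearrangements(sp, n_inversions = 1, lineage = "sp1")
  an2 <- anchor_pairs(an$gene_a, an$gene_b)
  flipped <- chain_anchors(an2, og, inv$genome)
  expect_setequal(paste(base$anchors$gene_a, base$anchors$gene_b),
                  paste(flipped$anchors$gene_a, flipped$anchors$gene_b))
  expect_true(any(flipped$blocks$orientation == "-"))
})

test_that("blocks partition anchors and respect the gap limit", {
  sim <- simulate_clade(sim_config(seed = 33, n_species = 1))
  an <- sim$anchors[["outgroup:sp1"]]
  bl <- chain_anchors(an, sim$genomes$outgroup, sim$genomes$sp1)
  expect_equal(anyDuplicated(paste(bl$anchors$gene_a, bl$anchors$gene_b)), 0)
  for (id in sample(unique(bl$anchors$block_id), 25)) {
    a <- bl$anchors[bl$anchors$block_id == id, ]
    expect_true(all(abs(diff(a$q_rank)) >= 1 & abs(diff(a$q_rank)) <= 5))
    expect_true(all(abs(diff(a$t_rank)) >= 1 & abs(diff(a$t_rank)) <= 5))
    o <- bl$blocks$orientation[bl$blocks$block_id == id]
    if (o == "+") expect_true(all(diff(a$t_rank) > 0))
    else expect_true(all(diff(a$t_rank) < 0))
  }
})

test_that("syntenic depth counts covering blocks", {
  ref <- rank_annotation("q")
  no_blocks <- chain_anchors(anchor_pairs(character(), character()),
                             ref, rank_annotation("t"))
  expect_true(all(syntenic_depth(no_blocks, ref) == 0))

  t <- rank_annotation("t")
  an <- anchor_pairs(sprintf("q%02d", 2:7), sprintf("t%02d", 2:7))
  bl <- chain_anchors(an, ref, t)
  d <- syntenic_depth(bl, ref)
  expect_equal(unname(d[sprintf("q%02d", 2:7)]), rep(1L, 6))
  expect_equal(unname(d[sprintf("q%02d", c(0, 1, 8))]), rep(0L, 3))

  # depth conservation: sum of depths = total span coverage of all blocks
  sim <- simulate_clade(sim_config(seed = 34, n_species = 1))
  blocks <- chain_anchors(sim$anchors[["outgroup:sp1"]],
                          sim$genomes$outgroup, sim$genomes$sp1)
  dd <- syntenic_depth(blocks, sim$genomes$outgroup)
  expect_equal(sum(dd),
               sum(blocks$blocks$q_end - blocks$blocks$q_start + 1))
})

test_that("syntenic gene pairs are the deduplicated union of block anchors", {
  q <- rank_annotation("q")
  t <- rank_annotation("t")
  an <- anchor_pairs(sprintf("q%02d", c(0:4, 10:14)),
                     sprintf("t%02d", c(0:4, 10:14)))
  bl <- chain_anchors(an, q, t)
  expect_equal(nrow(bl$blocks), 2)
  expect_equal(nrow(syntenic_gene_pairs(bl)), 10)
  empty <- chain_anchors(anchor_pairs(character(), character()), q, t)
  expect_equal(nrow(syntenic_gene_pairs(empty)), 0)
})

test_that("riparian ribbons carry a colour key per reference chromosome", {
  sim <- simulate_clade(lossfree_config(seed = 35))
  bl <- chain_anchors(anchor_pairs(sim$anchors[["outgroup:sp1"]]$gene_b,
                                   sim$anchors[["outgroup:sp1"]]$gene_a),
                      sim$genomes$sp1, sim$genomes$outgroup)
  rib <- riparian_data(bl, sim$genomes$outgroup)
  expect_equal(nrow(rib), nrow(bl$blocks))
  expect_true(all(rib$color_key %in% seq_along(sim$genomes$outgroup$chromosomes)))
  expect_equal(rib$color_key,
               match(rib$t_chrom, sim$genomes$outgroup$chromosomes))
})

test_that("clusters are connected components filtered by species span", {
  sp_map <- c(g1 = "A", g2 = "B", g3 = "C", h1 = "A", h2 = "A",
              k1 = "B", k2 = "B")
  pairs <- anchor_pairs(c("g1", "g2", "h1"), c("g2", "g3", "h2"))
  cl <- build_clusters(pairs, sp_map, min_species = 2)
  # the g-chain spans three species; the h pair is confined to species A
  expect_equal(length(unique(cl$members$cluster_id)), 1)
  expect_equal(sort(cl$members$gene_id), c("g1", "g2", "g3"))
  expect_equal(unname(cl$copy_number[, 1]), c(1L, 1L, 1L))

  cl2 <- build_clusters(anchor_pairs(c("g1", "k1"), c("g2", "k2")),
                        sp_map, min_species = 1)
  expect_equal(length(unique(cl2$members$cluster_id)), 2)

  expect_error(build_clusters(anchor_pairs("g1", "zz"), sp_map),
               "species")
})

test_that("cluster membership matches a breadth-first components oracle", {
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    genes <- sprintf("s%d_g%02d", sample(1:3, 30, replace = TRUE), 1:30)
    sp_map <- stats::setNames(sub("_.*", "", genes), genes)
    e <- data.frame(a = sample(genes, 25, replace = TRUE),
                    b = sample(genes, 25, replace = TRUE))
    e <- e[e$a != e$b, ]
    cl <- build_clusters(anchor_pairs(e$a, e$b), sp_map, min_species = 1)
    comp <- bfs_components(unique(c(e$a, e$b)), as.matrix(e))
    got <- stats::setNames(cl$members$cluster_id, cl$members$gene_id)
    # same partition: component labels in bijection
    tab <- table(got[names(comp)], comp)
    expect_true(all(rowSums(tab > 0) == 1))
    expect_true(all(colSums(tab > 0) == 1))
  }
})

test_that("phylogenomic profiles order similar clusters together", {
  sp_map <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B", c1 = "C", c2 = "C",
              a3 = "A", b3 = "B")
  pairs <- anchor_pairs(c("a1", "b1", "a2", "b2", "a3"),
                        c("b1", "c1", "b2", "c2", "b3"))
  cl <- build_clusters(pairs, sp_map)
  prof <- phylogenomic_profile(cl)
  expect_equal(ncol(prof$matrix), 3)
  # two clusters with identical copy-number columns must be adjacent leaves
  same <- which(apply(prof$matrix, 2, paste, collapse = "") ==
                  paste(c(1, 1, 1), collapse = ""))
  expect_equal(length(same), 2)
  expect_equal(unname(abs(diff(same))), 1L)

  single <- build_clusters(anchor_pairs("a1", "b1"), sp_map)
  p1 <- phylogenomic_profile(single)
  expect_equal(ncol(p1$matrix), 1)
})

test_that("clade sharing separates conserved from lineage-specific clusters", {
  sp_map <- c(a1 = "A", b1 = "B", c1 = "C", a2 = "A", a3 = "A")
  clades <- c(A = "west", B = "west", C = "east")
  pairs <- anchor_pairs(c("a1", "b1", "a2"), c("b1", "c1", "a3"))
  cl <- build_clusters(pairs, sp_map, min_species = 1)
  sh <- shared_cluster_counts(cl, clades)
  expect_equal(sh$conserved, 1)              # a1-b1-c1 spans west+east
  expect_equal(unname(sh$lineage_specific["west"]), 1)  # a2-a3
  expect_equal(unname(sh$lineage_specific["east"]), 0)

  empty <- build_clusters(anchor_pairs(character(), character()), sp_map)
  sh0 <- shared_cluster_counts(empty, clades)
  expect_equal(sh0$conserved, 0)
  expect_error(shared_cluster_counts(cl, c(A = "west", B = "west")),
               "clade")
})
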