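#' Simulation configuration
#'
#' Parameters of the synthetic clade generator. The generator emulates the
#' study design the analysis modules assume: a diploid outgroup that diverged
#' before a two-step whole-genome triplication, plus several descendants of
#' the triplicated ancestor that each underwent independent gene
#' fractionation (locally biased, globally unbiased, reciprocal across the
#' three homoeologous copies) and chromosomal rearrangements, with a planted
#' set of loss-immune triple-copy genes carrying tissue-partitioned
#' expression.
#'
#' @param n_chrom ancestral chromosome number (default 8).
#' @param genes_per_chrom genes per ancestral chromosome (default 500).
#' @param n_species number of triplicated descendants (default 4); one
#'   outgroup is always generated in addition.
#' @param retention_mean marginal per-copy gene retention probability after
#'   fractionation, in (0, 1] (default 0.41, i.e. a combined retention of
#'   123% out of the 300% ceiling). Planted loss-immune genes count toward
#'   this marginal, so the genome-wide per-copy retention equals
#'   `retention_mean` whatever `rtg_fraction` is.
#' @param window_bias_block size (in ancestral genes) of the windows within
#'   which fractionation is locally biased (default 100).
#' @param bias_concentration Dirichlet concentration controlling how biased
#'   the three per-window retention probabilities are (default 3; small
#'   values give strong local bias and strong reciprocity, `Inf` gives
#'   identical independent probabilities in every window).
#' @param rtg_fraction fraction of ancestral genes planted as loss-immune
#'   retained triplicated genes (default 0.02).
#' @param n_fissions,n_fusions,n_inversions,n_translocations rearrangement
#'   counts applied independently to each descendant lineage (defaults 3, 3,
#'   3, 1).
#' @param outgroup_inversions inversions applied to the outgroup lineage
#'   (default 2); the outgroup receives no fissions, fusions or
#'   translocations, modelling a structurally conservative sister lineage —
#'   the property that motivates using it as the reference karyotype.
#' @param n_tissues tissues in the simulated expression matrix (default 8).
#' @param seed integer seed driving the single shared random stream.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 8L, genes_per_chrom = 500L, n_species = 4L,
                       retention_mean = 0.41, window_bias_block = 100L,
                       bias_concentration = 3, rtg_fraction = 0.02,
                       n_fissions = 3L, n_fusions = 3L, n_inversions = 3L,
                       n_translocations = 1L, outgroup_inversions = 2L,
                       n_tissues = 8L, seed = 1L) {
  cfg <- list(n_chrom = as.integer(n_chrom),
              genes_per_chrom = as.integer(genes_per_chrom),
              n_species = as.integer(n_species),
              retention_mean = retention_mean,
              window_bias_block = as.integer(window_bias_block),
              bias_concentration = bias_concentration,
              rtg_fraction = rtg_fraction,
              n_fissions = as.integer(n_fissions),
              n_fusions = as.integer(n_fusions),
              n_inversions = as.integer(n_inversions),
              n_translocations = as.integer(n_translocations),
              outgroup_inversions = as.integer(outgroup_inversions),
              n_tissues = as.integer(n_tissues),
              seed = as.integer(seed))
  stopifnot(cfg$n_chrom >= 1, cfg$genes_per_chrom >= 2, cfg$n_species >= 1,
            cfg$retention_mean > 0, cfg$retention_mean <= 1,
            cfg$window_bias_block >= 1, cfg$bias_concentration > 0,
            cfg$rtg_fraction >= 0, cfg$rtg_fraction <= 1,
            cfg$n_fissions >= 0, cfg$n_fusions >= 0, cfg$n_inversions >= 0,
            cfg$n_translocations >= 0, cfg$n_tissues >= 2)
  class(cfg) <- "sim_config"
  cfg
}

# one Dirichlet(alpha, alpha, alpha) draw; Inf -> the symmetric point mass
rdirichlet3 <- function(alpha) {
  if (!is.finite(alpha)) return(rep(1 / 3, 3))
  g <- stats::rgamma(3, shape = alpha, rate = 1)
  if (sum(g) == 0) return(rep(1 / 3, 3))
  g / sum(g)
}

anc_gene_id <- function(chrom_idx, gene_idx) {
  sprintf("c%02dg%04d", chrom_idx, gene_idx)
}

#' Simulate the pre-triplication diploid ancestor
#'
#' Gene ids encode the ancestral identifier (`c<chrom>g<index>`), which all
#' descendant gene ids inherit; base-pair coordinates are synthetic (1 kb
#' gene spacing) and only used to carry rank order.
#'
#' @param config a [sim_config()].
#' @return a [genome_annotation()] for species `"ancestor"`.
#' @export
simulate_ancestor <- function(config = sim_config()) {
  set.seed(config$seed)
  simulate_ancestor_nogseed(config)
}

#' Apply the two-step whole-genome triplication
#'
#' First duplicates the genome (subgenomes `a` and `b`), then adds a third
#' copy (`c`); no divergence is modelled between the two steps. Every
#' ancestral gene ends with exactly three descendant copies, one per
#' subgenome, on triplicated chromosomes.
#'
#' @param ancestor diploid [genome_annotation()] whose gene ids are ancestral
#'   identifiers.
#' @return list with `genome` (the triplicated [genome_annotation()]) and
#'   `truth` (data.frame `gene_id`, `subgenome`, `ancestral_gene`).
#' @export
apply_wgt <- function(ancestor) {
  g <- ancestor$genes
  copy1 <- function(sub) {
    data.frame(gene_id = paste(sub, g$gene_id, sep = "_"),
               chrom = paste(g$chrom, sub, sep = "_"),
               start = g$start, end = g$end, strand = g$strand,
               stringsAsFactors = FALSE)
  }
  tetra <- rbind(copy1("a"), copy1("b"))   # step 1: tetraploid
  hexa <- rbind(tetra, copy1("c"))         # step 2: third subgenome
  truth <- data.frame(
    gene_id = hexa$gene_id,
    subgenome = sub("_.*$", "", hexa$gene_id),
    ancestral_gene = sub("^[abc]_", "", hexa$gene_id),
    stringsAsFactors = FALSE)
  list(genome = genome_annotation(hexa, species = "hexaploid_ancestor"),
       truth = truth)
}

#' Apply window-biased gene fractionation
#'
#' Retention probabilities are drawn per window of `window_bias_block`
#' ancestral genes: with `r = retention_mean` and a Dirichlet weight triple
#' `w` (concentration `bias_concentration`), the slot probabilities are
#' `p_s = r + m (3 w_s - 1)` with spread `m = min(r, (1 - r) / 2)`, which
#' keeps every probability in `[0, 1]`, makes the per-copy marginal exactly
#' `r` (so `retention_mean = 1` deletes nothing), and fixes the per-window
#' sum at `3 r`. Because the three per-window probabilities sum to a
#' constant, high retention of one homoeolog forces lower retention of the
#' other two — the reciprocal fractionation pattern. Each non-immune gene
#' copy then survives independently; genes in `rtg_set` always survive in
#' all three copies, and the survival probability of the remaining genes is
#' deflated so the overall marginal stays `retention_mean`.
#'
#' @param polyploid triplicated [genome_annotation()] from [apply_wgt()].
#' @param truth the truth data.frame from [apply_wgt()].
#' @param config a [sim_config()].
#' @param rtg_set character vector of loss-immune ancestral gene ids.
#' @return list with `genome` (fractionated annotation, ranks re-densified),
#'   `window_probs` (data.frame of the true per-window retention
#'   probabilities: `anc_chrom`, `window`, `p_a`, `p_b`, `p_c`) and
#'   `n_deleted`.
#' @export
apply_fractionation <- function(polyploid, truth, config, rtg_set = character()) {
  g <- polyploid$genes
  tr <- truth[match(g$gene_id, truth$gene_id), ]
  anc_chrom <- sub("g[0-9]+$", "", tr$ancestral_gene)
  anc_idx <- as.integer(sub("^c[0-9]+g", "", tr$ancestral_gene))
  win <- (anc_idx - 1L) %/% config$window_bias_block
  wkey <- paste(anc_chrom, win, sep = ":")
  uw <- sort(unique(wkey))
  r <- config$retention_mean
  m <- min(r, (1 - r) / 2)
  probs <- t(vapply(uw, function(k) {
    w <- rdirichlet3(config$bias_concentration)
    r + m * (3 * w - 1)
  }, numeric(3)))
  colnames(probs) <- c("a", "b", "c")
  # deflate non-immune survival so the marginal includes the immune genes
  f <- config$rtg_fraction
  p_gene <- probs[cbind(match(wkey, uw), match(tr$subgenome, colnames(probs)))]
  p_adj <- pmin(1, pmax(0, (p_gene - f) / (1 - f)))
  immune <- tr$ancestral_gene %in% rtg_set
  keep <- immune | (stats::runif(length(p_adj)) < p_adj)
  kept <- g[keep, c("gene_id", "chrom", "start", "end", "strand")]
  lost_chroms <- setdiff(g$chrom, kept$chrom)
  if (length(lost_chroms) > 0) {
    warning("fractionation emptied chromosome(s): ",
            paste(lost_chroms, collapse = ", "))
  }
  wp <- data.frame(anc_chrom = sub(":.*$", "", uw),
                   window = as.integer(sub("^.*:", "", uw)),
                   p_a = probs[, "a"], p_b = probs[, "b"], p_c = probs[, "c"],
                   stringsAsFactors = FALSE)
  rownames(wp) <- NULL
  list(genome = genome_annotation(kept, species = polyploid$species),
       window_probs = wp,
       n_deleted = sum(!keep))
}

# genome as a list of chromosomes, each an ordered gene data.frame (internal
# representation used while applying rearrangements)
as_chrom_list <- function(annotation) {
  g <- annotation$genes[order(annotation$genes$chrom, annotation$genes$rank), ]
  lapply(split(g[, c("gene_id", "strand")], g$chrom),
         function(x) { rownames(x) <- NULL; x })
}

chrom_list_to_annotation <- function(chroms, species) {
  dfs <- lapply(names(chroms), function(nm) {
    x <- chroms[[nm]]
    n <- nrow(x)
    data.frame(gene_id = x$gene_id, chrom = nm,
               start = (seq_len(n) - 1L) * 1000L,
               end = (seq_len(n) - 1L) * 1000L + 900L,
               strand = x$strand, stringsAsFactors = FALSE)
  })
  genome_annotation(do.call(rbind, dfs), species = species)
}

flip_chrom <- function(x) {
  x <- x[rev(seq_len(nrow(x))), ]
  x$strand <- ifelse(x$strand == "+", "-", "+")
  rownames(x) <- NULL
  x
}

gap_key <- function(u, v) paste(sort(c(u, v)), collapse = "|")

#' Apply chromosomal rearrangements
#'
#' Events are applied in the order fission, fusion, inversion,
#' translocation. Breakpoints are sampled uniformly over inter-gene gaps and
#' never reused within a lineage (each used gap, including gaps created by
#' fusions and translocations, is retired); fission and translocation
#' breakpoints additionally leave at least two genes on each side, the
#' smallest unit a collinear chain can evidence. Both rules keep event
#' counts identifiable from the resulting gene order. Fusions join two uniformly
#' chosen chromosome ends with random relative orientation; inversions
#' reverse a contiguous rank interval (uniform length between 2 genes and
#' half the chromosome) and flip strands; translocations reciprocally
#' exchange chromosome tails.
#'
#' @param genome a [genome_annotation()].
#' @param n_fissions,n_fusions,n_inversions,n_translocations event counts.
#' @param lineage label recorded in the event log.
#' @return list with `genome` (rearranged annotation; base-pair coordinates
#'   re-synthesised to match the new order) and `events` (data.frame
#'   `lineage`, `event`, `chrom`, `position`, `chrom2`, `position2`;
#'   positions are the 1-based rank of the gap within the chromosome at the
#'   time the event was applied).
#' @export
apply_rearrangements <- function(genome, n_fissions = 0L, n_fusions = 0L,
                                 n_inversions = 0L, n_translocations = 0L,
                                 lineage = genome$species) {
  chroms <- as_chrom_list(genome)
  used <- character()
  log <- list()
  note <- function(event, chrom, pos, chrom2 = NA, pos2 = NA) {
    log[[length(log) + 1]] <<- data.frame(
      lineage = lineage, event = event, chrom = chrom, position = pos,
      chrom2 = chrom2, position2 = pos2, stringsAsFactors = FALSE)
  }
  # candidate gaps; min_flank >= 2 keeps every fission/translocation product
  # at least two genes long, the smallest unit a collinear chain can detect,
  # so event counts stay identifiable from gene order
  free_gaps <- function(min_flank = 2L) {
    per_chrom <- lapply(names(chroms), function(nm) {
      x <- chroms[[nm]]
      n <- nrow(x)
      if (n < 2 * min_flank) return(NULL)
      pos <- min_flank:(n - min_flank)
      u <- x$gene_id[pos]; v <- x$gene_id[pos + 1]
      keys <- paste(pmin(u, v), pmax(u, v), sep = "|")
      ok <- !keys %in% used
      if (!any(ok)) return(NULL)
      data.frame(chrom = nm, pos = pos[ok], stringsAsFactors = FALSE)
    })
    do.call(rbind, per_chrom)
  }

  counter <- 0L
  fresh_name <- function(prefix) {
    counter <<- counter + 1L
    sprintf("%s_%s%02d", lineage, prefix, counter)
  }

  for (i in seq_len(n_fissions)) {
    gaps <- free_gaps()
    if (is.null(gaps) || nrow(gaps) == 0) {
      stop("requested fissions exceed available breakpoint gaps")
    }
    g <- gaps[sample.int(nrow(gaps), 1), ]
    x <- chroms[[g$chrom]]
    used <- c(used, gap_key(x$gene_id[g$pos], x$gene_id[g$pos + 1]))
    left <- x[seq_len(g$pos), , drop = FALSE]
    right <- x[(g$pos + 1):nrow(x), , drop = FALSE]
    rownames(left) <- rownames(right) <- NULL
    nm1 <- fresh_name("fis"); nm2 <- fresh_name("fis")
    chroms[[g$chrom]] <- NULL
    chroms[[nm1]] <- left
    chroms[[nm2]] <- right
    note("fission", g$chrom, g$pos)
  }

  for (i in seq_len(n_fusions)) {
    if (length(chroms) < 2) stop("not enough chromosomes to fuse")
    pick <- sample(names(chroms), 2)
    x <- chroms[[pick[1]]]; y <- chroms[[pick[2]]]
    if (sample(c(TRUE, FALSE), 1)) x <- flip_chrom(x)  # join at x's tail
    if (sample(c(TRUE, FALSE), 1)) y <- flip_chrom(y)  # join at y's head
    used <- c(used, gap_key(x$gene_id[nrow(x)], y$gene_id[1]))
    joined <- rbind(x, y)
    rownames(joined) <- NULL
    nm <- fresh_name("fus")
    chroms[[pick[1]]] <- NULL
    chroms[[pick[2]]] <- NULL
    chroms[[nm]] <- joined
    note("fusion", pick[1], nrow(x), pick[2], 0)
  }

  for (i in seq_len(n_inversions)) {
    cand <- names(chroms)[vapply(chroms, nrow, 0L) >= 4]
    if (length(cand) == 0) stop("no chromosome long enough to invert")
    done <- FALSE
    for (try in 1:100) {
      nm <- if (length(cand) == 1) cand else sample(cand, 1)
      x <- chroms[[nm]]
      n <- nrow(x)
      len <- sample(2:(n %/% 2), 1)
      s <- sample.int(n - len + 1, 1)
      e <- s + len - 1
      keys <- character()
      if (s > 1) keys <- c(keys, gap_key(x$gene_id[s - 1], x$gene_id[s]))
      if (e < n) keys <- c(keys, gap_key(x$gene_id[e], x$gene_id[e + 1]))
      if (any(keys %in% used)) next
      used <- c(used, keys)
      seg <- flip_chrom(x[s:e, , drop = FALSE])
      x[s:e, ] <- seg
      chroms[[nm]] <- x
      note("inversion", nm, s, nm, e)
      done <- TRUE
      break
    }
    if (!done) stop("could not place inversion without breakpoint reuse")
  }

  for (i in seq_len(n_translocations)) {
    cand <- names(chroms)[vapply(chroms, nrow, 0L) >= 4]
    if (length(cand) < 2) stop("not enough chromosomes to translocate")
    done <- FALSE
    for (try in 1:100) {
      pick <- sample(cand, 2)
      x <- chroms[[pick[1]]]; y <- chroms[[pick[2]]]
      px <- sample(2:(nrow(x) - 2), 1)
      py <- sample(2:(nrow(y) - 2), 1)
      kx <- gap_key(x$gene_id[px], x$gene_id[px + 1])
      ky <- gap_key(y$gene_id[py], y$gene_id[py + 1])
      if (kx %in% used || ky %in% used) next
      newx <- rbind(x[seq_len(px), ], y[(py + 1):nrow(y), ])
      newy <- rbind(y[seq_len(py), ], x[(px + 1):nrow(x), ])
      rownames(newx) <- rownames(newy) <- NULL
      used <- c(used, kx, ky,
                gap_key(newx$gene_id[px], newx$gene_id[px + 1]),
                gap_key(newy$gene_id[py], newy$gene_id[py + 1]))
      chroms[[pick[1]]] <- newx
      chroms[[pick[2]]] <- newy
      note("translocation", pick[1], px, pick[2], py)
      done <- TRUE
      break
    }
    if (!done) stop("could not place translocation without breakpoint reuse")
  }

  events <- if (length(log) > 0) do.call(rbind, log) else
    data.frame(lineage = character(), event = character(), chrom = character(),
               position = integer(), chrom2 = character(), position2 = integer())
  list(genome = chrom_list_to_annotation(chroms, genome$species),
       events = events)
}

rename_species <- function(annotation, species) {
  g <- annotation$genes
  g$gene_id <- paste(species, g$gene_id, sep = "_")
  g$chrom <- paste(species, g$chrom, sep = "_")
  genome_annotation(g[, c("gene_id", "chrom", "start", "end", "strand")],
                    species = species)
}

#' Simulate a full clade with ground truth
#'
#' Generates the diploid ancestor, applies the two-step triplication, and
#' derives one outgroup (ancestor plus outgroup-specific inversions, no
#' triplication, no gene loss) and `n_species` descendants (independent
#' fractionation plus rearrangements of the shared triplicated ancestor).
#' Truth anchors connect each outgroup gene to every surviving descendant
#' copy, and descendant genes to each other when they descend from the same
#' ancestral gene through the same subgenome. The expression matrix covers
#' the first descendant: each copy of a planted triple-copy gene is assigned
#' one preferred tissue (high mean, the three copies preferring different
#' tissues) against a low background, while all other genes are expressed
#' uniformly across tissues.
#'
#' @param config a [sim_config()].
#' @return list of class `clade_simulation` with elements `genomes` (named
#'   list of [genome_annotation()]; `"outgroup"` plus `"sp1"`..), `truth`
#'   (list: `genes`, `event_log`, `rtg_set`, `homoeologous_set_of`,
#'   `window_probs`, `ancestor`), `anchors` (named list of `anchor_pairs`,
#'   names like `"outgroup:sp1"` or `"sp1:sp2"`), `expression` (genes x
#'   tissues matrix) and `config`.
#' @export
simulate_clade <- function(config = sim_config()) {
  set.seed(config$seed)
  ancestor <- simulate_ancestor_nogseed(config)
  wgt <- apply_wgt(ancestor)

  n_anc <- n_genes(ancestor)
  anc_ids <- ancestor$genes$gene_id
  n_rtg <- round(config$rtg_fraction * n_anc)
  rtg_set <- if (n_rtg > 0) sort(sample(anc_ids, n_rtg)) else character()

  # truth homoeologous sets: each ancestral chromosome halved into 2 regions
  half <- ceiling(config$genes_per_chrom / 2)
  anc_chrom_idx <- as.integer(sub("^c0*([0-9]+)g.*$", "\\1", anc_ids))
  anc_gene_idx <- as.integer(sub("^c[0-9]+g", "", anc_ids))
  hset <- (anc_chrom_idx - 1L) * 2L + 1L + as.integer(anc_gene_idx > half)
  names(hset) <- anc_ids

  # outgroup: conservative sister, inversions only
  og <- apply_rearrangements(ancestor,
                             n_inversions = config$outgroup_inversions,
                             lineage = "outgroup")
  outgroup <- rename_species(og$genome, "outgroup")
  event_log <- og$events

  genomes <- list(outgroup = outgroup)
  truth_genes <- list()
  window_probs <- list()
  for (i in seq_len(config$n_species)) {
    sp <- sprintf("sp%d", i)
    fr <- apply_fractionation(wgt$genome, wgt$truth, config, rtg_set)
    re <- apply_rearrangements(fr$genome,
                               n_fissions = config$n_fissions,
                               n_fusions = config$n_fusions,
                               n_inversions = config$n_inversions,
                               n_translocations = config$n_translocations,
                               lineage = sp)
    genomes[[sp]] <- rename_species(re$genome, sp)
    event_log <- rbind(event_log, re$events)
    tg <- wgt$truth[wgt$truth$gene_id %in% re$genome$genes$gene_id, ]
    tg <- data.frame(gene_id = paste(sp, tg$gene_id, sep = "_"),
                     species = sp, subgenome = tg$subgenome,
                     ancestral_gene = tg$ancestral_gene,
                     stringsAsFactors = FALSE)
    truth_genes[[sp]] <- tg
    wp <- fr$window_probs; wp$species <- sp
    window_probs[[sp]] <- wp
  }
  truth_genes <- do.call(rbind, truth_genes)
  rownames(truth_genes) <- NULL

  # truth anchors
  out_id_of_anc <- stats::setNames(outgroup$genes$gene_id,
                                   sub("^outgroup_", "", outgroup$genes$gene_id))
  anchors <- list()
  sps <- sprintf("sp%d", seq_len(config$n_species))
  for (sp in sps) {
    tg <- truth_genes[truth_genes$species == sp, ]
    anchors[[paste("outgroup", sp, sep = ":")]] <-
      anchor_pairs(unname(out_id_of_anc[tg$ancestral_gene]), tg$gene_id)
  }
  if (length(sps) >= 2) {
    for (i in seq_along(sps)) for (j in seq_along(sps)) {
      if (i >= j) next
      ti <- truth_genes[truth_genes$species == sps[i], ]
      tj <- truth_genes[truth_genes$species == sps[j], ]
      key_i <- paste(ti$subgenome, ti$ancestral_gene)
      key_j <- paste(tj$subgenome, tj$ancestral_gene)
      m <- match(key_i, key_j)
      ok <- !is.na(m)
      anchors[[paste(sps[i], sps[j], sep = ":")]] <-
        anchor_pairs(ti$gene_id[ok], tj$gene_id[m[ok]])
    }
  }

  expression <- simulate_expression(truth_genes[truth_genes$species == sps[1], ],
                                    rtg_set, config)

  structure(
    list(genomes = genomes,
         truth = list(genes = truth_genes, event_log = event_log,
                      rtg_set = rtg_set, homoeologous_set_of = hset,
                      window_probs = do.call(rbind, window_probs),
                      ancestor = ancestor),
         anchors = anchors,
         expression = expression,
         config = config),
    class = "clade_simulation")
}

# ancestor without re-seeding (simulate_clade owns the seed)
simulate_ancestor_nogseed <- function(config) {
  nc <- config$n_chrom; np <- config$genes_per_chrom
  chrom <- rep(sprintf("chr%02d", seq_len(nc)), each = np)
  idx <- rep(seq_len(np), times = nc)
  start <- (idx - 1L) * 1000L
  genome_annotation(
    data.frame(gene_id = anc_gene_id(rep(seq_len(nc), each = np), idx),
               chrom = chrom, start = start, end = start + 900L,
               strand = sample(c("+", "-"), nc * np, replace = TRUE),
               stringsAsFactors = FALSE),
    species = "ancestor")
}

#' Simulate tissue expression for one species
#'
#' @param truth_genes truth rows (one species) with `gene_id`,
#'   `ancestral_gene`, `subgenome`.
#' @param rtg_set planted loss-immune ancestral gene ids.
#' @param config a [sim_config()].
#' @return numeric matrix (genes x tissues), TPM-like.
#' @export
simulate_expression <- function(truth_genes, rtg_set, config) {
  tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
  n <- nrow(truth_genes)
  # uniform low-specificity background for every gene
  mat <- matrix(stats::rlnorm(n * length(tissues), meanlog = log(10), sdlog = 0.4),
                nrow = n, dimnames = list(truth_genes$gene_id, tissues))
  is_rtg <- truth_genes$ancestral_gene %in% rtg_set
  for (anc in unique(truth_genes$ancestral_gene[is_rtg])) {
    rows <- which(truth_genes$ancestral_gene == anc)
    pref <- sample(seq_along(tissues), length(rows))
    for (k in seq_along(rows)) {
      mat[rows[k], ] <- stats::rlnorm(length(tissues), meanlog = log(1.5), sdlog = 0.5)
      mat[rows[k], pref[k]] <- stats::rlnorm(1, meanlog = log(80), sdlog = 0.3)
    }
  }
  mat
}

#' Write a simulated clade to disk
#'
#' Per-species BED files, truth anchor TSVs, truth tables, the expression
#' matrix and the configuration (JSON).
#'
#' @param sim a [simulate_clade()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$genomes)) {
    write_bed(sim$genomes[[sp]], file.path(dir, paste0(sp, ".bed")))
  }
  for (nm in names(sim$anchors)) {
    write_anchors(sim$anchors[[nm]],
                  file.path(dir, paste0("anchors_", gsub(":", "_", nm), ".tsv")))
  }
  write_tsv(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  write_tsv(sim$truth$event_log, file.path(dir, "truth_events.tsv"))
  write_tsv(data.frame(ancestral_gene = sim$truth$rtg_set),
            file.path(dir, "truth_rtgs.tsv"))
  expr <- data.frame(gene_id = rownames(sim$expression),
                     round(sim$expression, 4), check.names = FALSE)
  write_tsv(expr, file.path(dir, "expression.tsv"))
  cfg <- unclass(sim$config)
  cfg$bias_concentration <- ifelse(is.finite(cfg$bias_concentration),
                                   cfg$bias_concentration, "Inf")
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}
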