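#' Chaining parameters
#'
#' @param block_size minimum anchors per retained block (default 5, the
#'   classic "at least five genes" evidence threshold).
#' @param gap_size maximum rank gap between consecutive anchors of a chain,
#'   enforced in both genomes (default 5).
#' @return list of class `chain_params`.
#' @export
chain_params <- function(block_size = 5L, gap_size = 5L) {
  block_size <- as.integer(block_size); gap_size <- as.integer(gap_size)
  stopifnot(block_size >= 2, gap_size >= 1)
  structure(list(block_size = block_size, gap_size = gap_size),
            class = "chain_params")
}

# dynamic program: best collinear chain among anchors of one
# (query chrom, target chrom) group for one orientation.
# a: data.frame with qr, tr (query/target ranks). Returns indices into a of
# the best chain (possibly length 1), or integer(0) if a is empty.
best_chain_dp <- function(a, orientation, gap_size) {
  n <- nrow(a)
  if (n == 0) return(integer(0))
  ord <- if (orientation == "+") order(a$qr, a$tr) else order(a$qr, -a$tr)
  qr <- a$qr[ord]; tr <- a$tr[ord]
  dp <- rep(1L, n); pred <- rep(0L, n)
  sq <- qr; st <- tr   # chain start coordinates, for deterministic ties
  for (i in seq_len(n)) {
    lo <- qr[i] - gap_size
    # candidate predecessors: earlier in ord with qr in [qr[i]-gap, qr[i]-1];
    # qr is non-decreasing, so the range is found by binary search
    j1 <- findInterval(lo - 0.5, qr) + 1L
    j2 <- findInterval(qr[i] - 0.5, qr)
    j <- if (j1 <= j2) j1:j2 else integer(0)
    if (length(j) > 0) {
      dt <- if (orientation == "+") tr[i] - tr[j] else tr[j] - tr[i]
      j <- j[dt >= 1L & dt <= gap_size]
    }
    if (length(j) > 0) {
      best <- j[order(-dp[j], sq[j], st[j])][1]
      dp[i] <- dp[best] + 1L
      pred[i] <- best
      sq[i] <- sq[best]; st[i] <- st[best]
    }
  }
  end <- which(dp == max(dp))
  end <- end[order(sq[end], st[end], qr[end])][1]
  chain <- integer(0)
  k <- end
  while (k != 0L) { chain <- c(k, chain); k <- pred[k] }
  ord[chain]
}

#' Chain anchors into collinear synteny blocks
#'
#' For every (query chromosome, target chromosome) pair, repeatedly extracts
#' the highest-scoring collinear chain (score = anchor count; a chain is
#' strictly monotone in query rank and strictly increasing/decreasing in
#' target rank for +/- orientation, with consecutive rank gaps at most
#' `gap_size` in both genomes), removes its anchors together with every
#' remaining anchor that shares a query gene with it (so tandem-duplicate
#' anchors to the same target region cannot seed a second overlapping
#' block), and repeats until the best chain falls below `block_size`.
#' Best-chain ties are broken by smaller query start rank, then target start
#' rank, then + orientation. Chains shorter than `block_size` are discarded.
#'
#' Chained-gene removal is local to the (query chromosome, target
#' chromosome) pair: homoeologous copies of a region on *different* target
#' chromosomes each keep their own chain, which is what makes the syntenic
#' depth of a triplicated genome against its diploid sister read 3.
#'
#' @param anchors `anchor_pairs` (`gene_a` in `query`, `gene_b` in `target`).
#' @param query,target [genome_annotation()] objects.
#' @param params a [chain_params()].
#' @return object of class `synteny_blocks`: list with `blocks` (data.frame
#'   `block_id`, `q_chrom`, `q_start`, `q_end`, `t_chrom`, `t_start`,
#'   `t_end`, `orientation`, `n_anchors`; spans are rank intervals) and
#'   `anchors` (data.frame `block_id`, `gene_a`, `gene_b`, `q_rank`,
#'   `t_rank`, ordered along each chain).
#' @export
chain_anchors <- function(anchors, query, target, params = chain_params()) {
  qr <- rank_of(query); qc <- chrom_of(query)
  tr <- rank_of(target); tc <- chrom_of(target)
  known <- anchors$gene_a %in% names(qr) & anchors$gene_b %in% names(tr)
  if (any(!known)) {
    warning(sum(!known), " anchor(s) not found in the annotations; dropped")
    anchors <- anchors[known, , drop = FALSE]
  }
  empty_blocks <- data.frame(block_id = character(), q_chrom = character(),
                             q_start = integer(), q_end = integer(),
                             t_chrom = character(), t_start = integer(),
                             t_end = integer(), orientation = character(),
                             n_anchors = integer(), stringsAsFactors = FALSE)
  empty_anch <- data.frame(block_id = character(), gene_a = character(),
                           gene_b = character(), q_rank = integer(),
                           t_rank = integer(), stringsAsFactors = FALSE)
  if (nrow(anchors) == 0) {
    return(structure(list(blocks = empty_blocks, anchors = empty_anch),
                     class = "synteny_blocks"))
  }
  tab <- data.frame(gene_a = anchors$gene_a, gene_b = anchors$gene_b,
                    qc = unname(qc[anchors$gene_a]),
                    qr = unname(qr[anchors$gene_a]),
                    tc = unname(tc[anchors$gene_b]),
                    tr = unname(tr[anchors$gene_b]),
                    stringsAsFactors = FALSE)
  tab <- unique(tab)
  groups <- split(tab, paste(tab$qc, tab$tc, sep = "\r"))
  groups <- groups[order(names(groups))]
  blocks <- list(); banchors <- list()
  bid <- 0L
  for (grp in groups) {
    pool <- grp
    repeat {
      if (nrow(pool) == 0) break
      ch_p <- best_chain_dp(pool, "+", params$gap_size)
      ch_m <- best_chain_dp(pool, "-", params$gap_size)
      pick_p <- length(ch_p) >= length(ch_m)
      if (length(ch_p) == length(ch_m) && length(ch_p) > 0) {
        kp <- c(min(pool$qr[ch_p]), min(pool$tr[ch_p]))
        km <- c(min(pool$qr[ch_m]), min(pool$tr[ch_m]))
        pick_p <- kp[1] < km[1] || (kp[1] == km[1] && kp[2] <= km[2])
      }
      chain <- if (pick_p) ch_p else ch_m
      orientation <- if (pick_p) "+" else "-"
      if (length(chain) < params$block_size) break
      bid <- bid + 1L
      id <- sprintf("blk%05d", bid)
      cg <- pool[chain, ]
      blocks[[bid]] <- data.frame(
        block_id = id, q_chrom = cg$qc[1],
        q_start = min(cg$qr), q_end = max(cg$qr),
        t_chrom = cg$tc[1], t_start = min(cg$tr), t_end = max(cg$tr),
        orientation = orientation, n_anchors = nrow(cg),
        stringsAsFactors = FALSE)
      banchors[[bid]] <- data.frame(block_id = id, gene_a = cg$gene_a,
                                    gene_b = cg$gene_b, q_rank = cg$qr,
                                    t_rank = cg$tr, stringsAsFactors = FALSE)
      pool <- pool[!pool$gene_a %in% cg$gene_a, , drop = FALSE]
    }
  }
  out <- list(
    blocks = if (length(blocks) > 0) do.call(rbind, blocks) else empty_blocks,
    anchors = if (length(banchors) > 0) do.call(rbind, banchors) else empty_anch)
  rownames(out$blocks) <- rownames(out$anchors) <- NULL
  structure(out, class = "synteny_blocks")
}

#' @export
print.synteny_blocks <- function(x, ...) {
  cat(sprintf("synteny_blocks: %d block(s), %d chained anchor(s)\n",
              nrow(x$blocks), nrow(x$anchors)))
  invisible(x)
}

#' Per-gene syntenic depth
#'
#' Depth of a reference gene is the number of synteny blocks whose query
#' span covers its rank; blocks, not anchors, are counted, and non-anchor
#' genes inside a span are covered. A triplicated genome against a diploid
#' reference reads depth 3 along retained regions.
#'
#' @param blocks a `synteny_blocks` computed with `reference` as query.
#' @param reference the query-side [genome_annotation()].
#' @return named integer vector, gene id -> depth.
#' @export
syntenic_depth <- function(blocks, reference) {
  g <- reference$genes
  depth <- stats::setNames(integer(nrow(g)), g$gene_id)
  b <- blocks$blocks
  if (nrow(b) == 0) return(depth)
  for (chr in unique(b$q_chrom)) {
    gi <- which(g$chrom == chr)
    if (length(gi) == 0) next
    nmax <- max(g$rank[gi]) + 1L
    cov <- integer(nmax + 1L)
    bb <- b[b$q_chrom == chr, , drop = FALSE]
    for (k in seq_len(nrow(bb))) {
      s <- min(bb$q_start[k], nmax - 1L) + 1L
      e <- min(bb$q_end[k], nmax - 1L) + 1L
      cov[s] <- cov[s] + 1L
      cov[e + 1L] <- cov[e + 1L] - 1L
    }
    cov <- cumsum(cov[seq_len(nmax)])
    depth[gi] <- cov[g$rank[gi] + 1L]
  }
  depth
}

#' Syntenic gene pairs inside retained blocks
#'
#' @param blocks a `synteny_blocks`.
#' @return `anchor_pairs` (deduplicated union of chained anchors).
#' @export
syntenic_gene_pairs <- function(blocks) {
  a <- unique(blocks$anchors[, c("gene_a", "gene_b")])
  anchor_pairs(a$gene_a, a$gene_b)
}

#' Write synteny blocks as TSV
#' @param blocks a `synteny_blocks`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_blocks <- function(blocks, path) {
  write_tsv(blocks$blocks[, c("q_chrom", "q_start", "q_end", "t_chrom",
                              "t_start", "t_end", "orientation", "n_anchors",
                              "block_id")], path)
}

#' Ribbon data for riparian plots
#'
#' One ribbon per block, with a colour key tied to the reference (target)
#' chromosome so homologous regions share a colour across a stack of
#' genomes, following the usual riparian-plot convention.
#'
#' @param blocks a `synteny_blocks`.
#' @param reference the target-side [genome_annotation()] whose chromosomes
#'   key the colours.
#' @return data.frame `block_id`, `q_chrom`, `q_start`, `q_end`, `t_chrom`,
#'   `t_start`, `t_end`, `orientation`, `color_key` (integer index of the
#'   target chromosome).
#' @export
riparian_data <- function(blocks, reference) {
  b <- blocks$blocks
  b$color_key <- match(b$t_chrom, reference$chromosomes)
  b[, c("block_id", "q_chrom", "q_start", "q_end", "t_chrom", "t_start",
        "t_end", "orientation", "color_key")]
}
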