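#' Merge collinear level-1 segments into level-2 blocks
#'
#' Scans each ingroup chromosome left to right and merges consecutive
#' segments whose outgroup counterparts are physically adjacent: same
#' outgroup chromosome, consistent orientation, and outgroup rank intervals
#' within `adjacency_tol` ranks of each other (in the direction the
#' orientation implies). Segments with fewer than `min_size` anchors cannot
#' seed a merge but may be absorbed by one; unmerged segments pass through
#' unchanged, so level-2 coverage of the outgroup never drops below level-1
#' coverage.
#'
#' @param blocks `synteny_blocks` computed with the ingroup as query and the
#'   outgroup as target (level-1 segments).
#' @param ingroup,outgroup the two [genome_annotation()] objects.
#' @param min_size minimum anchors for a merge seed (default 3).
#' @param adjacency_tol outgroup rank adjacency tolerance (default 5).
#' @return object of class `level2_blocks`: list with `blocks` (data.frame
#'   `l2_id`, `members`, `in_chrom`, `in_start`, `in_end`, `out_chrom`,
#'   `out_start`, `out_end`, `orientation`, `n_anchors`) and `anchors`
#'   (level-1 anchors relabelled with `l2_id`).
#' @export
merge_level2 <- function(blocks, ingroup, outgroup, min_size = 3L,
                         adjacency_tol = 5L) {
  b <- blocks$blocks
  if (nrow(b) == 0) {
    return(structure(list(
      blocks = data.frame(l2_id = character(), members = character(),
                          in_chrom = character(), in_start = integer(),
                          in_end = integer(), out_chrom = character(),
                          out_start = integer(), out_end = integer(),
                          orientation = character(), n_anchors = integer(),
                          stringsAsFactors = FALSE),
      anchors = blocks$anchors), class = "level2_blocks"))
  }
  compatible <- function(cur, nxt) {
    if (cur$out_chrom != nxt$t_chrom) return(FALSE)
    if (cur$orientation != nxt$orientation) return(FALSE)
    gap <- if (cur$orientation == "+") nxt$t_start - cur$out_end
           else cur$out_start - nxt$t_end
    abs(gap) <= adjacency_tol
  }
  groups <- list()
  for (chr in unique(b$q_chrom)) {
    bb <- b[b$q_chrom == chr, , drop = FALSE]
    bb <- bb[order(bb$q_start, bb$block_id), , drop = FALSE]
    cur <- NULL
    for (k in seq_len(nrow(bb))) {
      row <- bb[k, ]
      if (!is.null(cur) && compatible(cur, row) &&
          (cur$seed || row$n_anchors >= min_size)) {
        cur$members <- c(cur$members, row$block_id)
        cur$out_start <- min(cur$out_start, row$t_start)
        cur$out_end <- max(cur$out_end, row$t_end)
        cur$in_end <- max(cur$in_end, row$q_end)
        cur$n_anchors <- cur$n_anchors + row$n_anchors
        cur$seed <- cur$seed || row$n_anchors >= min_size
      } else {
        if (!is.null(cur)) groups[[length(groups) + 1]] <- cur
        cur <- list(members = row$block_id, in_chrom = chr,
                    in_start = row$q_start, in_end = row$q_end,
                    out_chrom = row$t_chrom, out_start = row$t_start,
                    out_end = row$t_end, orientation = row$orientation,
                    n_anchors = row$n_anchors,
                    seed = row$n_anchors >= min_size)
      }
    }
    if (!is.null(cur)) groups[[length(groups) + 1]] <- cur
  }
  l2 <- do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    data.frame(l2_id = sprintf("l2b%04d", i),
               members = paste(g$members, collapse = ","),
               in_chrom = g$in_chrom, in_start = g$in_start,
               in_end = g$in_end, out_chrom = g$out_chrom,
               out_start = g$out_start, out_end = g$out_end,
               orientation = g$orientation, n_anchors = g$n_anchors,
               stringsAsFactors = FALSE)
  }))
  member_of <- do.call(rbind, lapply(seq_along(groups), function(i) {
    data.frame(block_id = groups[[i]]$members,
               l2_id = sprintf("l2b%04d", i), stringsAsFactors = FALSE)
  }))
  anch <- blocks$anchors
  anch$l2_id <- member_of$l2_id[match(anch$block_id, member_of$block_id)]
  structure(list(blocks = l2, anchors = anch), class = "level2_blocks")
}

#' Partition the outgroup into homoeologous-set regions
#'
#' Splits the outgroup chromosomes into `n_regions` contiguous rank regions.
#' With an integer `n_regions`, the `n_regions - n_chrom` cuts are first
#' apportioned to chromosomes (each extra cut goes to the chromosome with
#' the largest current mean region size, so 16 regions on 8 equally sized
#' chromosomes means exactly one internal cut per chromosome); within a
#' chromosome, cuts land on the strongest level-2 block boundaries (boundary
#' strength = number of block ends falling within a `boundary_window`-rank
#' window; chosen cuts suppress further candidates within `boundary_window`
#' ranks; ties go to the leftmost position). If a chromosome lacks boundary
#' candidates, its cuts fall at the midpoints of the largest uncut
#' intervals. With `n_regions = "auto"`, cuts are placed wherever the set of
#' covering level-2 blocks changes and the new composition persists for at
#' least `boundary_window` ranks.
#'
#' @param outgroup the outgroup [genome_annotation()].
#' @param level2 a [merge_level2()] result.
#' @param n_regions integer total region count (>= chromosome number), or
#'   `"auto"`.
#' @param boundary_window rank window for boundary clustering (default 10).
#' @return data.frame `set_index`, `chrom`, `start`, `end` (inclusive rank
#'   intervals tiling every chromosome).
#' @export
define_regions <- function(outgroup, level2, n_regions = 16L,
                           boundary_window = 10L) {
  chroms <- outgroup$chromosomes
  lens <- vapply(chroms, function(ch) sum(outgroup$genes$chrom == ch), 0L)
  cuts <- stats::setNames(vector("list", length(chroms)), chroms)
  b <- level2$blocks
  if (identical(n_regions, "auto")) {
    for (ch in chroms) {
      bb <- b[b$out_chrom == ch, , drop = FALSE]
      sig <- character(lens[[ch]])
      for (k in seq_len(nrow(bb))) {
        idx <- (bb$out_start[k]:bb$out_end[k]) + 1L
        idx <- idx[idx >= 1 & idx <= lens[[ch]]]
        sig[idx] <- paste(sig[idx], bb$l2_id[k])
      }
      r <- rle(sig)
      pos <- cumsum(r$lengths)
      ok <- which(r$lengths[-length(r$lengths)] >= boundary_window &
                    r$lengths[-1] >= boundary_window)
      cuts[[ch]] <- pos[ok]
    }
  } else {
    n_regions <- as.integer(n_regions)
    if (n_regions < length(chroms)) {
      stop("n_regions must be at least the chromosome number")
    }
    # apportion cuts: each extra cut to the chromosome with the largest
    # current mean region size (ties by chromosome order)
    quota <- stats::setNames(integer(length(chroms)), chroms)
    for (i in seq_len(n_regions - length(chroms))) {
      mean_size <- lens / (quota + 1)
      pick <- chroms[order(-mean_size, seq_along(chroms))][1]
      quota[pick] <- quota[pick] + 1L
    }
    events <- data.frame(chrom = character(), pos = integer())
    if (nrow(b) > 0) {
      events <- rbind(data.frame(chrom = b$out_chrom, pos = b$out_start),
                      data.frame(chrom = b$out_chrom, pos = b$out_end + 1L))
      events <- events[events$pos >= 1 &
                         events$pos <= lens[events$chrom] - 1L, , drop = FALSE]
    }
    half <- boundary_window / 2
    for (ch in chroms) {
      cand <- sort(unique(events$pos[events$chrom == ch]))
      ev <- events$pos[events$chrom == ch]
      for (i in seq_len(quota[[ch]])) {
        if (length(cand) > 0) {
          strength <- vapply(cand, function(p) sum(abs(ev - p) <= half), 0)
          pick <- cand[order(-strength, cand)][1]
          cuts[[ch]] <- sort(c(cuts[[ch]], pick))
          cand <- cand[abs(cand - pick) > boundary_window]
        } else {
          # midpoint fallback: bisect the largest remaining interval
          edges <- c(0L, cuts[[ch]], lens[[ch]])
          sizes <- diff(edges)
          j <- which.max(sizes)
          if (sizes[j] < 2) stop("cannot place further region cuts")
          cuts[[ch]] <- sort(c(cuts[[ch]], edges[j] + sizes[j] %/% 2L))
        }
      }
    }
  }
  regions <- list()
  for (ch in chroms) {
    edges <- c(0L, sort(unique(cuts[[ch]])), lens[[ch]])
    for (j in seq_len(length(edges) - 1)) {
      regions[[length(regions) + 1]] <- data.frame(
        chrom = ch, start = edges[j], end = edges[j + 1] - 1L,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, regions)
  out$set_index <- seq_len(nrow(out))
  out[, c("set_index", "chrom", "start", "end")]
}

#' Assign level-2 blocks to three homoeolog slots per region
#'
#' Formalises "proximity and complementarity" as a deterministic greedy
#' interval 3-colouring. Blocks straddling a region cut are split at the cut
#' (anchors partitioned by outgroup rank). Within each region, pieces are
#' processed by outgroup start rank and placed in a slot where they overlap
#' no already-assigned outgroup span (complementarity); among feasible slots
#' the one already holding a piece from the same ingroup chromosome wins
#' (proximity), then the slot with the most uncovered region, then slot
#' order. If every slot conflicts, the minimum-overlap slot is used and the
#' conflict logged. Slot labels a/b/c are arbitrary per set: with
#' homoeologous blocks this homogeneous, true subgenome phasing is not
#' attempted, so recovery is only ever evaluated up to relabelling.
#'
#' @param level2 a [merge_level2()] result.
#' @param regions a [define_regions()] result.
#' @param ingroup the ingroup [genome_annotation()].
#' @return object of class `agb_sets`: list with `assignments` (one row per
#'   placed piece: `set_index`, `slot`, `piece_id`, `l2_id`, `out_chrom`,
#'   `out_start`, `out_end`, `in_chrom`, `in_start`, `in_end`,
#'   `orientation`, `n_anchors`, `order_index`, `flipped`), `anchors`
#'   (anchor table with `piece_id`, `set_index`, `slot`), `regions` and
#'   `conflicts`.
#' @export
assign_homoeologs <- function(level2, regions, ingroup) {
  anch <- level2$anchors
  b <- level2$blocks
  # split blocks at region cuts: each anchor belongs to exactly one region
  reg_of <- function(chrom, rank) {
    hit <- regions$set_index[regions$chrom == chrom &
                               regions$start <= rank & regions$end >= rank]
    if (length(hit) == 0) NA_integer_ else hit[1]
  }
  anch$set_index <- mapply(function(ch, r) reg_of(ch, r),
                           b$out_chrom[match(anch$l2_id, b$l2_id)], anch$t_rank)
  anch <- anch[!is.na(anch$set_index), , drop = FALSE]
  anch$piece_id <- paste0(anch$l2_id, "@", anch$set_index)
  pieces <- do.call(rbind, lapply(split(anch, anch$piece_id), function(a) {
    l2row <- b[b$l2_id == a$l2_id[1], ]
    data.frame(piece_id = a$piece_id[1], l2_id = a$l2_id[1],
               set_index = a$set_index[1],
               out_chrom = l2row$out_chrom,
               out_start = min(a$t_rank), out_end = max(a$t_rank),
               in_chrom = l2row$in_chrom,
               in_start = min(a$q_rank), in_end = max(a$q_rank),
               orientation = l2row$orientation, n_anchors = nrow(a),
               stringsAsFactors = FALSE)
  }))
  slots <- c("a", "b", "c")
  assignments <- list(); conflicts <- list()
  for (ri in regions$set_index) {
    pp <- pieces[pieces$set_index == ri, , drop = FALSE]
    if (nrow(pp) == 0) next
    pp <- pp[order(pp$out_start, -pp$n_anchors, pp$piece_id), , drop = FALSE]
    reg_len <- regions$end[regions$set_index == ri] -
      regions$start[regions$set_index == ri] + 1L
    chrom_ids <- unique(pp$in_chrom)
    state <- lapply(slots, function(s) list(
      iv = NULL, inq = matrix(0L, 0, 3), covered = 0L))
    names(state) <- slots
    for (k in seq_len(nrow(pp))) {
      piece <- pp[k, ]
      ov <- vapply(slots, function(s) {
        iv <- state[[s]]$iv
        if (is.null(iv)) return(0L)
        sum(pmax(0L, pmin(iv[, 2], piece$out_end) -
                   pmax(iv[, 1], piece$out_start) + 1L))
      }, 0L)
      # proximity: rank distance to the nearest already-assigned piece on the
      # same ingroup chromosome (neighbouring blocks of one chromosome almost
      # always descend from the same homoeolog)
      prox <- vapply(slots, function(s) {
        ivq <- state[[s]]$inq
        ivq <- ivq[ivq[, 3] == match(piece$in_chrom, chrom_ids), ,
                   drop = FALSE]
        if (nrow(ivq) == 0) return(Inf)
        min(pmax(0L, pmax(ivq[, 1] - piece$in_end, piece$in_start - ivq[, 2])))
      }, numeric(1))
      covered <- vapply(slots, function(s) state[[s]]$covered, 0L)
      feas <- which(ov == 0L)
      if (length(feas) > 0) {
        pick <- feas[order(prox[feas], covered[feas], feas)][1]
      } else {
        pick <- order(ov, prox, seq_along(slots))[1]
        conflicts[[length(conflicts) + 1]] <- data.frame(
          piece_id = piece$piece_id, set_index = ri, slot = slots[pick],
          overlap = ov[pick], stringsAsFactors = FALSE)
      }
      s <- slots[pick]
      state[[s]]$iv <- rbind(state[[s]]$iv, c(piece$out_start, piece$out_end))
      state[[s]]$inq <- rbind(state[[s]]$inq,
                              c(piece$in_start, piece$in_end,
                                match(piece$in_chrom, chrom_ids)))
      state[[s]]$covered <- state[[s]]$covered +
        (piece$out_end - piece$out_start + 1L)
      piece$slot <- s
      assignments[[length(assignments) + 1]] <- piece
    }
  }
  assignments <- do.call(rbind, assignments)
  rownames(assignments) <- NULL
  assignments$order_index <- NA_integer_
  assignments$flipped <- FALSE
  key <- match(anch$piece_id, assignments$piece_id)
  anch$slot <- assignments$slot[key]
  structure(list(assignments = assignments,
                 anchors = anch[, c("piece_id", "l2_id", "set_index", "slot",
                                    "gene_a", "gene_b", "q_rank", "t_rank")],
                 regions = regions,
                 conflicts = if (length(conflicts) > 0)
                   do.call(rbind, conflicts) else
                     data.frame(piece_id = character(), set_index = integer(),
                                slot = character(), overlap = integer())),
            class = "agb_sets")
}

#' Order and orient blocks within each homoeolog slot (level 4)
#'
#' Within every (set, slot), blocks are sorted by the median outgroup rank
#' of their anchors, and a block is flipped when more than half of its
#' consecutive anchor pairs (in ingroup order) run against the outgroup
#' direction — maximising collinearity of the reconstructed block order with
#' the outgroup chromosomes.
#'
#' @param agb_sets an [assign_homoeologs()] result.
#' @return the `agb_sets` with `order_index` and `flipped` filled in.
#' @export
order_level4 <- function(agb_sets) {
  a <- agb_sets$assignments
  anch <- agb_sets$anchors
  med <- tapply(anch$t_rank, anch$piece_id, stats::median)
  revfrac <- vapply(split(anch, anch$piece_id), function(x) {
    x <- x[order(x$q_rank), ]
    if (nrow(x) < 2) return(0)
    mean(diff(x$t_rank) < 0)
  }, numeric(1))
  a$flipped <- unname(revfrac[a$piece_id] > 0.5)
  a$median_out <- unname(med[a$piece_id])
  for (key in unique(paste(a$set_index, a$slot))) {
    idx <- which(paste(a$set_index, a$slot) == key)
    ord <- idx[order(a$median_out[idx], a$piece_id[idx])]
    a$order_index[ord] <- seq_along(ord)
  }
  agb_sets$assignments <- a
  agb_sets
}

#' Build the model ancestral genome from ordered homoeolog sets
#'
#' Concatenates, for every homoeologous set and slot, the ingroup genes of
#' its blocks in level-4 order into one pseudo-chromosome (named
#' `AGB<set>_<slot>`), giving `3 x n_sets` pseudo-chromosomes that
#' approximate the triplicated ancestor. Each ingroup gene inside a block's
#' ingroup span is placed once; genes covered by two pieces go to the piece
#' with more anchors.
#'
#' @param agb_sets an ordered [order_level4()] result.
#' @param ingroup the ingroup [genome_annotation()].
#' @return object of class `model_genome`: list with `annotation` (the model
#'   [genome_annotation()]), `provenance` (data.frame `gene_id`, `agb`,
#'   `set_index`, `slot`), `agb_chroms` (per-AGB gene totals including empty
#'   slots) and `slot_totals` (genes per slot a/b/c).
#' @export
build_model_genome <- function(agb_sets, ingroup) {
  a <- agb_sets$assignments
  if (any(is.na(a$order_index))) a <- order_level4(agb_sets)$assignments
  g <- ingroup$genes
  assigned_piece <- rep(NA_character_, nrow(g))
  a_prio <- a[order(-a$n_anchors, a$piece_id), , drop = FALSE]
  for (k in seq_len(nrow(a_prio))) {
    sel <- which(g$chrom == a_prio$in_chrom[k] &
                   g$rank >= a_prio$in_start[k] &
                   g$rank <= a_prio$in_end[k] &
                   is.na(assigned_piece))
    assigned_piece[sel] <- a_prio$piece_id[k]
  }
  sets <- sort(unique(agb_sets$regions$set_index))
  slots <- c("a", "b", "c")
  rows <- list(); chromtab <- list()
  for (s in sets) for (sl in slots) {
    agb <- sprintf("AGB%02d_%s", s, sl)
    pieces <- a[a$set_index == s & a$slot == sl, , drop = FALSE]
    pieces <- pieces[order(pieces$order_index), , drop = FALSE]
    content <- list()
    for (k in seq_len(nrow(pieces))) {
      gi <- which(assigned_piece == pieces$piece_id[k])
      gi <- gi[order(g$rank[gi])]
      if (pieces$flipped[k]) gi <- rev(gi)
      content[[k]] <- gi
    }
    gi <- unlist(content)
    chromtab[[agb]] <- data.frame(agb = agb, set_index = s, slot = sl,
                                  n_genes = length(gi),
                                  stringsAsFactors = FALSE)
    if (length(gi) == 0) {
      warning("empty homoeolog slot: ", agb)
      next
    }
    n <- length(gi)
    rows[[agb]] <- data.frame(
      gene_id = g$gene_id[gi], chrom = agb,
      start = (seq_len(n) - 1L) * 1000L,
      end = (seq_len(n) - 1L) * 1000L + 900L,
      strand = g$strand[gi], stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  annotation <- genome_annotation(genes, species = "model_ancestor")
  agb_chroms <- do.call(rbind, chromtab)
  rownames(agb_chroms) <- NULL
  prov <- data.frame(gene_id = genes$gene_id, agb = genes$chrom,
                     stringsAsFactors = FALSE)
  prov$set_index <- agb_chroms$set_index[match(prov$agb, agb_chroms$agb)]
  prov$slot <- agb_chroms$slot[match(prov$agb, agb_chroms$agb)]
  slot_totals <- vapply(slots, function(sl)
    sum(agb_chroms$n_genes[agb_chroms$slot == sl]), 0L)
  structure(list(annotation = annotation, provenance = prov,
                 agb_chroms = agb_chroms, slot_totals = slot_totals),
            class = "model_genome")
}

#' @export
print.model_genome <- function(x, ...) {
  cat(sprintf("model_genome: %d AGB pseudo-chromosomes, %d genes (slots: %s)\n",
              nrow(x$agb_chroms), nrow(x$provenance),
              paste(sprintf("%s=%d", names(x$slot_totals), x$slot_totals),
                    collapse = ", ")))
  invisible(x)
}

#' Map a genome onto the model ancestral genome
#'
#' Labels every query gene covered by a synteny block with the model AGB the
#' block points to (ties resolved by more anchors, then earlier block
#' start), and summarises the per-chromosome AGB composition and per-window
#' densities of mapped genes and AGB switch points.
#'
#' @param query the query [genome_annotation()].
#' @param blocks `synteny_blocks` computed with `query` as query and
#'   `model$annotation` as target.
#' @param model a [build_model_genome()] result.
#' @param window window size in genes for the density track (default 50).
#' @return list with `genes` (data.frame `gene_id`, `chrom`, `rank`, `agb`,
#'   `set_index`, `slot`; unmapped genes carry `NA`), `composition`
#'   (chromosome x AGB count matrix) and `windows` (per-window mapped
#'   fraction and AGB switch count).
#' @export
map_to_agbs <- function(query, blocks, model, window = 50L) {
  g <- query$genes
  lab <- rep(NA_character_, nrow(g))
  b <- blocks$blocks
  if (nrow(b) > 0) {
    b <- b[order(-b$n_anchors, b$q_start, b$block_id), , drop = FALSE]
    for (k in seq_len(nrow(b))) {
      sel <- which(g$chrom == b$q_chrom[k] & g$rank >= b$q_start[k] &
                     g$rank <= b$q_end[k] & is.na(lab))
      lab[sel] <- b$t_chrom[k]
    }
  }
  genes <- data.frame(gene_id = g$gene_id, chrom = g$chrom, rank = g$rank,
                      agb = lab, stringsAsFactors = FALSE)
  m <- match(genes$agb, model$agb_chroms$agb)
  genes$set_index <- model$agb_chroms$set_index[m]
  genes$slot <- model$agb_chroms$slot[m]
  mapped <- genes[!is.na(genes$agb), ]
  composition <- if (nrow(mapped) > 0) {
    tab <- table(mapped$chrom, mapped$agb)
    matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  } else matrix(0L, 0, 0)
  wins <- list()
  for (chr in query$chromosomes) {
    gg <- genes[genes$chrom == chr, ]
    gg <- gg[order(gg$rank), ]
    starts <- seq(0L, max(0L, nrow(gg) - 1L), by = window)
    for (s in starts) {
      idx <- which(gg$rank >= s & gg$rank < s + window)
      lb <- gg$agb[idx]
      switches <- sum(diff(as.integer(factor(lb[!is.na(lb)]))) != 0)
      wins[[length(wins) + 1]] <- data.frame(
        chrom = chr, start = s, n = length(idx),
        mapped_fraction = if (length(idx) > 0) mean(!is.na(lb)) else NA_real_,
        agb_switches = switches, stringsAsFactors = FALSE)
    }
  }
  list(genes = genes, composition = composition,
       windows = do.call(rbind, wins))
}
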