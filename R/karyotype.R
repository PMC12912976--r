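#' Paint a genome by synteny-block homology to a reference
#'
#' Orders the blocks of a descendant-vs-reference comparison along each
#' descendant chromosome, giving the mosaic "painting" in which each segment
#' carries the reference chromosome it descends from. Blocks with
#' overlapping query spans are resolved in favour of more anchors, then
#' earlier start (losers are dropped and counted). Unpainted stretches are
#' kept as null segments so downstream code can see coverage gaps and
#' chromosomes without any block.
#'
#' @param blocks `synteny_blocks` computed with `descendant` as query and
#'   the reference as target.
#' @param descendant the query-side [genome_annotation()].
#' @return object of class `block_painting`: data.frame with one row per
#'   segment (`chrom`, `seg_start`, `seg_end` in descendant ranks,
#'   `block_id`, `source` = reference chromosome or `NA` for null segments,
#'   `t_start`, `t_end`, `orientation`, `n_anchors`), ordered along each
#'   chromosome; attribute `n_dropped` counts overlap-resolved blocks.
#' @export
paint_genome <- function(blocks, descendant) {
  b <- blocks$blocks
  segs <- list()
  n_dropped <- 0L
  for (chr in descendant$chromosomes) {
    len <- sum(descendant$genes$chrom == chr)
    bb <- b[b$q_chrom == chr, , drop = FALSE]
    kept <- bb[0, ]
    if (nrow(bb) > 0) {
      bb <- bb[order(-bb$n_anchors, bb$q_start, bb$block_id), , drop = FALSE]
      for (k in seq_len(nrow(bb))) {
        clash <- nrow(kept) > 0 &&
          any(bb$q_start[k] <= kept$q_end & bb$q_end[k] >= kept$q_start)
        if (clash) n_dropped <- n_dropped + 1L else kept <- rbind(kept, bb[k, ])
      }
      kept <- kept[order(kept$q_start), , drop = FALSE]
    }
    pos <- 0L
    add <- function(s, e, row) {
      segs[[length(segs) + 1]] <<- data.frame(
        chrom = chr, seg_start = s, seg_end = e,
        block_id = if (is.null(row)) NA_character_ else row$block_id,
        source = if (is.null(row)) NA_character_ else row$t_chrom,
        t_start = if (is.null(row)) NA_integer_ else row$t_start,
        t_end = if (is.null(row)) NA_integer_ else row$t_end,
        orientation = if (is.null(row)) NA_character_ else row$orientation,
        n_anchors = if (is.null(row)) 0L else row$n_anchors,
        stringsAsFactors = FALSE)
    }
    if (nrow(kept) == 0) {
      add(0L, len - 1L, NULL)
    } else {
      for (k in seq_len(nrow(kept))) {
        if (kept$q_start[k] > pos) add(pos, kept$q_start[k] - 1L, NULL)
        add(kept$q_start[k], kept$q_end[k], kept[k, ])
        pos <- kept$q_end[k] + 1L
      }
      if (pos <= len - 1L) add(pos, len - 1L, NULL)
    }
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  if (n_dropped > 0) {
    message(n_dropped, " block(s) dropped while resolving overlapping query spans")
  }
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("block_painting", "data.frame")
  out
}

#' Count fission and fusion events from a block painting
#'
#' A fusion is an adjacency between two painted segments that cannot be a
#' continuation of the same reference chromosome: the sources differ, or the
#' reference rank intervals are discontinuous (gap or overlap beyond
#' `junction_tol` ranks). Orientation is ignored, so inversions contribute
#' no junctions. Fissions are then recovered from the chromosome-count
#' balance `S = F + C_d - ploidy * C_r` (floored at 0), where `C_d` is the
#' descendant chromosome count and `C_r` the number of reference chromosomes
#' represented. Segments shorter than `min_segment` genes and null segments
#' are removed before junction counting, and consecutive continuation
#' segments are merged, so fractionation-induced micro-segments do not
#' inflate the counts.
#'
#' The estimator is exact on loss-free histories of fissions and fusions
#' without breakpoint reuse; translocation junctions are counted as fusions
#' (a documented bias of junction counting).
#'
#' @param painting a [paint_genome()] result.
#' @param reference the target-side [genome_annotation()].
#' @param ploidy copy number of the descendant relative to the reference
#'   (default 3 for a triplicated descendant of a diploid reference).
#' @param min_segment minimum painted-segment length in genes (default 3).
#' @param junction_tol maximum reference-rank gap (or overlap) between
#'   consecutive segments still read as a continuation (default 20).
#' @param include_unpainted also count descendant chromosomes that carry
#'   genes but no painted segment in `C_d` (default `TRUE`); every
#'   chromosome of a triplication descendant traces back to the reference,
#'   so dropping unpainted ones (e.g. tiny fission products below the block
#'   evidence threshold) would bias the fission count downward.
#' @return list with `fissions`, `fusions`, `c_desc`, `c_ref` and
#'   `junctions` (data.frame of counted junctions with both segments'
#'   coordinates).
#' @export
count_fissions_fusions <- function(painting, reference, ploidy = 3L,
                                   min_segment = 3L, junction_tol = 20L,
                                   include_unpainted = TRUE) {
  if (ploidy < 1) stop("ploidy must be >= 1")
  p <- painting[!is.na(painting$source), , drop = FALSE]
  p <- p[p$seg_end - p$seg_start + 1L >= min_segment, , drop = FALSE]
  continuation <- function(s1, s2) {
    if (s1$source != s2$source) return(FALSE)
    gap <- max(s1$t_start, s2$t_start) - min(s1$t_end, s2$t_end)
    abs(gap) <= junction_tol
  }
  junctions <- list()
  fusions <- 0L
  for (chr in unique(p$chrom)) {
    pp <- p[p$chrom == chr, , drop = FALSE]
    pp <- pp[order(pp$seg_start), , drop = FALSE]
    if (nrow(pp) < 2) next
    cur <- pp[1, ]
    for (k in 2:nrow(pp)) {
      nxt <- pp[k, ]
      if (continuation(cur, nxt)) {
        # merge: extend the running segment's reference interval
        cur$t_start <- min(cur$t_start, nxt$t_start)
        cur$t_end <- max(cur$t_end, nxt$t_end)
        cur$seg_end <- nxt$seg_end
      } else {
        fusions <- fusions + 1L
        junctions[[length(junctions) + 1]] <- data.frame(
          chrom = chr, position = nxt$seg_start,
          source_left = cur$source, source_right = nxt$source,
          t_end_left = cur$t_end, t_start_right = nxt$t_start,
          stringsAsFactors = FALSE)
        cur <- nxt
      }
    }
  }
  painted_chroms <- unique(p$chrom)
  c_desc <- length(painted_chroms)
  if (include_unpainted) {
    c_desc <- length(unique(painting$chrom))
  }
  c_ref <- length(intersect(unique(p$source), reference$chromosomes))
  fissions <- max(0L, fusions + c_desc - as.integer(ploidy) * c_ref)
  list(fissions = as.integer(fissions), fusions = fusions,
       c_desc = c_desc, c_ref = c_ref,
       junctions = if (length(junctions) > 0) do.call(rbind, junctions) else
         data.frame(chrom = character(), position = integer(),
                    source_left = character(), source_right = character(),
                    t_end_left = integer(), t_start_right = integer()))
}
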