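#' Per-slot presence calls from simulation truth
#'
#' For every reference (outgroup) gene and homoeolog slot, whether the
#' species retains the corresponding subgenome copy. This is the
#' ground-truth presence mode used to validate the synteny-anchored mode.
#'
#' @param truth_genes the `truth$genes` table of a [simulate_clade()] run.
#' @param species species to call.
#' @param outgroup the outgroup [genome_annotation()] (reference).
#' @return logical matrix, reference genes x slots (`a`, `b`, `c`), rows in
#'   reference gene order.
#' @export
presence_from_truth <- function(truth_genes, species, outgroup) {
  tg <- truth_genes[truth_genes$species == species, ]
  anc_of_ref <- sub("^outgroup_", "", outgroup$genes$gene_id)
  m <- matrix(FALSE, nrow = n_genes(outgroup), ncol = 3,
              dimnames = list(outgroup$genes$gene_id, c("a", "b", "c")))
  for (s in c("a", "b", "c")) {
    present <- tg$ancestral_gene[tg$subgenome == s]
    m[anc_of_ref %in% present, s] <- TRUE
  }
  m
}

#' Per-slot presence calls from an AGB assignment
#'
#' A reference gene is called retained in a slot when at least one synteny
#' anchor of that slot's blocks lands on it — retention is synteny-anchored,
#' not homology-anchored, so a copy that moved out of its block does not
#' count.
#'
#' @param agb_sets an [assign_homoeologs()] result (anchors carry the
#'   reference gene in `gene_b` and the slot label).
#' @param outgroup the reference [genome_annotation()].
#' @return logical matrix, reference genes x slots.
#' @export
presence_from_agb <- function(agb_sets, outgroup) {
  anch <- agb_sets$anchors
  m <- matrix(FALSE, nrow = n_genes(outgroup), ncol = 3,
              dimnames = list(outgroup$genes$gene_id, c("a", "b", "c")))
  for (s in c("a", "b", "c")) {
    m[rownames(m) %in% anch$gene_b[anch$slot == s], s] <- TRUE
  }
  m
}

#' Gene retention in sliding windows along the reference
#'
#' Retention of each homoeolog slot in sliding `window`-gene windows (step
#' `step`) along the reference chromosomes; combined retention is the
#' per-window sum over the three slots, bounded by 300%. A final partial
#' window is kept when it holds at least `step` genes.
#'
#' @param reference the reference [genome_annotation()].
#' @param presence logical matrix from [presence_from_truth()] or
#'   [presence_from_agb()] (rows in reference gene order).
#' @param window window size in genes (default 100).
#' @param step step in genes (default 50).
#' @return object of class `retention_profile`: list with `windows`
#'   (data.frame `chrom`, `start`, `size`), `retention` (windows x slots
#'   matrix of fractions) and `combined` (per-window sums).
#' @export
retention_windows <- function(reference, presence, window = 100L, step = 50L) {
  if (window < 2) stop("window must be at least 2 genes")
  stopifnot(nrow(presence) == n_genes(reference))
  g <- reference$genes
  wins <- list(); ret <- list()
  for (chr in reference$chromosomes) {
    idx <- which(g$chrom == chr)
    idx <- idx[order(g$rank[idx])]
    len <- length(idx)
    starts <- integer(0)
    s <- 0L
    while (s + window <= len) { starts <- c(starts, s); s <- s + step }
    if (len - s >= step && len > 0 && (length(starts) == 0 || s > 0)) {
      starts <- c(starts, s)  # final partial window with >= step genes
    }
    for (s in starts) {
      rows <- idx[(s + 1):min(len, s + window)]
      wins[[length(wins) + 1]] <- data.frame(chrom = chr, start = s,
                                             size = length(rows))
      ret[[length(ret) + 1]] <- colMeans(presence[rows, , drop = FALSE])
    }
  }
  retention <- do.call(rbind, ret)
  structure(list(windows = do.call(rbind, wins), retention = retention,
                 combined = rowSums(retention)),
            class = "retention_profile")
}

#' Reciprocity of fractionation between homoeolog slots
#'
#' Pearson correlations, across windows, of the per-window retention
#' deviations (retention minus the slot mean) for every slot pair. Negative
#' mean correlation indicates reciprocal fractionation: windows where one
#' homoeolog kept more genes tend to have lost more from the other two.
#'
#' @param profile a [retention_windows()] result (>= 10 windows).
#' @return list with `pairwise` (named vector, e.g. `a:b`) and
#'   `mean_correlation`; zero-variance slots give `NA` for their pairs.
#' @export
reciprocity <- function(profile) {
  r <- profile$retention
  if (nrow(r) < 10) stop("need at least 10 windows")
  dev <- sweep(r, 2, colMeans(r))
  slots <- colnames(r)
  pairs <- utils::combn(slots, 2)
  cors <- apply(pairs, 2, function(p) {
    x <- dev[, p[1]]; y <- dev[, p[2]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  })
  names(cors) <- apply(pairs, 2, paste, collapse = ":")
  list(pairwise = cors, mean_correlation = mean(cors, na.rm = TRUE))
}

#' Write a retention profile as TSV
#' @param profile a [retention_windows()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_retention <- function(profile, path) {
  df <- cbind(profile$windows, round(profile$retention, 6),
              combined = round(profile$combined, 6))
  write_tsv(df, path)
}
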