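#' Multispecies copy matrix
#'
#' Binary presence of each reference gene's three homoeologous copies in
#' every species, the substrate for calling retained triplicated genes.
#'
#' @param presence_list named list (by species) of logical matrices from
#'   [presence_from_truth()] or [presence_from_agb()] (reference genes x
#'   slots a/b/c, identical row order).
#' @param reference the reference [genome_annotation()].
#' @return object of class `copy_matrix`: list with `matrix` (genes x
#'   (species, slot) 0/1 integer matrix, columns named `species.slot`),
#'   `species` and `slots`.
#' @export
build_copy_matrix <- function(presence_list, reference) {
  slots <- c("a", "b", "c")
  cols <- list()
  for (sp in names(presence_list)) {
    p <- presence_list[[sp]]
    stopifnot(nrow(p) == n_genes(reference))
    missing <- setdiff(slots, colnames(p))
    if (length(missing) > 0) {
      warning("species ", sp, " missing slot(s) ",
              paste(missing, collapse = ","), "; filled with 0")
      for (s in missing) p <- cbind(p, stats::setNames(rep(FALSE, nrow(p)), s))
    }
    for (s in slots) cols[[paste(sp, s, sep = ".")]] <- as.integer(p[, s])
  }
  m <- do.call(cbind, cols)
  rownames(m) <- reference$genes$gene_id
  structure(list(matrix = m, species = names(presence_list), slots = slots),
            class = "copy_matrix")
}

#' Call retained triplicated genes (RTGs)
#'
#' A reference gene is an RTG when, for each of the three homoeolog slots,
#' the fraction of species retaining that copy is at least
#' `species_fraction` — i.e. all three triplication-derived paralogs are
#' consistently retained across the clade, with a bounded allowance for
#' copies missing in a few species.
#'
#' @param copy_matrix a [build_copy_matrix()] result (>= 2 species).
#' @param species_fraction per-slot species-presence threshold in (0, 1]
#'   (default 0.8).
#' @return data.frame of class `rtg_calls`: `gene_id`, `frac_a`, `frac_b`,
#'   `frac_c`, `rtg`, `mean_copies` (mean per-species copy count).
#' @export
call_rtgs <- function(copy_matrix, species_fraction = 0.8) {
  if (species_fraction <= 0 || species_fraction > 1) {
    stop("species_fraction must be in (0, 1]")
  }
  if (length(copy_matrix$species) < 2) stop("need at least 2 species")
  m <- copy_matrix$matrix
  fr <- vapply(copy_matrix$slots, function(s) {
    rowMeans(m[, grep(paste0("\\.", s, "$"), colnames(m)), drop = FALSE])
  }, numeric(nrow(m)))
  out <- data.frame(gene_id = rownames(m),
                    frac_a = fr[, "a"], frac_b = fr[, "b"], frac_c = fr[, "c"],
                    rtg = fr[, "a"] >= species_fraction &
                      fr[, "b"] >= species_fraction &
                      fr[, "c"] >= species_fraction,
                    mean_copies = rowSums(m) / length(copy_matrix$species),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("rtg_calls", "data.frame")
  out
}

#' RTG density and hotspot windows on a genome
#'
#' Counts members of a gene set in consecutive `window`-gene windows along
#' each chromosome and flags hotspots: windows whose count lies above the
#' 95th percentile of a permutation null in which the set labels are
#' shuffled over all genes. The strict `>` rule makes the test conservative
#' when window counts are small and discrete.
#'
#' @param gene_set character vector of gene ids (e.g. RTG paleoparalogs
#'   placed on the model genome).
#' @param genome the [genome_annotation()] to scan (e.g. the model genome's
#'   annotation).
#' @param window window size in genes (default 50).
#' @param nperm label permutations for the null (default 1000).
#' @param seed RNG seed.
#' @param quantile null quantile for flagging (default 0.95).
#' @return data.frame `chrom`, `start`, `n`, `count`, `hotspot`; attribute
#'   `threshold` holds the null cutoff.
#' @export
rtg_hotspots <- function(gene_set, genome, window = 50L, nperm = 1000L,
                         seed = 1L, quantile = 0.95) {
  g <- genome$genes[order(genome$genes$chrom, genome$genes$rank), ]
  is_in <- g$gene_id %in% gene_set
  wid <- factor(paste(g$chrom, g$rank %/% window), )
  wid <- factor(wid, levels = unique(as.character(wid)))
  n_win <- nlevels(wid)
  count_by_window <- function(flags) {
    as.integer(rowsum(as.integer(flags), wid, reorder = FALSE))
  }
  obs <- count_by_window(is_in)
  set.seed(seed)
  null_counts <- unlist(lapply(seq_len(nperm), function(i) {
    count_by_window(sample(is_in))
  }))
  threshold <- stats::quantile(null_counts, quantile, names = FALSE, type = 1)
  first <- match(levels(wid), as.character(wid))
  out <- data.frame(chrom = g$chrom[first],
                    start = (g$rank[first] %/% window) * window,
                    n = as.integer(tabulate(wid, n_win)),
                    count = obs,
                    hotspot = obs > threshold,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  out
}

#' Label over-representation in a gene set (Fisher exact)
#'
#' Two-sided Fisher exact test per label on the 2x2 table (in/out of the
#' gene set x has/lacks the label) over a background gene universe, with
#' Benjamini-Hochberg correction across labels. Odds ratios are the sample
#' cross-product ratios.
#'
#' @param gene_set genes of interest (must be contained in `background`).
#' @param annotation data.frame `gene_id`, `label` (one row per assignment).
#' @param background character vector, the gene universe.
#' @return data.frame `label`, `n_set`, `n_background`, `odds_ratio`,
#'   `p_value`, `q_value`, sorted by p-value.
#' @export
overrepresentation <- function(gene_set, annotation, background) {
  if (length(background) == 0) stop("empty background")
  out_of_bg <- setdiff(gene_set, background)
  if (length(out_of_bg) > 0) stop("gene_set not contained in background")
  all_labels <- unique(annotation$label)
  annotation <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  labels <- sort(unique(annotation$label))
  dropped <- setdiff(all_labels, labels)
  if (length(dropped) > 0) {
    warning(length(dropped), " label(s) absent from the background skipped")
  }
  if (length(labels) == 0) {
    warning("no annotation labels present in the background")
    return(data.frame(label = character(), n_set = integer(),
                      n_background = integer(), odds_ratio = numeric(),
                      p_value = numeric(), q_value = numeric()))
  }
  n_set <- length(gene_set)
  n_bg <- length(background)
  res <- do.call(rbind, lapply(labels, function(lb) {
    lab_genes <- unique(annotation$gene_id[annotation$label == lb])
    a <- length(intersect(gene_set, lab_genes))
    b <- n_set - a
    c2 <- length(lab_genes) - a
    d <- n_bg - n_set - c2
    or <- (a * d) / (b * c2)
    p <- stats::fisher.test(matrix(c(a, b, c2, d), 2, byrow = TRUE),
                            alternative = "two.sided")$p.value
    data.frame(label = lb, n_set = a, n_background = length(lab_genes),
               odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
  }))
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$label), ]
  rownames(res) <- NULL
  res
}

#' Tissue-specificity index tau
#'
#' `tau = sum(1 - x_i / max(x)) / (n - 1)`: 0 for perfectly uniform
#' expression, 1 for single-tissue expression; scale-invariant.
#'
#' @param x nonnegative expression vector over >= 2 tissues.
#' @return tau in `[0, 1]`, or `NA` for an all-zero vector.
#' @export
tau <- function(x) {
  if (length(x) < 2) stop("tau needs at least 2 tissues")
  if (any(x < 0)) stop("expression values must be nonnegative")
  mx <- max(x)
  if (mx == 0) return(NA_real_)
  sum(1 - x / mx) / (length(x) - 1)
}

#' Contrast expression specificity between gene groups
#'
#' Computes tau for each gene of two groups from a genes x tissues matrix
#' and compares the distributions with a two-sided Mann-Whitney test; also
#' returns per-gene z-scored expression for heatmap display.
#'
#' @param group1,group2 gene id vectors (e.g. RTG paleoparalogs vs
#'   single-copy genes); must be rows of `expression`.
#' @param expression numeric matrix, genes x tissues (TPM-like).
#' @return list with `tau1`, `tau2` (named numeric), `statistic`, `p_value`,
#'   and `zscores` (row-wise z-scored expression of both groups).
#' @export
tau_contrast <- function(group1, group2, expression) {
  if (ncol(expression) < 2) stop("need at least 2 tissues")
  g1 <- intersect(group1, rownames(expression))
  g2 <- intersect(group2, rownames(expression))
  if (length(g1) == 0 || length(g2) == 0) stop("empty gene group")
  tau1 <- apply(expression[g1, , drop = FALSE], 1, tau)
  tau2 <- apply(expression[g2, , drop = FALSE], 1, tau)
  wt <- stats::wilcox.test(tau1, tau2, alternative = "two.sided", exact = FALSE)
  zs <- t(apply(expression[c(g1, g2), , drop = FALSE], 1, function(x) {
    s <- stats::sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
  colnames(zs) <- colnames(expression)
  list(tau1 = tau1, tau2 = tau2,
       statistic = unname(wt$statistic), p_value = wt$p.value,
       zscores = zs)
}
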