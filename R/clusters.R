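#' Species lookup for multi-species gene sets
#'
#' @param annotations list of [genome_annotation()] objects.
#' @return named character vector, gene id -> species.
#' @export
species_map <- function(annotations) {
  out <- unlist(lapply(annotations, function(a) {
    stats::setNames(rep(a$species, n_genes(a)), a$genes$gene_id)
  }))
  names(out) <- sub("^[^.]*\\.", "", names(out))
  out
}

#' Microsynteny clusters from syntenic gene pairs
#'
#' Clusters are the connected components of the gene graph whose edges are
#' syntenic pairs (pooled over all genome pairs). Components spanning fewer
#' than `min_species` species are dropped.
#'
#' @param pairs `anchor_pairs` pooled across genome pairs (e.g. the union of
#'   [syntenic_gene_pairs()] outputs).
#' @param species named character vector, gene id -> species (see
#'   [species_map()]).
#' @param min_species minimum number of species a retained cluster must span
#'   (default 2).
#' @return object of class `synteny_clusters`: list with `members`
#'   (data.frame `cluster_id`, `species`, `gene_id`) and `copy_number`
#'   (species x cluster integer matrix).
#' @export
build_clusters <- function(pairs, species, min_species = 2L) {
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  unknown <- genes[!genes %in% names(species)]
  if (length(unknown) > 0) {
    stop("genes without a species assignment: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (length(genes) == 0) {
    return(structure(list(
      members = data.frame(cluster_id = character(), species = character(),
                           gene_id = character(), stringsAsFactors = FALSE),
      copy_number = matrix(0L, 0, 0)), class = "synteny_clusters"))
  }
  g <- igraph::graph_from_data_frame(pairs[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = genes))
  comp <- igraph::components(g)
  memb <- data.frame(gene_id = names(comp$membership),
                     comp = unname(comp$membership),
                     stringsAsFactors = FALSE)
  memb$species <- unname(species[memb$gene_id])
  nsp <- tapply(memb$species, memb$comp, function(s) length(unique(s)))
  keep <- as.integer(names(nsp)[nsp >= min_species])
  memb <- memb[memb$comp %in% keep, , drop = FALSE]
  # stable ids: order components by their smallest member gene id
  first_gene <- tapply(memb$gene_id, memb$comp, min)
  relabel <- stats::setNames(seq_along(first_gene),
                             names(first_gene)[order(first_gene)])
  memb$cluster_id <- sprintf("cl%05d", relabel[as.character(memb$comp)])
  memb <- memb[order(memb$cluster_id, memb$species, memb$gene_id),
               c("cluster_id", "species", "gene_id")]
  rownames(memb) <- NULL
  cn <- table(memb$species, memb$cluster_id)
  copy_number <- matrix(as.integer(cn), nrow = nrow(cn),
                        dimnames = dimnames(cn))
  structure(list(members = memb, copy_number = copy_number),
            class = "synteny_clusters")
}

#' @export
print.synteny_clusters <- function(x, ...) {
  cat(sprintf("synteny_clusters: %d cluster(s), %d gene(s), %d species\n",
              ncol(x$copy_number), nrow(x$members), nrow(x$copy_number)))
  invisible(x)
}

#' Phylogenomic copy-number profile
#'
#' Copy-number matrix (species x clusters) with columns ordered by
#' average-linkage hierarchical clustering on Euclidean distance between
#' copy-number columns, so clusters with similar phylogenetic distribution
#' sit together (heatmap-ready).
#'
#' @param clusters a [build_clusters()] result.
#' @param species_order row order (default: rows of the copy-number matrix).
#' @return list with `matrix` (reordered copy-number matrix) and
#'   `column_order` (cluster ids in leaf order).
#' @export
phylogenomic_profile <- function(clusters, species_order = rownames(clusters$copy_number)) {
  cn <- clusters$copy_number
  if (ncol(cn) == 0) stop("no clusters to profile")
  missing_sp <- setdiff(species_order, rownames(cn))
  if (length(missing_sp) > 0) {
    add <- matrix(0L, length(missing_sp), ncol(cn),
                  dimnames = list(missing_sp, colnames(cn)))
    cn <- rbind(cn, add)
  }
  cn <- cn[species_order, , drop = FALSE]
  cn <- cn[, order(colnames(cn)), drop = FALSE]  # deterministic input order
  if (ncol(cn) == 1) {
    return(list(matrix = cn, column_order = colnames(cn)))
  }
  hc <- stats::hclust(stats::dist(t(cn), method = "euclidean"),
                      method = "average")
  ord <- colnames(cn)[hc$order]
  list(matrix = cn[, ord, drop = FALSE], column_order = ord)
}

#' Clade-sharing summaries of clusters
#'
#' Counts, for every observed clade combination, the clusters whose members
#' span exactly that set of clades; also reports clusters spanning all
#' clades (`conserved`) and clusters confined to one clade
#' (`lineage_specific`).
#'
#' @param clusters a [build_clusters()] result.
#' @param clades named character vector, species -> clade.
#' @return list with `combinations` (data.frame `clades`, `n`), `conserved`
#'   (count) and `lineage_specific` (named integer vector by clade).
#' @export
shared_cluster_counts <- function(clusters, clades) {
  m <- clusters$members
  unknown <- setdiff(unique(m$species), names(clades))
  if (length(unknown) > 0) {
    stop("species without a clade assignment: ", paste(unknown, collapse = ", "))
  }
  all_clades <- sort(unique(clades))
  if (nrow(m) == 0) {
    return(list(combinations = data.frame(clades = character(), n = integer()),
                conserved = 0L,
                lineage_specific = stats::setNames(integer(length(all_clades)),
                                                   all_clades)))
  }
  combo <- tapply(clades[m$species], m$cluster_id,
                  function(x) paste(sort(unique(x)), collapse = "+"))
  tab <- table(combo)
  combinations <- data.frame(clades = names(tab), n = as.integer(tab),
                             stringsAsFactors = FALSE)
  conserved <- sum(combo == paste(all_clades, collapse = "+"))
  ls <- vapply(all_clades, function(cl) sum(combo == cl), integer(1))
  list(combinations = combinations, conserved = as.integer(conserved),
       lineage_specific = ls)
}
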