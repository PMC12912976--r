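#' Gene-order genome annotations
#'
#' A `genome_annotation` holds the gene models of one species as an ordered
#' gene table. All downstream computation in this package runs on gene-*rank*
#' coordinates (0-based index of a gene along its chromosome, ordered by
#' start position); base-pair coordinates are carried along but never used by
#' any algorithm. Coordinates are stored 0-based half-open regardless of the
#' input dialect (BED is native; GFF3 is shifted on load).
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (0-based half-open coordinates).
#' @param species species identifier.
#' @return object of class `genome_annotation`: a list with `species`,
#'   `chromosomes` (ordered chromosome ids) and `genes` (data.frame with an
#'   added dense 0-based `rank` column per chromosome).
#' @details Ranks are assigned by sorting on `(chrom, start, end, gene_id)`;
#'   the `(end, gene_id)` keys only break exact start ties, so rank order
#'   always agrees with start order. Duplicate gene ids are rejected.
#' @export
genome_annotation <- function(genes, species) {
  stopifnot(is.data.frame(genes))
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss) > 0) {
    stop("annotation is missing columns: ", paste(miss, collapse = ", "))
  }
  genes <- genes[, need, drop = FALSE]
  genes$gene_id <- as.character(genes$gene_id)
  genes$chrom <- as.character(genes$chrom)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- as.character(genes$strand)
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  if (anyDuplicated(genes$gene_id)) {
    dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
    stop("duplicate gene_id in annotation: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  if (any(genes$start >= genes$end)) {
    bad <- genes$gene_id[genes$start >= genes$end]
    stop("empty or inverted interval (start >= end) for gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  ord <- order(genes$chrom, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  genes$rank <- stats::ave(seq_len(nrow(genes)), genes$chrom,
                           FUN = function(i) seq_along(i) - 1L)
  genes$rank <- as.integer(genes$rank)
  structure(
    list(species = as.character(species),
         chromosomes = unique(genes$chrom),
         genes = genes),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation '%s': %d genes on %d chromosome(s)\n",
              x$species, nrow(x$genes), length(x$chromosomes)))
  invisible(x)
}

#' Number of genes in an annotation
#' @param annotation a `genome_annotation`.
#' @return integer gene count.
#' @export
n_genes <- function(annotation) nrow(annotation$genes)

# rank lookup: named integer vector gene_id -> rank (internal)
rank_of <- function(annotation) {
  stats::setNames(annotation$genes$rank, annotation$genes$gene_id)
}

chrom_of <- function(annotation) {
  stats::setNames(annotation$genes$chrom, annotation$genes$gene_id)
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 file (via rtracklayer), keeps features of one type and
#' orders them into gene ranks. GFF3 1-based closed coordinates are converted
#' to 0-based half-open.
#'
#' @param path GFF3 file.
#' @param species species identifier (default: file base name).
#' @param feature_type feature type to keep (default `"gene"`); which feature
#'   level (gene vs mRNA) best represents loci differs between annotation
#'   projects, so this is a knob rather than a constant.
#' @param id_attr attribute holding the gene identifier (default `"ID"`).
#' @return a [genome_annotation()].
#' @export
read_gff3 <- function(path, species = sub("\\.gff3?$", "", basename(path)),
                      feature_type = "gene", id_attr = "ID") {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df <- df[as.character(df$type) == feature_type, , drop = FALSE]
  if (nrow(df) == 0) {
    return(genome_annotation(
      data.frame(gene_id = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character()),
      species))
  }
  if (!id_attr %in% names(df)) {
    stop("GFF3 attribute '", id_attr, "' not present in ", path)
  }
  ids <- as.character(df[[id_attr]])
  if (anyNA(ids)) stop("missing '", id_attr, "' attribute on some ", feature_type, " features")
  genome_annotation(
    data.frame(gene_id = ids,
               chrom = as.character(df$seqnames),
               start = df$start - 1L,   # to 0-based half-open
               end = df$end,
               strand = as.character(df$strand),
               stringsAsFactors = FALSE),
    species)
}

#' Read gene models from BED
#'
#' 4+ column BED (chrom, start, end, name, [score, strand]); BED is 0-based
#' half-open, which is the package's native convention. Missing strand
#' defaults to `"+"`. Empty intervals (start >= end) are rejected.
#'
#' @param path BED file.
#' @param species species identifier (default: file base name).
#' @return a [genome_annotation()].
#' @export
read_bed <- function(path, species = sub("\\.bed$", "", basename(path))) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  content <- readLines(path)
  content <- content[!grepl("^#", content) & nzchar(trimws(content))]
  raw <- if (length(content) == 0) data.frame() else
    utils::read.table(text = content, sep = "\t", header = FALSE,
                      quote = "", fill = TRUE, stringsAsFactors = FALSE,
                      colClasses = "character")
  if (nrow(raw) == 0 || ncol(raw) < 4) {
    if (nrow(raw) == 0) {
      return(genome_annotation(
        data.frame(gene_id = character(), chrom = character(),
                   start = integer(), end = integer(), strand = character()),
        species))
    }
    stop("BED file needs >= 4 columns: ", path)
  }
  start <- suppressWarnings(as.integer(raw[[2]]))
  end <- suppressWarnings(as.integer(raw[[3]]))
  if (anyNA(start) || anyNA(end)) stop("non-integer BED coordinates in ", path)
  strand <- if (ncol(raw) >= 6) raw[[6]] else rep("+", nrow(raw))
  genome_annotation(
    data.frame(gene_id = raw[[4]], chrom = raw[[1]],
               start = start, end = end, strand = strand,
               stringsAsFactors = FALSE),
    species)
}

#' Write an annotation as BED6
#'
#' @param annotation a [genome_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(annotation, path) {
  g <- annotation$genes
  df <- data.frame(g$chrom, g$start, g$end, g$gene_id, 0L, g$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read homology anchor pairs
#'
#' TSV with columns `gene_a<TAB>gene_b[<TAB>score]`. Anchors whose genes are
#' absent from the query or target annotation are dropped with a warning
#' stating the count.
#'
#' @param path TSV file (lines starting with `#` are ignored).
#' @param query,target `genome_annotation` objects for the two genomes;
#'   `gene_a` must belong to `query`, `gene_b` to `target`.
#' @return data.frame of class `anchor_pairs` with columns `gene_a`,
#'   `gene_b`, `score` (score defaults to 1).
#' @export
read_anchors <- function(path, query, target) {
  if (!file.exists(path)) stop("anchor file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(anchor_pairs(character(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2)) {
    stop("anchor TSV needs >= 2 columns (line ",
         which(nf < 2)[1], " of ", path, ")")
  }
  score <- vapply(fields, function(f)
    if (length(f) >= 3) suppressWarnings(as.numeric(f[3])) else 1, numeric(1))
  score[is.na(score)] <- 1
  an <- anchor_pairs(vapply(fields, `[`, "", 1),
                     vapply(fields, `[`, "", 2), score)
  keep <- an$gene_a %in% query$genes$gene_id & an$gene_b %in% target$genes$gene_id
  if (any(!keep)) {
    warning(sum(!keep), " anchor(s) referenced unknown genes and were dropped")
  }
  an[keep, , drop = FALSE]
}

#' Construct anchor pairs
#'
#' @param gene_a,gene_b gene identifiers in the query and target genome.
#' @param score nonnegative anchor scores (default 1).
#' @return data.frame of class `anchor_pairs`.
#' @export
anchor_pairs <- function(gene_a, gene_b, score = rep(1, length(gene_a))) {
  stopifnot(length(gene_a) == length(gene_b))
  if (any(score < 0)) stop("anchor scores must be nonnegative")
  df <- data.frame(gene_a = as.character(gene_a),
                   gene_b = as.character(gene_b),
                   score = as.numeric(score),
                   stringsAsFactors = FALSE)
  class(df) <- c("anchor_pairs", "data.frame")
  df
}

#' Write anchor pairs as TSV
#' @param anchors an `anchor_pairs` data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_anchors <- function(anchors, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#gene_a\tgene_b\tscore", con)
  utils::write.table(anchors[, c("gene_a", "gene_b", "score")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# write a data.frame as TSV with a '#'-prefixed header line (internal)
write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

read_tsv <- function(path, col_names = NULL) {
  hdr <- readLines(path, n = 1)
  nm <- strsplit(sub("^#", "", hdr), "\t")[[1]]
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          quote = "", stringsAsFactors = FALSE)
  names(df) <- nm
  df
}
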