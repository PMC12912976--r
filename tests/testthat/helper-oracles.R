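# Independent brute-force oracles used to validate the package's algorithms.

# All chains a set of anchors admits: a subset of anchors is a valid chain if,
# sorted by query rank, it is strictly monotone in both genomes (one
# orientation) with consecutive rank gaps <= gap_size on both sides.
is_valid_chain <- function(qr, tr, gap_size) {
  o <- order(qr)
  qr <- qr[o]; tr <- tr[o]
  if (any(diff(qr) < 1) || any(diff(qr) > gap_size)) return(FALSE)
  dt <- diff(tr)
  (all(dt >= 1) && all(dt <= gap_size)) ||
    (all(dt <= -1) && all(dt >= -gap_size))
}

# maximum total number of anchors coverable by disjoint valid chains of size
# >= block_size; chains may share neither an anchor nor a query gene
# (tandem-duplicate constraint). Exhaustive over all subsets (n <= 12).
oracle_chain_max <- function(anchors, block_size = 5, gap_size = 5) {
  n <- nrow(anchors)
  if (n == 0) return(0L)
  chains <- list()
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < block_size) next
    if (anyDuplicated(anchors$qgene[idx])) next
    if (is_valid_chain(anchors$qr[idx], anchors$tr[idx], gap_size)) {
      chains[[length(chains) + 1]] <- idx
    }
  }
  if (length(chains) == 0) return(0L)
  best <- 0L
  pick <- function(i, used_anchor, used_gene, total) {
    if (total > best) best <<- total
    if (i > length(chains)) return()
    # bound: remaining chains can add at most their total size
    pick(i + 1, used_anchor, used_gene, total)
    ch <- chains[[i]]
    if (!any(ch %in% used_anchor) &&
        !any(anchors$qgene[ch] %in% used_gene)) {
      pick(i + 1, c(used_anchor, ch),
           c(used_gene, anchors$qgene[ch]), total + length(ch))
    }
  }
  pick(1L, integer(0), character(0), 0L)
  best
}

# random chaining instance between two 15-gene chromosomes; anchors are
# (rank, rank) pairs, so tandem duplicates arise naturally when one query
# gene anchors two target positions. Mixes diffuse anchors with a planted
# collinear run so nontrivial optima occur.
random_chain_instance <- function(seed) {
  set.seed(seed)
  n <- sample(4:12, 1)
  qr <- sample(0:14, n, replace = TRUE)
  tr <- sample(0:14, n, replace = TRUE)
  if (sample(c(TRUE, FALSE), 1)) {
    k <- min(n, sample(4:8, 1))
    s <- sample(0:5, 1)
    qr[seq_len(k)] <- s + seq_len(k) - 1
    tr[seq_len(k)] <- s + seq_len(k) - 1 + sample(c(0, 0, 1), k, replace = TRUE)
    tr <- pmin(tr, 14L)
  }
  df <- unique(data.frame(qr = qr, tr = tr))
  df$qgene <- sprintf("q%02d", df$qr)
  df$tgene <- sprintf("t%02d", df$tr)
  df
}

rank_annotation <- function(prefix, n = 15L, species = prefix) {
  genome_annotation(data.frame(
    gene_id = sprintf("%s%02d", prefix, 0:(n - 1)), chrom = paste0(prefix, "chr"),
    start = (0:(n - 1)) * 100L, end = (0:(n - 1)) * 100L + 50L,
    strand = "+"), species)
}

# run chain_anchors on an instance data.frame (qr, tr, qgene, tgene)
chain_instance <- function(df, params = chain_params()) {
  qann <- rank_annotation("q")
  tann <- rank_annotation("t")
  list(blocks = chain_anchors(anchor_pairs(df$qgene, df$tgene), qann, tann,
                              params),
       query = qann, target = tann)
}

# hand-rolled breadth-first connected components (oracle for build_clusters)
bfs_components <- function(vertices, edges) {
  adj <- lapply(stats::setNames(vector("list", length(vertices)), vertices),
                function(x) character(0))
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- stats::setNames(rep(NA_integer_, length(vertices)), vertices)
  k <- 0L
  for (v in vertices) {
    if (!is.na(comp[[v]])) next
    k <- k + 1L
    queue <- v
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[[u]])) next
      comp[[u]] <- k
      queue <- c(queue, adj[[u]][is.na(comp[adj[[u]]])])
    }
  }
  comp
}

# independent NG86 oracle: explicit recursion over substitution orderings,
# sites counted by looping over all nine single-nucleotide mutations
oracle_ng86 <- function(seq_a, seq_b) {
  gc <- Biostrings::GENETIC_CODE
  codons <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- codons(seq_a); cb <- codons(seq_b)
  site_s <- function(codon) {
    aa <- gc[[codon]]
    syn <- 0
    for (pos in 1:3) for (nt in c("A", "C", "G", "T")) {
      if (nt == substr(codon, pos, pos)) next
      mut <- codon; substr(mut, pos, pos) <- nt
      if (gc[[mut]] == aa && gc[[mut]] != "*") syn <- syn + 1
    }
    syn / 3
  }
  paths <- function(c1, c2) {
    if (c1 == c2) return(list(list(syn = 0, nsyn = 0, stop = FALSE)))
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    out <- list()
    for (p in pos) {
      mid <- c1; substr(mid, p, p) <- substr(c2, p, p)
      step_syn <- gc[[mid]] != "*" && gc[[mid]] == gc[[c1]]
      for (rest in paths(mid, c2)) {
        out[[length(out) + 1]] <- list(
          syn = rest$syn + as.integer(step_syn),
          nsyn = rest$nsyn + as.integer(!step_syn),
          stop = rest$stop || gc[[mid]] == "*")
      }
    }
    out
  }
  S <- (sum(vapply(ca, site_s, 0)) + sum(vapply(cb, site_s, 0))) / 2
  N <- 3 * length(ca) - S
  sd <- 0; nd <- 0
  for (i in seq_along(ca)) {
    pw <- paths(ca[i], cb[i])
    ok <- Filter(function(p) !p$stop, pw)
    if (length(ok) == 0) ok <- pw
    sd <- sd + mean(vapply(ok, `[[`, 0, "syn"))
    nd <- nd + mean(vapply(ok, `[[`, 0, "nsyn"))
  }
  ps <- sd / S; pn <- nd / N
  jc <- function(p) if (1 - 4 / 3 * p <= 0) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  list(ks = jc(ps), ka = jc(pn), ps = ps, pn = pn, S = S, N = N)
}

# random stop-free coding pair with at most max_diff substitutions
random_codon_pair <- function(n_codons, max_diff, seed) {
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  a <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  repeat {
    x <- strsplit(a, "")[[1]]
    for (p in sample(seq_along(x), sample(seq_len(max_diff), 1))) {
      x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
    }
    b <- paste(x, collapse = "")
    cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
    if (!any(gc[cb] == "*")) return(list(a = a, b = b))
  }
}

ari <- function(x, y) mclust::adjustedRandIndex(x, y)
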