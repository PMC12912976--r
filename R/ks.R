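# Nei-Gojobori (1986) synonymous/nonsynonymous rates with Jukes-Cantor
# correction. Sites: per codon position, the fraction of the three possible
# single-nucleotide changes that are synonymous (changes creating a stop
# count as nonsynonymous), so syn + nonsyn sites always total 3 per codon.
# Differences: codons differing at k positions are averaged over all k!
# substitution pathways that avoid stop codons (if every pathway passes
# through a stop, all pathways are averaged).

.ks_cache <- new.env(parent = emptyenv())

nt4 <- c("A", "C", "G", "T")

codon_aa <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

split_codons <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0) stop("sequence length not divisible by 3")
  if (grepl("[^ACGT]", seq)) stop("sequence contains non-ACGT characters")
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  if (any(codon_aa(codons) == "*")) stop("sequence contains a stop codon")
  codons
}

# synonymous site count of one codon (0..3)
syn_sites_codon <- function(codon) {
  key <- paste0("S:", codon)
  if (!is.null(.ks_cache[[key]])) return(.ks_cache[[key]])
  aa <- codon_aa(codon)
  syn <- 0
  for (pos in 1:3) {
    for (alt in setdiff(nt4, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      if (codon_aa(mut) == aa) syn <- syn + 1  # stop codons are nonsynonymous
    }
  }
  .ks_cache[[key]] <- syn / 3
  syn / 3
}

perms_of <- function(k) {
  switch(k,
         list(1L),
         list(c(1L, 2L), c(2L, 1L)),
         list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
              c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
}

# average (syn_diffs, nonsyn_diffs) between two codons over stop-avoiding
# substitution pathways
codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  key <- paste0("D:", c1, ">", c2)
  if (!is.null(.ks_cache[[key]])) return(.ks_cache[[key]])
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- perms_of(length(pos))
  walk <- function(order) {
    cur <- c1
    syn <- 0; nsyn <- 0; blocked <- FALSE
    for (p in pos[order]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (codon_aa(nxt) == "*") blocked <- TRUE
      if (codon_aa(nxt) == codon_aa(cur)) syn <- syn + 1 else nsyn <- nsyn + 1
      cur <- nxt
    }
    c(syn, nsyn, blocked)
  }
  res <- vapply(paths, walk, numeric(3))
  ok <- res[3, ] == 0
  use <- if (any(ok)) res[, ok, drop = FALSE] else res
  out <- c(mean(use[1, ]), mean(use[2, ]))
  .ks_cache[[key]] <- out
  out
}

#' Pairwise Ks and Ka (Nei-Gojobori 1986)
#'
#' Estimates synonymous (`ks`) and nonsynonymous (`ka`) substitutions per
#' site between two aligned coding sequences, with Jukes-Cantor multiple-hit
#' correction `k = -3/4 log(1 - 4/3 p)`. When the proportion of differences
#' reaches the correction's domain boundary (p >= 3/4) the estimate is
#' flagged saturated and returned as `NA`.
#'
#' @param seq_a,seq_b aligned coding sequences (character or
#'   `Biostrings::DNAString`); equal length, multiple of 3, ACGT only, no
#'   stop codons.
#' @return list of class `ks_estimate`: `syn_sites`, `nonsyn_sites`
#'   (averaged over the two sequences), `syn_diffs`, `nonsyn_diffs`, `ps`,
#'   `pn`, `ks`, `ka`, `saturated_s`, `saturated_n`, `n_codons`.
#' @export
ks_ng86 <- function(seq_a, seq_b) {
  seq_a <- as.character(seq_a); seq_b <- as.character(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) stop("sequences differ in length")
  ca <- split_codons(seq_a); cb <- split_codons(seq_b)
  s_a <- sum(vapply(ca, syn_sites_codon, numeric(1)))
  s_b <- sum(vapply(cb, syn_sites_codon, numeric(1)))
  syn_sites <- (s_a + s_b) / 2
  nonsyn_sites <- 3 * length(ca) - syn_sites
  d <- vapply(seq_along(ca), function(i) codon_pair_diffs(ca[i], cb[i]),
              numeric(2))
  syn_diffs <- sum(d[1, ]); nonsyn_diffs <- sum(d[2, ])
  ps <- if (syn_sites > 0) syn_diffs / syn_sites else 0
  pn <- if (nonsyn_sites > 0) nonsyn_diffs / nonsyn_sites else 0
  jc <- function(p) {
    if (1 - 4 / 3 * p <= 0) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  ks <- jc(ps); ka <- jc(pn)
  structure(list(syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
                 syn_diffs = syn_diffs, nonsyn_diffs = nonsyn_diffs,
                 ps = ps, pn = pn, ks = ks, ka = ka,
                 saturated_s = is.na(ks), saturated_n = is.na(ka),
                 n_codons = length(ca)),
            class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf("ks = %s, ka = %s (%d codons; ps = %.4f, pn = %.4f)\n",
              if (x$saturated_s) "saturated" else sprintf("%.4f", x$ks),
              if (x$saturated_n) "saturated" else sprintf("%.4f", x$ka),
              x$n_codons, x$ps, x$pn))
  invisible(x)
}

#' Ks for a list of gene pairs with sequences
#'
#' @param pairs `anchor_pairs` (or any data.frame with `gene_a`, `gene_b`).
#' @param sequences named character vector of coding sequences by gene id.
#' @return data.frame `gene_a`, `gene_b`, `ks`, `ka`, `saturated`; pairs
#'   with a missing sequence are skipped with a warning.
#' @export
ks_for_pairs <- function(pairs, sequences) {
  have <- pairs$gene_a %in% names(sequences) & pairs$gene_b %in% names(sequences)
  if (any(!have)) warning(sum(!have), " pair(s) without sequences skipped")
  pairs <- pairs[have, , drop = FALSE]
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    ks_ng86(sequences[[pairs$gene_a[i]]], sequences[[pairs$gene_b[i]]])
  })
  data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
             ks = vapply(res, function(x) if (x$saturated_s) NA_real_ else x$ks,
                         numeric(1)),
             ka = vapply(res, function(x) if (x$saturated_n) NA_real_ else x$ka,
                         numeric(1)),
             saturated = vapply(res, function(x) x$saturated_s, logical(1)),
             stringsAsFactors = FALSE)
}

#' Compare Ks distributions between homoeolog slots
#'
#' Per-slot medians and interquartile ranges plus pairwise two-sample
#' Kolmogorov-Smirnov statistics with permutation p-values (group labels
#' shuffled). Slot pairs with fewer than `min_n` values are reported `NA`.
#'
#' @param ks numeric Ks values (NA allowed, dropped).
#' @param slots slot label per value.
#' @param nperm permutations (default 200).
#' @param seed RNG seed for the permutations.
#' @param min_n minimum values per slot (default 10).
#' @return list with `summary` (per-slot n/median/IQR) and `pairwise`
#'   (data.frame `slot1`, `slot2`, `ks_stat`, `p_value`).
#' @export
ks_distributions_by_slot <- function(ks, slots, nperm = 200L, seed = 1L,
                                     min_n = 10L) {
  keep <- !is.na(ks)
  ks <- ks[keep]; slots <- as.character(slots)[keep]
  us <- sort(unique(slots))
  summary <- data.frame(
    slot = us,
    n = vapply(us, function(s) sum(slots == s), 0L),
    median = vapply(us, function(s) stats::median(ks[slots == s]), 0),
    iqr = vapply(us, function(s) stats::IQR(ks[slots == s]), 0))
  pairwise <- NULL
  if (length(us) >= 2) {
    set.seed(seed)
    combos <- utils::combn(us, 2)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(combos)), function(j) {
      s1 <- combos[1, j]; s2 <- combos[2, j]
      x <- ks[slots == s1]; y <- ks[slots == s2]
      if (length(x) < min_n || length(y) < min_n) {
        return(data.frame(slot1 = s1, slot2 = s2, ks_stat = NA_real_,
                          p_value = NA_real_))
      }
      d0 <- suppressWarnings(stats::ks.test(x, y)$statistic)
      pool <- c(x, y); nx <- length(x)
      dperm <- vapply(seq_len(nperm), function(i) {
        p <- sample(pool)
        suppressWarnings(stats::ks.test(p[seq_len(nx)], p[-seq_len(nx)])$statistic)
      }, numeric(1))
      data.frame(slot1 = s1, slot2 = s2, ks_stat = unname(d0),
                 p_value = (1 + sum(dperm >= d0)) / (nperm + 1))
    }))
  }
  list(summary = summary, pairwise = pairwise)
}

#' Read coding sequences from FASTA
#'
#' @param path FASTA file of in-frame coding sequences keyed by gene id.
#' @return named character vector.
#' @export
read_codon_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
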