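# Collinearity-block detection by greedy monotone chain extraction, and
# syntenic-depth profiling of a reference genome.

# DP for the longest strictly monotone chain among points (ra, rb) with rank
# gaps <= max_gap on both axes. `orient` is +1 (rb increasing) or -1.
# Points must be ordered by (ra, rb). Returns indices of the best chain.
longest_chain <- function(ra, rb, max_gap, orient) {
  n <- length(ra)
  L <- rep(1L, n)
  pred <- rep(0L, n)
  for (i in seq_len(n)[-1]) {
    j <- seq_len(i - 1)
    ok <- ra[j] < ra[i] & (ra[i] - ra[j]) <= max_gap &
      (orient * (rb[i] - rb[j])) > 0 &
      abs(rb[i] - rb[j]) <= max_gap
    if (any(ok)) {
      cand <- j[ok]
      best <- cand[which.max(L[cand])]   # first max: leftmost predecessor
      L[i] <- L[best] + 1L
      pred[i] <- best
    }
  }
  end <- which.max(L)                     # first max: leftmost chain end
  chain <- integer(L[end])
  k <- L[end]; i <- end
  while (i != 0L) { chain[k] <- i; k <- k - 1L; i <- pred[i] }
  chain
}

#' Collinearity blocks between two genomes
#'
#' Within each chromosome pair, homolog pairs are chained into maximal
#' monotone runs (ranks strictly increasing on the reference and strictly
#' increasing or decreasing on the query) with rank gaps of at most
#' `max_gap` on both genomes. Chains are extracted greedily by descending
#' length (deterministic tie-break: leftmost start, `+` orientation first);
#' chains shorter than `min_genes` gene pairs are discarded.
#'
#' @param order_a,order_b [gene_order()] tables (reference, query).
#' @param homologs data.frame with columns `gene_a` (in `order_a`) and
#'   `gene_b` (in `order_b`); pairs naming unknown genes are skipped with a
#'   warning.
#' @param min_genes minimal gene pairs per block (default 5).
#' @param max_gap maximal rank gap (default 10).
#' @return data.frame of blocks (`chrom_a`, `chrom_b`, `start_a`, `end_a`,
#'   `start_b`, `end_b`, `n_pairs`, `orientation`), with the per-block
#'   homolog chains in the `chains` attribute.
#' @export
collinear_blocks <- function(order_a, order_b, homologs, min_genes = 5,
                             max_gap = 10) {
  ia <- match(homologs$gene_a, order_a$gene_id)
  ib <- match(homologs$gene_b, order_b$gene_id)
  unknown <- is.na(ia) | is.na(ib)
  if (any(unknown)) {
    warning(sum(unknown), " homolog pair(s) reference unknown genes; skipped",
            call. = FALSE)
    homologs <- homologs[!unknown, , drop = FALSE]
    ia <- ia[!unknown]; ib <- ib[!unknown]
  }
  pts <- data.frame(gene_a = homologs$gene_a, gene_b = homologs$gene_b,
                    chrom_a = order_a$chrom[ia], rank_a = order_a$rank[ia],
                    chrom_b = order_b$chrom[ib], rank_b = order_b$rank[ib],
                    stringsAsFactors = FALSE)
  blocks <- list(); chains <- list()
  for (key in sort(unique(paste(pts$chrom_a, pts$chrom_b, sep = "\r")))) {
    parts <- strsplit(key, "\r")[[1]]
    sub <- pts[pts$chrom_a == parts[1] & pts$chrom_b == parts[2], ,
               drop = FALSE]
    sub <- sub[order(sub$rank_a, sub$rank_b), , drop = FALSE]
    while (nrow(sub) >= min_genes) {
      cp <- longest_chain(sub$rank_a, sub$rank_b, max_gap, +1L)
      cm <- longest_chain(sub$rank_a, sub$rank_b, max_gap, -1L)
      use_plus <- length(cp) >= length(cm)
      chain <- if (use_plus) cp else cm
      if (length(chain) < min_genes) break
      seg <- sub[chain, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <- data.frame(
        chrom_a = parts[1], chrom_b = parts[2],
        start_a = min(seg$rank_a), end_a = max(seg$rank_a),
        start_b = min(seg$rank_b), end_b = max(seg$rank_b),
        n_pairs = nrow(seg),
        orientation = if (use_plus) "+" else "-",
        stringsAsFactors = FALSE)
      chains[[length(chains) + 1L]] <- seg
      sub <- sub[-chain, , drop = FALSE]
    }
  }
  out <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(chrom_a = character(), chrom_b = character(),
               start_a = integer(), end_a = integer(),
               start_b = integer(), end_b = integer(),
               n_pairs = integer(), orientation = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "chains") <- chains
  out
}

#' Syntenic depth of a reference genome
#'
#' The depth of a reference gene is the number of distinct query blocks
#' whose reference rank interval covers the gene's rank. Reports the
#' per-gene depth, the depth histogram (including depth 0), and the modal
#' depth over genes with depth >= 1 — the signature of the genome
#' multiplication level (2 for a WGD, 3 for a WGT).
#'
#' @param blocks block table from [collinear_blocks()].
#' @param reference the reference [gene_order()].
#' @return list: `depth` (named integer per reference gene), `histogram`
#'   (table of depths), `modal_depth`.
#' @export
syntenic_depth <- function(blocks, reference) {
  depth <- integer(nrow(reference))
  names(depth) <- reference$gene_id
  if (nrow(blocks) > 0) {
    for (k in seq_len(nrow(blocks))) {
      hit <- reference$chrom == blocks$chrom_a[k] &
        reference$rank >= blocks$start_a[k] &
        reference$rank <= blocks$end_a[k]
      depth[hit] <- depth[hit] + 1L
    }
  }
  hist <- table(factor(depth, levels = 0:max(c(depth, 0L))))
  pos <- depth[depth >= 1]
  modal <- if (length(pos)) {
    tab <- table(pos)
    as.integer(names(tab)[which.max(tab)])
  } else NA_integer_
  list(depth = depth, histogram = hist, modal_depth = modal)
}
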