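#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson r with the classical t approximation:
#' `t = r * sqrt((n - 2) / (1 - r^2))` against a Student t distribution with
#' `n - 2` degrees of freedom, two-sided.
#'
#' @param x,y numeric vectors of equal length >= 3, non-constant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need n >= 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

# Rowwise correlation grid: rows of A against rows of B over shared columns.
cor_grid <- function(a, b) {
  r <- stats::cor(t(a), t(b))
  n <- ncol(a)
  r2 <- pmin(r^2, 1)
  t <- r * sqrt((n - 2) / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  p[r2 >= 1] <- 0
  list(r = r, p = p, n = n)
}

#' Build a gene-to-metabolite Pearson correlation network
#'
#' Correlates each gene row against each metabolite row over the shared
#' samples (inner join on sample id). With the default `positive_only`, an
#' edge is kept when the signed `r > r_cutoff` (strict) and `p < p_cutoff`
#' (strict); with `positive_only = FALSE` the cutoff applies to `|r|`
#' instead, admitting strong negative couplings. Inputs are expected to be
#' [normalize_profiles()] matrices, although the Pearson coefficient is
#' invariant to per-row location/scale.
#'
#' @param genes,metabolites numeric matrices with sample-id column names.
#' @param r_cutoff correlation cutoff (default 0.7, strict).
#' @param p_cutoff p-value cutoff (default 0.05, strict).
#' @param positive_only keep only positive correlations (default TRUE).
#' @param adjust_p apply Benjamini-Hochberg across the grid before the
#'   p cutoff (default FALSE: raw p-values, matching the screening usage).
#' @return data.frame of edges: `gene_id`, `metabolite_id`, `r`, `p`, `n`.
#' @export
build_network <- function(genes, metabolites, r_cutoff = 0.7,
                          p_cutoff = 0.05, positive_only = TRUE,
                          adjust_p = FALSE) {
  shared <- intersect(colnames(genes), colnames(metabolites))
  if (length(shared) < 3) {
    stop("need >= 3 shared samples between the two matrices", call. = FALSE)
  }
  dropped <- (ncol(genes) - length(shared)) +
    (ncol(metabolites) - length(shared))
  if (dropped > 0) {
    message(dropped, " unmatched sample column(s) dropped")
  }
  a <- genes[, shared, drop = FALSE]
  b <- metabolites[, shared, drop = FALSE]
  keep_a <- apply(a, 1, stats::sd) > 0
  keep_b <- apply(b, 1, stats::sd) > 0
  a <- a[keep_a, , drop = FALSE]; b <- b[keep_b, , drop = FALSE]
  g <- cor_grid(a, b)
  p <- g$p
  if (adjust_p) p[] <- stats::p.adjust(p, method = "BH")
  rr <- if (positive_only) g$r else abs(g$r)
  ok <- rr > r_cutoff & p < p_cutoff
  idx <- which(ok, arr.ind = TRUE)
  edges <- data.frame(gene_id = rownames(a)[idx[, 1]],
                      metabolite_id = rownames(b)[idx[, 2]],
                      r = g$r[idx], p = p[idx],
                      n = rep.int(g$n, nrow(idx)),
                      stringsAsFactors = FALSE)
  edges[order(edges$gene_id, edges$metabolite_id), , drop = FALSE]
}

#' Genes linked to given metabolites in a network
#'
#' @param network edge data.frame from [build_network()].
#' @param metabolite_ids metabolites of interest; unknown ids raise a
#'   warning and are skipped.
#' @return character vector of gene ids incident to the given metabolites.
#' @export
genes_linked_to <- function(network, metabolite_ids) {
  known <- metabolite_ids %in% network$metabolite_id
  if (any(!known)) {
    warning("metabolite id(s) not in network, skipped: ",
            paste(metabolite_ids[!known], collapse = ", "), call. = FALSE)
  }
  sort(unique(network$gene_id[network$metabolite_id %in% metabolite_ids]))
}

#' Cell and tissue networks, unioned
#'
#' The time-course (suspension cell) samples and the tissue panel give two
#' correlation networks built separately; the returned edge set is their
#' union (an edge found in both keeps the larger r).
#'
#' @param expr a [expression_matrix()].
#' @param peaks a [peak_table()].
#' @param ... thresholds passed to [build_network()].
#' @return edge data.frame with an extra `panel` column
#'   (`"cells"`, `"tissues"`).
#' @export
correlation_networks <- function(expr, peaks, ...) {
  d <- expr$design
  cells <- d$sample_id[d$condition %in% c("treated", "control")]
  tiss <- d$sample_id[d$condition == "tissue"]
  zg <- normalize_profiles(expr)
  zm <- normalize_profiles(peaks)
  e1 <- build_network(zg[, cells, drop = FALSE],
                      zm[, intersect(cells, colnames(zm)), drop = FALSE], ...)
  if (nrow(e1)) e1$panel <- "cells"
  e2 <- NULL
  if (length(tiss) >= 3) {
    e2 <- build_network(zg[, tiss, drop = FALSE],
                        zm[, intersect(tiss, colnames(zm)), drop = FALSE],
                        ...)
    if (nrow(e2)) e2$panel <- "tissues"
  }
  out <- rbind(e1, e2)
  if (is.null(out) || nrow(out) == 0) {
    return(data.frame(gene_id = character(), metabolite_id = character(),
                      r = numeric(), p = numeric(), n = integer(),
                      panel = character(), stringsAsFactors = FALSE))
  }
  out <- out[order(out$gene_id, out$metabolite_id, -out$r), , drop = FALSE]
  out[!duplicated(out[, c("gene_id", "metabolite_id")]), , drop = FALSE]
}
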