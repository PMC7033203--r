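#' RPKM from a count matrix
#'
#' Reads per kilobase per million mapped reads:
#' `RPKM[g, s] = 1e9 * count[g, s] / (length_bp[g] * total_counts[s])`.
#'
#' @param counts a [expression_matrix()] holding raw counts.
#' @return a [expression_matrix()] in RPKM units (same design and lengths).
#' @export
compute_rpkm <- function(counts) {
  stopifnot(inherits(counts, "tf_expression"))
  lib <- colSums(counts$values)
  zero <- lib == 0
  if (any(zero)) {
    stop("zero library size in sample(s): ",
         paste(colnames(counts$values)[zero], collapse = ", "), call. = FALSE)
  }
  rpkm <- 1e9 * counts$values /
    outer(counts$gene_lengths, lib)
  expression_matrix(rpkm, counts$design, counts$gene_lengths)
}

# Rowwise pooled-variance two-sample t on log2(x + 1) values.
# Degenerate zero-variance rows: p = 0 when the means differ, p = 1 when not.
row_t_pooled <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- apply(a, 1, stats::var); v2 <- apply(b, 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(t), df = n1 + n2 - 2)
  degen <- se == 0
  p[degen & m1 != m2] <- 0
  p[degen & m1 == m2] <- 1
  t[degen] <- ifelse(m1[degen] == m2[degen], 0, Inf * sign(m1 - m2)[degen])
  list(t = t, p = p)
}

#' Two-condition differential expression across a time course
#'
#' Per gene and per requested time point, a two-sided Student's t-test with
#' pooled variance on `log2(x + 1)` values of treated vs control replicates;
#' the fold change is the ratio of arithmetic means on the raw scale
#' (pseudocount 1). A gene is significant at a time point when
#' `p < alpha` and `max(fold, 1/fold) >= min_fold`; it is differentially
#' expressed overall when significant at one or more requested time points.
#'
#' @param m a [expression_matrix()] (counts or RPKM).
#' @param time_points_h time points to test (default the elicitation windows
#'   4, 12, 24, 48 and 72 h).
#' @param alpha p-value threshold (strict `<`).
#' @param min_fold minimal max-fold (either direction).
#' @return data.frame with columns `gene_id`, `time_h`, `fold_change`,
#'   `p_value`, `significant`; the per-gene any-time-point DE flag is the
#'   `de_genes` attribute.
#' @export
differential_expression <- function(m, time_points_h = c(4, 12, 24, 48, 72),
                                    alpha = 0.05, min_fold = 2) {
  stopifnot(inherits(m, "tf_expression"))
  d <- m$design
  res <- list()
  for (tp in time_points_h) {
    tr <- which(d$condition == "treated" & d$time_h == tp)
    co <- which(d$condition == "control" & d$time_h == tp)
    if (length(tr) < 2 || length(co) < 2) {
      stop("need >= 2 treated and control replicates at time ", tp, " h",
           call. = FALSE)
    }
    vt <- m$values[, tr, drop = FALSE]
    vc <- m$values[, co, drop = FALSE]
    tt <- row_t_pooled(log2(vt + 1), log2(vc + 1))
    fold <- (rowMeans(vt) + 1) / (rowMeans(vc) + 1)
    sig <- tt$p < alpha & pmax(fold, 1 / fold) >= min_fold
    res[[as.character(tp)]] <- data.frame(
      gene_id = rownames(m$values), time_h = tp, fold_change = fold,
      p_value = tt$p, significant = sig, row.names = NULL,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  de <- tapply(out$significant, out$gene_id, any)
  attr(out, "de_genes") <- names(de)[de]
  out
}

#' Focal-tissue dominance flags
#'
#' A gene is dominant in the focal tissue when its expression there is the
#' strict maximum across tissues and at least `min_ratio` times the median
#' of the other tissues (pseudocount 1 protects the ratio).
#'
#' @param m a [expression_matrix()] containing tissue samples.
#' @param focal focal tissue label (default `"root_bark"`).
#' @param min_ratio minimal focal / median-of-others ratio.
#' @return named logical vector over genes.
#' @export
tissue_dominance <- function(m, focal = "root_bark", min_ratio = 2) {
  stopifnot(inherits(m, "tf_expression"))
  d <- m$design
  tcols <- which(d$condition == "tissue")
  if (length(tcols) < 2) stop("need at least two tissues", call. = FALSE)
  if (!focal %in% d$tissue[tcols]) {
    stop("focal tissue '", focal, "' not present", call. = FALSE)
  }
  tis <- m$values[, tcols, drop = FALSE]
  labs <- d$tissue[tcols]
  # average replicates per tissue if present
  means <- sapply(unique(labs), function(l) {
    rowMeans(tis[, labs == l, drop = FALSE])
  })
  foc <- means[, focal]
  oth <- means[, colnames(means) != focal, drop = FALSE]
  flag <- foc > apply(oth, 1, max) &
    (foc + 1) / (apply(oth, 1, stats::median) + 1) >= min_ratio
  stats::setNames(flag, rownames(m$values))
}

#' Per-row z-scores of log-transformed profiles
#'
#' Applies `log2(x + 1)` then centers and scales each row to mean 0 and
#' standard deviation 1. Constant rows become all-zero and are flagged in the
#' `constant_rows` attribute.
#'
#' @param m a [expression_matrix()], a [peak_table()], or a plain matrix.
#' @return matrix of normalized profiles (same dimnames).
#' @export
normalize_profiles <- function(m) {
  x <- if (inherits(m, "tf_expression")) m$values
       else if (inherits(m, "tf_peaks")) m$intensities
       else m
  lx <- log2(x + 1)
  mu <- rowMeans(lx)
  sd <- apply(lx, 1, stats::sd)
  const <- sd == 0
  sd[const] <- 1
  z <- (lx - mu) / sd
  z[const, ] <- 0
  attr(z, "constant_rows") <- rownames(x)[const]
  z
}
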