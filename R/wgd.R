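# Paralog-divergence statistics: fourfold-degenerate transversions (4DTv),
# Nei-Gojobori (1986) Ks/Ka with Jukes-Cantor correction, molecular-clock
# conversion, and kernel-density peak detection over divergence distributions.

FOURFOLD_PREFIXES <- c("TC", "CT", "CC", "CG", "AC", "GT", "GC", "GG")

codon_table <- function() {
  if (is.null(.tf_cache$codon_table)) {
    gc <- Biostrings::GENETIC_CODE
    .tf_cache$codon_table <- gc
  }
  .tf_cache$codon_table
}

check_codon_pair <- function(p) {
  a <- toupper(p$seq_a); b <- toupper(p$seq_b)
  if (nchar(a) != nchar(b)) stop("unequal sequence lengths", call. = FALSE)
  if (nchar(a) %% 3 != 0) {
    stop("alignment length not a multiple of 3", call. = FALSE)
  }
  if (grepl("[^ACGT]", a) || grepl("[^ACGT]", b)) {
    stop("sequences must be gap-free A/C/G/T", call. = FALSE)
  }
  list(seq_a = a, seq_b = b)
}

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' Fourfold-degenerate site positions of a codon pair
#'
#' Codon positions where both sequences share the same first two bases and
#' that dinucleotide prefix makes the third position fourfold degenerate
#' under the standard genetic code (prefixes TC, CT, CC, CG, AC, GT, GC, GG).
#'
#' @param p codon pair: list with gap-free `seq_a`, `seq_b` of equal length,
#'   a multiple of 3.
#' @return integer vector of 1-based codon indices.
#' @export
fourfold_sites <- function(p) {
  p <- check_codon_pair(p)
  ca <- split_codons(p$seq_a); cb <- split_codons(p$seq_b)
  pa <- substr(ca, 1, 2); pb <- substr(cb, 1, 2)
  which(pa == pb & pa %in% FOURFOLD_PREFIXES)
}

#' 4DTv: transversion proportion at fourfold-degenerate sites
#'
#' The fraction of fourfold-degenerate third-codon positions whose bases
#' differ by a transversion (purine vs pyrimidine). Reported uncorrected for
#' multiple hits.
#'
#' @inheritParams fourfold_sites
#' @return value in [0, 1].
#' @export
fourdtv <- function(p) {
  p <- check_codon_pair(p)
  sites <- fourfold_sites(p)
  if (length(sites) == 0) {
    stop("no fourfold-degenerate sites; 4DTv undefined", call. = FALSE)
  }
  third_a <- substr(split_codons(p$seq_a)[sites], 3, 3)
  third_b <- substr(split_codons(p$seq_b)[sites], 3, 3)
  purine <- c("A", "G")
  tv <- (third_a %in% purine) != (third_b %in% purine)
  sum(tv) / length(sites)
}

# Precompute the NG86 machinery: per-codon synonymous site counts (changes to
# stop codons count as neither synonymous nor possible targets but leave the
# per-position denominator at 3, i.e. they are effectively nonsynonymous) and
# per-codon-pair synonymous/nonsynonymous difference counts averaged over
# minimal mutational pathways, excluding pathways through stop codons.
ng86_tables <- function() {
  if (!is.null(.tf_cache$ng86)) return(.tf_cache$ng86)
  gc <- codon_table()
  codons <- names(gc)
  aa <- unname(gc)
  ncod <- length(codons)
  cmat <- do.call(rbind, strsplit(codons, ""))

  syn_sites <- numeric(ncod)
  for (i in seq_len(ncod)) {
    if (aa[i] == "*") { syn_sites[i] <- NA; next }
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(BASES, cmat[i, pos])) {
        alt <- cmat[i, ]; alt[pos] <- b
        j <- match(paste(alt, collapse = ""), codons)
        if (aa[j] == "*") next
        if (aa[j] == aa[i]) s <- s + 1 / 3
      }
    }
    syn_sites[i] <- s
  }
  names(syn_sites) <- codons

  sd_tab <- matrix(NA_real_, ncod, ncod, dimnames = list(codons, codons))
  nd_tab <- sd_tab
  perms <- list(`1` = list(1L), `2` = list(1:2, 2:1),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (i in seq_len(ncod)) {
    if (aa[i] == "*") next
    for (j in seq_len(ncod)) {
      if (aa[j] == "*") next
      diffpos <- which(cmat[i, ] != cmat[j, ])
      k <- length(diffpos)
      if (k == 0) { sd_tab[i, j] <- 0; nd_tab[i, j] <- 0; next }
      tot_s <- 0; tot_n <- 0; nvalid <- 0
      for (ord in perms[[as.character(k)]]) {
        cur <- cmat[i, ]
        s <- 0; n <- 0; ok <- TRUE
        for (pos in diffpos[ord]) {
          prev_aa <- gc[[paste(cur, collapse = "")]]
          cur[pos] <- cmat[j, pos]
          nxt <- paste(cur, collapse = "")
          nxt_aa <- gc[[nxt]]
          if (nxt_aa == "*" && nxt != codons[j]) { ok <- FALSE; break }
          if (nxt_aa == prev_aa) s <- s + 1 else n <- n + 1
        }
        if (ok) { tot_s <- tot_s + s; tot_n <- tot_n + n
                  nvalid <- nvalid + 1 }
      }
      if (nvalid > 0) {
        sd_tab[i, j] <- tot_s / nvalid
        nd_tab[i, j] <- tot_n / nvalid
      }
    }
  }
  .tf_cache$ng86 <- list(syn_sites = syn_sites, sd = sd_tab, nd = nd_tab,
                         codons = codons, aa = aa)
  .tf_cache$ng86
}

#' Nei-Gojobori (1986) Ks and Ka with Jukes-Cantor correction
#'
#' Counts synonymous and nonsynonymous sites per codon (averaged over the two
#' sequences) and classifies observed differences by averaging over minimal
#' mutational pathways between the differing codons; pathways through stop
#' codons are excluded, and codon pairs with no stop-free pathway are skipped
#' with a warning. Proportions are corrected for multiple hits with the
#' Jukes-Cantor formula `K = -(3/4) ln(1 - 4 p / 3)`; `pS >= 3/4` flags the
#' pair as saturated (Ks undefined, `NA`).
#'
#' @inheritParams fourfold_sites
#' @return list: `pair_id`, `Ks`, `Ka`, `pS`, `pN`, `syn_sites`,
#'   `nonsyn_sites`, `saturated`.
#' @export
ks_ng86 <- function(p) {
  pid <- p$pair_id %||% NA_character_
  p <- check_codon_pair(p)
  tabs <- ng86_tables()
  ca <- split_codons(p$seq_a); cb <- split_codons(p$seq_b)
  ia <- match(ca, tabs$codons); ib <- match(cb, tabs$codons)
  if (any(tabs$aa[ia] == "*") || any(tabs$aa[ib] == "*")) {
    stop("internal stop codon in alignment", call. = FALSE)
  }
  sd_vals <- tabs$sd[cbind(ia, ib)]
  blocked <- is.na(sd_vals)
  if (any(blocked)) {
    warning(sum(blocked), " codon pair(s) skipped: all mutational pathways ",
            "pass through stop codons", call. = FALSE)
  }
  use <- !blocked
  S <- (sum(tabs$syn_sites[ia][use]) + sum(tabs$syn_sites[ib][use])) / 2
  N <- 3 * sum(use) - S
  Sd <- sum(tabs$sd[cbind(ia, ib)][use])
  Nd <- sum(tabs$nd[cbind(ia, ib)][use])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  saturated <- pS >= 0.75
  list(pair_id = pid, Ks = jc(pS), Ka = jc(pN), pS = pS, pN = pN,
       syn_sites = S, nonsyn_sites = N, saturated = saturated)
}

#' Convert Ks to divergence time
#'
#' Molecular-clock conversion `T = Ks / (2 r)`, reported in million years;
#' the default rate is the eudicot 6.5e-9 substitutions per site per year.
#'
#' @param Ks synonymous substitutions per synonymous site (>= 0; `NA` for a
#'   saturated pair propagates).
#' @param rate substitution rate r per site per year (> 0).
#' @return time in million years (MYA).
#' @export
ks_to_time <- function(Ks, rate = 6.5e-9) {
  if (rate <= 0) stop("rate must be positive", call. = FALSE)
  if (any(Ks < 0, na.rm = TRUE)) stop("Ks must be >= 0", call. = FALSE)
  Ks / (2 * rate) / 1e6
}

#' Divergence statistics for a list of codon pairs
#'
#' Convenience wrapper computing, per pair, NG86 Ks and Ka, 4DTv and the
#' clock-converted time.
#'
#' @param pairs list of codon pairs (as from [gen_paralog_pairs()]).
#' @param rate substitution rate per site per year.
#' @return data.frame: `pair_id`, `Ks`, `Ka`, `fourdtv`, `T_mya`,
#'   `saturated`.
#' @export
paralog_stats <- function(pairs, rate = 6.5e-9) {
  rows <- lapply(pairs, function(p) {
    ks <- ks_ng86(p)
    ftv <- tryCatch(fourdtv(p), error = function(e) NA_real_)
    data.frame(pair_id = ks$pair_id, Ks = ks$Ks, Ka = ks$Ka,
               fourdtv = ftv,
               T_mya = if (is.na(ks$Ks)) NA_real_ else
                 ks_to_time(ks$Ks, rate),
               saturated = ks$saturated, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect modes of a divergence distribution
#'
#' Gaussian kernel density estimate over the value range; modes are local
#' maxima of the density whose height exceeds `prominence` times the global
#' maximum, returned in ascending order.
#'
#' @param values numeric vector, length >= 20.
#' @param bandwidth KDE bandwidth (default: `stats::bw.nrd0`).
#' @param prominence relative height floor for a mode (default 0.05).
#' @return numeric vector of mode locations (ascending).
#' @export
detect_peaks <- function(values, bandwidth = NULL, prominence = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("empty input", call. = FALSE)
  if (length(values) < 20) {
    stop("need >= 20 values for density peak detection", call. = FALSE)
  }
  bw <- if (is.null(bandwidth)) stats::bw.nrd0(values) else bandwidth
  d <- stats::density(values, bw = bw, from = min(values), to = max(values),
                      n = 512)
  y <- d$y
  m <- length(y)
  is_max <- c(y[1] > y[2],
              y[2:(m - 1)] > y[1:(m - 2)] & y[2:(m - 1)] >= y[3:m],
              y[m] > y[m - 1])
  modes <- d$x[is_max & y >= prominence * max(y)]
  sort(modes)
}
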