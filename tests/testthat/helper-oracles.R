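# Independent brute-force oracles used across the suite. Each re-derives the
# quantity from first principles, sharing no code path with the package
# implementation it checks.

# --- Pearson r by explicit summation -----------------------------------------
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# --- Global affine-gap alignment (Gotoh), same scoring as the package --------
# gap of length L costs open + L * ext; substitution scores from BLOSUM62.
oracle_global_align <- function(a, b, open = 10, ext = 1) {
  subm <- triptofunnel:::blosum62()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * ext)
  for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * ext)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- subm[av[i - 1], bv[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - (open + ext), X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - (open + ext), Y[i, j - 1] - ext)
    }
  }
  best <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  # traceback (M preferred, then X, then Y) for the aligned strings
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  pa <- character(0); pb <- character(0)
  while (i > 1 || j > 1) {
    if (state == 1) {
      s <- subm[av[i - 1], bv[j - 1]]
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which.max(prev)
      pa <- c(av[i - 1], pa); pb <- c(bv[j - 1], pb)
      i <- i - 1; j <- j - 1
    } else if (state == 2) {
      from_m <- M[i - 1, j] - (open + ext)
      state <- if (X[i, j] == from_m) 1 else 2
      pa <- c(av[i - 1], pa); pb <- c("-", pb)
      i <- i - 1
    } else {
      from_m <- M[i, j - 1] - (open + ext)
      state <- if (Y[i, j] == from_m) 1 else 3
      pa <- c("-", pa); pb <- c(bv[j - 1], pb)
      j <- j - 1
    }
    if (i == 1 && j > 1) state <- 3
    if (j == 1 && i > 1) state <- 2
  }
  gap <- pa == "-" | pb == "-"
  keep <- which(!gap)
  if (length(keep) == 0) {
    ident <- 0
  } else {
    span <- min(keep):max(keep)
    ident <- 100 * sum(pa[span] == pb[span] & pa[span] != "-") / length(span)
  }
  list(score = best, identity = ident)
}

# --- Fourfold-degenerate sites from the genetic code itself ------------------
oracle_fourfold <- function(seq_a, seq_b) {
  gc <- Biostrings::GENETIC_CODE
  n <- nchar(seq_a)
  ca <- substring(seq_a, seq(1, n, 3), seq(3, n, 3))
  cb <- substring(seq_b, seq(1, n, 3), seq(3, n, 3))
  out <- integer(0)
  for (k in seq_along(ca)) {
    pa <- substr(ca[k], 1, 2); pb <- substr(cb[k], 1, 2)
    if (pa != pb) next
    aas <- unique(gc[paste0(pa, c("A", "C", "G", "T"))])
    if (length(aas) == 1 && aas != "*") out <- c(out, k)
  }
  out
}

oracle_fourdtv <- function(seq_a, seq_b) {
  sites <- oracle_fourfold(seq_a, seq_b)
  n <- nchar(seq_a)
  ca <- substring(seq_a, seq(1, n, 3), seq(3, n, 3))
  cb <- substring(seq_b, seq(1, n, 3), seq(3, n, 3))
  tv <- 0
  for (k in sites) {
    x <- substr(ca[k], 3, 3); y <- substr(cb[k], 3, 3)
    if ((x %in% c("A", "G")) != (y %in% c("A", "G"))) tv <- tv + 1
  }
  tv / length(sites)
}

# --- NG86 by direct pathway enumeration (recursive, no lookup tables) --------
oracle_ng86 <- function(seq_a, seq_b) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  syn_frac <- function(codon) {
    if (gc[codon] == "*") return(NA)
    s <- 0
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(codon, pos, pos))) {
        alt <- codon; substr(alt, pos, pos) <- b
        if (gc[alt] == "*") next
        if (gc[alt] == gc[codon]) s <- s + 1 / 3
      }
    }
    s
  }
  count_paths <- function(from, to) {
    d <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
    if (length(d) == 0) return(c(s = 0, n = 0, k = 1))
    tot <- c(s = 0, n = 0, k = 0)
    for (pos in d) {
      mid <- from; substr(mid, pos, pos) <- substr(to, pos, pos)
      if (gc[mid] == "*" && mid != to) next
      sub <- count_paths(mid, to)
      if (sub["k"] == 0) next
      step <- if (gc[mid] == gc[from]) c(1, 0) else c(0, 1)
      tot <- tot + c(s = step[1] * sub[["k"]] + sub[["s"]],
                     n = step[2] * sub[["k"]] + sub[["n"]],
                     k = sub[["k"]])
    }
    tot
  }
  n <- nchar(seq_a)
  ca <- substring(seq_a, seq(1, n, 3), seq(3, n, 3))
  cb <- substring(seq_b, seq(1, n, 3), seq(3, n, 3))
  S <- 0; Sd <- 0; Nd <- 0; used <- 0
  for (k in seq_along(ca)) {
    pth <- count_paths(ca[k], cb[k])
    if (pth[["k"]] == 0) next
    used <- used + 1
    S <- S + (syn_frac(ca[k]) + syn_frac(cb[k])) / 2
    Sd <- Sd + pth[["s"]] / pth[["k"]]
    Nd <- Nd + pth[["n"]] / pth[["k"]]
  }
  N <- 3 * used - S
  pS <- Sd / S; pN <- Nd / N
  list(pS = unname(pS), pN = unname(pN),
       Ks = if (pS < 0.75) -0.75 * log(1 - 4 * pS / 3) else NA,
       Ka = if (pN < 0.75) -0.75 * log(1 - 4 * pN / 3) else NA)
}

# --- Longest monotone chain by exhaustive recursion --------------------------
oracle_max_chain <- function(ra, rb, max_gap, orient) {
  n <- length(ra)
  if (n == 0) return(0L)
  memo <- rep(NA_integer_, n)
  longest_from <- function(i) {
    if (!is.na(memo[i])) return(memo[i])
    best <- 0L
    for (j in seq_len(n)) {
      if (ra[j] > ra[i] && ra[j] - ra[i] <= max_gap &&
          orient * (rb[j] - rb[i]) > 0 && abs(rb[j] - rb[i]) <= max_gap) {
        best <- max(best, longest_from(j))
      }
    }
    memo[i] <<- 1L + best
    memo[i]
  }
  max(vapply(seq_len(n), longest_from, integer(1)))
}

# --- Transitive closure clustering over an adjacency matrix ------------------
oracle_closure_clusters <- function(adj) {
  reach <- adj | diag(nrow(adj))
  repeat {
    nxt <- reach | (reach %*% reach > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  apply(reach, 1, function(row) paste(which(row), collapse = ","))
}

# --- Shared small fixtures ---------------------------------------------------
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed, n_genes = 120, n_cyp_genes = 16,
             n_pathway_genes = 4, n_peaks = 60, paralog_pairs = 20,
             n_codons = 120, ancestral_gene_count = 200, n_chromosomes = 4,
             family_genes_per_species = 8, n_shared_families = 8,
             protein_length = 120, ...)
}

random_aa <- function(len) {
  paste(sample(triptofunnel:::AA20, len, replace = TRUE), collapse = "")
}

mutate_aa <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  for (p in pos) ch[p] <- sample(setdiff(triptofunnel:::AA20, ch[p]), 1)
  paste(ch, collapse = "")
}

random_codons <- function(n) {
  paste(sample(triptofunnel:::sense_codons(), n, replace = TRUE),
        collapse = "")
}
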