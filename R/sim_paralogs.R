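BASES <- c("A", "C", "G", "T")

stop_codons <- function() c("TAA", "TAG", "TGA")

sense_codons <- function() {
  all <- as.vector(outer(outer(BASES, BASES, paste0), BASES, paste0))
  setdiff(all, stop_codons())
}

# Evolve an integer-coded (1..4) nucleotide vector for `t_years` under
# Jukes-Cantor at `rate` substitutions/site/year, rejecting changes that
# create in-frame stop codons.
jc_evolve <- function(anc, t_years, rate) {
  p_change <- 0.75 * (1 - exp(-4 * rate * t_years / 3))
  n <- length(anc)
  seq <- anc
  hit <- stats::runif(n) < p_change
  if (any(hit)) {
    shift <- sample.int(3, sum(hit), replace = TRUE)
    seq[hit] <- ((anc[hit] - 1L + shift) %% 4L) + 1L
  }
  # rejection: re-draw codons that became stops
  repeat {
    cod <- matrix(seq, nrow = 3)
    txt <- paste0(BASES[cod[1, ]], BASES[cod[2, ]], BASES[cod[3, ]])
    bad <- which(txt %in% stop_codons())
    if (length(bad) == 0) break
    for (c0 in bad) {
      idx <- (c0 - 1L) * 3L + 1:3
      hit <- stats::runif(3) < p_change
      seq[idx] <- anc[idx]
      if (any(hit)) {
        shift <- sample.int(3, sum(hit), replace = TRUE)
        seq[idx][hit] <- ((anc[idx][hit] - 1L + shift) %% 4L) + 1L
      }
    }
  }
  seq
}

#' Simulate paralog codon-pair alignments at known divergence times
#'
#' Each pair descends from a random stop-free ancestor coding sequence and
#' evolves independently down two lineages for `T` years under a Jukes-Cantor
#' per-site model at rate `r = cfg$subst_rate_per_site_per_year`;
#' substitutions creating in-frame stop codons are rejected. The expected raw
#' nucleotide difference between the two copies is
#' `p = 3/4 (1 - exp(-8 T r / 3))`; frames are preserved and no indels are
#' introduced, so each pair is already a gap-free codon alignment.
#'
#' @param cfg a [sim_config()]; `true_divergence_times_mya` is recycled
#'   across `paralog_pairs` pairs.
#' @return list with `pairs` (list of codon pairs: `pair_id`, `seq_a`,
#'   `seq_b`) and `truth` (`pair_true_times_mya`, named by pair id).
#' @export
gen_paralog_pairs <- function(cfg) {
  validate_sim_config(cfg)
  r <- cfg$subst_rate_per_site_per_year
  times <- rep(cfg$true_divergence_times_mya, length.out = cfg$paralog_pairs)
  p_exp <- 0.75 * (1 - exp(-8 * r * max(times) * 1e6 / 3))
  if (p_exp >= 0.70) {
    warning("requested divergence is near Jukes-Cantor saturation (expected ",
            "raw difference ", signif(p_exp, 3), ")", call. = FALSE)
  }
  base_of <- stats::setNames(seq_along(BASES), BASES)
  with_stream(cfg, 14L, {
    sense <- sense_codons()
    pairs <- vector("list", cfg$paralog_pairs)
    truth <- stats::setNames(times,
                             sprintf("PAIR%04d", seq_len(cfg$paralog_pairs)))
    for (i in seq_len(cfg$paralog_pairs)) {
      anc_cod <- sample(sense, cfg$n_codons, replace = TRUE)
      anc <- unname(base_of[unlist(strsplit(anc_cod, ""), use.names = FALSE)])
      t_years <- times[i] * 1e6
      a <- jc_evolve(anc, t_years, r)
      b <- jc_evolve(anc, t_years, r)
      pairs[[i]] <- list(pair_id = names(truth)[i],
                         seq_a = paste(BASES[a], collapse = ""),
                         seq_b = paste(BASES[b], collapse = ""))
    }
    list(pairs = pairs, truth = list(pair_true_times_mya = truth))
  })
}
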