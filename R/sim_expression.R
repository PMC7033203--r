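# Latent induction trajectory shared by pathway genes and target metabolites:
# a logistic in time, rescaled to run from 0 at the first sampled time to 1 at
# the last. Midpoint 48 h, scale 20 h — a conventional elicitation response.
latent_trajectory <- function(time_points_h, midpoint = 48, scale = 20) {
  l <- 1 / (1 + exp(-(time_points_h - midpoint) / scale))
  (l - l[1]) / (l[length(l)] - l[1])
}

# Sample design for the two-condition time course plus the tissue panel.
make_design <- function(cfg) {
  tc <- expand.grid(replicate = seq_len(cfg$n_replicates),
                    time_h = cfg$time_points_h,
                    condition = c("control", "treated"),
                    stringsAsFactors = FALSE)
  code <- ifelse(tc$condition == "treated", "CM", "CC")
  tc$sample_id <- sprintf("%s_%03d_r%d", code, tc$time_h, tc$replicate)
  tc$tissue <- NA_character_
  ti <- data.frame(sample_id = cfg$tissues, condition = "tissue",
                   time_h = NA_real_, tissue = cfg$tissues, replicate = 1L,
                   stringsAsFactors = FALSE)
  rbind(tc[, c("sample_id", "condition", "time_h", "tissue", "replicate")], ti)
}

#' Simulate a two-condition time-course + tissue expression matrix
#'
#' Draws integer-rounded log-normal counts for `n_genes` genes over the
#' elicited/control time course (with replicates) and a tissue panel. A
#' planted set of pathway CYPs, a tandem near-duplicate CYP pair and two bait
#' diterpene synthases (`TwCPS1`, `TwMS`) share one latent logistic induction
#' trajectory in the treated condition (gene-specific amplitude x latent +
#' multiplicative log-normal noise) and are dominant in root bark; all other
#' genes are independent of the latent.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `expr` (a [expression_matrix()]), `latent`
#'   (the trajectory over `cfg$time_points_h`) and `truth` (planted ids:
#'   `pathway_gene_ids`, `tandem_pair`, `bait_gene_ids`, `cyp_gene_ids`).
#' @export
gen_expression <- function(cfg) {
  validate_sim_config(cfg)
  if (cfg$n_pathway_genes > cfg$n_genes) {
    stop("invalid config: n_pathway_genes exceeds n_genes", call. = FALSE)
  }
  design <- make_design(cfg)
  latent <- latent_trajectory(cfg$time_points_h)

  n <- cfg$n_genes
  cyp_ids <- sprintf("TWCYP%03d", seq_len(cfg$n_cyp_genes))
  other_ids <- sprintf("TWGEN%03d", seq_len(n - cfg$n_cyp_genes - 2L))
  gene_ids <- c(cyp_ids, other_ids, "TwCPS1", "TwMS")
  pathway_ids <- cyp_ids[seq_len(cfg$n_pathway_genes)]
  tandem <- cyp_ids[cfg$n_pathway_genes + 1:2]
  baits <- c("TwCPS1", "TwMS")
  induced <- c(pathway_ids, tandem, baits)

  with_stream(cfg, 11L, {
    baseline <- exp(stats::rnorm(n, mean = log(120), sd = 0.8))
    names(baseline) <- gene_ids
    # amplitude: fold reached at latent = 1 in treated cells
    amp <- stats::runif(n, 2.5, 6)
    names(amp) <- gene_ids
    amp[induced] <- stats::runif(length(induced), cfg$induction_fold,
                                 cfg$induction_fold + 2.5)
    # the tandem duplicates mirror each other's regulation
    amp[tandem[2]] <- amp[tandem[1]]
    baseline[tandem[2]] <- baseline[tandem[1]]

    mu <- matrix(rep(baseline, nrow(design)), nrow = n,
                 dimnames = list(gene_ids, design$sample_id))
    treated_cols <- which(design$condition == "treated")
    for (j in treated_cols) {
      l <- latent[match(design$time_h[j], cfg$time_points_h)]
      mu[induced, j] <- baseline[induced] * (1 + (amp[induced] - 1) * l)
    }
    tissue_cols <- which(design$condition == "tissue")
    # induced genes: strong root-bark dominance; background genes: mild
    # random tissue preferences so the panel is not artificially flat
    tpref <- matrix(exp(stats::rnorm(n * length(tissue_cols), 0, 0.4)),
                    nrow = n)
    for (k in seq_along(tissue_cols)) {
      j <- tissue_cols[k]
      mu[, j] <- baseline * tpref[, k]
    }
    rb <- which(design$tissue == "root_bark")
    lowt <- tissue_cols[tissue_cols != rb]
    mu[induced, rb] <- baseline[induced] * 8
    mu[induced, lowt] <- baseline[induced] *
      matrix(stats::runif(length(induced) * length(lowt), 0.15, 0.6),
             nrow = length(induced))

    counts <- matrix(
      round(mu * exp(stats::rnorm(length(mu), 0, cfg$noise_sd))),
      nrow = n, dimnames = dimnames(mu))
    lengths_bp <- stats::setNames(
      round(stats::runif(n, 900, 2400)), gene_ids)

    list(expr = expression_matrix(counts, design, lengths_bp),
         latent = latent,
         truth = list(pathway_gene_ids = pathway_ids,
                      tandem_pair = tandem,
                      bait_gene_ids = baits,
                      cyp_gene_ids = cyp_ids))
  })
}
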