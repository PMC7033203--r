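#' Simulation configuration
#'
#' Collects every parameter of the synthetic multi-omics generators into a
#' validated object. The defaults reproduce the study design the package
#' targets: a two-condition (methyl-jasmonate elicited vs control) suspension
#' cell time course sampled at 0, 4, 12, 24, 48, 72, 120 and 240 h with three
#' replicates, a seven-tissue panel including root bark, an LC-MS feature
#' table with a diterpenoid mass window of 295-400 Da, a multi-species CYP
#' protein panel with a planted focal-species-specific subfamily (<55%
#' cross-species identity) and a ~97%-identical tandem duplicate pair, and
#' paralog coding-sequence pairs diverged under a Jukes-Cantor clock at
#' 6.5e-9 substitutions per site per year.
#'
#' @param seed integer seed; identical seed + config gives byte-identical
#'   simulated data sets.
#' @param n_genes total number of genes in the expression matrix (including
#'   the CYP panel and the two bait diterpene synthases).
#' @param n_cyp_genes number of genes annotated as CYPs; must not exceed
#'   `n_genes - 2` (two gene slots are reserved for the baits).
#' @param n_pathway_genes number of planted pathway CYPs sharing the latent
#'   induction trajectory.
#' @param time_points_h ordered vector of sampling times in hours.
#' @param tissues tissue labels; must contain `"root_bark"`.
#' @param n_replicates biological replicates per condition per time point.
#' @param n_peaks number of LC-MS features.
#' @param n_target_metabolites number of planted target (diterpenoid-like)
#'   peaks coupled to the latent trajectory.
#' @param mass_window numeric length-2, inclusive m/z window in Da.
#' @param induction_fold treated/control fold reached by targets (and, in
#'   expectation, pathway genes) once the latent trajectory saturates.
#' @param noise_sd log-scale standard deviation of multiplicative noise.
#' @param species species labels; the first is the focal species.
#' @param family_genes_per_species number of shared-family CYP proteins
#'   generated for each non-focal species.
#' @param n_shared_families number of cross-species CYP family roots.
#' @param protein_length amino-acid length of simulated proteins.
#' @param specific_max_xspecies_identity upper bound (percent) on the
#'   cross-species identity of the planted specific subfamily.
#' @param tandem_pair_identity target percent identity of the planted tandem
#'   duplicate pair.
#' @param paralog_pairs number of simulated paralog codon-pair alignments.
#' @param n_codons codons per simulated pair.
#' @param true_divergence_times_mya divergence time(s), million years,
#'   recycled across pairs.
#' @param subst_rate_per_site_per_year molecular-clock rate r.
#' @param ancestral_gene_count genes in the unduplicated reference genome.
#' @param n_chromosomes reference chromosomes.
#' @param triplication_loss_fraction per-copy gene-loss probability after
#'   triplication, in [0, 1).
#' @param inversion_rate probability that a local query window is inverted.
#'
#' @return an object of class `tf_sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 240L,
                       n_cyp_genes = 24L,
                       n_pathway_genes = 6L,
                       time_points_h = c(0, 4, 12, 24, 48, 72, 120, 240),
                       tissues = c("root_bark", "root", "stem_bark",
                                   "peeled_stem", "stem", "leaf", "flower"),
                       n_replicates = 3L,
                       n_peaks = 120L,
                       n_target_metabolites = 2L,
                       mass_window = c(295, 400),
                       induction_fold = 3.6,
                       noise_sd = 0.25,
                       species = c("Twilfordii", "Athaliana",
                                   "Slycopersicum", "Ptrichocarpa"),
                       family_genes_per_species = 16L,
                       n_shared_families = 16L,
                       protein_length = 180L,
                       specific_max_xspecies_identity = 55,
                       tandem_pair_identity = 97,
                       paralog_pairs = 100L,
                       n_codons = 300L,
                       true_divergence_times_mya = 21,
                       subst_rate_per_site_per_year = 6.5e-9,
                       ancestral_gene_count = 300L,
                       n_chromosomes = 5L,
                       triplication_loss_fraction = 0.4,
                       inversion_rate = 0.05) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    n_cyp_genes = as.integer(n_cyp_genes),
    n_pathway_genes = as.integer(n_pathway_genes),
    time_points_h = as.numeric(time_points_h),
    tissues = as.character(tissues),
    n_replicates = as.integer(n_replicates),
    n_peaks = as.integer(n_peaks),
    n_target_metabolites = as.integer(n_target_metabolites),
    mass_window = as.numeric(mass_window),
    induction_fold = as.numeric(induction_fold),
    noise_sd = as.numeric(noise_sd),
    species = as.character(species),
    family_genes_per_species = as.integer(family_genes_per_species),
    n_shared_families = as.integer(n_shared_families),
    protein_length = as.integer(protein_length),
    specific_max_xspecies_identity = as.numeric(specific_max_xspecies_identity),
    tandem_pair_identity = as.numeric(tandem_pair_identity),
    paralog_pairs = as.integer(paralog_pairs),
    n_codons = as.integer(n_codons),
    true_divergence_times_mya = as.numeric(true_divergence_times_mya),
    subst_rate_per_site_per_year = as.numeric(subst_rate_per_site_per_year),
    ancestral_gene_count = as.integer(ancestral_gene_count),
    n_chromosomes = as.integer(n_chromosomes),
    triplication_loss_fraction = as.numeric(triplication_loss_fraction),
    inversion_rate = as.numeric(inversion_rate)
  )
  class(cfg) <- "tf_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "tf_sim_config"))
  pos <- c("n_genes", "n_cyp_genes", "n_pathway_genes", "n_replicates",
           "n_peaks", "n_target_metabolites", "induction_fold", "noise_sd",
           "family_genes_per_species", "n_shared_families", "protein_length",
           "paralog_pairs", "n_codons", "subst_rate_per_site_per_year",
           "ancestral_gene_count", "n_chromosomes")
  for (f in pos) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0) {
      stop("invalid config: `", f, "` must be strictly positive", call. = FALSE)
    }
  }
  if (cfg$n_pathway_genes > cfg$n_genes) {
    stop("invalid config: n_pathway_genes exceeds n_genes", call. = FALSE)
  }
  if (cfg$n_pathway_genes + 2L > cfg$n_cyp_genes) {
    stop("invalid config: n_cyp_genes must hold the pathway genes plus the ",
         "tandem pair", call. = FALSE)
  }
  if (cfg$n_cyp_genes + 2L > cfg$n_genes) {
    stop("invalid config: n_genes must hold the CYP panel plus two baits",
         call. = FALSE)
  }
  if (length(cfg$mass_window) != 2L || cfg$mass_window[1] >= cfg$mass_window[2]) {
    stop("invalid config: mass_window must be (low, high) with low < high",
         call. = FALSE)
  }
  if (is.unsorted(cfg$time_points_h, strictly = TRUE)) {
    stop("invalid config: time_points_h must be strictly increasing",
         call. = FALSE)
  }
  if (!"root_bark" %in% cfg$tissues) {
    stop("invalid config: tissues must include 'root_bark'", call. = FALSE)
  }
  if (length(cfg$species) < 2L) {
    stop("invalid config: at least two species required", call. = FALSE)
  }
  if (cfg$tandem_pair_identity <= 0 || cfg$tandem_pair_identity > 100 ||
      cfg$specific_max_xspecies_identity <= 0 ||
      cfg$specific_max_xspecies_identity > 100) {
    stop("invalid config: identity targets must lie in (0, 100]",
         call. = FALSE)
  }
  if (any(cfg$true_divergence_times_mya < 0)) {
    stop("invalid config: divergence times must be non-negative",
         call. = FALSE)
  }
  if (cfg$triplication_loss_fraction < 0 || cfg$triplication_loss_fraction >= 1) {
    stop("invalid config: triplication_loss_fraction must lie in [0, 1)",
         call. = FALSE)
  }
  invisible(cfg)
}

# Deterministic per-generator RNG streams derived from the top-level seed.
# Offsets keep generators independent while one seed governs everything.
with_stream <- function(cfg, offset, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((cfg$seed %% 1000000L) * 1000L + offset)
  expr
}
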