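test_that("config validation rejects impossible studies", {
  expect_error(sim_config(n_genes = 10, n_cyp_genes = 8, n_pathway_genes = 20),
               "n_pathway_genes")
  expect_error(sim_config(mass_window = c(400, 295)), "mass_window")
  expect_error(sim_config(triplication_loss_fraction = 1), "loss_fraction")
  expect_error(sim_config(tandem_pair_identity = 140), "identity targets")
  expect_error(sim_config(n_peaks = 0), "strictly positive")
  expect_error(sim_config(species = "only_one"), "two species")
})

test_that("expression matrix has the design-forced shape and is seed-deterministic", {
  cfg <- sim_config(seed = 1, n_genes = 100, n_cyp_genes = 10,
                    n_pathway_genes = 5)
  ex <- gen_expression(cfg)
  n_samp <- length(cfg$time_points_h) * 2 * cfg$n_replicates +
    length(cfg$tissues)
  expect_equal(dim(ex$expr$values), c(100L, n_samp))
  expect_true(all(ex$truth$pathway_gene_ids %in% rownames(ex$expr$values)))
  expect_length(ex$truth$tandem_pair, 2)
  ex2 <- gen_expression(cfg)
  expect_identical(ex$expr$values, ex2$expr$values)
})

test_that("planted pathway genes co-vary more than random gene pairs", {
  cfg <- sim_config(seed = 1, n_genes = 100, n_cyp_genes = 10,
                    n_pathway_genes = 5)
  ex <- gen_expression(cfg)
  treated <- ex$expr$design$sample_id[ex$expr$design$condition == "treated"]
  z <- log2(ex$expr$values[, treated] + 1)
  path <- ex$truth$pathway_gene_ids
  pw <- stats::cor(t(z[path, ]))
  mean_path <- mean(pw[upper.tri(pw)])
  others <- setdiff(rownames(z), c(path, ex$truth$tandem_pair,
                                   ex$truth$bait_gene_ids))
  set.seed(42)
  rnd <- replicate(100, {
    ij <- sample(others, 2)
    stats::cor(z[ij[1], ], z[ij[2], ])
  })
  expect_gt(mean_path, mean(rnd))
})

test_that("metabolome plants targets inside the mass window at the set fold", {
  cfg <- sim_config(seed = 3, n_peaks = 50, n_target_metabolites = 2)
  ex <- gen_expression(cfg)
  mb <- gen_metabolome(cfg, ex$latent)
  expect_equal(nrow(mb$peaks$peaks), 50)
  expect_length(mb$truth$target_metabolite_ids, 2)
  tmz <- mb$peaks$peaks$mz[mb$peaks$peaks$peak_id %in%
                             mb$truth$target_metabolite_ids]
  expect_true(all(tmz >= 295 & tmz <= 400))
  tfr <- mb$peaks$peaks$fragment_count[mb$peaks$peaks$peak_id %in%
                                         mb$truth$target_metabolite_ids]
  expect_true(all(tfr >= 1))
  # realized fold at the final time point approximates the configured 3.6
  d <- mb$peaks$design
  last <- max(cfg$time_points_h)
  tr <- d$sample_id[d$condition == "treated" & d$time_h == last]
  co <- d$sample_id[d$condition == "control" & d$time_h == last]
  x <- mb$peaks$intensities[mb$truth$target_metabolite_ids, , drop = FALSE]
  fold <- rowMeans(x[, tr, drop = FALSE]) / rowMeans(x[, co, drop = FALSE])
  # log-normal noise at sd 0.25 over 2 x 3 replicates: 3 sigma ~ 0.45 in log
  expect_true(all(abs(log(fold) - log(3.6)) < 0.45))
  expect_error(gen_metabolome(cfg, ex$latent[-1]), "length")
})

test_that("protein families carry the planted identity structure", {
  cfg <- small_config(seed = 2)
  pf <- gen_protein_families(cfg)
  expect_equal(nrow(pf$proteins),
               cfg$n_cyp_genes +
                 (length(cfg$species) - 1) * cfg$family_genes_per_species)
  expect_setequal(unique(pf$proteins$species), cfg$species)
  tp <- pf$truth$tandem_pair
  foc <- pf$proteins[pf$proteins$species == cfg$species[1], ]
  hit <- pairwise_identity(foc[foc$gene_id == tp[1], ],
                           foc[foc$gene_id == tp[2], ])
  expect_lt(abs(hit$percent_identity - cfg$tandem_pair_identity), 1 + 1e-9)
  # every planted specific gene stays below 55% identity to all other species
  sp <- species_specific(pf$proteins, cfg$species[1], 55)
  expect_true(all(pf$truth$specific_gene_ids %in% sp))
})

test_that("paralog pairs follow the Jukes-Cantor divergence expectation", {
  cfg0 <- sim_config(seed = 5, paralog_pairs = 3, n_codons = 50,
                     true_divergence_times_mya = 0)
  pp0 <- gen_paralog_pairs(cfg0)
  for (p in pp0$pairs) expect_identical(p$seq_a, p$seq_b)

  cfg <- sim_config(seed = 5, paralog_pairs = 60, n_codons = 500,
                    true_divergence_times_mya = 21)
  pp <- gen_paralog_pairs(cfg)
  difs <- vapply(pp$pairs, function(p) {
    a <- strsplit(p$seq_a, "")[[1]]; b <- strsplit(p$seq_b, "")[[1]]
    mean(a != b)
  }, numeric(1))
  lens <- vapply(pp$pairs, function(p) nchar(p$seq_a), numeric(1))
  expect_true(all(lens %% 3 == 0))
  expect_false(any(grepl("-", vapply(pp$pairs, `[[`, "", "seq_a"))))
  p_exp <- 0.75 * (1 - exp(-8 * 21e6 * 6.5e-9 / 3))
  se <- sqrt(p_exp * (1 - p_exp) / (60 * 1500))
  # stop-codon rejection slightly depresses realized divergence; allow for
  # that small deterministic bias on top of sampling error
  expect_lt(abs(mean(difs) - p_exp), 4 * se + 0.002)
  # deep time triggers the saturation warning
  expect_warning(
    gen_paralog_pairs(sim_config(seed = 1, paralog_pairs = 1, n_codons = 30,
                                 true_divergence_times_mya = 500)),
    "saturation")
})

test_that("triplicated map plants a 3x homology structure with losses", {
  cfg <- sim_config(seed = 4, ancestral_gene_count = 200, n_chromosomes = 4,
                    triplication_loss_fraction = 1e-12, inversion_rate = 0)
  mp <- gen_triplicated_map(cfg)
  per_gene <- table(mp$homologs$gene_a)
  expect_true(all(per_gene == 3))
  expect_false(any(mp$homologs$gene_a == mp$homologs$gene_b))

  cfg2 <- sim_config(seed = 4, ancestral_gene_count = 500, n_chromosomes = 5,
                     triplication_loss_fraction = 0.4)
  mp2 <- gen_triplicated_map(cfg2)
  retained <- table(factor(mp2$homologs$gene_a,
                           levels = mp2$ref$gene_id))
  m <- mean(retained[retained > 0])
  exp_mean <- 3 * 0.6 / (1 - 0.4^3)   # homologs per reference gene with >= 1
  expect_lt(abs(m - exp_mean), 0.15)
  expect_error(gen_triplicated_map(sim_config(ancestral_gene_count = 60,
                                              n_chromosomes = 1)), NA)
})

test_that("generators are reproducible through their own readers", {
  cfg <- small_config(seed = 7)
  dir <- withr::local_tempdir()
  st <- simulate_study(cfg, outdir = dir)
  ex <- read_expression_tsv(file.path(dir, "expression.tsv"),
                            file.path(dir, "gene_lengths.tsv"))
  expect_equal(ex$values, st$expr$values)
  expect_equal(ex$design, st$expr$design)
  pk <- read_peaks_csv(file.path(dir, "peaks.csv"))
  expect_equal(pk$peaks$mz, st$peaks$peaks$mz, tolerance = 1e-6)
  expect_equal(dim(pk$intensities), dim(st$peaks$intensities))
  pr <- read_protein_fasta(file.path(dir, "proteins.fasta"))
  expect_equal(pr$sequence, st$proteins$sequence)
  expect_equal(pr$species, st$proteins$species)
  pp <- read_codon_pairs_fasta(file.path(dir, "paralog_pairs.fasta"))
  expect_equal(pp, st$paralogs)
  go <- read_gene_order_tsv(file.path(dir, "gene_order_query.tsv"))
  expect_equal(go$gene_id, st$map$query$gene_id)
  tr <- read_truth_json(file.path(dir, "truth.json"))
  expect_setequal(tr$pathway_gene_ids, st$truth$pathway_gene_ids)
})
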