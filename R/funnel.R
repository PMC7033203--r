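#' Funnel configuration
#'
#' Thresholds and inputs of the staged CYP-candidate screen. Defaults mirror
#' the screening thresholds used throughout the package: RPKM > 1 for
#' "reasonably well-expressed", differential expression tested at 4, 12, 24,
#' 48 and 72 h, root-bark dominance, the 55% subfamily-specificity cutoff,
#' the 97% near-duplicate cutoff, and the network's r > 0.7 for bait
#' similarity.
#'
#' @param target_metabolite_ids metabolite ids anchoring stage 1.
#' @param bait_gene_ids pathway-anchor genes (e.g. the CPS/MS diterpene
#'   synthase pair) whose profiles define "highly similar expression".
#' @param cyp_gene_ids the annotated CYP universe.
#' @param rpkm_min expression floor (strict `>`).
#' @param de_times_h time points for the DE criterion.
#' @param de_alpha,de_min_fold DE thresholds.
#' @param focal_tissue,tissue_min_ratio tissue-dominance criterion.
#' @param focal_species focal species for specificity.
#' @param specificity_cutoff percent identity below which a CYP is
#'   species-specific.
#' @param dup_cutoff percent identity at which candidates collapse.
#' @param r_cutoff bait-similarity Pearson cutoff (strict `>`).
#' @param exclusion_list gene ids with known or irrelevant function,
#'   removed at the last stage.
#' @return list of class `tf_funnel_config`.
#' @export
funnel_config <- function(target_metabolite_ids, bait_gene_ids,
                          cyp_gene_ids, rpkm_min = 1,
                          de_times_h = c(4, 12, 24, 48, 72),
                          de_alpha = 0.05, de_min_fold = 2,
                          focal_tissue = "root_bark", tissue_min_ratio = 2,
                          focal_species = "Twilfordii",
                          specificity_cutoff = 55, dup_cutoff = 97,
                          r_cutoff = 0.7, exclusion_list = character()) {
  stopifnot(rpkm_min >= 0, de_alpha > 0, de_alpha <= 1, de_min_fold >= 1,
            specificity_cutoff > 0, specificity_cutoff <= 100,
            dup_cutoff > 0, dup_cutoff <= 100,
            r_cutoff >= 0, r_cutoff <= 1)
  structure(list(target_metabolite_ids = target_metabolite_ids,
                 bait_gene_ids = bait_gene_ids,
                 cyp_gene_ids = cyp_gene_ids, rpkm_min = rpkm_min,
                 de_times_h = de_times_h, de_alpha = de_alpha,
                 de_min_fold = de_min_fold, focal_tissue = focal_tissue,
                 tissue_min_ratio = tissue_min_ratio,
                 focal_species = focal_species,
                 specificity_cutoff = specificity_cutoff,
                 dup_cutoff = dup_cutoff, r_cutoff = r_cutoff,
                 exclusion_list = exclusion_list),
            class = "tf_funnel_config")
}

#' Run the staged CYP-candidate funnel
#'
#' Stages:
#' 1. network-linked: CYPs with an edge to a target metabolite;
#' 2. expressed: stage 1 restricted to RPKM > `rpkm_min` in >= 1 sample;
#' 3. specificity-augmented: stage 2 unioned with species-specific CYPs
#'    that are elicitation-induced (DE) or focal-tissue-dominant;
#' 4. pattern: stage 3 restricted to genes that are DE at >= 1 configured
#'    time point or tissue-dominant, AND whose expression profile has
#'    Pearson r above `r_cutoff` to at least one bait gene;
#' 5. final: stage 4 minus the exclusion list, then near-duplicate collapse
#'    at `dup_cutoff` percent identity.
#' Candidates are ranked by their best correlation to a target metabolite.
#'
#' @param expr count-scale [expression_matrix()].
#' @param network edge table from [build_network()] or
#'   [correlation_networks()].
#' @param proteins [protein_records()] covering (at least) the focal-species
#'   CYPs; genes without a protein record stay their own representative.
#' @param cfg a [funnel_config()].
#' @return object of class `tf_funnel_report`: `stages` (list of
#'   name/rule/ids/count), `candidates` (ranked data.frame `gene_id`,
#'   `best_r`, `representative_of`).
#' @export
run_funnel <- function(expr, network, proteins, cfg) {
  stopifnot(inherits(cfg, "tf_funnel_config"),
            inherits(expr, "tf_expression"))
  if (!all(cfg$bait_gene_ids %in% rownames(expr$values))) {
    stop("bait gene(s) missing from expression data: ",
         paste(setdiff(cfg$bait_gene_ids, rownames(expr$values)),
               collapse = ", "), call. = FALSE)
  }
  stages <- list()
  push <- function(name, rule, ids) {
    stages[[length(stages) + 1L]] <<- list(name = name, rule = rule,
                                           ids = sort(ids),
                                           count = length(ids))
  }

  s1 <- intersect(genes_linked_to(network, cfg$target_metabolite_ids),
                  cfg$cyp_gene_ids)
  push("network_linked",
       "CYP with a network edge to a target metabolite", s1)

  rpkm <- compute_rpkm(expr)
  expressed <- rownames(rpkm$values)[
    apply(rpkm$values, 1, max) > cfg$rpkm_min]
  s2 <- intersect(s1, expressed)
  push("expressed", sprintf("RPKM > %g in >= 1 sample", cfg$rpkm_min), s2)

  de <- differential_expression(expr, cfg$de_times_h, cfg$de_alpha,
                                cfg$de_min_fold)
  de_genes <- attr(de, "de_genes")
  dom <- tissue_dominance(expr, cfg$focal_tissue, cfg$tissue_min_ratio)
  dom_genes <- names(dom)[dom]
  specific <- if (is.null(proteins) || nrow(proteins) == 0) character() else
    tryCatch(species_specific(proteins, cfg$focal_species,
                              cfg$specificity_cutoff),
             error = function(e) character())
  spec_in <- intersect(intersect(specific, cfg$cyp_gene_ids),
                       union(de_genes, dom_genes))
  s3 <- union(s2, spec_in)
  push("specificity_augmented",
       sprintf("union with species-specific CYPs (< %g%% cross-species identity) that are induced or %s-dominant",
               cfg$specificity_cutoff, cfg$focal_tissue), s3)

  zg <- normalize_profiles(expr)
  bait_r <- if (length(s3)) {
    g <- cor_grid(zg[s3, , drop = FALSE],
                  zg[cfg$bait_gene_ids, , drop = FALSE])
    apply(g$r, 1, max)
  } else numeric()
  pattern_ok <- union(de_genes, dom_genes)
  s4 <- s3[s3 %in% pattern_ok & bait_r > cfg$r_cutoff]
  push("pattern",
       sprintf("DE at >= 1 of {%s} h or %s-dominant, and bait r > %g",
               paste(cfg$de_times_h, collapse = ","), cfg$focal_tissue,
               cfg$r_cutoff), s4)

  s5 <- setdiff(s4, cfg$exclusion_list)
  rep_of <- stats::setNames(s5, s5)
  if (length(s5) > 1 && !is.null(proteins)) {
    prot5 <- proteins[proteins$species == cfg$focal_species &
                        proteins$gene_id %in% s5, , drop = FALSE]
    if (nrow(prot5) > 1) {
      cl <- collapse_near_duplicates(prot5, cfg$dup_cutoff)
      rep_of[names(cl$clusters)] <- cl$clusters
    }
  }
  final <- sort(unique(unname(rep_of)))
  push("final",
       sprintf("minus exclusions, near-duplicates collapsed at %g%% identity",
               cfg$dup_cutoff), final)

  best_r <- vapply(final, function(g) {
    e <- network[network$gene_id == g &
                   network$metabolite_id %in% cfg$target_metabolite_ids, ]
    if (nrow(e)) max(e$r) else NA_real_
  }, numeric(1))
  cand <- data.frame(gene_id = final, best_r = best_r,
                     representative_of = vapply(final, function(g) {
                       paste(sort(names(rep_of)[rep_of == g]),
                             collapse = ";")
                     }, character(1)),
                     stringsAsFactors = FALSE)
  cand <- cand[order(-ifelse(is.na(cand$best_r), -Inf, cand$best_r),
                     cand$gene_id), , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(stages = stages, candidates = cand),
            class = "tf_funnel_report")
}

#' @export
print.tf_funnel_report <- function(x, ...) {
  cat("candidate funnel:\n")
  for (s in x$stages) cat(sprintf("  %-24s %3d  (%s)\n", s$name, s$count,
                                  s$rule))
  cat("ranked candidates:\n")
  print(x$candidates)
  invisible(x)
}

#' Write a funnel report to disk
#'
#' One TSV per stage (`stage_<n>_<name>.tsv` with the surviving gene ids), a
#' ranked candidate table, and a human-readable `summary.txt` with counts
#' and rules. Output is deterministic: identical reports yield identical
#' bytes.
#'
#' @param report a `tf_funnel_report`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "tf_funnel_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (i in seq_along(report$stages)) {
    s <- report$stages[[i]]
    path <- file.path(dir, sprintf("stage_%d_%s.tsv", i, s$name))
    utils::write.table(data.frame(gene_id = s$ids), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    paths <- c(paths, path)
  }
  cpath <- file.path(dir, "candidates.tsv")
  utils::write.table(report$candidates, cpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  spath <- file.path(dir, "summary.txt")
  lines <- c("candidate funnel summary", "")
  for (i in seq_along(report$stages)) {
    s <- report$stages[[i]]
    lines <- c(lines, sprintf("stage %d %-24s n=%-4d rule: %s", i, s$name,
                              s$count, s$rule))
  }
  writeLines(lines, spath)
  invisible(c(paths, cpath, spath))
}
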