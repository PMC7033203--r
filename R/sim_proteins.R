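AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# Substitute exactly n_mut positions to a different residue.
mutate_protein <- function(seq, n_mut) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), min(n_mut, length(ch)))
  for (p in pos) {
    ch[p] <- sample(setdiff(AA20, ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# Mutate `seq` so that the measured global-alignment identity of the copy to
# the original lands in [target, target + tol] percent (at the target or just
# above it, so a duplicate planted for a ">= cutoff" collapse always
# collapses). The mutation count -> identity map is stochastic (alignment may
# open gaps; sequence length quantizes identity), so the count is adjusted by
# feedback.
copy_at_identity <- function(seq, target, tol = 1, max_iter = 25) {
  len <- nchar(seq)
  m <- max(0L, round(len * (1 - target / 100)))
  for (i in seq_len(max_iter)) {
    cand <- mutate_protein(seq, m)
    got <- align_identity(seq, cand)$percent_identity
    if (got >= target && got - target <= tol) return(cand)
    m <- max(0L, m + round(len * (got - target) / 100 / 2) +
               sample(c(-1L, 0L, 1L), 1))
  }
  stop("could not reach target identity ", target, " within ", max_iter,
       " attempts", call. = FALSE)
}

#' Simulate multi-species protein families with planted structure
#'
#' Builds a multi-species CYP-like protein panel: shared family roots from
#' which every species' members diverge by point substitution (cross-species
#' identities well above the subfamily cutoff), plus a planted focal-species-
#' specific subfamily grown from an unrelated root (best cross-species
#' identity below `cfg$specific_max_xspecies_identity`) that contains a
#' tandem near-duplicate pair at `cfg$tandem_pair_identity` percent identity
#' (achieved by rejection-adjusted mutation counts, tolerance +/- 1 point).
#'
#' @param cfg a [sim_config()].
#' @param focal_ids gene ids for the focal species (default: the CYP ids
#'   used by [gen_expression()], so the two modules share a namespace).
#' @param specific_ids planted specific subfamily, a subset of `focal_ids`
#'   (default: pathway genes plus the tandem pair).
#' @param tandem_pair length-2 id vector, a subset of `specific_ids`.
#' @return list with `proteins` (a [protein_records()] frame) and `truth`
#'   (`specific_gene_ids`, `tandem_pair`).
#' @export
gen_protein_families <- function(cfg, focal_ids = NULL, specific_ids = NULL,
                                 tandem_pair = NULL) {
  validate_sim_config(cfg)
  if (length(cfg$species) < 2) stop("need >= 2 species", call. = FALSE)
  if (is.null(focal_ids)) {
    focal_ids <- sprintf("TWCYP%03d", seq_len(cfg$n_cyp_genes))
  }
  if (is.null(specific_ids)) {
    specific_ids <- focal_ids[seq_len(cfg$n_pathway_genes + 2L)]
  }
  if (is.null(tandem_pair)) {
    tandem_pair <- focal_ids[cfg$n_pathway_genes + 1:2]
  }
  stopifnot(all(specific_ids %in% focal_ids),
            length(tandem_pair) == 2, all(tandem_pair %in% specific_ids))
  focal <- cfg$species[1]
  with_stream(cfg, 13L, {
    roots <- replicate(cfg$n_shared_families,
                       random_protein(cfg$protein_length))
    frac_shared <- 0.12   # per-copy divergence from the family root

    recs <- list()
    # non-focal species: shared-family members only
    for (sp in cfg$species[-1]) {
      nsp <- cfg$family_genes_per_species
      fam <- rep(seq_len(cfg$n_shared_families), length.out = nsp)
      seqs <- vapply(fam, function(f) {
        mutate_protein(roots[f], round(cfg$protein_length * frac_shared))
      }, character(1))
      recs[[sp]] <- data.frame(
        gene_id = sprintf("%s_CYP%03d", sp, seq_len(nsp)),
        species = sp, sequence = seqs, stringsAsFactors = FALSE)
    }
    # focal species: specific subfamily from its own root, the rest shared
    spec_root <- random_protein(cfg$protein_length)
    seqs <- character(length(focal_ids))
    names(seqs) <- focal_ids
    core_spec <- setdiff(specific_ids, tandem_pair[2])
    for (id in core_spec) {
      seqs[id] <- mutate_protein(spec_root,
                                 round(cfg$protein_length * 0.15))
    }
    seqs[tandem_pair[2]] <- copy_at_identity(seqs[tandem_pair[1]],
                                             cfg$tandem_pair_identity)
    rest <- setdiff(focal_ids, specific_ids)
    fam <- rep(seq_len(cfg$n_shared_families), length.out = length(rest))
    for (k in seq_along(rest)) {
      seqs[rest[k]] <- mutate_protein(
        roots[fam[k]], round(cfg$protein_length * frac_shared))
    }
    recs[[focal]] <- data.frame(gene_id = focal_ids, species = focal,
                                sequence = unname(seqs),
                                stringsAsFactors = FALSE)
    all <- do.call(rbind, recs)
    rownames(all) <- NULL
    list(proteins = protein_records(all$gene_id, all$species, all$sequence),
         truth = list(specific_gene_ids = specific_ids,
                      tandem_pair = tandem_pair))
  })
}
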