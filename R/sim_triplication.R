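#' Simulate a triplicated gene-order map with gene loss
#'
#' The reference genome is the ancestral gene order over
#' `cfg$n_chromosomes` chromosomes. The query genome carries three
#' homeologous copies of each reference chromosome (query chromosomes
#' suffixed `a`, `b`, `c`; gene ids suffixed `_a`, `_b`, `_c`), after which
#' each gene copy is lost independently with probability
#' `cfg$triplication_loss_fraction` and local windows of six query genes are
#' inverted with probability `cfg$inversion_rate`. Homology pairs link every
#' retained copy to its reference gene.
#'
#' @param cfg a [sim_config()]; `ancestral_gene_count` must be >= 50.
#' @return list with `ref` and `query` ([gene_order()] tables), `homologs`
#'   (data.frame `gene_a` = reference id, `gene_b` = query id) and `truth`
#'   (`ortho_groups`: reference id -> retained query ids; `multiplication`).
#' @export
gen_triplicated_map <- function(cfg) {
  validate_sim_config(cfg)
  if (cfg$ancestral_gene_count < 50) {
    stop("ancestral_gene_count must be >= 50", call. = FALSE)
  }
  n <- cfg$ancestral_gene_count
  chrom <- sort(rep_len(seq_len(cfg$n_chromosomes), n))
  ref_ids <- sprintf("AG%05d", seq_len(n))
  ref <- gene_order("reference", paste0("rchr", chrom), ref_ids)

  with_stream(cfg, 15L, {
    q_chrom <- character(0); q_ids <- character(0)
    for (c0 in seq_len(cfg$n_chromosomes)) {
      idx <- which(chrom == c0)
      for (copy in c("a", "b", "c")) {
        ids1 <- paste0(ref_ids[idx], "_", copy)
        keep <- stats::runif(length(ids1)) >= cfg$triplication_loss_fraction
        ids1 <- ids1[keep]
        # local inversions over windows of six retained genes
        if (length(ids1) >= 6 && cfg$inversion_rate > 0) {
          starts <- seq(1, length(ids1) - 5, by = 6)
          for (s in starts) {
            if (stats::runif(1) < cfg$inversion_rate) {
              ids1[s:(s + 5)] <- rev(ids1[s:(s + 5)])
            }
          }
        }
        q_chrom <- c(q_chrom, rep(paste0("qchr", c0, copy), length(ids1)))
        q_ids <- c(q_ids, ids1)
      }
    }
    query <- gene_order("query", q_chrom, q_ids)
    homologs <- data.frame(gene_a = sub("_[abc]$", "", q_ids),
                           gene_b = q_ids, stringsAsFactors = FALSE)
    ortho <- split(homologs$gene_b, homologs$gene_a)
    list(ref = ref, query = query, homologs = homologs,
         truth = list(ortho_groups = ortho, multiplication = 3L))
  })
}
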