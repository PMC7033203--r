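# Readers and writers for the plain-text interchange formats: TSV expression
# matrices and gene lengths, CSV peak tables, FASTA protein/CDS sets with
# species tags, TSV gene orders and homolog pairs, edge lists (TSV and SIF),
# Ks tables, block tables and the planted-truth manifest (JSON).

#' @export
#' @rdname expression_io
write_expression_tsv <- function(expr, values_path, lengths_path = NULL) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, values_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(lengths_path)) {
    utils::write.table(
      data.frame(gene_id = names(expr$gene_lengths),
                 length_bp = unname(expr$gene_lengths)),
      lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(values_path)
}

#' Expression matrix TSV round-trip
#'
#' The matrix TSV has a `gene_id` column then one column per sample; sample
#' ids encode `CC`/`CM` condition, time and replicate
#' (`CM_048_r2`) or a bare tissue label. Lengths travel in a two-column TSV.
#'
#' @param expr a [expression_matrix()] (writer).
#' @param values_path,lengths_path file paths.
#' @return the [expression_matrix()] (reader) or the path (writer,
#'   invisibly).
#' @export
#' @rdname expression_io
read_expression_tsv <- function(values_path, lengths_path) {
  df <- utils::read.delim(values_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$gene_id
  len <- utils::read.delim(lengths_path, stringsAsFactors = FALSE)
  gl <- stats::setNames(len$length_bp, len$gene_id)
  expression_matrix(vals, design_from_sample_ids(colnames(vals)), gl)
}

# Recover the sample design from encoded sample ids.
design_from_sample_ids <- function(ids) {
  tc <- grepl("^C[CM]_\\d+_r\\d+$", ids)
  cond <- ifelse(tc, ifelse(grepl("^CM", ids), "treated", "control"),
                 "tissue")
  time_h <- rep(NA_real_, length(ids))
  time_h[tc] <- as.numeric(sub("^C[CM]_(\\d+)_r\\d+$", "\\1", ids[tc]))
  rep <- rep(1L, length(ids))
  rep[tc] <- as.integer(sub("^.*_r(\\d+)$", "\\1", ids[tc]))
  data.frame(sample_id = ids, condition = cond, time_h = time_h,
             tissue = ifelse(tc, NA_character_, ids), replicate = rep,
             stringsAsFactors = FALSE)
}

#' Peak table CSV round-trip
#'
#' Columns: `peak_id,mz,rt,fragment_count`, then one intensity column per
#' sample.
#'
#' @param t a [peak_table()] (writer).
#' @param path file path.
#' @return the [peak_table()] (reader) or the path (writer, invisibly).
#' @export
#' @rdname peaks_io
write_peaks_csv <- function(t, path) {
  df <- cbind(t$peaks, as.data.frame(t$intensities, check.names = FALSE))
  utils::write.csv(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
#' @rdname peaks_io
read_peaks_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- df[, c("peak_id", "mz", "rt", "fragment_count")]
  intens <- as.matrix(df[, setdiff(names(df), names(meta)), drop = FALSE])
  rownames(intens) <- meta$peak_id
  peak_table(meta, intens, design_from_sample_ids(colnames(intens)))
}

#' Protein FASTA with species tags
#'
#' Headers are written as `>gene_id species=<label>`; the reader parses the
#' tag back (a missing tag yields species `NA`).
#'
#' @param proteins a [protein_records()] frame (writer).
#' @param path FASTA path.
#' @return [protein_records()] (reader) or the path (writer, invisibly).
#' @export
#' @rdname fasta_io
write_protein_fasta <- function(proteins, path) {
  seqs <- Biostrings::AAStringSet(proteins$sequence)
  names(seqs) <- paste0(proteins$gene_id, " species=", proteins$species)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @export
#' @rdname fasta_io
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  hdr <- names(seqs)
  id <- sub("\\s.*$", "", hdr)
  sp <- ifelse(grepl("species=", hdr),
               sub("^.*species=(\\S+).*$", "\\1", hdr), NA_character_)
  protein_records(id, sp, as.character(seqs))
}

#' Codon-pair alignments as interleaved FASTA
#'
#' Each pair occupies two records, `<pair_id>|a` and `<pair_id>|b`.
#'
#' @param pairs list of codon pairs (writer).
#' @param path FASTA path.
#' @return pair list (reader) or the path (writer, invisibly).
#' @export
#' @rdname pairs_io
write_codon_pairs_fasta <- function(pairs, path) {
  seqs <- unlist(lapply(pairs, function(p) {
    stats::setNames(c(p$seq_a, p$seq_b),
                    paste0(p$pair_id, "|", c("a", "b")))
  }))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @export
#' @rdname pairs_io
read_codon_pairs_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\|[ab]$", "", names(seqs))
  lapply(unique(ids), function(id) {
    list(pair_id = id,
         seq_a = as.character(seqs[[paste0(id, "|a")]]),
         seq_b = as.character(seqs[[paste0(id, "|b")]]))
  })
}

#' Gene-order and homolog-pair TSV round-trips
#'
#' Gene orders use columns `genome, chrom, rank, gene_id`; homolog pairs use
#' `gene_a, gene_b`.
#'
#' @param x a [gene_order()] table or homolog-pair data.frame (writers).
#' @param path file path.
#' @export
#' @rdname synteny_io
write_gene_order_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
#' @rdname synteny_io
read_gene_order_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- gene_order(df$genome[1], df$chrom, df$gene_id)
  if (!identical(out$rank, df$rank)) {
    stop("ranks in file are not consecutive within chromosomes",
         call. = FALSE)
  }
  out
}

#' @export
#' @rdname synteny_io
write_homologs_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
#' @rdname synteny_io
read_homologs_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Edge-list export: TSV and SIF
#'
#' The SIF export (`gene<TAB>pcc<TAB>metabolite`) is directly loadable by
#' Cytoscape.
#'
#' @param edges edge data.frame from [build_network()].
#' @param path file path.
#' @export
#' @rdname network_io
write_edges_tsv <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
#' @rdname network_io
write_edges_sif <- function(edges, path) {
  writeLines(paste(edges$gene_id, "pcc", edges$metabolite_id, sep = "\t"),
             path)
  invisible(path)
}

#' Planted-truth manifest (JSON)
#'
#' @param truth named list of planted ground truth.
#' @param path JSON path.
#' @export
#' @rdname truth_io
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @export
#' @rdname truth_io
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
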