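#' Expression matrix with sample design and gene lengths
#'
#' A genes x samples abundance table bundled with its sample design (condition,
#' time point, tissue, replicate) and per-gene transcript lengths. This is the
#' common currency of the expression-side operations (RPKM, differential
#' expression, tissue dominance, profile normalization).
#'
#' @param values numeric genes x samples matrix, finite and non-negative, with
#'   rownames (gene ids) and colnames (sample ids).
#' @param design data.frame with columns `sample_id`, `condition` (one of
#'   `"treated"`, `"control"`, `"tissue"`), `time_h` (NA for tissue samples),
#'   `tissue` (NA for time-course samples) and `replicate`.
#' @param gene_lengths named numeric vector of transcript lengths in bp, one
#'   positive entry per gene.
#' @return object of class `tf_expression`.
#' @export
expression_matrix <- function(values, design, gene_lengths) {
  stopifnot(is.matrix(values), is.data.frame(design))
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("values must have unique gene-id rownames", call. = FALSE)
  }
  if (!identical(colnames(values), as.character(design$sample_id))) {
    stop("column names must match design$sample_id in order", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("values must be finite and non-negative", call. = FALSE)
  }
  need <- c("sample_id", "condition", "time_h", "tissue", "replicate")
  if (!all(need %in% names(design))) {
    stop("design must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  gl <- gene_lengths[rownames(values)]
  if (any(is.na(gl)) || any(gl <= 0)) {
    stop("every gene needs a positive length", call. = FALSE)
  }
  structure(list(values = values, design = design,
                 gene_lengths = gl),
            class = "tf_expression")
}

#' @export
print.tf_expression <- function(x, ...) {
  cat("tf_expression:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  tab <- table(x$design$condition)
  cat("  samples:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' LC-MS peak table
#'
#' Feature-level LC-MS data: per-peak m/z, retention time and fragment count,
#' plus a peaks x samples intensity matrix sharing the sample design of the
#' expression data.
#'
#' @param peaks data.frame with columns `peak_id`, `mz` (Da, > 0), `rt`
#'   (minutes) and `fragment_count` (integer >= 0).
#' @param intensities numeric peaks x samples matrix (finite, >= 0) with
#'   rownames equal to `peaks$peak_id`.
#' @param design sample design data.frame as in [expression_matrix()].
#' @return object of class `tf_peaks`.
#' @export
peak_table <- function(peaks, intensities, design) {
  stopifnot(is.data.frame(peaks), is.matrix(intensities))
  need <- c("peak_id", "mz", "rt", "fragment_count")
  if (!all(need %in% names(peaks))) {
    stop("peaks must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(peaks$peak_id)) stop("duplicate peak ids", call. = FALSE)
  if (any(peaks$mz <= 0)) stop("mz must be positive", call. = FALSE)
  if (any(peaks$fragment_count < 0)) {
    stop("fragment_count must be >= 0", call. = FALSE)
  }
  if (nrow(peaks) > 0 &&
      !identical(rownames(intensities), as.character(peaks$peak_id))) {
    stop("intensity rownames must equal peaks$peak_id", call. = FALSE)
  }
  if (any(!is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  structure(list(peaks = peaks, intensities = intensities, design = design),
            class = "tf_peaks")
}

#' @export
print.tf_peaks <- function(x, ...) {
  cat("tf_peaks:", nrow(x$peaks), "peaks x", ncol(x$intensities),
      "samples\n")
  invisible(x)
}

# Subset a peak table by peak id, preserving structure.
subset_peaks <- function(t, keep_ids) {
  idx <- match(keep_ids, t$peaks$peak_id)
  peak_table(t$peaks[idx, , drop = FALSE],
             t$intensities[idx, , drop = FALSE],
             t$design)
}

#' Protein record set
#'
#' Amino-acid sequences with species labels, the substrate of the identity
#' classifier. Stored as a data.frame so that subsetting stays ordinary.
#'
#' @param gene_id character gene ids, unique within species.
#' @param species character species labels.
#' @param sequence character amino-acid strings (20 AA alphabet plus X).
#' @return data.frame of class `tf_proteins`.
#' @export
protein_records <- function(gene_id, species, sequence) {
  stopifnot(length(gene_id) == length(species),
            length(gene_id) == length(sequence))
  if (any(nchar(sequence) == 0)) stop("empty sequence", call. = FALSE)
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence)
  if (any(bad)) {
    stop("invalid residues in sequence(s): ",
         paste(gene_id[bad], collapse = ", "), call. = FALSE)
  }
  key <- paste(species, gene_id)
  if (anyDuplicated(key)) stop("duplicate (species, gene_id)", call. = FALSE)
  structure(data.frame(gene_id = gene_id, species = species,
                       sequence = sequence, stringsAsFactors = FALSE),
            class = c("tf_proteins", "data.frame"))
}

#' Gene-order table
#'
#' Per-chromosome ordered gene lists with 1-based consecutive ranks; the
#' substrate of collinearity-block detection.
#'
#' @param genome single genome label.
#' @param chrom character chromosome per gene.
#' @param gene_id unique gene ids.
#' @return data.frame of class `tf_gene_order` with columns `genome`,
#'   `chrom`, `rank`, `gene_id`; rank runs 1..n within each chromosome in
#'   input order.
#' @export
gene_order <- function(genome, chrom, gene_id) {
  if (anyDuplicated(gene_id)) stop("duplicate gene ids", call. = FALSE)
  rank <- stats::ave(seq_along(gene_id), chrom, FUN = seq_along)
  structure(data.frame(genome = genome, chrom = chrom, rank = rank,
                       gene_id = gene_id, stringsAsFactors = FALSE),
            class = c("tf_gene_order", "data.frame"))
}
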