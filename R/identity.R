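# Global protein alignment identity, the workhorse of the CYP classifier.
# Scoring: BLOSUM62, affine gaps (open 10, extend 1), true global (Needleman-
# Wunsch). Percent identity = matches / aligned columns excluding terminal-gap
# columns (BLAST-like for near-global homologs); coverage is role-specific.

.tf_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.tf_cache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .tf_cache$BLOSUM62 <- e$BLOSUM62
  }
  .tf_cache$BLOSUM62
}

check_protein <- function(seq, id = "sequence") {
  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWYX]", seq)
  if (bad > 0) {
    stop("invalid residue at position ", bad, " of ", id, call. = FALSE)
  }
  if (nchar(seq) < 10) {
    stop("sequence ", id, " shorter than 10 residues", call. = FALSE)
  }
  invisible(TRUE)
}

# Vectorized core: one query against many subjects, one alignment call.
# Returns a data.frame with percent_identity, query_coverage and
# alignment_length per subject.
align_identity <- function(query, subjects) {
  pats <- Biostrings::AAStringSet(rep(query, length(subjects)))
  subs <- Biostrings::AAStringSet(subjects)
  aln <- Biostrings::pairwiseAlignment(
    pattern = pats, subject = subs,
    substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 1, type = "global")
  pa <- as.character(Biostrings::pattern(aln))
  pb <- as.character(Biostrings::subject(aln))
  out <- mapply(function(a, b, qlen) {
    ca <- strsplit(a, "")[[1]]
    cb <- strsplit(b, "")[[1]]
    gap <- ca == "-" | cb == "-"
    ncol <- length(ca)
    i0 <- 1L
    while (i0 <= ncol && gap[i0]) i0 <- i0 + 1L
    i1 <- ncol
    while (i1 >= 1L && gap[i1]) i1 <- i1 - 1L
    if (i0 > i1) {
      return(c(identity = 0, coverage = 0, len = 0))
    }
    keep <- i0:i1
    matches <- sum(ca[keep] == cb[keep] & ca[keep] != "-")
    c(identity = 100 * matches / length(keep),
      coverage = 100 * sum(ca[keep] != "-") / qlen,
      len = length(keep))
  }, pa, pb, nchar(query), USE.NAMES = FALSE)
  data.frame(percent_identity = out["identity", ],
             query_coverage = out["coverage", ],
             alignment_length = as.integer(out["len", ]))
}

as_protein_df <- function(x) {
  if (inherits(x, "tf_proteins") || is.data.frame(x)) return(x)
  if (is.list(x) && !is.null(x$sequence)) {
    return(data.frame(gene_id = x$gene_id %||% "query",
                      species = x$species %||% NA_character_,
                      sequence = x$sequence, stringsAsFactors = FALSE))
  }
  stop("expected protein record(s)", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percent identity between two proteins by global alignment
#'
#' Aligns two amino-acid sequences globally (BLOSUM62, affine gaps) and
#' reports percent identity over aligned columns excluding terminal-gap
#' columns, query coverage, and alignment length. Identity is symmetric under
#' swapping the roles; coverage is computed on the query.
#'
#' @param a,b protein records: single rows of a [protein_records()] frame or
#'   lists with `gene_id` and `sequence`.
#' @return one-row data.frame (an identity hit): `query_id`, `subject_id`,
#'   `percent_identity`, `query_coverage`, `alignment_length`.
#' @export
pairwise_identity <- function(a, b) {
  a <- as_protein_df(a); b <- as_protein_df(b)
  check_protein(a$sequence[1], a$gene_id[1])
  check_protein(b$sequence[1], b$gene_id[1])
  st <- align_identity(a$sequence[1], b$sequence[1])
  data.frame(query_id = a$gene_id[1], subject_id = b$gene_id[1],
             percent_identity = st$percent_identity,
             query_coverage = st$query_coverage,
             alignment_length = st$alignment_length,
             stringsAsFactors = FALSE)
}

#' Homolog search by coverage and identity thresholds
#'
#' Scores every seed x target pair by global-alignment identity and keeps
#' hits with coverage of the seed at least `min_cov` percent and identity
#' strictly above `min_id` percent.
#'
#' @param seeds,targets [protein_records()] frames.
#' @param min_cov minimum percent coverage of the seed (inclusive).
#' @param min_id identity threshold, strict (`> min_id`).
#' @return data.frame of identity hits (possibly 0 rows).
#' @export
find_homologs <- function(seeds, targets, min_cov = 50, min_id = 50) {
  seeds <- as_protein_df(seeds); targets <- as_protein_df(targets)
  if (nrow(seeds) == 0 || nrow(targets) == 0) {
    stop("seed and target sets must be non-empty", call. = FALSE)
  }
  hits <- do.call(rbind, lapply(seq_len(nrow(seeds)), function(i) {
    st <- align_identity(seeds$sequence[i], targets$sequence)
    data.frame(query_id = seeds$gene_id[i], subject_id = targets$gene_id,
               percent_identity = st$percent_identity,
               query_coverage = st$query_coverage,
               alignment_length = st$alignment_length,
               stringsAsFactors = FALSE)
  }))
  hits[hits$query_coverage >= min_cov & hits$percent_identity > min_id, ,
       drop = FALSE]
}

#' Species-specific genes at an identity cutoff
#'
#' A focal-species gene is species-specific when its best global-alignment
#' identity to any protein of any other species is strictly below the cutoff
#' (55% marks separate CYP subfamily assignment).
#'
#' @param proteins a [protein_records()] frame with >= 2 species.
#' @param focal focal species label.
#' @param cutoff percent identity cutoff (strict `<`).
#' @return character vector of specific focal gene ids; the per-gene maximum
#'   cross-species identity is attached as the `max_xspecies_identity`
#'   attribute.
#' @export
species_specific <- function(proteins, focal, cutoff = 55) {
  proteins <- as_protein_df(proteins)
  if (length(unique(proteins$species)) < 2) {
    stop("need proteins from at least two species", call. = FALSE)
  }
  if (!focal %in% proteins$species) {
    stop("focal species '", focal, "' absent from protein set", call. = FALSE)
  }
  foc <- proteins[proteins$species == focal, , drop = FALSE]
  oth <- proteins[proteins$species != focal, , drop = FALSE]
  best <- vapply(seq_len(nrow(foc)), function(i) {
    max(align_identity(foc$sequence[i], oth$sequence)$percent_identity)
  }, numeric(1))
  names(best) <- foc$gene_id
  out <- foc$gene_id[best < cutoff]
  attr(out, "max_xspecies_identity") <- best
  out
}

#' Collapse near-duplicate proteins into representatives
#'
#' Single-linkage clusters over pairs with identity at or above the cutoff
#' (`>=`, per "97% identical"); each cluster is represented by its longest
#' sequence, ties broken by the lexicographically smallest gene id.
#'
#' @param genes a [protein_records()] frame.
#' @param cutoff percent identity at which two proteins are near-duplicates.
#' @return list with `representatives` (character ids) and `clusters`
#'   (named character: gene id -> representative id).
#' @export
collapse_near_duplicates <- function(genes, cutoff = 97) {
  genes <- as_protein_df(genes)
  n <- nrow(genes)
  if (n == 0) return(list(representatives = character(), clusters = character()))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      st <- align_identity(genes$sequence[i],
                           genes$sequence[(i + 1):n])
      for (k in which(st$percent_identity >= cutoff)) {
        ri <- find(i); rj <- find(i + k)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  reps <- vapply(split(seq_len(n), root), function(idx) {
    len <- nchar(genes$sequence[idx])
    cand <- idx[len == max(len)]
    cand[order(genes$gene_id[cand])][1]
  }, integer(1))
  rep_of <- stats::setNames(genes$gene_id[reps[as.character(root)]],
                            genes$gene_id)
  list(representatives = sort(unique(unname(rep_of))),
       clusters = rep_of)
}
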