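prot <- function(id, seq, sp = "X") list(gene_id = id, species = sp,
                                         sequence = seq)

test_that("pairwise identity handles trivial and boundary cases", {
  s <- random_aa(60)
  set.seed(51)
  hit <- pairwise_identity(prot("a", s), prot("b", s))
  expect_equal(hit$percent_identity, 100)
  expect_equal(hit$query_coverage, 100)
  h2 <- pairwise_identity(prot("a", "ACDEACDEAC"), prot("b", "ACDFACDEAC"))
  expect_equal(h2$percent_identity, 90)  # 9/10 matching columns, no gaps
  expect_error(pairwise_identity(prot("a", "ACDEZZZZZZ"), prot("b", s)),
               "position")
  expect_error(pairwise_identity(prot("a", "ACD"), prot("b", s)),
               "shorter")
})

test_that("identity equals an independent Gotoh DP oracle with the same scoring", {
  set.seed(52)
  # substitution-only pairs: unique gapless optimum, exact identity match
  for (k in 1:40) {
    len <- sample(20:60, 1)
    a <- random_aa(len)
    b <- mutate_aa(a, sample(1:round(len / 3), 1))
    got <- pairwise_identity(prot("a", a), prot("b", b))
    orc <- oracle_global_align(a, b)
    expect_equal(got$percent_identity, orc$identity, tolerance = 1e-9)
  }
  # indel pairs: optimal score must agree (co-optimal tracebacks may differ)
  for (k in 1:10) {
    len <- sample(30:50, 1)
    a <- random_aa(len)
    cut <- sample(5:(len - 10), 1)
    b <- paste0(substr(a, 1, cut), substr(a, cut + 4, len))
    b <- mutate_aa(b, 2)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = triptofunnel:::blosum62(),
      gapOpening = 10, gapExtension = 1, type = "global")
    expect_equal(Biostrings::score(aln), oracle_global_align(a, b)$score)
  }
})

test_that("identity is symmetric in the pair", {
  set.seed(53)
  for (k in 1:10) {
    a <- random_aa(40); b <- mutate_aa(random_aa(40), 5)
    expect_equal(pairwise_identity(prot("a", a), prot("b", b))$percent_identity,
                 pairwise_identity(prot("b", b), prot("a", a))$percent_identity,
                 tolerance = 1e-9)
  }
})

test_that("find_homologs applies >50% identity strictly and >=50% coverage", {
  set.seed(54)
  seed_seq <- random_aa(50)
  targets <- protein_records(
    c("self", "far"), c("T", "T"),
    c(seed_seq, random_aa(50)))
  seeds <- protein_records("seed", "S", seed_seq)
  hits <- find_homologs(seeds, targets, min_cov = 50, min_id = 50)
  expect_true("self" %in% hits$subject_id)
  expect_false("far" %in% hits$subject_id)
  # boundary: a pair at exactly the threshold identity is dropped
  half <- mutate_aa(seed_seq, 25)
  id_half <- pairwise_identity(prot("a", seed_seq), prot("b", half))
  hits2 <- find_homologs(seeds,
                         protein_records("half", "T", half),
                         min_cov = 0, min_id = id_half$percent_identity)
  expect_equal(nrow(hits2), 0)
  # kept set equals a brute-force threshold scan
  tg <- protein_records(sprintf("t%d", 1:8), rep("T", 8),
                        vapply(1:8, function(i) mutate_aa(seed_seq,
                                                          sample(2:30, 1)),
                               character(1)))
  hits3 <- find_homologs(seeds, tg, min_cov = 50, min_id = 50)
  brute <- vapply(seq_len(8), function(i) {
    h <- pairwise_identity(prot("seed", seed_seq), prot("t", tg$sequence[i]))
    h$query_coverage >= 50 && h$percent_identity > 50
  }, logical(1))
  expect_setequal(hits3$subject_id, tg$gene_id[brute])
})

test_that("species specificity is strict at the cutoff and monotone in it", {
  set.seed(55)
  base <- random_aa(80)
  pr <- protein_records(
    c("f_spec", "f_shared", "o1", "o2"),
    c("F", "F", "O", "O"),
    c(random_aa(80), mutate_aa(base, 8), base, mutate_aa(base, 10)))
  sp <- species_specific(pr, "F", 55)
  expect_true("f_spec" %in% sp)
  expect_false("f_shared" %in% sp)   # ~90% match cross-species
  best <- attr(sp, "max_xspecies_identity")
  expect_true(best[["f_shared"]] > 55)
  # monotone: raising the cutoff never shrinks the specific set
  for (cut in c(20, 40, 60, 80)) {
    lo <- species_specific(pr, "F", cut)
    hi <- species_specific(pr, "F", cut + 15)
    expect_true(all(lo %in% hi))
  }
  expect_error(species_specific(pr[pr$species == "F", ], "F"), "two species")
  expect_error(species_specific(pr, "Z"), "absent")
})

test_that("near-duplicate collapse equals transitive-closure clustering", {
  set.seed(56)
  base <- random_aa(60)
  # chain: a~b and b~c at >= 97%, d distinct -> {a,b,c} + {d}
  a <- base
  b <- mutate_aa(a, 1)
  c_ <- mutate_aa(b, 1)
  d <- random_aa(60)
  pr <- protein_records(c("a", "b", "c", "d"), rep("F", 4), c(a, b, c_, d))
  cl <- collapse_near_duplicates(pr, cutoff = 96)
  expect_length(cl$representatives, 2)
  expect_equal(unname(cl$clusters[["a"]]), unname(cl$clusters[["c"]]))
  expect_equal(unname(cl$clusters[["d"]]), "d")
  # all-distinct set collapses to itself
  pr2 <- protein_records(c("x", "y"), c("F", "F"),
                         c(random_aa(50), random_aa(50)))
  cl2 <- collapse_near_duplicates(pr2, 97)
  expect_setequal(cl2$representatives, c("x", "y"))
  # random clustered set vs an independent matrix-closure oracle
  seqs <- c(base, mutate_aa(base, 1), mutate_aa(base, 2),
            random_aa(60), random_aa(60))
  pr3 <- protein_records(sprintf("g%d", 1:5), rep("F", 5), seqs)
  n <- 5
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    id <- pairwise_identity(prot("i", seqs[i]), prot("j", seqs[j]))
    adj[i, j] <- adj[j, i] <- id$percent_identity >= 95
  }
  want <- oracle_closure_clusters(adj)
  cl3 <- collapse_near_duplicates(pr3, 95)
  got <- cl3$clusters[pr3$gene_id]
  expect_equal(length(unique(got)), length(unique(want)))
  expect_equal(as.integer(factor(got, levels = unique(got))),
               as.integer(factor(want, levels = unique(want))))
  # every input maps to exactly one representative
  expect_setequal(names(cl3$clusters), pr3$gene_id)
  expect_lte(length(cl3$representatives), nrow(pr3))
})
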