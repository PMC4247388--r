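test_that("self-alignment scores are maximal with identity and coverage 1", {
  hit <- score_pair("MKVLLW", "MKVLLW", mode = "protein")
  expect_equal(hit$identity, 1)
  expect_equal(hit$query_coverage, 1)
  worse <- score_pair("MKVLLW", "MKALLW", mode = "protein")
  expect_lt(worse$score, hit$score)
  expect_error(score_pair("MKV", "MKZ", mode = "protein"), "invalid for mode")
  expect_error(score_pair("MKV", "ACGT", mode = "nucleotide"), "invalid for mode")
  expect_error(score_pair("", "MKV"), "non-empty")
})

test_that("pairwise scores equal an independent affine-gap DP oracle", {
  set.seed(21)
  for (i in 1:20) {
    a <- random_protein(sample(10:60, 1))
    b <- random_protein(sample(10:60, 1))
    got <- score_pair(a, b, mode = "protein")$score
    want <- oracle_align_score(a, b, oracle_blosum62)
    expect_equal(got, want, label = sprintf("pair %d", i))
  }
})

test_that("best hits of a set against itself form the identity mapping", {
  set.seed(22)
  seqs <- tibble::tibble(id = paste0("p", 1:6),
                         seq = vapply(1:6, function(i) random_protein(40),
                                      character(1)))
  bh <- best_hits(seqs, seqs, mode = "protein")
  expect_identical(bh$subject_id, bh$query_id)
})

test_that("best hits ignore mutuality and are invariant to subject order", {
  # hand-scored 3x3 matrix: q1's best is s2, but s2's best is q3
  mat <- matrix(c(5, 9, 1,
                  2, 3, 8,
                  4, 10, 6), nrow = 3, byrow = TRUE,
                dimnames = list(c("q1", "q2", "q3"), c("s1", "s2", "s3")))
  bh <- orthoscan:::best_from_matrix(mat)
  expect_identical(bh$subject_id[bh$query_id == "q1"], "s2")
  perm <- mat[, c(3, 1, 2)]
  expect_identical(orthoscan:::best_from_matrix(perm), bh)
  # and the non-mutual query is absent from the reciprocal pairs
  rev_best <- orthoscan:::best_from_matrix(t(mat))
  expect_identical(rev_best$subject_id[rev_best$query_id == "s2"], "q3")
  mutual <- oracle_mutual_best(mat)
  expect_false("q1" %in% mutual$query)
})

test_that("a planted near-identical pair is the only reciprocal best hit", {
  set.seed(23)
  ref <- tibble::tibble(id = paste0("g", 1:5),
                        seq = vapply(1:5, function(i) random_protein(50),
                                     character(1)))
  member_seq <- ref$seq[3]
  substr(member_seq, 10, 10) <- "A"
  members <- tibble::tibble(
    id = c("tA", "tB", "tC"),
    seq = c(random_protein(50), member_seq, random_protein(50)))
  pairs <- reciprocal_best_pairs(ref, members, mode = "protein",
                                 species_id = "spX")
  expect_true(nrow(pairs) >= 1)
  expect_true(any(pairs$reference_gene_id == "g3" &
                    pairs$member_transcript_id == "tB"))
  # every emitted pair re-verifies as mutual under the independent oracle
  mat <- outer(seq_len(nrow(ref)), seq_len(nrow(members)),
               Vectorize(function(i, j) {
                 oracle_align_score(ref$seq[i], members$seq[j], oracle_blosum62)
               }))
  dimnames(mat) <- list(ref$id, members$id)
  mutual <- oracle_mutual_best(mat)
  expect_setequal(paste(pairs$reference_gene_id, pairs$member_transcript_id),
                  paste(mutual$query, mutual$subject))
})

test_that("set declaration requires a pair in every panel species", {
  panel <- paste0("sp", 1:10)
  pairs <- tidyr::expand_grid(reference_gene_id = c("gA", "gB"),
                              species_id = panel) |>
    dplyr::mutate(member_transcript_id = paste0(species_id, "_t")) |>
    dplyr::filter(!(reference_gene_id == "gB" & species_id == "sp10"))
  sets <- declare_ortholog_sets(pairs, panel)
  expect_identical(sets$status[sets$reference_gene_id == "gA"], "complete")
  expect_identical(sets$status[sets$reference_gene_id == "gB"], "incomplete")
  expect_identical(sets$missing_species[[which(sets$reference_gene_id == "gB")]],
                   "sp10")
})

test_that("complete-set counts equal the per-species intersection oracle", {
  set.seed(24)
  panel <- paste0("sp", 1:6)
  genes <- paste0("g", 1:30)
  pairs <- dplyr::bind_rows(lapply(panel, function(sp) {
    got <- sample(genes, sample(20:30, 1))
    tibble::tibble(reference_gene_id = got, species_id = sp,
                   member_transcript_id = paste0(sp, "_", got))
  }))
  sets <- declare_ortholog_sets(pairs, panel)
  want <- Reduce(intersect, lapply(panel, function(sp) {
    pairs$reference_gene_id[pairs$species_id == sp]
  }))
  expect_setequal(sets$reference_gene_id[sets$status == "complete"], want)
})

test_that("the start/stop fraction boundary at 80% is inclusive", {
  members <- tibble::tibble(
    species_id = paste0("sp", 1:10),
    seq = strrep("A", 300),
    has_start = c(rep(TRUE, 8), FALSE, FALSE),
    has_stop = TRUE)
  expect_true(refine_ortholog_set(members)$kept)
  members$has_start[8] <- FALSE   # 7/10
  rep7 <- refine_ortholog_set(members)
  expect_false(rep7$kept)
  expect_true(all(rep7$offending_members[[1]]$reason == "startstop"))
})

test_that("the length window [0.5, 1.5] x median is inclusive", {
  base <- tibble::tibble(species_id = paste0("sp", 1:9),
                         seq = strrep("A", 300),
                         has_start = TRUE, has_stop = TRUE)
  at_bound <- base
  at_bound$seq[9] <- strrep("A", 450)      # exactly 1.5 x median(300)
  expect_true(refine_ortholog_set(at_bound)$kept)
  above <- base
  above$seq[9] <- strrep("A", 453)         # 1.5 x median + 3 nt
  rep_above <- refine_ortholog_set(above)
  expect_false(rep_above$kept)
  off <- rep_above$offending_members[[1]]
  expect_identical(off$species_id, "sp9")
  expect_identical(off$reason, "length")
})

test_that("refinement equals an independently coded predicate on random sets", {
  set.seed(25)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    lens <- sample(60:600, n, replace = TRUE)
    members <- tibble::tibble(
      species_id = sample(paste0("sp", 1:n)),   # shuffled order
      seq = vapply(lens, function(l) strrep("A", l), character(1)),
      has_start = runif(n) < 0.85,
      has_stop = runif(n) < 0.85)
    got <- refine_ortholog_set(members)
    frac <- mean(members$has_start & members$has_stop)
    med <- median(nchar(members$seq))
    want <- frac >= 0.8 &&
      all(nchar(members$seq) >= 0.5 * med & nchar(members$seq) <= 1.5 * med)
    expect_identical(got$kept, want, label = sprintf("set %d", i))
  }
})

test_that("annotation assignment applies the strict identity/coverage rule", {
  hit <- function(id, idy, cov, ev) {
    tibble::tibble(query_id = "pep1", subject_id = id, score = 100,
                   identity = idy, query_coverage = cov, evalue = ev)
  }
  expect_true(assign_reference_protein(hit("r1", 0.51, 0.76, 1e-6))$assigned)
  expect_false(assign_reference_protein(hit("r1", 0.50, 0.90, 1e-6))$assigned)
  expect_false(assign_reference_protein(hit("r1", 0.90, 0.75, 1e-6))$assigned)
  expect_false(assign_reference_protein(hit("r1", 0.90, 0.90, 1e-4))$assigned)
  # best eligible hit wins by score
  hits <- dplyr::bind_rows(
    tibble::tibble(query_id = "pep1", subject_id = "rA", score = 80,
                   identity = 0.9, query_coverage = 0.9, evalue = 1e-10),
    tibble::tibble(query_id = "pep1", subject_id = "rB", score = 120,
                   identity = 0.6, query_coverage = 0.8, evalue = 1e-8))
  expect_identical(assign_reference_protein(hits)$reference_id, "rB")
})

test_that("tabular hits ingest with identity rescaling and bit-score best hits", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "pep1\trefA\t95.0\t100\t5\t0\t1\t100\t1\t100\t1e-50\t200",
    "pep1\trefB\t80.0\t100\t20\t0\t1\t100\t1\t100\t1e-30\t150",
    "pep2\trefC\t60.0\t50\t20\t1\t1\t50\t1\t50\t1e-10\t90"), path)
  hits <- read_tabular_hits(path, query_lengths = c(pep1 = 100, pep2 = 80))
  expect_equal(hits$identity, c(0.95, 0.80, 0.60))
  expect_equal(hits$query_coverage, c(1, 1, 50 / 80))
  bh <- best_hits_from_table(hits)
  expect_identical(bh$subject_id[bh$query_id == "pep1"], "refA")
})

test_that("zero-corruption synthetic sets survive the full pipeline; a 0.4 truncation is dropped for length", {
  tree <- "((sp01:0.05,sp02:0.05):0.03,(sp03:0.05,sp04:0.05):0.03);"
  genes <- paste0("g", 1:3)
  refs <- list(); all_transcripts <- list(); cds_members <- list()
  for (g in genes) {
    root <- random_root_cds(80, seed = derive_seed(30, g))
    ev <- evolve_cds(root, tree, rate = 0.3, seed = 31, gene_id = g)
    refs[[g]] <- tibble::tibble(id = g, seq = root)
    # one member of g2 truncated to 40% of its length; everything else clean
    member_cds <- ev$cds
    truncated <- g == "g2" & member_cds$species_id == "sp04"
    member_cds$seq[truncated] <-
      substr(member_cds$seq[truncated], 1,
             floor(0.4 * nchar(member_cds$seq[truncated])))
    mk <- make_transcripts(ev$cds, seed = 32, gene_id = g)
    mk$transcripts$seq[mk$transcripts$species_id == "sp04" & g == "g2"] <-
      paste0("TAA", member_cds$seq[truncated])
    all_transcripts[[g]] <- mk$transcripts
    cds_members[[g]] <- tibble::tibble(
      reference_gene_id = g,
      species_id = member_cds$species_id,
      seq = member_cds$seq,
      has_start = TRUE,
      has_stop = !truncated)
  }
  ref_tbl <- dplyr::bind_rows(refs)
  pairs <- dplyr::bind_rows(lapply(paste0("sp0", 1:4), function(sp) {
    members <- dplyr::bind_rows(all_transcripts) |>
      dplyr::filter(species_id == sp)
    reciprocal_best_pairs(ref_tbl,
                          dplyr::transmute(members, id = transcript_id, seq = seq),
                          mode = "nucleotide", species_id = sp)
  }))
  sets <- declare_ortholog_sets(pairs, paste0("sp0", 1:4))
  expect_true(all(sets$status == "complete"))
  reports <- refine_ortholog_set(dplyr::bind_rows(cds_members))
  expect_true(reports$kept[reports$reference_gene_id == "g1"])
  expect_true(reports$kept[reports$reference_gene_id == "g3"])
  g2 <- reports[reports$reference_gene_id == "g2", ]
  expect_false(g2$kept)
  expect_true(any(g2$offending_members[[1]]$reason == "length"))
})
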