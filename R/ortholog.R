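# Ortholog-set construction: deterministic pairwise similarity scoring,
# bidirectional best hits against a reference gene set, declaration of
# cross-species ortholog sets, and the two refinement filters (start/stop
# presence in at least 80% of members; member length within +/-50% of the
# set median). An ingest path for 12-column tabular search output covers
# the case where similarity hits come from an external engine; the
# decision rules applied downstream are identical for either source.

# Protein pairs (comparable lengths) are scored by global alignment
# with BLOSUM62; nucleotide scoring is ends-free ("overlap"), the right
# shape for a coding sequence matched against a transcript that carries
# UTRs, and plays the role of the seed-and-extend engines it stands in
# for. Both are symmetric in their arguments.
aln_params <- function(mode) {
  if (mode == "protein") {
    utils::data("BLOSUM62", package = "Biostrings", envir = environment())
    list(mat = get("BLOSUM62", envir = environment()),
         gap_open = 10, gap_ext = 4, type = "global")
  } else {
    list(mat = Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3),
         gap_open = 10, gap_ext = 4, type = "overlap")
  }
}

as_stringset <- function(seqs, mode) {
  if (mode == "protein") Biostrings::AAStringSet(seqs)
  else Biostrings::DNAStringSet(seqs)
}

check_mode_alphabet <- function(seqs, mode) {
  ok <- if (mode == "nucleotide") "ACGTN" else
    paste0(names(residue_groups()) |> paste(collapse = ""), "X")
  bad <- gsub(sprintf("[%s]", ok), "", toupper(seqs))
  if (any(nzchar(bad))) {
    abort(sprintf("sequence contains characters invalid for mode '%s': '%s'",
                  mode, substr(bad[nzchar(bad)][1], 1, 10)))
  }
  invisible(TRUE)
}

#' Score one sequence pair by global alignment
#'
#' Affine-gap dynamic-programming alignment: global (Needleman-Wunsch,
#' BLOSUM62) for proteins, ends-free overlap alignment (match +2 /
#' mismatch -3) for nucleotides, gap opening 10 and extension 4 in both
#' modes. Identity is matches divided by alignment columns; query
#' coverage is the fraction of query residues aligned opposite a
#' subject residue (not a gap).
#'
#' @param a Query sequence (character scalar).
#' @param b Subject sequence.
#' @param mode `"protein"` or `"nucleotide"`.
#' @return A one-row tibble: `score`, `identity`, `query_coverage`,
#'   `alignment_length`.
#' @export
#' @examples
#' score_pair("MKV", "MAV", mode = "protein")
score_pair <- function(a, b, mode = c("protein", "nucleotide")) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) abort("sequences must be non-empty")
  a <- toupper(a); b <- toupper(b)
  check_mode_alphabet(c(a, b), mode)
  p <- aln_params(mode)
  pa <- Biostrings::pairwiseAlignment(
    as_stringset(a, mode), as_stringset(b, mode)[[1]],
    substitutionMatrix = p$mat, gapOpening = p$gap_open,
    gapExtension = p$gap_ext, type = p$type)
  ncol_aln <- nchar(as.character(Biostrings::alignedPattern(pa)))
  matches <- Biostrings::nmatch(pa)
  aligned_query <- matches + Biostrings::nmismatch(pa)
  tibble(
    score = as.numeric(Biostrings::score(pa)),
    identity = matches / ncol_aln,
    query_coverage = aligned_query / nchar(a),
    alignment_length = ncol_aln
  )
}

# Full score matrix queries x subjects using one vectorised alignment
# call per subject. Global alignment scores are symmetric, so callers
# reuse one matrix for both search directions.
score_matrix <- function(queries, subjects, mode) {
  check_mode_alphabet(c(queries$seq, subjects$seq), mode)
  p <- aln_params(mode)
  qset <- as_stringset(setNames(queries$seq, queries$id), mode)
  mat <- matrix(NA_real_, nrow(queries), nrow(subjects),
                dimnames = list(queries$id, subjects$id))
  for (j in seq_len(nrow(subjects))) {
    mat[, j] <- Biostrings::pairwiseAlignment(
      qset, as_stringset(subjects$seq[j], mode)[[1]],
      substitutionMatrix = p$mat, gapOpening = p$gap_open,
      gapExtension = p$gap_ext, type = p$type, scoreOnly = TRUE)
  }
  mat
}

best_from_matrix <- function(mat) {
  # highest score per row; ties -> lexicographically smaller subject id
  subj_order <- order(colnames(mat))
  m <- mat[, subj_order, drop = FALSE]
  idx <- apply(m, 1L, which.max)
  tibble(
    query_id = rownames(mat),
    subject_id = colnames(m)[idx],
    score = m[cbind(seq_len(nrow(m)), idx)]
  )
}

#' Best similarity hit per query
#'
#' Each query maps to its single highest-scoring subject under the
#' deterministic global-alignment scorer; ties break to the
#' lexicographically smaller subject id. Mutuality is *not* checked
#' here — see [reciprocal_best_pairs()].
#'
#' @param queries,subjects Tibbles with columns `id` and `seq`.
#' @param mode `"protein"` or `"nucleotide"`.
#' @return A tibble `query_id`, `subject_id`, `score`.
#' @export
best_hits <- function(queries, subjects, mode = c("protein", "nucleotide")) {
  mode <- match.arg(mode)
  if (!nrow(queries) || !nrow(subjects)) abort("empty query or subject set")
  best_from_matrix(score_matrix(queries, subjects, mode))
}

#' Reciprocal (bidirectional) best-hit ortholog pairs
#'
#' A pair is declared between a reference gene and one species' member
#' sequence exactly when each is the other's best hit. Since the global
#' alignment score is symmetric, one all-vs-all score matrix serves both
#' directions.
#'
#' @param ref A tibble of reference sequences (`id`, `seq`).
#' @param members A tibble of one species' sequences (`id`, `seq`).
#' @param mode `"protein"` or `"nucleotide"`.
#' @param species_id Optional species label carried into the output.
#' @return A tibble `reference_gene_id`, `member_transcript_id`,
#'   `species_id`, `score`, sorted by `reference_gene_id`.
#' @export
reciprocal_best_pairs <- function(ref, members,
                                  mode = c("protein", "nucleotide"),
                                  species_id = NA_character_) {
  mode <- match.arg(mode)
  if (!nrow(ref) || !nrow(members)) abort("empty reference or member set")
  mat <- score_matrix(ref, members, mode)
  fwd <- best_from_matrix(mat)
  rev <- best_from_matrix(t(mat))
  rev_best <- setNames(rev$subject_id, rev$query_id)
  mutual <- fwd[rev_best[fwd$subject_id] == fwd$query_id, ]
  tibble(
    reference_gene_id = mutual$query_id,
    member_transcript_id = mutual$subject_id,
    species_id = species_id,
    score = mutual$score
  ) |> arrange(.data$reference_gene_id)
}

#' Read 12-column tabular similarity hits
#'
#' Reads the standard tab-separated search output
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore`). Percent identity is rescaled to a fraction;
#' query coverage is computed when query lengths are supplied.
#'
#' @param path Path to the tabular file (no header).
#' @param query_lengths Optional named vector of query lengths used to
#'   derive `query_coverage = (qend - qstart + 1) / length`.
#' @return A tibble with the 12 standard columns plus `identity` and
#'   (optionally) `query_coverage`.
#' @export
read_tabular_hits <- function(path, query_lengths = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  hits <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE)
  hits <- mutate(hits, identity = .data$pident / 100)
  if (!is.null(query_lengths)) {
    hits <- mutate(hits, query_coverage =
                     (abs(.data$qend - .data$qstart) + 1) /
                     unname(query_lengths[.data$qseqid]))
  }
  hits
}

#' Best hits from a precomputed hit table
#'
#' Applies the same per-query best-hit rule as [best_hits()] to an
#' external hit table, ranking by descending bit score with ties to the
#' lexicographically smaller subject id.
#'
#' @param hits A tibble with at least `qseqid`, `sseqid`, `bitscore`.
#' @return A tibble `query_id`, `subject_id`, `score`.
#' @export
best_hits_from_table <- function(hits) {
  hits |>
    group_by(.data$qseqid) |>
    arrange(desc(.data$bitscore), .data$sseqid, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    dplyr::transmute(query_id = .data$qseqid, subject_id = .data$sseqid,
                     score = .data$bitscore)
}

#' Declare ortholog sets across a species panel
#'
#' A reference gene attains a *complete* ortholog set exactly when a
#' reciprocal-best-hit pair exists for every species in the panel.
#' Incomplete sets are retained with their status for reporting.
#'
#' @param pairs A tibble of pairs across species (`reference_gene_id`,
#'   `species_id`, `member_transcript_id`).
#' @param panel Character vector of species ids required for
#'   completeness.
#' @return A tibble `reference_gene_id`, `n_species`, `status`
#'   (`"complete"`/`"incomplete"`), `missing_species` (list column).
#' @export
declare_ortholog_sets <- function(pairs, panel) {
  stopifnot(length(panel) > 0)
  pairs |>
    group_by(.data$reference_gene_id) |>
    summarise(
      n_species = dplyr::n_distinct(.data$species_id),
      missing_species = list(setdiff(panel, .data$species_id)),
      .groups = "drop") |>
    mutate(status = ifelse(lengths(.data$missing_species) == 0L,
                           "complete", "incomplete")) |>
    select("reference_gene_id", "n_species", "status", "missing_species") |>
    arrange(.data$reference_gene_id)
}

refine_one <- function(members, min_startstop_frac, length_window) {
  frac <- mean(members$has_start & members$has_stop)
  med <- median(nchar(members$seq))
  lo <- (1 - length_window) * med
  hi <- (1 + length_window) * med
  off_ss <- members$species_id[!(members$has_start & members$has_stop)]
  len <- nchar(members$seq)
  off_len <- members$species_id[len < lo | len > hi]
  offending <- bind_rows(
    tibble(species_id = off_ss, reason = rep("startstop", length(off_ss))),
    tibble(species_id = off_len, reason = rep("length", length(off_len))))
  tibble(
    kept = frac >= min_startstop_frac && length(off_len) == 0L,
    startstop_fraction = frac,
    median_length = med,
    offending_members = list(offending)
  )
}

#' Apply the two ortholog-set refinement filters
#'
#' A set is kept when (a) at least 80% of member sequences carry both a
#' start and a stop codon, and (b) every member length lies within
#' +/-50% of the median member length (nucleotides; bounds inclusive,
#' median of an even count is the mean of the two central values).
#' Members violating either predicate are listed with the reason
#' (`"startstop"` or `"length"`).
#'
#' @param members A tibble with columns `species_id`, `seq`,
#'   `has_start`, `has_stop` — one ortholog set — or, with a
#'   `reference_gene_id` column, many sets at once.
#' @param min_startstop_frac Start/stop fraction threshold (default
#'   0.8, inclusive).
#' @param length_window Half-width of the relative length window
#'   (default 0.5, i.e. `[0.5, 1.5] * median`, inclusive).
#' @return A tibble with one row per set: `kept`,
#'   `startstop_fraction`, `median_length`, `offending_members` (list
#'   column of tibbles), preceded by `reference_gene_id` when present.
#' @export
refine_ortholog_set <- function(members, min_startstop_frac = 0.8,
                                length_window = 0.5) {
  needed <- c("species_id", "seq", "has_start", "has_stop")
  if (!all(needed %in% names(members))) {
    abort(paste("members needs columns", paste(needed, collapse = ", ")))
  }
  if ("reference_gene_id" %in% names(members)) {
    return(
      members |>
        dplyr::group_split(.data$reference_gene_id) |>
        purrr::map(function(g) {
          dplyr::bind_cols(
            tibble(reference_gene_id = g$reference_gene_id[1]),
            refine_one(g, min_startstop_frac, length_window))
        }) |>
        bind_rows() |>
        arrange(.data$reference_gene_id))
  }
  refine_one(members, min_startstop_frac, length_window)
}

#' Assign candidate peptides to reference proteins from a hit table
#'
#' Per peptide, the highest-scoring hit is accepted when it clears an
#' E-value cut-off of `1e-5` (when an `evalue` column is present),
#' exceeds 50% overall amino-acid identity and spans more than 75% of
#' the query length; otherwise the peptide is left unassigned. The
#' identity and coverage inequalities are strict.
#'
#' @param hits A tibble with `query_id`, `subject_id`, `score`,
#'   `identity`, `query_coverage` and optionally `evalue`.
#' @param max_evalue E-value cut-off (default `1e-5`, inclusive).
#' @param min_identity Identity threshold (default 0.5, exclusive).
#' @param min_coverage Query-coverage threshold (default 0.75,
#'   exclusive).
#' @return A tibble `query_id`, `reference_id` (`NA` when unassigned),
#'   `assigned`.
#' @export
assign_reference_protein <- function(hits, max_evalue = 1e-5,
                                     min_identity = 0.5, min_coverage = 0.75) {
  stopifnot(all(c("query_id", "subject_id", "score", "identity",
                  "query_coverage") %in% names(hits)))
  eligible <- hits |>
    filter(.data$identity > min_identity,
           .data$query_coverage > min_coverage)
  if ("evalue" %in% names(hits)) {
    eligible <- filter(eligible, .data$evalue <= max_evalue)
  }
  best <- eligible |>
    group_by(.data$query_id) |>
    arrange(desc(.data$score), .data$subject_id, .by_group = TRUE) |>
    slice(1L) |>
    ungroup() |>
    select("query_id", reference_id = "subject_id")
  tibble(query_id = unique(hits$query_id)) |>
    left_join(best, by = "query_id") |>
    mutate(assigned = !is.na(.data$reference_id))
}
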