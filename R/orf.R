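# Reference-ORF construction: six-frame complete-ORF search and the
# representative-coding-sequence rule (longest transcript first, then
# longest complete ORF within it).

orfs_one_strand <- function(seq, strand, min_protein_len) {
  n <- nchar(seq)
  tab <- codon_table()
  out <- vector("list", 3L)
  for (frame in 0:2) {
    n_codon <- (n - frame) %/% 3L
    if (n_codon < 2L) next
    starts_nt <- frame + seq(1L, by = 3L, length.out = n_codon)
    codons <- substring(seq, starts_nt, starts_nt + 2L)
    is_start <- codons == START_CODON            # N-containing codons fail both
    is_stop <- codons %in% STOP_CODONS
    si <- which(is_start)
    ti <- which(is_stop)
    if (!length(si) || !length(ti)) next
    # next in-frame stop at or after each start
    nxt <- ti[findInterval(si - 1L, ti) + 1L]
    ok <- !is.na(nxt)
    si <- si[ok]; nxt <- nxt[ok]
    plen <- nxt - si                             # protein length in aa
    keep <- plen >= min_protein_len
    if (!any(keep)) next
    si <- si[keep]; nxt <- nxt[keep]; plen <- plen[keep]
    aa <- unname(tab[codons])
    aa[is.na(aa)] <- "X"
    out[[frame + 1L]] <- tibble(
      start = starts_nt[si] - 1L,                # 0-based
      end = starts_nt[nxt] + 2L,                 # half-open, includes stop
      frame = frame,
      strand = strand,
      length_nt = starts_nt[nxt] + 2L - (starts_nt[si] - 1L),
      protein = vapply(seq_along(si), function(k) {
        paste(aa[si[k]:(nxt[k] - 1L)], collapse = "")
      }, character(1))
    )
  }
  bind_rows(out)
}

#' Find all complete open reading frames in six frames
#'
#' A complete ORF runs from an `ATG` to the next in-frame stop codon.
#' Both strands are scanned; any codon containing `N` is treated as
#' neither start nor stop and translates to `X`. Coordinates are 0-based
#' half-open on the strand the ORF is read from (`strand = "-"` means
#' coordinates on the reverse complement of the input), and the interval
#' includes the stop codon.
#'
#' @param seq A DNA character scalar over `{A,C,G,T,N}`.
#' @param min_protein_len Minimum protein length in residues (stop
#'   excluded), >= 1.
#' @return A tibble with columns `start`, `end`, `frame`, `strand`,
#'   `length_nt`, `protein`, sorted by decreasing length then
#'   `(strand, start)`. Zero rows if no ORF qualifies.
#' @export
#' @examples
#' find_orfs("ATGAAATAG", min_protein_len = 1)
find_orfs <- function(seq, min_protein_len = 100L) {
  empty <- tibble(start = integer(), end = integer(), frame = integer(),
                  strand = character(), length_nt = integer(),
                  protein = character())
  if (!nzchar(seq)) return(empty)
  seq <- check_dna(seq)
  stopifnot(min_protein_len >= 1)
  fwd <- orfs_one_strand(seq, "+", min_protein_len)
  rev <- orfs_one_strand(reverse_complement(seq), "-", min_protein_len)
  out <- bind_rows(fwd, rev)
  if (!nrow(out)) return(empty)
  arrange(out, desc(.data$length_nt), .data$strand, .data$start)
}

#' Select the representative (reference) ORF for a gene
#'
#' Among a gene's transcripts the longest transcript (in nucleotides) is
#' kept — transcript length, not ORF length, picks the representative —
#' and the longest complete ORF within it becomes the reference ORF.
#' Ties on transcript length go to the lexicographically smaller
#' transcript id; ties on ORF length to the smaller start coordinate,
#' then the `+` strand. A gene whose chosen transcript holds no complete
#' ORF of the minimum length yields a rejection row, not an error.
#'
#' @param gene_id Gene identifier carried into the output.
#' @param transcripts A tibble with columns `transcript_id` and `seq`
#'   (at least one row).
#' @param min_protein_len Minimum protein length in residues.
#' @return A one-row tibble: `gene_id`, `transcript_id`, `status`
#'   (`"ok"` or `"rejected"`), `reason` (`NA` when ok), `start`, `end`,
#'   `strand`, `nucleotide_seq`, `protein_seq`. The emitted coding
#'   sequence always satisfies the codon invariants of [validate_cds()].
#' @export
select_reference_orf <- function(gene_id, transcripts, min_protein_len = 100L) {
  if (!nrow(transcripts)) abort("at least one transcript is required")
  tr <- arrange(transcripts, desc(nchar(.data$seq)), .data$transcript_id)
  chosen <- tr[1L, ]
  orfs <- find_orfs(chosen$seq, min_protein_len)
  rejection <- function(reason) {
    tibble(gene_id = gene_id, transcript_id = chosen$transcript_id,
           status = "rejected", reason = reason,
           start = NA_integer_, end = NA_integer_, strand = NA_character_,
           nucleotide_seq = NA_character_, protein_seq = NA_character_)
  }
  if (!nrow(orfs)) return(rejection("no complete ORF"))
  best <- arrange(orfs, desc(.data$length_nt), .data$start, .data$strand)[1L, ]
  template <- if (best$strand == "+") toupper(chosen$seq) else
    reverse_complement(chosen$seq)
  nt <- substr(template, best$start + 1L, best$end)
  validate_cds(nt)
  tibble(gene_id = gene_id, transcript_id = chosen$transcript_id,
         status = "ok", reason = NA_character_,
         start = best$start, end = best$end, strand = best$strand,
         nucleotide_seq = nt, protein_seq = best$protein)
}

#' Select reference ORFs for many genes at once
#'
#' @param transcripts A tibble with columns `gene_id`, `transcript_id`,
#'   `seq`.
#' @param min_protein_len Minimum protein length in residues.
#' @return A tibble with one row per gene, as in
#'   [select_reference_orf()].
#' @export
select_reference_orfs <- function(transcripts, min_protein_len = 100L) {
  transcripts |>
    dplyr::group_split(.data$gene_id) |>
    purrr::map(function(g) {
      select_reference_orf(g$gene_id[1], g, min_protein_len)
    }) |>
    bind_rows() |>
    arrange(.data$gene_id)
}
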