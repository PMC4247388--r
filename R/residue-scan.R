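# Lineage-unique residue scanning: find alignment columns where the
# focal species carries a residue whose chemical class (acidic, basic,
# cysteine, other) is absent from every informative residue of all the
# other species, and report each call with a reference-protein
# coordinate and a compact change string such as "STQ174R".

#' Classify residues into the four-group chemical model
#'
#' @param aa Character vector of single residues (upper case).
#' @param model A residue-to-group mapping, default [residue_groups()].
#' @return Character vector of group names. Gaps, `X` or non-standard
#'   characters raise an error; callers are expected to pre-filter.
#' @export
#' @examples
#' classify_residue(c("E", "K", "C", "W"))
classify_residue <- function(aa, model = residue_groups()) {
  out <- unname(model[aa])
  if (anyNA(out)) {
    bad <- unique(aa[is.na(out)])
    abort(sprintf("cannot classify non-standard residue(s): %s",
                  paste(bad, collapse = ", ")))
  }
  out
}

aln_to_matrix <- function(aln) {
  if (!all(c("species_id", "seq") %in% names(aln))) {
    abort("alignment needs columns species_id, seq")
  }
  lens <- nchar(aln$seq)
  if (length(unique(lens)) != 1L) abort("aligned rows must have equal length")
  mat <- do.call(rbind, strsplit(toupper(aln$seq), ""))
  rownames(mat) <- aln$species_id
  mat
}

#' Map an alignment column to a 1-based reference-protein position
#'
#' The reference position of a column is the count of non-gap reference
#' residues in columns up to and including it (so positions follow the
#' reference species' ungapped protein, the convention used for
#' human-protein numbering of reported sites).
#'
#' @param aln An aligned tibble (`species_id`, `seq`).
#' @param column 0-based alignment column.
#' @param reference Reference species id.
#' @return 1-based integer position. The reference must be non-gap at
#'   the column.
#' @export
#' @examples
#' aln <- tibble::tibble(species_id = "ref", seq = "M-KV")
#' map_to_reference_position(aln, 2, "ref")
map_to_reference_position <- function(aln, column, reference) {
  mat <- aln_to_matrix(aln)
  if (!reference %in% rownames(mat)) abort("reference species not in alignment")
  row <- mat[reference, ]
  if (column < 0 || column >= length(row)) abort("column out of range")
  if (row[column + 1L] == "-") {
    abort("reference species has a gap at the requested column")
  }
  sum(row[seq_len(column + 1L)] != "-")
}

#' Format a compact change string
#'
#' Concatenates the distinct residues seen in the other species —
#' ordered by descending frequency among informative others, ties
#' alphabetical — then the 1-based reference position, then the focal
#' residue: e.g. `"STQ174R"`.
#'
#' @param others Character vector (multiset) of the other species'
#'   informative residues at the column.
#' @param position 1-based reference position.
#' @param focal Focal residue.
#' @return The change string.
#' @export
#' @examples
#' format_change_string(c("S", "S", "T", "T", "Q"), 174, "R")
format_change_string <- function(others, position, focal) {
  if (!length(others)) abort("others must be non-empty")
  tab <- table(others)
  ord <- names(tab)[order(-as.integer(tab), names(tab))]
  paste0(paste(ord, collapse = ""), position, focal)
}

#' Parse a change string back into its parts
#'
#' Inverse of [format_change_string()] up to residue multiplicity.
#'
#' @param x Change string such as `"STQ174R"`.
#' @return A list with `others` (distinct residues, in string order),
#'   `position` and `focal`.
#' @export
parse_change_string <- function(x) {
  m <- regmatches(x, regexec("^([A-Z]+)([0-9]+)([A-Z])$", x))[[1]]
  if (length(m) != 4L) abort(sprintf("malformed change string '%s'", x))
  list(others = strsplit(m[2], "")[[1]],
       position = as.integer(m[3]),
       focal = m[4])
}

#' Scan an alignment for lineage-unique cross-group residues
#'
#' Emits one call per alignment column where (a) the focal species
#' carries a standard residue, (b) at least `min_informative_others`
#' other species carry informative (non-gap, non-`X`) residues, (c) the
#' focal residue's chemical group is absent from every informative
#' other residue, and (d) the reference species is non-gap at the
#' column. Gaps among the other species are ignored; `X` is ignored
#' under `treat_x = "ignore"` or disqualifies the column under
#' `"disqualify"`. A focal gap or `X` skips the column.
#'
#' @param aln An aligned tibble (`species_id`, `seq`), equal-length
#'   rows over the 20 residues, `-` and `X`.
#' @param focal Focal species id.
#' @param reference Reference species id used for coordinate reporting
#'   (may equal `focal`).
#' @param min_informative_others Minimum informative other residues per
#'   column (default 30).
#' @param treat_x `"ignore"` (default) or `"disqualify"`.
#' @param model Residue-group model, default [residue_groups()].
#' @return A tibble sorted by column: `column` (0-based),
#'   `reference_position` (1-based), `focal_residue`, `focal_group`,
#'   `others_residues` (list column of the informative multiset),
#'   `others_groups` (collapsed, sorted, `/`-separated),
#'   `n_informative`, `change_string`.
#' @export
scan_alignment <- function(aln, focal, reference = focal,
                           min_informative_others = 30L,
                           treat_x = c("ignore", "disqualify"),
                           model = residue_groups()) {
  treat_x <- match.arg(treat_x)
  stopifnot(min_informative_others >= 1)
  mat <- aln_to_matrix(aln)
  for (sp in c(focal, reference)) {
    if (!sp %in% rownames(mat)) {
      abort(sprintf("species '%s' not in alignment", sp))
    }
  }
  focal_row <- mat[focal, ]
  ref_row <- mat[reference, ]
  others <- mat[setdiff(rownames(mat), focal), , drop = FALSE]
  n_col <- ncol(mat)
  ref_pos <- cumsum(ref_row != "-")

  group_of <- function(x) unname(model[x])   # NA for gap/X
  focal_groups <- group_of(focal_row)

  calls <- vector("list", n_col)
  for (j in seq_len(n_col)) {
    fg <- focal_groups[j]
    if (is.na(fg)) next                       # focal gap/X/non-standard
    if (ref_row[j] == "-") next
    col <- others[, j]
    if (treat_x == "disqualify" && any(col == "X")) next
    informative <- col[col != "-" & col != "X"]
    if (length(informative) < min_informative_others) next
    og <- group_of(informative)
    if (anyNA(og)) next                       # unexpected characters
    if (fg %in% og) next
    calls[[j]] <- tibble(
      column = j - 1L,
      reference_position = as.integer(ref_pos[j]),
      focal_residue = unname(focal_row[j]),
      focal_group = fg,
      others_residues = list(unname(informative)),
      others_groups = paste(sort(unique(og)), collapse = "/"),
      n_informative = length(informative),
      change_string = format_change_string(informative, ref_pos[j],
                                           focal_row[j])
    )
  }
  out <- bind_rows(calls)
  if (!nrow(out)) {
    out <- tibble(column = integer(), reference_position = integer(),
                  focal_residue = character(), focal_group = character(),
                  others_residues = list(), others_groups = character(),
                  n_informative = integer(), change_string = character())
  }
  out
}

#' Neutral false-positive simulation for the scanner
#'
#' Evolves `n_columns` independent protein columns along the tree with
#' no planted cross-group events and scans them exactly as production
#' alignments are scanned; every call is therefore a chance event. The
#' observed count and per-column rate are reported with an exact
#' binomial confidence interval.
#'
#' @param tree An `ape::phylo` tree or newick string; the focal species
#'   must be a leaf.
#' @param focal Focal species id.
#' @param n_columns Number of neutral columns to simulate.
#' @param rate Substitution-rate multiplier for the column evolution.
#' @param seed Integer seed.
#' @param min_informative_others Passed to [scan_alignment()]; default
#'   scales to the panel when the tree is small.
#' @param conf_level Confidence level of the binomial interval.
#' @return A one-row tibble: `n_columns`, `n_calls`, `rate`, `ci_lo`,
#'   `ci_hi`.
#' @export
neutral_fp_simulation <- function(tree, focal, n_columns = 1000L, rate = 1,
                                  seed = 1, min_informative_others = NULL,
                                  conf_level = 0.95) {
  tree <- check_tree(tree, focal)
  if (is.null(min_informative_others)) {
    min_informative_others <- max(1L, min(30L, length(tree$tip.label) - 1L))
  }
  aln <- evolve_protein_columns(tree, n_columns, rate = rate, seed = seed)
  calls <- scan_alignment(aln, focal = focal, reference = focal,
                          min_informative_others = min_informative_others)
  ci <- binom.test(nrow(calls), n_columns, conf.level = conf_level)$conf.int
  tibble(n_columns = n_columns, n_calls = nrow(calls),
         rate = nrow(calls) / n_columns,
         ci_lo = ci[1], ci_hi = ci[2])
}
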