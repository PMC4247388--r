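# Internal helpers shared across modules: deterministic seed streams and
# plain-character sequence manipulation. Sequences are held as uppercase
# character scalars; Biostrings is used at file and alignment boundaries.

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODON <- "ATG"

# Standard genetic code (table 1), stop = "*". Taken from Biostrings at
# load time so the lookup used everywhere is the canonical one.
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
}

#' Derive a child random seed from a root seed and string labels
#'
#' Child streams are derived by stable hashing of the root seed together
#' with identifying labels (for example a gene id and a species id), so
#' that adding one simulated gene never perturbs the random draws of
#' another. The hash is a plain polynomial rolling hash over the UTF-8
#' bytes, reduced modulo a Mersenne prime below 2^31.
#'
#' @param seed Integer root seed.
#' @param ... Character or numeric labels identifying the child stream.
#' @return A single integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "geneA", "speciesX")
derive_seed <- function(seed, ...) {
  labels <- paste(c(format(seed, scientific = FALSE), ...), collapse = "\x1f")
  bytes <- utf8ToInt(labels)
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% m
  as.integer(h)
}

with_seed <- function(seed, code) {
  if (requireNamespace("withr", quietly = TRUE)) {
    return(withr::with_seed(seed, code))
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

check_dna <- function(seq, allow_n = TRUE, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq)) {
    abort(sprintf("%s must be a single character string", what))
  }
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- gsub(sprintf("[%s]", alphabet), "", toupper(seq))
  if (nzchar(bad)) {
    abort(sprintf("%s contains characters outside {%s}: '%s'",
                  what, alphabet, substr(bad, 1, 10)))
  }
  toupper(seq)
}

reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

split_codons <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, by = 3L, length.out = n), seq(3L, by = 3L, length.out = n))
}

#' Translate a coding sequence with the standard genetic code
#'
#' Codons containing `N` translate to `X`; stop codons translate to `*`.
#' Trailing bases that do not fill a codon are ignored.
#'
#' @param seq A DNA character scalar over `{A,C,G,T,N}`.
#' @return The amino-acid string.
#' @export
#' @examples
#' translate_cds("ATGAAATAG")
translate_cds <- function(seq) {
  seq <- check_dna(seq)
  codons <- split_codons(seq)
  tab <- codon_table()
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Violations of the four coding-sequence invariants (empty chr if valid):
# length divisible by 3, leading ATG, terminal stop, no internal stop.
cds_violations <- function(seq) {
  seq <- toupper(seq)
  out <- character(0)
  if (nchar(seq) %% 3L != 0L) out <- c(out, "length not divisible by 3")
  if (nchar(seq) < 6L) return(c(out, "shorter than two codons"))
  codons <- split_codons(seq)
  if (codons[1] != START_CODON) out <- c(out, "does not begin with ATG")
  if (!codons[length(codons)] %in% STOP_CODONS)
    out <- c(out, "does not end with a stop codon")
  internal <- codons[-length(codons)]
  if (any(internal %in% STOP_CODONS)) out <- c(out, "internal stop codon")
  out
}

#' Validate a coding sequence against the codon invariants
#'
#' A valid coding sequence has length divisible by three, begins with
#' `ATG`, ends with one of `TAA`/`TAG`/`TGA`, and carries no internal
#' stop codon.
#'
#' @param seq A DNA character scalar.
#' @param error If `TRUE` (default), raise an error naming the violated
#'   invariant; otherwise return violations invisibly.
#' @return Invisibly, a character vector of violations (empty if valid).
#' @export
#' @examples
#' validate_cds("ATGAAATAG")
validate_cds <- function(seq, error = TRUE) {
  seq <- check_dna(seq)
  v <- cds_violations(seq)
  if (length(v) && error) {
    abort(paste0("invalid coding sequence: ", paste(v, collapse = "; ")))
  }
  invisible(v)
}

#' Read a FASTA file into a tibble
#'
#' @param path Path to a (possibly wrapped) FASTA file.
#' @param type `"dna"` or `"protein"`.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the header) and `seq`.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") {
    Biostrings::readDNAStringSet(path)
  } else {
    Biostrings::readAAStringSet(path)
  }
  tibble(
    id = vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L),
    seq = as.character(set)
  )
}

#' Write sequences from a tibble to a FASTA file
#'
#' @param x A tibble with columns `id` and `seq`.
#' @param path Output path.
#' @param type `"dna"` or `"protein"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") {
    Biostrings::DNAStringSet(setNames(x$seq, x$id))
  } else {
    Biostrings::AAStringSet(setNames(x$seq, x$id))
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
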