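# Independent oracles used across the suite. Each re-derives its result
# from first principles (brute force, enumeration or the textbook
# formula) and never calls the implementation it checks.

oracle_genetic_code <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]), collapse = "")
}

# Brute-force six-frame complete-ORF search: every ATG paired with the
# next in-frame stop, on both strands, codon by codon.
oracle_find_orfs <- function(seq, min_protein_len) {
  seq <- toupper(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else oracle_revcomp(seq)
    n <- nchar(s)
    for (i in seq_len(max(0L, n - 5L))) {
      if (substr(s, i, i + 2L) != "ATG") next
      j <- i + 3L
      while (j + 2L <= n) {
        cod <- substr(s, j, j + 2L)
        if (cod %in% c("TAA", "TAG", "TGA")) {
          plen <- (j - i) / 3L
          if (plen >= min_protein_len) {
            aa <- vapply(seq(i, j - 3L, by = 3L), function(k) {
              a <- oracle_genetic_code[substr(s, k, k + 2L)]
              if (is.na(a)) "X" else unname(a)
            }, character(1))
            rows[[length(rows) + 1L]] <- data.frame(
              start = i - 1L, end = j + 2L, frame = (i - 1L) %% 3L,
              strand = strand, length_nt = j + 2L - (i - 1L),
              protein = paste(aa, collapse = ""))
          }
          break
        }
        j <- j + 3L
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), end = integer(), frame = integer(),
                      strand = character(), length_nt = integer(),
                      protein = character()))
  }
  out <- do.call(rbind, rows)
  out[order(-out$length_nt, out$strand, out$start), , drop = FALSE]
}

# Gotoh affine-gap global alignment score; gap of length L costs
# open + ext * L. Independent of the package's aligner.
oracle_align_score <- function(a, b, submat, open = 10, ext = 4) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  Ix <- matrix(NEG, n + 1L, m + 1L)  # gap in b (a residue vs gap)
  Iy <- matrix(NEG, n + 1L, m + 1L)  # gap in a
  M[1, 1] <- 0
  for (i in 2:(n + 1L)) Ix[i, 1] <- -open - ext * (i - 1L)
  for (j in 2:(m + 1L)) Iy[1, j] <- -open - ext * (j - 1L)
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      sc <- submat[av[i - 1L], bv[j - 1L]]
      M[i, j] <- max(M[i - 1L, j - 1L], Ix[i - 1L, j - 1L],
                     Iy[i - 1L, j - 1L]) + sc
      Ix[i, j] <- max(M[i - 1L, j] - open - ext, Ix[i - 1L, j] - ext,
                      Iy[i - 1L, j] - open - ext)
      Iy[i, j] <- max(M[i, j - 1L] - open - ext, Iy[i, j - 1L] - ext,
                      Ix[i, j - 1L] - open - ext)
    }
  }
  max(M[n + 1L, m + 1L], Ix[n + 1L, m + 1L], Iy[n + 1L, m + 1L])
}

oracle_blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

# Exhaustive mutual-best enumeration from a hand-computed score matrix.
oracle_mutual_best <- function(mat) {
  pairs <- list()
  for (q in rownames(mat)) {
    best_s <- colnames(mat)[order(-mat[q, ], colnames(mat))][1]
    best_q <- rownames(mat)[order(-mat[, best_s], rownames(mat))][1]
    if (identical(best_q, q)) {
      pairs[[length(pairs) + 1L]] <- data.frame(query = q, subject = best_s)
    }
  }
  if (!length(pairs)) return(data.frame(query = character(), subject = character()))
  do.call(rbind, pairs)
}

# Per-column recheck of the unique-residue rule, with its own copy of
# the four-group model.
oracle_groups <- c(
  E = "acidic", D = "acidic", K = "basic", H = "basic", R = "basic",
  C = "cysteine",
  S = "other", T = "other", Y = "other", N = "other", Q = "other",
  G = "other", A = "other", V = "other", L = "other", I = "other",
  F = "other", P = "other", M = "other", W = "other")

oracle_scan_column <- function(focal, others, reference, min_informative) {
  if (!focal %in% names(oracle_groups)) return(FALSE)
  if (reference == "-") return(FALSE)
  informative <- others[others %in% names(oracle_groups)]
  if (length(informative) < min_informative) return(FALSE)
  !(oracle_groups[focal] %in% oracle_groups[informative])
}

# Direct-formula TMM (doubly trimmed, precision-weighted mean of M).
oracle_tmm <- function(mat, logratio_trim = 0.3, abundance_trim = 0.05) {
  lib <- colSums(mat)
  uq <- apply(mat, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  one <- function(obs, refv, nO, nR) {
    keep <- obs > 0 & refv > 0
    obs <- obs[keep]; refv <- refv[keep]
    M <- log2((obs / nO) / (refv / nR))
    A <- 0.5 * log2((obs / nO) * (refv / nR))
    w <- (nO - obs) / (nO * obs) + (nR - refv) / (nR * refv)
    n <- length(M)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * abundance_trim) + 1; hiS <- n + 1 - loS
    keep2 <- rank(M) >= loL & rank(M) <= hiL & rank(A) >= loS & rank(A) <= hiS
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  }
  f <- vapply(seq_len(ncol(mat)),
              function(j) one(mat[, j], mat[, ref], lib[j], lib[ref]),
              numeric(1))
  f / exp(mean(log(f)))
}

# Step-up definition: q(i) = min over j >= i of min(1, p(j) * m / j).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q_sorted[i] <- min(pmin(1, p[o][js] * m / js))
  }
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# One-sided hypergeometric tail by exhaustive enumeration.
oracle_hyper_tail <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Textbook pooled two-sample t-test on one gene's values.
oracle_two_sample_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  s2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(s2 * (1 / n1 + 1 / n2))
  list(t = t, df = n1 + n2 - 2,
       p = 2 * stats::pt(abs(t), n1 + n2 - 2, lower.tail = FALSE))
}

random_protein <- function(n) {
  paste(sample(names(oracle_groups), n, replace = TRUE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
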