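# Synthetic-data generators: coding sequences evolved along a phylogeny,
# planted lineage-unique substitutions, transcripts with UTRs and
# deliberate corruptions, and negative-binomial count matrices with
# planted log2 fold-changes. Every generator is a pure function of its
# inputs and a seed. The substitution process is deliberately simple
# (uniform nucleotide replacement with rejection of frame-breaking
# changes); it exercises the downstream set logic and makes no claim of
# evolutionary realism.

as_phylo_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    return(ape::read.tree(text = tree))
  }
  abort("tree must be an ape 'phylo' object or a newick string")
}

check_tree <- function(tree, focal_species = NULL) {
  tree <- as_phylo_tree(tree)
  if (anyDuplicated(tree$tip.label)) abort("tree leaf labels must be unique")
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  if (any(tree$edge.length < 0)) abort("branch lengths must be >= 0")
  if (!is.null(focal_species) && !focal_species %in% tree$tip.label) {
    abort(sprintf("focal species '%s' is not a leaf of the tree", focal_species))
  }
  tree
}

# Stable clade identifier per node: the sorted tip labels below it.
# Used to derive per-branch random streams that do not depend on node
# numbering internals.
clade_ids <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  ids <- character(n_node)
  ids[seq_len(n_tip)] <- tree$tip.label
  for (node in (n_tip + 1L):n_node) {
    tips <- ape::extract.clade(tree, node)$tip.label
    ids[node] <- paste(sort(tips), collapse = "|")
  }
  ids
}

#' Generate a random species tree for simulations
#'
#' A convenience wrapper around [ape::rtree()] producing a rooted tree
#' with branch lengths rescaled to a chosen mean, deterministic under a
#' seed. Species are labelled `sp01`, `sp02`, ...
#'
#' @param n_species Number of leaves (>= 2).
#' @param mean_branch_length Mean branch length in expected
#'   substitutions per site (default 0.05).
#' @param seed Integer seed.
#' @return An `ape::phylo` tree.
#' @export
random_species_tree <- function(n_species, mean_branch_length = 0.05, seed = 1) {
  stopifnot(n_species >= 2)
  with_seed(derive_seed(seed, "tree", n_species), {
    tree <- ape::rtree(n_species,
                       tip.label = sprintf("sp%02d", seq_len(n_species)))
    tree$edge.length <- tree$edge.length *
      (mean_branch_length / mean(tree$edge.length))
    tree
  })
}

#' Generate a random valid root coding sequence
#'
#' @param n_codons Number of codons including start and stop.
#' @param seed Integer seed.
#' @return A DNA string beginning `ATG`, ending with a stop codon, with
#'   no internal stop.
#' @export
random_root_cds <- function(n_codons, seed = 1) {
  stopifnot(n_codons >= 3)
  tab <- codon_table()
  sense <- names(tab)[!names(tab) %in% STOP_CODONS]
  with_seed(derive_seed(seed, "root_cds", n_codons), {
    inner <- sample(sense, n_codons - 2L, replace = TRUE)
    paste(c(START_CODON, inner[-1], sample(STOP_CODONS, 1L)), collapse = "")
  })
}

mutate_branch <- function(seq, branch_len, rate, preserve_frame) {
  n <- nchar(seq)
  p_sub <- 1 - exp(-branch_len * rate)
  hit <- which(runif(n) < p_sub)
  if (!length(hit)) return(seq)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1]]
  n_codon <- n %/% 3L
  for (pos in hit) {
    new <- sample(setdiff(bases, chars[pos]), 1L)
    if (preserve_frame) {
      ci <- (pos - 1L) %/% 3L + 1L
      cod <- chars[(3L * ci - 2L):(3L * ci)]
      cod[(pos - 1L) %% 3L + 1L] <- new
      cod <- paste(cod, collapse = "")
      ok <- if (ci == 1L) {
        cod == START_CODON
      } else if (ci == n_codon) {
        cod %in% STOP_CODONS
      } else {
        !cod %in% STOP_CODONS
      }
      if (!ok) next
    }
    chars[pos] <- new
  }
  paste(chars, collapse = "")
}

#' Evolve a coding sequence along a phylogeny
#'
#' Nucleotide substitutions are proposed per site with probability
#' `1 - exp(-branch_length * rate)` per branch and replaced uniformly by
#' one of the three other bases. With `preserve_frame = TRUE` proposals
#' that would create an internal stop codon, destroy the start codon or
#' destroy the terminal stop are rejected, so every leaf sequence
#' satisfies the same codon invariants as the root.
#'
#' @param root_cds A valid coding sequence (see [validate_cds()]).
#' @param tree An `ape::phylo` tree or newick string with branch lengths
#'   in expected substitutions per site.
#' @param rate Non-negative rate multiplier applied to branch lengths.
#' @param preserve_frame Keep codon invariants intact (default `TRUE`).
#' @param seed Integer seed; per-branch streams are derived with
#'   [derive_seed()] from `seed`, `gene_id` and the clade below each
#'   branch, so sequences are reproducible gene by gene.
#' @param gene_id Label mixed into the derived seeds.
#' @return A list with `cds` and `protein`, each a tibble with columns
#'   `species_id` and `seq` (one row per leaf).
#' @export
#' @examples
#' tr <- random_species_tree(4, seed = 1)
#' ev <- evolve_cds(random_root_cds(50, 1), tr, rate = 1, seed = 1)
#' ev$cds
evolve_cds <- function(root_cds, tree, rate = 1, preserve_frame = TRUE,
                       seed = 1, gene_id = "gene") {
  root_cds <- check_dna(root_cds, allow_n = FALSE, what = "root_cds")
  validate_cds(root_cds)
  stopifnot(rate >= 0)
  tree <- check_tree(tree)
  ids <- clade_ids(tree)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  seqs <- vector("character", n_tip + tree$Nnode)
  seqs[root] <- root_cds
  edges <- tree$edge[order(tree$edge[, 1L]), , drop = FALSE]
  # preorder: parents always appear before their children in reorder()
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[i, 1L]
    child <- ord$edge[i, 2L]
    bl <- ord$edge.length[i]
    branch_seed <- derive_seed(seed, gene_id, "branch", ids[child])
    seqs[child] <- with_seed(branch_seed, {
      mutate_branch(seqs[parent], bl, rate, preserve_frame)
    })
  }
  cds <- tibble(species_id = tree$tip.label, seq = seqs[seq_len(n_tip)])
  list(
    cds = cds,
    protein = mutate(cds, seq = vapply(.data$seq, function(s) {
      p <- translate_cds(s)
      sub("\\*$", "", p)
    }, character(1)))
  )
}

#' Residue groups of the four-class chemical model
#'
#' The partition of the 20 standard amino acids used throughout the
#' unique-residue scanner: acidic `{E,D}`, basic `{K,H,R}`, cysteine
#' `{C}` and other (the remaining 14 residues).
#'
#' @return A named character vector mapping residue to group name.
#' @export
#' @examples
#' residue_groups()[c("E", "K", "C", "W")]
residue_groups <- function() {
  groups <- list(
    acidic = c("E", "D"),
    basic = c("K", "H", "R"),
    cysteine = "C",
    other = c("S", "T", "Y", "N", "Q", "G", "A", "V", "L", "I", "F", "P", "M", "W")
  )
  out <- setNames(rep(names(groups), lengths(groups)), unlist(groups))
  stopifnot(length(out) == 20L, !anyDuplicated(names(out)))
  out
}

#' Plant a lineage-unique cross-group substitution in a protein column
#'
#' Places, at one alignment position of the focal species, a residue
#' from `target_group` while guaranteeing that no other species carries
#' a residue of that group at the position. If any non-focal residue
#' already falls in `target_group`, the whole non-focal column is first
#' homogenised to a random residue drawn from a single non-target group
#' (recorded in the truth). The returned truth record is what the
#' scanner in [scan_alignment()] must recover.
#'
#' @param proteins A tibble with columns `species_id` and `seq`
#'   (ungapped, equal-length protein strings).
#' @param focal Focal species id.
#' @param position 1-based residue position.
#' @param target_group One of `"acidic"`, `"basic"`, `"cysteine"`,
#'   `"other"`.
#' @param seed Integer seed.
#' @param gene_id Label recorded in the truth and mixed into the seed.
#' @return A list with `proteins` (modified tibble) and `truth`, a
#'   one-row tibble with the planted residue, the background residues
#'   and the class change (e.g. `"other->basic"`).
#' @export
plant_unique_substitution <- function(proteins, focal, position, target_group,
                                      seed = 1, gene_id = "gene") {
  groups <- residue_groups()
  if (!target_group %in% unique(groups)) {
    abort(sprintf("unknown residue group '%s'", target_group))
  }
  if (!focal %in% proteins$species_id) abort("focal species not present")
  lens <- nchar(proteins$seq)
  if (position < 1 || any(position > lens)) {
    abort("position outside the bounds of at least one sequence")
  }
  seqs <- setNames(proteins$seq, proteins$species_id)
  others <- setdiff(proteins$species_id, focal)
  bg <- substring(seqs[others], position, position)
  members <- names(groups)[groups == target_group]
  if (all(groups[bg] == target_group) && length(members) <= 1L) {
    abort(sprintf(
      "cannot plant: background column is already group '%s' and the group has a single member",
      target_group))
  }
  homogenized <- FALSE
  with_seed(derive_seed(seed, gene_id, "plant", position, target_group), {
    if (any(groups[bg] == target_group)) {
      donor_groups <- setdiff(unique(groups), target_group)
      g <- sample(donor_groups, 1L)
      res <- sample(names(groups)[groups == g], 1L)
      bg <- rep(res, length(others))
      for (sp in others) {
        s <- seqs[[sp]]
        substr(s, position, position) <- res
        seqs[[sp]] <- s
      }
      homogenized <- TRUE
    }
    planted <- sample(members, 1L)
  })
  s <- seqs[[focal]]
  substr(s, position, position) <- planted
  seqs[[focal]] <- s
  truth <- tibble(
    gene_id = gene_id,
    species_id = focal,
    reference_position = as.integer(position),
    background_residues = paste(sort(unique(bg)), collapse = ""),
    planted_residue = planted,
    class_change = paste0(
      paste(sort(unique(unname(groups[unique(bg)]))), collapse = "/"),
      "->", target_group),
    homogenized = homogenized
  )
  list(
    proteins = tibble(species_id = proteins$species_id,
                      seq = unname(seqs[proteins$species_id])),
    truth = truth
  )
}

random_utr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Build transcripts around coding sequences, with optional corruptions
#'
#' Each coding sequence receives random 5' and 3' UTRs (uniform lengths
#' on `utr_range`), then per-transcript corruptions are applied with the
#' given probabilities: the start codon mutated away, the stop codon
#' mutated to a sense codon, or truncation to a fraction of the CDS
#' length. The returned truth table records which transcripts still
#' contain their coding sequence as a recoverable complete ORF.
#'
#' @param cds A tibble with columns `species_id` and `seq`, each a valid
#'   coding sequence.
#' @param utr_range Length-2 integer vector, UTR length bounds in nt.
#' @param p_drop_start,p_drop_stop,p_truncate Corruption probabilities
#'   in `[0, 1]`.
#' @param truncate_frac Fraction of the CDS kept when truncating, in
#'   `(0, 1)`.
#' @param seed Integer seed.
#' @param gene_id Label mixed into derived seeds.
#' @return A list with `transcripts` (tibble: `species_id`,
#'   `transcript_id`, `seq`) and `truth` (tibble: `species_id`,
#'   `transcript_id`, `has_start`, `has_stop`, `truncated`,
#'   `orf_valid`).
#' @export
make_transcripts <- function(cds, utr_range = c(20L, 150L),
                             p_drop_start = 0, p_drop_stop = 0,
                             p_truncate = 0, truncate_frac = 0.6,
                             seed = 1, gene_id = "gene") {
  stopifnot(nrow(cds) > 0)
  probs <- c(p_drop_start, p_drop_stop, p_truncate)
  if (any(probs < 0 | probs > 1)) abort("corruption probabilities must be in [0,1]")
  if (truncate_frac <= 0 || truncate_frac >= 1) {
    abort("truncate_frac must lie in (0,1)")
  }
  rows <- purrr::pmap(cds, function(species_id, seq) {
    validate_cds(seq)
    with_seed(derive_seed(seed, gene_id, "transcript", species_id), {
      body <- seq
      drop_start <- runif(1) < p_drop_start
      drop_stop <- runif(1) < p_drop_stop
      truncated <- runif(1) < p_truncate
      if (truncated) {
        keep <- max(6L, floor(nchar(body) * truncate_frac))
        body <- substr(body, 1L, keep)
      }
      if (drop_start) substr(body, 1L, 3L) <- "ATT"
      has_stop_codon <- nchar(body) %% 3L == 0L &&
        substr(body, nchar(body) - 2L, nchar(body)) %in% STOP_CODONS
      if (drop_stop && has_stop_codon) {
        substr(body, nchar(body) - 2L, nchar(body)) <- "CAA"
        has_stop_codon <- FALSE
      }
      utr5 <- random_utr(sample(utr_range[1]:utr_range[2], 1L))
      # in-frame stop at the junction so no upstream ATG can extend the
      # embedded ORF through the UTR boundary
      substr(utr5, nchar(utr5) - 2L, nchar(utr5)) <- "TAA"
      utr3 <- random_utr(sample(utr_range[1]:utr_range[2], 1L))
      tibble(
        species_id = species_id,
        transcript_id = paste0(species_id, "_", gene_id, "_t1"),
        seq = paste0(utr5, body, utr3),
        has_start = !drop_start & !(truncated && nchar(body) < 3L),
        has_stop = has_stop_codon,
        truncated = truncated,
        orf_valid = !drop_start && !drop_stop && !truncated
      )
    })
  })
  out <- bind_rows(rows)
  list(
    transcripts = select(out, "species_id", "transcript_id", "seq"),
    truth = select(out, "species_id", "transcript_id", "has_start",
                   "has_stop", "truncated", "orf_valid")
  )
}

#' Simulate a negative-binomial count matrix with planted fold-changes
#'
#' Gene-wise relative abundances are drawn once from a gamma
#' distribution and normalised to sum to one; the expected count of gene
#' g in sample s is `library_size[s] * abundance[g] * 2^effect[g]` when
#' the sample belongs to the focal group (and without the effect term
#' otherwise). Counts are drawn negative-binomial with the given
#' dispersion (`size = 1/dispersion`).
#'
#' @param n_genes Number of genes; ids are `g0001`, ...
#' @param samples A tibble with columns `sample_id`, `species_id`,
#'   `group` (`"focal"` or `"other"`); at least two samples per group.
#' @param library_sizes Named positive numeric vector (per `sample_id`),
#'   or a single value recycled.
#' @param dispersion Negative-binomial dispersion, > 0.
#' @param planted_effects Named numeric vector of log2 fold-changes
#'   (focal vs other), names are gene ids to perturb.
#' @param seed Integer seed.
#' @return A list with `counts` (tibble: `gene_id` plus one column per
#'   sample) and `truth` (tibble: `gene_id`, `log2_effect`).
#' @export
simulate_counts <- function(n_genes, samples, library_sizes = 1e6,
                            dispersion = 0.05, planted_effects = NULL,
                            seed = 1) {
  stopifnot(n_genes >= 1)
  if (!all(c("sample_id", "species_id", "group") %in% names(samples))) {
    abort("samples needs columns sample_id, species_id, group")
  }
  if (!all(samples$group %in% c("focal", "other"))) {
    abort("group must be 'focal' or 'other'")
  }
  if (any(table(samples$group) < 2) || length(unique(samples$group)) < 2) {
    abort("need at least two samples in each of the focal and other groups")
  }
  ns <- nrow(samples)
  if (length(library_sizes) == 1L && is.null(names(library_sizes))) {
    library_sizes <- setNames(rep(library_sizes, ns), samples$sample_id)
  }
  if (!all(samples$sample_id %in% names(library_sizes))) {
    abort("library_sizes must be named per sample_id")
  }
  library_sizes <- library_sizes[samples$sample_id]
  if (any(library_sizes <= 0)) abort("library sizes must be positive")
  if (dispersion <= 0) abort("nb dispersion must be > 0")
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  effects <- setNames(rep(0, n_genes), gene_ids)
  if (length(planted_effects)) {
    if (!all(names(planted_effects) %in% gene_ids)) {
      abort("planted_effects names must be simulated gene ids")
    }
    effects[names(planted_effects)] <- planted_effects
  }
  counts <- with_seed(derive_seed(seed, "counts", n_genes, ns), {
    abundance <- rgamma(n_genes, shape = 0.7, rate = 1)
    abundance <- abundance / sum(abundance)
    mat <- matrix(0L, n_genes, ns, dimnames = list(gene_ids, samples$sample_id))
    for (j in seq_len(ns)) {
      mu <- library_sizes[j] * abundance
      if (samples$group[j] == "focal") mu <- mu * 2^effects
      mat[, j] <- rnbinom(n_genes, mu = mu, size = 1 / dispersion)
    }
    mat
  })
  list(
    counts = dplyr::bind_cols(tibble(gene_id = gene_ids),
                              as_tibble(counts)),
    truth = tibble(gene_id = gene_ids, log2_effect = unname(effects))
  )
}

#' Evolve independent protein alignment columns along a phylogeny
#'
#' Each column starts from a root residue drawn uniformly from the 20
#' standard amino acids and evolves along the tree; on each branch a
#' column substitutes with probability `1 - exp(-branch_length * rate)`,
#' replacing the residue uniformly by another residue — optionally
#' restricted to residues of the same chemical class
#' (`within_group_only`), which by construction can never produce a
#' cross-group call in the focal lineage. Used as the neutral background
#' for false-positive characterisation of the scanner.
#'
#' @param tree An `ape::phylo` tree or newick string.
#' @param n_columns Number of independent columns.
#' @param rate Rate multiplier.
#' @param within_group_only Restrict substitutions to the residue's own
#'   class (default `FALSE`).
#' @param seed Integer seed.
#' @return A tibble with columns `species_id` and `seq` (gapless,
#'   aligned protein strings of length `n_columns`).
#' @export
evolve_protein_columns <- function(tree, n_columns, rate = 1,
                                   within_group_only = FALSE, seed = 1) {
  tree <- check_tree(tree)
  stopifnot(n_columns >= 1, rate >= 0)
  groups <- residue_groups()
  aas <- names(groups)
  ids <- clade_ids(tree)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  node_seqs <- vector("list", n_tip + tree$Nnode)
  node_seqs[[root]] <- with_seed(derive_seed(seed, "cols", "root"), {
    sample(aas, n_columns, replace = TRUE)
  })
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (i in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[i, 1L]
    child <- ord$edge[i, 2L]
    bl <- ord$edge.length[i]
    res <- node_seqs[[parent]]
    node_seqs[[child]] <- with_seed(
      derive_seed(seed, "cols", "branch", ids[child]), {
        p_sub <- 1 - exp(-bl * rate)
        hit <- which(runif(n_columns) < p_sub)
        for (k in hit) {
          pool <- if (within_group_only) {
            setdiff(aas[groups == groups[[res[k]]]], res[k])
          } else {
            setdiff(aas, res[k])
          }
          if (length(pool)) res[k] <- sample(pool, 1L)
        }
        res
      })
  }
  tibble(
    species_id = tree$tip.label,
    seq = vapply(seq_len(n_tip),
                 function(i) paste(node_seqs[[i]], collapse = ""),
                 character(1))
  )
}
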