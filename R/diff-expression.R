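# Differential expression under the triple threshold: TMM normalisation
# (via edgeR's reference implementation behind this module's surface),
# log-CPM transformation, a two-group (moderated) t contrast, BH
# adjustment, an approximate B (log posterior odds) statistic, the
# flagging rule |log2FC| >= 2 AND adjusted P <= 0.05 AND B >= 2.945, and
# term fold-enrichment with one-sided Fisher's exact tests.

counts_to_matrix <- function(counts) {
  if (is.matrix(counts)) {
    storage.mode(counts) <- "double"
    return(counts)
  }
  if (!"gene_id" %in% names(counts)) {
    abort("counts must be a matrix or a tibble with a gene_id column")
  }
  mat <- as.matrix(counts[setdiff(names(counts), "gene_id")])
  rownames(mat) <- counts$gene_id
  storage.mode(mat) <- "double"
  mat
}

check_counts <- function(mat) {
  if (any(mat < 0)) abort("counts must be non-negative")
  if (any(mat != round(mat))) abort("counts must be integers")
  invisible(mat)
}

#' Trimmed-mean-of-M-values (TMM) normalisation factors
#'
#' Per-sample scaling factors computed as the doubly trimmed (30% on M,
#' 5% on A, two-sided), precision-weighted mean of per-gene log2 count
#' ratios against a reference sample — the reference defaulting to the
#' sample whose upper quartile is closest to the mean upper quartile.
#' Factors are rescaled to geometric mean 1. The computation is
#' delegated to edgeR's reference implementation of the algorithm.
#'
#' @param counts A count matrix or tibble (`gene_id` plus one column
#'   per sample).
#' @param ref_sample Optional reference sample id.
#' @param logratio_trim,abundance_trim Two-sided trim fractions
#'   (defaults 0.30 and 0.05).
#' @return A tibble `sample_id`, `lib_size`, `norm_factor`.
#' @export
tmm_factors <- function(counts, ref_sample = NULL,
                        logratio_trim = 0.30, abundance_trim = 0.05) {
  mat <- check_counts(counts_to_matrix(counts))
  ref_col <- NULL
  if (!is.null(ref_sample)) {
    ref_col <- match(ref_sample, colnames(mat))
    if (is.na(ref_col)) abort(sprintf("unknown reference sample '%s'", ref_sample))
  }
  f <- edgeR::calcNormFactors(mat, method = "TMM", refColumn = ref_col,
                              logratioTrim = logratio_trim,
                              sumTrim = abundance_trim)
  if (any(!is.finite(f)) || any(f <= 0)) {
    bad <- colnames(mat)[!is.finite(f) | f <= 0]
    abort(sprintf("TMM factor undefined for sample(s) %s (no genes shared with the reference?)",
                  paste(bad, collapse = ", ")))
  }
  tibble(sample_id = colnames(mat), lib_size = unname(colSums(mat)),
         norm_factor = unname(f))
}

#' Log2 counts per million on effective library sizes
#'
#' `log2((count + 0.5) / (lib_size * factor + 1) * 1e6)` — the common
#' CPM convention with a half-count pseudocount and one pseudo-read in
#' the effective library.
#'
#' @param counts Count matrix or tibble (`gene_id` + samples).
#' @param factors Output of [tmm_factors()], or `NULL` for factors of 1.
#' @return A tibble `gene_id` plus one numeric column per sample.
#' @export
log_cpm <- function(counts, factors = NULL) {
  mat <- check_counts(counts_to_matrix(counts))
  if (is.null(factors)) {
    factors <- tibble(sample_id = colnames(mat),
                      lib_size = unname(colSums(mat)),
                      norm_factor = 1)
  }
  stopifnot(setequal(factors$sample_id, colnames(mat)))
  f <- factors[match(colnames(mat), factors$sample_id), ]
  eff <- f$lib_size * f$norm_factor
  out <- log2(sweep(mat + 0.5, 2L, eff + 1, "/") * 1e6)
  dplyr::bind_cols(tibble(gene_id = rownames(mat) %||% as.character(seq_len(nrow(mat)))),
                   as_tibble(out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-group contrast on log-CPM values
#'
#' Per gene, `logFC = mean(focal) - mean(other)` in log2 units and a
#' two-sample t statistic on the pooled variance. With
#' `moderation = "shrink"` the gene variance is shrunk towards a prior:
#' `s2_post = (d0 * s0^2 + d * s^2) / (d0 + d)` with `d0` prior degrees
#' of freedom and `s0^2` the prior variance (estimated as the mean
#' gene variance when not supplied), and the t statistic gains
#' `d0 + d` degrees of freedom. `moderation = "none"` is the ordinary
#' two-sample pooled t test, which errors on genes with zero within-
#' group variance.
#'
#' @param logcpm Output of [log_cpm()] (tibble or matrix).
#' @param labels A tibble `sample_id`, `group` with `group` in
#'   `{"focal", "other"}` and at least two samples per group.
#' @param moderation `"shrink"` (default) or `"none"`.
#' @param prior_df Prior degrees of freedom `d0` (default 4).
#' @param prior_var Prior variance `s0^2`; default the mean of the
#'   per-gene pooled variances.
#' @return A tibble `gene_id`, `logFC`, `t`, `df`, `p_raw`.
#' @export
group_contrast <- function(logcpm, labels,
                           moderation = c("shrink", "none"),
                           prior_df = 4, prior_var = NULL) {
  moderation <- match.arg(moderation)
  mat <- if (is.matrix(logcpm)) logcpm else {
    m <- as.matrix(logcpm[setdiff(names(logcpm), "gene_id")])
    rownames(m) <- logcpm$gene_id
    m
  }
  stopifnot(all(c("sample_id", "group") %in% names(labels)),
            all(labels$group %in% c("focal", "other")))
  labels <- labels[match(colnames(mat), labels$sample_id), ]
  if (anyNA(labels$sample_id)) abort("labels must cover every sample column")
  i1 <- labels$group == "focal"
  i2 <- labels$group == "other"
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) abort("need >= 2 samples per group")
  m1 <- rowMeans(mat[, i1, drop = FALSE])
  m2 <- rowMeans(mat[, i2, drop = FALSE])
  v1 <- apply(mat[, i1, drop = FALSE], 1L, var)
  v2 <- apply(mat[, i2, drop = FALSE], 1L, var)
  d <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d
  if (moderation == "none") {
    if (any(s2 <= 0)) {
      abort("zero within-group variance with moderation = 'none'; use moderation = 'shrink'")
    }
    s2_post <- s2
    df <- d
  } else {
    s0 <- prior_var %||% mean(s2)
    s2_post <- (prior_df * s0 + d * s2) / (prior_df + d)
    df <- prior_df + d
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- unname((m1 - m2) / se)
  tibble(
    gene_id = rownames(mat) %||% as.character(seq_len(nrow(mat))),
    logFC = unname(m1 - m2),
    t = tstat,
    df = df,
    p_raw = unname(2 * pt(abs(tstat), df, lower.tail = FALSE))
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Approximate B (log posterior odds) statistic
#'
#' A deliberately simple two-component posterior-odds statistic on the
#' moderated t: under H0 the t statistic follows a t distribution with
#' `df` degrees of freedom; under H1 the same distribution scaled by
#' `sqrt(1 + v1)`. `B = ln(p1 f1(t) / ((1 - p1) f0(t)))` with prior
#' proportion `p1` of differentially expressed genes. This preserves
#' the decision rule of a log-posterior-odds threshold while making no
#' claim to reproduce any particular empirical-Bayes fit; B values from
#' an external fit can be supplied to [call_differential()] instead.
#'
#' @param t Vector of (moderated) t statistics.
#' @param df Degrees of freedom.
#' @param prior_prop Prior proportion of DE genes (default 0.01).
#' @param scale_var Variance inflation `v1` under H1 (default 16).
#' @return Vector of B values (natural-log odds).
#' @export
approximate_b <- function(t, df, prior_prop = 0.01, scale_var = 16) {
  stopifnot(prior_prop > 0, prior_prop < 1, scale_var > 0)
  r <- sqrt(1 + scale_var)
  log(prior_prop) + dt(t / r, df, log = TRUE) - log(r) -
    log(1 - prior_prop) - dt(t, df, log = TRUE)
}

#' Smallest B threshold guaranteeing a posterior probability
#'
#' B is a natural-log posterior odds, so the smallest three-decimal
#' threshold `b` with `sigmoid(b) >= prob` is `ln(prob / (1 - prob))`
#' rounded up at the third decimal. For `prob = 0.95` this gives
#' `ln(19) = 2.944...`, i.e. `2.945`.
#'
#' @param prob Posterior probability in (0, 1).
#' @return The threshold, a multiple of 0.001.
#' @export
#' @examples
#' b_threshold_from_probability(0.95)
b_threshold_from_probability <- function(prob) {
  if (!is.numeric(prob) || length(prob) != 1L || prob <= 0 || prob >= 1) {
    abort("prob must be a single number in (0, 1)")
  }
  x <- log(prob / (1 - prob))
  ceiling(x * 1000 - 1e-9) / 1000
}

#' Flag genes under the triple threshold
#'
#' A gene is flagged exactly when `|logFC| >= lfc_min` AND
#' `p_adj <= padj_max` AND `B >= b_min`. Unflagged genes are annotated
#' with the first failing condition in the order (lfc, padj, B).
#'
#' @param records A tibble with columns `logFC`, `p_adj` and (unless
#'   `check_b = FALSE`) `B`.
#' @param lfc_min Absolute log2 fold-change threshold (default 2).
#' @param padj_max Adjusted-P threshold (default 0.05).
#' @param b_min B threshold (default 2.945, the log-odds of a 95%
#'   posterior probability).
#' @param check_b Set `FALSE` to drop the B condition when no B column
#'   is available.
#' @return `records` with `flagged` (logical) and `reason`
#'   (`NA` when flagged; else `"lfc"`, `"padj"` or `"B"`).
#' @export
call_differential <- function(records, lfc_min = 2, padj_max = 0.05,
                              b_min = 2.945, check_b = TRUE) {
  stopifnot(lfc_min >= 0, padj_max > 0, padj_max <= 1)
  needed <- c("logFC", "p_adj", if (check_b) "B")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    abort(paste0("records missing column(s): ", paste(missing, collapse = ", "),
                 if ("B" %in% missing)
                   " (supply B or set check_b = FALSE)" else ""))
  }
  pass_lfc <- abs(records$logFC) >= lfc_min
  pass_padj <- records$p_adj <= padj_max
  pass_b <- if (check_b) records$B >= b_min else rep(TRUE, nrow(records))
  reason <- rep(NA_character_, nrow(records))
  reason[!pass_b] <- "B"
  reason[!pass_padj] <- "padj"
  reason[!pass_lfc] <- "lfc"
  mutate(records, flagged = pass_lfc & pass_padj & pass_b, reason = reason)
}

#' One-vs-rest differential expression pipeline
#'
#' Runs the full stage on a raw count table: TMM factors, log-CPM,
#' two-group moderated t contrast, BH adjustment, approximate B, and
#' the triple-threshold call. Returns a fitted object with [tidy()],
#' [glance()] and [autoplot()] methods.
#'
#' @param counts Count tibble (`gene_id` + samples) or matrix.
#' @param labels A tibble `sample_id`, `group` (`"focal"`/`"other"`),
#'   optionally `species_id`.
#' @param lfc_min,padj_max,b_min Thresholds for [call_differential()].
#' @param moderation,prior_df,prior_var Passed to [group_contrast()].
#' @param prior_prop,scale_var Passed to [approximate_b()].
#' @return An object of class `de_fit`: a list with `records` (per-gene
#'   tibble), `factors`, `labels` and `thresholds`.
#' @export
de_analysis <- function(counts, labels, lfc_min = 2, padj_max = 0.05,
                        b_min = 2.945, moderation = "shrink",
                        prior_df = 4, prior_var = NULL,
                        prior_prop = 0.01, scale_var = 16) {
  factors <- tmm_factors(counts)
  lc <- log_cpm(counts, factors)
  fit <- group_contrast(lc, labels, moderation = moderation,
                        prior_df = prior_df, prior_var = prior_var)
  records <- fit |>
    mutate(p_adj = bh_adjust(.data$p_raw),
           B = approximate_b(.data$t, .data$df, prior_prop, scale_var)) |>
    call_differential(lfc_min, padj_max, b_min)
  structure(
    list(records = records, factors = factors, labels = labels,
         thresholds = c(lfc_min = lfc_min, padj_max = padj_max, b_min = b_min)),
    class = "de_fit")
}

#' @export
print.de_fit <- function(x, ...) {
  cat(sprintf(
    "Two-group differential expression fit: %d genes, %d samples, %d flagged\n",
    nrow(x$records), nrow(x$factors), sum(x$records$flagged)))
  cat(sprintf("Thresholds: |logFC| >= %g, adj. P <= %g, B >= %g\n",
              x$thresholds["lfc_min"], x$thresholds["padj_max"],
              x$thresholds["b_min"]))
  invisible(x)
}

#' Per-gene results of a differential expression fit
#'
#' @param x A `de_fit` object.
#' @param ... Unused.
#' @return The per-gene record tibble (`gene_id`, `logFC`, `t`, `df`,
#'   `p_raw`, `p_adj`, `B`, `flagged`, `reason`).
#' @method tidy de_fit
#' @export
tidy.de_fit <- function(x, ...) x$records

#' One-row summary of a differential expression fit
#'
#' @param x A `de_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with gene/sample counts, the number of
#'   flagged genes and the thresholds applied.
#' @method glance de_fit
#' @export
glance.de_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x$records),
    n_samples = nrow(x$factors),
    n_flagged = sum(x$records$flagged),
    lfc_min = unname(x$thresholds["lfc_min"]),
    padj_max = unname(x$thresholds["padj_max"]),
    b_min = unname(x$thresholds["b_min"])
  )
}

#' Volcano plot of a differential expression fit
#'
#' @param object A `de_fit` object.
#' @param ... Unused.
#' @return A ggplot: log2 fold-change against -log10 adjusted P, with
#'   flagged genes highlighted and the thresholds drawn.
#' @method autoplot de_fit
#' @export
autoplot.de_fit <- function(object, ...) {
  rec <- object$records
  th <- object$thresholds
  ggplot2::ggplot(rec, ggplot2::aes(.data$logFC, -log10(.data$p_adj),
                                    colour = .data$flagged)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.4) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * th["lfc_min"],
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(th["padj_max"]),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold-change (focal vs other)",
                  y = "-log10 adjusted P", colour = "flagged") +
    ggplot2::theme_minimal()
}

#' Term fold-enrichment with one-sided Fisher's exact tests
#'
#' For each term, the 2x2 table (in list / not in list) x (in term /
#' not in term) over the background universe is tested one-sided in the
#' enrichment direction, and fold enrichment is the term frequency in
#' the list divided by its frequency in the background. Terms with no
#' background members are dropped; terms with zero list overlap are
#' reported with fold 0 (and p = 1).
#'
#' @param gene_list Character vector of genes of interest (must be a
#'   subset of `background`).
#' @param term_map A tibble `term`, `gene_id` mapping terms to
#'   background genes (a flat mapping; no ontology structure).
#' @param background Character vector: the gene universe.
#' @return A tibble per term: `term`, `list_count`, `list_size`,
#'   `background_count`, `background_size`, `fold_enrichment`,
#'   `fisher_p`, sorted by `fisher_p`.
#' @export
term_enrichment <- function(gene_list, term_map, background) {
  background <- unique(background)
  if (!length(background)) abort("background must be non-empty")
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% background)) {
    abort("gene_list must be a subset of background")
  }
  stopifnot(all(c("term", "gene_id") %in% names(term_map)))
  n <- length(gene_list)
  N <- length(background)
  term_map |>
    filter(.data$gene_id %in% background) |>
    group_by(.data$term) |>
    summarise(
      list_count = sum(unique(.data$gene_id) %in% gene_list),
      background_count = dplyr::n_distinct(.data$gene_id),
      .groups = "drop") |>
    mutate(
      list_size = n,
      background_size = N,
      fold_enrichment = (.data$list_count / n) / (.data$background_count / N),
      fisher_p = purrr::map2_dbl(.data$list_count, .data$background_count,
        function(k, K) {
          tab <- matrix(c(k, n - k, K - k, (N - n) - (K - k)), nrow = 2)
          fisher.test(tab, alternative = "greater")$p.value
        })) |>
    select("term", "list_count", "list_size", "background_count",
           "background_size", "fold_enrichment", "fisher_p") |>
    arrange(.data$fisher_p, .data$term)
}

#' Dot plot of term enrichment results
#'
#' @param enrichment Output of [term_enrichment()].
#' @param max_terms Show at most this many terms (by P-value).
#' @return A ggplot of fold enrichment per term, sized by list count
#'   and coloured by -log10 Fisher P.
#' @export
plot_enrichment <- function(enrichment, max_terms = 20L) {
  df <- head(arrange(enrichment, .data$fisher_p), max_terms)
  df$term <- factor(df$term, levels = rev(df$term))
  ggplot2::ggplot(df, ggplot2::aes(.data$fold_enrichment, .data$term,
                                   size = .data$list_count,
                                   colour = -log10(.data$fisher_p))) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fold enrichment", y = NULL, size = "genes in list",
                  colour = "-log10 P") +
    ggplot2::theme_minimal()
}
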