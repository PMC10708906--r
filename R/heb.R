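# Homeolog expression bias (HEB): per-group classification of homeolog
# pairs by the >2-fold TPM rule, cross-group consistency and converse
# dominance accounting, drought-induction testing, and TE-density
# association.

#' Flag homeolog pairs with no usable expression
#'
#' A pair is filtered iff every sample's TPM is below `threshold` for BOTH
#' genes (rule `"both"`, the default) — this keeps pairs where one homeolog
#' is silenced, the biologically interesting case. Rule `"either"` filters
#' when either gene fails in every sample.
#'
#' @param pairs pair table (`bhd_gene`, `bhs_gene`).
#' @param expr TPM matrix (genes x samples, rownames = gene ids).
#' @param threshold TPM threshold (default 1).
#' @param rule `"both"` or `"either"`.
#' @return `pairs` with a logical `filtered` column added.
#' @export
filter_low_expression <- function(pairs, expr, threshold = 1,
                                  rule = c("both", "either")) {
  rule <- match.arg(rule)
  missing_genes <- setdiff(c(pairs$bhd_gene, pairs$bhs_gene), rownames(expr))
  if (length(missing_genes) > 0) {
    stop("genes missing from expression matrix: ",
         paste(utils::head(missing_genes, 5), collapse = ", "), call. = FALSE)
  }
  low_d <- apply(expr[pairs$bhd_gene, , drop = FALSE] < threshold, 1, all)
  low_s <- apply(expr[pairs$bhs_gene, , drop = FALSE] < threshold, 1, all)
  pairs$filtered <- if (rule == "both") low_d & low_s else low_d | low_s
  ax_log("filter_low_expression: %d/%d pairs filtered (TPM < %g in all samples, rule = %s)",
         sum(pairs$filtered), nrow(pairs), threshold, rule)
  pairs
}

# The 2-fold dominance rule on raw replicate-mean TPMs. Strict inequality;
# zeros need no special casing: 0 vs 0 is neutral (0 > 0 is false) and
# x > 0 vs 0 is dominant (x > fold * 0).
bias_call <- function(mean_bhd, mean_bhs, fold = 2.0) {
  ifelse(mean_bhs > fold * mean_bhd, "BhS_dominant",
         ifelse(mean_bhd > fold * mean_bhs, "BhD_dominant", "neutral"))
}

#' Classify homeolog expression bias per (tissue, condition) group
#'
#' Replicate TPMs are averaged per gene within each group; a pair is
#' BhS-dominant in a group iff `mean_bhs > fold * mean_bhd` (strict, on the
#' raw means), symmetrically for BhD, neutral otherwise. Pairs failing the
#' low-expression filter carry call `"filtered"` in every group. The
#' reported `log2_ratio` is `log2((mean_bhs + eps) / (mean_bhd + eps))`
#' with pseudocount `eps` used only inside the ratio, never in the fold
#' rule.
#'
#' @param pairs pair table (`bhd_gene`, `bhs_gene`).
#' @param expr TPM matrix (genes x samples).
#' @param meta sample metadata (`sample_id`, `tissue`, `condition`,
#'   `replicate`).
#' @param fold dominance fold threshold (default 2).
#' @param eps pseudocount for the log ratio (default 0.1 TPM).
#' @param tpm_threshold low-expression filter threshold.
#' @param filter_rule passed to [filter_low_expression()].
#' @return long data.frame: one row per pair per group with `pair_id,
#'   bhd_gene, bhs_gene, tissue, condition, group, mean_bhd, mean_bhs,
#'   log2_ratio, call`.
#' @export
heb_classify <- function(pairs, expr, meta, fold = 2.0, eps = 0.1,
                         tpm_threshold = 1, filter_rule = "both") {
  ax_assert(all(meta$sample_id %in% colnames(expr)),
            "metadata names samples absent from the expression matrix")
  pairs <- filter_low_expression(pairs, expr, threshold = tpm_threshold,
                                 rule = filter_rule)
  pair_id <- paste(pairs$bhd_gene, pairs$bhs_gene, sep = "|")
  groups <- unique(meta[, c("tissue", "condition")])
  out <- lapply(seq_len(nrow(groups)), function(g) {
    sel <- meta$tissue == groups$tissue[g] &
      meta$condition == groups$condition[g]
    samples <- meta$sample_id[sel]
    mean_d <- rowMeans(expr[pairs$bhd_gene, samples, drop = FALSE])
    mean_s <- rowMeans(expr[pairs$bhs_gene, samples, drop = FALSE])
    call <- ifelse(pairs$filtered, "filtered",
                   bias_call(mean_d, mean_s, fold = fold))
    data.frame(pair_id = pair_id, bhd_gene = pairs$bhd_gene,
               bhs_gene = pairs$bhs_gene, tissue = groups$tissue[g],
               condition = groups$condition[g],
               group = paste(groups$tissue[g], groups$condition[g], sep = "."),
               mean_bhd = unname(mean_d), mean_bhs = unname(mean_s),
               log2_ratio = unname(log2((mean_s + eps) / (mean_d + eps))),
               call = call, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Summarise the bias distribution per group
#'
#' @param calls call table from [heb_classify()].
#' @return data.frame, one row per group: class counts and percentages and
#'   the median/mean `log2_ratio` over retained (non-filtered) pairs.
#' @export
bias_distribution <- function(calls) {
  ax_assert(nrow(calls) > 0, "empty call table")
  groups <- split(calls, calls$group)
  rows <- lapply(groups, function(g) {
    ret <- g[g$call != "filtered", , drop = FALSE]
    ax_assert(nrow(ret) > 0, paste0("group ", g$group[1],
                                    " has no retained pairs"))
    n_ret <- nrow(ret)
    data.frame(group = g$group[1], tissue = g$tissue[1],
               condition = g$condition[1], n_pairs = nrow(g),
               n_filtered = sum(g$call == "filtered"),
               n_neutral = sum(ret$call == "neutral"),
               n_bhs_dominant = sum(ret$call == "BhS_dominant"),
               n_bhd_dominant = sum(ret$call == "BhD_dominant"),
               pct_bhs_dominant = as_percent(sum(ret$call == "BhS_dominant"), n_ret),
               pct_bhd_dominant = as_percent(sum(ret$call == "BhD_dominant"), n_ret),
               median_log2_ratio = stats::median(ret$log2_ratio),
               mean_log2_ratio = mean(ret$log2_ratio),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# wide pair x group call matrix (filtered pairs dropped)
calls_wide <- function(calls) {
  groups <- sort(unique(calls$group))
  keep <- calls$pair_id[calls$call != "filtered"]
  calls <- calls[calls$pair_id %in% keep, , drop = FALSE]
  ids <- unique(calls$pair_id)
  m <- matrix(NA_character_, length(ids), length(groups),
              dimnames = list(ids, groups))
  m[cbind(match(calls$pair_id, ids), match(calls$group, groups))] <- calls$call
  if (anyNA(m)) {
    stop("pair universes differ between groups", call. = FALSE)
  }
  m
}

#' Cross-group consistency of expression bias
#'
#' Counts pairs biased (non-neutral) in every group, and — of those — pairs
#' with the same dominance direction in every group (the "consistent"
#' set). Also reports the pairwise group overlaps of biased pairs.
#'
#' @param calls call table from [heb_classify()] over >= 2 groups.
#' @return list: `n_pairs`, `n_biased_all_groups`, `n_consistent`,
#'   `consistent_pairs` (ids), `per_group` (from [bias_distribution()]),
#'   `pairwise` (group pairs with both-biased / same-direction / converse
#'   counts).
#' @export
consistency_across_groups <- function(calls) {
  m <- calls_wide(calls)
  ax_assert(ncol(m) >= 2, "need at least two groups")
  biased <- m %in% c("BhS_dominant", "BhD_dominant")
  dim(biased) <- dim(m)
  all_biased <- rowSums(biased) == ncol(m)
  consistent <- all_biased &
    apply(m, 1, function(r) length(unique(r)) == 1)
  pw <- list()
  cmb <- utils::combn(colnames(m), 2)
  for (k in seq_len(ncol(cmb))) {
    a <- m[, cmb[1, k]]; b <- m[, cmb[2, k]]
    ab <- a %in% c("BhS_dominant", "BhD_dominant") &
      b %in% c("BhS_dominant", "BhD_dominant")
    pw[[k]] <- data.frame(group_a = cmb[1, k], group_b = cmb[2, k],
                          n_both_biased = sum(ab),
                          n_same_direction = sum(ab & a == b),
                          n_converse = sum(ab & a != b),
                          stringsAsFactors = FALSE)
  }
  list(n_pairs = nrow(m),
       n_biased_all_groups = sum(all_biased),
       n_consistent = sum(consistent),
       consistent_pairs = rownames(m)[consistent],
       per_group = bias_distribution(calls),
       pairwise = do.call(rbind, pw))
}

#' Converse dominance between two groups
#'
#' Pairs BhS-dominant in one group and BhD-dominant in the other. The
#' percentage denominator is the number of pairs biased in at least one of
#' the two groups (the denominator convention is not uniquely determined by
#' published summaries; this one is documented and fixed).
#'
#' @param calls call table from [heb_classify()].
#' @param group_a,group_b group labels (`"tissue.condition"`).
#' @return list `n_converse, n_denominator, pct, pairs`.
#' @export
converse_dominance <- function(calls, group_a, group_b) {
  m <- calls_wide(calls)
  ax_assert(all(c(group_a, group_b) %in% colnames(m)),
            "unknown group label")
  a <- m[, group_a]; b <- m[, group_b]
  dom <- c("BhS_dominant", "BhD_dominant")
  converse <- a %in% dom & b %in% dom & a != b
  denom <- a %in% dom | b %in% dom
  list(n_converse = sum(converse), n_denominator = sum(denom),
       pct = if (sum(denom) > 0) as_percent(sum(converse), sum(denom)) else NA_real_,
       pairs = rownames(m)[converse])
}

# exact permutation null of the rank-sum statistic (midranks for ties);
# feasible up to 8 per group (choose(16, 8) = 12870 assignments)
exact_ranksum <- function(x, y, alternative) {
  r <- rank(c(x, y))
  n1 <- length(x)
  obs <- sum(r[seq_len(n1)])
  sums <- utils::combn(r, n1, sum)
  p <- switch(alternative,
              greater = mean(sums >= obs - 1e-9),
              less = mean(sums <= obs + 1e-9),
              two.sided = {
                e <- mean(sums)
                mean(abs(sums - e) >= abs(obs - e) - 1e-9)
              },
              stop("unknown alternative: ", alternative))
  list(statistic = obs - n1 * (n1 + 1) / 2, p_value = p)
}

#' Rank-sum induction test for one gene between two conditions
#'
#' Mann-Whitney/Wilcoxon rank-sum test on per-replicate TPMs. For up to 8
#' replicates per group the null is the exact permutation distribution of
#' the rank-sum statistic (midranks for ties) — the three-replicate design
#' makes asymptotic p-values meaningless; larger groups fall back to the
#' normal approximation with tie correction.
#'
#' @param control,treatment numeric TPM vectors (>= 2 replicates each).
#' @param alternative `"two.sided"` (default), `"greater"` (treatment
#'   shifted up) or `"less"`.
#' @return list `statistic, p_value, fold_change` (mean treatment / mean
#'   control), `direction` (`"induced"`, `"repressed"`, `"unchanged"`).
#' @export
induction_test <- function(control, treatment, alternative = "two.sided") {
  if (length(control) < 2 || length(treatment) < 2) {
    stop("need at least 2 replicates per group", call. = FALSE)
  }
  if (length(control) <= 8 && length(treatment) <= 8) {
    wt <- exact_ranksum(treatment, control, alternative)
    wt <- list(statistic = wt$statistic, p.value = wt$p_value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(treatment, control,
                                              alternative = alternative,
                                              exact = FALSE))
  }
  fc <- mean(treatment) / mean(control)
  direction <- if (mean(treatment) > mean(control)) "induced"
  else if (mean(treatment) < mean(control)) "repressed" else "unchanged"
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       fold_change = fc, direction = direction)
}

#' TE density in the flanks (and body) of genes
#'
#' Fraction of bases in `[start - flank, end + flank]` (clipped to the
#' chromosome) covered by TE intervals.
#'
#' @param genes gene interval table (`chrom, start, end`, optional
#'   `gene_id` used to name the result).
#' @param te TE interval table (`chrom, start, end`); merged per chromosome
#'   before counting.
#' @param flank flank width each side in bp (default 2000).
#' @param chrom_lengths optional named vector of chromosome lengths for
#'   right-clipping.
#' @return numeric vector of densities in `[0, 1]`, one per gene. Genes on
#'   chromosomes absent from the TE set get density 0 with one warning.
#' @export
te_flank_density <- function(genes, te, flank = 2000, chrom_lengths = NULL) {
  validate_intervals(genes, "gene")
  if (nrow(te) > 0) validate_intervals(te, "TE")
  te_m <- if (nrow(te) > 0) merge_spans(te) else te
  missing_chroms <- setdiff(unique(genes$chrom), unique(te$chrom))
  if (length(missing_chroms) > 0) {
    warning("no TE annotations on chromosome(s): ",
            paste(missing_chroms, collapse = ", "), "; density set to 0")
  }
  te_by_chrom <- split(te_m, te_m$chrom)
  dens <- vapply(seq_len(nrow(genes)), function(i) {
    ws <- max(0, genes$start[i] - flank)
    we <- genes$end[i] + flank
    if (!is.null(chrom_lengths) && genes$chrom[i] %in% names(chrom_lengths)) {
      we <- min(we, chrom_lengths[[genes$chrom[i]]])
    }
    m <- te_by_chrom[[genes$chrom[i]]]
    if (is.null(m)) return(0)
    sum(overlap_len(m$start, m$end, ws, we)) / (we - ws)
  }, 0)
  if ("gene_id" %in% names(genes)) names(dens) <- genes$gene_id
  dens
}

#' TE-density association with expression bias
#'
#' Three tests over a stable-bias pair set (pairs with a consistent
#' dominance direction in every group): (i) paired Wilcoxon signed-rank on
#' TE densities grouped by subgenome (BhD vs BhS member of each pair);
#' (ii) paired Wilcoxon grouped by bias role (dominant vs submissive gene);
#' (iii) Pearson correlation between `log2(TPM + eps)` and TE density
#' across all genes (optional, when `gene_tbl` is supplied).
#'
#' @param stable_pairs data.frame with `direction` (`"BhS_dominant"` /
#'   `"BhD_dominant"`), `te_density_bhd`, `te_density_bhs`.
#' @param gene_tbl optional data.frame with `mean_tpm` and `te_density` per
#'   gene for the genome-wide correlation.
#' @param eps pseudocount inside the log (default 0.1).
#' @return list with `subgenome_test`, `domsub_test` (each `statistic`,
#'   `p_value`, `median_diff`), and `pearson` (`r`, `p_value`, `n`) or
#'   `NULL`.
#' @export
te_bias_association <- function(stable_pairs, gene_tbl = NULL, eps = 0.1) {
  if (nrow(stable_pairs) < 10) {
    stop("need at least 10 stable-bias pairs", call. = FALSE)
  }
  paired_wilcox <- function(x, y) {
    d <- x - y
    if (all(d == 0)) {
      return(list(statistic = NA_real_, p_value = 1, median_diff = 0))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
    list(statistic = unname(wt$statistic), p_value = wt$p.value,
         median_diff = stats::median(d))
  }
  dom <- ifelse(stable_pairs$direction == "BhS_dominant",
                stable_pairs$te_density_bhs, stable_pairs$te_density_bhd)
  sub <- ifelse(stable_pairs$direction == "BhS_dominant",
                stable_pairs$te_density_bhd, stable_pairs$te_density_bhs)
  pearson <- NULL
  if (!is.null(gene_tbl)) {
    ct <- stats::cor.test(log2(gene_tbl$mean_tpm + eps), gene_tbl$te_density,
                          method = "pearson")
    pearson <- list(r = unname(ct$estimate), p_value = ct$p.value,
                    n = nrow(gene_tbl))
  }
  list(subgenome_test = paired_wilcox(stable_pairs$te_density_bhd,
                                      stable_pairs$te_density_bhs),
       domsub_test = paired_wilcox(dom, sub),
       pearson = pearson)
}
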