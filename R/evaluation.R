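#' @title Interaction-prediction benchmark: ROC/AUC over functional
#'   similarity
#' @description Known genetic and protein-protein interactions serve as
#'   positive instances; in the absence of validated negatives, every
#'   other unordered gene pair in the evaluation universe is treated as
#'   negative. This conservative assumption deflates the measured AUC but
#'   affects baseline and augmented annotation sets identically, so their
#'   comparison remains valid.
#' @name evaluation
NULL

#' Construct an evaluation set
#'
#' @param positives canonical interaction-pair table
#'   ([interaction_pairs()]).
#' @param gene_universe character vector of gene ids; negatives are all
#'   unordered pairs over the universe that are not positive. Every
#'   positive pair's genes must be in the universe.
#' @return object of class `evaluation_set`.
#' @export
evaluation_set <- function(positives, gene_universe) {
  gene_universe <- sort(unique(as.character(gene_universe)))
  missing <- setdiff(unique(c(positives$a, positives$b)), gene_universe)
  if (length(missing)) {
    stop("positive-pair gene(s) outside the universe: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  structure(list(positives = positives, gene_universe = gene_universe),
            class = "evaluation_set")
}

#' @export
print.evaluation_set <- function(x, ...) {
  n <- length(x$gene_universe)
  cat(sprintf("Evaluation set: %d positive pairs, %d genes (%d candidate pairs)\n",
              nrow(x$positives), n, n * (n - 1) / 2))
  invisible(x)
}

#' Filter interaction pairs by inferred-function coverage
#'
#' Removes interaction pairs for which no novel function was inferred:
#' under the default `"either"` policy a pair is kept when at least one
#' partner has >= 1 novel inferred function; `"both"` requires both
#' partners. The gene universe of the resulting evaluation set is the
#' genes of the kept pairs plus all profiled genes.
#'
#' @param pairs canonical interaction-pair table.
#' @param inferred [infer_functions()] table; rows with `novel == TRUE`
#'   count (if novelty is unclassified, i.e. all `NA`, every inferred
#'   function counts as novel).
#' @param profiles optional named profile list contributing genes to the
#'   universe.
#' @param policy `"either"` (default) or `"both"`.
#' @return an [evaluation_set()].
#' @export
filter_pairs <- function(pairs, inferred, profiles = NULL,
                         policy = c("either", "both")) {
  policy <- match.arg(policy)
  novel_flag <- inferred$novel
  if (all(is.na(novel_flag))) novel_flag <- rep(TRUE, nrow(inferred))
  novel_genes <- unique(inferred$gene[novel_flag %in% TRUE])
  in_a <- pairs$a %in% novel_genes
  in_b <- pairs$b %in% novel_genes
  keep <- if (policy == "either") in_a | in_b else in_a & in_b
  kept <- pairs[keep, , drop = FALSE]
  universe <- unique(c(kept$a, kept$b, names(profiles)))
  evaluation_set(kept, universe)
}

#' ROC curve and AUC from scores and labels
#'
#' Builds the ROC curve by sweeping a threshold over the scores from high
#' to low; tied scores collapse into a single threshold step (a diagonal
#' segment), so the trapezoidal area equals the Mann-Whitney statistic
#' U / (n_pos * n_neg) with average-rank tie handling.
#'
#' @param scores numeric vector.
#' @param labels logical vector (`TRUE` = positive instance).
#' @return object of class `roc_result`: `curve` (data frame `fpr`,
#'   `tpr`, starting at (0,0) and ending at (1,1)), `auc`, `n_pos`,
#'   `n_neg`.
#' @examples
#' roc_from_scores(c(.9, .8, .4, .2), c(TRUE, TRUE, FALSE, FALSE))$auc
#' @export
roc_from_scores <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L) stop("no positive instances")
  if (n_neg == 0L) stop("no negative instances")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # group tied scores into single threshold steps
  grp <- cumsum(!duplicated(s))
  tp <- tapply(l, grp, sum)
  fp <- tapply(!l, grp, sum)
  tpr <- c(0, cumsum(tp)) / n_pos
  fpr <- c(0, cumsum(fp)) / n_neg
  k <- length(tpr)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-k]) / 2)
  structure(
    list(curve = data.frame(fpr = unname(fpr), tpr = unname(tpr)),
         auc = unname(auc), n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$curve$fpr, x$curve$tpr, type = "l",
       xlab = "False positive rate", ylab = "True positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

# score all unordered candidate pairs over the universe; returns
# data.frame(a, b, score, label)
score_candidate_pairs <- function(eval_set, profiles) {
  genes <- eval_set$gene_universe
  n <- length(genes)
  if (n < 2L) stop("gene universe has fewer than 2 genes")
  pos_key <- pair_key(eval_set$positives)
  cmb <- utils::combn(genes, 2L)
  a <- cmb[1, ]
  b <- cmb[2, ]
  empty <- list(gene = NA, closed_terms = character())
  prof <- function(g) profiles[[g]] %||% empty
  score <- vapply(seq_along(a), function(i) jaccard(prof(a[i]), prof(b[i])), numeric(1))
  data.frame(a = a, b = b, score = score,
             label = paste(a, b, sep = "\r") %in% pos_key,
             stringsAsFactors = FALSE)
}

#' Pooled ROC over all candidate pairs
#'
#' Scores every unordered pair in the evaluation universe by Jaccard
#' functional similarity and computes the ROC of recovering the positive
#' interaction pairs.
#'
#' @param eval_set an [evaluation_set()].
#' @param profiles named profile list; genes without a profile score as
#'   empty sets.
#' @return a [`roc_result`][roc_from_scores].
#' @export
pooled_roc <- function(eval_set, profiles) {
  cand <- score_candidate_pairs(eval_set, profiles)
  roc_from_scores(cand$score, cand$label)
}

#' Per-gene ROC areas from ranked neighbour lists
#'
#' For each gene with at least one interaction partner and one negative
#' candidate, the AUC of its own similarity ranking with its partners as
#' positives. Genes not qualifying are omitted and counted in the
#' `diagnostics` attribute.
#'
#' @inheritParams pooled_roc
#' @return data frame `gene`, `auc`, `n_pos`, `n_neg`.
#' @export
per_gene_aucs <- function(eval_set, profiles) {
  genes <- eval_set$gene_universe
  partners <- list()
  for (i in seq_len(nrow(eval_set$positives))) {
    a <- eval_set$positives$a[i]
    b <- eval_set$positives$b[i]
    partners[[a]] <- c(partners[[a]], b)
    partners[[b]] <- c(partners[[b]], a)
  }
  empty <- list(gene = NA, closed_terms = character())
  prof <- function(g) profiles[[g]] %||% empty
  out_gene <- character(); out_auc <- numeric(); out_np <- integer(); out_nn <- integer()
  omitted <- 0L
  for (g in genes) {
    pos <- unique(partners[[g]])
    others <- setdiff(genes, g)
    n_pos <- length(pos)
    n_neg <- length(others) - n_pos
    if (n_pos < 1L || n_neg < 1L) {
      omitted <- omitted + 1L
      next
    }
    scores <- vapply(others, function(o) jaccard(prof(g), prof(o)), numeric(1))
    r <- roc_from_scores(scores, others %in% pos)
    out_gene <- c(out_gene, g)
    out_auc <- c(out_auc, r$auc)
    out_np <- c(out_np, n_pos)
    out_nn <- c(out_nn, n_neg)
  }
  out <- data.frame(gene = out_gene, auc = out_auc, n_pos = out_np,
                    n_neg = out_nn, stringsAsFactors = FALSE)
  attr(out, "diagnostics") <- list(genes_omitted = omitted)
  out
}

#' Compare baseline and augmented annotation profiles
#'
#' Computes the pooled ROC AUC for both profile sets and the per-gene AUC
#' lists over genes qualifying in both, then a one-tailed paired t-test of
#' the alternative "augmented > baseline". The paired per-gene AUC is the
#' unit of comparison; the pooled AUCs are reported alongside. When all
#' per-gene differences are exactly zero the t statistic is undefined and
#' the p-value is reported as 0.5 (no evidence either way).
#'
#' @param baseline_profiles,augmented_profiles named profile lists over
#'   the same genes.
#' @param eval_set an [evaluation_set()].
#' @return object of class `comparison_result`: `auc_baseline`,
#'   `auc_augmented`, `per_gene` (data frame `gene`, `auc_baseline`,
#'   `auc_augmented`), `p_value` (NA with a `note` when fewer than 2
#'   paired genes qualify).
#' @export
compare_profiles <- function(baseline_profiles, augmented_profiles, eval_set) {
  roc_base <- pooled_roc(eval_set, baseline_profiles)
  roc_aug <- pooled_roc(eval_set, augmented_profiles)
  pg_base <- per_gene_aucs(eval_set, baseline_profiles)
  pg_aug <- per_gene_aucs(eval_set, augmented_profiles)
  m <- merge(pg_base[c("gene", "auc")], pg_aug[c("gene", "auc")],
             by = "gene", suffixes = c("_baseline", "_augmented"))
  note <- NULL
  if (nrow(m) < 2L) {
    p <- NA_real_
    note <- "fewer than 2 paired genes; p-value undefined"
  } else {
    d <- m$auc_augmented - m$auc_baseline
    if (all(d == 0)) {
      p <- 0.5
    } else if (stats::sd(d) == 0) {
      p <- if (mean(d) > 0) 0 else 1
    } else {
      p <- stats::t.test(m$auc_augmented, m$auc_baseline, paired = TRUE,
                         alternative = "greater")$p.value
    }
  }
  structure(
    list(auc_baseline = roc_base$auc, auc_augmented = roc_aug$auc,
         roc_baseline = roc_base, roc_augmented = roc_aug,
         per_gene = m, p_value = p, note = note),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Pooled ROC AUC: baseline %.4f, augmented %.4f\n",
              x$auc_baseline, x$auc_augmented))
  cat(sprintf("Per-gene paired comparison over %d genes: one-tailed p = %s\n",
              nrow(x$per_gene),
              if (is.na(x$p_value)) paste0("NA (", x$note, ")") else format.pval(x$p_value)))
  invisible(x)
}

#' Export normalized rank positions of positive pairs
#'
#' For each positive interaction pair, the normalized position of each
#' partner in the other's ranked similarity list, averaged over the two
#' directions; 0 means both partners are each other's functionally most
#' similar gene, 1 the least similar. One row per pair with the baseline
#' and augmented positions side by side.
#'
#' @inheritParams compare_profiles
#' @param path output TSV path.
#' @return the written data frame, invisibly.
#' @export
write_pair_ranks <- function(eval_set, baseline_profiles, augmented_profiles, path) {
  norm_pos <- function(profiles) {
    ranks <- lapply(stats::setNames(eval_set$gene_universe, eval_set$gene_universe),
                    function(g) rank_neighbors(g, profiles)$tie_rank)
    n_cand <- length(eval_set$gene_universe) - 1L
    vapply(seq_len(nrow(eval_set$positives)), function(i) {
      a <- eval_set$positives$a[i]
      b <- eval_set$positives$b[i]
      ((ranks[[a]][[b]] - 1) + (ranks[[b]][[a]] - 1)) / (2 * (n_cand - 1))
    }, numeric(1))
  }
  out <- data.frame(
    geneA = eval_set$positives$a, geneB = eval_set$positives$b,
    rank_baseline = norm_pos(baseline_profiles),
    rank_augmented = norm_pos(augmented_profiles),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
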