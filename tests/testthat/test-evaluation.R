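test_that("pair filtering keeps pairs with novel-function coverage", {
  pairs <- interaction_pairs(c("a", "c", "e"), c("b", "d", "f"),
                             "genetic", "synthetic")
  inferred <- data.frame(gene = c("a", "c", "d"), term = "GO:1",
                         novel = c(TRUE, FALSE, TRUE),
                         stringsAsFactors = FALSE)
  either <- filter_pairs(pairs, inferred)
  expect_equal(either$positives$a, c("a", "c"))  # a novel; d novel covers (c,d)
  both <- filter_pairs(pairs, inferred, policy = "both")
  expect_equal(nrow(both$positives), 0L)  # b never gained a novel function
  none <- filter_pairs(pairs, inferred[0, ])
  expect_equal(nrow(none$positives), 0L)
})

test_that("perfect and inverted rankings give AUC 1 and 0", {
  r <- roc_from_scores(c(.9, .8, .3, .1), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(r$auc, 1)
  expect_equal(r$curve[1, ], data.frame(fpr = 0, tpr = 0), ignore_attr = TRUE)
  expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
  expect_equal(roc_from_scores(c(.1, .9), c(TRUE, FALSE))$auc, 0)
  expect_error(roc_from_scores(1:3, c(TRUE, TRUE, TRUE)), "negative")
  expect_error(roc_from_scores(1:3, c(FALSE, FALSE, FALSE)), "positive")
})

test_that("ROC coordinates are monotone and AUC is rank-invariant", {
  set.seed(61)
  scores <- sample(seq(0, 1, by = 0.1), 60, replace = TRUE)  # heavy ties
  labels <- runif(60) < 0.4
  r <- roc_from_scores(scores, labels)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  # strictly monotone transformation leaves the AUC unchanged
  expect_equal(roc_from_scores(exp(3 * scores), labels)$auc, r$auc)
})

test_that("threshold-sweep AUC equals the Mann-Whitney statistic", {
  # hand-set 6-pair toy against the exhaustive concordance count
  scores <- c(0.9, 0.7, 0.7, 0.5, 0.3, 0.1)
  labels <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  expect_equal(roc_from_scores(scores, labels)$auc,
               oracle_concordance_auc(scores, labels))
  set.seed(62)
  for (rep in 1:30) {
    n <- sample(10:60, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
    labels <- runif(n) < runif(1, 0.2, 0.8)
    if (!any(labels) || all(labels)) next
    auc <- roc_from_scores(scores, labels)$auc
    expect_equal(auc, oracle_mw_auc(scores, labels), tolerance = 1e-12)
    expect_equal(auc, oracle_concordance_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(63)
  scores <- round(runif(200), 2)
  labels <- runif(200) < 0.5
  ours <- roc_from_scores(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = labels, predictor = scores,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("pooled ROC scores all candidate pairs over the universe", {
  prof <- profiles_from_sets(list(
    a = c("T:1", "T:2"), b = c("T:1", "T:2"), c = "T:9", d = "T:8"
  ))
  pos <- interaction_pairs("a", "b", "protein-protein", "synthetic")
  es <- evaluation_set(pos, names(prof))
  r <- pooled_roc(es, prof)
  expect_equal(r$n_pos, 1L)
  expect_equal(r$n_neg, 5L)
  expect_identical(r$auc, 1)  # the only positive pair has the top score
})

test_that("per-gene AUC is 1 when the partner tops the ranking, 0 when last", {
  prof <- profiles_from_sets(list(
    g = c("T:1", "T:2"), top = c("T:1", "T:2"), far = "T:9", mid = "T:1"
  ))
  es <- evaluation_set(interaction_pairs("g", "top", "genetic", "s"),
                       names(prof))
  pg <- per_gene_aucs(es, prof)
  expect_equal(pg$auc[pg$gene == "g"], 1)
  es2 <- evaluation_set(interaction_pairs("g", "far", "genetic", "s"),
                        names(prof))
  pg2 <- per_gene_aucs(es2, prof)
  expect_equal(pg2$auc[pg2$gene == "g"], 0)
})

test_that("per-gene AUCs match the Mann-Whitney oracle", {
  set.seed(64)
  univ <- sprintf("T:%03d", 1:25)
  sets <- lapply(1:20, function(i) sample(univ, sample(1:6, 1)))
  names(sets) <- paste0("GN:", 1:20)
  prof <- profiles_from_sets(sets)
  pos <- interaction_pairs(sample(names(sets), 8), sample(names(sets), 8),
                           "genetic", "s")
  es <- evaluation_set(pos, names(sets))
  pg <- per_gene_aucs(es, prof)
  partners <- function(g) unique(c(pos$b[pos$a == g], pos$a[pos$b == g]))
  for (i in seq_len(nrow(pg))) {
    g <- pg$gene[i]
    others <- setdiff(names(sets), g)
    scores <- vapply(others, function(o) jaccard(prof[[g]], prof[[o]]),
                     numeric(1))
    expect_equal(pg$auc[i], oracle_mw_auc(scores, others %in% partners(g)),
                 tolerance = 1e-12)
  }
})

test_that("identical baseline and augmented profiles give p = 0.5, delta 0", {
  set.seed(65)
  univ <- sprintf("T:%03d", 1:20)
  sets <- lapply(1:12, function(i) sample(univ, 4))
  names(sets) <- paste0("GN:", 1:12)
  prof <- profiles_from_sets(sets)
  pos <- interaction_pairs(paste0("GN:", 1:4), paste0("GN:", 5:8), "genetic", "s")
  es <- evaluation_set(pos, names(sets))
  cmp <- compare_profiles(prof, prof, es)
  expect_equal(cmp$auc_baseline, cmp$auc_augmented)
  expect_equal(cmp$p_value, 0.5)
  expect_equal(mean(cmp$per_gene$auc_augmented - cmp$per_gene$auc_baseline), 0)
})

test_that("augmenting profiles with held-out truth raises the AUC and the
          p-value matches the closed-form paired t", {
  w <- generate_world(world_params(annotation_subsample_rate = 0.5, seed = 67),
                      tempfile())
  anns <- parse_gaf(w$files[["gaf"]])
  inf <- infer_functions(w$phenotype_annotations, w$eq_definitions,
                         w$genotype_map)
  cls <- classify_novelty(inf, anns, w$go_ontology)
  manual <- filter_by_evidence(anns, c("IMP", "IDA", "EXP"))
  genes <- names(w$true_functions)
  base <- build_profiles(genes, manual, w$go_ontology)
  aug <- build_profiles(genes, manual, w$go_ontology, extra = cls$inferred)
  es <- filter_pairs(w$planted_interactions, cls$inferred, profiles = base)
  cmp <- compare_profiles(base, aug, es)
  expect_gt(cmp$auc_augmented, cmp$auc_baseline)
  # the reported p is the one-tailed paired t over per-gene AUCs: a
  # constant-plus-jitter difference vector reproduces it from the t CDF
  d <- cmp$per_gene$auc_augmented - cmp$per_gene$auc_baseline
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(cmp$p_value,
               pt(tstat, df = length(d) - 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("treating planted positives as negatives only deflates the AUC", {
  set.seed(68)
  univ <- sprintf("T:%03d", 1:30)
  genes <- paste0("GN:", 1:16)
  shared <- sample(univ, 5)
  # first 8 genes share a core annotation -> they are mutually similar
  sets <- c(lapply(1:8, function(i) c(shared, sample(univ, 2))),
            lapply(1:8, function(i) sample(univ, 4)))
  names(sets) <- genes
  prof <- profiles_from_sets(sets)
  all_pos <- interaction_pairs(paste0("GN:", c(1, 3, 5, 7)),
                               paste0("GN:", c(2, 4, 6, 8)), "genetic", "s")
  full <- pooled_roc(evaluation_set(all_pos, genes), prof)
  # hide half the true interactions: they fall into the negative pool
  held_out <- pooled_roc(evaluation_set(all_pos[1:2, ], genes), prof)
  expect_lte(held_out$auc, full$auc)
})

test_that("pair-rank export puts mutually top-ranked pairs at 0", {
  prof <- profiles_from_sets(list(
    a = c("T:1", "T:2"), b = c("T:1", "T:2"), c = "T:8", d = "T:9"
  ))
  es <- evaluation_set(interaction_pairs("a", "b", "genetic", "s"),
                       names(prof))
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- write_pair_ranks(es, prof, prof, path)
  expect_equal(out$rank_baseline, 0)
  expect_true(file.exists(path))
})
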