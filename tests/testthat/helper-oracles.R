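# Independent oracles and small fixture builders used across the suite.

# Brute-force ancestor closure by repeated edge expansion over a parent
# list (independent of the package's BFS).
oracle_closure <- function(parent_list, seed) {
  result <- unique(seed)
  repeat {
    expanded <- unique(c(result, unlist(parent_list[result], use.names = FALSE)))
    if (length(expanded) == length(result)) {
      return(sort(result))
    }
    result <- expanded
  }
}

# Brute-force descendant set: all terms whose oracle closure meets roots.
oracle_descendants <- function(parent_list, roots) {
  ids <- names(parent_list)
  sort(unique(c(roots, ids[vapply(ids, function(t) {
    any(oracle_closure(parent_list, t) %in% roots)
  }, logical(1))])))
}

# Random DAG serialized as OBO text, with the generating edge list kept
# for round-trip comparison. Term 1 is the root.
random_obo_fixture <- function(n, branching = 2, seed = 1) {
  set.seed(seed)
  ids <- sprintf("T:%04d", seq_len(n))
  parents <- vector("list", n)
  names(parents) <- ids
  lines <- c("format-version: 1.2", "")
  for (i in seq_len(n)) {
    stanza <- c("[Term]", paste0("id: ", ids[i]), paste0("name: term ", i))
    if (i > 1) {
      k <- sample.int(min(branching, i - 1L), 1L)
      ps <- ids[sort(sample.int(i - 1L, k))]
      parents[[i]] <- ps
      stanza <- c(stanza, paste0("is_a: ", ps))
    } else {
      parents[[i]] <- character()
    }
    lines <- c(lines, stanza, "")
  }
  list(text = lines, ids = ids, parents = parents)
}

# Mann-Whitney AUC with average-rank tie handling: U / (n_pos * n_neg).
oracle_mw_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Exhaustive concordance count: P(score_pos > score_neg) + 0.5 P(equal).
oracle_concordance_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Profiles straight from term sets (no ontology), for similarity and ROC
# tests that do not need a closure.
profiles_from_sets <- function(sets) {
  out <- lapply(names(sets), function(g) list(gene = g, closed_terms = sets[[g]]))
  names(out) <- names(sets)
  out
}

# The worked-example inputs: a lactation-failure phenotype term defined as
# quality 'lacking processual parts' inhering in the GO process lactation.
vgf_fixture_files <- function(dir) {
  defs <- file.path(dir, "mp-definitions.obo")
  writeLines(c(
    "[Term]",
    "id: MP:0010249",
    "name: lactation failure",
    "intersection_of: PATO:0001558",
    "intersection_of: inheres_in GO:0007595"
  ), defs)
  phens <- file.path(dir, "phenotypes.tsv")
  writeLines("MGI:2179681\tMP:0010249", phens)
  gmap <- file.path(dir, "genotype_map.tsv")
  writeLines("MGI:2179681\tVgf", gmap)
  list(definitions = defs, phenotypes = phens, genotype_map = gmap)
}
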