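#' @title Inferring GO functions from mutant phenotypes
#' @description The core inference rule: if a mutation in a gene leads to
#'   a phenotypic abnormality in a biological process or function, the
#'   gene must have been involved in that process. Phenotype-ontology
#'   terms are decomposed through their Entity/Quality definitions; when
#'   the affected entity is a GO term, it is transferred to every gene
#'   mutated in the annotated genotype.
#' @name inference
NULL

#' Infer GO functions from phenotype annotations
#'
#' For each phenotype annotation the affected GO entity (or entities) is
#' identified: pre-composed phenotype terms are looked up in the EQ
#' definition map and their GO differentia fillers extracted
#' ([extract_go_entities()]); post-composed annotations contribute their
#' entity member directly when its prefix is GO. The subject (genotype,
#' morpholino or gene) is resolved to mutated genes through `gmap`; when a
#' genotype maps to several genes, every mapped gene receives the
#' function. Each distinct (gene, GO term) pair is emitted once with
#' merged provenance, in canonical (gene, term) order.
#'
#' Annotations contribute nothing when their term has no definition, the
#' definition has no GO entity, or the subject is absent from `gmap`;
#' each case is counted in the `diagnostics` attribute.
#'
#' @param phens phenotype-annotation table ([parse_phenotype_table()]).
#' @param defs EQ definition map ([parse_eq_definitions()]); may be empty
#'   when all annotations are post-composed.
#' @param gmap named list subject -> gene ids, or `NULL` for the identity
#'   mapping (subjects already are genes).
#' @param ont optional ontology (unused by the rule itself; accepted for
#'   interface symmetry with the evaluation operations).
#' @param go_prefixes identifier prefixes counted as GO entities.
#' @return data frame of class `inferred_functions` with columns `gene`,
#'   `term`, `novel` (NA until [classify_novelty()] is applied) and a
#'   list-column `provenance` of `"subject phenotype"` strings.
#' @examples
#' defs <- parse_eq_definitions(text = c(
#'   "[Term]", "id: MP:0010249",
#'   "intersection_of: PATO:0001558",
#'   "intersection_of: inheres_in GO:0007595"))
#' phens <- parse_phenotype_table(text = "MGI:2179681\tMP:0010249")
#' infer_functions(phens, defs, gmap = list("MGI:2179681" = "Vgf"))
#' @export
infer_functions <- function(phens, defs, gmap = NULL, ont = NULL,
                            go_prefixes = "GO") {
  n_in <- nrow(phens)
  skipped_subject <- 0L
  skipped_nodef <- 0L
  skipped_noentity <- 0L
  acc <- new.env(parent = emptyenv())  # key gene\rterm -> provenance vector
  for (i in seq_len(n_in)) {
    subject <- phens$subject[i]
    if (is.null(gmap)) {
      genes <- subject
    } else {
      genes <- gmap[[subject]]
      if (is.null(genes)) {
        skipped_subject <- skipped_subject + 1L
        next
      }
    }
    if (!is.na(phens$phenotype[i])) {
      pid <- phens$phenotype[i]
      d <- defs[[pid]]
      if (is.null(d)) {
        skipped_nodef <- skipped_nodef + 1L
        next
      }
      entities <- extract_go_entities(d, go_prefixes)
      prov_label <- pid
    } else {
      ent <- phens$entity[i]
      entities <- ent[id_prefix(ent) %in% go_prefixes]
      prov_label <- paste0(phens$entity[i], "/", phens$quality[i])
    }
    if (length(entities) == 0L) {
      skipped_noentity <- skipped_noentity + 1L
      next
    }
    for (g in genes) {
      for (t in entities) {
        key <- paste(g, t, sep = "\r")
        assign(key, c(if (exists(key, envir = acc, inherits = FALSE)) get(key, envir = acc),
                      paste(subject, prov_label)),
               envir = acc)
      }
    }
  }
  keys <- sort(ls(envir = acc))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    gene = vapply(parts, `[`, character(1), 1),
    term = vapply(parts, `[`, character(1), 2),
    novel = rep(NA, length(keys)),
    stringsAsFactors = FALSE
  )
  out$provenance <- I(lapply(keys, function(k) sort(unique(get(k, envir = acc)))))
  class(out) <- c("inferred_functions", "data.frame")
  attr(out, "diagnostics") <- list(
    rows_in = n_in,
    rows_parsed = n_in - skipped_subject - skipped_nodef - skipped_noentity,
    rows_skipped = skipped_subject + skipped_nodef + skipped_noentity,
    skipped_unmapped_subject = skipped_subject,
    skipped_no_definition = skipped_nodef,
    skipped_no_go_entity = skipped_noentity
  )
  out
}

#' Classify inferred functions as novel or known
#'
#' An inferred pair (g, t) is KNOWN when t lies in the superclass closure
#' of g's existing manual-evidence annotation terms — i.e. the inference
#' adds no information beyond (or is more general than) what is already
#' annotated. Otherwise it is NOVEL. `mode = "exact"` instead requires an
#' identical existing term.
#'
#' @param inferred table from [infer_functions()].
#' @param existing GAF annotation table (NOT rows are dropped internally).
#' @param ont ontology used for the closure.
#' @param manual_codes evidence codes counted as manually created
#'   annotation (default [manual_evidence_codes()]).
#' @param mode `"closure"` (subsumption, default) or `"exact"`.
#' @param relations closure edge types, see [superclass_closure()].
#' @return list with `inferred` (the input with `novel` filled in) and
#'   `summary` = `c(novel = ..., known = ...)`.
#' @export
classify_novelty <- function(inferred, existing, ont,
                             manual_codes = manual_evidence_codes(),
                             mode = c("closure", "exact"),
                             relations = "is_a") {
  mode <- match.arg(mode)
  manual <- filter_by_evidence(default_annotations(existing), manual_codes)
  terms_by_gene <- split(manual$term, manual$gene)
  known_ids <- c(ont$terms$id, ont$dangling)
  closed_cache <- list()
  gene_known_set <- function(g) {
    ts <- unique(terms_by_gene[[g]])
    if (is.null(ts) || length(ts) == 0L) return(character())
    if (mode == "exact") return(ts)
    key <- g
    if (!is.null(closed_cache[[key]])) return(closed_cache[[key]])
    ts <- intersect(ts, known_ids)
    cl <- if (length(ts)) superclass_closure(ont, ts, relations) else character()
    closed_cache[[key]] <<- cl
    cl
  }
  novel <- logical(nrow(inferred))
  for (g in unique(inferred$gene)) {
    idx <- which(inferred$gene == g)
    ks <- gene_known_set(g)
    novel[idx] <- !(inferred$term[idx] %in% ks)
  }
  inferred$novel <- novel
  list(inferred = inferred,
       summary = c(novel = sum(novel), known = sum(!novel)))
}

#' Audit inferred functions against existing annotation in a GO
#' neighbourhood
#'
#' For every gene inferred to `focus_term`, lists its existing annotations
#' that lie in the descendant closure of any neighbourhood root — the
#' machinery behind a "does this gene already have relevant annotation?"
#' table (e.g. genes inferred to erythrocyte development, audited against
#' all child classes of myeloid cell differentiation or erythrocyte
#' homeostasis).
#'
#' @param inferred table from [infer_functions()].
#' @param existing GAF annotation table.
#' @param ont ontology.
#' @param focus_term the inferred GO term being audited.
#' @param neighbourhood_roots GO terms whose descendant closures count as
#'   "relevant" existing annotation.
#' @param relations closure edge types.
#' @return data frame with columns `gene`, `existing` (relevant existing
#'   terms, `|`-joined, empty when none) and `inferred` (= `focus_term`).
#' @export
neighbourhood_audit <- function(inferred, existing, ont, focus_term,
                                neighbourhood_roots, relations = "is_a") {
  relevant <- descendant_closure(ont, neighbourhood_roots, relations)
  genes <- sort(unique(inferred$gene[inferred$term == focus_term]))
  existing <- default_annotations(existing)
  rel_terms <- vapply(genes, function(g) {
    ts <- sort(unique(existing$term[existing$gene == g & existing$term %in% relevant]))
    paste(ts, collapse = "|")
  }, character(1))
  data.frame(gene = genes, existing = unname(rel_terms),
             inferred = rep(focus_term, length(genes)),
             stringsAsFactors = FALSE)
}

#' Write inferred functions as a GAF 2.1 file
#'
#' Electronically inferred annotations carry the IEA evidence code; the
#' provenance phenotype identifier goes in the with/from column.
#'
#' @param inferred table from [infer_functions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_inferred_gaf <- function(inferred, path) {
  withf <- vapply(inferred$provenance, function(p) {
    phens <- vapply(strsplit(p, " ", fixed = TRUE), function(x) x[length(x)], character(1))
    paste(unique(phens), collapse = "|")
  }, character(1))
  anns <- data.frame(gene = inferred$gene, term = inferred$term,
                     evidence = rep("IEA", nrow(inferred)),
                     with_field = as.character(withf),
                     stringsAsFactors = FALSE)
  write_gaf(anns, path)
}

#' Write inferred functions as plain TSV
#'
#' Columns: gene, GO id, novel flag, provenance (`;`-joined
#' `"subject phenotype"` entries).
#'
#' @inheritParams write_inferred_gaf
#' @return `path`, invisibly.
#' @export
write_inferred_tsv <- function(inferred, path) {
  prov <- vapply(inferred$provenance, paste, character(1), collapse = ";")
  writeLines(c("gene\tterm\tnovel\tprovenance",
               paste(inferred$gene, inferred$term, inferred$novel, prov, sep = "\t")),
             path)
  invisible(path)
}

#' Read an inferred-function TSV written by [write_inferred_tsv()]
#' @param file path.
#' @return `inferred_functions` data frame.
#' @export
read_inferred_tsv <- function(file) {
  lines <- read_input_lines(file)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  out <- data.frame(
    gene = vapply(fields, `[`, character(1), 1),
    term = vapply(fields, `[`, character(1), 2),
    novel = as.logical(vapply(fields, `[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
  out$provenance <- I(lapply(fields, function(f) {
    if (length(f) >= 4) strsplit(f[4], ";", fixed = TRUE)[[1]] else character()
  }))
  class(out) <- c("inferred_functions", "data.frame")
  out
}
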