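#' @title Seeded synthetic worlds with known ground truth
#' @description Generates a complete, internally consistent miniature of
#'   the data ecosystem the pipeline consumes: a GO-like DAG, a quality
#'   ontology, a phenotype ontology with Entity/Quality cross-product
#'   definitions, a baseline GAF (subsampled true functions plus IGI/IPI
#'   interaction rows), phenotype annotations derived from true functions,
#'   and STRING/BioGRID interaction files — all with a ledger of the
#'   planted truth so any module's output can be scored exactly.
#' @name synthetic
NULL

#' Parameters of a synthetic world
#'
#' All Bernoulli thinning steps (annotation subsampling, phenotyping,
#' noise corruption, interaction planting) draw one uniform per candidate
#' item regardless of the rate, so under a fixed seed the selected sets
#' are nested across rate levels: raising `noise_rate` only corrupts
#' additional annotations, never different ones.
#'
#' @param n_go_terms number of GO-like terms (term 1 is the root).
#' @param go_dag_branching maximum number of is_a parents per term.
#' @param n_phenotype_terms number of phenotype-ontology terms.
#' @param fraction_defined share of phenotype terms carrying an EQ
#'   definition (default 0.71, the completeness typical of a mature
#'   phenotype ontology with formal definitions).
#' @param fraction_go_entity share of definitions whose entity filler is a
#'   GO term rather than an anatomy term.
#' @param n_genes number of genes.
#' @param functions_per_gene true GO functions planted per gene.
#' @param annotation_subsample_rate share of true functions present in the
#'   baseline GAF (incomplete curation).
#' @param phenotyping_rate share of true functions expressed as phenotype
#'   annotations.
#' @param noise_rate share of phenotype annotations corrupted to a random
#'   wrong phenotype term.
#' @param interaction_coupling scale of the logistic link between
#'   shared-true-function count and interaction probability.
#' @param seed integer seed; the same seed yields a byte-identical world.
#' @return object of class `world_params`.
#' @export
world_params <- function(n_go_terms = 150L, go_dag_branching = 2L,
                         n_phenotype_terms = 150L, fraction_defined = 0.71,
                         fraction_go_entity = 0.6, n_genes = 80L,
                         functions_per_gene = 4L,
                         annotation_subsample_rate = 0.7,
                         phenotyping_rate = 0.8, noise_rate = 0.05,
                         interaction_coupling = 0.6, seed = 42L) {
  p <- list(n_go_terms = as.integer(n_go_terms),
            go_dag_branching = as.integer(go_dag_branching),
            n_phenotype_terms = as.integer(n_phenotype_terms),
            fraction_defined = fraction_defined,
            fraction_go_entity = fraction_go_entity,
            n_genes = as.integer(n_genes),
            functions_per_gene = as.integer(functions_per_gene),
            annotation_subsample_rate = annotation_subsample_rate,
            phenotyping_rate = phenotyping_rate,
            noise_rate = noise_rate,
            interaction_coupling = interaction_coupling,
            seed = as.integer(seed))
  rates <- c("fraction_defined", "fraction_go_entity",
             "annotation_subsample_rate", "phenotyping_rate", "noise_rate",
             "interaction_coupling")
  for (r in rates) {
    if (p[[r]] < 0 || p[[r]] > 1) stop(r, " must be in [0, 1]")
  }
  for (cnt in c("n_go_terms", "n_phenotype_terms", "n_genes",
                "functions_per_gene", "go_dag_branching")) {
    if (p[[cnt]] < 1L) stop(cnt, " must be positive")
  }
  if (p$functions_per_gene > p$n_go_terms) {
    stop("functions_per_gene cannot exceed n_go_terms")
  }
  structure(p, class = "world_params")
}

# in-memory ontology constructor used by the generator
make_ontology <- function(ids, names, namespace, parents, obsolete = NULL) {
  if (is.null(obsolete)) obsolete <- rep(FALSE, length(ids))
  names(parents) <- ids
  structure(
    list(terms = data.frame(id = ids, name = names, namespace = namespace,
                            obsolete = obsolete, stringsAsFactors = FALSE),
         parents = parents, relations = list(), dangling = character()),
    class = "obo_ontology"
  )
}

# random DAG over n terms: term 1 is the root, each later term gets
# 1..branching parents among earlier terms
random_dag_parents <- function(n, branching, ids) {
  parents <- vector("list", n)
  parents[[1]] <- character()
  for (i in seq_len(n)[-1]) {
    k <- sample.int(min(branching, i - 1L), 1L)
    parents[[i]] <- ids[sort(sample.int(i - 1L, k))]
  }
  parents
}

#' Generate a synthetic world
#'
#' Emits all input files of the pipeline into `dir` and returns a ledger
#' holding the planted ground truth. The generation is fully determined
#' by `params$seed`: the same parameters produce byte-identical files.
#' A manifest (`manifest.tsv`) lists every emitted file with its MD5.
#'
#' @param params a [world_params()] object.
#' @param dir output directory (created if needed).
#' @return object of class `world_ledger`: `params`, `files` (named
#'   paths), `true_functions` (named list gene -> GO terms),
#'   `expressed_functions` (the subset expressed as uncorrupted phenotype
#'   annotations), `planted_interactions` (canonical pair table),
#'   `defined_terms`, plus the in-memory ontologies (`go_ontology`,
#'   `phenotype_ontology`), definitions (`eq_definitions`) and genotype
#'   map (`genotype_map`).
#' @export
generate_world <- function(params = world_params(), dir = tempfile("world")) {
  stopifnot(inherits(params, "world_params"))
  p <- params
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(p$seed)

  ## 1. GO-like DAG
  go_ids <- sprintf("GO:%07d", seq_len(p$n_go_terms))
  go_parents <- random_dag_parents(p$n_go_terms, p$go_dag_branching, go_ids)
  ont_go <- make_ontology(go_ids, paste("process", seq_len(p$n_go_terms)),
                          "biological_process", go_parents)

  ## 2. quality ontology (flat list of PATO-like qualities)
  n_qual <- 8L
  pato_ids <- sprintf("PATO:%07d", seq_len(n_qual))
  ont_pato <- make_ontology(pato_ids, paste("quality", seq_len(n_qual)),
                            "quality", rep(list(character()), n_qual))

  ## 3. phenotype ontology with EQ definitions
  n_ph <- p$n_phenotype_terms
  ph_ids <- sprintf("PH:%07d", seq_len(n_ph))
  ph_parents <- random_dag_parents(n_ph, 1L, ph_ids)
  anat_ids <- sprintf("UBERON:%07d", seq_len(n_ph))
  u_def <- stats::runif(n_ph)
  u_ent <- stats::runif(n_ph)
  genus_pick <- sample.int(n_qual, n_ph, replace = TRUE)
  defined <- u_def < p$fraction_defined
  go_entity <- u_ent < p$fraction_go_entity
  if (!any(defined)) stop("parameters yield zero defined phenotype terms")
  defs <- list()
  entity_of <- rep(NA_character_, n_ph)
  for (i in which(defined)) {
    entity_of[i] <- if (go_entity[i]) go_ids[((i - 1L) %% p$n_go_terms) + 1L] else anat_ids[i]
    defs[[ph_ids[i]]] <- structure(
      list(defined_term = ph_ids[i], genus = pato_ids[genus_pick[i]],
           differentia = data.frame(relation = "inheres_in",
                                    filler = entity_of[i],
                                    stringsAsFactors = FALSE)),
      class = "eq_definition"
    )
  }
  ont_ph <- make_ontology(ph_ids, paste("phenotype", seq_len(n_ph)),
                          "phenotype", ph_parents)
  # phenotype term expressing each GO term (first defined GO-entity term)
  ph_of_go <- list()
  for (i in which(defined & go_entity)) {
    t <- entity_of[i]
    if (is.null(ph_of_go[[t]])) ph_of_go[[t]] <- ph_ids[i]
  }
  def_go_terms <- ph_ids[defined & go_entity]

  ## 4. genes, genotypes, true functions
  gene_ids <- sprintf("GN:%04d", seq_len(p$n_genes))
  geno_ids <- sprintf("GT:%04d", seq_len(p$n_genes))
  gmap <- stats::setNames(as.list(gene_ids), geno_ids)
  true_functions <- lapply(seq_len(p$n_genes), function(i) {
    sort(go_ids[sample.int(p$n_go_terms, p$functions_per_gene)])
  })
  names(true_functions) <- gene_ids

  ## 5. baseline GAF (subsampled true functions, manual evidence)
  gf_gene <- rep(gene_ids, each = p$functions_per_gene)
  gf_term <- unlist(true_functions, use.names = FALSE)
  nf <- length(gf_gene)
  u_sub <- stats::runif(nf)
  ev_pick <- sample(c("IMP", "IDA", "EXP"), nf, replace = TRUE)
  in_gaf <- u_sub < p$annotation_subsample_rate
  gaf <- data.frame(gene = gf_gene[in_gaf], term = gf_term[in_gaf],
                    evidence = ev_pick[in_gaf], stringsAsFactors = FALSE)

  ## 6. phenotype annotations from true functions
  u_phen <- stats::runif(nf)
  u_noise <- stats::runif(nf)
  u_repl <- stats::runif(nf)
  subj <- character(); phen <- character()
  expressed <- stats::setNames(vector("list", p$n_genes), gene_ids)
  K <- length(def_go_terms)
  for (j in seq_len(nf)) {
    if (u_phen[j] >= p$phenotyping_rate) next
    pterm <- ph_of_go[[gf_term[j]]]
    if (is.null(pterm)) next
    if (u_noise[j] < p$noise_rate && K > 1L) {
      ri <- floor(u_repl[j] * (K - 1L)) + 1L
      wrong <- setdiff(def_go_terms, pterm)[ri]
      pterm <- wrong
    } else {
      g <- gf_gene[j]
      expressed[[g]] <- sort(unique(c(expressed[[g]], gf_term[j])))
    }
    subj <- c(subj, geno_ids[match(gf_gene[j], gene_ids)])
    phen <- c(phen, pterm)
  }
  phens <- data.frame(subject = subj, phenotype = phen,
                      entity = NA_character_, quality = NA_character_,
                      stringsAsFactors = FALSE)

  ## 7. interactions: P(interact) = coupling * logistic(2*(shared - 1))
  cmb <- utils::combn(p$n_genes, 2L)
  npairs <- ncol(cmb)
  u_int <- stats::runif(npairs)
  u_kind <- stats::runif(npairs)
  pa <- character(); pb <- character(); pkind <- character()
  for (k in seq_len(npairs)) {
    i <- cmb[1, k]; j <- cmb[2, k]
    shared <- length(intersect(true_functions[[i]], true_functions[[j]]))
    prob <- p$interaction_coupling * stats::plogis(2 * (shared - 1))
    if (u_int[k] < prob) {
      pa <- c(pa, gene_ids[i]); pb <- c(pb, gene_ids[j])
      pkind <- c(pkind, if (u_kind[k] < 0.5) "genetic" else "protein-protein")
    }
  }
  planted <- interaction_pairs(pa, pb, pkind, "synthetic")

  ## 8. encode interactions: IGI/IPI GAF rows, STRING and BioGRID files
  int_rows <- data.frame(gene = character(), term = character(),
                         evidence = character(), with_field = character(),
                         stringsAsFactors = FALSE)
  for (k in seq_len(nrow(planted))) {
    a <- planted$a[k]; b <- planted$b[k]
    shared <- intersect(true_functions[[a]], true_functions[[b]])
    term <- if (length(shared)) shared[1] else true_functions[[a]][1]
    code <- if (planted$kind[k] == "genetic") "IGI" else "IPI"
    int_rows <- rbind(int_rows, data.frame(gene = a, term = term,
                                           evidence = code, with_field = b,
                                           stringsAsFactors = FALSE))
  }
  gaf$with_field <- character(nrow(gaf))
  gaf_all <- rbind(gaf, int_rows)
  string_pairs <- planted[planted$kind == "protein-protein", , drop = FALSE]
  string_scores <- sample(150:999, nrow(string_pairs), replace = TRUE)

  ## 9. emit files
  files <- c(
    go_ontology = file.path(dir, "go.obo"),
    quality_ontology = file.path(dir, "qualities.obo"),
    phenotype_ontology = file.path(dir, "phenotypes.obo"),
    gaf = file.path(dir, "annotations.gaf"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    genotype_map = file.path(dir, "genotype_map.tsv"),
    string = file.path(dir, "string_links.txt"),
    biogrid = file.path(dir, "biogrid.txt")
  )
  write_obo(ont_go, files[["go_ontology"]])
  write_obo(ont_pato, files[["quality_ontology"]])
  write_obo(ont_ph, files[["phenotype_ontology"]], defs = defs)
  write_gaf(gaf_all, files[["gaf"]])
  write_phenotype_table(phens, files[["phenotypes"]])
  write_genotype_map(gmap, files[["genotype_map"]])
  write_string_links(string_pairs, files[["string"]], scores = string_scores)
  write_biogrid(planted, files[["biogrid"]])
  manifest <- data.frame(file = basename(unname(files)),
                         md5 = unname(tools::md5sum(unname(files))),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  structure(
    list(params = p, dir = dir, files = files, manifest = manifest,
         true_functions = true_functions,
         expressed_functions = lapply(expressed, function(x) x %||% character()),
         planted_interactions = planted,
         defined_terms = ph_ids[defined],
         go_ontology = ont_go, phenotype_ontology = ont_ph,
         quality_ontology = ont_pato, eq_definitions = defs,
         genotype_map = gmap, phenotype_annotations = phens,
         baseline_gaf = gaf_all),
    class = "world_ledger"
  )
}

#' @export
print.world_ledger <- function(x, ...) {
  cat(sprintf(paste0("Synthetic world (seed %d): %d GO terms, %d phenotype terms ",
                     "(%d defined), %d genes, %d planted interactions\n"),
              x$params$seed, x$params$n_go_terms, x$params$n_phenotype_terms,
              length(x$defined_terms), x$params$n_genes,
              nrow(x$planted_interactions)))
  invisible(x)
}

#' Curated audit table: mouse genes inferred to erythrocyte development
#'
#' The packaged transcription of a published audit of phenotype-inferred
#' annotations to erythrocyte development (GO:0048821) in mouse: for each
#' gene, any existing GO annotation in the erythroid/myeloid
#' neighbourhood and an example allele supporting the new annotation.
#' Useful as a realistic fixture for [neighbourhood_audit()] output
#' shapes. Allele superscripts were not recoverable from the source
#' transcription; such entries carry the base allele symbol only.
#'
#' @return data frame with columns `mgi_id`, `gene`,
#'   `existing_annotation` (GO id and name, or empty) and `allele`.
#' @export
table3_fixture <- function() {
  path <- system.file("extdata", "table3_erythrocyte_development.tsv",
                      package = "phenofun", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character", fill = TRUE)
  tab[is.na(tab)] <- ""
  tab
}
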