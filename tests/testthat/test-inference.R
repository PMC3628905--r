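# The canonical worked example: a targeted Vgf mutation shows lactation
# failure; the phenotype decomposes into quality 'lacking processual
# parts' and entity lactation (a GO process), so Vgf is inferred to be
# involved in lactation.
test_that("the lactation-failure example infers (Vgf, GO:0007595)", {
  fx <- vgf_fixture_files(withr::local_tempdir())
  defs <- parse_eq_definitions(fx$definitions)
  phens <- parse_phenotype_table(fx$phenotypes)
  gmap <- parse_genotype_map(fx$genotype_map)
  inf <- infer_functions(phens, defs, gmap)
  expect_equal(nrow(inf), 1L)
  expect_equal(inf$gene, "Vgf")
  expect_equal(inf$term, "GO:0007595")
  expect_equal(inf$provenance[[1]], "MGI:2179681 MP:0010249")
})

test_that("anatomy-only definitions and unmapped subjects contribute nothing", {
  defs <- parse_eq_definitions(text = c(
    "[Term]", "id: MP:0000010",
    "intersection_of: PATO:0000001",
    "intersection_of: inheres_in UBERON:0000001"
  ))
  phens <- parse_phenotype_table(text = c("S:1\tMP:0000010", "S:2\tMP:0000010",
                                          "S:3\tMP:9999999"))
  gmap <- list("S:1" = "GN:1", "S:3" = "GN:3")
  inf <- infer_functions(phens, defs, gmap)
  expect_equal(nrow(inf), 0L)
  d <- diagnostics(inf)
  expect_equal(d$skipped_unmapped_subject, 1L)
  expect_equal(d$skipped_no_go_entity, 1L)
  expect_equal(d$skipped_no_definition, 1L)
  expect_equal(d$rows_in, d$rows_parsed + d$rows_skipped)
})

test_that("a genotype mapping to several genes assigns the function to all", {
  defs <- parse_eq_definitions(text = c(
    "[Term]", "id: MP:0000011",
    "intersection_of: PATO:0000001",
    "intersection_of: inheres_in GO:0000123"
  ))
  phens <- parse_phenotype_table(text = "GT:1\tMP:0000011")
  inf <- infer_functions(phens, defs, list("GT:1" = c("GN:1", "GN:2")))
  expect_equal(inf$gene, c("GN:1", "GN:2"))
  expect_equal(unique(inf$term), "GO:0000123")
})

test_that("post-composed annotations use the entity member directly", {
  phens <- parse_phenotype_table(text = c(
    "GN:1\tGO:0007595\tPATO:0001558",
    "GN:2\tUBERON:0000001\tPATO:0001558"
  ), dialect = "zfin-postcomposed")
  inf <- infer_functions(phens, defs = list(), gmap = NULL)
  expect_equal(inf$gene, "GN:1")
  expect_equal(inf$term, "GO:0007595")
})

test_that("inference output is independent of input ordering", {
  w <- generate_world(world_params(n_genes = 20L, seed = 31), tempfile())
  defs <- w$eq_definitions
  phens <- w$phenotype_annotations
  gmap <- w$genotype_map
  a <- infer_functions(phens, defs, gmap)
  set.seed(1)
  b <- infer_functions(phens[sample(nrow(phens)), ], defs, gmap)
  expect_equal(a$gene, b$gene)
  expect_equal(a$term, b$term)
  expect_equal(a$provenance, b$provenance)
})

test_that("every inferred term traces back to a provenance phenotype entity", {
  w <- generate_world(world_params(seed = 32), tempfile())
  inf <- infer_functions(w$phenotype_annotations, w$eq_definitions,
                         w$genotype_map)
  for (i in sample(nrow(inf), 25)) {
    phens <- vapply(strsplit(inf$provenance[[i]], " ", fixed = TRUE),
                    `[`, character(1), 2)
    fillers <- unlist(lapply(phens, function(p) {
      extract_go_entities(w$eq_definitions[[p]])
    }))
    expect_true(inf$term[i] %in% fillers)
  }
})

test_that("novelty is subsumption against manual-evidence closure", {
  ont <- parse_obo(text = c(
    "[Term]", "id: GO:0000001", "name: parent",
    "[Term]", "id: GO:0000002", "name: child", "is_a: GO:0000001"
  ))
  gaf_line <- function(gene, term, ev) {
    paste("DB", gene, "s", "", term, "R:1", ev, "", "P", "", "", "gene",
          "taxon:0", "20121113", "x", "", "", sep = "\t")
  }
  existing <- parse_gaf(text = c(
    gaf_line("GN:1", "GO:0000001", "IMP"),   # exact match for GN:1
    gaf_line("GN:2", "GO:0000002", "IMP"),   # subclass of the inference
    gaf_line("GN:3", "GO:0000001", "IEA")    # electronic only
  ))
  inferred <- infer_functions(
    parse_phenotype_table(text = c("GN:1\tMP:1", "GN:2\tMP:1", "GN:3\tMP:1",
                                   "GN:4\tMP:1")),
    parse_eq_definitions(text = c(
      "[Term]", "id: MP:1",
      "intersection_of: PATO:1",
      "intersection_of: inheres_in GO:0000001")),
    gmap = NULL
  )
  cls <- classify_novelty(inferred, existing, ont)
  got <- setNames(cls$inferred$novel, cls$inferred$gene)
  expect_false(got[["GN:1"]])  # identical annotation exists
  expect_false(got[["GN:2"]])  # subsumed by the subclass annotation
  expect_true(got[["GN:3"]])   # IEA does not count as manual evidence
  expect_true(got[["GN:4"]])   # no annotation at all
  expect_equal(sum(cls$summary), nrow(cls$inferred))
  # exact mode does not credit the subclass annotation
  exact <- classify_novelty(inferred, existing, ont, mode = "exact")
  expect_true(setNames(exact$inferred$novel, exact$inferred$gene)[["GN:2"]])
})

test_that("enlarging the manual evidence set only moves novel -> known", {
  w <- generate_world(world_params(seed = 33), tempfile())
  anns <- parse_gaf(w$files[["gaf"]])
  inf <- infer_functions(w$phenotype_annotations, w$eq_definitions,
                         w$genotype_map)
  small <- classify_novelty(inf, anns, w$go_ontology, manual_codes = "IMP")
  large <- classify_novelty(inf, anns, w$go_ontology,
                            manual_codes = c("IMP", "IDA", "EXP", "IGI", "IPI"))
  expect_true(all(large$inferred$novel <= small$inferred$novel))
  expect_lte(large$summary[["novel"]], small$summary[["novel"]])
})

test_that("neighbourhood audit lists relevant existing annotation", {
  # miniature erythroid neighbourhood: development and differentiation
  # both under myeloid cell differentiation
  ont <- parse_obo(text = c(
    "[Term]", "id: GO:0030099", "name: myeloid cell differentiation",
    "[Term]", "id: GO:0034101", "name: erythrocyte homeostasis",
    "[Term]", "id: GO:0030218", "name: erythrocyte differentiation",
    "is_a: GO:0030099",
    "[Term]", "id: GO:0048821", "name: erythrocyte development",
    "is_a: GO:0030218",
    "[Term]", "id: GO:0099999", "name: unrelated process"
  ))
  gaf_line <- function(gene, term) {
    paste("DB", gene, "s", "", term, "R:1", "IMP", "", "P", "", "", "gene",
          "taxon:0", "20121113", "x", "", "", sep = "\t")
  }
  existing <- parse_gaf(text = c(gaf_line("Ahsp", "GO:0030218"),
                                 gaf_line("Abcb6", "GO:0099999")))
  inferred <- data.frame(gene = c("Ahsp", "Abcb6"),
                         term = "GO:0048821", novel = NA,
                         stringsAsFactors = FALSE)
  audit <- neighbourhood_audit(inferred, existing, ont,
                               focus_term = "GO:0048821",
                               neighbourhood_roots = c("GO:0030099", "GO:0034101"))
  expect_equal(audit$existing[audit$gene == "Ahsp"], "GO:0030218")
  expect_equal(audit$existing[audit$gene == "Abcb6"], "")
})

test_that("audit agrees with a brute-force descendant oracle", {
  fx <- random_obo_fixture(60, branching = 2, seed = 41)
  ont <- parse_obo(text = fx$text)
  set.seed(42)
  roots <- sample(fx$ids, 3)
  expect_equal(descendant_closure(ont, roots),
               oracle_descendants(fx$parents, roots))
})

test_that("the packaged erythrocyte-development audit table is intact", {
  tab <- table3_fixture()
  expect_equal(tab$existing_annotation[tab$gene == "Ahsp"],
               "GO:0030218 erythrocyte differentiation")
  expect_equal(tab$existing_annotation[tab$gene == "Abcb6"], "")
  path <- system.file("extdata", "table3_erythrocyte_development.tsv",
                      package = "phenofun")
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(nrow(tab), length(body) - 1L)
})

test_that("inferred functions export to GAF (IEA) and TSV and read back", {
  fx <- vgf_fixture_files(withr::local_tempdir())
  inf <- infer_functions(parse_phenotype_table(fx$phenotypes),
                         parse_eq_definitions(fx$definitions),
                         parse_genotype_map(fx$genotype_map))
  gaf_path <- withr::local_tempfile(fileext = ".gaf")
  write_inferred_gaf(inf, gaf_path)
  back <- parse_gaf(gaf_path)
  expect_equal(back$evidence, "IEA")
  expect_equal(back$with_field, "MP:0010249")
  tsv_path <- withr::local_tempfile(fileext = ".tsv")
  write_inferred_tsv(inf, tsv_path)
  back2 <- read_inferred_tsv(tsv_path)
  expect_equal(back2$gene, inf$gene)
  expect_equal(back2$term, inf$term)
})
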