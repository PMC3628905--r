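#' @title GAF, phenotype-table and genotype-map readers/writers
#' @name annotations
NULL

new_diag <- function(rows_in, rows_parsed, rows_skipped) {
  list(rows_in = rows_in, rows_parsed = rows_parsed, rows_skipped = rows_skipped)
}

#' Parser diagnostics
#'
#' Every reader in the package attaches a `diagnostics` attribute with at
#' least `rows_in`, `rows_parsed` and `rows_skipped`; this accessor
#' returns it. The conservation law `rows_in == rows_parsed + rows_skipped`
#' holds for all parsers.
#'
#' @param x a parser result.
#' @return the diagnostics list (or `NULL`).
#' @export
diagnostics <- function(x) {
  attr(x, "diagnostics")
}

#' Parse a GAF 2.x gene-association file
#'
#' Reads tab-delimited GAF body rows (17 columns; comment lines start with
#' `!`). The gene identifier is taken verbatim from column 2 (DB Object
#' ID), the GO term from column 5, the evidence code from column 7 and the
#' with/from field from column 8. Rows whose qualifier contains `NOT` are
#' kept in the returned table but flagged `negated`; [default_annotations()]
#' drops them, since a NOT annotation asserts absence of function.
#'
#' @param file path (plain or `.gz`) or connection.
#' @param text optional character vector of GAF text.
#' @return data frame with columns `db`, `gene`, `symbol`, `qualifier`,
#'   `term`, `evidence`, `with_field`, `aspect`, `taxon`, `negated`;
#'   a `diagnostics` attribute counts malformed rows that were skipped.
#' @export
parse_gaf <- function(file = NULL, text = NULL) {
  lines <- read_input_lines(file, text)
  body <- lines[!startsWith(lines, "!") & nzchar(trimws(lines))]
  rows_in <- length(body)
  fields <- strsplit(body, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) length(f) >= 15L && length(f) <= 17L, logical(1))
  if (any(!ok)) {
    warning(sprintf("skipped %d GAF row(s) with wrong column count", sum(!ok)))
  }
  fields <- fields[ok]
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else "", character(1))
  ann <- data.frame(
    db = get(1), gene = get(2), symbol = get(3), qualifier = get(4),
    term = get(5), evidence = get(7), with_field = get(8),
    aspect = get(9), taxon = get(13), stringsAsFactors = FALSE
  )
  ann$negated <- grepl("(^|\\|)NOT($|\\|)", ann$qualifier)
  attr(ann, "diagnostics") <- new_diag(rows_in, nrow(ann), rows_in - nrow(ann))
  ann
}

#' Default annotation set (NOT rows excluded)
#' @param anns a GAF table from [parse_gaf()].
#' @return the subset of rows not flagged `negated`.
#' @export
default_annotations <- function(anns) {
  anns[!anns$negated, , drop = FALSE]
}

#' Filter annotations by evidence code
#'
#' @param anns a GAF annotation table.
#' @param codes character vector of evidence codes to keep (e.g. the
#'   manual-experimental set `c("EXP","IDA","IPI","IMP","IGI","IEP")`).
#' @return the subsequence of rows with `evidence` in `codes`, order
#'   preserved.
#' @export
filter_by_evidence <- function(anns, codes) {
  anns[anns$evidence %in% codes, , drop = FALSE]
}

#' Manual-experimental GO evidence codes
#'
#' The evidence codes treated as manually created, experimentally backed
#' annotation when deciding whether an inferred function is novel.
#' @return character vector.
#' @export
manual_evidence_codes <- function() {
  c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP")
}

# split a GAF with/from field on the GAF 2.x separators "|" and ","
split_with_field <- function(x) {
  strsplit(x, "[|,]")
}

#' Write an annotation table as GAF 2.1
#'
#' @param anns annotation table (as from [parse_gaf()], or with at least
#'   `gene`, `term`, `evidence`; missing columns are filled with blanks).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(anns, path) {
  n <- nrow(anns)
  col <- function(nm, default = "") {
    if (nm %in% names(anns)) as.character(anns[[nm]]) else rep(default, n)
  }
  db <- col("db")
  blank <- db == ""
  if (any(blank)) db[blank] <- id_prefix(anns$gene[blank])
  lines <- paste(
    db, col("gene"), col("symbol"), col("qualifier"), col("term"),
    col("reference", "REF:0000001"), col("evidence"), col("with_field"),
    col("aspect", "P"), "", "", col("type", "gene"),
    col("taxon", "taxon:0"), col("date", "20121113"), col("assigned_by", "phenofun"),
    "", "",
    sep = "\t"
  )
  writeLines(c("!gaf-version: 2.1", lines), path)
  invisible(path)
}

#' Parse a phenotype-annotation table
#'
#' Two tab-separated dialects are supported. `canonical`:
#' `subject <TAB> phenotype-term` (a pre-composed phenotype-ontology
#' term). `zfin-postcomposed`:
#' `subject <TAB> entity-term <TAB> quality-term`, as used when phenotypes
#' are annotated directly with an entity and a PATO quality. An optional
#' header row naming the documented columns is skipped. Rows with an empty
#' phenotype (or entity) field are skipped with a warning and counted.
#'
#' @inheritParams parse_gaf
#' @param dialect `"canonical"` or `"zfin-postcomposed"`.
#' @return data frame with columns `subject`, `phenotype` (NA for
#'   post-composed rows), `entity`, `quality` (NA for pre-composed rows);
#'   `diagnostics` attribute as for all parsers.
#' @export
parse_phenotype_table <- function(file = NULL, text = NULL,
                                  dialect = c("canonical", "zfin-postcomposed")) {
  dialect <- match.arg(dialect)
  lines <- read_input_lines(file, text)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && identical(tolower(fields[[1]][1]), "subject")) {
    fields <- fields[-1]
  }
  rows_in <- length(fields)
  need <- if (dialect == "canonical") 2L else 3L
  subj <- character(0); phen <- character(0); ent <- character(0); qual <- character(0)
  skipped <- 0L
  for (f in fields) {
    if (length(f) < need || !nzchar(trimws(f[2]))) {
      skipped <- skipped + 1L
      next
    }
    subj <- c(subj, trimws(f[1]))
    if (dialect == "canonical") {
      phen <- c(phen, trimws(f[2])); ent <- c(ent, NA_character_); qual <- c(qual, NA_character_)
    } else {
      phen <- c(phen, NA_character_); ent <- c(ent, trimws(f[2]))
      qual <- c(qual, if (length(f) >= 3) trimws(f[3]) else NA_character_)
    }
  }
  if (skipped) warning(sprintf("skipped %d phenotype row(s) with empty phenotype field", skipped))
  out <- data.frame(subject = subj, phenotype = phen, entity = ent,
                    quality = qual, stringsAsFactors = FALSE)
  attr(out, "diagnostics") <- new_diag(rows_in, nrow(out), skipped)
  out
}

#' Write a phenotype-annotation table
#' @param phens table from [parse_phenotype_table()] (either dialect).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_table <- function(phens, path) {
  post <- is.na(phens$phenotype)
  if (any(post)) {
    writeLines(c("subject\tentity\tquality",
                 paste(phens$subject, phens$entity, phens$quality, sep = "\t")), path)
  } else {
    writeLines(c("subject\tphenotype",
                 paste(phens$subject, phens$phenotype, sep = "\t")), path)
  }
  invisible(path)
}

#' Parse a genotype/morpholino-to-gene mapping table
#'
#' Aggregates a tab-separated file (ZFIN `Morpholinos.txt` /
#' `genotype_features.txt` style) into a multimap from subject identifier
#' (genotype, morpholino) to the set of mutated gene identifiers. Rows
#' missing either identifier are skipped and counted.
#'
#' @inheritParams parse_gaf
#' @param subject_col,gene_col 1-based column indices of the subject and
#'   gene identifier.
#' @return named list: subject id -> character vector of gene ids;
#'   `diagnostics` attribute as for all parsers.
#' @export
parse_genotype_map <- function(file = NULL, text = NULL,
                               subject_col = 1L, gene_col = 2L) {
  lines <- read_input_lines(file, text)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && identical(tolower(fields[[1]][subject_col]), "subject")) {
    fields <- fields[-1]
  }
  rows_in <- length(fields)
  m <- list()
  skipped <- 0L
  for (f in fields) {
    need <- max(subject_col, gene_col)
    if (length(f) < need || !nzchar(trimws(f[subject_col])) || !nzchar(trimws(f[gene_col]))) {
      skipped <- skipped + 1L
      next
    }
    s <- trimws(f[subject_col])
    g <- trimws(f[gene_col])
    m[[s]] <- unique(c(m[[s]], g))
  }
  attr(m, "diagnostics") <- new_diag(rows_in, rows_in - skipped, skipped)
  m
}

#' Identity genotype map
#'
#' For databases where phenotype subjects already are gene identifiers.
#' @param genes character vector of gene ids.
#' @return named list mapping each gene to itself.
#' @export
identity_genotype_map <- function(genes) {
  genes <- unique(as.character(genes))
  stats::setNames(as.list(genes), genes)
}

#' Write a genotype-to-gene map
#' @param gmap named list subject -> genes.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_map <- function(gmap, path) {
  subs <- rep(names(gmap), lengths(gmap))
  writeLines(c("subject\tgene", paste(subs, unlist(gmap, use.names = FALSE), sep = "\t")), path)
  invisible(path)
}
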