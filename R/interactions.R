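#' @title Interaction-pair datasets: GAF IGI/IPI, STRING, BioGRID
#' @name interactions
NULL

#' Construct a canonical interaction-pair table
#'
#' Pairs are undirected: each row is canonicalized so that `a < b`
#' lexicographically, self-pairs are dropped, and duplicates (same pair
#' and kind) are removed.
#'
#' @param a,b character vectors of gene ids.
#' @param kind `"genetic"`, `"protein-protein"` or `"mixed"` (recycled).
#' @param source data source label (recycled).
#' @return data frame with columns `a`, `b`, `kind`, `source`.
#' @export
interaction_pairs <- function(a = character(), b = character(),
                              kind = character(), source = character()) {
  n <- length(a)
  stopifnot(length(b) == n)
  if (n == 0L) {
    return(data.frame(a = character(), b = character(), kind = character(),
                      source = character(), stringsAsFactors = FALSE))
  }
  kind <- rep_len(kind, n)
  source <- rep_len(source, n)
  keep <- a != b
  a <- a[keep]; b <- b[keep]; kind <- kind[keep]; source <- source[keep]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(a = a, b = b, kind = kind, source = source,
                    stringsAsFactors = FALSE)
  out <- out[!duplicated(out[c("a", "b", "kind")]), , drop = FALSE]
  out <- out[order(out$a, out$b, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

pair_key <- function(pairs) {
  paste(pairs$a, pairs$b, sep = "\r")
}

# merge rows with the same unordered pair; conflicting kinds become "mixed"
merge_pair_kinds <- function(pairs) {
  if (nrow(pairs) == 0L) return(pairs)
  key <- pair_key(pairs)
  kinds <- split(pairs$kind, key)
  srcs <- split(pairs$source, key)
  first <- pairs[!duplicated(key), , drop = FALSE]
  ukey <- key[!duplicated(key)]
  first$kind <- vapply(kinds[ukey], function(k) {
    k <- unique(k)
    if (length(k) == 1L) k else "mixed"
  }, character(1))
  first$source <- vapply(srcs[ukey], function(s) paste(sort(unique(s)), collapse = "+"),
                         character(1))
  first <- first[order(first$a, first$b), , drop = FALSE]
  rownames(first) <- NULL
  first
}

#' Mine interaction pairs from GAF IGI/IPI annotations
#'
#' GO annotations with the IGI (inferred from genetic interaction) or IPI
#' (inferred from physical interaction) evidence code carry the
#' interaction partner in the with/from column. Each with-entry whose
#' identifier prefix matches the annotated gene's namespace yields one
#' undirected pair; entries from other namespaces (e.g. GO ids) are
#' skipped and counted in diagnostics.
#'
#' @param anns annotation table from [parse_gaf()].
#' @param code `"IGI"` (pairs of kind `genetic`) or `"IPI"`
#'   (`protein-protein`).
#' @return canonical pair table (see [interaction_pairs()]) with a
#'   `diagnostics` attribute counting skipped with-entries.
#' @export
extract_interactions_from_gaf <- function(anns, code = c("IGI", "IPI")) {
  code <- match.arg(code)
  kind <- if (code == "IGI") "genetic" else "protein-protein"
  rows <- anns[anns$evidence == code, , drop = FALSE]
  a <- character(); b <- character()
  skipped <- 0L
  entries_in <- 0L
  if (nrow(rows)) {
    withs <- split_with_field(rows$with_field)
    for (i in seq_len(nrow(rows))) {
      g <- rows$gene[i]
      ns <- id_prefix(g)
      for (w in withs[[i]]) {
        w <- trimws(w)
        if (!nzchar(w)) next
        entries_in <- entries_in + 1L
        if (is_term_id(w) && id_prefix(w) == ns && w != g) {
          a <- c(a, g); b <- c(b, w)
        } else {
          skipped <- skipped + 1L
        }
      }
    }
  }
  out <- interaction_pairs(a, b, kind, paste0("gaf-", tolower(code)))
  attr(out, "diagnostics") <- new_diag(entries_in, entries_in - skipped, skipped)
  out
}

#' Parse a STRING links file
#'
#' Whitespace-delimited rows `protein1 protein2 combined_score` (a header
#' row starting with `protein1` is skipped). Rows below the score
#' threshold are dropped; identifiers can be mapped to gene ids through
#' `id_map`, and unmappable identifiers are skipped and counted.
#'
#' @inheritParams parse_gaf
#' @param score_threshold minimum combined score to keep (default 0, i.e.
#'   all rows).
#' @param id_map optional named character vector or function mapping
#'   protein identifiers to gene ids; `NA` results drop the row.
#' @return canonical pair table of kind `protein-protein`, source
#'   `string`, with diagnostics.
#' @export
parse_string_links <- function(file = NULL, text = NULL,
                               score_threshold = 0, id_map = NULL) {
  lines <- read_input_lines(file, text)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "\\s+")
  if (length(fields) && identical(tolower(fields[[1]][1]), "protein1")) {
    fields <- fields[-1]
  }
  rows_in <- length(fields)
  map1 <- function(x) {
    if (is.null(id_map)) return(x)
    if (is.function(id_map)) return(id_map(x))
    out <- unname(id_map[x])
    out
  }
  a <- character(); b <- character()
  skipped <- 0L
  for (f in fields) {
    if (length(f) < 3L || is.na(suppressWarnings(sc <- as.numeric(f[3])))) {
      skipped <- skipped + 1L
      next
    }
    if (sc < score_threshold) {
      skipped <- skipped + 1L
      next
    }
    ga <- map1(f[1]); gb <- map1(f[2])
    if (is.na(ga) || is.na(gb)) {
      skipped <- skipped + 1L
      next
    }
    a <- c(a, ga); b <- c(b, gb)
  }
  out <- interaction_pairs(a, b, "protein-protein", "string")
  attr(out, "diagnostics") <- new_diag(rows_in, rows_in - skipped, skipped)
  out
}

#' Write a STRING-style links file
#' @param pairs pair table.
#' @param path output path.
#' @param scores optional numeric scores (default 900).
#' @return `path`, invisibly.
#' @export
write_string_links <- function(pairs, path, scores = NULL) {
  if (is.null(scores)) scores <- rep(900L, nrow(pairs))
  writeLines(c("protein1 protein2 combined_score",
               paste(pairs$a, pairs$b, scores)), path)
  invisible(path)
}

#' Parse a BioGRID tab-format interaction file
#'
#' Tab-delimited rows with an experimental-system-type column
#' distinguishing `physical` from `genetic` interactions; column positions
#' are configurable (defaults: interactor A, interactor B, system type in
#' columns 1-3). Lines starting with `#` and a header row are skipped.
#' A pair observed with both system types gets kind `"mixed"`.
#'
#' @inheritParams parse_gaf
#' @param a_col,b_col,type_col 1-based column indices.
#' @return canonical pair table with kinds `protein-protein`, `genetic` or
#'   `mixed`, source `biogrid`, with diagnostics.
#' @export
parse_biogrid <- function(file = NULL, text = NULL,
                          a_col = 1L, b_col = 2L, type_col = 3L) {
  lines <- read_input_lines(file, text)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && grepl("interactor", tolower(fields[[1]][a_col]))) {
    fields <- fields[-1]
  }
  rows_in <- length(fields)
  a <- character(); b <- character(); kind <- character()
  skipped <- 0L
  for (f in fields) {
    need <- max(a_col, b_col, type_col)
    ty <- if (length(f) >= type_col) tolower(trimws(f[type_col])) else ""
    if (length(f) < need || !nzchar(f[a_col]) || !nzchar(f[b_col]) ||
        !(ty %in% c("physical", "genetic"))) {
      skipped <- skipped + 1L
      next
    }
    a <- c(a, trimws(f[a_col])); b <- c(b, trimws(f[b_col]))
    kind <- c(kind, if (ty == "physical") "protein-protein" else "genetic")
  }
  out <- merge_pair_kinds(interaction_pairs(a, b, kind, "biogrid"))
  attr(out, "diagnostics") <- new_diag(rows_in, rows_in - skipped, skipped)
  out
}

#' Write a BioGRID-style tab file
#' @param pairs pair table (`mixed` pairs emit one physical and one
#'   genetic row).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_biogrid <- function(pairs, path) {
  rows <- character()
  for (i in seq_len(nrow(pairs))) {
    k <- pairs$kind[i]
    types <- switch(k, "protein-protein" = "physical", "genetic" = "genetic",
                    "mixed" = c("physical", "genetic"), "physical")
    rows <- c(rows, paste(pairs$a[i], pairs$b[i], types, sep = "\t"))
  }
  writeLines(c("Interactor A\tInteractor B\tExperimental System Type", rows), path)
  invisible(path)
}

#' Union of interaction datasets
#'
#' Deduplicates pairs across sources within one evaluation; a pair seen
#' with different kinds becomes `"mixed"`.
#' @param ... pair tables.
#' @return one canonical pair table.
#' @export
combine_interactions <- function(...) {
  merge_pair_kinds(do.call(rbind, lapply(list(...), function(p) {
    p[c("a", "b", "kind", "source")]
  })))
}
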