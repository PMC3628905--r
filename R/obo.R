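#' @title OBO ontology parsing and subsumption closure
#' @description Parsers for the OBO 1.2 flat-file format and for
#'   cross-product ("equivalence axiom") definition files, together with
#'   graph utilities: superclass closure, descendant closure and a
#'   definition-completeness report.
#' @name obo
NULL

# Read lines from a path (plain or gzip), a connection, or pass through a
# character vector that is already split into lines.
read_input_lines <- function(file = NULL, text = NULL) {
  if (!is.null(text)) {
    return(unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)))
  }
  if (inherits(file, "connection")) {
    return(readLines(file, warn = FALSE))
  }
  stopifnot(is.character(file), length(file) == 1L)
  if (grepl("\\.gz$", file)) {
    con <- gzfile(file, "rt")
    on.exit(close(con))
    return(readLines(con, warn = FALSE))
  }
  readLines(file, warn = FALSE)
}

#' Validate a CURIE-style term identifier
#'
#' A valid identifier has exactly one colon separating a non-empty prefix
#' from a non-empty local part, e.g. `"GO:0007595"`.
#'
#' @param x character vector of candidate identifiers.
#' @return logical vector.
#' @export
is_term_id <- function(x) {
  grepl("^[^:[:space:]]+:[^:[:space:]]+$", x)
}

#' Prefix of a CURIE identifier
#' @param x character vector of identifiers.
#' @return character vector of prefixes (text before the first colon).
#' @export
id_prefix <- function(x) {
  sub(":.*$", "", x)
}

# Split OBO text into stanzas. Trailing "!"-comments are stripped first
# (the OBO convention for inline comments, e.g. `is_a: GO:1 ! name`).
# Returns a list of list(type = stanza name, keys = chr, vals = chr).
obo_stanzas <- function(lines) {
  lines <- sub("\\s+!.*$", "", lines)
  lines <- trimws(lines)
  stanzas <- list()
  cur_type <- NA_character_
  keys <- character()
  vals <- character()
  flush <- function() {
    if (!is.na(cur_type)) {
      stanzas[[length(stanzas) + 1L]] <<- list(type = cur_type, keys = keys, vals = vals)
    }
  }
  for (ln in lines) {
    if (!nzchar(ln)) next
    if (grepl("^\\[[^]]+\\]$", ln)) {
      flush()
      cur_type <- sub("^\\[([^]]+)\\]$", "\\1", ln)
      keys <- character()
      vals <- character()
    } else if (!is.na(cur_type)) {
      m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
      if (length(m) == 3L) {
        keys <- c(keys, m[2])
        vals <- c(vals, m[3])
      }
    }
  }
  flush()
  stanzas
}

# Depth-first search for a cycle in the is_a graph. Returns NULL when the
# graph is acyclic, otherwise one cycle as a character vector of term ids.
find_isa_cycle <- function(parents) {
  color <- new.env(parent = emptyenv())  # 1 = on stack, 2 = done
  cycle <- NULL
  visit <- function(v, stack) {
    st <- mget(v, envir = color, ifnotfound = 0L)[[1]]
    if (st == 1L) {
      i <- match(v, stack)
      cycle <<- c(stack[i:length(stack)], v)
      return(TRUE)
    }
    if (st == 2L) return(FALSE)
    assign(v, 1L, envir = color)
    for (p in parents[[v]] %||% character()) {
      if (!is.null(parents[[p]]) || p %in% names(parents)) {
        if (visit(p, c(stack, v))) return(TRUE)
      }
    }
    assign(v, 2L, envir = color)
    FALSE
  }
  for (v in names(parents)) {
    if (visit(v, character())) break
  }
  cycle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse an OBO 1.2 ontology
#'
#' Reads `[Term]` stanzas and recognizes the tags `id`, `name`,
#' `namespace`, `is_a`, `relationship` and `is_obsolete`; everything else
#' is ignored. Obsolete terms are retained but flagged, and their outgoing
#' edges are never used by [superclass_closure()]. Parent references to
#' terms that are not declared in the file ("dangling", common with
#' cross-ontology references) are kept as edges to phantom terms and
#' reported in the `dangling` field.
#'
#' @param file path to an OBO file (plain or `.gz`), or a connection.
#' @param text optional character vector of OBO text, used instead of `file`.
#' @return an object of class `obo_ontology`: a list with
#'   \describe{
#'     \item{terms}{data frame with columns `id`, `name`, `namespace`,
#'       `obsolete`}
#'     \item{parents}{named list: term id -> character vector of `is_a`
#'       parents}
#'     \item{relations}{named list: relation name -> named list of term id
#'       -> targets (from `relationship:` tags)}
#'     \item{dangling}{ids referenced as parents but not declared}
#'   }
#' @examples
#' ont <- parse_obo(text = c(
#'   "[Term]", "id: GO:0000001", "name: root",
#'   "[Term]", "id: GO:0000002", "name: child", "is_a: GO:0000001"))
#' ont$parents[["GO:0000002"]]
#' @export
parse_obo <- function(file = NULL, text = NULL) {
  st <- obo_stanzas(read_input_lines(file, text))
  terms <- Filter(function(s) identical(s$type, "Term"), st)
  n <- length(terms)
  ids <- character(n)
  nms <- character(n)
  nss <- character(n)
  obs <- logical(n)
  parents <- vector("list", n)
  relations <- list()
  for (i in seq_len(n)) {
    keys <- terms[[i]]$keys
    vals <- terms[[i]]$vals
    id <- vals[keys == "id"]
    if (length(id) == 0L || !nzchar(id[1])) {
      stop(sprintf("malformed [Term] stanza #%d: missing id", i))
    }
    ids[i] <- id[1]
    nm <- vals[keys == "name"]
    nms[i] <- if (length(nm)) nm[1] else ""
    ns <- vals[keys == "namespace"]
    nss[i] <- if (length(ns)) ns[1] else ""
    ob <- vals[keys == "is_obsolete"]
    obs[i] <- length(ob) > 0L && tolower(ob[1]) == "true"
    parents[[i]] <- unique(vals[keys == "is_a"])
    for (rv in vals[keys == "relationship"]) {
      parts <- strsplit(trimws(rv), "\\s+")[[1]]
      if (length(parts) >= 2L) {
        rel <- parts[1]
        if (is.null(relations[[rel]])) relations[[rel]] <- list()
        relations[[rel]][[ids[i]]] <- unique(c(relations[[rel]][[ids[i]]], parts[2]))
      }
    }
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate term id: ", dup)
  }
  names(parents) <- ids
  all_parents <- unique(unlist(parents, use.names = FALSE))
  dangling <- setdiff(all_parents, ids)
  # cycle check on the is_a graph restricted to non-obsolete terms
  live <- parents[!obs]
  cyc <- find_isa_cycle(live)
  if (!is.null(cyc)) {
    stop("cyclic is_a graph: ", paste(cyc, collapse = " -> "))
  }
  structure(
    list(
      terms = data.frame(id = ids, name = nms, namespace = nss,
                         obsolete = obs, stringsAsFactors = FALSE),
      parents = parents,
      relations = relations,
      dangling = dangling
    ),
    class = "obo_ontology"
  )
}

#' @export
print.obo_ontology <- function(x, ...) {
  cat(sprintf("OBO ontology: %d terms (%d obsolete), %d dangling parent refs\n",
              nrow(x$terms), sum(x$terms$obsolete), length(x$dangling)))
  if (length(x$relations)) {
    cat("relationship types:", paste(names(x$relations), collapse = ", "), "\n")
  }
  invisible(x)
}

# Parent-edge lookup honouring the closure relation configuration and
# never expanding obsolete terms.
edge_parents <- function(ont, term, relations) {
  out <- character()
  if ("is_a" %in% relations) out <- c(out, ont$parents[[term]] %||% character())
  for (rel in setdiff(relations, "is_a")) {
    out <- c(out, ont$relations[[rel]][[term]] %||% character())
  }
  out
}

#' Superclass closure of a term set
#'
#' Returns the smallest superset of `seed` closed under parent traversal —
#' the set `Cl(A)` used by the Jaccard functional similarity. The closure
#' is reflexive (`seed` is always contained in the result). Only `is_a`
#' edges are traversed by default; `relations` may add `part_of` or other
#' relationship types. Obsolete terms contribute no outgoing edges.
#'
#' @param ont an [`obo_ontology`][parse_obo] object.
#' @param seed character vector of term ids; all must exist in `ont`
#'   (phantom/dangling ids are allowed and treated as leaves).
#' @param relations character vector of edge types to traverse.
#' @return character vector of term ids (sorted).
#' @examples
#' ont <- parse_obo(text = c(
#'   "[Term]", "id: A:1", "[Term]", "id: A:2", "is_a: A:1",
#'   "[Term]", "id: A:3", "is_a: A:2"))
#' superclass_closure(ont, "A:3")
#' @export
superclass_closure <- function(ont, seed, relations = "is_a") {
  stopifnot(inherits(ont, "obo_ontology"))
  seed <- unique(as.character(seed))
  if (length(seed) == 0L) return(character())
  known <- c(ont$terms$id, ont$dangling)
  unknown <- setdiff(seed, known)
  if (length(unknown)) {
    stop("unknown term id(s): ", paste(unknown, collapse = ", "))
  }
  obsolete <- ont$terms$id[ont$terms$obsolete]
  seen <- new.env(parent = emptyenv())
  for (s in seed) assign(s, TRUE, envir = seen)
  queue <- seed
  while (length(queue)) {
    t <- queue[[1]]
    queue <- queue[-1]
    if (t %in% obsolete) next
    for (p in edge_parents(ont, t, relations)) {
      if (!exists(p, envir = seen, inherits = FALSE)) {
        assign(p, TRUE, envir = seen)
        queue <- c(queue, p)
      }
    }
  }
  sort(ls(envir = seen))
}

#' Descendant closure of a term set
#'
#' The reflexive set of all terms from which any root in `roots` is
#' reachable via the chosen relations — i.e. the subclasses of the roots.
#' Used to delimit an annotation "neighbourhood" when auditing inferred
#' functions against existing annotations.
#'
#' @inheritParams superclass_closure
#' @param roots character vector of term ids.
#' @return character vector of term ids (sorted).
#' @export
descendant_closure <- function(ont, roots, relations = "is_a") {
  stopifnot(inherits(ont, "obo_ontology"))
  roots <- unique(as.character(roots))
  known <- c(ont$terms$id, ont$dangling)
  unknown <- setdiff(roots, known)
  if (length(unknown)) {
    stop("unknown term id(s): ", paste(unknown, collapse = ", "))
  }
  # invert the edge maps once
  children <- list()
  add_edge <- function(child, parent) {
    children[[parent]] <<- c(children[[parent]], child)
  }
  obsolete <- ont$terms$id[ont$terms$obsolete]
  for (t in names(ont$parents)) {
    if (t %in% obsolete) next
    if ("is_a" %in% relations) for (p in ont$parents[[t]]) add_edge(t, p)
  }
  for (rel in setdiff(relations, "is_a")) {
    m <- ont$relations[[rel]]
    for (t in names(m)) {
      if (t %in% obsolete) next
      for (p in m[[t]]) add_edge(t, p)
    }
  }
  seen <- new.env(parent = emptyenv())
  for (r in roots) assign(r, TRUE, envir = seen)
  queue <- roots
  while (length(queue)) {
    t <- queue[[1]]
    queue <- queue[-1]
    for (ch in children[[t]] %||% character()) {
      if (!exists(ch, envir = seen, inherits = FALSE)) {
        assign(ch, TRUE, envir = seen)
        queue <- c(queue, ch)
      }
    }
  }
  sort(ls(envir = seen))
}

#' Parse Entity/Quality cross-product definitions
#'
#' Reads the "equivalence axiom" OBO dialect in which a phenotype term is
#' logically defined by `intersection_of` lines: one genus line (a bare
#' quality term, PATO expected) and zero or more differentia lines of the
#' form `intersection_of: <relation> <filler>`. Only terms with at least
#' one `intersection_of` line appear in the result; all other terms are
#' "undefined" for completeness reporting.
#'
#' @inheritParams parse_obo
#' @return named list (by defined term id) of `eq_definition` objects:
#'   `list(defined_term, genus, differentia)` where `differentia` is a
#'   data frame with columns `relation` and `filler`. A `diagnostics`
#'   attribute counts malformed differentia lines that were skipped.
#' @examples
#' defs <- parse_eq_definitions(text = c(
#'   "[Term]", "id: MP:0010249", "name: lactation failure",
#'   "intersection_of: PATO:0001558",
#'   "intersection_of: inheres_in GO:0007595"))
#' defs[["MP:0010249"]]$genus
#' @export
parse_eq_definitions <- function(file = NULL, text = NULL) {
  st <- obo_stanzas(read_input_lines(file, text))
  terms <- Filter(function(s) identical(s$type, "Term"), st)
  defs <- list()
  skipped <- 0L
  for (s in terms) {
    id <- s$vals[s$keys == "id"]
    if (length(id) == 0L) next
    id <- id[1]
    ix <- s$vals[s$keys == "intersection_of"]
    if (length(ix) == 0L) next
    genus <- NA_character_
    rels <- character()
    fillers <- character()
    for (v in ix) {
      parts <- strsplit(trimws(v), "\\s+")[[1]]
      if (length(parts) == 1L && is_term_id(parts[1])) {
        if (is.na(genus)) genus <- parts[1]
      } else if (length(parts) >= 2L && is_term_id(parts[2])) {
        rels <- c(rels, parts[1])
        fillers <- c(fillers, parts[2])
      } else {
        warning(sprintf("skipping malformed intersection_of line for %s: '%s'", id, v))
        skipped <- skipped + 1L
      }
    }
    defs[[id]] <- structure(
      list(defined_term = id, genus = genus,
           differentia = data.frame(relation = rels, filler = fillers,
                                    stringsAsFactors = FALSE)),
      class = "eq_definition"
    )
  }
  attr(defs, "diagnostics") <- list(lines_skipped = skipped, terms_defined = length(defs))
  defs
}

#' @export
print.eq_definition <- function(x, ...) {
  cat(sprintf("EQ definition of %s\n  quality (genus): %s\n", x$defined_term, x$genus))
  if (nrow(x$differentia)) {
    for (i in seq_len(nrow(x$differentia))) {
      cat(sprintf("  %s -> %s\n", x$differentia$relation[i], x$differentia$filler[i]))
    }
  }
  invisible(x)
}

#' Definition-completeness report
#'
#' Counts the non-obsolete classes of a phenotype ontology and how many of
#' them carry an EQ definition — the completeness summary reported for
#' phenotype ontologies with formal definitions.
#'
#' @param ont an [`obo_ontology`][parse_obo] object.
#' @param defs a definition map from [parse_eq_definitions()].
#' @return list with elements `classes` and `defined` (`defined <= classes`).
#' @export
definition_completeness <- function(ont, defs) {
  live <- ont$terms$id[!ont$terms$obsolete]
  list(classes = length(live), defined = length(intersect(names(defs), live)))
}

#' Extract GO entities from an EQ definition
#'
#' Returns the differentia fillers whose identifier prefix marks them as
#' Gene Ontology terms. Anatomy or cell-type fillers are excluded, and the
#' genus (the quality) is never returned: only the affected GO entity can
#' be transferred to a gene as a function.
#'
#' @param d an `eq_definition`.
#' @param go_prefixes identifier prefixes counted as GO (default `"GO"`).
#' @return character vector of GO term ids (unique, sorted).
#' @export
extract_go_entities <- function(d, go_prefixes = "GO") {
  stopifnot(inherits(d, "eq_definition"))
  f <- d$differentia$filler
  sort(unique(f[id_prefix(f) %in% go_prefixes]))
}

#' Write an ontology (with optional EQ definitions) as OBO 1.2
#'
#' @param ont an [`obo_ontology`][parse_obo] object.
#' @param path output file path.
#' @param defs optional definition map; matching terms get
#'   `intersection_of` lines.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ont, path, defs = NULL) {
  stopifnot(inherits(ont, "obo_ontology"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(ont$terms))) {
    id <- ont$terms$id[i]
    out <- c("[Term]", paste0("id: ", id))
    if (nzchar(ont$terms$name[i])) out <- c(out, paste0("name: ", ont$terms$name[i]))
    if (nzchar(ont$terms$namespace[i])) out <- c(out, paste0("namespace: ", ont$terms$namespace[i]))
    for (p in ont$parents[[id]]) out <- c(out, paste0("is_a: ", p))
    for (rel in names(ont$relations)) {
      for (tgt in ont$relations[[rel]][[id]] %||% character()) {
        out <- c(out, paste0("relationship: ", rel, " ", tgt))
      }
    }
    d <- defs[[id]]
    if (!is.null(d)) {
      if (!is.na(d$genus)) out <- c(out, paste0("intersection_of: ", d$genus))
      if (nrow(d$differentia)) {
        out <- c(out, paste0("intersection_of: ", d$differentia$relation,
                             " ", d$differentia$filler))
      }
    }
    if (ont$terms$obsolete[i]) out <- c(out, "is_obsolete: true")
    writeLines(c(out, ""), con)
  }
  invisible(path)
}
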