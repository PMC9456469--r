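#' Gene Ontology DAG container
#'
#' A minimal rooted acyclic `is_a` graph: a term table (id, name, namespace)
#' plus a child-to-parents adjacency list. Constructed by [parse_obo()] or
#' [simulate_ontology()]; validated for acyclicity and edge closure.
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param parents named list mapping each term id to a character vector of
#'   `is_a` parent ids (empty vector for roots).
#' @return An object of class `go_dag`.
#' @export
go_dag <- function(terms, parents) {
  stopifnot(is.data.frame(terms), all(c("id", "name", "namespace") %in% names(terms)))
  if (anyDuplicated(terms$id)) stop2("duplicate term ids")
  parents <- parents[terms$id]
  names(parents) <- terms$id
  parents <- lapply(parents, function(p) if (is.null(p)) character(0) else p)
  missing <- setdiff(unique(unlist(parents)), terms$id)
  if (length(missing))
    stop2("is_a target(s) not defined as terms: ", paste(missing, collapse = ", "))
  dag <- structure(list(terms = terms, parents = parents), class = "go_dag")
  topo_sort(dag)  # errors on cycles
  dag
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("go_dag: %d terms, %d is_a edges, root(s): %s\n",
              nrow(x$terms), sum(lengths(x$parents)),
              paste(dag_roots(x), collapse = ", ")))
  invisible(x)
}

#' @rdname go_dag
#' @param dag a `go_dag`.
#' @export
dag_roots <- function(dag) dag$terms$id[lengths(dag$parents) == 0L]

# Kahn topological sort on child->parent edges; returns ids ordered so that
# every term precedes its parents (leaves first). Errors naming a cycle.
topo_sort <- function(dag) {
  ids <- dag$terms$id
  children <- dag_children(dag)
  # out-degree = number of parents still unprocessed
  out_deg <- lengths(dag$parents)
  names(out_deg) <- ids
  # process terms whose children are all done: start from leaves in the
  # child->parent orientation, i.e. terms that are nobody's parent
  n_child <- lengths(children)[ids]
  queue <- ids[n_child == 0L]
  order <- character(0)
  remaining <- n_child
  names(remaining) <- ids
  while (length(queue)) {
    t <- queue[[1L]]; queue <- queue[-1L]
    order <- c(order, t)
    for (p in dag$parents[[t]]) {
      remaining[[p]] <- remaining[[p]] - 1L
      if (remaining[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (length(order) < length(ids)) {
    cyc <- setdiff(ids, order)
    stop2("cycle detected in is_a graph involving: ",
          paste(sort(cyc), collapse = ", "))
  }
  order
}

dag_children <- function(dag) {
  ch <- lapply(stats::setNames(dag$terms$id, dag$terms$id),
               function(i) character(0))
  for (t in dag$terms$id) {
    for (p in dag$parents[[t]]) ch[[p]] <- c(ch[[p]], t)
  }
  ch
}

#' Parse a minimal OBO 1.2 document
#'
#' Reads `[Term]` stanzas with `id`, `name`, `namespace`, `is_a` tags.
#' Comments after `!` on `is_a` lines are dropped; stanzas with
#' `is_obsolete: true` are skipped. Only `is_a` relations are kept.
#'
#' @param text character: either a path to an `.obo` file or the document
#'   as a character vector of lines / single string.
#' @param namespace optional namespace filter (e.g. `"biological_process"`);
#'   `NULL` keeps every namespace.
#' @return A [go_dag()].
#' @export
parse_obo <- function(text, namespace = NULL) {
  lines <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    readLines(text) else unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function(cur, terms) {
    if (is.null(cur) || isTRUE(cur$obsolete)) return(terms)
    terms[[length(terms) + 1L]] <- cur
    terms
  }
  for (ln in lines) {
    if (ln == "[Term]") {
      terms <- flush(cur, terms)
      cur <- list(id = NA_character_, name = "", namespace = "",
                  is_a = character(0), obsolete = FALSE)
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {  # other stanza type ends a term
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      if (startsWith(ln, "id:")) cur$id <- trimws(sub("^id:", "", ln))
      else if (startsWith(ln, "name:")) cur$name <- trimws(sub("^name:", "", ln))
      else if (startsWith(ln, "namespace:"))
        cur$namespace <- trimws(sub("^namespace:", "", ln))
      else if (startsWith(ln, "is_a:")) {
        tgt <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        cur$is_a <- c(cur$is_a, tgt)
      } else if (startsWith(ln, "is_obsolete:"))
        cur$obsolete <- grepl("true", ln)
    }
  }
  terms <- flush(cur, terms)
  if (!length(terms)) stop2("no [Term] stanzas found")
  df <- data.frame(id = vapply(terms, `[[`, "", "id"),
                   name = vapply(terms, `[[`, "", "name"),
                   namespace = vapply(terms, `[[`, "", "namespace"),
                   stringsAsFactors = FALSE)
  parents <- lapply(terms, `[[`, "is_a")
  names(parents) <- df$id
  if (!is.null(namespace)) {
    keep <- df$namespace == namespace
    df <- df[keep, , drop = FALSE]
    parents <- lapply(parents[df$id], intersect, df$id)
  }
  go_dag(df, parents)
}

#' Write a DAG as minimal OBO 1.2
#'
#' Deterministic output: terms sorted by id, `is_a` targets sorted, so a
#' fixed DAG always serializes to byte-identical text and
#' `parse_obo(write_obo(dag))` round-trips the graph exactly.
#'
#' @param dag a [go_dag()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "go_dag"))
  ord <- order(dag$terms$id)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in ord) {
    id <- dag$terms$id[i]
    ps <- sort(dag$parents[[id]])
    out <- c("[Term]",
             paste0("id: ", id),
             paste0("name: ", dag$terms$name[i]),
             paste0("namespace: ", dag$terms$namespace[i]),
             if (length(ps)) paste0("is_a: ", ps))
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

#' Propagate direct annotations up the DAG (true-path rule)
#'
#' A gene directly annotated to a term is implicitly annotated to all of the
#' term's ancestors: `propagated[t]` is the union of the direct gene sets of
#' `t` and of every descendant of `t`, computed in reverse-topological order
#' (children before parents). The root therefore collects every annotated
#' gene.
#'
#' @param dag a [go_dag()].
#' @param direct named list mapping gene id to a character vector of directly
#'   annotated term ids.
#' @return An object of class `go_annotation`: list with `direct` (as given)
#'   and `propagated` (named list term id -> sorted character vector of genes).
#' @export
propagate <- function(dag, direct) {
  stopifnot(inherits(dag, "go_dag"))
  used <- unique(unlist(direct))
  unknown <- setdiff(used, dag$terms$id)
  if (length(unknown))
    stop2("annotation refers to unknown term id(s): ",
          paste(sort(unknown), collapse = ", "))
  direct_by_term <- lapply(stats::setNames(dag$terms$id, dag$terms$id),
                           function(i) character(0))
  for (g in names(direct)) {
    for (t in unique(direct[[g]]))
      direct_by_term[[t]] <- c(direct_by_term[[t]], g)
  }
  ord <- topo_sort(dag)  # children before parents
  prop <- direct_by_term
  for (t in ord) {
    for (p in dag$parents[[t]])
      prop[[p]] <- c(prop[[p]], prop[[t]])
  }
  prop <- lapply(prop, function(g) sort(unique(g)))
  structure(list(direct = direct, propagated = prop),
            class = "go_annotation")
}

#' @export
print.go_annotation <- function(x, ...) {
  cat(sprintf("go_annotation: %d genes, %d terms with annotations\n",
              length(x$direct), sum(lengths(x$propagated) > 0L)))
  invisible(x)
}

#' Restrict an annotation to a gene universe
#'
#' Intersects every propagated term set with the universe and drops terms
#' whose restricted set is smaller than `min_size`.
#'
#' @param ann a `go_annotation` from [propagate()].
#' @param universe nonempty character vector of genes.
#' @param min_size minimum restricted set size to keep a term (default 1).
#' @return A `go_annotation` whose `propagated` sets live in the universe.
#' @export
restrict_to_universe <- function(ann, universe, min_size = 1L) {
  stopifnot(inherits(ann, "go_annotation"))
  if (length(universe) == 0L) stop2("empty gene universe")
  prop <- lapply(ann$propagated, intersect, x = universe)
  prop <- prop[lengths(prop) >= min_size]
  structure(list(direct = ann$direct[names(ann$direct) %in% universe],
                 propagated = prop),
            class = "go_annotation")
}

#' Read / write a two-column gene-to-term annotation TSV
#'
#' @param path TSV file with columns `gene`, `term` (direct annotations).
#' @return Named list gene -> character vector of term ids.
#' @export
read_annotation_tsv <- function(path) {
  df <- read_tsv_simple(path)
  split(df$term, df$gene)
}

#' @rdname read_annotation_tsv
#' @param direct named list gene -> term ids.
#' @export
write_annotation_tsv <- function(direct, path) {
  genes <- sort(names(direct))
  df <- data.frame(
    gene = rep(genes, lengths(direct[genes])),
    term = unlist(lapply(direct[genes], sort), use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv_det(df, path)
}

#' Read a transcription-factor catalog (one symbol per line)
#'
#' @param path text file path.
#' @return Character vector of symbols.
#' @export
read_tf_catalog <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' @rdname read_tf_catalog
#' @param catalog character vector of symbols.
#' @export
write_tf_catalog <- function(catalog, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(catalog, con)
  invisible(path)
}
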