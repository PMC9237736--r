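#' Construct an ontology DAG from child-to-parent edges
#'
#' Terms are organized as a directed acyclic graph of `child -> parent` edges
#' (as in the Gene Ontology). Acyclicity is verified at construction.
#'
#' @param edges Two-column data frame or matrix with columns `child`, `parent`,
#'   or `NULL` for an edgeless term set.
#' @param terms Optional character vector of term ids; defaults to the edge
#'   endpoints. All edge endpoints must be listed.
#' @return An object of class `ontology_dag` with fields `terms` (sorted) and
#'   `edges` (data frame `child`, `parent`).
#' @export
ontology_dag <- function(edges = NULL, terms = NULL) {
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- data.frame(child = character(0), parent = character(0))
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    colnames(edges) <- c("child", "parent")
    edges$child <- as.character(edges$child)
    edges$parent <- as.character(edges$parent)
    edges <- unique(edges)
  }
  if (is.null(terms)) terms <- unique(c(edges$child, edges$parent))
  terms <- sort(unique(as.character(terms)))
  missing <- setdiff(c(edges$child, edges$parent), terms)
  if (length(missing))
    stop("edge endpoint(s) not in terms: ", paste(missing, collapse = ", "))
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                       vertices = data.frame(name = terms))
    if (!igraph::is_dag(g)) stop("edge set contains a cycle")
  }
  structure(list(terms = terms, edges = edges), class = "ontology_dag")
}

#' @export
#' @method print ontology_dag
print.ontology_dag <- function(x, ...) {
  cat(sprintf("ontology_dag: %d terms, %d child->parent edges\n",
              length(x$terms), nrow(x$edges)))
  invisible(x)
}

# igraph handle (child -> parent direction), cached per call site
dag_graph <- function(dag) {
  igraph::graph_from_data_frame(dag$edges, directed = TRUE,
                                vertices = data.frame(name = dag$terms))
}

#' Direct parents of a term
#' @param dag An `ontology_dag`.
#' @param term A term id.
#' @return Character vector of parent term ids.
#' @export
dag_parents <- function(dag, term) {
  sort(dag$edges$parent[dag$edges$child == term])
}

#' Direct children of a term
#' @param dag An `ontology_dag`.
#' @param term A term id.
#' @return Character vector of child term ids.
#' @export
dag_children <- function(dag, term) {
  sort(dag$edges$child[dag$edges$parent == term])
}

#' All ancestors of a term (transitive parents, excluding the term)
#' @param dag An `ontology_dag`.
#' @param term A term id.
#' @return Character vector of ancestor term ids.
#' @export
dag_ancestors <- function(dag, term) {
  if (!term %in% dag$terms) stop("term not in DAG: ", term)
  if (!nrow(dag$edges)) return(character(0))
  g <- dag_graph(dag)
  sort(setdiff(names(igraph::subcomponent(g, term, mode = "out")), term))
}

#' All descendants of a term (transitive children, excluding the term)
#' @param dag An `ontology_dag`.
#' @param term A term id.
#' @return Character vector of descendant term ids.
#' @export
dag_descendants <- function(dag, term) {
  if (!term %in% dag$terms) stop("term not in DAG: ", term)
  if (!nrow(dag$edges)) return(character(0))
  g <- dag_graph(dag)
  sort(setdiff(names(igraph::subcomponent(g, term, mode = "in")), term))
}

# named list term -> ancestors, computed in one pass
dag_ancestor_table <- function(dag) {
  if (!nrow(dag$edges))
    return(setNames(rep(list(character(0)), length(dag$terms)), dag$terms))
  g <- dag_graph(dag)
  setNames(lapply(dag$terms, function(t)
    setdiff(names(igraph::subcomponent(g, t, mode = "out")), t)), dag$terms)
}

#' Read an ontology DAG from a file
#'
#' Accepts either a two-column `child<TAB>parent` edge TSV (no header) or a
#' minimal OBO subset in which only `[Term]`, `id:` and `is_a:` lines are
#' interpreted. Both are normalized to the same edge set.
#'
#' @param path Path to the file.
#' @return An `ontology_dag`.
#' @export
read_dag <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^\\[Term\\]", lines))) {
    terms <- character(0); edges <- list(); cur <- NA_character_
    for (ln in lines) {
      if (grepl("^\\[Term\\]", ln)) { cur <- NA_character_; next }
      if (grepl("^id:", ln)) {
        cur <- trimws(sub("^id:", "", ln)); terms <- c(terms, cur); next
      }
      if (grepl("^is_a:", ln) && !is.na(cur)) {
        parent <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        edges[[length(edges) + 1]] <- c(cur, parent)
      }
    }
    edges <- if (length(edges)) do.call(rbind, edges) else NULL
    return(ontology_dag(edges, terms = unique(c(terms, if (!is.null(edges)) c(edges)))))
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(ontology_dag())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) stop("edge TSV must have two tab-separated columns")
  ontology_dag(data.frame(child = vapply(parts, `[`, character(1), 1L),
                          parent = vapply(parts, `[`, character(1), 2L)))
}

#' Write an ontology DAG as a child/parent edge TSV
#' @param dag An `ontology_dag`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dag <- function(dag, path) {
  write.table(dag$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
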