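#' Disease term DAG
#'
#' The directed acyclic graph of one disease: its focal term together
#' with every ancestor term, connected by child -> parent edges. Each
#' term contributes to the disease's semantics with a weight that decays
#' by the factor `delta` per hop away from the focal term.
#'
#' @param disease_id focal term (the disease itself).
#' @param edges two-column data frame (`child`, `parent`) of directed
#'   edges among the DAG's terms. May be empty for a single-term DAG.
#' @param nodes optional character vector of term ids; defaults to the
#'   focal term plus every term mentioned in `edges`.
#' @param delta semantic contribution factor in \[0, 1\].
#' @return object of class `disease_dag`.
#' @details The graph must be acyclic and every node must be an ancestor
#'   of (or equal to) the focal term, i.e. reachable from it along
#'   child -> parent edges.
#' @examples
#' dag <- disease_dag("D1", data.frame(child = "D1", parent = "root"))
#' @export
disease_dag <- function(disease_id, edges, nodes = NULL, delta = 0.5) {
  stopifnot(is.character(disease_id), length(disease_id) == 1)
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    names(edges)[1:2] <- c("child", "parent")
    edges$child <- as.character(edges$child)
    edges$parent <- as.character(edges$parent)
  } else {
    edges <- data.frame(child = character(0), parent = character(0))
  }
  if (is.null(nodes)) {
    nodes <- unique(c(disease_id, edges$child, edges$parent))
  }
  nodes <- as.character(nodes)
  if (!disease_id %in% nodes) {
    stop("focal disease term must be a node of its DAG", call. = FALSE)
  }
  if (!all(edges$child %in% nodes) || !all(edges$parent %in% nodes)) {
    stop("edges mention terms outside the node set", call. = FALSE)
  }
  if (!is.numeric(delta) || delta < 0 || delta > 1) {
    stop("`delta` must lie in [0, 1]", call. = FALSE)
  }

  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = data.frame(name = nodes))
  if (!igraph::is_dag(g)) {
    stop(sprintf("term graph of '%s' contains a cycle", disease_id),
         call. = FALSE)
  }
  reach <- igraph::subcomponent(g, disease_id, mode = "out")
  unreachable <- setdiff(nodes, igraph::V(g)$name[reach])
  if (length(unreachable) > 0) {
    stop(sprintf("term '%s' is not an ancestor of focal disease '%s'",
                 unreachable[1], disease_id),
         call. = FALSE)
  }

  structure(list(disease_id = disease_id, nodes = nodes, edges = edges,
                 delta = delta, graph = g),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("disease DAG of '%s': %d terms, %d edges, delta = %g\n",
              x$disease_id, length(x$nodes), nrow(x$edges), x$delta))
  invisible(x)
}

#' Per-term semantic contributions of a disease DAG
#'
#' The focal term contributes 1; every other term `d` contributes
#' `delta` times the largest contribution among its children inside the
#' DAG. Terms are processed children-before-parents, so the result
#' equals `delta^h` with `h` the minimum hop count from the focal term.
#'
#' @param dag a [disease_dag()].
#' @return named numeric vector of contributions in (0, 1\], one per
#'   term, with `contributions[disease_id] == 1`.
#' @export
compute_contributions <- function(dag) {
  stopifnot(inherits(dag, "disease_dag"))
  # topological order of the child -> parent graph puts children first
  ord <- igraph::V(dag$graph)$name[igraph::topo_sort(dag$graph, mode = "out")]
  contrib <- setNames(rep(NA_real_, length(ord)), ord)
  contrib[dag$disease_id] <- 1
  children_of <- split(dag$edges$child, dag$edges$parent)
  for (term in ord) {
    if (term == dag$disease_id) next
    kids <- children_of[[term]]
    vals <- contrib[kids]
    if (length(vals) == 0 || anyNA(vals)) {
      # cannot happen for a validated DAG (every node reachable from focal)
      stop(sprintf("term '%s' has no evaluated child", term), call. = FALSE)
    }
    contrib[term] <- dag$delta * max(vals)
  }
  contrib[dag$nodes]
}

#' Semantic value of a disease
#'
#' Sum of all term contributions of the disease's DAG; at least 1 since
#' the focal term always contributes 1.
#'
#' @param contributions named contribution vector from
#'   [compute_contributions()], or a [disease_dag()] (contributions are
#'   computed on the fly).
#' @return a single number >= 1.
#' @export
semantic_value <- function(contributions) {
  if (inherits(contributions, "disease_dag")) {
    contributions <- compute_contributions(contributions)
  }
  if (length(contributions) == 0) {
    stop("empty contribution map", call. = FALSE)
  }
  sum(contributions)
}

#' Semantic similarity between two diseases
#'
#' Shared ancestor terms contribute from both sides; the similarity is
#' the summed shared contribution divided by the sum of the two
#' diseases' semantic values. It lies in \[0, 1\], equals 1 for
#' identical DAGs and 0 for DAGs sharing no terms.
#'
#' @param cm_i,cm_j named contribution vectors (same `delta`), or
#'   [disease_dag()] objects.
#' @return a single number in \[0, 1\].
#' @export
semantic_similarity <- function(cm_i, cm_j) {
  if (inherits(cm_i, "disease_dag")) cm_i <- compute_contributions(cm_i)
  if (inherits(cm_j, "disease_dag")) cm_j <- compute_contributions(cm_j)
  shared <- intersect(names(cm_i), names(cm_j))
  num <- sum(cm_i[shared]) + sum(cm_j[shared])
  num / (sum(cm_i) + sum(cm_j))
}

#' Pairwise disease semantic similarity matrix
#'
#' @param dags named list of [disease_dag()] objects, one per disease;
#'   names are the disease labels (default: each DAG's focal term).
#' @return symmetric similarity matrix with unit diagonal
#'   (kind `"semantic"`).
#' @export
disease_semantic_matrix <- function(dags) {
  stopifnot(is.list(dags), length(dags) >= 1)
  bad <- which(!vapply(dags, inherits, logical(1), what = "disease_dag"))
  if (length(bad) > 0) {
    nm <- names(dags)[bad[1]] %||% as.character(bad[1])
    stop(sprintf("missing or invalid DAG for disease '%s'", nm), call. = FALSE)
  }
  if (is.null(names(dags))) {
    names(dags) <- vapply(dags, function(d) d$disease_id, character(1))
  }
  deltas <- vapply(dags, function(d) d$delta, numeric(1))
  if (length(unique(deltas)) != 1) {
    stop("all DAGs must share the same `delta`", call. = FALSE)
  }
  labels <- names(dags)
  check_labels(labels, length(dags), "disease")
  cms <- lapply(dags, compute_contributions)
  n <- length(cms)
  S <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        S[i, j] <- S[j, i] <- semantic_similarity(cms[[i]], cms[[j]])
      }
    }
  }
  dimnames(S) <- list(labels, labels)
  similarity_matrix(S, kind = "semantic")
}

#' Extract per-disease DAGs from a global ontology
#'
#' Each disease's DAG is the ancestor closure of its focal term in the
#' shared term hierarchy: the focal term, every term reachable from it
#' along child -> parent edges, and the edges among those terms.
#'
#' @param ontology two-column data frame (`child`, `parent`) of the
#'   global hierarchy.
#' @param mapping named character vector or two-column data frame
#'   (`disease`, `term`) mapping disease labels to focal terms.
#' @param delta semantic contribution factor passed to each DAG.
#' @return named list of [disease_dag()] objects, one per disease.
#' @export
dags_from_ontology <- function(ontology, mapping, delta = 0.5) {
  ontology <- as.data.frame(ontology)
  names(ontology)[1:2] <- c("child", "parent")
  if (is.data.frame(mapping)) {
    mapping <- setNames(as.character(mapping[[2]]), as.character(mapping[[1]]))
  }
  check_labels(names(mapping), length(mapping), "disease")
  # a focal term absent from the edge list becomes a single-node DAG
  g <- igraph::graph_from_data_frame(
    ontology, directed = TRUE,
    vertices = data.frame(name = unique(c(ontology$child, ontology$parent,
                                          unname(mapping))))
  )
  if (!igraph::is_dag(g)) {
    stop("ontology contains a cycle", call. = FALSE)
  }
  dags <- lapply(names(mapping), function(dis) {
    term <- mapping[[dis]]
    anc <- igraph::V(g)$name[igraph::subcomponent(g, term, mode = "out")]
    sub <- ontology[ontology$child %in% anc & ontology$parent %in% anc, ,
                    drop = FALSE]
    disease_dag(term, sub, nodes = anc, delta = delta)
  })
  setNames(dags, names(mapping))
}

#' Similarity between a disease and a disease set
#'
#' The best match: the maximum semantic similarity between `d` and any
#' member of `S`.
#'
#' @param d disease label.
#' @param S nonempty character vector of disease labels.
#' @param Sdis disease semantic similarity matrix containing all labels.
#' @return a single number in \[0, 1\].
#' @export
set_to_disease_similarity <- function(d, S, Sdis) {
  if (length(S) == 0) {
    stop("disease set is empty", call. = FALSE)
  }
  labels <- rownames(Sdis)
  missing <- setdiff(c(d, S), labels)
  if (length(missing) > 0) {
    stop(sprintf("disease '%s' not present in the similarity matrix", missing[1]),
         call. = FALSE)
  }
  max(Sdis[d, S])
}

#' lncRNA functional similarity from associated disease sets
#'
#' Two lncRNAs are functionally similar when the diseases associated
#' with one resemble the diseases associated with the other. Every
#' disease of either set is matched to its best counterpart in the other
#' set and the matches are averaged over both set sizes.
#'
#' An lncRNA with no associated disease has an undefined disease set;
#' its self-similarity is set to 1 and its similarity to every other
#' lncRNA to 0, so isolated rows do not poison the matrix.
#'
#' @param Y binary association matrix (lncRNAs x diseases).
#' @param Sdis disease semantic similarity matrix over `colnames(Y)`.
#' @return symmetric lncRNA similarity matrix (kind `"functional"`).
#' @export
lnc_functional_similarity <- function(Y, Sdis) {
  check_labels_agree(colnames(Y), colnames(Sdis), "disease")
  nl <- nrow(Y)
  sets <- lapply(seq_len(nl), function(i) colnames(Y)[Y[i, ] > 0])
  S <- diag(1, nl)
  if (nl > 1) {
    for (i in seq_len(nl - 1)) {
      for (j in seq((i + 1), nl)) {
        s1 <- sets[[i]]; s2 <- sets[[j]]
        if (length(s1) == 0 || length(s2) == 0) {
          S[i, j] <- S[j, i] <- 0
          next
        }
        block <- Sdis[s1, s2, drop = FALSE]
        val <- (sum(apply(block, 1, max)) + sum(apply(block, 2, max))) /
          (length(s1) + length(s2))
        S[i, j] <- S[j, i] <- val
      }
    }
  }
  dimnames(S) <- list(rownames(Y), rownames(Y))
  similarity_matrix(S, kind = "functional")
}
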