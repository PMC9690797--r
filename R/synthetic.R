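#' Specification of a synthetic desk-scale dataset
#'
#' Describes the generator that emulates the structure the method
#' assumes: a term hierarchy giving nontrivial disease semantic
#' similarity, and a sparse bipartite association matrix with planted
#' co-association blocks aligned to subtrees of the hierarchy, so that
#' semantically similar diseases share lncRNAs.
#'
#' @param n_lnc,n_dis entity counts (>= `n_blocks` each).
#' @param n_blocks number of planted blocks.
#' @param density_in,density_out association probability inside /
#'   outside a planted block; `density_in > density_out`.
#' @param dag_depth,dag_branching shape of the rooted term hierarchy;
#'   the leaf layer must offer at least `n_dis` terms across
#'   `n_blocks` first-level subtrees.
#' @param seed integer governing every random draw.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_lnc = 30, n_dis = 24, n_blocks = 3,
                           density_in = 0.35, density_out = 0.02,
                           dag_depth = 3, dag_branching = 3, seed = 1L) {
  stop_unless(n_lnc >= n_blocks, n_dis >= n_blocks, n_blocks >= 1,
              msg = "entity counts must be >= `n_blocks` >= 1")
  stop_unless(density_in > density_out, density_in <= 1, density_out >= 0,
              msg = "`density_in` must exceed `density_out`, both in [0, 1]")
  stop_unless(dag_depth >= 1, dag_branching >= 1,
              msg = "`dag_depth` and `dag_branching` must be >= 1")
  structure(list(n_lnc = as.integer(n_lnc), n_dis = as.integer(n_dis),
                 n_blocks = as.integer(n_blocks),
                 density_in = density_in, density_out = density_out,
                 dag_depth = as.integer(dag_depth),
                 dag_branching = as.integer(dag_branching),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Synthetic term hierarchy and disease-to-term mapping
#'
#' Builds a complete rooted tree of `dag_depth` levels below the root
#' with branching factor `dag_branching`, as child -> parent edges.
#' Diseases are assigned to leaf terms round-robin over the first-level
#' subtrees, so diseases of the same planted block sit under the same
#' subtree and have a recent common ancestor (hence high semantic
#' similarity), while diseases of different blocks only meet at the
#' root.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `ontology` (data frame `child`, `parent`),
#'   `mapping` (named character vector disease label -> term id) and
#'   `blocks_dis` (integer block index per disease).
#' @export
make_ontology <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  b <- spec$dag_branching
  # levels: root = "t0"; level L has b^L terms
  edges <- list()
  level_terms <- "t0"
  for (L in seq_len(spec$dag_depth)) {
    parents <- rep(level_terms, each = b)
    kids <- sprintf("t%d_%d", L, seq_along(parents))
    edges[[L]] <- data.frame(child = kids, parent = parents,
                             stringsAsFactors = FALSE)
    level_terms <- kids
  }
  ontology <- do.call(rbind, edges)
  leaves <- level_terms
  if (length(leaves) < spec$n_dis) {
    stop(sprintf("hierarchy offers %d leaf terms for %d diseases",
                 length(leaves), spec$n_dis), call. = FALSE)
  }

  # first-level subtree of each leaf: leaf index maps to subtree
  # ceiling(idx / b^(depth-1)) when depth >= 1
  per_subtree <- length(leaves) / spec$dag_branching
  subtree_of_leaf <- ceiling(seq_along(leaves) / per_subtree)

  dis_labels <- sprintf("d%02d", seq_len(spec$n_dis))
  blocks_dis <- block_assignment(spec$n_dis, spec$n_blocks)
  mapping <- character(spec$n_dis)
  used <- logical(length(leaves))
  for (i in seq_len(spec$n_dis)) {
    subtree <- ((blocks_dis[i] - 1) %% spec$dag_branching) + 1
    candidates <- which(subtree_of_leaf == subtree & !used)
    if (length(candidates) == 0) candidates <- which(!used)
    if (length(candidates) == 0) {
      stop("more diseases than leaf terms", call. = FALSE)
    }
    mapping[i] <- leaves[candidates[1]]
    used[candidates[1]] <- TRUE
  }
  names(mapping) <- dis_labels
  list(ontology = ontology, mapping = mapping, blocks_dis = blocks_dis)
}

#' Synthetic planted-block association matrix
#'
#' lncRNAs and diseases are partitioned into `n_blocks` groups; a cell
#' is 1 with probability `density_in` when its lncRNA and disease belong
#' to the same block and `density_out` otherwise. All draws are governed
#' by `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param blocks_dis optional disease block assignment (from
#'   [make_ontology()]) to keep the matrix aligned with the hierarchy.
#' @return list with the binary association matrix `Y` and the block
#'   assignments `blocks_lnc`, `blocks_dis`.
#' @export
make_associations <- function(spec, blocks_dis = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(blocks_dis)) {
    blocks_dis <- block_assignment(spec$n_dis, spec$n_blocks)
  }
  blocks_lnc <- block_assignment(spec$n_lnc, spec$n_blocks)
  set.seed(spec$seed)
  prob <- ifelse(outer(blocks_lnc, blocks_dis, "=="),
                 spec$density_in, spec$density_out)
  Y <- matrix(rbinom(length(prob), 1, prob), nrow = spec$n_lnc,
              dimnames = list(sprintf("l%02d", seq_len(spec$n_lnc)),
                              sprintf("d%02d", seq_len(spec$n_dis))))
  list(Y = association_matrix(Y), blocks_lnc = blocks_lnc,
       blocks_dis = blocks_dis)
}

# contiguous, nearly equal-sized block labels 1..k
block_assignment <- function(n, k) {
  sort(rep_len(seq_len(k), n))
}

#' Complete synthetic dataset
#'
#' Convenience wrapper tying [make_ontology()] and
#' [make_associations()] together and precomputing the per-disease DAGs
#' and the disease semantic similarity matrix.
#'
#' @param spec a [synthetic_spec()].
#' @param delta semantic contribution factor for the DAGs.
#' @return list with `Y`, `ontology`, `mapping`, `dags`, `Sdis`,
#'   `blocks_lnc`, `blocks_dis` and the `spec`.
#' @examples
#' sim <- synthetic_dataset(synthetic_spec(n_lnc = 10, n_dis = 9, seed = 3))
#' dim(sim$Y)
#' @export
synthetic_dataset <- function(spec = synthetic_spec(), delta = 0.5) {
  ont <- make_ontology(spec)
  assoc <- make_associations(spec, blocks_dis = ont$blocks_dis)
  dags <- dags_from_ontology(ont$ontology, ont$mapping, delta = delta)
  Sdis <- disease_semantic_matrix(dags)
  list(Y = assoc$Y, ontology = ont$ontology, mapping = ont$mapping,
       dags = dags, Sdis = Sdis,
       blocks_lnc = assoc$blocks_lnc, blocks_dis = ont$blocks_dis,
       spec = spec)
}
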