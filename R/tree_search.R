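# Heuristic and exact search for minimum-length trees: random stepwise
# addition, SPR/TBR branch swapping to a local optimum, the parsimony
# ratchet, and branch-and-bound enumeration for small taxon sets.
# Search always operates on unrooted binary trees; rooting is a
# display/reporting step.

# phylo from the compiled engine's edge matrix
phylo_from_edge <- function(edge, m) {
  ntip <- length(m$taxa)
  tr <- structure(list(edge = edge, tip.label = m$taxa, Nnode = ntip - 2L),
                  class = "phylo")
  attr(tr, "order") <- "cladewise"
  tr
}

# edge matrix for the engine: unrooted binary, tips renumbered to matrix order
engine_edges <- function(tree, m) {
  tree <- ape::unroot(tree)
  if (!ape::is.binary(tree))
    stop("search requires a binary (fully resolved) tree", call. = FALSE)
  tree_edges_for(tree, m)$edge
}

#' Search configuration
#'
#' Defaults follow the published ratchet protocol where stated (200 ratchet
#' iterations) and the cited method's mid-range recommendation otherwise
#' (15\% of characters upweighted by a factor of 2 per iteration).
#'
#' @param seed integer RNG seed; fixes the whole search.
#' @param n_addition_replicates random-addition starting trees.
#' @param swap `"TBR"` or `"SPR"`.
#' @param n_ratchet_iterations ratchet cycles after the initial swap.
#' @param perturb_fraction fraction of characters upweighted per cycle.
#' @param perturb_weight integer weight applied to upweighted characters.
#' @param max_trees_held cap on stored equally optimal topologies.
#' @param collapse collapse zero-minimum-length internal edges when counting
#'   distinct optimal topologies.
#' @return A `search_config` list.
#' @export
search_config <- function(seed = 1L, n_addition_replicates = 10L,
                          swap = c("TBR", "SPR"), n_ratchet_iterations = 200L,
                          perturb_fraction = 0.15, perturb_weight = 2L,
                          max_trees_held = 100L, collapse = TRUE) {
  swap <- match.arg(swap)
  stopifnot(perturb_fraction > 0, perturb_fraction < 1,
            perturb_weight >= 2, n_ratchet_iterations >= 0,
            n_addition_replicates >= 1, max_trees_held >= 1)
  structure(list(seed = as.integer(seed),
                 n_addition_replicates = as.integer(n_addition_replicates),
                 swap = swap,
                 n_ratchet_iterations = as.integer(n_ratchet_iterations),
                 perturb_fraction = perturb_fraction,
                 perturb_weight = as.integer(perturb_weight),
                 max_trees_held = as.integer(max_trees_held),
                 collapse = isTRUE(collapse)),
            class = "search_config")
}

#' Random-addition (Wagner) starting tree
#'
#' Greedy stepwise addition in an RNG-shuffled taxon order; each taxon is
#' inserted on the edge giving the smallest incremental length, ties going
#' to the first edge in a deterministic enumeration.
#'
#' @param m a `char_matrix` with at least 3 taxa.
#' @param seed integer seed (same seed, same tree).
#' @param polymorphism `"ambiguous"` or `"strict"`.
#' @return An unrooted binary `phylo`.
#' @export
random_addition_tree <- function(m, seed = 1L,
                                 polymorphism = c("ambiguous", "strict")) {
  polymorphism <- match.arg(polymorphism)
  ntip <- n_taxa(m)
  if (ntip < 3) stop("need at least 3 taxa", call. = FALSE)
  blocks <- char_blocks(m, polymorphism = polymorphism)
  ord <- local({ set.seed(seed); sample.int(ntip) - 1L })
  res <- cpp_random_addition(ord, blocks, rep(1L, n_char(m)))
  phylo_from_edge(res$edge, m)
}

#' One branch-swapping improvement step
#'
#' Explores the SPR or TBR neighborhood of `tree` in a deterministic order
#' and applies the first strictly shorter rearrangement found; returns the
#' input tree unchanged at a local optimum.  With `fixpoint = TRUE` the
#' process is iterated until no improving neighbor exists.
#'
#' @param tree unrooted binary `phylo` over the matrix taxa.
#' @param m a `char_matrix`.
#' @param mode `"TBR"` (superset of SPR) or `"SPR"`.
#' @param fixpoint iterate to a local optimum.
#' @param weights optional integer character weights.
#' @param polymorphism `"ambiguous"` or `"strict"`.
#' @return A `phylo` with attribute `"steps"` (its weighted length).
#' @export
branch_swap <- function(tree, m, mode = c("TBR", "SPR"), fixpoint = FALSE,
                        weights = NULL, polymorphism = c("ambiguous", "strict")) {
  mode <- match.arg(mode)
  polymorphism <- match.arg(polymorphism)
  blocks <- char_blocks(m, polymorphism = polymorphism)
  if (is.null(weights)) weights <- rep(1L, n_char(m))
  res <- cpp_search(engine_edges(tree, m), n_taxa(m), blocks,
                    as.integer(weights), mode == "TBR",
                    if (fixpoint) .Machine$integer.max else 1L)
  out <- phylo_from_edge(res$edge, m)
  attr(out, "steps") <- as.integer(res$length)
  out
}

# internal: swap an engine edge matrix to its local optimum
swap_fix <- function(edge, ntip, blocks, weights, tbr) {
  cpp_search(edge, ntip, blocks, as.integer(weights), tbr,
             .Machine$integer.max)
}

# canonical signature of an unrooted topology: sorted bipartition strings;
# optionally after collapsing internal edges of minimum length zero
topology_signature <- function(tree, m = NULL, collapse = FALSE) {
  if (collapse) tree <- collapse_min_zero(tree, m)
  paste(sort(bipartition_strings(tree)), collapse = "|")
}

bipartition_strings <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  labs <- tree$tip.label
  anchor <- sort(labs)[1]
  parts <- ape::prop.part(tree)
  out <- character(0)
  for (p in parts) {
    side <- labs[p]
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    if (anchor %in% side) side <- setdiff(labs, side)
    out <- c(out, paste(sort(side), collapse = ";"))
  }
  unique(out)
}

# collapse internal edges on which every character admits a change-free
# most-parsimonious reconstruction
collapse_min_zero <- function(tree, m) {
  tree <- ape::unroot(tree)
  forced <- edge_forced_changes(tree, m)
  ntip <- length(tree$tip.label)
  internal <- tree$edge[, 2] > ntip
  drop <- which(internal & forced == 0)
  if (!length(drop)) return(tree)
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree$edge.length[drop] <- 0
  tree <- ape::di2multi(tree, tol = 0.5)
  tree$edge.length <- NULL
  tree
}

#' Parsimony ratchet search
#'
#' Heuristic minimum-length search: random-addition starting trees swapped
#' to a local optimum, then ratchet cycles that (a) upweight a random
#' subset of characters, (b) swap to a local optimum under the perturbed
#' weights, (c) restore unit weights and swap again, and (d) accept the
#' result when no longer than the running best.  All distinct optimal
#' topologies encountered are retained (deduplicated as unrooted
#' topologies, by default after collapsing zero-minimum-length edges).
#' Every returned tree is independently re-scored with [tree_length()]
#' before the result is returned.
#'
#' @param m a `char_matrix`.
#' @param config a [search_config()].
#' @param polymorphism `"ambiguous"` or `"strict"`.
#' @param quiet suppress progress messages.
#' @return A `search_result`: `best_length`, `best_trees` (multiPhylo),
#'   `trajectory`, `config`.
#' @export
ratchet_search <- function(m, config = search_config(),
                           polymorphism = c("ambiguous", "strict"),
                           quiet = TRUE) {
  polymorphism <- match.arg(polymorphism)
  ntip <- n_taxa(m)
  ncha <- n_char(m)
  blocks <- char_blocks(m, polymorphism = polymorphism)
  w1 <- rep(1L, ncha)
  tbr <- config$swap == "TBR"
  set.seed(config$seed)

  best_len <- Inf
  best_edges <- list()
  sigs <- character(0)
  note_tree <- function(edge, len) {
    if (len < best_len) {
      best_len <<- len
      best_edges <<- list(edge)
      sigs <<- topology_signature(phylo_from_edge(edge, m), m,
                                  collapse = config$collapse)
    } else if (len == best_len && length(best_edges) < config$max_trees_held) {
      sig <- topology_signature(phylo_from_edge(edge, m), m,
                                collapse = config$collapse)
      if (!(sig %in% sigs)) {
        best_edges <<- c(best_edges, list(edge))
        sigs <<- c(sigs, sig)
      }
    }
  }

  for (r in seq_len(config$n_addition_replicates)) {
    ord <- sample.int(ntip) - 1L
    st <- cpp_random_addition(ord, blocks, w1)
    res <- swap_fix(st$edge, ntip, blocks, w1, tbr)
    note_tree(res$edge, res$length)
    if (!quiet)
      message(sprintf("addition replicate %d: length %d (best %d)",
                      r, as.integer(res$length), as.integer(best_len)))
  }

  cur <- best_edges[[1]]
  trajectory <- integer(config$n_ratchet_iterations)
  nsel <- max(1L, round(config$perturb_fraction * ncha))
  for (it in seq_len(config$n_ratchet_iterations)) {
    sel <- sample.int(ncha, nsel)
    w2 <- w1
    w2[sel] <- config$perturb_weight
    p1 <- swap_fix(cur, ntip, blocks, w2, tbr)
    p2 <- swap_fix(p1$edge, ntip, blocks, w1, tbr)
    if (p2$length <= best_len) cur <- p2$edge
    note_tree(p2$edge, p2$length)
    trajectory[it] <- as.integer(best_len)
    if (!quiet && it %% 20 == 0)
      message(sprintf("ratchet iteration %d: best length %d", it,
                      as.integer(best_len)))
  }

  trees <- lapply(best_edges, phylo_from_edge, m = m)
  relen <- vapply(trees, tree_length, 1, m = m, polymorphism = polymorphism)
  if (!all(relen == best_len))
    stop("internal error: best tree re-scored to a different length",
         call. = FALSE)
  class(trees) <- "multiPhylo"
  structure(list(best_length = as.integer(best_len), best_trees = trees,
                 trajectory = trajectory, config = config,
                 polymorphism = polymorphism),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("search_result: best length %d, %d distinct optimal topolog%s\n",
              x$best_length, length(x$best_trees),
              if (length(x$best_trees) == 1) "y" else "ies"))
  invisible(x)
}

#' Exact search by branch and bound
#'
#' Enumerates addition trees with lower-bound pruning (the length of a
#' partial tree never decreases as taxa are added), returning the provably
#' optimal length and the complete set of optimal topologies.  Guarded to
#' at most 11 taxa.
#'
#' @param m a `char_matrix` with 4 to 11 taxa.
#' @param polymorphism `"ambiguous"` or `"strict"`.
#' @return A `search_result` (with `trajectory = NULL`).
#' @export
branch_and_bound <- function(m, polymorphism = c("ambiguous", "strict")) {
  polymorphism <- match.arg(polymorphism)
  ntip <- n_taxa(m)
  if (ntip > 11)
    stop("branch_and_bound is limited to 11 taxa (", ntip, " given); ",
         "use ratchet_search for larger matrices", call. = FALSE)
  if (ntip < 3) stop("need at least 3 taxa", call. = FALSE)
  blocks <- char_blocks(m, polymorphism = polymorphism)
  res <- cpp_bab(ntip, blocks, rep(1L, n_char(m)))
  trees <- lapply(res$edges, phylo_from_edge, m = m)
  class(trees) <- "multiPhylo"
  structure(list(best_length = as.integer(res$length), best_trees = trees,
                 trajectory = NULL, config = NULL,
                 polymorphism = polymorphism),
            class = "search_result")
}

#' Root a tree at an outgroup taxon
#'
#' Places the root on the outgroup's pendant edge.  The unrooted topology
#' (and therefore every parsimony length) is unchanged; the ingroup forms
#' the root's other child clade.
#'
#' @param tree a `phylo`.
#' @param outgroup tip label to root at.
#' @return A rooted `phylo`.
#' @export
root_at_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("unknown outgroup taxon: ", outgroup, call. = FALSE)
  ape::root(ape::unroot(tree), outgroup = outgroup, resolve.root = TRUE)
}

#' Strict consensus of trees
#'
#' @param trees a `multiPhylo` (or list) of trees over the same leaf set.
#' @return A `phylo` containing exactly the bipartitions common to all
#'   input trees.
#' @export
strict_consensus <- function(trees) {
  if (inherits(trees, "phylo")) return(trees)
  if (!length(trees)) stop("no trees given", call. = FALSE)
  labs <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(labs, identical, TRUE, y = labs[[1]])))
    stop("trees have mismatched leaf sets", call. = FALSE)
  if (length(trees) == 1) return(trees[[1]])
  class(trees) <- "multiPhylo"
  ape::consensus(trees, p = 1, rooted = FALSE)
}

#' Robinson-Foulds distance
#'
#' Number of bipartitions present in exactly one of the two unrooted
#' topologies; 0 iff the topologies are identical.
#'
#' @param a,b `phylo` trees over the same leaf set.
#' @return Integer distance.
#' @export
robinson_foulds <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label))
    stop("trees have mismatched leaf sets", call. = FALSE)
  sa <- bipartition_strings(a)
  sb <- bipartition_strings(b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}
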