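# Simulation of discrete character evolution on known trees, used to
# validate scoring, search and mapping without external data.  Unordered
# characters evolve under a k-state symmetric (Mk-type) jump process;
# ordered characters under a stepwise random walk restricted to +/-1 moves
# (matching unit-additive cost structure).  Every substitution event is
# logged so parsimony-versus-truth comparisons are exact.

#' Simulation configuration
#'
#' @param n_taxa number of tips (>= 4).
#' @param n_characters number of characters.
#' @param fraction_ordered fraction of characters evolved (and scored) as
#'   ordered; the rest are unordered (stored as binary when two-state).
#' @param states_per_character number of states k per character (2-5).
#' @param substitution_rate expected substitutions per unit branch length.
#' @param tree_shape `"yule"`, `"balanced"` or `"caterpillar"`.
#' @param missing_rate probability a cell is knocked out to missing (1 is
#'   allowed as a degenerate case).
#' @param polymorphism_rate probability a surviving cell becomes a 2-state
#'   polymorphism (its state plus an adjacent state).
#' @param seed integer seed fixing all draws.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_taxa = 12L, n_characters = 75L,
                       fraction_ordered = 0.4, states_per_character = 3L,
                       substitution_rate = 0.5,
                       tree_shape = c("yule", "balanced", "caterpillar"),
                       missing_rate = 0, polymorphism_rate = 0, seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(n_taxa >= 4, n_characters >= 1,
            fraction_ordered >= 0, fraction_ordered <= 1,
            states_per_character >= 2, states_per_character <= 5,
            substitution_rate >= 0,
            missing_rate >= 0, missing_rate <= 1,
            polymorphism_rate >= 0, polymorphism_rate < 1)
  structure(list(n_taxa = as.integer(n_taxa),
                 n_characters = as.integer(n_characters),
                 fraction_ordered = fraction_ordered,
                 states_per_character = as.integer(states_per_character),
                 substitution_rate = substitution_rate,
                 tree_shape = tree_shape,
                 missing_rate = missing_rate,
                 polymorphism_rate = polymorphism_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a tree with branch lengths
#'
#' Topology of the requested shape (Yule/random, fully balanced, or
#' caterpillar), with exponential(1) branch lengths.  `"balanced"`
#' requires a power-of-two number of taxa.
#'
#' @param config a [sim_config()].
#' @return A rooted binary `phylo` with branch lengths and tips
#'   `t1..tn`.
#' @export
simulate_tree <- function(config = sim_config()) {
  n <- config$n_taxa
  if (n < 4) stop("need at least 4 taxa", call. = FALSE)
  set.seed(config$seed)
  tree <- switch(config$tree_shape,
    yule = ape::rphylo(n, birth = 1, death = 0),
    balanced = {
      if (bitwAnd(n, n - 1L) != 0L)
        stop("balanced shape requires a power-of-two number of taxa",
             call. = FALSE)
      ape::stree(n, "balanced")
    },
    caterpillar = ape::stree(n, "left"))
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree)
  tree$tip.label <- paste0("t", seq_len(n))
  tree$edge.length <- stats::rexp(nrow(tree$edge), rate = 1)
  tree
}

#' Simulate characters on a tree
#'
#' The root state is uniform on `0..k-1`; along each branch, substitution
#' events occur as a Poisson process with the configured rate.  Unordered
#' characters jump to a uniformly chosen different state; ordered
#' characters move by +/-1 (reflecting at the boundary states).  The
#' realized number of state-changing events per character is recorded in
#' `attr(, "events")`, and per-character kinds in the returned matrix.
#'
#' @param tree a `phylo` with branch lengths.
#' @param config a [sim_config()].
#' @return A `char_matrix` with attributes `"events"` (integer vector of
#'   realized change events per character) and `"tree"` (the generating
#'   tree).
#' @export
simulate_characters <- function(tree, config = sim_config()) {
  if (is.null(tree$edge.length))
    stop("tree must have branch lengths", call. = FALSE)
  set.seed(config$seed + 1L)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  k <- config$states_per_character
  ncha <- config$n_characters
  n_ord <- round(config$fraction_ordered * ncha)
  kinds <- rep("unordered", ncha)
  if (n_ord > 0) kinds[seq_len(n_ord)] <- "ordered"
  pre <- ape::reorder.phylo(tree, "cladewise")
  root <- pre$edge[1, 1]
  cells <- matrix(NA_integer_, ntip, ncha)
  events <- integer(ncha)
  for (j in seq_len(ncha)) {
    state <- integer(nn)
    state[root] <- sample.int(k, 1) - 1L
    nev <- 0L
    for (e in seq_len(nrow(pre$edge))) {
      p <- pre$edge[e, 1]; ch <- pre$edge[e, 2]
      s <- state[p]
      nsub <- stats::rpois(1, config$substitution_rate * pre$edge.length[e])
      if (nsub > 0) {
        for (i in seq_len(nsub)) {
          if (kinds[j] == "ordered") {
            s <- if (s == 0L) 1L
                 else if (s == k - 1L) s - 1L
                 else s + sample(c(-1L, 1L), 1)
          } else {
            s <- (s + sample.int(k - 1L, 1)) %% k
          }
        }
        nev <- nev + nsub
      }
      state[ch] <- s
    }
    events[j] <- nev
    cells[, j] <- bitwShiftL(1L, state[seq_len(ntip)])
  }
  # two-state unordered columns are cost-equivalent to binary; store as such
  kinds[kinds == "unordered" &
          vapply(seq_len(ncha), function(j)
            length(unique(cells[, j])) <= 2, TRUE)] <- "binary"
  out <- char_matrix(tree$tip.label, cells, kinds)
  attr(out, "events") <- events
  attr(out, "tree") <- tree
  out
}

#' Degrade a matrix with missing data and polymorphism
#'
#' Each cell is independently set to missing with `missing_rate`; each
#' surviving single-state cell is expanded to a two-state polymorphism
#' (its state plus an adjacent state, keeping ordered-character cost
#' semantics meaningful) with `polymorphism_rate`.  Dimensions and
#' character kinds are unchanged.
#'
#' @param m a `char_matrix`.
#' @param config a [sim_config()] supplying the rates and seed.
#' @return A degraded `char_matrix`.
#' @export
degrade_matrix <- function(m, config) {
  stopifnot(config$missing_rate >= 0, config$missing_rate <= 1,
            config$polymorphism_rate >= 0, config$polymorphism_rate < 1)
  set.seed(config$seed + 2L)
  ntax <- n_taxa(m); ncha <- n_char(m)
  cells <- m$cells
  for (i in seq_len(ntax)) {
    for (j in seq_len(ncha)) {
      if (stats::runif(1) < config$missing_rate) {
        cells[i, j] <- NA_integer_
        next
      }
      if (config$polymorphism_rate > 0 && !is.na(cells[i, j]) &&
          stats::runif(1) < config$polymorphism_rate) {
        st <- decode_mask(cells[i, j])
        if (length(st) == 1) {
          dom <- m$state_domain[[j]]
          if (m$chars$kind[j] == "binary") {
            # stay inside the two-state domain
            others <- setdiff(dom, st)
            if (!length(others)) next
            other <- others[1]
          } else {
            kmax <- max(c(dom, st))
            other <- if (st == kmax && st > 0) st - 1L else st + 1L
          }
          cells[i, j] <- encode_states(c(st, other))
        }
      }
    }
  }
  out <- char_matrix(m$taxa, cells, m$chars$kind, m$chars$label)
  attr(out, "events") <- attr(m, "events")
  attr(out, "tree") <- attr(m, "tree")
  out
}
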