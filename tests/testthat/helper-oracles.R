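# Independent oracles and generators used across the suite.
#
# The length oracle enumerates every internal-node state assignment
# explicitly, sharing no code with the dynamic-programming scorer.

# col: list of integer state sets in tip order, NA_integer_ for missing
oracle_column_length <- function(tree, col, kind) {
  ntip <- length(tree$tip.label)
  obs <- unlist(col[!vapply(col, function(s) length(s) == 1 && is.na(s), TRUE)])
  if (length(unique(obs)) <= 1) return(0L)
  k <- max(obs) + 1L
  cost <- step_matrix(kind, k)
  nint <- tree$Nnode
  states <- as.matrix(expand.grid(rep(list(0:(k - 1L)), nint)))
  total <- rep(0L, nrow(states))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1] - ntip
    ch <- tree$edge[e, 2]
    sp <- states[, p]
    if (ch <= ntip) {
      s <- col[[ch]]
      if (length(s) == 1 && is.na(s)) next
      total <- total + apply(matrix(cost[cbind(rep(sp, each = length(s)) + 1L,
                                               rep(s, nrow(states)) + 1L)],
                                    ncol = nrow(states)), 2, min)
    } else {
      total <- total + cost[cbind(sp + 1L, states[, ch - ntip] + 1L)]
    }
  }
  min(total)
}

rand_unrooted_tree <- function(n) ape::unroot(ape::rtree(n, br = NULL))

rand_col <- function(n, kmax = 4, miss = 0.15, poly = 0.15) {
  lapply(seq_len(n), function(i) {
    if (runif(1) < miss) return(NA_integer_)
    s <- sample.int(kmax, 1) - 1L
    if (runif(1) < poly) sort(unique(c(s, sample.int(kmax, 1) - 1L))) else s
  })
}

# homoplasy-free binary matrix: one character per internal edge of the tree,
# marking the tips of that clade; each character needs exactly one change on
# the generating tree
clean_clade_matrix <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  cols <- list()
  for (p in parts) {
    if (length(p) <= 1 || length(p) >= ntip - 1) next
    v <- rep(0L, ntip)
    v[p] <- 1L
    cols[[length(cols) + 1]] <- v
  }
  cells <- do.call(cbind, lapply(cols, function(v) bitwShiftL(1L, v)))
  char_matrix(tree$tip.label, cells, rep("binary", length(cols)))
}

# unrooted quartet ((A,B),(C,D)) as a phylo object
quartet_tree <- function(labels = c("A", "B", "C", "D")) {
  t <- ape::read.tree(text = sprintf("((%s,%s),(%s,%s));",
                                     labels[1], labels[2], labels[3], labels[4]))
  ape::unroot(t)
}

# total cost implied by a node state assignment
implied_cost <- function(tree, assign, kind, k) {
  cost <- step_matrix(kind, k)
  sum(cost[cbind(assign[tree$edge[, 1]] + 1L, assign[tree$edge[, 2]] + 1L)])
}
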