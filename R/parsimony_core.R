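# Parsimony length computation under mixed additive/nonadditive costs.
#
# Every length is an exact integer, computed by generalized Sankoff dynamic
# programming in compiled code.  Leaf ambiguity (missing cells and
# polymorphic terminals scored as ambiguity) enters through leaf cost
# vectors: 0 for allowed states, effectively infinite otherwise.  The
# optional "strict" polymorphism mode charges each polymorphic terminal for
# the span of its listed states (Farris-style polymorphism counting, the
# convention of Winclada/Nona) on top of the distance to the subtending
# node's state.

BIG_COST <- 268435456L  # 1L << 28, matches the compiled code

#' Step (cost) matrix for a character kind
#'
#' Nonadditive (unordered) characters charge one step for any change;
#' additive (ordered) characters charge `|i - j|` steps ("unit-additive").
#' Binary characters use the (identical) unit cost.
#'
#' @param kind `"binary"`, `"ordered"` or `"unordered"`.
#' @param nstates number of states `k`; states are `0..k-1`.
#' @return Integer `k x k` cost matrix.
#' @export
step_matrix <- function(kind = c("unordered", "ordered", "binary"), nstates) {
  kind <- match.arg(kind)
  k <- as.integer(nstates)
  s <- seq_len(k) - 1L
  if (kind == "ordered") abs(outer(s, s, "-")) else (outer(s, s, "!=")) * 1L
}

# normalize a column given as a list of state sets (NA = missing), a plain
# integer vector, or a character vector of cell symbols ("0", "01", "?")
normalize_column <- function(column) {
  if (is.numeric(column)) column <- as.list(column)
  if (is.character(column))
    column <- lapply(column, function(x) {
      if (x %in% MISSING_SYMBOLS) NA_integer_
      else as.integer(strsplit(x, "")[[1]])
    })
  lapply(column, function(s) {
    if (length(s) == 1 && is.na(s)) NA_integer_ else as.integer(s)
  })
}

# span of a state set under a kind's cost (steps obligated by observing all
# of the set's states in one terminal)
set_span <- function(s, kind) {
  if (length(s) <= 1) return(0L)
  if (kind == "ordered") max(s) - min(s) else length(s) - 1L
}

# Build the per-character blocks handed to the compiled scorer: state count,
# cost matrix and leaf cost vectors (rows in `taxa_order`).
char_blocks <- function(m, taxa_order = seq_along(m$taxa),
                        polymorphism = c("ambiguous", "strict")) {
  polymorphism <- match.arg(polymorphism)
  ncha <- n_char(m)
  lapply(seq_len(ncha), function(j) {
    dom <- m$state_domain[[j]]
    kind <- m$chars$kind[j]
    k <- if (length(dom)) max(dom) + 1L else 1L
    cost <- step_matrix(kind, k)
    leaf <- matrix(0L, length(taxa_order), k)
    for (i in seq_along(taxa_order)) {
      mask <- m$cells[taxa_order[i], j]
      if (is.na(mask)) next
      st <- decode_mask(mask)
      if (polymorphism == "ambiguous" || length(st) == 1) {
        v <- rep(BIG_COST, k)
        v[st + 1L] <- 0L
      } else {
        v <- set_span(st, kind) +
          vapply(0:(k - 1L), function(s) min(cost[s + 1L, st + 1L]), 1L)
      }
      leaf[i, ] <- v
    }
    list(k = k, cost = cost, leaf = leaf)
  })
}

# map an ape tree onto the matrix's taxon numbering; returns list(edge, ntip,
# nnode) with tips renumbered so tip i = taxon i of the matrix
tree_edges_for <- function(tree, m) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object", call. = FALSE)
  if (!setequal(tree$tip.label, m$taxa))
    stop("tree tip labels do not match matrix taxa", call. = FALSE)
  ntip <- length(tree$tip.label)
  perm <- match(tree$tip.label, m$taxa)
  edge <- tree$edge
  istip <- edge <= ntip
  edge[istip] <- perm[edge[istip]]
  list(edge = edge, ntip = ntip, nnode = ntip + tree$Nnode)
}

#' Parsimony length of a tree for a whole matrix
#'
#' Sums the minimum number of character-state changes over all characters,
#' each scored with its kind-appropriate cost (unit for binary/unordered,
#' `|i - j|` for ordered).  Missing cells are free for any state;
#' polymorphic cells are scored as ambiguity by default, or charged their
#' state-set span in `"strict"` mode.  The result is independent of where
#' (or whether) the tree is rooted.
#'
#' @param tree a `phylo` tree whose tip labels are exactly the matrix taxa;
#'   may be rooted or unrooted, binary or multifurcating.
#' @param m a `char_matrix`.
#' @param polymorphism `"ambiguous"` (default) or `"strict"`.
#' @param weights optional integer weight per character (used by the
#'   ratchet); default all 1.
#' @param per_character return the per-character step vector instead of the
#'   total.
#' @return Integer total steps, or an integer vector when `per_character`.
#' @export
tree_length <- function(tree, m, polymorphism = c("ambiguous", "strict"),
                        weights = NULL, per_character = FALSE) {
  polymorphism <- match.arg(polymorphism)
  te <- tree_edges_for(tree, m)
  blocks <- char_blocks(m, polymorphism = polymorphism)
  if (is.null(weights)) weights <- rep(1L, n_char(m))
  pc <- cpp_score_tree(te$edge, te$ntip, te$nnode, blocks, as.integer(weights))
  if (per_character) pc else sum(pc * weights)
}

#' Parsimony length of a single character on a tree
#'
#' @param tree a `phylo`; tip labels must name every cell of the column.
#' @param column the character's cells: a list of integer state sets (with
#'   `NA` for missing), a plain state vector, or cell symbols such as
#'   `"0"`, `"02"`, `"?"`.  Named entries are matched to tip labels;
#'   unnamed columns are taken in tip-label order.
#' @param kind `"unordered"`, `"ordered"` or `"binary"`.
#' @param polymorphism `"ambiguous"` or `"strict"`.
#' @return Integer number of steps.
#' @export
character_length <- function(tree, column, kind = c("unordered", "ordered", "binary"),
                             polymorphism = c("ambiguous", "strict")) {
  kind <- match.arg(kind)
  col <- normalize_column(column)
  taxa <- tree$tip.label
  if (!is.null(names(column))) {
    if (!all(taxa %in% names(column)))
      stop("leaf without a cell: ",
           paste(setdiff(taxa, names(column)), collapse = ", "), call. = FALSE)
    col <- col[taxa]
  } else if (length(col) != length(taxa)) {
    stop("column length does not match number of tips", call. = FALSE)
  }
  m <- column_matrix(taxa, col, kind)
  tree_length(tree, m, polymorphism = polymorphism)
}

# one-column char_matrix helper
column_matrix <- function(taxa, col, kind) {
  masks <- vapply(col, function(s) {
    if (length(s) == 1 && is.na(s)) NA_integer_ else encode_states(s)
  }, 1L)
  dom <- sort(unique(unlist(col[!vapply(col, function(s)
    length(s) == 1 && is.na(s), TRUE)])))
  if (kind == "binary" && length(dom) > 2) kind <- "unordered"
  char_matrix(taxa, matrix(masks, ncol = 1), kind)
}

#' Minimum conceivable steps of a character
#'
#' The smallest number of steps the column can require on any tree,
#' minimizing over resolutions of missing/polymorphic cells: for unordered
#' characters, (size of a minimal state set hitting every cell) - 1; for
#' ordered characters, the minimal spanned state range.
#'
#' @inheritParams character_length
#' @return Integer.
#' @export
min_steps <- function(column, kind = c("unordered", "ordered", "binary")) {
  kind <- match.arg(kind)
  col <- normalize_column(column)
  col <- col[!vapply(col, function(s) length(s) == 1 && is.na(s), TRUE)]
  if (!length(col)) return(0L)
  dom <- sort(unique(unlist(col)))
  if (length(dom) <= 1) return(0L)
  if (kind == "ordered") {
    lo <- max(vapply(col, min, 1L))
    hi <- min(vapply(col, max, 1L))
    return(max(0L, lo - hi))
  }
  for (sz in seq_along(dom)) {
    hit <- utils::combn(dom, sz, function(cc)
      all(vapply(col, function(s) any(s %in% cc), TRUE)), simplify = TRUE)
    if (any(hit)) return(sz - 1L)
  }
  length(dom) - 1L
}

#' Maximum steps of a character
#'
#' The parsimony length of the column on the star (single internal node)
#' tree, minimizing over the central state and over resolutions of
#' ambiguous cells.  Used as `g` in the retention index.
#'
#' @inheritParams character_length
#' @return Integer.
#' @export
max_steps <- function(column, kind = c("unordered", "ordered", "binary")) {
  kind <- match.arg(kind)
  col <- normalize_column(column)
  col <- col[!vapply(col, function(s) length(s) == 1 && is.na(s), TRUE)]
  if (!length(col)) return(0L)
  dom <- sort(unique(unlist(col)))
  k <- max(dom) + 1L
  cost <- step_matrix(kind, k)
  min(vapply(0:(k - 1L), function(centre)
    sum(vapply(col, function(s) min(cost[centre + 1L, s + 1L]), 1L)), 1L))
}

#' Most-parsimonious ancestral state assignment for one character
#'
#' Returns one optimal state per node (tips included: ambiguous tips are
#' resolved).  Ties between equally parsimonious child states are broken by
#' the chosen resolution: `"ACCTRAN"` accelerates transformations rootward
#' (prefers making the change on the current edge), `"DELTRAN"` delays them
#' tipward (prefers keeping the parent's state); remaining ties go to the
#' lowest state.  The implied total cost always equals
#' [character_length()].
#'
#' @param tree a rooted `phylo`.
#' @inheritParams character_length
#' @param resolution `"ACCTRAN"` or `"DELTRAN"`.
#' @return Integer vector of states indexed by node number
#'   (`1..Ntip+Nnode`, ape numbering).
#' @export
ancestral_states <- function(tree, column, kind = c("unordered", "ordered", "binary"),
                             resolution = c("ACCTRAN", "DELTRAN"),
                             polymorphism = c("ambiguous", "strict")) {
  kind <- match.arg(kind)
  resolution <- match.arg(resolution)
  polymorphism <- match.arg(polymorphism)
  if (!ape::is.rooted(tree))
    stop("ancestral_states requires a rooted tree", call. = FALSE)
  col <- normalize_column(column)
  taxa <- tree$tip.label
  if (!is.null(names(column))) col <- col[taxa]
  m <- column_matrix(taxa, col, kind)
  blocks <- char_blocks(m)
  sankoff_assign(tree, blocks[[1]], resolution,
                 if (polymorphism == "strict")
                   char_blocks(m, polymorphism = "strict")[[1]] else NULL)
}

# down-pass Sankoff vectors for one character block on a rooted tree;
# returns matrix (nodes x k)
sankoff_down <- function(tree, block) {
  k <- block$k
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  V <- matrix(0L, nn, k)
  V[seq_len(ntip), ] <- block$leaf
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    trans <- vapply(seq_len(k), function(s)
      min(block$cost[s, ] + V[ch, ]), 1L)
    V[p, ] <- V[p, ] + trans
  }
  V
}

sankoff_assign <- function(tree, block, resolution, strict_block = NULL) {
  use <- if (is.null(strict_block)) block else strict_block
  k <- use$k
  ntip <- length(tree$tip.label)
  V <- sankoff_down(tree, use)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  root <- edge[nrow(edge), 1]
  assign <- integer(ntip + tree$Nnode)
  assign[root] <- which.min(V[root, ]) - 1L
  for (e in rev(seq_len(nrow(edge)))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    sp <- assign[p]
    tot <- use$cost[sp + 1L, ] + V[ch, ]
    cand <- which(tot == min(tot)) - 1L
    if (resolution == "DELTRAN") {
      assign[ch] <- if (sp %in% cand) sp else cand[1]
    } else {
      d <- use$cost[sp + 1L, cand + 1L]
      assign[ch] <- cand[which.max(d)][1]
    }
  }
  assign
}

# Per-edge forced changes: for each edge, the extra cost of requiring both
# endpoints to share a state, summed over characters.  Zero means every
# character admits a most-parsimonious reconstruction with no change on the
# edge (the edge has minimum length zero).
edge_forced_changes <- function(tree, m, polymorphism = "ambiguous") {
  blocks <- char_blocks(m, taxa_order = match(tree$tip.label, m$taxa),
                        polymorphism = polymorphism)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  post <- ape::reorder.phylo(tree, "postorder")$edge
  forced <- numeric(nrow(post))
  for (block in blocks) {
    k <- block$k
    if (k == 1) next
    V <- sankoff_down(tree, block)
    root <- post[nrow(post), 1]
    charlen <- min(V[root, ])
    # up-pass: cost of everything outside subtree(v) given v's own state
    UP <- matrix(0L, nn, k)
    kids <- split(post[, 2], post[, 1])
    for (e in rev(seq_len(nrow(post)))) {
      p <- post[e, 1]; ch <- post[e, 2]
      sibs <- setdiff(kids[[as.character(p)]], ch)
      sibcost <- rep(0L, k)
      for (b in sibs)
        sibcost <- sibcost + vapply(seq_len(k), function(s)
          min(block$cost[s, ] + V[b, ]), 1L)
      UP[ch, ] <- vapply(seq_len(k), function(s)
        min(block$cost[, s] + UP[p, ] + sibcost), 1L)
    }
    for (e in seq_len(nrow(post))) {
      ch <- post[e, 2]
      same <- min(UP[ch, ] + V[ch, ])
      forced[e] <- forced[e] + (same - charlen)
    }
  }
  # return in the order of tree$edge
  key <- paste(post[, 1], post[, 2])
  forced[match(paste(tree$edge[, 1], tree$edge[, 2]), key)]
}
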