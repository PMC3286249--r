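# Ensemble fit statistics (consistency and retention indices) and
# Fig-style apomorphy mapping of state transformations onto edges.

matrix_column <- function(m, j) {
  lapply(seq_len(n_taxa(m)), function(i) {
    mask <- m$cells[i, j]
    if (is.na(mask)) NA_integer_ else decode_mask(mask)
  })
}

# per-cell obligate spans (the strict-polymorphism surcharge per character)
poly_spans <- function(m) {
  vapply(seq_len(n_char(m)), function(j) {
    kind <- m$chars$kind[j]
    sum(vapply(m$cells[, j], function(mask) {
      if (is.na(mask)) return(0L)
      set_span(decode_mask(mask), kind)
    }, 1L))
  }, 1L)
}

#' Fit statistics of a tree on a matrix
#'
#' Computes exact integer observed steps `s`, minimum conceivable steps
#' `m` and maximum (star-tree) steps `g` for every character, and the
#' ensemble consistency index `CI = sum(m)/L`, retention index
#' `RI = (sum(g) - L)/(sum(g) - sum(m))` and rescaled consistency index
#' `RC = CI * RI`, where `L = sum(s)` is the tree length.  Both the
#' all-characters ensembles and the variants restricted to
#' parsimony-informative characters (those with `g > m`, i.e. able to show
#' homoplasy on some tree) are reported; per-character ratios `ci = m/s`
#' and `ri = (g - s)/(g - m)` are `NA` where undefined.
#'
#' In `"strict"` polymorphism mode each polymorphic cell's obligate state
#' span is charged to `s`, `m` and `g` alike (Farris polymorphism
#' counting), which adds a tree-independent constant to the length.
#'
#' @param tree a `phylo` over the matrix taxa.
#' @param m a `char_matrix`.
#' @param polymorphism `"ambiguous"` (default) or `"strict"`.
#' @return A `fit_report` with components `tree_length`, `per_character`
#'   (data frame), `ensemble` and `ensemble_informative` (named vectors),
#'   and 2-decimal `rounded` values.
#' @export
fit_report <- function(tree, m, polymorphism = c("ambiguous", "strict")) {
  polymorphism <- match.arg(polymorphism)
  ncha <- n_char(m)
  s <- tree_length(tree, m, polymorphism = polymorphism, per_character = TRUE)
  kinds <- m$chars$kind
  mi <- vapply(seq_len(ncha), function(j)
    min_steps(matrix_column(m, j), kinds[j]), 1L)
  gi <- vapply(seq_len(ncha), function(j)
    max_steps(matrix_column(m, j), kinds[j]), 1L)
  if (polymorphism == "strict") {
    sp <- poly_spans(m)
    mi <- mi + sp
    gi <- gi + sp
  }
  L <- sum(s)
  stopifnot(all(mi <= s), all(s <= gi))
  ens <- function(idx) {
    M <- sum(mi[idx]); G <- sum(gi[idx]); Ls <- sum(s[idx])
    ci <- if (Ls > 0) M / Ls else NA_real_
    ri <- if (G > M) (G - Ls) / (G - M) else NA_real_
    c(CI = ci, RI = ri, RC = ci * ri)
  }
  informative <- gi > mi
  per_char <- data.frame(
    index = m$chars$index, label = m$chars$label, kind = kinds,
    steps = s, min_steps = mi, max_steps = gi,
    informative = informative,
    ci = ifelse(s > 0, mi / s, NA_real_),
    ri = ifelse(gi > mi, (gi - s) / (gi - mi), NA_real_))
  ensemble <- ens(rep(TRUE, ncha))
  ensemble_inf <- ens(informative)
  structure(list(tree_length = L,
                 per_character = per_char,
                 ensemble = ensemble,
                 ensemble_informative = ensemble_inf,
                 rounded = round(c(ensemble[c("CI", "RI")],
                                   CI_informative = unname(ensemble_inf["CI"]),
                                   RI_informative = unname(ensemble_inf["RI"])), 2),
                 polymorphism = polymorphism),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit_report (%s polymorphism): length %d\n",
              x$polymorphism, x$tree_length))
  cat(sprintf("  all characters:        CI = %.4f  RI = %.4f  RC = %.4f\n",
              x$ensemble["CI"], x$ensemble["RI"], x$ensemble["RC"]))
  cat(sprintf("  informative only (%2d): CI = %.4f  RI = %.4f  RC = %.4f\n",
              sum(x$per_character$informative),
              x$ensemble_informative["CI"], x$ensemble_informative["RI"],
              x$ensemble_informative["RC"]))
  invisible(x)
}

#' Map character-state transformations onto edges
#'
#' For every character, reconstructs one most-parsimonious ancestral state
#' assignment (ACCTRAN or DELTRAN tie-breaking, see [ancestral_states()])
#' on the rooted tree and records every edge whose endpoints differ.  Each
#' record carries the printed 1-based character number, the parent and
#' child states, and the number of steps the transformation costs (always
#' 1 for binary/unordered characters, `|from - to|` for additive ones);
#' record steps sum to the tree length.  With
#' `resolution = "unambiguous"` only records common to ACCTRAN and
#' DELTRAN are kept (their step sums may then fall short of the length).
#'
#' @param tree a `phylo` rooted at the outgroup (see [root_at_outgroup()]).
#' @param m a `char_matrix`.
#' @param resolution `"ACCTRAN"`, `"DELTRAN"` or `"unambiguous"`.
#' @return An `apomorphy_map` data frame with columns `edge`
#'   (row of `tree$edge`), `parent`, `child`, `character`, `label`,
#'   `from`, `to`, `steps`.
#' @export
map_apomorphies <- function(tree, m, resolution = c("ACCTRAN", "DELTRAN",
                                                    "unambiguous")) {
  resolution <- match.arg(resolution)
  if (!ape::is.rooted(tree))
    stop("map_apomorphies requires a rooted tree; see root_at_outgroup()",
         call. = FALSE)
  if (!setequal(tree$tip.label, m$taxa))
    stop("tree tip labels do not match matrix taxa", call. = FALSE)
  blocks <- char_blocks(m, taxa_order = match(tree$tip.label, m$taxa))
  recs <- list()
  for (j in seq_len(n_char(m))) {
    block <- blocks[[j]]
    if (block$k <= 1) next
    asg <- if (resolution == "unambiguous") {
      a1 <- sankoff_assign(tree, block, "ACCTRAN")
      a2 <- sankoff_assign(tree, block, "DELTRAN")
      list(a1, a2)
    } else {
      list(sankoff_assign(tree, block, resolution))
    }
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      keep <- all(vapply(asg, function(a) a[p] != a[ch], TRUE))
      if (resolution == "unambiguous")
        keep <- keep && asg[[1]][p] == asg[[2]][p] && asg[[1]][ch] == asg[[2]][ch]
      if (!keep) next
      a <- asg[[1]]
      recs[[length(recs) + 1]] <- data.frame(
        edge = e, parent = p, child = ch,
        character = m$chars$index[j], label = m$chars$label[j],
        from = a[p], to = a[ch],
        steps = block$cost[a[p] + 1L, a[ch] + 1L])
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(edge = integer(0), parent = integer(0), child = integer(0),
               character = integer(0), label = character(0),
               from = integer(0), to = integer(0), steps = integer(0))
  out <- out[order(out$edge, out$character), ]
  rownames(out) <- NULL
  class(out) <- c("apomorphy_map", "data.frame")
  attr(out, "resolution") <- resolution
  out
}

#' @export
print.apomorphy_map <- function(x, max_edges = 10, ...) {
  cat(sprintf("apomorphy_map (%s): %d transformations, %d steps on %d edges\n",
              attr(x, "resolution"), nrow(x), sum(x$steps),
              length(unique(x$edge))))
  shown <- 0
  for (e in unique(x$edge)) {
    if (shown >= max_edges) { cat("  ...\n"); break }
    rows <- x[x$edge == e, ]
    cat(sprintf("  edge %d (%d -> %d):  %s\n", e, rows$parent[1], rows$child[1],
                paste(sprintf("%d: %d>%d", rows$character, rows$from, rows$to),
                      collapse = "  ")))
    shown <- shown + 1
  }
  invisible(x)
}
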