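# One-command reproduction of the bundled Moriomorphini analysis and the
# same pipeline for user matrices.  Outputs: best tree(s) as Newick
# (rooted at the outgroup when one is given), a fit report as JSON, an
# apomorphy table as TSV, and a run manifest sufficient to reproduce the
# run byte-for-byte.

write_run_outputs <- function(m, result, outgroup, output_dir, resolution) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  best <- result$best_trees[[1]]
  files <- character(0)

  tree_out <- if (!is.null(outgroup)) root_at_outgroup(best, outgroup) else best
  nwk <- file.path(output_dir, "best_tree.nwk")
  ape::write.tree(tree_out, file = nwk)
  files <- c(files, nwk)
  if (length(result$best_trees) > 1) {
    all_nwk <- file.path(output_dir, "best_trees.nwk")
    ape::write.tree(result$best_trees, file = all_nwk)
    files <- c(files, all_nwk)
  }

  fr <- fit_report(best, m, polymorphism = result$polymorphism)
  fit_json <- file.path(output_dir, "fit_report.json")
  jsonlite::write_json(
    list(tree_length = fr$tree_length,
         ensemble = as.list(fr$ensemble),
         ensemble_informative = as.list(fr$ensemble_informative),
         rounded = as.list(fr$rounded),
         per_character = fr$per_character),
    fit_json, auto_unbox = TRUE, digits = NA, na = "null")
  files <- c(files, fit_json)

  if (!is.null(outgroup)) {
    apo <- map_apomorphies(root_at_outgroup(best, outgroup), m, resolution)
    apo_tsv <- file.path(output_dir, "apomorphies.tsv")
    utils::write.table(apo, apo_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, apo_tsv)
  }
  list(files = files, fit = fr)
}

verify_outputs <- function(m, result, nwk_path) {
  reread <- ape::read.tree(nwk_path)
  reread$tip.label <- gsub("_", " ", reread$tip.label)
  len <- tree_length(reread, m, polymorphism = result$polymorphism)
  if (len != result$best_length)
    stop("re-scored length ", len, " does not match reported best length ",
         result$best_length, call. = FALSE)
  invisible(len)
}

#' Reproduce the bundled Moriomorphini analysis
#'
#' Loads the bundled 22 x 75 matrix, runs the parsimony ratchet (TBR, 200
#' iterations by default), writes the best tree rooted at the
#' *Trechus obtusus* outgroup, the fit report, the ACCTRAN apomorphy table
#' and a run manifest, then re-parses and re-scores the emitted tree as a
#' self-check.  Polymorphic terminals are scored as totally ambiguous; the
#' manifest additionally records the polymorphism-aware (strict) length of
#' the same topology, the convention under which the original analysis
#' printed its tree length.
#'
#' @param output_dir directory for outputs (created if needed).
#' @param seed integer seed.
#' @param iterations ratchet iterations.
#' @param quiet suppress progress messages.
#' @return The run manifest (a list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_published_analysis <- function(output_dir, seed = 1L, iterations = 200L,
                                   quiet = FALSE) {
  m <- load_moriomorphini()
  config <- search_config(seed = seed, n_ratchet_iterations = iterations)
  result <- ratchet_search(m, config, quiet = quiet)
  outgroup <- "Trechus obtusus"
  out <- write_run_outputs(m, result, outgroup, output_dir, "ACCTRAN")
  verify_outputs(m, result, file.path(output_dir, "best_tree.nwk"))
  strict_len <- tree_length(result$best_trees[[1]], m, polymorphism = "strict")
  manifest <- list(
    input = "bundled moriomorphini.nex",
    fixture_md5 = MORIOMORPHINI_MD5,
    tool_version = as.character(utils::packageVersion("moriomorph")),
    config = unclass(config),
    outgroup = outgroup,
    best_length = result$best_length,
    best_length_strict_polymorphism = strict_len,
    n_best_trees = length(result$best_trees),
    ensemble = as.list(out$fit$ensemble),
    ensemble_informative = as.list(out$fit$ensemble_informative),
    files = basename(out$files))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!quiet)
    message(sprintf("best length %d (%d strict-polymorphism), %d tree(s)",
                    result$best_length, strict_len, length(result$best_trees)))
  invisible(manifest)
}

#' Run the parsimony pipeline on a user matrix
#'
#' Parses the matrix, searches with the ratchet (a 3-taxon matrix skips
#' the search: only one topology exists), writes the same output set as
#' [run_published_analysis()] (apomorphies only when an outgroup is given),
#' and re-verifies every emitted tree.
#'
#' @param matrix_path path to the matrix document.
#' @param dialect `"nexus"` or `"tnt"`.
#' @param config a [search_config()].
#' @param outgroup optional outgroup taxon for rooting/apomorphies.
#' @param output_dir directory for outputs.
#' @param resolution apomorphy resolution, see [map_apomorphies()].
#' @param quiet suppress progress messages.
#' @return The run manifest, invisibly.
#' @export
run_user_analysis <- function(matrix_path, dialect = c("nexus", "tnt"),
                              config = search_config(), outgroup = NULL,
                              output_dir = ".", resolution = "ACCTRAN",
                              quiet = FALSE) {
  dialect <- match.arg(dialect)
  m <- parse_matrix(readLines(matrix_path), dialect)
  if (!is.null(outgroup) && !outgroup %in% m$taxa)
    stop("outgroup '", outgroup, "' is not a taxon of the matrix",
         call. = FALSE)
  if (n_taxa(m) == 3) {
    tr <- phylo_from_edge(matrix(c(4L, 1L, 4L, 2L, 4L, 3L), ncol = 2,
                                 byrow = TRUE), m)
    result <- structure(list(best_length = tree_length(tr, m),
                             best_trees = structure(list(tr),
                                                    class = "multiPhylo"),
                             trajectory = integer(0), config = config,
                             polymorphism = "ambiguous"),
                        class = "search_result")
  } else {
    result <- ratchet_search(m, config, quiet = quiet)
  }
  out <- write_run_outputs(m, result, outgroup, output_dir, resolution)
  verify_outputs(m, result, file.path(output_dir, "best_tree.nwk"))
  manifest <- list(
    input = matrix_path,
    input_md5 = unname(tools::md5sum(matrix_path)),
    tool_version = as.character(utils::packageVersion("moriomorph")),
    config = unclass(config),
    outgroup = outgroup,
    best_length = result$best_length,
    n_best_trees = length(result$best_trees),
    ensemble = as.list(out$fit$ensemble),
    files = basename(out$files))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
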