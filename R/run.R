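# End-to-end orchestration: root -> label -> annotate -> merge -> summarize.
# These functions back the command-line interface in inst/cli/cta.R; errors
# of class "cladetax_input_error" map to exit code 2 there, everything else
# to 1.

#' Assemble and validate a run configuration
#'
#' @param tree Path to the Newick tree (reference + query tips).
#' @param ref_taxonomy Path to the reference taxonomy TSV.
#' @param nbc Path to the NBC classification TSV for the query ASVs.
#' @param synonyms Optional path to a synonym TSV (rank, alias, canonical).
#' @param threshold Support threshold f in (0.5, 1]; 1 = strict congruence.
#' @param ranks Rank names, most general first.
#' @param gap_policy `"truncate"` or `"error"` for non-prefix lineages.
#' @param conflict_policy `"keep-nbc"` or `"prefer-cta"`.
#' @param to_rank Optional rank the query traversal must reach.
#' @param out Output directory.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return Validated config list of class `cta_config`.
#' @export
run_config <- function(tree, ref_taxonomy, nbc, synonyms = NULL,
                       threshold = 1.0, ranks = default_ranks(),
                       gap_policy = c("truncate", "error"),
                       conflict_policy = c("keep-nbc", "prefer-cta"),
                       to_rank = NULL, out = ".",
                       log_level = c("info", "quiet", "debug")) {
  gap_policy <- match.arg(gap_policy)
  conflict_policy <- match.arg(conflict_policy)
  log_level <- match.arg(log_level)
  for (p in c(tree = tree, ref_taxonomy = ref_taxonomy, nbc = nbc,
              if (!is.null(synonyms)) c(synonyms = synonyms))) {
    if (!file.exists(p)) stop_input("input file not found: ", p)
  }
  if (!is.numeric(threshold) || threshold <= 0.5 || threshold > 1) {
    stop_input("threshold must lie in (0.5, 1]")
  }
  if (!is.null(to_rank) && !(to_rank %in% ranks)) {
    stop_input("to_rank '", to_rank, "' is not a configured rank")
  }
  structure(list(tree = tree, ref_taxonomy = ref_taxonomy, nbc = nbc,
                 synonyms = synonyms, threshold = threshold, ranks = ranks,
                 gap_policy = gap_policy, conflict_policy = conflict_policy,
                 to_rank = to_rank, out = out, log_level = log_level),
            class = "cta_config")
}

log_msg <- function(config, level, ...) {
  lv <- c(quiet = 0L, info = 1L, debug = 2L)
  if (lv[[config$log_level]] >= lv[[level]]) message(...)
}

#' Run the full annotation pipeline
#'
#' Reads the tree and tables, normalizes all lineages through the synonym
#' map, midpoint-roots the tree if it is unrooted, labels every node from
#' the reference tips, annotates each query ASV from its nearest labeled
#' ancestor, merges with the NBC table (never overwriting an NBC label) and
#' writes `rooted_tree.nwk`, `node_annotations.tsv`, `annotation.tsv`,
#' `summary.json` and `summary.txt` into the output directory.  Outputs are
#' deterministic: identical inputs give byte-identical files.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the rooted tree, node annotation, merged
#'   table, summary and output paths.
#' @export
run_annotate <- function(config) {
  stopifnot(inherits(config, "cta_config"))
  syn <- if (!is.null(config$synonyms)) read_synonyms(config$synonyms)
  ref <- read_taxonomy(config$ref_taxonomy, ranks = config$ranks,
                       gap_policy = config$gap_policy)
  nbc <- read_taxonomy(config$nbc, ranks = config$ranks,
                       gap_policy = config$gap_policy)
  ref <- normalize_lineage(ref, syn)
  nbc <- normalize_lineage(nbc, syn)
  phy <- read_newick(config$tree)

  both <- intersect(rownames(nbc), rownames(ref))
  if (length(both)) {
    stop_input("ASV(s) listed in both the NBC and the reference table ",
               "(ambiguous role): ", paste(utils::head(both, 5L),
                                           collapse = ", "))
  }
  queries <- setdiff(phy$tip.label, rownames(ref))
  no_nbc <- setdiff(queries, rownames(nbc))
  if (length(no_nbc)) {
    stop_input("query tip(s) missing from the NBC table: ",
               paste(utils::head(no_nbc, 5L), collapse = ", "),
               if (length(no_nbc) > 5L) ", ..." else "")
  }
  log_msg(config, "info", "tips: ", ape::Ntip(phy),
          " (references: ", nrow(ref[rownames(ref) %in% phy$tip.label, ,
                                     drop = FALSE]),
          ", queries: ", length(queries), "); threshold f = ",
          format(config$threshold), "; ranks: ",
          paste(config$ranks, collapse = ", "))
  if (!ape::is.rooted(phy)) {
    log_msg(config, "info", "tree is unrooted; applying midpoint rooting")
    phy <- midpoint_root(phy)
  }
  # canonicalize node numbering through a Newick round-trip, so the node
  # ids in the written annotation tables match a re-parse of the written
  # rooted tree (ids are a deterministic function of the Newick string)
  phy <- read_newick(text = ape::write.tree(phy))
  ref <- ref[rownames(ref) %in% phy$tip.label, , drop = FALSE]
  ann <- label_nodes(phy, ref, f = config$threshold)
  n_labeled <- sum(rowSums(!is.na(ann$lineage)) > 0L)
  log_msg(config, "info", "labeled nodes: ", n_labeled, " of ",
          nrow(ann$lineage))
  qa <- annotate_queries(phy, ann, queries, to_rank = config$to_rank)
  cta <- as.matrix(qa[, config$ranks, drop = FALSE])
  rownames(cta) <- qa$asv
  node <- stats::setNames(qa$node, qa$asv)
  merged <- merge_with_nbc(nbc, cta, conflict_policy = config$conflict_policy,
                           supporting_node = node)
  summ <- summarize_annotation(merged)
  log_msg(config, "info", "CTA-filled rows: ", summ$n_reclassified, " of ",
          summ$n_asv)

  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tree = file.path(config$out, "rooted_tree.nwk"),
             nodes = file.path(config$out, "node_annotations.tsv"),
             table = file.path(config$out, "annotation.tsv"),
             json = file.path(config$out, "summary.json"),
             txt = file.path(config$out, "summary.txt"))
  write_newick(phy, paths["tree"])
  write_node_annotations(ann, paths["nodes"])
  write_annotation_table(merged, paths["table"])
  js <- list(n_asv = summ$n_asv,
             n_reclassified = summ$n_reclassified,
             frac_reclassified = round(summ$frac_reclassified, 3),
             n_conflict = summ$n_conflict,
             threshold = config$threshold,
             ranks = config$ranks,
             per_rank = summ$per_rank)
  jsonlite::write_json(js, paths["json"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::capture.output(print(summ), file = paths["txt"])
  invisible(list(tree = phy, nodes = ann, table = merged, summary = summ,
                 paths = paths))
}

#' Collapse nested node labels from annotate outputs
#'
#' Reads `rooted_tree.nwk` and `node_annotations.tsv` produced by
#' [run_annotate()] and writes `collapsed.tsv`: for every (rank, label) the
#' most-ancestral node(s) carrying it (see [collapse_nested_labels()]).
#'
#' @param dir Directory holding the annotate outputs (also receives the
#'   result).
#' @param ranks Rank names used in the run.
#' @return The written path, invisibly.
#' @export
run_collapse <- function(dir, ranks = default_ranks()) {
  tree_p <- file.path(dir, "rooted_tree.nwk")
  nodes_p <- file.path(dir, "node_annotations.tsv")
  for (p in c(tree_p, nodes_p)) {
    if (!file.exists(p)) {
      stop_input("missing annotate output: ", p, " (run annotate first)")
    }
  }
  phy <- read_newick(tree_p)
  d <- utils::read.delim(nodes_p, colClasses = "character",
                         check.names = FALSE)
  lin <- as.matrix(d[, ranks, drop = FALSE])
  lin[lin == "NA"] <- NA_character_
  rownames(lin) <- d$node
  ann <- structure(list(lineage = lin,
                        support = matrix(NA_real_, nrow(lin), ncol(lin)),
                        n_ref = as.integer(d$n_ref), ranks = ranks,
                        f = NA_real_, n_tip = ape::Ntip(phy)),
                   class = "cta_nodes")
  out <- collapse_nested_labels(phy, ann)
  path <- file.path(dir, "collapsed.tsv")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Drop reference tips from an annotated tree
#'
#' Writes a query-only tree (`query_tree.nwk`): reference tips are removed
#' and the unifurcations suppressed, preserving all query-to-query path
#' distances — the form used for downstream visualization of annotated
#' ASVs.
#'
#' @param tree Path to the (rooted or unrooted) Newick tree.
#' @param ref_taxonomy Path to the reference taxonomy TSV; its ids are the
#'   tips to drop.
#' @param out Output directory.
#' @param ranks Rank names for parsing the reference table.
#' @return The written path, invisibly.
#' @export
run_prune_refs <- function(tree, ref_taxonomy, out = ".",
                           ranks = default_ranks()) {
  phy <- read_newick(tree)
  ref <- read_taxonomy(ref_taxonomy, ranks = ranks)
  drop <- intersect(rownames(ref), phy$tip.label)
  pruned <- prune_tips(phy, drop)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out, "query_tree.nwk")
  write_newick(pruned, path)
  invisible(path)
}

#' Simulate a scenario and write its files
#'
#' Convenience wrapper: builds the scenario, simulates taxonomy and tree,
#' and writes the five scenario files via [write_scenario()].
#'
#' @param seed Integer seed.
#' @param out Output directory.
#' @param ... Passed to [planted_scenario()].
#' @return The written paths, invisibly.
#' @export
run_simulate <- function(seed = 1L, out = ".", ...) {
  sc <- planted_scenario(seed = seed, ...)
  sim <- simulate_tree(sc)
  write_scenario(sim, out)
}
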