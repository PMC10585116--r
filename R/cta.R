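# Cladal taxonomic annotation: propagate reference-tip lineages to internal
# nodes by consensus, annotate query tips from their nearest labeled
# ancestor, and merge with an NBC table without ever overwriting it.

#' Label tree nodes from reference tips
#'
#' Assigns every node of a rooted tree the most specific lineage congruent
#' across the reference tips descending from it, under the support threshold
#' `f` (see [consensus_lineage()]).  Only reference lineages contribute:
#' query tips (tips absent from `ref`) and nodes with no reference
#' descendants receive an all-unassigned lineage.  Reference tips carry
#' their own lineage with support 1.
#'
#' @param phy A rooted `phylo` (run [midpoint_root()] first if needed).
#' @param ref Character matrix of reference lineages, rownames = tip labels
#'   (a subset of the tree's tips), columns = ranks, `NA` = unassigned.
#'   Lineages are assumed normalized (see [normalize_lineage()]).
#' @param f Support threshold in `(0.5, 1]`; 1 demands strict congruence.
#' @return A `cta_nodes` object: list with `lineage` and `support` matrices
#'   (one row per node id, tips included), `n_ref` (labeled reference
#'   descendants per node), `ranks`, `f`, `n_tip`.
#' @export
label_nodes <- function(phy, ref, f = 1.0) {
  if (!inherits(phy, "phylo")) stop_input("phy must be a phylo object")
  if (!ape::is.rooted(phy)) {
    stop_input("tree is unrooted; run midpoint_root() first")
  }
  if (!is.matrix(ref) || (nrow(ref) > 0L && is.null(rownames(ref)))) {
    stop_input("ref must be a character matrix with tip labels as rownames")
  }
  extra <- setdiff(rownames(ref), phy$tip.label)
  if (length(extra)) {
    stop_input("reference table names tips absent from the tree: ",
               paste(utils::head(extra, 5L), collapse = ", "),
               if (length(extra) > 5L) ", ..." else "")
  }
  ranks <- colnames(ref)
  ntip <- ape::Ntip(phy)
  nnode <- ntip + phy$Nnode
  ref_idx <- match(rownames(ref), phy$tip.label)

  # reference tip ids under each node, accumulated in one postorder pass
  desc <- rep(list(integer(0)), nnode)
  for (i in seq_along(ref_idx)) desc[[ref_idx[i]]] <- i
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }

  lineage <- matrix(NA_character_, nrow = nnode, ncol = length(ranks),
                    dimnames = list(seq_len(nnode), ranks))
  support <- matrix(NA_real_, nrow = nnode, ncol = length(ranks),
                    dimnames = list(seq_len(nnode), ranks))
  n_ref <- integer(nnode)
  for (n in seq_len(nnode)) {
    ids <- desc[[n]]
    if (length(ids) == 0L) next
    cons <- consensus_lineage(ref[ids, , drop = FALSE], f = f)
    lineage[n, ] <- cons$lineage
    support[n, ] <- cons$support
    n_ref[n] <- cons$n
  }
  structure(list(lineage = lineage, support = support, n_ref = n_ref,
                 ranks = ranks, f = f, n_tip = ntip),
            class = "cta_nodes")
}

#' @export
print.cta_nodes <- function(x, ...) {
  labeled <- sum(rowSums(!is.na(x$lineage)) > 0L)
  cat("Cladal node annotation: ", nrow(x$lineage), " nodes (",
      x$n_tip, " tips), ", labeled, " carrying a lineage, f = ",
      format(x$f), "\n", sep = "")
  invisible(x)
}

#' Annotate query tips by rootward traversal
#'
#' Walks from each query tip parent-by-parent toward the root and adopts the
#' full lineage of the first node carrying an assignment.  By default any
#' assigned rank stops the walk; with `to_rank` the walk continues until a
#' node assigned at that rank (or deeper) is met.  A query whose walk
#' reaches the root without meeting an assignment is returned all-unassigned
#' with node `NA`.
#'
#' @param phy The rooted `phylo` used for [label_nodes()].
#' @param ann The `cta_nodes` annotation for `phy`.
#' @param queries Character vector of query tip labels.
#' @param to_rank Optional rank name to traverse to.
#' @return `data.frame` with columns `asv`, `node`, then one column per rank.
#' @export
annotate_queries <- function(phy, ann, queries, to_rank = NULL) {
  stopifnot(inherits(ann, "cta_nodes"))
  queries <- as.character(queries)
  missing <- setdiff(queries, phy$tip.label)
  if (length(missing)) {
    stop_input("query tip(s) not in the tree: ",
               paste(missing, collapse = ", "))
  }
  ranks <- ann$ranks
  stop_col <- if (is.null(to_rank)) 0L else match(to_rank, ranks)
  if (!is.null(to_rank) && is.na(stop_col)) {
    stop_input("to_rank '", to_rank, "' is not one of: ",
               paste(ranks, collapse = ", "))
  }
  par <- parent_vec(phy)
  lin <- matrix(NA_character_, nrow = length(queries), ncol = length(ranks),
                dimnames = list(queries, ranks))
  node <- rep(NA_integer_, length(queries))
  for (i in seq_along(queries)) {
    w <- par[match(queries[i], phy$tip.label)]
    while (w != 0L) {
      hit <- if (stop_col > 0L) {
        !is.na(ann$lineage[w, stop_col])
      } else {
        any(!is.na(ann$lineage[w, ]))
      }
      if (hit) {
        lin[i, ] <- ann$lineage[w, ]
        node[i] <- w
        break
      }
      w <- par[w]
    }
  }
  out <- data.frame(asv = queries, node = node, lin,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Merge cladal annotations with an NBC taxonomy
#'
#' The classifier's labels are authoritative: a rank the NBC assigned is
#' kept verbatim, and cladal (CTA) labels only fill ranks the NBC left
#' unassigned.  A CTA lineage disagreeing with the NBC at an NBC-assigned
#' rank is a conflict: under the default `"keep-nbc"` policy nothing is
#' filled for that ASV and the conflicting ranks are flagged; under
#' `"prefer-cta"` the CTA labels replace the row from the first conflicting
#' rank down (still flagged).  Prefix contiguity is re-enforced on every
#' merged lineage.
#'
#' @param nbc Character matrix of NBC lineages, rownames = ASV ids.
#' @param cta Character matrix of CTA lineages for a subset of the same
#'   ASVs (rownames must be contained in `nbc`'s), same rank columns.
#' @param conflict_policy `"keep-nbc"` (default) or `"prefer-cta"`.
#' @param supporting_node Optional named integer vector (ASV -> node id of
#'   the labeled ancestor), recorded in the output.
#' @return `data.frame` of class `annotation_table`: columns `asv`, one per
#'   rank, one `source_<rank>` per rank (`NBC`, `CTA` or `unassigned`),
#'   `tax_source` (`CTA` iff any rank was filled by CTA), `supporting_node`,
#'   `conflicts` (comma-separated conflicting ranks or empty).
#' @export
merge_with_nbc <- function(nbc, cta,
                           conflict_policy = c("keep-nbc", "prefer-cta"),
                           supporting_node = NULL) {
  conflict_policy <- match.arg(conflict_policy)
  if (!is.matrix(nbc) || !is.matrix(cta)) {
    stop_input("nbc and cta must be lineage matrices")
  }
  if (!identical(colnames(nbc), colnames(cta))) {
    stop_input("nbc and cta tables use different rank sets")
  }
  orphan <- setdiff(rownames(cta), rownames(nbc))
  if (length(orphan)) {
    stop_input("CTA annotations for ASV(s) absent from the NBC table: ",
               paste(orphan, collapse = ", "))
  }
  ranks <- colnames(nbc)
  asv <- rownames(nbc)
  if (is.null(asv)) {
    if (nrow(nbc) > 0L) stop_input("nbc must have ASV ids as rownames")
    asv <- character(0)
  }
  merged <- enforce_prefix(nbc)
  src <- matrix(ifelse(is.na(merged), "unassigned", "NBC"),
                nrow = nrow(merged), ncol = ncol(merged),
                dimnames = dimnames(merged))
  conflicts <- character(length(asv))
  for (i in seq_along(asv)) {
    j <- match(asv[i], rownames(cta))
    if (is.na(j)) next
    cl <- cta[j, ]
    if (all(is.na(cl))) next
    nb <- merged[i, ]
    confl <- which(!is.na(nb) & !is.na(cl) & nb != cl)
    if (length(confl)) {
      conflicts[i] <- paste(ranks[confl], collapse = ",")
      if (conflict_policy == "prefer-cta") {
        from <- confl[1L]
        take <- from:length(ranks)
        merged[i, take] <- cl[take]
        src[i, take] <- ifelse(is.na(cl[take]), "unassigned", "CTA")
      }
    } else {
      fill <- which(is.na(nb) & !is.na(cl))
      if (length(fill)) {
        merged[i, fill] <- cl[fill]
        src[i, fill] <- "CTA"
      }
    }
    # re-enforce prefix contiguity after the fill
    row <- enforce_prefix(merged[i, ])
    src[i, is.na(row)] <- "unassigned"
    merged[i, ] <- row
  }
  tax_source <- ifelse(rowSums(src == "CTA") > 0L, "CTA", "NBC")
  # the supporting node is only meaningful for rows that adopted CTA labels
  node <- rep(NA_integer_, length(asv))
  if (!is.null(supporting_node)) {
    hit <- match(asv, names(supporting_node))
    take <- !is.na(hit) & tax_source == "CTA"
    node[take] <- as.integer(supporting_node[hit[take]])
  }
  srcd <- as.data.frame(src, stringsAsFactors = FALSE)
  names(srcd) <- paste0("source_", ranks)
  out <- data.frame(asv = asv, merged, srcd,
                    tax_source = tax_source,
                    supporting_node = node,
                    conflicts = conflicts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("annotation_table", "data.frame")
  out
}

#' Summarize a merged annotation table
#'
#' Counts, per rank, how many ASVs were unassigned before the cladal fill
#' (ranks not sourced from the NBC) and after it, plus how many rows gained
#' at least one cladal label ("reclassified") and how many carry conflicts.
#'
#' @param table An `annotation_table` from [merge_with_nbc()].
#' @return List of class `cta_summary` with elements `n_asv`, `per_rank`
#'   (`data.frame`: rank, unassigned_before, unassigned_after),
#'   `n_reclassified`, `frac_reclassified`, `n_conflict`.
#' @export
summarize_annotation <- function(table) {
  src_cols <- grep("^source_", names(table), value = TRUE)
  ranks <- sub("^source_", "", src_cols)
  n <- nrow(table)
  before <- vapply(src_cols, function(cc) sum(table[[cc]] != "NBC"),
                   integer(1))
  after <- vapply(src_cols, function(cc) sum(table[[cc]] == "unassigned"),
                  integer(1))
  n_cta <- if (n) sum(table$tax_source == "CTA") else 0L
  n_conf <- if (n) sum(nzchar(table$conflicts)) else 0L
  structure(list(
    n_asv = n,
    per_rank = data.frame(rank = ranks,
                          unassigned_before = unname(before),
                          unassigned_after = unname(after),
                          stringsAsFactors = FALSE),
    n_reclassified = n_cta,
    frac_reclassified = if (n) n_cta / n else 0,
    n_conflict = n_conf), class = "cta_summary")
}

#' @export
print.cta_summary <- function(x, ...) {
  cat("ASVs:            ", x$n_asv, "\n", sep = "")
  cat("Reclassified:    ", x$n_reclassified, " (",
      sprintf("%.1f%%", 100 * x$frac_reclassified), ")\n", sep = "")
  cat("With conflicts:  ", x$n_conflict, "\n", sep = "")
  cat("Unassigned ranks (before -> after cladal fill):\n")
  for (i in seq_len(nrow(x$per_rank))) {
    cat(sprintf("  %-8s %4d -> %4d\n", x$per_rank$rank[i],
                x$per_rank$unassigned_before[i],
                x$per_rank$unassigned_after[i]))
  }
  invisible(x)
}

#' Write node annotations as TSV
#'
#' One row per node id with the lineage, per-rank support (3 decimals) and
#' the count of labeled reference descendants.
#'
#' @param ann A `cta_nodes` object.
#' @param path Output path.
#' @export
write_node_annotations <- function(ann, path) {
  supp <- ann$support
  supp_chr <- matrix(ifelse(is.na(supp), "NA", sprintf("%.3f", supp)),
                     nrow = nrow(supp))
  d <- data.frame(node = as.integer(rownames(ann$lineage)),
                  ann$lineage, supp_chr,
                  n_ref = ann$n_ref,
                  check.names = FALSE, stringsAsFactors = FALSE)
  names(d) <- c("node", ann$ranks, paste0("support_", ann$ranks), "n_ref")
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a merged annotation table as TSV
#'
#' @param table An `annotation_table`.
#' @param path Output path.
#' @export
write_annotation_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
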