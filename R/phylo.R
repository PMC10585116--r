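# Tree ingestion and manipulation on top of ape's "phylo" representation.
# Node identifiers throughout the package are ape node numbers: tips are
# 1..Ntip in tip-label order of the parsed file, internal nodes Ntip+1 ..
# Ntip+Nnode.  They are deterministic for a given Newick string.

#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] adding the validation the annotation
#' algorithm relies on: unique tip labels and no negative branch lengths.
#' Quoted labels, internal node labels and missing branch lengths are
#' tolerated (metric operations will refuse trees without lengths).
#'
#' @param file Path to a Newick file, or `NULL` when `text` is given.
#' @param text Newick string, alternative to `file`.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(file = NULL, text = NULL) {
  if (is.null(file) && is.null(text)) stop_input("give a file or text")
  if (!is.null(file) && !file.exists(file)) {
    stop_input("tree file not found: ", file)
  }
  phy <- tryCatch(
    if (is.null(text)) ape::read.tree(file) else ape::read.tree(text = text),
    error = function(e) stop_input("failed to parse Newick: ",
                                   conditionMessage(e)),
    warning = function(w) stop_input("failed to parse Newick: ",
                                     conditionMessage(w)))
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop_input("failed to parse Newick",
               if (!is.null(file)) paste0(" from ", file) else "")
  }
  if (anyDuplicated(phy$tip.label)) {
    stop_input("tree has duplicated tip labels: ",
               paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
                     collapse = ", "))
  }
  if (!is.null(phy$edge.length) && any(phy$edge.length < 0)) {
    stop_input("tree has negative branch lengths")
  }
  phy
}

#' Write a tree in Newick format
#'
#' @param phy A `phylo` object.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_newick <- function(phy, file) {
  ape::write.tree(phy, file = file)
  invisible(file)
}

check_metric <- function(phy, op) {
  if (is.null(phy$edge.length) || anyNA(phy$edge.length)) {
    stop_input(op, " requires branch lengths on every edge")
  }
  if (any(phy$edge.length < 0)) stop_input(op, ": negative branch lengths")
}

root_node <- function(phy) ape::Ntip(phy) + 1L

# parent of every node (0 for the root), indexed by node id
parent_vec <- function(phy) {
  p <- integer(ape::Ntip(phy) + phy$Nnode)
  p[phy$edge[, 2L]] <- phy$edge[, 1L]
  p
}

edge_length_between <- function(phy, a, b) {
  i <- which((phy$edge[, 1L] == a & phy$edge[, 2L] == b) |
             (phy$edge[, 1L] == b & phy$edge[, 2L] == a))
  if (length(i) != 1L) stop_internal("no unique edge between nodes ", a,
                                     " and ", b)
  phy$edge.length[i]
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest tip-to-tip path, so the
#' maximum root-to-tip distance is minimized and the two diameter tips sit
#' at equal distance from the root.  When several tip pairs realize the
#' diameter, the lexicographically smallest pair of tip labels is used, for
#' determinism.  When the midpoint coincides with an existing node the root
#' is placed at that node's position (the binary root then carries one
#' zero-length child edge, keeping the tree rooted in the ape sense).
#' Already-midpoint-rooted trees are returned unchanged.
#'
#' @param phy A `phylo` with branch lengths on every edge.
#' @return A rooted `phylo`; total branch length is conserved.
#' @examples
#' midpoint_root(read_newick(text = "(A:1,B:3);"))
#' @export
midpoint_root <- function(phy) {
  if (ape::Ntip(phy) < 2L) stop_input("midpoint rooting needs >= 2 tips")
  check_metric(phy, "midpoint rooting")
  dt <- stats::cophenetic(phy)
  dt <- dt[order(rownames(dt)), order(colnames(dt))]
  dmax <- max(dt)
  hit <- which(dt == dmax, arr.ind = TRUE)
  hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
  # rows/cols sorted by label, which(...) scans column-major: the first hit
  # is the lexicographically smallest (t1, t2) pair
  t1 <- rownames(dt)[hit[1L, 1L]]
  t2 <- colnames(dt)[hit[1L, 2L]]
  i1 <- match(t1, phy$tip.label)
  i2 <- match(t2, phy$tip.label)
  path <- ape::nodepath(phy, i1, i2)
  seg <- vapply(seq_len(length(path) - 1L), function(k) {
    edge_length_between(phy, path[k], path[k + 1L])
  }, numeric(1))
  cum <- c(0, cumsum(seg))
  half <- dmax / 2
  tol <- 1e-9 * max(1, dmax)
  # already rooted here?
  rt <- root_node(phy)
  at <- which(abs(cum - half) <= tol)
  if (ape::is.rooted(phy) && length(at) && path[at[1L]] == rt) {
    return(phy)
  }
  k <- max(which(cum <= half + tol & seq_along(cum) < length(cum)))
  u <- path[k]; v <- path[k + 1L]
  x_from_u <- min(max(half - cum[k], 0), seg[k])
  # orient along the tree's parent -> child direction for rerooting
  if (any(phy$edge[, 1L] == u & phy$edge[, 2L] == v)) {
    child <- v; pos <- x_from_u
  } else {
    child <- u; pos <- seg[k] - x_from_u
  }
  out <- phytools::reroot(phy, node.number = child, position = pos)
  out$node.label <- NULL  # reroot may fabricate empty labels
  out
}

#' Prune tips from a tree
#'
#' Removes the listed tips and suppresses the resulting degree-2 nodes,
#' summing their incident branch lengths, so pairwise path distances among
#' the retained tips are unchanged.
#'
#' @param phy A `phylo`.
#' @param drop Character vector of tip labels to remove (may be empty).
#' @return The pruned `phylo`.
#' @export
prune_tips <- function(phy, drop) {
  drop <- unique(as.character(drop))
  if (length(drop) == 0L) return(phy)
  missing <- setdiff(drop, phy$tip.label)
  if (length(missing)) {
    stop_input("cannot drop tip(s) absent from the tree: ",
               paste(missing, collapse = ", "))
  }
  if (ape::Ntip(phy) - length(drop) < 2L) {
    stop_input("pruning would leave fewer than 2 tips")
  }
  ape::drop.tip(phy, drop, collapse.singles = TRUE)
}

#' Most-ancestral nodes per taxonomic label
#'
#' For each (rank, label) carried by node annotations, keeps only the nodes
#' with no ancestor carrying the same label at the same rank — the
#' most-ancestral representatives of each labeled clade.  A label that is
#' polyphyletic on the tree keeps one row per disjoint occurrence, so the
#' retained nodes always form an antichain in the ancestor order.
#'
#' @param phy The rooted `phylo` the annotations were computed on.
#' @param ann A `cta_nodes` annotation from [label_nodes()].
#' @param ranks Ranks to report (default: all annotated ranks).
#' @return `data.frame` with columns `rank`, `label`, `node`.
#' @export
collapse_nested_labels <- function(phy, ann, ranks = NULL) {
  stopifnot(inherits(ann, "cta_nodes"))
  lin <- ann$lineage
  if (is.null(ranks)) ranks <- colnames(lin)
  par <- parent_vec(phy)
  keep_rows <- list()
  for (r in ranks) {
    labs <- lin[, r]
    for (L in unique(labs[!is.na(labs)])) {
      nodes <- as.integer(rownames(lin)[which(!is.na(labs) & labs == L)])
      in_set <- logical(length(par))
      in_set[nodes] <- TRUE
      top <- vapply(nodes, function(n) {
        a <- par[n]
        while (a != 0L) {
          if (in_set[a]) return(FALSE)
          a <- par[a]
        }
        TRUE
      }, logical(1))
      if (any(top)) {
        keep_rows[[length(keep_rows) + 1L]] <-
          data.frame(rank = r, label = L, node = sort(nodes[top]),
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(keep_rows)) {
    return(data.frame(rank = character(), label = character(),
                      node = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, keep_rows)
  rownames(out) <- NULL
  out
}
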