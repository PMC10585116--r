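# Independent oracles and fixture generators shared across the suite.

RANKS <- default_ranks()

# random prefix-shaped lineages drawn from a small label pool so that
# consensus computations are non-trivial
rand_lineages <- function(n, ranks = RANKS, n_labels = 3L, p_stop = 0.2,
                          prefix = "L") {
  m <- matrix(NA_character_, n, length(ranks),
              dimnames = list(NULL, ranks))
  for (i in seq_len(n)) {
    depth <- 0L
    while (depth < length(ranks) && stats::runif(1) >= p_stop) {
      depth <- depth + 1L
    }
    for (j in seq_len(depth)) {
      m[i, j] <- paste0(prefix, substr(ranks[j], 1L, 1L),
                        sample.int(n_labels, 1L))
    }
  }
  m
}

# brute-force node labeling: gather reference descendants of each node with
# phangorn (independent of the package's postorder accumulation) and call
# the consensus directly
oracle_label_nodes <- function(phy, ref, f) {
  ntip <- ape::Ntip(phy)
  nnode <- ntip + phy$Nnode
  ranks <- colnames(ref)
  lin <- matrix(NA_character_, nnode, length(ranks),
                dimnames = list(seq_len(nnode), ranks))
  dl <- phangorn::Descendants(phy, seq_len(nnode), type = "tips")
  for (n in seq_len(nnode)) {
    keep <- intersect(phy$tip.label[dl[[n]]], rownames(ref))
    if (length(keep) == 0L) next
    lin[n, ] <- consensus_lineage(ref[keep, , drop = FALSE], f = f)$lineage
  }
  lin
}

# exact minimax root-to-tip depth over every point of every edge.  For a
# candidate root at distance x from the child end of an edge, the depth is
# max(x + A, (len - x) + B) with A/B the largest tip distance reached
# through the child/parent end; that envelope is V-shaped, so a grid plus
# its single crossing point gives the exact minimum.
oracle_minimax_depth <- function(phy, ngrid = 11L) {
  d <- ape::dist.nodes(phy)
  nt <- ape::Ntip(phy)
  best <- Inf
  for (e in seq_len(nrow(phy$edge))) {
    p <- phy$edge[e, 1L]; ch <- phy$edge[e, 2L]
    len <- phy$edge.length[e]
    a <- d[ch, seq_len(nt)]   # via the child end
    b <- d[p, seq_len(nt)]    # via the parent end
    childside <- (a - b) < (len - 1e-12)
    A <- if (any(childside)) max(a[childside]) else -Inf
    B <- if (any(!childside)) max(b[!childside]) else -Inf
    xs <- c(seq(0, len, length.out = ngrid), (len + B - A) / 2)
    xs <- unique(pmin(pmax(xs, 0), len))
    xs <- xs[is.finite(xs)]
    for (x in xs) {
      best <- min(best, max(x + A, (len - x) + B))
    }
  }
  best
}

# ancestor/descendant directional prefix check: every assigned rank of the
# ancestor must carry the same label in the descendant
is_rank_prefix <- function(anc, desc) {
  ia <- which(!is.na(anc))
  all(!is.na(desc[ia]) & desc[ia] == anc[ia])
}

count_ancestor_violations <- function(phy, ann, internal_only = FALSE) {
  par <- integer(nrow(ann$lineage))
  par[phy$edge[, 2L]] <- phy$edge[, 1L]
  labeled <- which(rowSums(!is.na(ann$lineage)) > 0L)
  if (internal_only) labeled <- labeled[labeled > ape::Ntip(phy)]
  v <- 0L
  for (n in labeled) {
    a <- par[n]
    while (a != 0L) {
      if (any(!is.na(ann$lineage[a, ])) &&
          !is_rank_prefix(ann$lineage[a, ], ann$lineage[n, ])) {
        v <- v + 1L
      }
      a <- par[a]
    }
  }
  v
}

# small planted simulation with selectable noise, midpoint-rooted
planted_run <- function(seed, label_dropout = 0, f = 1.0, ...) {
  sc <- planted_scenario(seed = seed, label_dropout = label_dropout, ...)
  sim <- simulate_tree(sc)
  rooted <- midpoint_root(sim$tree)
  ann <- label_nodes(rooted, sim$ref_taxonomy, f = f)
  list(scenario = sc, sim = sim, tree = rooted, ann = ann)
}

lineage_of <- function(truth, tip, ranks = RANKS) {
  unname(unlist(truth[match(tip, truth$tip), ranks]))
}

# worked micro-example: three query ASVs nested in labeled genus clades,
# mirroring the family-assigned/genus-missing, nothing-assigned and
# fully-assigned NBC patterns
micro_fixture <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- paste0(
    "(((RAlb1:0.02,(RAlb2:0.01,ASV291:0.015):0.01):0.05,",
    "(RPont1:0.02,(RPont2:0.02,ASV1376:0.01):0.02):0.05):0.1,",
    "(RKeto1:0.03,(RKeto2:0.02,ASV167:0.02):0.01):0.1);")
  writeLines(tree, file.path(dir, "tree.nwk"))
  ref <- c(
    "id\tlineage",
    "RAlb1\tBacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales;Rhodobacteraceae;Albimonas",
    "RAlb2\tBacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales;Rhodobacteraceae;Albimonas",
    "RPont1\tBacteria;Proteobacteria;Alphaproteobacteria;Caulobacterales;Hyphomonadaceae;Ponticaulis",
    "RPont2\tBacteria;Proteobacteria;Alphaproteobacteria;Caulobacterales;Hyphomonadaceae;Ponticaulis",
    "RKeto1\tBacteria;Proteobacteria;Gammaproteobacteria;Pseudomonadales;Alcanivoracaceae;Ketobacter",
    "RKeto2\tBacteria;Proteobacteria;Gammaproteobacteria;Pseudomonadales;Alcanivoracaceae;Ketobacter")
  writeLines(ref, file.path(dir, "ref.tsv"))
  nbc <- c(
    "asv\tlineage",
    "ASV291\tBacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales;Rhodobacteraceae;NA",
    "ASV1376\tBacteria;Proteobacteria;Alphaproteobacteria;Caulobacterales;Hyphomonadaceae;NA",
    "ASV167\tBacteria;Proteobacteria;Gammaproteobacteria;Pseudomonadales;Alcanivoracaceae;Ketobacter")
  writeLines(nbc, file.path(dir, "nbc.tsv"))
  list(tree = file.path(dir, "tree.nwk"),
       ref = file.path(dir, "ref.tsv"),
       nbc = file.path(dir, "nbc.tsv"))
}
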