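# Planted-clade simulator.  Emulates the structure the annotation method
# relies on in real 16S data: a taxonomy-shaped tree whose genus clades
# contain curated reference tips plus unknown query ASVs grafted inside,
# with optional reference label dropout, an NBC table whose deep ranks fail
# more often than shallow ones, and divergent outgroup queries attached
# above every labeled clade.  All randomness derives from one seed.

#' Define a planted-clade simulation scenario
#'
#' @param seed Integer seed; fully determines the simulated outputs.
#' @param ranks Rank names, most general first.
#' @param branching Children per taxon at each rank: one entry per rank,
#'   each either a single count or a `c(lo, hi)` range sampled per taxon.
#'   The default, two children at every rank, yields 64 genus clades.
#' @param refs_per_genus Range (or single count) of reference tips per
#'   genus clade.
#' @param queries_per_genus Range (or single count) of query ASV tips
#'   grafted inside each genus clade.
#' @param label_dropout Fraction of reference lineages truncated at a
#'   random rank, emulating incompletely curated references.
#' @param nbc_failure Per-rank probability that the simulated classifier
#'   fails at that rank (all deeper ranks then fail too).  The default
#'   increases with depth, mimicking a naive Bayesian classifier at 16S V4
#'   resolution where genus calls fail far more often than phylum calls.
#' @param outgroup_queries Number of divergent query tips attached at the
#'   base of the tree, outside every labeled clade.
#' @param mean_branch_length Mean of the exponential branch-length draw
#'   (substitutions/site analog).
#' @param outgroup_branch_length Pendant length of outgroup tips; long, so
#'   outgroups carry the tree diameter and midpoint rooting lands at their
#'   attachment point.
#' @return List of class `cta_scenario`.
#' @export
planted_scenario <- function(seed = 1L,
                             ranks = default_ranks(),
                             branching = rep(2L, length(ranks)),
                             refs_per_genus = c(2L, 3L),
                             queries_per_genus = c(1L, 2L),
                             label_dropout = 0,
                             nbc_failure = c(0, 0.02, 0.05, 0.1, 0.2, 0.4),
                             outgroup_queries = 2L,
                             mean_branch_length = 0.05,
                             outgroup_branch_length = 1.5) {
  if (!is.list(branching)) branching <- as.list(branching)
  if (length(branching) != length(ranks)) {
    stop_input("branching needs one entry per rank")
  }
  if (length(nbc_failure) == 1L) {
    nbc_failure <- rep(nbc_failure, length(ranks))
  }
  if (length(nbc_failure) != length(ranks)) {
    stop_input("nbc_failure needs one probability per rank (or one scalar)")
  }
  if (label_dropout < 0 || label_dropout >= 1) {
    stop_input("label_dropout must lie in [0, 1)")
  }
  if (any(unlist(branching) < 1L)) stop_input("branching counts must be >= 1")
  if (min(refs_per_genus) < 1L) stop_input("refs_per_genus must be >= 1")
  if (min(queries_per_genus) < 0L) stop_input("queries_per_genus must be >= 0")
  structure(list(seed = as.integer(seed), ranks = ranks,
                 branching = branching,
                 refs_per_genus = refs_per_genus,
                 queries_per_genus = queries_per_genus,
                 label_dropout = label_dropout,
                 nbc_failure = nbc_failure,
                 outgroup_queries = as.integer(outgroup_queries),
                 mean_branch_length = mean_branch_length,
                 outgroup_branch_length = outgroup_branch_length),
            class = "cta_scenario")
}

draw_range <- function(rng) {
  if (length(rng) == 1L) return(as.integer(rng))
  sample(seq.int(min(rng), max(rng)), 1L)
}

#' Simulate a reference taxonomy
#'
#' Builds a rank-complete taxonomy with the scenario's branching factors:
#' labels are unique within each rank (K1, P1, P2, C1, ...), and each genus
#' carries a full kingdom-to-genus lineage.
#'
#' @param scenario A [planted_scenario()].
#' @return Character matrix, one row per genus, columns = ranks.
#' @export
simulate_taxonomy <- function(scenario) {
  stopifnot(inherits(scenario, "cta_scenario"))
  set.seed(scenario$seed)
  ranks <- scenario$ranks
  prefix <- toupper(substr(ranks, 1L, 1L))
  if (anyDuplicated(prefix)) prefix <- paste0(toupper(substr(ranks, 1L, 1L)),
                                              seq_along(ranks))
  counters <- integer(length(ranks))
  rows <- list()
  grow <- function(depth, lineage) {
    n <- draw_range(scenario$branching[[depth]])
    for (i in seq_len(n)) {
      counters[depth] <<- counters[depth] + 1L
      lab <- paste0(prefix[depth], counters[depth])
      lin <- c(lineage, lab)
      if (depth == length(ranks)) {
        rows[[length(rows) + 1L]] <<- lin
      } else {
        grow(depth + 1L, lin)
      }
    }
  }
  grow(1L, character())
  out <- do.call(rbind, rows)
  dimnames(out) <- list(NULL, ranks)
  out
}

# random binary (coalescent-style) newick over pre-rendered leaf strings
rand_clade <- function(leaves, mean_bl) {
  while (length(leaves) > 1L) {
    i <- sample(seq_along(leaves), 2L)
    joined <- sprintf("(%s:%s,%s:%s)", leaves[[i[1L]]],
                      format(stats::rexp(1L, 1 / mean_bl), digits = 8),
                      leaves[[i[2L]]],
                      format(stats::rexp(1L, 1 / mean_bl), digits = 8))
    leaves <- c(leaves[-i], joined)
  }
  leaves[[1L]]
}

#' Simulate a tree with planted clade taxonomy and ground truth
#'
#' Builds a phylogeny whose clade structure mirrors the simulated taxonomy:
#' each genus is a clade of reference tips with query ASVs grafted inside,
#' genera nest inside families and so on up to kingdoms, and outgroup
#' queries attach at the base, outside every labeled clade.  Emits the tree
#' unrooted (basal multifurcation) so a full run must midpoint-root it.
#' Alongside the tree it returns the ground truth (role, true lineage and
#' planted depth per tip), the reference taxonomy table after label
#' dropout, and a simulated NBC table for the queries with per-rank
#' geometric failure.
#'
#' @param scenario A [planted_scenario()].
#' @param taxonomy Optional taxonomy matrix from [simulate_taxonomy()]
#'   (recomputed from the scenario when omitted).
#' @return List with elements `tree` (`phylo`), `truth` (`data.frame`:
#'   `tip`, `role`, one column per rank, `depth`), `ref_taxonomy` and `nbc`
#'   (lineage matrices), and `scenario`.
#' @export
simulate_tree <- function(scenario, taxonomy = NULL) {
  stopifnot(inherits(scenario, "cta_scenario"))
  if (is.null(taxonomy)) taxonomy <- simulate_taxonomy(scenario)
  set.seed(scenario$seed + 1000003L)
  ranks <- scenario$ranks
  nr <- length(ranks)
  mbl <- scenario$mean_branch_length
  bl <- function() format(stats::rexp(1L, 1 / mbl), digits = 8)

  n_gen <- nrow(taxonomy)
  ref_names <- list(); qry_names <- list()
  qctr <- 0L
  genus_clades <- character(n_gen)
  for (g in seq_len(n_gen)) {
    nref <- draw_range(scenario$refs_per_genus)
    nqry <- draw_range(scenario$queries_per_genus)
    refs <- sprintf("REF%d_%d", g, seq_len(nref))
    qrys <- if (nqry > 0L) sprintf("ASV%d", qctr + seq_len(nqry)) else
      character()
    qctr <- qctr + nqry
    ref_names[[g]] <- refs
    qry_names[[g]] <- qrys
    genus_clades[g] <- rand_clade(as.list(c(refs, qrys)), mbl)
  }

  # nest genus clades following the taxonomy hierarchy; unary taxonomy
  # levels collapse (no singleton nodes in the emitted Newick)
  nest <- function(depth, rows) {
    if (depth == nr) {
      stopifnot(length(rows) == 1L)
      return(genus_clades[rows])
    }
    groups <- split(rows, factor(taxonomy[rows, depth + 1L],
                                 levels = unique(taxonomy[rows, depth + 1L])))
    if (length(groups) == 1L) return(nest(depth + 1L, groups[[1L]]))
    kids <- vapply(groups, function(rr) {
      sprintf("%s:%s", nest(depth + 1L, rr), bl())
    }, character(1))
    sprintf("(%s)", paste(kids, collapse = ","))
  }
  kingdoms <- split(seq_len(n_gen),
                    factor(taxonomy[, 1L], levels = unique(taxonomy[, 1L])))
  top <- vapply(kingdoms, function(rr) {
    sprintf("%s:%s", nest(1L, rr), bl())
  }, character(1))
  outg <- character(0)
  if (scenario$outgroup_queries > 0L) {
    outg <- sprintf("OUT%d:%s", seq_len(scenario$outgroup_queries),
                    format(scenario$outgroup_branch_length, digits = 8))
  }
  parts <- c(top, outg)
  newick <- if (length(parts) == 1L) {
    paste0(sub(":[^:]*$", "", parts), ";")
  } else {
    paste0("(", paste(parts, collapse = ","), ");")
  }
  tree <- read_newick(text = newick)

  # ground truth
  tips <- character(0); genus_of <- integer(0); role <- character(0)
  for (g in seq_len(n_gen)) {
    tt <- c(ref_names[[g]], qry_names[[g]])
    tips <- c(tips, tt)
    genus_of <- c(genus_of, rep(g, length(tt)))
    role <- c(role, rep(c("reference", "query"),
                        c(length(ref_names[[g]]), length(qry_names[[g]]))))
  }
  lin <- taxonomy[genus_of, , drop = FALSE]
  depth <- rep(nr, length(tips))
  if (scenario$outgroup_queries > 0L) {
    on <- sprintf("OUT%d", seq_len(scenario$outgroup_queries))
    tips <- c(tips, on)
    role <- c(role, rep("query", length(on)))
    lin <- rbind(lin, matrix(NA_character_, nrow = length(on), ncol = nr))
    depth <- c(depth, rep(0L, length(on)))
  }
  truth <- data.frame(tip = tips, role = role, lin, depth = depth,
                      check.names = FALSE, stringsAsFactors = FALSE)
  rownames(truth) <- NULL

  # reference table with label dropout
  is_ref <- truth$role == "reference"
  ref_tax <- as.matrix(truth[is_ref, ranks, drop = FALSE])
  rownames(ref_tax) <- truth$tip[is_ref]
  if (scenario$label_dropout > 0 && nrow(ref_tax) > 0L) {
    hit <- stats::runif(nrow(ref_tax)) < scenario$label_dropout
    for (i in which(hit)) {
      keep <- sample.int(nr - 1L, 1L)
      ref_tax[i, (keep + 1L):nr] <- NA_character_
    }
  }

  # NBC table for queries: truncate the true lineage at the first failing
  # rank (outgroups are novel lineages: all unassigned)
  is_qry <- truth$role == "query"
  nbc <- as.matrix(truth[is_qry, ranks, drop = FALSE])
  rownames(nbc) <- truth$tip[is_qry]
  for (i in seq_len(nrow(nbc))) {
    if (all(is.na(nbc[i, ]))) next
    fail <- stats::runif(nr) < scenario$nbc_failure
    if (any(fail)) nbc[i, which(fail)[1L]:nr] <- NA_character_
  }
  list(tree = tree, truth = truth, ref_taxonomy = ref_tax, nbc = nbc,
       scenario = scenario)
}

#' Corrupt a tree for negative tests
#'
#' `"shuffle-k-tips"` permutes the labels of `k` sampled tips (a cyclic
#' shift of the sampled labels, so every sampled tip moves), breaking the
#' concordance between tree position and taxonomy.  `"perturb-lengths"`
#' rescales every branch length by a random positive factor, which must not
#' change node labeling at all (labeling is topology-only).
#'
#' @param phy A `phylo`.
#' @param mode `"shuffle-k-tips"` or `"perturb-lengths"`.
#' @param seed Integer seed.
#' @param k Number of tips to shuffle.
#' @param tips Candidate tip labels to sample from (default: all tips).
#' @return The corrupted `phylo`.
#' @export
corrupt_tree <- function(phy, mode = c("shuffle-k-tips", "perturb-lengths"),
                         seed = 1L, k = 0L, tips = NULL) {
  mode <- match.arg(mode)
  set.seed(as.integer(seed))
  if (mode == "perturb-lengths") {
    check_metric(phy, "perturb-lengths")
    phy$edge.length <- phy$edge.length *
      exp(stats::rnorm(length(phy$edge.length), sd = 0.25))
    return(phy)
  }
  if (k == 0L) return(phy)
  if (is.null(tips)) tips <- phy$tip.label
  bad <- setdiff(tips, phy$tip.label)
  if (length(bad)) stop_input("unknown tip(s): ", paste(bad, collapse = ", "))
  if (k > length(tips)) stop_input("k exceeds the candidate tip count")
  pick <- sample(tips, k)
  idx <- match(pick, phy$tip.label)
  phy$tip.label[idx] <- pick[c(seq_len(k)[-1L], 1L)]
  phy
}

#' Write simulator outputs to a directory
#'
#' Emits `tree.nwk`, `ref_taxonomy.tsv`, `nbc.tsv`, `truth.tsv` and
#' `scenario.json` (seed and all parameters).
#'
#' @param sim Output of [simulate_tree()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             ref = file.path(dir, "ref_taxonomy.tsv"),
             nbc = file.path(dir, "nbc.tsv"),
             truth = file.path(dir, "truth.tsv"),
             scenario = file.path(dir, "scenario.json"))
  write_newick(sim$tree, paths["tree"])
  write_taxonomy(sim$ref_taxonomy, paths["ref"])
  write_taxonomy(sim$nbc, paths["nbc"], id_name = "asv")
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  sc <- sim$scenario
  class(sc) <- NULL
  jsonlite::write_json(sc, paths["scenario"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
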