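mklin <- function(...) {
  rows <- list(...)
  m <- do.call(rbind, lapply(rows, function(r) {
    c(r, rep(NA_character_, 6 - length(r)))
  }))
  colnames(m) <- RANKS
  m
}

test_that("label_nodes annotates from reference descendants only", {
  # cherry of two identical references: parent unanimous at full depth
  t <- midpoint_root(read_newick(text = "((R1:1,R2:1):1,(Q1:1,Q2:1):1);"))
  ref <- mklin(c("A", "B", "C"), c("A", "B", "C"))
  rownames(ref) <- c("R1", "R2")
  ann <- label_nodes(t, ref, f = 1)
  cherry <- ape::getMRCA(t, c("R1", "R2"))
  expect_equal(unname(ann$lineage[cherry, 1:3]), c("A", "B", "C"))
  expect_equal(unname(ann$support[cherry, 1:3]), c(1, 1, 1))
  expect_equal(ann$n_ref[cherry], 2L)

  # reference tips carry their own lineage; query tips and query-only
  # nodes carry nothing
  r1 <- match("R1", t$tip.label)
  expect_equal(unname(ann$lineage[r1, 1:3]), c("A", "B", "C"))
  qnode <- ape::getMRCA(t, c("Q1", "Q2"))
  expect_true(all(is.na(ann$lineage[qnode, ])))
  expect_true(all(is.na(ann$lineage[match("Q1", t$tip.label), ])))

  # phylum-level split among descendants stops the label at kingdom
  ref2 <- mklin(c("A", "B", "C"), c("A", "E", "F"))
  rownames(ref2) <- c("R1", "R2")
  ann2 <- label_nodes(t, ref2, f = 1)
  expect_equal(unname(ann2$lineage[cherry, ]), c("A", NA, NA, NA, NA, NA))

  expect_error(label_nodes(ape::unroot(t), ref, f = 1), "midpoint_root",
               class = "cladetax_input_error")
  badref <- ref; rownames(badref) <- c("R1", "NOT_A_TIP")
  expect_error(label_nodes(t, badref, f = 1), "NOT_A_TIP",
               class = "cladetax_input_error")
})

test_that("label_nodes equals the brute-force oracle and is idempotent", {
  for (seed in c(101, 102)) {
    run <- planted_run(seed = seed, label_dropout = 0.2,
                       f = 0.75, branching = c(2, 2, 2, 1, 2, 2))
    oracle <- oracle_label_nodes(run$tree, run$sim$ref_taxonomy, f = 0.75)
    expect_identical(unname(run$ann$lineage), unname(oracle))
    again <- label_nodes(run$tree, run$sim$ref_taxonomy, f = 0.75)
    expect_identical(again, run$ann)
  }
})

test_that("annotate_queries walks rootward to the first labeled node", {
  t <- midpoint_root(read_newick(
    text = "(((R1:1,Q1:1):1,R2:1):2,(Q2:1,Q3:1):2);"))
  ref <- mklin(c("A", "B", "C", "D", "E", "G1"),
               c("A", "B", "C", "D", "E", "G1"))
  rownames(ref) <- c("R1", "R2")
  ann <- label_nodes(t, ref, f = 1)
  qa <- annotate_queries(t, ann, c("Q1", "Q2", "Q3"))
  # Q1 sits inside the genus clade: full genus lineage from its parent
  expect_equal(unname(unlist(qa[qa$asv == "Q1", RANKS])),
               c("A", "B", "C", "D", "E", "G1"))
  expect_equal(qa$node[qa$asv == "Q1"], ape::getMRCA(t, c("R1", "Q1")))
  # Q2/Q3 pair has no reference below its parent; first labeled node is
  # deeper rootward
  expect_equal(unname(unlist(qa[qa$asv == "Q2", RANKS])),
               unname(unlist(qa[qa$asv == "Q3", RANKS])))

  expect_error(annotate_queries(t, ann, c("Q1", "ZZ")), "ZZ",
               class = "cladetax_input_error")
  expect_error(annotate_queries(t, ann, "Q1", to_rank = "species"),
               class = "cladetax_input_error")

  # zero references anywhere: every query comes back all-unassigned
  t2 <- midpoint_root(read_newick(text = "((Q1:1,Q2:1):1,Q3:2);"))
  ann2 <- label_nodes(t2, ref[0, , drop = FALSE], f = 1)
  qa2 <- annotate_queries(t2, ann2, c("Q1", "Q2", "Q3"))
  expect_true(all(is.na(qa2[, RANKS])))
  expect_true(all(is.na(qa2$node)))
})

test_that("to_rank continues the walk until the target rank is assigned", {
  t <- midpoint_root(read_newick(
    text = "(((R1:1,Q1:1):1,(R2:1,R3:1):1):1,R4:3);"))
  # R1 genus-split against nothing at its node; parent of Q1 has only R1
  ref <- mklin(c("A", "B", "C", "D", "E", NA),
               c("A", "B", "C", "D", "E", "G1"),
               c("A", "B", "C", "D", "E", "G1"),
               c("A", "F"))
  rownames(ref) <- c("R1", "R2", "R3", "R4")
  ann <- label_nodes(t, ref, f = 1)
  default <- annotate_queries(t, ann, "Q1")
  expect_true(is.na(default$genus))         # stops at R1's parent
  deep <- annotate_queries(t, ann, "Q1", to_rank = "genus")
  expect_equal(deep$genus, "G1")            # walks on to the R1-R3 node
  expect_false(deep$node == default$node)
})

test_that("merge_with_nbc fills only classifier gaps and never overwrites", {
  nbc <- mklin(c("Bacteria", "Proteobacteria", "Alphaproteobacteria",
                 "Rhodobacterales", "Rhodobacteraceae"),
               c("Bacteria", "Proteobacteria", "Gammaproteobacteria",
                 "Pseudomonadales", "Alcanivoracaceae", "Ketobacter"))
  rownames(nbc) <- c("ASV291", "ASV167")
  cta <- mklin(c("Bacteria", "Proteobacteria", "Alphaproteobacteria",
                 "Rhodobacterales", "Rhodobacteraceae", "Albimonas"))
  rownames(cta) <- "ASV291"
  m <- merge_with_nbc(nbc, cta)
  r291 <- m[m$asv == "ASV291", ]
  expect_equal(r291$genus, "Albimonas")
  expect_equal(r291$source_genus, "CTA")
  expect_equal(r291$source_family, "NBC")
  expect_equal(r291$tax_source, "CTA")
  r167 <- m[m$asv == "ASV167", ]
  expect_equal(r167$tax_source, "NBC")
  expect_equal(r167$genus, "Ketobacter")
  expect_true(all(m$conflicts == ""))

  # conflict at an NBC-assigned rank: NBC kept, flagged, nothing filled
  cta2 <- mklin(c("Bacteria", "Proteobacteria", "Alphaproteobacteria",
                  "Rhodobacterales", "OtherFamily", "Albimonas"))
  rownames(cta2) <- "ASV291"
  m2 <- merge_with_nbc(nbc, cta2)
  r <- m2[m2$asv == "ASV291", ]
  expect_equal(r$family, "Rhodobacteraceae")
  expect_true(is.na(r$genus))
  expect_equal(r$conflicts, "family")
  expect_equal(r$tax_source, "NBC")

  # prefer-cta overwrites from the first conflicting rank down
  m3 <- merge_with_nbc(nbc, cta2, conflict_policy = "prefer-cta")
  r <- m3[m3$asv == "ASV291", ]
  expect_equal(r$family, "OtherFamily")
  expect_equal(r$genus, "Albimonas")
  expect_equal(r$conflicts, "family")
  expect_equal(r$tax_source, "CTA")

  orphan <- cta; rownames(orphan) <- "ASV999"
  expect_error(merge_with_nbc(nbc, orphan), "ASV999",
               class = "cladetax_input_error")
  badranks <- cta; colnames(badranks) <- rev(RANKS)
  expect_error(merge_with_nbc(nbc, badranks),
               class = "cladetax_input_error")
})

test_that("merged lineages stay prefix-contiguous", {
  # CTA shallower than the NBC gap: the fill cannot skip ranks
  nbc <- mklin(c("A", "B"))
  rownames(nbc) <- "q"
  cta <- mklin(c("A", "B", NA))  # nothing assignable below class
  rownames(cta) <- "q"
  m <- merge_with_nbc(nbc, cta)
  expect_true(all(is.na(m[1, c("class", "order", "family", "genus")])))

  set.seed(99)
  for (i in 1:20) {
    nbc <- rand_lineages(10); rownames(nbc) <- paste0("q", 1:10)
    cta <- rand_lineages(10, n_labels = 2); rownames(cta) <- paste0("q", 1:10)
    m <- merge_with_nbc(nbc, cta)
    lin <- as.matrix(m[, RANKS])
    for (j in seq_len(nrow(lin))) {
      gap <- which(is.na(lin[j, ]))
      if (length(gap)) expect_true(all(is.na(lin[j, gap[1]:6])))
    }
  }
})

test_that("holding out a reference and re-annotating returns its lineage", {
  run <- planted_run(seed = 55)
  ref <- run$sim$ref_taxonomy
  set.seed(1)
  for (tip in sample(rownames(ref), 10)) {
    ann <- label_nodes(run$tree, ref[setdiff(rownames(ref), tip), ,
                                     drop = FALSE], f = 1)
    got <- annotate_queries(run$tree, ann, tip)
    truth <- ref[tip, ]
    ig <- which(!is.na(unlist(got[1, RANKS])))
    # annotation is a prefix of the true lineage
    expect_true(all(unlist(got[1, RANKS])[ig] == truth[ig]))
  }
})

test_that("summarize_annotation counts match a direct recount", {
  empty <- merge_with_nbc(mklin(c("A"))[0, , drop = FALSE],
                          mklin(c("A"))[0, , drop = FALSE])
  s0 <- summarize_annotation(empty)
  expect_equal(s0$n_asv, 0)
  expect_equal(s0$n_reclassified, 0)
  expect_equal(s0$frac_reclassified, 0)

  nbc <- mklin(c("A", "B"), c("A", "B", "C"), c("A"), c("A", "B", "C"))
  rownames(nbc) <- paste0("q", 1:4)
  cta <- mklin(c("A", "B", "X"))
  rownames(cta) <- "q1"
  s <- summarize_annotation(merge_with_nbc(nbc, cta))
  expect_equal(s$n_reclassified, 1)
  expect_equal(s$frac_reclassified, 0.25)

  # simulated run: report equals an independent recount of the table
  run <- planted_run(seed = 77)
  q <- run$sim$truth$tip[run$sim$truth$role == "query"]
  qa <- annotate_queries(run$tree, run$ann, q)
  cta <- as.matrix(qa[, RANKS]); rownames(cta) <- qa$asv
  m <- merge_with_nbc(run$sim$nbc, cta)
  s <- summarize_annotation(m)
  expect_equal(s$n_reclassified,
               sum(apply(m[, paste0("source_", RANKS)] == "CTA", 1, any)))
  expect_equal(s$per_rank$unassigned_after[6],
               sum(m$source_genus == "unassigned"))
  expect_equal(s$per_rank$unassigned_before[6],
               sum(is.na(run$sim$nbc[, "genus"])))
})
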