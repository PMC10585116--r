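# Lineage algebra: ranked lineages are character vectors (or row-wise
# matrices) with one entry per rank, NA marking an unassigned rank.  A valid
# lineage is prefix-contiguous: no rank is assigned below an unassigned one.

#' Default taxonomic ranks
#'
#' The six Linnean ranks used for 16S classification, kingdom through genus.
#'
#' @return Character vector of rank names, most general first.
#' @export
default_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus")
}

#' Default unassigned sentinels
#'
#' Field values in taxonomy tables that denote an unassigned rank.
#'
#' @return Character vector of sentinel strings (the empty string included).
#' @export
default_sentinels <- function() {
  c("", "NA", "Unassigned", "unclassified")
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("cladetax_input_error", "cladetax_error")))
}

stop_internal <- function(...) {
  stop(errorCondition(paste0(...), class = "cladetax_error"))
}

trimws2 <- function(x) trimws(x, which = "both")

#' Enforce prefix contiguity on lineages
#'
#' Sets every rank below the first unassigned rank to unassigned, so that
#' assigned ranks always form a contiguous prefix.
#'
#' @param lin Character vector (one lineage) or character matrix (one lineage
#'   per row, one column per rank); `NA` marks unassigned ranks.
#' @return Object of the same shape with any post-gap labels removed.
#' @export
enforce_prefix <- function(lin) {
  if (is.matrix(lin)) {
    if (nrow(lin) == 0L) return(lin)
    out <- t(apply(lin, 1L, enforce_prefix))
    dimnames(out) <- dimnames(lin)
    out
  } else {
    gap <- which(is.na(lin))
    if (length(gap) && gap[1L] < length(lin)) {
      lin[gap[1L]:length(lin)] <- NA_character_
    }
    lin
  }
}

#' Parse delimited lineage strings
#'
#' Turns Silva/LTP-style strings such as
#' `"Bacteria;Proteobacteria;Alphaproteobacteria"` into ranked lineages.
#' Missing trailing ranks are padded as unassigned; sentinel values (see
#' [default_sentinels()]) are converted to `NA`.  A label appearing below an
#' unassigned rank violates prefix contiguity and is handled by `gap_policy`:
#' `"truncate"` drops everything from the first gap (with a warning),
#' `"error"` aborts.
#'
#' @param text Character vector of lineage strings.
#' @param ranks Character vector of rank names (default [default_ranks()]).
#' @param delim Field delimiter, default `";"`.
#' @param sentinels Values treated as unassigned.
#' @param gap_policy `"truncate"` or `"error"`.
#' @param ids Optional row identifiers used in error messages and as
#'   rownames of the result.
#' @return Character matrix, one row per input string, one column per rank.
#' @examples
#' parse_lineage("Bacteria;Proteobacteria;Alphaproteobacteria")
#' @export
parse_lineage <- function(text, ranks = default_ranks(), delim = ";",
                          sentinels = default_sentinels(),
                          gap_policy = c("truncate", "error"),
                          ids = NULL) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(length(ranks) >= 1L, !anyDuplicated(ranks))
  if (is.null(ids)) ids <- as.character(seq_along(text))
  parts <- strsplit(as.character(text), delim, fixed = TRUE)
  out <- matrix(NA_character_, nrow = length(text), ncol = length(ranks),
                dimnames = list(ids, ranks))
  n_gap <- 0L
  for (i in seq_along(parts)) {
    p <- trimws2(parts[[i]])
    if (length(p) > length(ranks)) {
      stop_input("lineage for '", ids[i], "' has ", length(p),
                 " fields but only ", length(ranks), " ranks are defined")
    }
    p[p %in% sentinels] <- NA_character_
    row <- rep(NA_character_, length(ranks))
    row[seq_along(p)] <- p
    gap <- which(is.na(row))
    if (length(gap) && any(!is.na(row[gap[1L]:length(row)]))) {
      if (gap_policy == "error") {
        stop_input("lineage for '", ids[i],
                   "' has a label below an unassigned rank")
      }
      n_gap <- n_gap + 1L
      row <- enforce_prefix(row)
    }
    out[i, ] <- row
  }
  if (n_gap > 0L) {
    warning(n_gap, " lineage(s) truncated at the first unassigned rank",
            call. = FALSE)
  }
  out
}

#' Format ranked lineages as delimited strings
#'
#' Inverse of [parse_lineage()]; unassigned ranks are written as the first
#' sentinel (`"NA"` by default) and trailing unassigned ranks are kept so the
#' string always has one field per rank.
#'
#' @param lin Lineage vector or matrix.
#' @param delim Field delimiter.
#' @param na How to render unassigned ranks.
#' @return Character vector of lineage strings.
#' @export
format_lineage <- function(lin, delim = ";", na = "NA") {
  if (!is.matrix(lin)) lin <- matrix(lin, nrow = 1L)
  lin[is.na(lin)] <- na
  apply(lin, 1L, paste, collapse = delim)
}

#' Build a synonym map
#'
#' A synonym map resolves homotypic synonyms — alternative names for the same
#' taxon at the same rank (for instance the phylum spelled both
#' "Planctomycetes" and "Planctomycetota") — to a single canonical label so
#' that congruence is tested on nomenclature-independent labels.
#'
#' @param rank,alias,canonical Equal-length character vectors; one entry per
#'   synonym triple.
#' @return A `data.frame` of class `synonym_map` with columns `rank`,
#'   `alias`, `canonical`.
#' @details The map must be idempotent: no alias may map to two different
#'   canonicals at the same rank, and a canonical must not itself be an alias
#'   at that rank.
#' @export
synonym_map <- function(rank = character(), alias = character(),
                        canonical = character()) {
  m <- data.frame(rank = trimws2(as.character(rank)),
                  alias = trimws2(as.character(alias)),
                  canonical = trimws2(as.character(canonical)),
                  stringsAsFactors = FALSE)
  key <- paste(m$rank, m$alias, sep = "\r")
  if (nrow(m) &&
      any(tapply(m$canonical, key, function(x) length(unique(x))) > 1L)) {
    stop_input("synonym map maps an alias to two different canonicals ",
               "at the same rank")
  }
  m <- m[!duplicated(key), , drop = FALSE]
  bad <- paste(m$rank, m$canonical, sep = "\r") %in% key
  if (any(bad)) {
    stop_input("synonym map is not idempotent: canonical label(s) ",
               paste(unique(m$canonical[bad]), collapse = ", "),
               " are themselves aliases at the same rank")
  }
  class(m) <- c("synonym_map", "data.frame")
  m
}

#' Read a synonym map from a TSV file
#'
#' Expects a tab-separated file with columns `rank`, `alias`, `canonical`
#' (header required).
#'
#' @param path Path to the file.
#' @return A [synonym_map()].
#' @export
read_synonyms <- function(path) {
  if (!file.exists(path)) stop_input("synonym file not found: ", path)
  d <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("rank", "alias", "canonical")
  if (!all(need %in% names(d))) {
    stop_input("synonym file ", path, " must have columns ",
               paste(need, collapse = ", "))
  }
  synonym_map(d$rank, d$alias, d$canonical)
}

#' Normalize lineages through a synonym map
#'
#' Replaces each assigned label by its canonical name when the label is a
#' registered alias at that rank; unassigned ranks and unknown labels pass
#' through unchanged.  The operation is idempotent.
#'
#' @param lin Lineage vector or matrix (columns named by rank).
#' @param syn A [synonym_map()]; `NULL` is treated as empty.
#' @return Lineage of the same shape with canonical labels.
#' @export
normalize_lineage <- function(lin, syn = NULL) {
  if (is.null(syn) || nrow(syn) == 0L) return(lin)
  vec <- !is.matrix(lin)
  if (vec) lin <- matrix(lin, nrow = 1L, dimnames = list(NULL, names(lin)))
  ranks <- colnames(lin)
  if (is.null(ranks)) stop_input("lineage matrix must have rank colnames")
  for (r in intersect(ranks, unique(syn$rank))) {
    s <- syn[syn$rank == r, , drop = FALSE]
    idx <- match(lin[, r], s$alias)
    hit <- !is.na(idx)
    lin[hit, r] <- s$canonical[idx[hit]]
  }
  if (vec) lin[1L, ] else lin
}

#' Consensus lineage of a set of lineages
#'
#' The congruence computation used to label tree nodes.  Proceeding from the
#' most general rank: among lineages assigned at that rank that also match
#' the consensus adopted at all shallower ranks, a label is adopted when its
#' fraction reaches the support threshold `f`; otherwise the consensus stops
#' and all deeper ranks stay unassigned.  Lineages unassigned at a rank do
#' not enter that rank's denominator (missing reference knowledge does not
#' veto a label), while lineages that conflict with an adopted label are
#' excluded from all deeper ranks.  `f = 1` is strict congruence of all
#' known labels; `0.5 < f < 1` is the majority-rule relaxation.
#'
#' @param lineages Character matrix, one lineage per row, columns named by
#'   rank; must be non-empty.
#' @param f Support threshold in `(0.5, 1]`.
#' @return A list with `lineage` (the consensus, `NA` below the stopping
#'   rank), `support` (fraction backing each adopted label, `NA` elsewhere)
#'   and `n` (number of input lineages with at least one assigned rank).
#' @examples
#' m <- rbind(c("Bacteria", "Proteobacteria", "Alphaproteobacteria"),
#'            c("Bacteria", "Proteobacteria", "Gammaproteobacteria"))
#' colnames(m) <- c("kingdom", "phylum", "class")
#' consensus_lineage(m, f = 1)$lineage
#' @export
consensus_lineage <- function(lineages, f = 1.0) {
  if (!is.matrix(lineages)) {
    stop_input("consensus_lineage expects a lineage matrix")
  }
  if (nrow(lineages) == 0L) {
    stop_input("consensus_lineage called on an empty lineage set")
  }
  if (!is.numeric(f) || length(f) != 1L || f <= 0.5 || f > 1) {
    stop_input("support threshold f must lie in (0.5, 1]")
  }
  ranks <- colnames(lineages)
  nr <- ncol(lineages)
  cons <- stats::setNames(rep(NA_character_, nr), ranks)
  supp <- stats::setNames(rep(NA_real_, nr), ranks)
  active <- rep(TRUE, nrow(lineages))
  for (r in seq_len(nr)) {
    lab <- lineages[active, r]
    lab <- lab[!is.na(lab)]
    if (length(lab) == 0L) break
    tab <- sort(table(lab), decreasing = TRUE)
    frac <- as.numeric(tab[1L]) / length(lab)
    if (frac < f - 1e-12) break
    best <- names(tab)[1L]
    cons[r] <- best
    supp[r] <- frac
    active <- active & (is.na(lineages[, r]) | lineages[, r] == best)
  }
  known <- rowSums(!is.na(lineages)) > 0L
  list(lineage = cons, support = supp, n = sum(known))
}

#' Rank-wise comparison of two lineages
#'
#' Classifies each rank of a pair of lineages as `agree` (both assigned,
#' equal), `conflict` (both assigned, different), `a-only` / `b-only`
#' (assigned on one side only) or `both-unassigned`.  This drives
#' "reclassified vs. no change" style reports.
#'
#' @param a,b Lineage vectors over the same rank set.
#' @return Named character vector, one relation per rank.
#' @export
lineage_compare <- function(a, b) {
  if (length(a) != length(b) ||
      (!is.null(names(a)) && !is.null(names(b)) &&
       !identical(names(a), names(b)))) {
    stop_input("lineage_compare: lineages use different rank sets")
  }
  rel <- ifelse(is.na(a) & is.na(b), "both-unassigned",
         ifelse(is.na(b), "a-only",
         ifelse(is.na(a), "b-only",
         ifelse(a == b, "agree", "conflict"))))
  stats::setNames(rel, names(a))
}

#' Read a taxonomy table
#'
#' Reads a TSV whose first column holds sequence/ASV identifiers, followed
#' either by a single semicolon-delimited lineage column or by one column per
#' rank (matched to `ranks` case-insensitively).
#'
#' @inheritParams parse_lineage
#' @param path Path to the file.
#' @return Character matrix of lineages, rownames = identifiers.
#' @export
read_taxonomy <- function(path, ranks = default_ranks(),
                          sentinels = default_sentinels(),
                          gap_policy = c("truncate", "error")) {
  gap_policy <- match.arg(gap_policy)
  if (!file.exists(path)) stop_input("taxonomy file not found: ", path)
  d <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (ncol(d) < 2L) {
    stop_input("taxonomy file ", path,
               " needs an id column plus lineage column(s)")
  }
  ids <- trimws2(d[[1L]])
  if (anyDuplicated(ids)) {
    stop_input("taxonomy file ", path, " has duplicated ids: ",
               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (ncol(d) == 2L) {
    return(parse_lineage(d[[2L]], ranks = ranks, sentinels = sentinels,
                         gap_policy = gap_policy, ids = ids))
  }
  hit <- match(tolower(ranks), tolower(names(d)))
  if (anyNA(hit)) {
    stop_input("taxonomy file ", path, " lacks column(s): ",
               paste(ranks[is.na(hit)], collapse = ", "))
  }
  m <- as.matrix(d[, hit, drop = FALSE])
  m <- matrix(trimws2(m), nrow = nrow(m), dimnames = list(ids, ranks))
  m[m %in% sentinels] <- NA_character_
  bad <- apply(m, 1L, function(x) {
    g <- which(is.na(x)); length(g) && any(!is.na(x[g[1L]:length(x)]))
  })
  if (any(bad)) {
    if (gap_policy == "error") {
      stop_input("taxonomy file ", path, " has label(s) below an unassigned ",
                 "rank for: ", paste(ids[bad], collapse = ", "))
    }
    warning(sum(bad), " lineage(s) truncated at the first unassigned rank",
            call. = FALSE)
    m <- enforce_prefix(m)
  }
  m
}

#' Write a lineage matrix as a per-rank TSV
#'
#' @param lin Lineage matrix (rownames = ids).
#' @param path Output path.
#' @param id_name Header for the identifier column.
#' @export
write_taxonomy <- function(lin, path, id_name = "id") {
  d <- data.frame(rownames(lin), lin, check.names = FALSE,
                  stringsAsFactors = FALSE)
  names(d)[1L] <- id_name
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
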