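#' One-sided Fisher's exact p-value for enrichment
#'
#' Upper-tail probability of the 2x2 table `(a, b; c, d)` under the
#' hypergeometric null: the chance of an overlap at least as large as `a`
#' given the margins. Equals `fisher.test(..., alternative = "greater")`.
#' Vectorized over table entries.
#'
#' @param a Overlap count (in pathway and in target set).
#' @param b In pathway, not in target set.
#' @param c_ In target set, not in pathway.
#' @param d In neither.
#' @return p-value(s) in (0, 1].
#' @export
fisher_p <- function(a, b, c_, d) {
  stats::phyper(a - 1, a + b, c_ + d, a + c_, lower.tail = FALSE)
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then member genes.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors (gene sets).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L]
  }, character(1), USE.NAMES = FALSE)
  sets
}

#' Read a microRNA-to-target-gene map
#'
#' Two-column CSV (`mir`, `gene`), one interaction per row.
#'
#' @param path Path to the CSV file.
#' @return Named list: one character vector of target genes per microRNA.
#' @export
read_mir_targets <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("target map needs two columns (mir, gene)",
                         call. = FALSE)
  split(d[[2L]], d[[1L]])
}

#' Fisher's-exact gene-set enrichment of microRNA targets
#'
#' Pools the target genes of the given microRNAs (union by default) and tests
#' each pathway for over-representation with a one-sided Fisher's exact test
#' on the 2x2 table (pathway-and-target, pathway-not-target, target-not-
#' pathway, remainder of the universe). All sets are intersected with the
#' background universe first. Results are ranked by ascending p-value, with
#' the contributing microRNAs (those with at least one gene in the overlap)
#' annotated per pathway.
#'
#' @param mirs Character vector of microRNA names.
#' @param targets Named list mapping microRNA name to target genes (see
#'   [read_mir_targets()]).
#' @param pathways Named list of pathway gene sets (see [read_gmt()]).
#' @param universe Character vector: the background gene universe.
#' @param mode `"union"` (default): test the pooled target set; `"per_mir"`:
#'   test each microRNA's target set separately.
#' @return Data frame with `pathway` (and `mir` in per-miR mode), `overlap`,
#'   `pathway_size`, `target_size`, `p_value`, `contributing_mirs`,
#'   `overlap_genes`, sorted by ascending p.
#' @export
fisher_enrichment <- function(mirs, targets, pathways, universe,
                              mode = c("union", "per_mir")) {
  mode <- match.arg(mode)
  if (!length(universe)) stop("empty gene universe", call. = FALSE)
  universe <- unique(universe)
  absent <- setdiff(mirs, names(targets))
  if (length(absent)) {
    stop("microRNA(s) absent from target map: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  tsets <- lapply(targets[mirs], function(g) intersect(unique(g), universe))
  psets <- lapply(pathways, function(g) intersect(unique(g), universe))

  test_one <- function(tset, pset, label_mirs) {
    ov <- intersect(tset, pset)
    a <- length(ov)
    b <- length(pset) - a
    c_ <- length(tset) - a
    d <- length(universe) - a - b - c_
    p <- fisher_p(a, b, c_, d)
    contrib <- label_mirs[vapply(label_mirs, function(m) {
      length(intersect(tsets[[m]], ov)) > 0
    }, logical(1))]
    list(overlap = a, pathway_size = length(pset), target_size = length(tset),
         p_value = p,
         contributing_mirs = paste(contrib, collapse = ";"),
         overlap_genes = paste(sort(ov), collapse = ";"))
  }

  rows <- list()
  if (mode == "union") {
    tset <- unique(unlist(tsets, use.names = FALSE))
    for (pw in names(psets)) {
      r <- test_one(tset, psets[[pw]], mirs)
      rows[[length(rows) + 1L]] <- data.frame(pathway = pw, r,
                                              stringsAsFactors = FALSE)
    }
  } else {
    for (m in mirs) {
      for (pw in names(psets)) {
        r <- test_one(tsets[[m]], psets[[pw]], m)
        rows[[length(rows) + 1L]] <- data.frame(pathway = pw, mir = m, r,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}
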