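#' Tissue expression reference panel
#'
#' A genes x tissues matrix of non-negative expression values (RPKM-like
#' units, one averaged value per gene per tissue), the reference for
#' tissue-specific enrichment analysis and for the tissue-set gene pool.
#'
#' @param expr Numeric matrix, genes in rows (rownames = symbols),
#'   tissues in columns (unique colnames).
#' @return Object of class `"tissue_panel"` with element `expr`.
#' @export
tissue_panel <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) stop("'expr' must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("'expr' needs gene rownames and tissue colnames")
  }
  if (anyDuplicated(colnames(expr))) stop("tissue names must be unique")
  if (anyDuplicated(rownames(expr))) stop("gene names must be unique")
  if (any(expr < 0) || anyNA(expr)) stop("expression values must be non-negative")
  rownames(expr) <- toupper(trimws(rownames(expr)))
  structure(list(expr = expr), class = "tissue_panel")
}

#' @export
print.tissue_panel <- function(x, ...) {
  cat(sprintf("Tissue expression panel: %d genes x %d tissues\n",
              nrow(x$expr), ncol(x$expr)))
  invisible(x)
}

#' Tissue-specificity scores
#'
#' For each gene and tissue, a leave-one-tissue-out z-like score:
#' (expression in the tissue minus the mean across the other tissues)
#' divided by (the SD across the other tissues plus a small epsilon). A
#' gene expressed in exactly one tissue scores maximally there and
#' negatively elsewhere; a gene with zero variance across tissues scores
#' 0 everywhere by convention.
#'
#' @param panel A [tissue_panel()].
#' @param eps Stabilizer added to the denominator (default 1e-8).
#' @return Numeric score matrix, same shape as the expression matrix.
#' @export
tissue_specificity_scores <- function(panel, eps = 1e-8) {
  stopifnot(inherits(panel, "tissue_panel"))
  x <- panel$expr
  k <- ncol(x)
  if (k < 2L) stop("need at least two tissues")
  tot <- rowSums(x)
  totsq <- rowSums(x^2)
  other_mean <- (tot - x) / (k - 1L)
  # SD over the k-1 other tissues (population form)
  other_var <- (totsq - x^2) / (k - 1L) - other_mean^2
  other_var[other_var < 0] <- 0
  score <- (x - other_mean) / (sqrt(other_var) + eps)
  score[tot == 0 | apply(x, 1L, stats::var) == 0, ] <- 0
  dimnames(score) <- dimnames(x)
  score
}

#' Per-tissue specific gene sets
#'
#' The top fraction of genes by specificity score in each tissue, ties
#' broken by gene-symbol order for determinism.
#'
#' @param scores Score matrix from [tissue_specificity_scores()].
#' @param top_fraction Fraction of genes per tissue in (0, 1); default
#'   0.05.
#' @return Named list of sorted gene-symbol vectors, one per tissue.
#' @export
define_tissue_specific_sets <- function(scores, top_fraction = 0.05) {
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction >= 1) {
    stop("'top_fraction' must lie in (0, 1)")
  }
  n_top <- floor(nrow(scores) * top_fraction)
  if (n_top < 1L) stop("'top_fraction' yields empty tissue sets")
  genes <- rownames(scores)
  sets <- lapply(colnames(scores), function(t) {
    ord <- order(-scores[, t], genes)
    sort(genes[ord[seq_len(n_top)]])
  })
  stats::setNames(sets, colnames(scores))
}

#' Tissue-specific enrichment analysis (TSEA)
#'
#' Tests a query gene list against each tissue's specific gene set by
#' one-sided (greater) Fisher's exact test over a background universe,
#' with BH adjustment across tissues. Enrichment, not depletion, is the
#' question asked, hence the one-sided default. Query genes absent from
#' the background are dropped with a message.
#'
#' @param query Character vector of gene symbols.
#' @param tissue_sets Named list of tissue-specific gene sets (subsets of
#'   `background`).
#' @param background Character vector, the gene universe (defaults to the
#'   union of all tissue sets if `NULL` is not supplied explicitly by the
#'   caller via a panel; normally pass all panel genes).
#' @return `data.frame` of class `"tsea_result"`, one row per tissue,
#'   ranked by adjusted p: columns `tissue`, `overlap`, `set_size`,
#'   `query_size`, `background_size`, `p`, `adj_p`.
#' @export
tsea_enrich <- function(query, tissue_sets, background) {
  query <- unique(toupper(trimws(query)))
  background <- unique(toupper(trimws(background)))
  dropped <- setdiff(query, background)
  if (length(dropped) > 0L) {
    message(sprintf("tsea_enrich: %d query gene(s) not in background dropped",
                    length(dropped)))
  }
  q <- intersect(query, background)
  if (length(q) == 0L) stop("query has no overlap with the background")
  nb <- length(background)
  rows <- lapply(names(tissue_sets), function(t) {
    ts <- intersect(tissue_sets[[t]], background)
    a <- length(intersect(q, ts))
    b <- length(q) - a
    cc <- length(ts) - a
    d <- nb - a - b - cc
    data.frame(tissue = t, overlap = a, set_size = length(ts),
               query_size = length(q), background_size = nb,
               p = fisher_exact_2x2(c(a, b, cc, d), alternative = "greater"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out <- out[order(out$adj_p, out$p, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tsea_result", "data.frame")
  out
}

#' @export
print.tsea_result <- function(x, ...) {
  cat(sprintf("TSEA: %d tissue(s), query of %d gene(s), background of %d\n",
              nrow(x), x$query_size[1L], x$background_size[1L]))
  print(utils::head(as.data.frame(x), 10L), ...)
  invisible(x)
}

#' TSEA across a ladder of query-defining thresholds
#'
#' Rebuilds the query at each raw p-value cutoff (genes with `p <
#' threshold`) and runs [tsea_enrich()], producing a tissue x threshold
#' grid of enrichment results. Thresholds must be sorted decreasing so
#' queries are nested. A threshold with an empty query yields `NULL` for
#' that column rather than an error.
#'
#' @param gene_p Named numeric vector of raw gene p-values.
#' @param thresholds Decreasing vector of raw-p cutoffs.
#' @param tissue_sets,background As in [tsea_enrich()].
#' @return Named list (one element per threshold) of `"tsea_result"`
#'   objects or `NULL` for empty queries, with attribute `"grid"`: a
#'   tissue x threshold matrix of adjusted p-values.
#' @export
tsea_threshold_scan <- function(gene_p, thresholds, tissue_sets, background) {
  if (is.null(names(gene_p))) stop("'gene_p' must be a named vector")
  if (is.unsorted(rev(thresholds), strictly = TRUE)) {
    stop("'thresholds' must be sorted strictly decreasing")
  }
  res <- lapply(thresholds, function(th) {
    q <- names(gene_p)[gene_p < th]
    if (length(intersect(toupper(trimws(q)), toupper(trimws(background)))) == 0L) {
      return(NULL)
    }
    tsea_enrich(q, tissue_sets, background)
  })
  names(res) <- as.character(thresholds)
  tn <- names(tissue_sets)
  grid <- matrix(NA_real_, length(tn), length(thresholds),
                 dimnames = list(tn, as.character(thresholds)))
  for (j in seq_along(res)) {
    if (!is.null(res[[j]])) {
      grid[res[[j]]$tissue, j] <- res[[j]]$adj_p
    }
  }
  attr(res, "grid") <- grid
  res
}
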