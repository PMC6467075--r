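#' Per-dimension gene-level association table
#'
#' The ingest container for one line of evidence: gene symbols with raw
#' p-values and, optionally, BH-adjusted p-values, log2 fold changes and
#' a tissue label. Gene symbols are upper-cased and whitespace-trimmed;
#' duplicate rows for the same gene (within the same tissue) are resolved
#' by keeping the record with the minimum raw p, mirroring the
#' most-significant-probe rule used for methylation arrays.
#'
#' @param gene Character vector of gene symbols.
#' @param p Raw p-values in \[0, 1\].
#' @param adj_p Optional adjusted p-values; computed by [bh_adjust()] at
#'   labelling time when absent.
#' @param log2fc Optional log2 fold changes (expression dimension).
#' @param tissue Optional tissue label, one per record.
#' @param dimension Name of the evidence dimension (e.g. `"gwas"`).
#' @return A `data.frame` of class `"evidence_table"` with columns
#'   `gene`, `p` and any of `adj_p`, `log2fc`, `tissue` supplied, plus a
#'   `"dimension"` attribute.
#' @export
evidence_table <- function(gene, p, adj_p = NULL, log2fc = NULL,
                           tissue = NULL, dimension = "evidence") {
  gene <- toupper(trimws(as.character(gene)))
  if (any(gene == "" | is.na(gene))) stop("gene symbols must be non-empty")
  if (length(p) != length(gene)) stop("'gene' and 'p' lengths differ")
  if (any(is.na(p) | p < 0 | p > 1)) stop("raw p-values must lie in [0, 1]")
  df <- data.frame(gene = gene, p = as.numeric(p), stringsAsFactors = FALSE)
  if (!is.null(adj_p)) {
    if (any(is.na(adj_p) | adj_p < 0 | adj_p > 1)) {
      stop("adjusted p-values must lie in [0, 1]")
    }
    df$adj_p <- as.numeric(adj_p)
  }
  if (!is.null(log2fc)) df$log2fc <- as.numeric(log2fc)
  if (!is.null(tissue)) df$tissue <- as.character(tissue)

  key <- if (is.null(tissue)) df$gene else paste(df$gene, df$tissue, sep = "\r")
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    # keep minimum raw p per gene (per tissue); ties by first occurrence
    ord <- order(key, df$p)
    df <- df[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
    df <- df[order(df$gene), , drop = FALSE]
    warning(sprintf("dimension '%s': %d duplicate gene record(s) collapsed by minimum raw p",
                    dimension, n_dup))
  }
  rownames(df) <- NULL
  attr(df, "dimension") <- dimension
  class(df) <- c("evidence_table", "data.frame")
  df
}

#' @export
print.evidence_table <- function(x, ...) {
  cat(sprintf("Evidence table '%s': %d records", attr(x, "dimension"), nrow(x)))
  if (!is.null(x$tissue)) {
    cat(sprintf(" in %d tissue(s)", length(unique(x$tissue))))
  }
  cat("\n")
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Collapse probe-level statistics to gene level
#'
#' Maps array probes to genes and keeps, for each gene, the record of its
#' most significant probe (minimum raw p), carrying that probe's other
#' statistics along. Probes missing from the map are dropped with a
#' message.
#'
#' @param probes `data.frame` with columns `probe`, `p` and optionally
#'   further statistics (e.g. `log2fc`).
#' @param probe_map `data.frame` with columns `probe`, `gene`.
#' @param dimension Dimension name for the resulting table.
#' @return An [evidence_table()] with one record per mapped gene.
#' @export
collapse_probes <- function(probes, probe_map, dimension = "methylation") {
  if (!all(c("probe", "p") %in% names(probes))) {
    stop("'probes' needs columns 'probe' and 'p'")
  }
  if (!all(c("probe", "gene") %in% names(probe_map))) {
    stop("'probe_map' needs columns 'probe' and 'gene'")
  }
  idx <- match(probes$probe, probe_map$probe)
  unmapped <- sum(is.na(idx))
  if (unmapped > 0L) {
    message(sprintf("collapse_probes: dropping %d unmapped probe(s)", unmapped))
  }
  keep <- !is.na(idx)
  if (!any(keep)) stop("no probe in the table maps to a gene")
  gene <- probe_map$gene[idx[keep]]
  tab <- probes[keep, , drop = FALSE]
  # pick the most significant probe per gene
  ord <- order(gene, tab$p)
  first <- !duplicated(gene[ord])
  sel <- tab[ord, , drop = FALSE][first, , drop = FALSE]
  evidence_table(gene = gene[ord][first], p = sel$p,
                 log2fc = sel$log2fc, dimension = dimension)
}

#' Domain-specific significance rule for one evidence dimension
#'
#' Encodes a per-dimension labelling threshold: a strict FDR cutoff on
#' the BH-adjusted p-value, optionally combined with a strict minimum
#' absolute log2 fold change. Typical settings are `fdr = 0.05` for GWAS
#' gene scores and differential expression, `fdr = 0.2` for eQTL/TWAS
#' integration and methylation, and `abs_log2fc = 0.58` (fold change 1.5)
#' for the expression dimension.
#'
#' @param fdr Adjusted-p cutoff in (0, 1]; a gene is labelled positive
#'   only when `adj_p < fdr` (strict).
#' @param abs_log2fc Optional minimum `|log2fc|` (strict `>`), or `NULL`.
#' @return An object of class `"threshold_rule"`.
#' @export
threshold_rule <- function(fdr = 0.05, abs_log2fc = NULL) {
  if (!is.numeric(fdr) || length(fdr) != 1L || fdr <= 0 || fdr > 1) {
    stop("'fdr' must be a single value in (0, 1]")
  }
  if (!is.null(abs_log2fc) &&
      (!is.numeric(abs_log2fc) || length(abs_log2fc) != 1L || abs_log2fc < 0)) {
    stop("'abs_log2fc' must be a single non-negative value or NULL")
  }
  structure(list(fdr = fdr, abs_log2fc = abs_log2fc),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  cat(sprintf("Threshold rule: adjusted p < %g", x$fdr))
  if (!is.null(x$abs_log2fc)) cat(sprintf(" and |log2FC| > %g", x$abs_log2fc))
  cat("\n")
  invisible(x)
}

#' Label genes of one dimension as significant or not
#'
#' Applies a [threshold_rule()] to an [evidence_table()], yielding the
#' 0/1 gene labels that feed the binary evidence matrix. If the table
#' carries no `adj_p` column, BH adjustment is computed over the table's
#' raw p-values (per dimension, per tissue — never jointly across
#' dimensions). All inequalities are strict: a gene whose adjusted p
#' equals the cutoff is labelled 0.
#'
#' @param table An [evidence_table()] covering a single tissue (or no
#'   tissue column); see [merge_tissue_dimensions()] for multi-tissue
#'   dimensions.
#' @param rule A [threshold_rule()].
#' @return Named integer vector of 0/1 labels, one per gene.
#' @export
label_dimension <- function(table, rule) {
  stopifnot(inherits(table, "evidence_table"), inherits(rule, "threshold_rule"))
  if (!is.null(table$tissue) && length(unique(table$tissue)) > 1L) {
    stop("table spans multiple tissues; label each tissue separately and merge")
  }
  adj <- table$adj_p
  if (is.null(adj)) adj <- bh_adjust(table$p)
  lab <- adj < rule$fdr
  if (!is.null(rule$abs_log2fc)) {
    if (is.null(table$log2fc)) {
      stop(sprintf("rule requires a fold-change column but dimension '%s' has none",
                   attr(table, "dimension")))
    }
    lab <- lab & (abs(table$log2fc) > rule$abs_log2fc)
  }
  stats::setNames(as.integer(lab), table$gene)
}

#' Split a multi-tissue evidence table by tissue
#'
#' @param table An [evidence_table()] with a `tissue` column.
#' @return Named list of single-tissue evidence tables.
#' @export
split_tissues <- function(table) {
  stopifnot(inherits(table, "evidence_table"))
  if (is.null(table$tissue)) stop("table has no tissue column")
  dimn <- attr(table, "dimension")
  lapply(split(as.data.frame(table), table$tissue), function(d) {
    evidence_table(d$gene, d$p, adj_p = d$adj_p, log2fc = d$log2fc,
                   tissue = d$tissue,
                   dimension = sprintf("%s:%s", dimn, d$tissue[1L]))
  })
}

#' Merge per-tissue labels of one dimension by union
#'
#' Tissue-resolved dimensions (eQTL integration, TWAS) produce one label
#' vector per tissue over the same gene universe; the dimension's label
#' is their element-wise logical OR — a gene significant in any tissue is
#' significant for the dimension.
#'
#' @param labels Named list of 0/1 label vectors sharing an identical
#'   gene universe (same names, same order).
#' @return Single named 0/1 integer vector.
#' @export
merge_tissue_dimensions <- function(labels) {
  if (!is.list(labels) || length(labels) == 0L) {
    stop("'labels' must be a non-empty list of label vectors")
  }
  genes <- names(labels[[1L]])
  for (l in labels) {
    if (is.null(names(l)) || !identical(names(l), genes)) {
      stop("label vectors do not share an identical gene universe")
    }
  }
  merged <- Reduce(`|`, lapply(labels, function(l) l != 0L))
  stats::setNames(as.integer(merged), genes)
}

#' Coerce a binary matrix to an evidence matrix
#'
#' Wraps an existing genes x dimensions 0/1 matrix as an
#' `"evidence_matrix"` without applying the evidence-set row
#' restriction — useful when labels were produced outside the package
#' or when all-zero rows must be kept (e.g. for null calibrations over
#' a fixed universe).
#'
#' @param m Integer/numeric matrix of 0/1 entries with gene rownames
#'   and dimension colnames.
#' @param provenance Optional provenance list.
#' @return An `"evidence_matrix"`.
#' @export
as_evidence_matrix <- function(m, provenance = list(type = "custom")) {
  new_evidence_matrix(m, provenance = provenance)
}

# validating internal constructor
new_evidence_matrix <- function(m, provenance = list()) {
  stopifnot(is.matrix(m))
  if (!all(m %in% c(0L, 1L))) stop("evidence matrix entries must be 0 or 1")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("evidence matrix needs gene rownames and dimension colnames")
  }
  if (anyDuplicated(rownames(m))) stop("duplicate genes in evidence matrix")
  storage.mode(m) <- "integer"
  structure(m, class = c("evidence_matrix", class(m)),
            provenance = provenance)
}

#' Build the evidence-set (ES) binary matrix
#'
#' Aligns per-dimension label vectors on the union of their gene
#' universes (genes absent from a dimension count as unlabelled, 0) and
#' restricts rows to genes carrying at least one positive label — the
#' evidence-set genes. Genes are ordered alphabetically so the matrix is
#' invariant to input ordering.
#'
#' @param labels Named list (>= 2 entries) of named 0/1 label vectors,
#'   one per evidence dimension.
#' @return An `"evidence_matrix"`: integer genes x dimensions matrix with
#'   a `provenance` attribute recording per-dimension positive counts and
#'   the evidence-count histogram (how many genes carry exactly k lines
#'   of evidence).
#' @export
build_es_matrix <- function(labels) {
  if (!is.list(labels) || length(labels) < 2L) {
    stop("need at least two labelled dimensions")
  }
  if (is.null(names(labels)) || any(names(labels) == "")) {
    stop("'labels' must be a named list of dimensions")
  }
  universe <- sort(unique(unlist(lapply(labels, names), use.names = FALSE)))
  if (length(universe) == 0L) stop("no genes in any dimension")
  m <- vapply(labels, function(l) {
    v <- integer(length(universe))
    v[match(names(l), universe)] <- as.integer(l != 0L)
    v
  }, integer(length(universe)))
  m <- matrix(m, nrow = length(universe), ncol = length(labels),
              dimnames = list(universe, names(labels)))
  rs <- rowSums(m)
  if (!any(rs > 0)) stop("no gene carries any positive evidence label")
  m <- m[rs > 0, , drop = FALSE]
  hist <- table(factor(rowSums(m), levels = seq_len(ncol(m))))
  new_evidence_matrix(m, provenance = list(
    type = "ES",
    n_positive = colSums(m),
    evidence_count_histogram = stats::setNames(as.integer(hist), names(hist))
  ))
}

#' Extend an ES matrix to the tissue-set (TS) matrix
#'
#' Adds to the evidence-set universe all genes expressed above
#' `expr_min` (strict `>`) in any of the named reference tissues. The
#' added tissue-set genes carry no evidence and receive all-zero rows;
#' evidence-set genes are retained even when not expressed. This larger
#' matrix probes whether prioritization is robust to diluting the
#' universe with weakly supported genes.
#'
#' @param es An `"evidence_matrix"` from [build_es_matrix()].
#' @param panel A [tissue_panel()] expression reference.
#' @param tissues Character vector of panel tissue names defining the
#'   expressed-gene pool.
#' @param expr_min Expression threshold (default 1, RPKM-like units).
#' @return An `"evidence_matrix"` over the enlarged universe.
#' @export
build_ts_matrix <- function(es, panel, tissues, expr_min = 1) {
  stopifnot(inherits(es, "evidence_matrix"), inherits(panel, "tissue_panel"))
  missing_t <- setdiff(tissues, colnames(panel$expr))
  if (length(missing_t) > 0L) {
    stop("unknown tissue(s): ", paste(missing_t, collapse = ", "))
  }
  expr <- panel$expr[, tissues, drop = FALSE]
  expressed <- rownames(expr)[apply(expr > expr_min, 1L, any)]
  universe <- sort(union(rownames(es), expressed))
  m <- matrix(0L, nrow = length(universe), ncol = ncol(es),
              dimnames = list(universe, colnames(es)))
  m[rownames(es), ] <- unclass(es)[, , drop = FALSE]
  prov <- attr(es, "provenance")
  prov$type <- "TS"
  prov$tissues <- tissues
  prov$expr_min <- expr_min
  prov$n_ts_only <- length(universe) - nrow(es)
  new_evidence_matrix(m, provenance = prov)
}

#' @export
print.evidence_matrix <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("Binary evidence matrix (%s): %d genes x %d dimensions\n",
              if (is.null(prov$type)) "custom" else prov$type,
              nrow(x), ncol(x)))
  cat("Positives per dimension:\n")
  print(colSums(unclass(x)))
  invisible(x)
}

#' Pairwise association between evidence dimensions
#'
#' For every unordered pair of dimensions, tests whether positive labels
#' co-occur more (or less) often than expected by chance, via Fisher's
#' exact test on the 2x2 table (positive in both / in one / in neither)
#' over the matrix's gene universe. Association, not direction, is the
#' question, so the default is two-sided.
#'
#' @param m An `"evidence_matrix"`.
#' @param alternative Passed to [fisher_exact_2x2()].
#' @return Symmetric dimension x dimension matrix of p-values with `NA`
#'   on the diagonal.
#' @export
pairwise_dimension_association <- function(m,
                                           alternative = c("two.sided", "greater")) {
  stopifnot(inherits(m, "evidence_matrix"))
  alternative <- match.arg(alternative)
  d <- ncol(m)
  if (d < 2L) stop("need at least two dimensions")
  out <- matrix(NA_real_, d, d, dimnames = list(colnames(m), colnames(m)))
  mm <- unclass(m)
  n <- nrow(mm)
  for (i in seq_len(d - 1L)) {
    for (j in (i + 1L):d) {
      a <- sum(mm[, i] == 1L & mm[, j] == 1L)
      b <- sum(mm[, i] == 1L & mm[, j] == 0L)
      cc <- sum(mm[, i] == 0L & mm[, j] == 1L)
      dd <- n - a - b - cc
      p <- fisher_exact_2x2(c(a, b, cc, dd), alternative = alternative)
      out[i, j] <- out[j, i] <- p
    }
  }
  out
}
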