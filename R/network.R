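#' Undirected gene-gene interaction network
#'
#' Builds a protein-protein interaction network from an edge table.
#' Edges are symmetrized into a canonical (smaller symbol, larger symbol)
#' order, de-duplicated (conflicting duplicate confidences resolved by
#' maximum), and self-loops are dropped.
#'
#' @param edges `data.frame` with columns `from`, `to` and optionally
#'   `confidence` (in \[0, 1\]).
#' @param source Free-text label for the network's origin.
#' @return Object of class `"interaction_network"` with elements `edges`
#'   (canonical `data.frame`), `nodes` (sorted symbols) and `source`.
#' @export
interaction_network <- function(edges, source = "unspecified") {
  if (!all(c("from", "to") %in% names(edges))) {
    stop("'edges' needs columns 'from' and 'to'")
  }
  from <- toupper(trimws(as.character(edges$from)))
  to <- toupper(trimws(as.character(edges$to)))
  conf <- edges$confidence
  if (!is.null(conf)) {
    if (any(is.na(conf) | conf < 0 | conf > 1)) {
      stop("edge confidences must lie in [0, 1]")
    }
  }
  keep <- from != to
  if (sum(!keep) > 0L) {
    message(sprintf("interaction_network: dropped %d self-loop(s)", sum(!keep)))
  }
  from <- from[keep]; to <- to[keep]
  if (!is.null(conf)) conf <- conf[keep]
  a <- pmin(from, to); b <- pmax(from, to)
  key <- paste(a, b, sep = "\r")
  if (is.null(conf)) {
    dup <- duplicated(key)
    df <- data.frame(from = a[!dup], to = b[!dup], stringsAsFactors = FALSE)
  } else {
    cmax <- tapply(conf, key, max)
    dup <- duplicated(key)
    df <- data.frame(from = a[!dup], to = b[!dup],
                     confidence = as.vector(cmax[key[!dup]]),
                     stringsAsFactors = FALSE)
  }
  df <- df[order(df$from, df$to), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(edges = df, nodes = sort(unique(c(df$from, df$to))),
                 source = source),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("Interaction network '%s': %d nodes, %d edges%s\n",
              x$source, length(x$nodes), nrow(x$edges),
              if (is.null(x$edges$confidence)) "" else " (with confidence)"))
  invisible(x)
}

#' Count interactions internal to a gene set
#'
#' Number of network edges with both endpoints in the set. Genes absent
#' from the network simply contribute no edges.
#'
#' @param net An [interaction_network()].
#' @param gene_set Character vector of gene symbols.
#' @return Non-negative integer.
#' @export
count_internal_edges <- function(net, gene_set) {
  stopifnot(inherits(net, "interaction_network"))
  gene_set <- toupper(trimws(gene_set))
  sum(net$edges$from %in% gene_set & net$edges$to %in% gene_set)
}

#' Size-matched resampling test for network interconnection
#'
#' Asks whether a candidate gene set carries more internal interactions
#' than size-matched random gene sets. The observed count uses the
#' annotated subset (the V genes present in the network); each of the
#' `n_resamples` null sets draws V nodes uniformly without replacement
#' from the universe (by default, the network's node set, so observed and
#' null sets share the annotation rate) and its internal edges are
#' counted. The empirical p-value is the upper-tail rank via
#' [empirical_pvalue()].
#'
#' @param net An [interaction_network()].
#' @param gene_set Query gene symbols.
#' @param n_resamples Number of random sets (default 10000).
#' @param seed Integer RNG seed.
#' @param universe Sampling pool; default `NULL` uses the network nodes.
#' @param correction `"plus_one"` (default) or `"raw"`, see
#'   [empirical_pvalue()].
#' @return Object of class `"ppi_resampling_test"`: `observed`, `V`
#'   (annotated genes), `E` (= `observed`), `null` (integer vector),
#'   `p`, `n_resamples`, `seed`, `universe_size`, `dropped` (query genes
#'   absent from the universe).
#' @export
ppi_resampling_test <- function(net, gene_set, n_resamples = 10000L,
                                seed = 1L, universe = NULL,
                                correction = c("plus_one", "raw")) {
  stopifnot(inherits(net, "interaction_network"))
  correction <- match.arg(correction)
  gene_set <- unique(toupper(trimws(gene_set)))
  if (is.null(universe)) universe <- net$nodes
  universe <- unique(toupper(trimws(universe)))
  annotated <- intersect(gene_set, universe)
  v <- length(annotated)
  if (v == 0L) stop("no query gene is annotated in the sampling universe")
  if (v > length(universe)) stop("universe smaller than the annotated set")
  observed <- count_internal_edges(net, annotated)

  ei <- match(net$edges$from, universe)
  ej <- match(net$edges$to, universe)
  in_univ <- !is.na(ei) & !is.na(ej)
  ei <- ei[in_univ]; ej <- ej[in_univ]
  nu <- length(universe)
  set.seed(as.integer(seed))
  null <- integer(n_resamples)
  member <- logical(nu)
  for (r in seq_len(n_resamples)) {
    pick <- sample.int(nu, v)
    member[pick] <- TRUE
    null[r] <- sum(member[ei] & member[ej])
    member[pick] <- FALSE
  }
  structure(list(observed = observed, V = v, E = observed, null = null,
                 p = empirical_pvalue(observed, null, correction = correction),
                 n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed), universe_size = nu,
                 dropped = setdiff(gene_set, universe),
                 correction = correction),
            class = "ppi_resampling_test")
}

#' @export
print.ppi_resampling_test <- function(x, ...) {
  cat(sprintf("PPI resampling test: V = %d annotated genes, E = %d internal edges\n",
              x$V, x$E))
  cat(sprintf("null mean %.2f over %d resamples; empirical p = %.4g (%s)\n",
              mean(x$null), x$n_resamples, x$p, x$correction))
  if (length(x$dropped) > 0L) {
    cat(sprintf("(%d query gene(s) not annotated in the universe)\n",
                length(x$dropped)))
  }
  invisible(x)
}

#' Crosstalk edges between candidate genes and drug targets
#'
#' Filters a confidence-scored interaction network to the edges linking
#' a query set (e.g. prioritized disease genes) to a target set (e.g.
#' approved drug targets) with confidence strictly above
#' `min_confidence`. An edge scored exactly at the cutoff is excluded.
#' Genes present in both sets are reported separately, not as crosstalk.
#'
#' @param net An [interaction_network()] with a `confidence` column.
#' @param query_genes,target_genes Character vectors of symbols.
#' @param min_confidence Strict lower bound on confidence (default 0.35,
#'   the usual medium-confidence cut for experimentally supported
#'   interactions).
#' @return `data.frame` with columns `query`, `target`, `confidence`,
#'   plus attribute `"overlap"` (genes in both input sets).
#' @export
drug_target_crosstalk <- function(net, query_genes, target_genes,
                                  min_confidence = 0.35) {
  stopifnot(inherits(net, "interaction_network"))
  if (is.null(net$edges$confidence)) {
    stop("network carries no confidence scores")
  }
  q <- unique(toupper(trimws(query_genes)))
  t <- unique(toupper(trimws(target_genes)))
  e <- net$edges[net$edges$confidence > min_confidence, , drop = FALSE]
  qt <- e$from %in% q & e$to %in% t
  tq <- e$from %in% t & e$to %in% q
  out <- rbind(
    data.frame(query = e$from[qt], target = e$to[qt],
               confidence = e$confidence[qt], stringsAsFactors = FALSE),
    data.frame(query = e$to[tq], target = e$from[tq],
               confidence = e$confidence[tq], stringsAsFactors = FALSE))
  out <- out[out$query != out$target, , drop = FALSE]
  out <- unique(out)
  out <- out[order(out$query, out$target), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "overlap") <- sort(intersect(q, t))
  out
}

#' Gene-set enrichment by Fisher's exact test
#'
#' Generic over-representation analysis of a query list against a named
#' collection of gene sets over a background universe: one-sided
#' (greater) Fisher per set, BH adjustment across the sets of the
#' collection, ranked by adjusted p.
#'
#' @param query Character vector of gene symbols.
#' @param collections Named list of gene sets.
#' @param background Character vector, the universe; sets are
#'   intersected with it before testing.
#' @return `data.frame` with columns `set`, `overlap`, `set_size`,
#'   `query_size`, `p`, `adj_p`, ranked by adjusted p.
#' @export
gene_set_enrichment <- function(query, collections, background) {
  query <- unique(toupper(trimws(query)))
  background <- unique(toupper(trimws(background)))
  q <- intersect(query, background)
  if (length(q) == 0L) stop("query has no overlap with the background")
  if (is.null(names(collections)) || any(names(collections) == "")) {
    stop("'collections' must be a named list of gene sets")
  }
  nb <- length(background)
  rows <- lapply(names(collections), function(s) {
    gs <- intersect(unique(toupper(trimws(collections[[s]]))), background)
    a <- length(intersect(q, gs))
    b <- length(q) - a
    cc <- length(gs) - a
    d <- nb - a - b - cc
    data.frame(set = s, overlap = a, set_size = length(gs),
               query_size = length(q),
               p = fisher_exact_2x2(c(a, b, cc, d), alternative = "greater"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out <- out[order(out$adj_p, out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}
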