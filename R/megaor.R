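#' Per-dimension odds ratio of a candidate gene set
#'
#' For one evidence dimension, the association between membership in the
#' candidate set S and a positive evidence label, as the odds ratio of
#' the 2x2 table (in S & labelled, in S & not, outside & labelled,
#' outside & not) over the matrix universe.
#'
#' @param m An `"evidence_matrix"` (or 0/1 matrix with dimnames).
#' @param genes Character vector, the candidate set S (subset of the
#'   universe, neither empty nor the whole universe).
#' @param dim Dimension name or column index.
#' @param zero_cell Zero-cell policy, see [odds_ratio_2x2()].
#' @return A single non-negative number.
#' @export
dimension_or <- function(m, genes, dim, zero_cell = c("haldane", "none")) {
  zero_cell <- match.arg(zero_cell)
  m <- as_binary_matrix(m)
  idx <- set_index(m, genes)
  lab <- m[, dim] == 1L
  a <- sum(lab[idx]); b <- sum(!lab[idx])
  cc <- sum(lab[-idx]); d <- sum(!lab[-idx])
  odds_ratio_2x2(c(a, b, cc, d), zero_cell = zero_cell)
}

#' Penalized combined odds ratio (cOR) of a candidate gene set
#'
#' The MegaOR objective. With per-dimension odds ratios OR_1..OR_d and
#' their mean mu, the combined OR is
#' \deqn{cOR = \mu - \sqrt{\sum_d (OR_d - \mu)^2 / d}}
#' i.e. the mean minus the (population) standard deviation of the
#' per-dimension ORs. The deviation term penalizes sets whose evidence
#' load is carried by a few dimensions only, balancing the lines of
#' evidence. cOR equals mu exactly when all dimension ORs agree and is
#' otherwise strictly smaller.
#'
#' @inheritParams dimension_or
#' @param penalty_divisor `"d"` (default, population SD) or `"d-1"`
#'   (sample SD) in the deviation term.
#' @return List of class `"cor_profile"` with elements `or` (named
#'   per-dimension ORs), `mu`, `penalty`, `cor` and `d`.
#' @export
combined_or <- function(m, genes, zero_cell = c("haldane", "none"),
                        penalty_divisor = c("d", "d-1")) {
  zero_cell <- match.arg(zero_cell)
  penalty_divisor <- match.arg(penalty_divisor)
  m <- as_binary_matrix(m)
  if (ncol(m) < 2L) stop("cOR needs at least two evidence dimensions")
  ors <- vapply(colnames(m), function(dn) {
    dimension_or(m, genes, dn, zero_cell = zero_cell)
  }, numeric(1L))
  profile_from_ors(ors, penalty_divisor)
}

profile_from_ors <- function(ors, penalty_divisor) {
  d <- length(ors)
  mu <- mean(ors)
  div <- if (penalty_divisor == "d") d else d - 1L
  penalty <- sqrt(sum((ors - mu)^2) / div)
  structure(list(or = ors, mu = mu, penalty = penalty,
                 cor = mu - penalty, d = d),
            class = "cor_profile")
}

#' @export
print.cor_profile <- function(x, digits = 4, ...) {
  cat("Per-dimension odds ratios:\n")
  print(round(x$or, digits))
  cat(sprintf("mu = %.*f, penalty (SD) = %.*f, cOR = %.*f\n",
              digits, x$mu, digits, x$penalty, digits, x$cor))
  invisible(x)
}

# ---- internal machinery ----------------------------------------------------

as_binary_matrix <- function(m) {
  if (inherits(m, "evidence_matrix")) return(unclass(m))
  if (!is.matrix(m)) stop("'m' must be a matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("'m' needs gene rownames and dimension colnames")
  }
  if (!all(m %in% c(0L, 1L))) stop("'m' must be binary")
  storage.mode(m) <- "integer"
  m
}

set_index <- function(m, genes) {
  idx <- match(genes, rownames(m))
  if (anyNA(idx)) stop("gene(s) not in the matrix universe: ",
                       paste(utils::head(genes[is.na(idx)], 3L), collapse = ", "))
  if (anyDuplicated(idx)) stop("duplicate genes in candidate set")
  if (length(idx) == 0L || length(idx) == nrow(m)) {
    stop("candidate set must be a proper non-empty subset of the universe")
  }
  idx
}

# cOR for each row of a count matrix A (candidates x dimensions), where
# A[i, j] = number of set members positive in dimension j. Vectorized;
# haldane correction applied per candidate x dimension cell block.
cor_from_counts <- function(A, n, K, N, zero_cell = "haldane", div_d = TRUE) {
  if (is.null(dim(A))) A <- matrix(A, nrow = 1L)
  r <- nrow(A); d <- ncol(A)
  Km <- matrix(K, nrow = r, ncol = d, byrow = TRUE)
  a <- A
  b <- n - A
  cc <- Km - A
  dd <- N - n - cc
  if (zero_cell == "haldane") {
    z <- (a == 0) | (b == 0) | (cc == 0) | (dd == 0)
    h <- 0.5 * z
    a <- a + h; b <- b + h; cc <- cc + h; dd <- dd + h
  }
  or <- (a * dd) / (b * cc)
  mu <- rowMeans(or)
  div <- if (div_d) d else d - 1L
  pen <- sqrt(rowSums((or - mu)^2) / div)
  list(or = or, mu = mu, penalty = pen, cor = mu - pen)
}

#' Single MegaOR optimization run
#'
#' Finds a gene set of fixed size `n` maximizing the combined odds ratio
#' by hill climbing: starting from a seeded uniform random size-`n` set,
#' single-gene swaps (one member out, one non-member in) are evaluated
#' and a strictly improving swap is accepted until no swap improves the
#' cOR (the stable status) or `max_iters` swaps have been made.
#'
#' Because the objective depends on the set only through its per-dimension
#' positive counts, genes with identical label rows are exchangeable;
#' swaps are therefore evaluated over label-pattern classes (at most
#' `2^d`), which is exactly equivalent to scanning all member/non-member
#' gene pairs but far cheaper. Under `method = "steepest"` the best
#' improving swap is taken, ties broken by the lexicographically smallest
#' (outgoing gene, incoming gene) pair; `method = "first"` accepts the
#' first improving swap in a seeded random scan order, which is faster on
#' large universes.
#'
#' @inheritParams combined_or
#' @param n Target set size, `2 <= n < nrow(m)`.
#' @param seed Integer seed for the random initial set (and scan order
#'   under `method = "first"`).
#' @param max_iters Maximum accepted swaps before giving up.
#' @param method `"steepest"` (default) or `"first"`.
#' @return Object of class `"megaor_run"`: `genes` (the stable set,
#'   sorted), `profile` (a `"cor_profile"`), `trace` (cOR after the
#'   initial set and each accepted swap; strictly increasing),
#'   `converged`, `iterations`, `seed`, `n`.
#' @export
megaor_optimize <- function(m, n, seed = 1L, max_iters = 10000L,
                            zero_cell = c("haldane", "none"),
                            penalty_divisor = c("d", "d-1"),
                            method = c("steepest", "first")) {
  zero_cell <- match.arg(zero_cell)
  penalty_divisor <- match.arg(penalty_divisor)
  method <- match.arg(method)
  mm <- as_binary_matrix(m)
  N <- nrow(mm); d <- ncol(mm)
  if (d < 2L) stop("need at least two dimensions")
  if (n < 2L || n >= N) stop("'n' must satisfy 2 <= n < number of genes")
  genes <- rownames(mm)
  K <- colSums(mm)
  div_d <- penalty_divisor == "d"

  # label-pattern classes
  pat_key <- as.vector(mm %*% (2L^(seq_len(d) - 1L)))
  pats <- sort(unique(pat_key))
  P <- length(pats)
  pat_of <- match(pat_key, pats)                  # gene -> pattern index
  L <- mm[!duplicated(pat_of), , drop = FALSE][order(unique(pat_of)), , drop = FALSE]
  L <- matrix(L, nrow = P, ncol = d)              # pattern label rows
  avail <- tabulate(pat_of, nbins = P)

  set.seed(as.integer(seed))
  in_set <- logical(N)
  in_set[sample.int(N, n)] <- TRUE
  cnt <- tabulate(pat_of[in_set], nbins = P)      # members per pattern

  # precompute move templates: all ordered pattern pairs (out p, in q)
  mv_out <- rep(seq_len(P), each = P)
  mv_in <- rep(seq_len(P), times = P)
  keep <- mv_out != mv_in
  mv_out <- mv_out[keep]; mv_in <- mv_in[keep]
  dL <- L[mv_in, , drop = FALSE] - L[mv_out, , drop = FALSE]

  a <- as.vector(crossprod(L, cnt))               # current per-dim counts
  cur <- cor_from_counts(a, n, K, N, zero_cell, div_d)$cor
  trace <- cur
  iter <- 0L
  converged <- FALSE
  repeat {
    feas <- cnt[mv_out] > 0L & cnt[mv_in] < avail[mv_in]
    if (!any(feas)) { converged <- TRUE; break }
    idx <- which(feas)
    Acand <- matrix(a, nrow = length(idx), ncol = d, byrow = TRUE) +
      dL[idx, , drop = FALSE]
    cors <- cor_from_counts(Acand, n, K, N, zero_cell, div_d)$cor
    if (method == "steepest") {
      best <- max(cors)
      if (!(best > cur)) { converged <- TRUE; break }
      tied <- idx[cors >= best - 1e-12]
      if (length(tied) > 1L) {
        # lexicographic (outgoing gene, incoming gene) tie-break
        outg <- vapply(tied, function(k) min(genes[pat_of == mv_out[k] & in_set]),
                       character(1L))
        ing <- vapply(tied, function(k) min(genes[pat_of == mv_in[k] & !in_set]),
                      character(1L))
        pick <- tied[order(outg, ing)][1L]
      } else pick <- tied
      new_cor <- cors[match(pick, idx)]
    } else {
      scan <- sample.int(length(idx))
      imp <- which(cors[scan] > cur)
      if (length(imp) == 0L) { converged <- TRUE; break }
      pick <- idx[scan[imp[1L]]]
      new_cor <- cors[scan[imp[1L]]]
    }
    p <- mv_out[pick]; q <- mv_in[pick]
    out_gene <- min(genes[pat_of == p & in_set])
    in_gene <- min(genes[pat_of == q & !in_set])
    in_set[match(out_gene, genes)] <- FALSE
    in_set[match(in_gene, genes)] <- TRUE
    cnt[p] <- cnt[p] - 1L; cnt[q] <- cnt[q] + 1L
    a <- a + dL[pick, ]
    cur <- new_cor
    trace <- c(trace, cur)
    iter <- iter + 1L
    if (iter >= max_iters) break
  }
  if (!converged) warning("megaor_optimize: max_iters reached before stable status")

  prof <- cor_from_counts(a, n, K, N, zero_cell, div_d)
  ors <- stats::setNames(as.vector(prof$or), colnames(mm))
  structure(list(genes = sort(genes[in_set]),
                 profile = profile_from_ors(
                   ors, if (div_d) "d" else "d-1"),
                 trace = trace, converged = converged,
                 iterations = iter, seed = as.integer(seed), n = n),
            class = "megaor_run")
}

#' @export
print.megaor_run <- function(x, ...) {
  cat(sprintf("MegaOR run (seed %d): |S| = %d, cOR = %.4f after %d swap(s)%s\n",
              x$seed, x$n, x$profile$cor, x$iterations,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Consensus genes across multi-restart MegaOR runs
#'
#' Stable sets from different random restarts need not agree; genes
#' retained in more than `min_freq` of the runs (strict `>`, default more
#' than 50%) form the consensus set for that size.
#'
#' @param runs List of `"megaor_run"` objects sharing the same `n`.
#' @param min_freq Frequency threshold in \[0, 1); strict.
#' @return Object of class `"megaor_consensus"`: `frequency` (named,
#'   sorted decreasing, over all genes seen in any run), `consensus`
#'   (sorted gene vector), `mean_or` (per-dimension OR averaged over
#'   runs), `mean_cor`, `n`, `n_runs`.
#' @export
consensus_genes <- function(runs, min_freq = 0.5) {
  if (length(runs) == 0L) stop("'runs' must contain at least one run")
  if (!all(vapply(runs, inherits, logical(1L), "megaor_run"))) {
    stop("'runs' must be a list of megaor_run objects")
  }
  ns <- vapply(runs, `[[`, numeric(1L), "n")
  if (length(unique(ns)) != 1L) stop("runs have heterogeneous set sizes")
  tab <- table(unlist(lapply(runs, `[[`, "genes")))
  freq <- stats::setNames(as.vector(tab) / length(runs), names(tab))
  freq <- freq[order(-freq, names(freq))]
  or_mat <- do.call(rbind, lapply(runs, function(r) r$profile$or))
  structure(list(frequency = freq,
                 consensus = sort(names(freq)[freq > min_freq]),
                 mean_or = colMeans(or_mat),
                 mean_cor = mean(vapply(runs, function(r) r$profile$cor,
                                        numeric(1L))),
                 min_freq = min_freq,
                 n = ns[1L], n_runs = length(runs)),
            class = "megaor_consensus")
}

#' @export
print.megaor_consensus <- function(x, ...) {
  cat(sprintf("MegaOR consensus at n = %d over %d runs: %d gene(s) with frequency > %g\n",
              x$n, x$n_runs, length(x$consensus), x$min_freq))
  invisible(x)
}

#' Fit a consensus MegaOR gene set at a fixed size
#'
#' The main fitting interface: runs [megaor_optimize()] from `restarts`
#' random initial sets (restart seeds derived deterministically from
#' `seed`) and calls the consensus across the stable sets. Returns a
#' classed fit with `print`, `summary`, `coef` and `plot` methods.
#'
#' @inheritParams megaor_optimize
#' @param restarts Number of random restarts (default 100).
#' @param min_freq Consensus frequency threshold, strict (default 0.5).
#' @return Object of class `"megaor"`: `consensus` (a
#'   `"megaor_consensus"`), `runs` (list of `"megaor_run"`), `best`
#'   (the run with the highest cOR), plus the call parameters.
#' @examples
#' sim <- simulate_binary_matrix(n_genes = 60, n_planted = 12, n_dimensions = 3,
#'                               planted_hit_rate = 0.9,
#'                               background_hit_rate = 0.05, seed = 1)
#' fit <- megaor(sim$matrix, n = 12, restarts = 10, seed = 1)
#' fit
#' coef(fit)
#' @export
megaor <- function(m, n, restarts = 100L, seed = 1L, min_freq = 0.5,
                   max_iters = 10000L,
                   zero_cell = c("haldane", "none"),
                   penalty_divisor = c("d", "d-1"),
                   method = c("steepest", "first")) {
  zero_cell <- match.arg(zero_cell)
  penalty_divisor <- match.arg(penalty_divisor)
  method <- match.arg(method)
  if (restarts < 1L) stop("'restarts' must be >= 1")
  runs <- lapply(seq_len(restarts), function(i) {
    megaor_optimize(m, n, seed = as.integer(seed) + i - 1L,
                    max_iters = max_iters, zero_cell = zero_cell,
                    penalty_divisor = penalty_divisor, method = method)
  })
  cons <- consensus_genes(runs, min_freq = min_freq)
  best <- runs[[which.max(vapply(runs, function(r) r$profile$cor, numeric(1L)))]]
  structure(list(consensus = cons, runs = runs, best = best,
                 n = n, restarts = restarts, seed = as.integer(seed),
                 min_freq = min_freq, zero_cell = zero_cell,
                 penalty_divisor = penalty_divisor, method = method),
            class = "megaor")
}

#' @export
print.megaor <- function(x, ...) {
  cat(sprintf("MegaOR fit: set size n = %d, %d restarts\n", x$n, x$restarts))
  cat(sprintf("  best cOR: %.4f   mean cOR: %.4f\n",
              x$best$profile$cor, x$consensus$mean_cor))
  cat(sprintf("  consensus (frequency > %g): %d gene(s)\n",
              x$min_freq, length(x$consensus$consensus)))
  invisible(x)
}

#' @export
summary.megaor <- function(object, ...) {
  conv <- vapply(object$runs, `[[`, logical(1L), "converged")
  iters <- vapply(object$runs, `[[`, integer(1L), "iterations")
  out <- list(n = object$n, restarts = object$restarts,
              consensus_size = length(object$consensus$consensus),
              mean_or = object$consensus$mean_or,
              best_profile = object$best$profile,
              mean_cor = object$consensus$mean_cor,
              converged = sum(conv), mean_iterations = mean(iters),
              frequency = object$consensus$frequency)
  class(out) <- "summary.megaor"
  out
}

#' @export
print.summary.megaor <- function(x, ...) {
  cat(sprintf("MegaOR fit at n = %d (%d restarts, %d converged, mean %.1f swaps)\n",
              x$n, x$restarts, x$converged, x$mean_iterations))
  cat(sprintf("Consensus size: %d   mean cOR: %.4f\n",
              x$consensus_size, x$mean_cor))
  cat("Mean per-dimension OR across runs:\n")
  print(round(x$mean_or, 3))
  cat("Best run profile:\n")
  print(x$best_profile)
  invisible(x)
}

#' @describeIn megaor Mean per-dimension odds ratios across restarts.
#' @param object,... Method arguments.
#' @export
coef.megaor <- function(object, ...) object$consensus$mean_or

#' Plot gene occurrence frequencies of a MegaOR fit
#'
#' Frequency-versus-rank curve over the restarts: genes to the right of
#' the threshold line are the consensus set.
#'
#' @param x A `"megaor"` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.megaor <- function(x, ...) {
  f <- rev(x$consensus$frequency)
  graphics::plot(seq_along(f), f, type = "h",
                 col = ifelse(f > x$min_freq, "forestgreen", "grey60"),
                 xlab = "gene rank (increasing frequency)",
                 ylab = "occurrence frequency across restarts",
                 main = sprintf("MegaOR gene stability at n = %d", x$n), ...)
  graphics::abline(h = x$min_freq, lty = 2, col = "red")
  invisible(x)
}

#' MegaOR across a grid of set sizes
#'
#' Runs the full multi-restart fit at each size, then summarizes how the
#' consensus evolves: larger sizes typically cover nearly all consensus
#' genes of smaller sizes (the nesting diagnostic, `coverage`), and the
#' consensus converges once the size exceeds the evidence-rich core (the
#' stability diagnostic, `jaccard`, the Jaccard similarity of adjacent
#' consensus sets). The stable size is the smaller size of the first
#' adjacent pair whose Jaccard similarity reaches `stable_jaccard`; if
#' no pair qualifies, the pair with the highest similarity is used.
#'
#' @inheritParams megaor
#' @param sizes Increasing integer vector of set sizes.
#' @param stable_jaccard Adjacent-size Jaccard similarity required to
#'   call stability outright (default 0.9).
#' @return Object of class `"megaor_grid"`: `fits` (named list of
#'   `"megaor"` objects), `coverage` (fraction of each consensus covered
#'   by the next size's), `jaccard` (adjacent-size Jaccard
#'   similarities), `consensus_sizes`, `stable_size`,
#'   `stable_consensus`, `mean_or` (size x dimension matrix of mean
#'   ORs).
#' @export
megaor_grid <- function(m, sizes, restarts = 100L, seed = 1L, min_freq = 0.5,
                        stable_jaccard = 0.9, ...) {
  if (is.unsorted(sizes, strictly = TRUE)) stop("'sizes' must be strictly increasing")
  fits <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    fits[[i]] <- megaor(m, n = sizes[i], restarts = restarts,
                        seed = as.integer(seed) + (i - 1L) * restarts,
                        min_freq = min_freq, ...)
  }
  names(fits) <- as.character(sizes)
  cons <- lapply(fits, function(f) f$consensus$consensus)
  csz <- vapply(cons, length, integer(1L))
  k <- length(sizes)
  coverage <- jaccard <- rep(NA_real_, max(k - 1L, 0L))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      inter <- length(intersect(cons[[i]], cons[[i + 1L]]))
      uni <- length(union(cons[[i]], cons[[i + 1L]]))
      coverage[i] <- if (csz[i] == 0L) 0 else inter / csz[i]
      jaccard[i] <- if (uni == 0L) 0 else inter / uni
    }
    names(coverage) <- names(jaccard) <-
      sprintf("%d->%d", sizes[-k], sizes[-1L])
  }
  stable_i <- if (k == 1L) 1L else {
    ok <- which(jaccard >= stable_jaccard)
    if (length(ok) > 0L) ok[1L] else which.max(jaccard)
  }
  mean_or <- do.call(rbind, lapply(fits, function(f) f$consensus$mean_or))
  rownames(mean_or) <- as.character(sizes)
  structure(list(fits = fits, sizes = sizes, coverage = coverage,
                 jaccard = jaccard,
                 consensus_sizes = csz, stable_size = sizes[stable_i],
                 stable_consensus = cons[[stable_i]], mean_or = mean_or,
                 restarts = restarts, seed = as.integer(seed)),
            class = "megaor_grid")
}

#' @export
print.megaor_grid <- function(x, ...) {
  cat(sprintf("MegaOR size grid (%d restarts per size):\n", x$restarts))
  df <- data.frame(size = x$sizes, consensus = x$consensus_sizes,
                   coverage_next = c(round(x$coverage, 3), NA),
                   jaccard_next = c(round(x$jaccard, 3), NA))
  print(df, row.names = FALSE)
  cat(sprintf("Stable size: %d (consensus of %d genes)\n",
              x$stable_size, length(x$stable_consensus)))
  invisible(x)
}

#' Plot a MegaOR size grid
#'
#' Left panel: mean per-dimension OR against set size. Right panel:
#' consensus size against set size, the plateau marking the stable
#' status.
#'
#' @param x A `"megaor_grid"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.megaor_grid <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::matplot(x$sizes, x$mean_or, type = "b", pch = 19, lty = 1,
                    xlab = "set size n", ylab = "mean dimension OR", ...)
  graphics::legend("topright", legend = colnames(x$mean_or),
                   col = seq_len(ncol(x$mean_or)), pch = 19, cex = 0.7)
  graphics::plot(x$sizes, x$consensus_sizes, type = "b", pch = 19,
                 xlab = "set size n", ylab = "consensus size")
  graphics::abline(v = x$stable_size, lty = 2, col = "red")
  invisible(x)
}
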