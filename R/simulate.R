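#' Configuration of a synthetic multi-omics study
#'
#' Describes the generative model for a complete synthetic study: a gene
#' universe with a planted disease-gene set, per-dimension true-signal
#' indicators, sub-uniform p-values for signals, a fold-change column for
#' the expression dimension, probe-level records for the methylation
#' dimension, and a shared per-gene latent that correlates the
#' tissue-resolved dimensions (mimicking the strong association observed
#' between eQTL-integration and TWAS evidence in real studies).
#'
#' The defaults emulate a mid-sized disease study: 1,600 genes of which
#' 200 are disease genes, five evidence dimensions (GWAS gene scores,
#' eQTL integration and TWAS each across three tissues, differential
#' expression with fold changes, probe-level methylation), a 60% chance
#' that a planted gene is a true signal in any given dimension against a
#' 5% background rate, and Beta(0.1, 1) signal p-values.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_planted Number of planted disease genes (`< n_genes`).
#' @param dimensions List of dimension descriptors: each a list with
#'   `name`, `kind` (one of `"pvalue_only"`, `"pvalue_with_fc"`,
#'   `"probe_level"`) and optionally `tissues` (character vector).
#' @param planted_hit_rate Probability a planted gene is a true signal
#'   in a given dimension.
#' @param background_hit_rate Same for non-planted genes; must be
#'   strictly smaller than `planted_hit_rate`.
#' @param signal_p_shape Either `c(shape1, shape2)` of the Beta
#'   distribution for signal p-values (default `c(0.1, 1)`), or a single
#'   number giving a constant signal p (useful for degenerate checks).
#' @param cross_tissue_latent Logical; when `TRUE`, tissue-resolved
#'   dimensions draw their true-signal indicator from one shared
#'   per-gene latent with probability `latent_share_prob`, inducing
#'   cross-dimension correlation without changing marginal rates.
#' @param latent_share_prob Probability that a tissue-resolved
#'   dimension's indicator copies the shared latent (default 0.9; high
#'   sharing is needed for the eQTL/TWAS association to survive
#'   restriction to the evidence-set universe, mirroring the dominant
#'   eQTL-TWAS dependence seen in real multi-omics panels).
#' @param tissue_activation Probability a signal manifests in each
#'   individual tissue, given the dimension-level signal (at least one
#'   tissue is always active so the tissue union reproduces the
#'   dimension indicator).
#' @param fc_effect Mean |log2 fold change| of expression signals.
#' @param max_probes Methylation probes per gene are drawn uniformly
#'   from `1:max_probes` (default 5).
#' @param rng_seed Integer seed; a fixed seed makes the study
#'   byte-identical across calls.
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_genes = 1600L,
                              n_planted = 200L,
                              dimensions = default_dimensions(),
                              planted_hit_rate = 0.6,
                              background_hit_rate = 0.05,
                              signal_p_shape = c(0.1, 1),
                              cross_tissue_latent = TRUE,
                              latent_share_prob = 0.9,
                              tissue_activation = 0.7,
                              fc_effect = 1,
                              max_probes = 5L,
                              rng_seed = 1L) {
  if (n_planted >= n_genes) stop("'n_planted' must be smaller than 'n_genes'")
  if (!(background_hit_rate >= 0 && background_hit_rate < planted_hit_rate &&
        planted_hit_rate <= 1)) {
    stop("need 0 <= background_hit_rate < planted_hit_rate <= 1")
  }
  if (!length(signal_p_shape) %in% c(1L, 2L) || any(signal_p_shape <= 0)) {
    stop("'signal_p_shape' must be one constant p or two positive Beta shapes")
  }
  nm <- vapply(dimensions, `[[`, character(1L), "name")
  if (anyDuplicated(nm)) stop("dimension names must be unique")
  kinds <- vapply(dimensions, `[[`, character(1L), "kind")
  if (!all(kinds %in% c("pvalue_only", "pvalue_with_fc", "probe_level"))) {
    stop("unknown dimension kind")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_planted = as.integer(n_planted),
                 dimensions = dimensions,
                 planted_hit_rate = planted_hit_rate,
                 background_hit_rate = background_hit_rate,
                 signal_p_shape = signal_p_shape,
                 cross_tissue_latent = isTRUE(cross_tissue_latent),
                 latent_share_prob = latent_share_prob,
                 tissue_activation = tissue_activation,
                 fc_effect = fc_effect,
                 max_probes = as.integer(max_probes),
                 rng_seed = as.integer(rng_seed)),
            class = "simulation_config")
}

#' Default five-dimension study design
#'
#' GWAS gene scores, eQTL integration and TWAS (each over whole blood,
#' spleen and small intestine), differential expression with fold
#' changes, and probe-level methylation.
#' @return List of dimension descriptors for [simulation_config()].
#' @export
default_dimensions <- function() {
  tissues <- c("whole_blood", "spleen", "small_intestine")
  list(list(name = "gwas", kind = "pvalue_only"),
       list(name = "eqtl", kind = "pvalue_only", tissues = tissues),
       list(name = "twas", kind = "pvalue_only", tissues = tissues),
       list(name = "expression", kind = "pvalue_with_fc"),
       list(name = "methylation", kind = "probe_level"))
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf("Synthetic study: %d genes (%d planted), %d dimensions, seed %d\n",
              x$n_genes, x$n_planted, length(x$dimensions), x$rng_seed))
  cat(sprintf("hit rates %.2f (planted) vs %.2f (background)\n",
              x$planted_hit_rate, x$background_hit_rate))
  invisible(x)
}

draw_signal_p <- function(n, shape) {
  if (n == 0L) return(numeric(0))
  if (length(shape) == 1L) rep(shape, n) else stats::rbeta(n, shape[1L], shape[2L])
}

#' Generate a synthetic evidence study
#'
#' Draws the full study described by a [simulation_config()]: for each
#' dimension, every gene receives a raw p-value — sub-uniform for true
#' signals, Uniform(0, 1) otherwise. The expression dimension adds log2
#' fold changes centred at `fc_effect` in absolute value for signals and
#' near 0 otherwise; tissue-resolved dimensions emit one record per gene
#' per tissue; the methylation dimension emits 1 to `max_probes` probe
#' records per gene together with its probe-to-gene map.
#'
#' @param cfg A [simulation_config()].
#' @return List of class `"evidence_study"` with elements
#'   \describe{
#'     \item{tables}{named list of [evidence_table()] objects (for the
#'       probe-level dimension, a list with `probes` and `probe_map`).}
#'     \item{truth}{ground truth: `planted_genes`, `indicator` (genes x
#'       dimensions 0/1 true-signal matrix), `genes`.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
generate_evidence_study <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$rng_seed)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))
  planted <- sort(sample(genes, cfg$n_planted))
  rate <- ifelse(genes %in% planted, cfg$planted_hit_rate,
                 cfg$background_hit_rate)
  dn <- vapply(cfg$dimensions, `[[`, character(1L), "name")

  # shared latent indicator for tissue-resolved dimensions
  latent <- stats::rbinom(cfg$n_genes, 1L, rate)
  indicator <- matrix(0L, cfg$n_genes, length(dn),
                      dimnames = list(genes, dn))
  tables <- vector("list", length(dn))
  names(tables) <- dn
  for (j in seq_along(cfg$dimensions)) {
    dsc <- cfg$dimensions[[j]]
    tissues <- dsc$tissues
    own <- stats::rbinom(cfg$n_genes, 1L, rate)
    if (!is.null(tissues) && cfg$cross_tissue_latent) {
      use_latent <- stats::rbinom(cfg$n_genes, 1L, cfg$latent_share_prob) == 1L
      h <- ifelse(use_latent, latent, own)
    } else {
      h <- own
    }
    indicator[, j] <- h

    if (dsc$kind == "probe_level") {
      n_probes <- sample.int(cfg$max_probes, cfg$n_genes, replace = TRUE)
      probe_gene <- rep(genes, times = n_probes)
      probe_id <- sprintf("cg%07d", seq_along(probe_gene))
      p <- stats::runif(length(probe_gene))
      # the gene's first probe carries the signal p when the gene is a signal
      first <- c(1L, 1L + cumsum(n_probes))[seq_len(cfg$n_genes)]
      sig <- which(h == 1L)
      p[first[sig]] <- draw_signal_p(length(sig), cfg$signal_p_shape)
      tables[[j]] <- list(
        probes = data.frame(probe = probe_id, p = p, stringsAsFactors = FALSE),
        probe_map = data.frame(probe = probe_id, gene = probe_gene,
                               stringsAsFactors = FALSE))
    } else if (!is.null(tissues)) {
      nt <- length(tissues)
      act <- matrix(stats::rbinom(cfg$n_genes * nt, 1L, cfg$tissue_activation),
                    cfg$n_genes, nt)
      none <- rowSums(act) == 0L
      # force at least one active tissue so the union equals the indicator
      act[cbind(which(none), sample.int(nt, sum(none), replace = TRUE))] <- 1L
      act <- act * h
      p <- matrix(stats::runif(cfg$n_genes * nt), cfg$n_genes, nt)
      nsig <- sum(act == 1L)
      p[act == 1L] <- draw_signal_p(nsig, cfg$signal_p_shape)
      tables[[j]] <- evidence_table(
        gene = rep(genes, times = nt),
        p = as.vector(p),
        tissue = rep(tissues, each = cfg$n_genes),
        dimension = dsc$name)
    } else {
      p <- stats::runif(cfg$n_genes)
      sig <- which(h == 1L)
      p[sig] <- draw_signal_p(length(sig), cfg$signal_p_shape)
      if (dsc$kind == "pvalue_with_fc") {
        fc <- stats::rnorm(cfg$n_genes, 0, 0.1)
        fc[sig] <- sample(c(-1, 1), length(sig), replace = TRUE) *
          stats::rnorm(length(sig), cfg$fc_effect, 0.25)
        tables[[j]] <- evidence_table(genes, p, log2fc = fc,
                                      dimension = dsc$name)
      } else {
        tables[[j]] <- evidence_table(genes, p, dimension = dsc$name)
      }
    }
  }
  structure(list(tables = tables,
                 truth = list(planted_genes = planted,
                              indicator = indicator, genes = genes),
                 config = cfg),
            class = "evidence_study")
}

#' @export
print.evidence_study <- function(x, ...) {
  cat("Synthetic evidence study\n")
  print(x$config)
  cat("Dimensions:", paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate a binary evidence matrix directly
#'
#' The matrix-level view of the generator: per-dimension 0/1 labels are
#' drawn straight from the planted/background hit rates (each gene's
#' label in each dimension is an independent Bernoulli draw at its
#' rate), and the evidence-set restriction keeps genes with at least one
#' positive label. This is the ground-truth indicator the p-value layer
#' of [generate_evidence_study()] encodes, and is the right input for
#' studying the set optimizer in isolation.
#'
#' @param n_genes,n_planted Universe and planted-set sizes.
#' @param n_dimensions Number of evidence dimensions.
#' @param planted_hit_rate,background_hit_rate Label rates.
#' @param seed Integer RNG seed.
#' @param dimension_names Optional character vector of length
#'   `n_dimensions`.
#' @return List: `matrix` (an `"evidence_matrix"` restricted to genes
#'   with evidence), `truth` (`planted_genes`, full `indicator` matrix).
#' @export
simulate_binary_matrix <- function(n_genes = 1600L, n_planted = 200L,
                                   n_dimensions = 5L,
                                   planted_hit_rate = 0.6,
                                   background_hit_rate = 0.05,
                                   seed = 1L,
                                   dimension_names = NULL) {
  if (!(background_hit_rate >= 0 && background_hit_rate < planted_hit_rate &&
        planted_hit_rate <= 1)) {
    stop("need 0 <= background_hit_rate < planted_hit_rate <= 1")
  }
  if (is.null(dimension_names)) {
    dimension_names <- sprintf("dim%d", seq_len(n_dimensions))
  }
  set.seed(as.integer(seed))
  genes <- sprintf("G%05d", seq_len(n_genes))
  planted <- sort(sample(genes, n_planted))
  rate <- ifelse(genes %in% planted, planted_hit_rate, background_hit_rate)
  ind <- matrix(stats::rbinom(n_genes * n_dimensions, 1L, rep(rate, n_dimensions)),
                n_genes, n_dimensions,
                dimnames = list(genes, dimension_names))
  labels <- lapply(seq_len(n_dimensions),
                   function(j) stats::setNames(ind[, j], genes))
  names(labels) <- dimension_names
  list(matrix = build_es_matrix(labels),
       truth = list(planted_genes = planted, indicator = ind, genes = genes))
}

#' Generate a synthetic tissue expression panel
#'
#' Log-normal baseline expression with, in each tissue, a fraction of
#' genes up-shifted to make them tissue specific. Planted disease genes
#' are preferentially assigned specificity in the planted tissues, so a
#' query made of planted genes should rank those tissues first in TSEA.
#'
#' @param genes Character vector of gene symbols (the panel rows).
#' @param tissues Character vector of tissue names, or a count (named
#'   `tissue01`...).
#' @param frac_specific Fraction of genes made specific per tissue, in
#'   (0, 1); default 0.05.
#' @param planted_genes Genes to bias toward the planted tissues
#'   (optional).
#' @param planted_tissues Tissues receiving the planted genes' specific
#'   expression (must be among `tissues`).
#' @param planted_assign Fraction of planted genes assigned specificity
#'   in a planted tissue (default 0.8).
#' @param specific_shift Multiplicative up-shift for specific genes
#'   (default 50; genuinely tissue-restricted genes are expressed
#'   tens-fold above their level elsewhere, which keeps them at the top
#'   of the specificity ranking despite the log-normal baseline noise).
#' @param seed Integer RNG seed.
#' @return A [tissue_panel()] with attribute `"truth"`: the per-tissue
#'   assigned specific genes.
#' @export
generate_tissue_panel <- function(genes, tissues = 47L, frac_specific = 0.05,
                                  planted_genes = character(0),
                                  planted_tissues = character(0),
                                  planted_assign = 0.8,
                                  specific_shift = 50, seed = 1L) {
  if (is.numeric(tissues)) tissues <- sprintf("tissue%02d", seq_len(tissues))
  if (frac_specific <= 0 || frac_specific >= 1) {
    stop("'frac_specific' must lie in (0, 1)")
  }
  if (!all(planted_tissues %in% tissues)) {
    stop("'planted_tissues' must be a subset of 'tissues'")
  }
  genes <- toupper(trimws(genes))
  planted_genes <- intersect(toupper(trimws(planted_genes)), genes)
  set.seed(as.integer(seed))
  ng <- length(genes); nt <- length(tissues)
  expr <- matrix(stats::rlnorm(ng * nt, meanlog = 1, sdlog = 1), ng, nt,
                 dimnames = list(genes, tissues))
  n_spec <- max(1L, floor(ng * frac_specific))
  assigned <- stats::setNames(vector("list", nt), tissues)

  planted_pick <- character(0)
  if (length(planted_genes) > 0L && length(planted_tissues) > 0L) {
    planted_pick <- sample(planted_genes,
                           round(planted_assign * length(planted_genes)))
    home <- sample(planted_tissues, length(planted_pick), replace = TRUE)
    for (t in planted_tissues) {
      g <- planted_pick[home == t]
      expr[g, t] <- expr[g, t] * specific_shift
      assigned[[t]] <- g
    }
  }
  pool <- setdiff(genes, planted_pick)
  for (t in tissues) {
    need <- n_spec - length(assigned[[t]])
    if (need > 0L) {
      g <- sample(pool, min(need, length(pool)))
      expr[g, t] <- expr[g, t] * specific_shift
      assigned[[t]] <- sort(c(assigned[[t]], g))
    }
  }
  panel <- tissue_panel(expr)
  attr(panel, "truth") <- list(specific = assigned,
                               planted_tissues = planted_tissues,
                               planted_specific = sort(planted_pick))
  panel
}

#' Generate a synthetic interaction network with a planted module
#'
#' An Erdos-Renyi background over the node set with the edge probability
#' boosted inside a planted module, so the module is preferentially
#' interconnected. Every edge carries a Uniform(0, 1) confidence score.
#'
#' @param nodes Character vector of node symbols, or a count.
#' @param background_edge_p Edge probability between node pairs outside
#'   the module.
#' @param planted_module Character vector of module nodes (subset of
#'   `nodes`), possibly empty.
#' @param within_module_edge_p Edge probability inside the module; must
#'   satisfy `background_edge_p <= within_module_edge_p`, with strict
#'   inequality when a module is planted.
#' @param seed Integer RNG seed.
#' @return An [interaction_network()] with attribute `"truth"` (the
#'   module node set).
#' @export
generate_ppi_network <- function(nodes, background_edge_p = 0.01,
                                 planted_module = character(0),
                                 within_module_edge_p = 0.3, seed = 1L) {
  if (is.numeric(nodes)) nodes <- sprintf("G%05d", seq_len(nodes))
  nodes <- toupper(trimws(nodes))
  if (background_edge_p < 0 || background_edge_p > 1 ||
      within_module_edge_p < 0 || within_module_edge_p > 1) {
    stop("edge probabilities must lie in [0, 1]")
  }
  if (length(planted_module) > 0L &&
      background_edge_p >= within_module_edge_p) {
    stop("need background_edge_p < within_module_edge_p for a planted module")
  }
  planted_module <- intersect(toupper(trimws(planted_module)), nodes)
  set.seed(as.integer(seed))
  n <- length(nodes)
  in_mod <- nodes %in% planted_module
  ut <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  p <- ifelse(in_mod[ut[, 1L]] & in_mod[ut[, 2L]],
              within_module_edge_p, background_edge_p)
  hit <- stats::runif(nrow(ut)) < p
  edges <- data.frame(from = nodes[ut[hit, 1L]],
                      to = nodes[ut[hit, 2L]],
                      confidence = stats::runif(sum(hit)),
                      stringsAsFactors = FALSE)
  net <- interaction_network(edges, source = "synthetic")
  # isolated nodes are still part of the universe
  net$nodes <- sort(unique(c(net$nodes, nodes)))
  attr(net, "truth") <- list(planted_module = sort(planted_module))
  net
}
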