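#' Pipeline configuration
#'
#' Collects the inputs and parameters of a full analysis run into one
#' validated object. Evidence dimensions are described by a named list;
#' each entry gives the table path, its [threshold_rule()], and (for
#' probe-level data) the probe-to-gene map path. Optional inputs —
#' expression panel, interaction networks, drug-target list, gene-set
#' collection — switch their stages on; when absent the stage is skipped
#' with a notice and the rest of the analysis completes.
#'
#' @param evidence Named list; each element a list with `path`, `rule`
#'   (a [threshold_rule()]) and optionally `probe_map` (path).
#' @param panel Optional path to a tissue expression panel TSV.
#' @param ts_tissues Tissues defining the tissue-set gene pool (used
#'   with `panel`).
#' @param expr_min Expression cutoff for the tissue-set pool.
#' @param tsea_top_fraction Tissue-specific set size as a fraction of
#'   panel genes.
#' @param networks Optional named character vector of edge-list paths.
#' @param drug_targets Optional character vector of drug-target gene
#'   symbols (crosstalk runs against the first confidence-scored
#'   network).
#' @param collections Optional path to a GMT gene-set collection.
#' @param sizes Set-size grid for the MegaOR stage.
#' @param restarts Restarts per size.
#' @param min_freq Consensus frequency threshold (strict).
#' @param n_resamples Resamples for the PPI test.
#' @param min_confidence Crosstalk confidence cutoff (strict).
#' @param seed Master seed; all stage seeds are derived from it
#'   (MegaOR uses `seed`, the PPI test for network k uses
#'   `seed + 10000 + k`).
#' @param outdir Output directory (created if needed).
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(evidence, panel = NULL, ts_tissues = NULL,
                            expr_min = 1, tsea_top_fraction = 0.05,
                            networks = NULL, drug_targets = NULL,
                            collections = NULL,
                            sizes = c(150L, 190L, 230L, 270L, 310L, 350L, 390L, 430L),
                            restarts = 100L, min_freq = 0.5,
                            n_resamples = 10000L, min_confidence = 0.35,
                            seed = 1L, outdir = "megaor_out") {
  if (!is.list(evidence) || length(evidence) < 2L ||
      is.null(names(evidence)) || any(names(evidence) == "")) {
    stop("'evidence' must be a named list of at least two dimensions")
  }
  for (nm in names(evidence)) {
    e <- evidence[[nm]]
    if (is.null(e$path) || !file.exists(e$path)) {
      stop(sprintf("evidence dimension '%s': missing table file", nm))
    }
    if (!inherits(e$rule, "threshold_rule")) {
      stop(sprintf("evidence dimension '%s': 'rule' must be a threshold_rule", nm))
    }
    if (!is.null(e$probe_map) && !file.exists(e$probe_map)) {
      stop(sprintf("evidence dimension '%s': probe map not found", nm))
    }
  }
  for (p in c(panel, unname(networks), collections)) {
    if (!is.null(p) && !file.exists(p)) stop("input file not found: ", p)
  }
  structure(list(evidence = evidence, panel = panel,
                 ts_tissues = ts_tissues, expr_min = expr_min,
                 tsea_top_fraction = tsea_top_fraction,
                 networks = networks, drug_targets = drug_targets,
                 collections = collections, sizes = as.integer(sizes),
                 restarts = as.integer(restarts), min_freq = min_freq,
                 n_resamples = as.integer(n_resamples),
                 min_confidence = min_confidence,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full prioritization pipeline
#'
#' Executes, in order: probe collapse, per-dimension labelling (with
#' per-tissue BH adjustment and tissue-union merging), evidence-set
#' matrix construction, pairwise dimension association, tissue-set
#' matrix and TSEA (when a panel is configured), the MegaOR size grid
#' with consensus calling, PPI resampling tests, drug-target crosstalk
#' and gene-set enrichment (when their inputs are configured). All stage
#' tables are written under `config$outdir` with provenance headers, and
#' a JSON manifest records parameters, seeds and the output inventory.
#'
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with the in-memory stage results:
#'   `labels`, `es`, `pairwise`, `ts`, `tsea`, `grid`, `consensus`,
#'   `ppi`, `crosstalk`, `enrichment`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  chash <- config_hash(unclass(config))
  prov <- list(seed = config$seed, config = chash)
  outfile <- function(name) file.path(config$outdir, name)
  out <- list()

  labels <- stage("label", {
    lab <- list()
    for (nm in names(config$evidence)) {
      e <- config$evidence[[nm]]
      tab <- if (!is.null(e$probe_map)) {
        collapse_probes(read_tsv(e$path), read_tsv(e$probe_map),
                        dimension = nm)
      } else {
        read_evidence_table(e$path, dimension = nm)
      }
      lab[[nm]] <- if (!is.null(tab$tissue) && length(unique(tab$tissue)) > 1L) {
        merge_tissue_dimensions(lapply(split_tissues(tab), label_dimension,
                                       rule = e$rule))
      } else {
        label_dimension(tab, e$rule)
      }
    }
    lab
  })
  out$labels <- labels

  out$es <- stage("es_matrix", {
    es <- build_es_matrix(labels)
    write_evidence_matrix(es, outfile("es_matrix.tsv"), comments = prov)
    hist <- attr(es, "provenance")$evidence_count_histogram
    write_tsv(data.frame(lines_of_evidence = names(hist),
                         n_genes = as.integer(hist)),
              outfile("evidence_count_histogram.tsv"), comments = prov)
    es
  })

  out$pairwise <- stage("pairwise", {
    pw <- pairwise_dimension_association(out$es)
    write_tsv(data.frame(dimension = rownames(pw), pw, check.names = FALSE),
              outfile("pairwise_association.tsv"), comments = prov)
    pw
  })

  if (!is.null(config$panel)) {
    panel <- stage("panel", read_tissue_panel(config$panel))
    out$ts <- stage("ts_matrix", {
      if (is.null(config$ts_tissues)) NULL else {
        ts <- build_ts_matrix(out$es, panel, config$ts_tissues,
                              expr_min = config$expr_min)
        write_evidence_matrix(ts, outfile("ts_matrix.tsv"), comments = prov)
        ts
      }
    })
    out$tsea <- stage("tsea", {
      scores <- tissue_specificity_scores(panel)
      sets <- define_tissue_specific_sets(scores, config$tsea_top_fraction)
      res <- tsea_enrich(rownames(out$es), sets, rownames(panel$expr))
      write_tsv(as.data.frame(res), outfile("tsea_evidence_genes.tsv"),
                comments = prov)
      res
    })
  } else {
    message("run_pipeline: no expression panel configured; ",
            "TS-matrix and TSEA stages skipped")
  }

  out$grid <- stage("megaor", {
    sizes <- config$sizes[config$sizes < nrow(out$es)]
    if (length(sizes) == 0L) stop("all grid sizes exceed the matrix universe")
    grid <- megaor_grid(out$es, sizes, restarts = config$restarts,
                        seed = config$seed, min_freq = config$min_freq)
    for (s in names(grid$fits)) {
      f <- grid$fits[[s]]
      write_tsv(data.frame(gene = names(f$consensus$frequency),
                           frequency = f$consensus$frequency),
                outfile(sprintf("consensus_n%s.tsv", s)), comments = prov)
    }
    runs_json <- lapply(grid$fits, function(f) {
      lapply(f$runs, function(r) {
        list(seed = r$seed, n = r$n, cor = r$profile$cor,
             or = as.list(r$profile$or), iterations = r$iterations,
             converged = r$converged)
      })
    })
    jsonlite::write_json(runs_json, outfile("megaor_runs.json"),
                         auto_unbox = TRUE, digits = NA)
    write_tsv(data.frame(size = grid$sizes, grid$mean_or,
                         consensus_size = grid$consensus_sizes,
                         check.names = FALSE),
              outfile("megaor_size_summary.tsv"), comments = prov)
    grid
  })
  out$consensus <- out$grid$stable_consensus

  if (!is.null(config$networks)) {
    out$ppi <- stage("ppi_test", {
      res <- list()
      for (k in seq_along(config$networks)) {
        nm <- names(config$networks)[k]
        net <- read_edge_list(config$networks[[k]], source = nm)
        res[[nm]] <- ppi_resampling_test(net, out$consensus,
                                         n_resamples = config$n_resamples,
                                         seed = config$seed + 10000L + k)
      }
      jsonlite::write_json(
        lapply(res, function(r) list(V = r$V, E = r$E, p = r$p,
                                     n_resamples = r$n_resamples,
                                     seed = r$seed)),
        outfile("ppi_tests.json"), auto_unbox = TRUE, digits = NA)
      res
    })
    if (!is.null(config$drug_targets)) {
      out$crosstalk <- stage("crosstalk", {
        conf_nets <- Filter(function(p) {
          !is.null(read_edge_list(p)$edges$confidence)
        }, as.list(config$networks))
        if (length(conf_nets) == 0L) {
          message("run_pipeline: no confidence-scored network; crosstalk skipped")
          NULL
        } else {
          net <- read_edge_list(conf_nets[[1L]])
          ct <- drug_target_crosstalk(net, out$consensus,
                                      config$drug_targets,
                                      min_confidence = config$min_confidence)
          write_tsv(ct, outfile("drug_target_crosstalk.tsv"), comments = prov)
          ct
        }
      })
    }
  } else {
    message("run_pipeline: no interaction network configured; ",
            "PPI and crosstalk stages skipped")
  }

  if (!is.null(config$collections)) {
    out$enrichment <- stage("enrich", {
      sets <- read_gmt(config$collections)
      enr <- gene_set_enrichment(out$consensus, sets,
                                 background = rownames(out$es))
      write_tsv(enr, outfile("gene_set_enrichment.tsv"), comments = prov)
      enr
    })
  }

  out$manifest <- stage("manifest", {
    man <- list(package = "megaor",
                version = as.character(utils::packageVersion("megaor")),
                r_version = as.character(getRversion()),
                seed = config$seed, config_hash = chash,
                parameters = list(sizes = config$sizes,
                                  restarts = config$restarts,
                                  min_freq = config$min_freq,
                                  n_resamples = config$n_resamples,
                                  min_confidence = config$min_confidence),
                stable_size = out$grid$stable_size,
                n_consensus = length(out$consensus),
                outputs = setdiff(list.files(config$outdir),
                                  "manifest.json"))
    jsonlite::write_json(man, outfile("manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man
  })
  invisible(out)
}

#' Write a synthetic study to disk
#'
#' Materializes a generated study (and optional panel and network) in
#' the pipeline's input formats, plus a JSON truth manifest recording
#' the configuration, seed and planted genes — the synthetic counterpart
#' of assembling a study from exported association tables.
#'
#' @param study An `"evidence_study"` from [generate_evidence_study()].
#' @param dir Output directory (created if needed).
#' @param panel Optional [tissue_panel()] to write alongside.
#' @param network Optional [interaction_network()] to write alongside.
#' @return (Invisibly) named vector of written file paths.
#' @export
write_study <- function(study, dir, panel = NULL, network = NULL) {
  stopifnot(inherits(study, "evidence_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- study$config
  prov <- list(seed = cfg$rng_seed, config = config_hash(unclass(cfg)))
  paths <- c()
  for (nm in names(study$tables)) {
    tab <- study$tables[[nm]]
    if (is.list(tab) && !inherits(tab, "evidence_table")) {
      p1 <- file.path(dir, sprintf("%s_probes.tsv", nm))
      p2 <- file.path(dir, sprintf("%s_probe_map.tsv", nm))
      write_tsv(tab$probes, p1, comments = prov)
      write_tsv(tab$probe_map, p2, comments = prov)
      paths[sprintf("%s_probes", nm)] <- p1
      paths[sprintf("%s_probe_map", nm)] <- p2
    } else {
      p <- file.path(dir, sprintf("%s.tsv", nm))
      write_evidence_table(tab, p, comments = prov)
      paths[nm] <- p
    }
  }
  if (!is.null(panel)) {
    paths["panel"] <- file.path(dir, "tissue_panel.tsv")
    write_tissue_panel(panel, paths["panel"], comments = prov)
  }
  if (!is.null(network)) {
    paths["network"] <- file.path(dir, "ppi_edges.tsv")
    write_edge_list(network, paths["network"], comments = prov)
  }
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(seed = cfg$rng_seed,
         config = unclass(cfg)[setdiff(names(unclass(cfg)), "dimensions")],
         dimensions = lapply(cfg$dimensions, function(d) d),
         planted_genes = study$truth$planted_genes),
    truth_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths["truth"] <- truth_path
  invisible(paths)
}
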