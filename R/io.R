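# Flat-file I/O. Every writer prepends '# key: value' comment lines
# (at minimum the master seed and a config hash) so each output records
# its provenance; readers skip '#' lines.

fnv1a_hash <- function(x) {
  # 32-bit FNV-1a over the UTF-8 bytes of a string, as 8 hex digits.
  # Arithmetic kept in doubles and split into 16-bit halves so the
  # multiply never exceeds 2^53 (R has no native unsigned 32-bit type).
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b)
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  fnv1a_hash(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE))
}

#' Write a table as tab-separated text with provenance comments
#'
#' @param df `data.frame` to write.
#' @param path Output file.
#' @param comments Named character/list; each entry becomes a
#'   `# name: value` header line.
#' @export
write_tsv <- function(df, path, comments = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments) > 0L) {
    writeLines(sprintf("# %s: %s", names(comments),
                       vapply(comments, as.character, character(1L))), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table, skipping comment lines
#'
#' @param path Input file.
#' @return `data.frame`.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    quote = "", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a per-dimension evidence table from TSV
#'
#' Expected columns: `gene`, `p`, optionally `adj_p`, `log2fc` (or `fc`,
#' converted as `log2fc = log2(fc)`), `tissue`.
#'
#' @param path Input TSV.
#' @param dimension Dimension name; defaults to the file name sans
#'   extension.
#' @return An [evidence_table()].
#' @export
read_evidence_table <- function(path, dimension = NULL) {
  if (is.null(dimension)) {
    dimension <- sub("\\.[^.]*$", "", basename(path))
  }
  df <- read_tsv(path)
  if (!all(c("gene", "p") %in% names(df))) {
    stop(sprintf("'%s' lacks required columns 'gene' and 'p'", path))
  }
  log2fc <- df$log2fc
  if (is.null(log2fc) && !is.null(df$fc)) log2fc <- log2(df$fc)
  evidence_table(df$gene, df$p, adj_p = df$adj_p, log2fc = log2fc,
                 tissue = df$tissue, dimension = dimension)
}

#' Write an evidence table to TSV
#' @param table An [evidence_table()].
#' @param path Output file.
#' @param comments Provenance comments, see [write_tsv()].
#' @export
write_evidence_table <- function(table, path, comments = NULL) {
  stopifnot(inherits(table, "evidence_table"))
  write_tsv(as.data.frame(table), path,
            comments = c(list(dimension = attr(table, "dimension")), comments))
}

#' Write a binary evidence matrix to TSV
#' @param m An `"evidence_matrix"`.
#' @inheritParams write_evidence_table
#' @export
write_evidence_matrix <- function(m, path, comments = NULL) {
  stopifnot(inherits(m, "evidence_matrix"))
  df <- data.frame(gene = rownames(m), unclass(m)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, comments = comments)
}

#' Read a binary evidence matrix from TSV
#' @param path Input file (first column `gene`, remaining columns 0/1
#'   dimensions).
#' @return An `"evidence_matrix"`.
#' @export
read_evidence_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "integer"
  new_evidence_matrix(m, provenance = list(type = "file", path = path))
}

#' Write a tissue expression panel to TSV
#' @param panel A [tissue_panel()].
#' @inheritParams write_evidence_table
#' @export
write_tissue_panel <- function(panel, path, comments = NULL) {
  stopifnot(inherits(panel, "tissue_panel"))
  df <- data.frame(gene = rownames(panel$expr), panel$expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path, comments = comments)
}

#' Read a tissue expression panel from TSV
#' @param path Input file (first column `gene`, one column per tissue).
#' @return A [tissue_panel()].
#' @export
read_tissue_panel <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  tissue_panel(m)
}

#' Write a network edge list to TSV
#' @param net An [interaction_network()].
#' @inheritParams write_evidence_table
#' @export
write_edge_list <- function(net, path, comments = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  write_tsv(net$edges, path,
            comments = c(list(source = net$source), comments))
}

#' Read a network edge list from TSV
#'
#' Two columns (`from`, `to`) or three (plus `confidence`); header
#' optional column names `gene_a`/`gene_b` are also accepted.
#'
#' @param path Input file.
#' @param source Network label; defaults to the file name.
#' @return An [interaction_network()].
#' @export
read_edge_list <- function(path, source = NULL) {
  if (is.null(source)) source <- sub("\\.[^.]*$", "", basename(path))
  df <- read_tsv(path)
  names(df)[names(df) == "gene_a"] <- "from"
  names(df)[names(df) == "gene_b"] <- "to"
  interaction_network(df, source = source)
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated format: set name, description, then member
#' genes.
#'
#' @param path Input .gmt file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write a GMT gene-set collection
#' @param sets Named list of character vectors.
#' @param path Output .gmt file.
#' @export
write_gmt <- function(sets, path) {
  if (is.null(names(sets))) stop("'sets' must be named")
  fgsea::writeGmtPathways(sets, path)
  invisible(path)
}
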