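# Readers and writers for the external formats the pipeline touches:
# plain expression TSV, GEO series-matrix tables, two-column / BioGRID TAB
# edge lists, probe-to-gene collapsing, and network export (SIF / GraphML /
# edge TSV).

#' Read an expression matrix from a tab-separated file
#'
#' The file must have a header row of sample ids and gene ids in the first
#' column.  Samples without an entry in `group_spec` are dropped with a
#' warning; duplicated gene or sample ids and non-numeric cells are hard
#' errors.
#'
#' @param path Path to a TSV file.
#' @param group_spec Named character vector mapping sample id to group label.
#' @param allow_negative Permit negative values (log-scale input).
#' @return An [expression_matrix()].
#' @export
read_expression_tsv <- function(path, group_spec, allow_negative = FALSE) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "\"")
  .table_to_expression(tab, group_spec, allow_negative, path)
}

.table_to_expression <- function(tab, group_spec, allow_negative, path) {
  if (ncol(tab) < 2) stop("expression table needs a gene column and >= 1 sample: ", path)
  gid <- .strip_quotes(tab[[1]])
  sid <- .strip_quotes(colnames(tab)[-1])
  if (anyDuplicated(sid))
    stop("duplicate sample id in header: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (anyDuplicated(gid))
    stop("duplicate gene id: ", paste(unique(gid[duplicated(gid)]), collapse = ", "))
  vals <- matrix(NA_real_, nrow(tab), length(sid), dimnames = list(gid, sid))
  for (j in seq_along(sid)) {
    col <- suppressWarnings(as.numeric(.strip_quotes(tab[[j + 1L]])))
    bad <- which(is.na(col) & !is.na(tab[[j + 1L]]))
    if (length(bad))
      stop(sprintf("non-numeric value at gene '%s', sample '%s'", gid[bad[1]], sid[j]))
    vals[, j] <- col
  }
  known <- sid %in% names(group_spec)
  if (!all(known)) {
    warning(sum(!known), " sample(s) absent from group_spec dropped: ",
            paste(utils::head(sid[!known], 5), collapse = ", "))
    vals <- vals[, known, drop = FALSE]
    sid <- sid[known]
  }
  expression_matrix(vals, group_spec[sid], allow_negative = allow_negative)
}

.strip_quotes <- function(x) gsub('^"|"$', "", trimws(x))

#' Write an expression matrix as TSV
#' @param expr An `ExpressionMatrix`.
#' @param path Output path.
#' @param gene_col Name of the first (gene id) column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path, gene_col = "gene_id") {
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- gene_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GEO series-matrix file
#'
#' Parses the series-matrix dialect: `!`-prefixed metadata lines are ignored
#' and the expression table is delimited by the
#' `!series_matrix_table_begin` / `!series_matrix_table_end` markers.
#' Quoted ids are unquoted.
#'
#' @inheritParams read_expression_tsv
#' @return An [expression_matrix()].
#' @export
read_geo_series_matrix <- function(path, group_spec, allow_negative = FALSE) {
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
    stop("series-matrix table markers not found in ", path)
  block <- lines[(beg + 1L):(end - 1L)]
  tab <- utils::read.delim(text = block, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "\"")
  .table_to_expression(tab, group_spec, allow_negative, path)
}

#' Write an expression matrix in the GEO series-matrix dialect
#' @inheritParams write_expression_tsv
#' @return `path`, invisibly.
#' @export
write_geo_series_matrix <- function(expr, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("!Series_title\t\"synthetic expression series\"",
               "!series_matrix_table_begin"), con)
  header <- paste(c("\"ID_REF\"", sprintf('"%s"', colnames(expr$values))),
                  collapse = "\t")
  writeLines(header, con)
  body <- apply(expr$values, 1L, function(v) paste(v, collapse = "\t"))
  writeLines(paste(sprintf('"%s"', rownames(expr$values)), body, sep = "\t"), con)
  writeLines("!series_matrix_table_end", con)
  invisible(path)
}

#' Construct an undirected, deduplicated edge list
#'
#' Edges are stored in canonical order (`a <= b` lexicographically);
#' duplicates collapse and self-loops are dropped.
#'
#' @param a,b Character vectors of endpoint gene ids.
#' @param source Optional per-edge annotation (e.g. `"database"`, `"decoy"`).
#' @return A data.frame of class `EdgeList` with columns `a`, `b`, `source`.
#' @export
edge_list <- function(a, b, source = NULL) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b)) stop("endpoint vectors differ in length")
  if (is.null(source)) source <- rep(NA_character_, length(a))
  loop <- a == b
  if (any(loop)) message("dropped ", sum(loop), " self-loop(s)")
  a2 <- pmin(a[!loop], b[!loop])
  b2 <- pmax(a[!loop], b[!loop])
  src <- as.character(source)[!loop]
  key <- paste(a2, b2, sep = "\r")
  keep <- !duplicated(key)
  out <- data.frame(a = a2[keep], b = b2[keep], source = src[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EdgeList", "data.frame")
  out
}

#' Read a candidate PPI edge list
#'
#' Two dialects are supported: `two_column_tsv` (first two columns are the
#' endpoints; a header line is detected and skipped when its first field is
#' non-numeric and repeated nowhere as a gene) and `biogrid_tab` (BioGRID TAB
#' with official-symbol columns, restricted to rows whose two organism fields
#' both equal `taxon`).
#'
#' @param path Path to the edge file.
#' @param dialect `"two_column_tsv"` or `"biogrid_tab"`.
#' @param taxon NCBI taxon id both interactors must match (biogrid_tab only).
#' @param header Does a two-column file carry a header row?  Default `TRUE`.
#' @return An [edge_list()].
#' @export
read_edge_list <- function(path, dialect = c("two_column_tsv", "biogrid_tab"),
                           taxon = 9606, header = TRUE) {
  dialect <- match.arg(dialect)
  if (dialect == "two_column_tsv") {
    tab <- utils::read.delim(path, header = header, sep = "\t",
                             check.names = FALSE, colClasses = "character")
    if (ncol(tab) < 2) stop("two-column edge file needs >= 2 columns: ", path)
    edge_list(tab[[1]], tab[[2]])
  } else {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character",
                             comment.char = "")
    want <- c("Official Symbol Interactor A", "Official Symbol Interactor B",
              "Organism Interactor A", "Organism Interactor B")
    miss <- setdiff(want, colnames(tab))
    if (length(miss))
      stop("BioGRID TAB columns missing: ", paste(miss, collapse = ", "))
    ok <- tab[["Organism Interactor A"]] == as.character(taxon) &
      tab[["Organism Interactor B"]] == as.character(taxon)
    edge_list(tab[ok, want[1]], tab[ok, want[2]])
  }
}

#' Collapse probe-level rows to gene-level rows
#'
#' @param expr `ExpressionMatrix` whose rows are probe ids.
#' @param probe_map data.frame with columns `probe` and `gene` (many probes
#'   to one gene allowed; a probe must map to a single gene).
#' @param policy `"max_mean"` keeps, per gene, the probe with the highest mean
#'   intensity; `"mean"` averages all probes of a gene.
#' @return Gene-level `ExpressionMatrix`.
#' @export
collapse_probes <- function(expr, probe_map, policy = c("max_mean", "mean")) {
  policy <- match.arg(policy)
  pm <- data.frame(probe = as.character(probe_map$probe),
                   gene = as.character(probe_map$gene),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(pm$probe))
    stop("probe mapped to more than one gene: ",
         paste(unique(pm$probe[duplicated(pm$probe)]), collapse = ", "))
  probes <- rownames(expr$values)
  mapped <- probes %in% pm$probe
  if (!all(mapped))
    message("dropped ", sum(!mapped), " unmapped probe(s)")
  v <- expr$values[mapped, , drop = FALSE]
  gene <- pm$gene[match(rownames(v), pm$probe)]
  genes <- sort(unique(gene))
  out <- matrix(NA_real_, length(genes), ncol(v),
                dimnames = list(genes, colnames(v)))
  rmeans <- rowMeans(v)
  for (g in genes) {
    rows <- which(gene == g)
    if (policy == "mean" || length(rows) == 1L) {
      out[g, ] <- colMeans(v[rows, , drop = FALSE])
    } else {
      # deterministic: highest mean, ties broken by probe id order
      pick <- rows[order(-rmeans[rows], rownames(v)[rows])][1L]
      out[g, ] <- v[pick, ]
    }
  }
  expression_matrix(out, expr$groups, allow_negative = TRUE)
}

#' Export a fitted or differential network
#'
#' Writes an `AssociationModel` or `DifferenceNetwork` for downstream graph
#' tools (e.g. Cytoscape).  GraphML carries the rewiring score as a node
#' attribute and the signed coefficient difference as an edge attribute, so
#' positive and negative `d_ij` stay distinguishable; `edge_tsv` is a plain
#' table; `sif` is the minimal Cytoscape interaction format.  An empty
#' network yields a valid zero-edge file.
#'
#' @param x An `AssociationModel` or `DifferenceNetwork`.
#' @param path Output path.
#' @param format `"graphml"`, `"sif"`, or `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(x, path, format = c("graphml", "sif", "edge_tsv")) {
  format <- match.arg(format)
  ed <- network_edges(x)
  nodes <- network_nodes(x)
  if (format == "edge_tsv") {
    utils::write.table(ed, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  if (format == "sif") {
    rel <- ifelse(ed$weight >= 0, "pp", "pn")
    lines <- if (nrow(ed)) paste(ed$from, rel, ed$to, sep = "\t") else character()
    iso <- setdiff(nodes$id, unique(c(ed$from, ed$to)))
    writeLines(c(lines, iso), path)
    return(invisible(path))
  }
  g <- igraph::graph_from_data_frame(ed, directed = TRUE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Edge table of a network object
#' @param x `AssociationModel` or `DifferenceNetwork`.
#' @return data.frame with `from`, `to`, `weight` (alpha-hat or signed d_ij).
#' @export
network_edges <- function(x) UseMethod("network_edges")

#' @export
network_edges.AssociationModel <- function(x) {
  ed <- x$edges
  data.frame(from = ed$target, to = ed$neighbor, weight = ed$alpha,
             stringsAsFactors = FALSE)
}

#' @export
network_edges.DifferenceNetwork <- function(x) {
  # rows are independent target regressions, so entries are directed
  # target -> neighbor; both orientations may carry distinct d_ij
  idx <- which(x$D != 0, arr.ind = TRUE)
  g <- rownames(x$D)
  out <- data.frame(from = g[idx[, 1]], to = g[idx[, 2]],
                    weight = x$D[idx], stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}

#' Node table of a network object
#' @param x `AssociationModel` or `DifferenceNetwork`.
#' @return data.frame with node `id` plus score attributes.
#' @export
network_nodes <- function(x) UseMethod("network_nodes")

#' @export
network_nodes.AssociationModel <- function(x)
  data.frame(id = rownames(x$coef), stringsAsFactors = FALSE)

#' @export
network_nodes.DifferenceNetwork <- function(x) {
  out <- data.frame(id = rownames(x$D), srv = unname(x$srv),
                    stringsAsFactors = FALSE)
  if (!is.null(x$p)) out$p <- unname(x$p)
  out
}
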