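# Core containers
#
# Expression is a plain numeric matrix: rows = probes/genes (unique
# rownames), columns = samples (unique colnames), values = log2 intensity.
# Survival is a data.frame with columns sample/time/event plus optional
# covariates. A network is a list(nodes, edges) of class
# "interaction_network". Readers validate and reject rather than coerce.

#' Validate a log2 expression matrix
#'
#' @param values numeric matrix, probes in rows, samples in columns; rownames
#'   and colnames must be present and unique, all values finite.
#' @return the validated matrix (invisibly unchanged).
#' @export
expression_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_format("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_format("expression matrix needs probe rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop_format("duplicate probe ids: ",
                paste(head(unique(rownames(values)[duplicated(rownames(values))]), 3),
                      collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop_format("duplicate sample ids: ",
                paste(head(unique(colnames(values)[duplicated(colnames(values))]), 3),
                      collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop_format("non-finite expression value at row ", bad[1], ", col ", bad[2])
  }
  values
}

#' Construct a survival table
#'
#' @param sample character sample ids (unique).
#' @param time follow-up time in months, non-negative.
#' @param event event indicator, 0 = censored, 1 = event.
#' @param covariates optional data.frame of per-sample covariates.
#' @return data.frame of class `survival_data`.
#' @export
survival_data <- function(sample, time, event, covariates = NULL) {
  sample <- as.character(sample)
  if (anyDuplicated(sample)) stop_format("duplicate sample ids in survival table")
  time <- as.numeric(time); event <- as.numeric(event)
  if (length(time) != length(sample) || length(event) != length(sample))
    stop_format("survival columns have unequal lengths")
  if (any(!is.finite(time)) || any(time < 0)) stop_format("times must be finite and >= 0")
  if (!all(event %in% c(0, 1))) stop_format("event must be 0/1")
  out <- data.frame(sample = sample, time = time, event = event,
                    stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    if (nrow(covariates) != length(sample))
      stop_format("covariate rows do not match samples")
    out <- cbind(out, covariates)
  }
  class(out) <- c("survival_data", "data.frame")
  out
}

as_survival_data <- function(df) {
  need <- c("sample", "time", "event")
  if (!all(need %in% names(df)))
    stop_format("survival table must have columns: ", paste(need, collapse = ", "))
  survival_data(df$sample, df$time, df$event,
                covariates = df[setdiff(names(df), need)])
}

#' Construct an interaction network
#'
#' Simple undirected graph on gene symbols. Self-loops are dropped and
#' duplicate edges (in either orientation) deduplicated.
#'
#' @param edges two-column character matrix or data.frame of gene pairs.
#' @param nodes optional character vector of nodes (isolated nodes allowed);
#'   defaults to the union of edge endpoints.
#' @return list(nodes, edges) of class `interaction_network`; edges is a
#'   data.frame with columns `from`, `to`.
#' @export
interaction_network <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  if (length(edges) == 0) edges <- matrix(character(0), ncol = 2)
  storage.mode(edges) <- "character"
  loops <- edges[, 1] == edges[, 2]
  n_loops <- sum(loops)
  if (n_loops > 0) {
    message("dropped ", n_loops, " self-loop(s)")
    edges <- edges[!loops, , drop = FALSE]
  }
  # canonical orientation, then dedupe
  flip <- edges[, 1] > edges[, 2]
  edges[flip, ] <- edges[flip, 2:1]
  edges <- unique(edges)
  nodes <- sort(unique(c(nodes, as.vector(edges))))
  structure(list(nodes = nodes,
                 edges = data.frame(from = edges[, 1], to = edges[, 2],
                                    stringsAsFactors = FALSE)),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("interaction_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

# ---- readers ---------------------------------------------------------------

#' Read a log2 expression matrix (TSV or GCT 1.2)
#'
#' TSV: first column probe ids, header row of sample ids. GCT: `#1.2` line,
#' dims line, then NAME/Description columns before the samples.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`.
#' @return validated numeric matrix (probes x samples).
#' @export
read_expression <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("no such file: ", path)
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    probes <- as.character(df[[1]])
    body <- df[, -1, drop = FALSE]
  } else {
    header <- readLines(path, n = 2)
    if (length(header) < 2 || !startsWith(header[1], "#1.2"))
      stop_format("not a GCT 1.2 file: ", path)
    dims <- as.integer(strsplit(header[2], "\t")[[1]][1:2])
    df <- read.delim(path, skip = 2, check.names = FALSE, stringsAsFactors = FALSE)
    if (nrow(df) != dims[1] || ncol(df) - 2L != dims[2])
      stop_format("GCT declared dims ", dims[1], "x", dims[2],
                  " do not match body ", nrow(df), "x", ncol(df) - 2L)
    probes <- as.character(df[[1]])
    body <- df[, -(1:2), drop = FALSE]
  }
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop_format("non-numeric cell at row ", bad, ", column ", names(body)[j])
    }
  }
  m <- as.matrix(body)
  rownames(m) <- probes
  expression_matrix(m)
}

#' Write a log2 expression matrix
#'
#' @param expr matrix as from [read_expression()].
#' @param path output path.
#' @param format `"tsv"` or `"gct"`.
#' @export
write_expression <- function(expr, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  expr <- expression_matrix(expr)
  if (format == "tsv") {
    df <- data.frame(probe = rownames(expr), expr, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(expr), ncol(expr), sep = "\t")), con)
    df <- data.frame(NAME = rownames(expr), Description = "na", expr,
                     check.names = FALSE)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a survival table (TSV: sample, time, event, covariates...)
#' @param path file path.
#' @return `survival_data` data.frame.
#' @export
read_survival <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  as_survival_data(read.delim(path, stringsAsFactors = FALSE))
}

#' Write a survival table
#' @param surv `survival_data`.
#' @param path output path.
#' @export
write_survival <- function(surv, path) {
  write.table(surv, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an interaction network (edge list TSV or SIF)
#'
#' Edge TSV: two tab-separated gene symbols per line (header optional,
#' detected by a `from<TAB>to` first line). SIF: `node relation partner...`,
#' whitespace-separated; one edge per partner.
#'
#' @param path file path.
#' @param format `"edge_tsv"` or `"sif"`.
#' @return `interaction_network`.
#' @export
read_network <- function(path, format = c("edge_tsv", "sif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty network file: ", path)
    return(interaction_network(matrix(character(0), ncol = 2)))
  }
  if (format == "edge_tsv") {
    if (identical(tolower(strsplit(lines[1], "\t")[[1]][1:2]), c("from", "to")))
      lines <- lines[-1]
    parts <- strsplit(lines, "\t")
    bad <- which(vapply(parts, length, 1L) < 2L)
    if (length(bad)) stop_format("malformed edge line ", bad[1], " in ", path)
    edges <- t(vapply(parts, function(p) p[1:2], character(2)))
  } else {
    edges <- matrix(character(0), ncol = 2)
    for (i in seq_along(lines)) {
      tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
      if (length(tok) == 1) next  # isolated node line is legal SIF
      if (length(tok) < 3) stop_format("malformed SIF line ", i, " in ", path)
      edges <- rbind(edges, cbind(tok[1], tok[-(1:2)]))
    }
  }
  interaction_network(edges)
}

#' Write an interaction network as an edge-list TSV
#' @param net `interaction_network`.
#' @param path output path.
#' @export
write_network <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: name, description, then members, tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors, with a `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  short <- which(vapply(parts, length, 1L) < 3L)
  if (length(short)) stop_format("GMT line ", short[1], " has no members")
  nm <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(nm)) stop_format("duplicate gene-set name: ",
                                     nm[duplicated(nm)][1])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- setNames(vapply(parts, `[[`, "", 2), nm)
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a 2-column probe-to-gene mapping TSV
#' @param path file path (columns: probe, gene; header optional).
#' @return named character vector, `names` = probes, values = gene symbols.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop_input("no such file: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   header = FALSE, col.names = c("probe", "gene"))
  if (identical(tolower(df$probe[1]), "probe")) df <- df[-1, ]
  if (anyDuplicated(df$probe)) stop_format("duplicate probe in mapping")
  setNames(as.character(df$gene), as.character(df$probe))
}

#' Collapse probes to gene symbols
#'
#' Probes mapping to the same gene are combined: `"mean"` (arithmetic mean of
#' log2 values, used before subtype assignment) or `"max_var"` (keep the
#' highest-variance probe, used for network mapping).
#'
#' @param expr probe-level matrix.
#' @param probe_to_gene named character vector probe -> gene.
#' @param method `"mean"` or `"max_var"`.
#' @return gene-level expression matrix.
#' @export
collapse_to_genes <- function(expr, probe_to_gene, method = c("mean", "max_var")) {
  method <- match.arg(method)
  keep <- rownames(expr) %in% names(probe_to_gene)
  expr <- expr[keep, , drop = FALSE]
  if (nrow(expr) == 0) stop_input("no probes covered by the mapping")
  gene <- probe_to_gene[rownames(expr)]
  if (method == "mean") {
    m <- rowsum(expr, gene) / as.vector(table(gene)[sort(unique(gene))])
    return(m)
  }
  v <- apply(expr, 1, var)
  best <- vapply(split(seq_len(nrow(expr)), gene), function(idx)
    idx[which.max(v[idx])], 1L)
  m <- expr[best, , drop = FALSE]
  rownames(m) <- names(best)
  m
}
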