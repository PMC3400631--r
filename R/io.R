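#' Read a tab-delimited expression matrix
#'
#' Expects genes as rows and conditions as columns: a header row of condition
#' identifiers (first cell is the gene-id column name) and one row per gene
#' with the gene identifier in the first column. Lines starting with `#` are
#' metadata comments. Missing cells (`NA` or empty) are either rejected
#' (`impute = "none"`) or replaced by the row mean (`impute = "row_mean"`).
#'
#' @param path File path.
#' @param impute `"none"` (default) or `"row_mean"`.
#' @return Numeric matrix with gene row names and condition column names.
#' @export
read_expression_matrix <- function(path, impute = c("none", "row_mean")) {
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- count.fields(path, sep = "\t", comment.char = "#", quote = "")
  nf <- nf[!is.na(nf) & nf > 0L]
  if (length(nf) == 0L) stop("empty expression file: ", path)
  if (length(unique(nf)) != 1L) stop("ragged rows in ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE,
                   quote = "", colClasses = "character")
  if (ncol(df) < 2L) stop("expression file needs a gene-id column plus data columns")
  gene_ids <- as.character(df[[1L]])
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    lines <- which(gene_ids %in% dup)
    stop("duplicate gene id(s) ", paste(dup, collapse = ", "),
         " at data line(s) ", paste(lines, collapse = ", "))
  }
  condition_ids <- colnames(df)[-1L]
  if (anyDuplicated(condition_ids)) stop("duplicate condition id(s)")

  raw <- as.matrix(df[, -1L, drop = FALSE])
  missing <- is.na(raw) | raw == "" | raw == "NA"
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- !missing & is.na(vals)
  if (any(bad)) {
    i <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-numeric cell '", raw[bad][1L], "' for gene ", gene_ids[i[1L]],
         ", condition ", condition_ids[i[2L]])
  }
  if (any(missing)) {
    if (impute == "none") {
      stop(sum(missing), " missing cell(s); rerun with impute = \"row_mean\"",
           " or clean the file")
    }
    all_na <- rowSums(!is.na(vals)) == 0L
    if (any(all_na)) stop("all-missing row(s): ", paste(gene_ids[all_na], collapse = ", "))
    for (r in which(rowSums(is.na(vals)) > 0L)) {
      vals[r, is.na(vals[r, ])] <- mean(vals[r, ], na.rm = TRUE)
    }
    message("imputed ", sum(missing), " missing cell(s) by row mean")
  }
  dimnames(vals) <- list(gene_ids, condition_ids)
  validate_expression_matrix(vals)
}

validate_expression_matrix <- function(expr) {
  if (inherits(expr, "synthetic_dataset")) expr <- expr$expr
  expr <- as.matrix(expr)
  storage.mode(expr) <- "double"
  if (is.null(rownames(expr)) || anyDuplicated(rownames(expr))) {
    stop("expression matrix needs unique gene row names")
  }
  if (is.null(colnames(expr))) {
    colnames(expr) <- paste0("cond", seq_len(ncol(expr)))
  }
  if (!all(is.finite(expr))) stop("expression matrix has non-finite values")
  expr
}

#' Write an expression matrix as TSV
#'
#' @param expr Genes x conditions matrix with dimnames.
#' @param path Output path.
#' @param meta Named list written as `# key=value` header comments.
#' @export
write_expression_matrix <- function(expr, path, meta = list()) {
  expr <- validate_expression_matrix(expr)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(meta_header(meta), con)
  writeLines(paste(c("gene_id", colnames(expr)), collapse = "\t"), con)
  chr <- matrix(sprintf("%.17g", expr), nrow(expr), ncol(expr))
  write.table(cbind(rownames(expr), chr),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

meta_header <- function(meta = list()) {
  meta <- c(list(generator = paste0("dbomm ", as.character(utils::packageVersion("dbomm")))),
            meta)
  vapply(names(meta), function(k) paste0("# ", k, "=", meta[[k]]), character(1L))
}

#' Read a two-column TF -> target edge list as a reference network
#'
#' Tab-delimited with optional `#` comment lines and an optional header.
#' Edges are filtered to genes present in the expression matrix, self-loops
#' dropped and duplicates collapsed; every dropped count is reported so the
#' filtering is auditable.
#'
#' @param path File path.
#' @param expr Expression matrix defining the usable gene universe (optional;
#'   if omitted the universe is the edge endpoints).
#' @return A [reference_network()].
#' @export
read_reference_network <- function(path, expr = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no edges in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("malformed edge line(s) in ", path)
  df <- data.frame(tf = vapply(parts, `[[`, "", 1L),
                   target = vapply(parts, `[[`, "", 2L),
                   stringsAsFactors = FALSE)
  if (identical(tolower(df$tf[1L]), "tf") ||
      identical(tolower(df$tf[1L]), "regulator")) {
    df <- df[-1L, , drop = FALSE]
  }
  n0 <- nrow(df)
  if (!is.null(expr)) {
    expr <- validate_expression_matrix(expr)
    keep <- df$tf %in% rownames(expr) & df$target %in% rownames(expr)
    if (n_drop <- sum(!keep)) {
      message("dropped ", n_drop, " edge(s) with gene(s) absent from the expression matrix")
    }
    df <- df[keep, , drop = FALSE]
  }
  n_self <- sum(df$tf == df$target)
  if (n_self > 0L) message("dropped ", n_self, " self-regulation edge(s)")
  df <- df[df$tf != df$target, , drop = FALSE]
  n_dup <- nrow(df) - nrow(unique(df))
  if (n_dup > 0L) message("collapsed ", n_dup, " duplicate edge(s)")
  df <- unique(df)
  if (nrow(df) == 0L) stop("no edges remain after filtering ", path)
  genes <- if (is.null(expr)) NULL else rownames(expr)
  suppressMessages(reference_network(df, genes = genes))
}

#' Write dependency scores as TSV
#'
#' Columns: `gene_a`, `gene_b`, `method`, `score`, `n_components_joint`,
#' `n_components_x`, `n_components_y` (component columns empty for non-model
#' methods), preceded by `# key=value` metadata comments recording at least
#' the method and orientation.
#'
#' @param scores A `dependency_scores` object.
#' @param path Output path.
#' @param meta Extra metadata entries.
#' @export
write_scores <- function(scores, path, meta = list()) {
  stopifnot(inherits(scores, "dependency_scores"))
  meta <- c(list(method = attr(scores, "method"),
                 orientation = attr(scores, "orientation")), meta)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(meta_header(meta), con)
  out <- data.frame(gene_a = scores$gene_a, gene_b = scores$gene_b,
                    method = attr(scores, "method"),
                    score = sprintf("%.10g", scores$score),
                    n_components_joint = int_or_blank(scores$n_components_joint),
                    n_components_x = int_or_blank(scores$n_components_x),
                    n_components_y = int_or_blank(scores$n_components_y),
                    stringsAsFactors = FALSE)
  writeLines(paste(colnames(out), collapse = "\t"), con)
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

int_or_blank <- function(x) ifelse(is.na(x), "", as.character(x))

#' Read a scores TSV written by [write_scores()]
#'
#' @param path File path.
#' @return A `dependency_scores` object.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read_meta(path)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE, quote = "")
  need <- c("gene_a", "gene_b", "score")
  if (!all(need %in% colnames(df))) stop("not a scores file: ", path)
  method <- if (!is.null(meta$method)) meta$method else unique(df$method)[1L]
  out <- data.frame(gene_a = as.character(df$gene_a),
                    gene_b = as.character(df$gene_b),
                    score = as.numeric(df$score),
                    n_components_joint = suppressWarnings(as.integer(df$n_components_joint)),
                    n_components_x = suppressWarnings(as.integer(df$n_components_x)),
                    n_components_y = suppressWarnings(as.integer(df$n_components_y)),
                    stringsAsFactors = FALSE)
  structure(out, method = method, orientation = measure_orientation(method),
            class = c("dependency_scores", "data.frame"))
}

read_meta <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[grepl("^#", lines)]
  kv <- regmatches(lines, regexec("^#\\s*([^=]+)=(.*)$", lines))
  kv <- kv[lengths(kv) == 3L]
  out <- lapply(kv, `[[`, 3L)
  names(out) <- vapply(kv, function(m) trimws(m[[2L]]), character(1L))
  out
}

#' Write a precision-recall curve as TSV
#'
#' @param curve A [pr_curve()] result.
#' @param path Output path.
#' @param meta Extra metadata entries.
#' @export
write_pr_curve <- function(curve, path, meta = list()) {
  stopifnot(inherits(curve, "pr_curve"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(meta_header(c(list(method = attr(curve, "method"),
                                n_real = attr(curve, "n_real"),
                                n_scored = attr(curve, "n_scored")), meta)), con)
  writeLines(paste(colnames(curve), collapse = "\t"), con)
  write.table(curve, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write an inferred network as a TSV edge list (optionally SIF)
#'
#' @param network Data frame from [infer_network()].
#' @param path Output path.
#' @param format `"tsv"` (tf, target, score columns) or `"sif"`
#'   (`tf regulates target`).
#' @param meta Extra metadata entries.
#' @export
write_edges <- function(network, path, format = c("tsv", "sif"), meta = list()) {
  format <- match.arg(format)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (format == "tsv") {
    writeLines(meta_header(meta), con)
    writeLines("tf\ttarget\tscore", con)
    if (nrow(network) > 0L) {
      write.table(data.frame(network$tf, network$target,
                             sprintf("%.10g", network$score)),
                  con, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
  } else {
    if (nrow(network) > 0L) {
      writeLines(paste(network$tf, "regulates", network$target, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Write a synthetic dataset to disk
#'
#' Expression TSV, gold-standard edge TSV, and a JSON sidecar echoing the
#' generator parameters and seed so the dataset can be regenerated
#' bit-identically.
#'
#' @param ds A `synthetic_dataset`.
#' @param prefix Output path prefix; writes `<prefix>_expr.tsv`,
#'   `<prefix>_gold_edges.tsv`, `<prefix>_params.json`.
#' @return The three paths, invisibly.
#' @export
write_dataset <- function(ds, prefix) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  p_expr <- paste0(prefix, "_expr.tsv")
  p_edges <- paste0(prefix, "_gold_edges.tsv")
  p_json <- paste0(prefix, "_params.json")
  meta <- list(seed = ds$seed, noise_level = ds$noise_level)
  write_expression_matrix(ds$expr, p_expr, meta = meta)
  con <- file(p_edges, open = "wt")
  writeLines(c(meta_header(meta), "tf\ttarget"), con)
  write.table(ds$gold_edges, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  close(con)
  jsonlite::write_json(
    list(seed = ds$seed, noise_level = ds$noise_level,
         n_genes = nrow(ds$expr), tfs = ds$tfs,
         params = ds$params[setdiff(names(ds$params), "genes")]),
    p_json, auto_unbox = TRUE, digits = NA)
  invisible(c(expr = p_expr, edges = p_edges, params = p_json))
}
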