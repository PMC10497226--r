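#' Read a delimited numeric matrix
#'
#' TSV or CSV with a header row of variable names; the separator is
#' auto-detected from the header line.
#'
#' @param path File path.
#' @param expected_role Optional label (`"Y"`, `"X"`, `"U"`, `"W"`)
#'   used in error messages.
#' @return Numeric matrix with column names.
#' @export
read_matrix <- function(path, expected_role = NULL) {
  role <- if (is.null(expected_role)) basename(path) else expected_role
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  if (anyDuplicated(names(df))) {
    stop(sprintf("%s: duplicate column names", role))
  }
  if (!all(vapply(df, is.numeric, logical(1)))) {
    stop(sprintf("%s: non-numeric cells", role))
  }
  as.matrix(df)
}

#' Read a data set (Y and X) from delimited files
#'
#' @param y_path,x_path Paths to the primary- and intervention-variable
#'   matrices.
#' @return A [new_dataset()].
#' @export
read_dataset <- function(y_path, x_path) {
  Y <- read_matrix(y_path, "Y")
  X <- read_matrix(x_path, "X")
  if (nrow(Y) != nrow(X)) {
    stop(sprintf("row counts differ between %s (%d) and %s (%d)",
                 y_path, nrow(Y), x_path, nrow(X)))
  }
  new_dataset(Y, X)
}

#' Write a numeric matrix as TSV with a header
#'
#' @param m Matrix.
#' @param path Output path.
#' @export
write_matrix <- function(m, path) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize graph edges to TSV
#'
#' Columns `src_kind` (`Y` or `X`), `src_index`, `dst_index`, 1-based.
#'
#' @param g An [intervention_dag()] or [ancestral_graph()].
#' @param path Output path.
#' @export
write_edges <- function(g, path) {
  if (inherits(g, "intervention_dag")) {
    pe <- g$primary_edges; ie <- g$intervention_edges
  } else if (inherits(g, "ancestral_graph")) {
    pe <- g$ancestral_edges; ie <- g$candidate_intervention_edges
  } else stop("write_edges: unsupported object")
  df <- rbind(
    if (nrow(pe) > 0L) data.frame(src_kind = "Y", src_index = pe[, 1L],
                                  dst_index = pe[, 2L]),
    if (nrow(ie) > 0L) data.frame(src_kind = "X", src_index = ie[, 1L],
                                  dst_index = ie[, 2L]))
  if (is.null(df)) df <- data.frame(src_kind = character(0),
                                    src_index = integer(0),
                                    dst_index = integer(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read graph edges from TSV
#'
#' @param path File written by [write_edges()].
#' @param p,q Dimensions of the graph.
#' @param as `"dag"` or `"arg"`.
#' @return An [intervention_dag()] or [ancestral_graph()].
#' @export
read_edges <- function(path, p, q, as = c("dag", "arg")) {
  as <- match.arg(as)
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "integer", "integer"))
  pe <- as.matrix(df[df$src_kind == "Y", c("src_index", "dst_index")])
  ie <- as.matrix(df[df$src_kind == "X", c("src_index", "dst_index")])
  if (as == "dag") intervention_dag(p, q, pe, ie)
  else ancestral_graph(p, q, pe, ie)
}

#' Parse a hypothesis string
#'
#' `"k>j"` pairs separated by commas specify an edge hypothesis;
#' [parse_pathway()] expands `"a>b>c"` into consecutive-pair edges of a
#' pathway hypothesis. `format_hypothesis()` inverts both.
#'
#' @param s String such as `"1>3,2>3"`.
#' @return A [hypothesis_spec()].
#' @export
parse_hypothesis <- function(s) {
  parts <- strsplit(trimws(strsplit(s, ",")[[1]]), ">")
  edges <- do.call(rbind, lapply(parts, function(x) as.integer(x[1:2])))
  if (anyNA(edges)) stop("parse_hypothesis: expected 'k>j[,k>j...]'")
  hypothesis_spec(edges, mode = "edge")
}

#' @rdname parse_hypothesis
#' @export
parse_pathway <- function(s) {
  nodes <- as.integer(strsplit(trimws(s), ">")[[1]])
  if (length(nodes) < 2L || anyNA(nodes)) {
    stop("parse_pathway: expected 'a>b>c...'")
  }
  hypothesis_spec(cbind(nodes[-length(nodes)], nodes[-1L]), mode = "pathway")
}

#' @rdname parse_hypothesis
#' @param h A [hypothesis_spec()].
#' @export
format_hypothesis <- function(h) {
  if (h$mode == "pathway") {
    paste(c(h$edges[, 1L], h$edges[nrow(h$edges), 2L]), collapse = ">")
  } else {
    paste(sprintf("%d>%d", h$edges[, 1L], h$edges[, 2L]), collapse = ",")
  }
}

#' Write a test report (JSON) with its graph edge lists
#'
#' Writes `<path>.json` holding the statistics, p-value, classification,
#' replicate counts and configuration echo, plus `<path>_arg.tsv` with
#' the estimated ancestral relations, and optionally a DOT rendering of
#' the graph with hypothesized edges annotated.
#'
#' @param report A `dp_test_report`.
#' @param path Output path prefix.
#' @param dot Also write `<path>.dot`.
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, path, dot = FALSE) {
  stopifnot(inherits(report, "dp_test_report"))
  cls <- report$classification
  obj <- list(
    mode = report$mode,
    method = report$method,
    hypothesis_degenerate = cls$degenerate,
    hypothesis_regular = cls$regular,
    nondegenerate_edges = apply(cls$nondegenerate_edges, 1L,
                                function(e) sprintf("%d>%d", e[1], e[2])),
    lr = report$lr,
    pvalue = report$pvalue,
    M_total = report$M_total,
    M_valid = report$M_valid,
    alpha = report$alpha,
    seed = report$seed,
    reject = report$reject)
  if (!is.null(report$per_edge)) obj$per_edge <- report$per_edge
  json_path <- paste0(path, ".json")
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  if (!is.null(report$arg)) {
    write_edges(report$arg, paste0(path, "_arg.tsv"))
    if (dot) write_dot(report$arg, report, paste0(path, ".dot"))
  }
  invisible(json_path)
}

## DOT rendering of an ARG with hypothesized edges annotated.
write_dot <- function(arg, report, path) {
  h <- report$classification$nondegenerate_edges
  lines <- c("digraph arg {",
             sprintf("  Y%d -> Y%d;", arg$ancestral_edges[, 1L],
                     arg$ancestral_edges[, 2L]),
             if (nrow(h) > 0L)
               sprintf("  Y%d -> Y%d [style=dashed, color=red];",
                       h[, 1L], h[, 2L]),
             "}")
  writeLines(lines, path)
  invisible(path)
}
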