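#' Read a directed weighted edge list
#'
#' Reads a plain-text edge list with one edge per line: `source target weight`
#' and, with `has_distance = TRUE`, a fourth `distance` column. Fields are
#' tab- (or whitespace-) separated; lines starting with `#` and blank lines
#' are ignored. Node identifiers are kept as opaque strings in
#' first-appearance order.
#'
#' Self-loops are dropped with a warning (the edge clustering coefficient and
#' the local relative density are degenerate for them). Duplicate ordered
#' pairs are aggregated by summing their weights (distances are averaged),
#' with a warning.
#'
#' @param path Path to the edge-list file.
#' @param has_distance Logical; if `TRUE` a fourth per-edge geometric
#'   distance column is read into the `distance` edge attribute.
#' @return A directed [igraph::igraph] with a positive `weight` edge
#'   attribute (and `distance` if requested).
#' @seealso [write_edge_list()], [compute_lengths()]
#' @export
read_edge_list <- function(path, has_distance = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty edge list: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[ \t]+")
  ncol_need <- if (has_distance) 4L else 3L
  nf <- lengths(fields)
  if (any(nf < ncol_need))
    stop("line ", lineno[which(nf < ncol_need)[1L]], ": expected at least ",
         ncol_need, " fields", call. = FALSE)
  src <- vapply(fields, `[[`, "", 1L)
  dst <- vapply(fields, `[[`, "", 2L)
  w <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(!is.finite(w) | w <= 0)
  if (length(bad))
    stop("line ", lineno[bad[1L]], ": weight must be a positive number",
         call. = FALSE)
  d <- NULL
  if (has_distance) {
    d <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
    bad <- which(!is.finite(d) | d < 0)
    if (length(bad))
      stop("line ", lineno[bad[1L]], ": distance must be a non-negative number",
           call. = FALSE)
  }

  # node order = first appearance (sources and targets interleaved by line)
  nodes <- unique(as.vector(rbind(src, dst)))

  loops <- src == dst
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
    src <- src[!loops]; dst <- dst[!loops]
    w <- w[!loops]; if (!is.null(d)) d <- d[!loops]
  }

  key <- paste(src, dst, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate edge(s) aggregated by weight sum",
            call. = FALSE)
    first <- !duplicated(key)
    w <- as.vector(tapply(w, factor(key, levels = key[first]), sum))
    if (!is.null(d))
      d <- as.vector(tapply(d, factor(key, levels = key[first]), mean))
    src <- src[first]; dst <- dst[first]
  }

  if (length(src) == 0L) {
    warning("no edges remain after filtering", call. = FALSE)
    return(igraph::make_empty_graph(n = 0, directed = TRUE) +
             igraph::vertices(nodes))
  }

  el <- data.frame(from = src, to = dst, weight = w, stringsAsFactors = FALSE)
  if (!is.null(d)) el$distance <- d
  igraph::graph_from_data_frame(el, directed = TRUE,
                                vertices = data.frame(name = nodes))
}

#' Write a directed weighted edge list
#'
#' Inverse of [read_edge_list()]: tab-separated `source target weight`
#' (`distance` appended when present), preceded by `#`-comment header lines.
#'
#' @param g Directed weighted graph.
#' @param path Output file path.
#' @param header Character vector of comment lines written (each prefixed
#'   with `"# "`) before the data.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path, header = character()) {
  .check_dwgraph(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  df <- data.frame(from = el[, 1L], to = el[, 2L],
                   weight = igraph::E(g)$weight, stringsAsFactors = FALSE)
  if (!is.null(igraph::E(g)$distance)) df$distance <- igraph::E(g)$distance
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste("#", header), con)
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read or write a partition file
#'
#' Partition files are tab-separated `node cluster` rows where cluster ids
#' are 0-based integers in generator order; `#` lines are comments. In R the
#' partition is a named integer membership vector with 1-based cluster
#' indices (the file writer converts).
#'
#' @param path File path.
#' @return For `read_partition()`, a named integer vector of 1-based cluster
#'   memberships.
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.table(path, header = FALSE, sep = "\t", comment.char = "#",
                   col.names = c("node", "cluster"),
                   colClasses = c("character", "integer"))
  if (nrow(df) == 0L) stop("empty partition file: ", path, call. = FALSE)
  if (anyDuplicated(df$node))
    stop("duplicated node(s) in partition file", call. = FALSE)
  setNames(df$cluster + 1L, df$node)
}

#' @rdname read_partition
#' @param membership Named integer vector of 1-based cluster memberships, or
#'   a `voronoi_partition` object.
#' @param header Character vector of comment lines for the file header.
#' @export
write_partition <- function(membership, path, header = character()) {
  membership <- as_membership(membership)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste("#", header), con)
  write.table(data.frame(names(membership), unname(membership) - 1L),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
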