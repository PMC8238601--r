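#' Table dialect for delimited text inputs
#'
#' @param delimiter single-character field separator.
#' @param header logical; if `TRUE` the first non-comment row is skipped.
#' @param comment_prefix lines starting with this prefix are skipped before
#'   parsing.
#' @return list of class `table_dialect`.
#' @export
table_dialect <- function(delimiter = "\t", header = FALSE, comment_prefix = "#") {
  if (!is.character(delimiter) || length(delimiter) != 1L || nchar(delimiter) != 1L) {
    stop("delimiter must be a single character")
  }
  structure(list(delimiter = delimiter, header = isTRUE(header),
                 comment_prefix = comment_prefix),
            class = "table_dialect")
}

# read a delimited file into a list of character-vector rows, keeping the
# original 1-based line number of each row for error messages
read_rows <- function(path, dialect) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lineno <- seq_along(lines)
  keep <- !startsWith(lines, dialect$comment_prefix) & nzchar(trimws(lines))
  lines <- lines[keep]; lineno <- lineno[keep]
  if (dialect$header && length(lines)) {
    lines <- lines[-1L]; lineno <- lineno[-1L]
  }
  list(fields = strsplit(lines, dialect$delimiter, fixed = TRUE), lineno = lineno)
}

normalize_symbol <- function(x) toupper(trimws(x))

#' Read a protein-protein interaction edge list
#'
#' Reads a two-column delimited file of gene symbols. Pairs are returned
#' exactly as read (no deduplication, no reordering); symbols are
#' whitespace-trimmed and uppercased. Extra columns beyond the first two are
#' ignored.
#'
#' @param path file path.
#' @param dialect a [table_dialect()]; default tab-separated, no header.
#' @return data.frame with character columns `from` and `to`; zero rows for an
#'   empty file.
#' @export
read_edge_list <- function(path, dialect = table_dialect()) {
  rows <- read_rows(path, dialect)
  nf <- lengths(rows$fields)
  bad <- which(nf < 2L)
  if (length(bad)) {
    stop("malformed edge row (need >= 2 columns) at line ",
         rows$lineno[bad[1]], " of ", path)
  }
  if (!length(rows$fields)) {
    return(data.frame(from = character(), to = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    from = normalize_symbol(vapply(rows$fields, `[[`, "", 1L)),
    to = normalize_symbol(vapply(rows$fields, `[[`, "", 2L)),
    stringsAsFactors = FALSE
  )
}

#' Read disease genes with relevance scores
#'
#' Two-column delimited file: gene symbol, nonnegative relevance score (the
#' disease-association weight attached to each pathogenic gene).
#'
#' @inheritParams read_edge_list
#' @return data.frame with columns `symbol` (uppercased) and `relevance_score`.
#' @export
read_disease_genes <- function(path, dialect = table_dialect()) {
  rows <- read_rows(path, dialect)
  nf <- lengths(rows$fields)
  bad <- which(nf < 2L)
  if (length(bad)) {
    stop("malformed disease-gene row at line ", rows$lineno[bad[1]], " of ", path)
  }
  if (!length(rows$fields)) {
    return(data.frame(symbol = character(), relevance_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  score <- suppressWarnings(as.numeric(vapply(rows$fields, `[[`, "", 2L)))
  if (anyNA(score)) {
    stop("non-numeric relevance score at line ", rows$lineno[which(is.na(score))[1]],
         " of ", path)
  }
  if (any(score < 0)) stop("negative relevance score in ", path)
  data.frame(symbol = normalize_symbol(vapply(rows$fields, `[[`, "", 1L)),
             relevance_score = score, stringsAsFactors = FALSE)
}

#' Read component-target associations
#'
#' Two-column delimited file: component id, target gene symbol. Component ids
#' are trimmed but never uppercased (they live in their own namespace, e.g.
#' `EXD8`-style codes); target symbols are trimmed and uppercased.
#'
#' @inheritParams read_edge_list
#' @return data.frame with columns `component` and `target`.
#' @export
read_associations <- function(path, dialect = table_dialect()) {
  rows <- read_rows(path, dialect)
  nf <- lengths(rows$fields)
  bad <- which(nf < 2L)
  if (length(bad)) {
    stop("malformed association row at line ", rows$lineno[bad[1]], " of ", path)
  }
  if (!length(rows$fields)) {
    return(data.frame(component = character(), target = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(component = trimws(vapply(rows$fields, `[[`, "", 1L)),
             target = normalize_symbol(vapply(rows$fields, `[[`, "", 2L)),
             stringsAsFactors = FALSE)
}

#' Read a component property table
#'
#' Delimited file with columns: component id, name, herbs (herb codes
#' separated by `;`), MW (Da), OB (percent), Caco2, DL, and optionally
#' include_listed (0/1 or TRUE/FALSE). Missing ADME values may be written as
#' `NA` or left empty.
#'
#' @inheritParams read_edge_list
#' @return data.frame of component records (see [component_records()]).
#' @export
read_components <- function(path, dialect = table_dialect()) {
  rows <- read_rows(path, dialect)
  nf <- lengths(rows$fields)
  bad <- which(nf < 7L)
  if (length(bad)) {
    stop("malformed component row (need >= 7 columns) at line ",
         rows$lineno[bad[1]], " of ", path)
  }
  if (!length(rows$fields)) return(component_records(data.frame()))
  f <- function(i) vapply(rows$fields, function(r) if (length(r) >= i) r[[i]] else "", "")
  num <- function(x) suppressWarnings(as.numeric(x))
  inc <- if (any(nf >= 8L)) {
    v <- trimws(f(8))
    v %in% c("1", "TRUE", "true", "T", "yes")
  } else rep(FALSE, length(rows$fields))
  component_records(data.frame(
    id = trimws(f(1)), name = trimws(f(2)), herbs = trimws(f(3)),
    mw = num(f(4)), ob = num(f(5)), caco2 = num(f(6)), dl = num(f(7)),
    include_listed = inc, stringsAsFactors = FALSE
  ))
}

#' Read a GMT gene-set file
#'
#' Broad-standard GMT: each row is `term-id <TAB> description <TAB> gene1
#' <TAB> ...`. Duplicate genes within a set are collapsed; empty sets and
#' duplicate term ids are rejected.
#'
#' @param path file path.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  rows <- read_rows(path, table_dialect("\t", header = FALSE, comment_prefix = "#"))
  nf <- lengths(rows$fields)
  bad <- which(nf < 3L)
  if (length(bad)) {
    stop("GMT row with fewer than 3 fields at line ", rows$lineno[bad[1]], " of ", path)
  }
  ids <- vapply(rows$fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate GMT term id: ", ids[duplicated(ids)][1])
  }
  sets <- lapply(rows$fields, function(r) {
    genes <- unique(normalize_symbol(r[-(1:2)]))
    genes[nzchar(genes)]
  })
  if (any(lengths(sets) == 0L)) {
    stop("empty gene set in GMT row at line ", rows$lineno[which(lengths(sets) == 0L)[1]])
  }
  names(sets) <- ids
  desc <- vapply(rows$fields, `[[`, "", 2L)
  names(desc) <- ids
  gene_set_collection(sets, descriptions = desc)
}

#' Write a gene-set collection to GMT
#' @param collection a [gene_set_collection()]
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a typed network as SIF plus a node-attribute table
#'
#' Writes `<path>.sif` (one row per undirected edge, `A <relation> B`, with
#' endpoints in lexicographic order and each edge written once) and
#' `<path>.nodes.tsv` (columns `id`, `role`, `weight`). [read_network()] on
#' the same prefix reproduces an equal network.
#'
#' @param net a `typed_network`
#' @param path output path prefix (without extension).
#' @return character vector of the two file paths, invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(is_typed_network(net))
  sif <- paste0(path, ".sif")
  ntsv <- paste0(path, ".nodes.tsv")
  edges <- network_edges(net)
  writeLines(sprintf("%s\t%s\t%s", edges$from, edges$relation, edges$to), sif)
  nodes <- network_nodes(net)
  utils::write.table(nodes, ntsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(sif, ntsv))
}

#' Read a typed network written by [write_network()]
#' @param path path prefix used at write time.
#' @return a `typed_network`.
#' @export
read_network <- function(path) {
  sif <- paste0(path, ".sif")
  ntsv <- paste0(path, ".nodes.tsv")
  nodes <- utils::read.table(ntsv, sep = "\t", header = TRUE,
                             colClasses = c("character", "character", "numeric"))
  lines <- readLines(sif, warn = FALSE)
  lines <- lines[nzchar(lines)]
  edges <- if (length(lines)) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 3L)) stop("malformed SIF row in ", sif)
    data.frame(from = vapply(parts, `[[`, "", 1L),
               relation = vapply(parts, `[[`, "", 2L),
               to = vapply(parts, `[[`, "", 3L), stringsAsFactors = FALSE)
  } else NULL
  typed_network(nodes, edges)
}

#' Write a network summary as JSON
#' @param net a `typed_network`
#' @param path output path
#' @return `path`, invisibly.
#' @export
write_network_summary <- function(net, path) {
  jsonlite::write_json(network_summary(net), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
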