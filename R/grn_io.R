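# Reading/writing signed regulatory networks and the transcription-unit
# (operon) pre-collapse.

#' Default effect-token dialect
#'
#' Maps common edge-type tokens found in regulatory-network edge lists to the
#' canonical effect levels.
#'
#' @export
default_dialect <- function() {
  c("+" = "activation", "-" = "repression", "+-" = "dual", "-+" = "dual",
    "dual" = "dual", "activation" = "activation", "repression" = "repression",
    "activator" = "activation", "repressor" = "repression")
}

#' Read a signed regulatory network from a TSV edge list
#'
#' Expects at least three tab-separated columns: source, target, effect
#' token. Lines starting with `#` are ignored; a header line is detected when
#' its third field is not a known token. Node identifiers are normalized to
#' lowercase so that gene-name capitalization variants (crp vs CRP) refer to
#' one node. Exact duplicate rows are dropped with one warning each; the same
#' regulator pair may appear with different effects and all are kept as
#' distinct typed edges.
#'
#' @param path path to the edge-list file
#' @param dialect named character vector mapping effect tokens to
#'   [EFFECTS] values; defaults to [default_dialect()]
#' @return a [signed_digraph]
#' @export
read_grn_edge_list <- function(path, dialect = default_dialect()) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) return(signed_digraph())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("line ", lineno[which(nf < 3L)[1L]],
         ": fewer than 3 tab-separated columns (source, target, effect)")
  }
  src <- tolower(trimws(vapply(fields, `[[`, "", 1L)))
  tgt <- tolower(trimws(vapply(fields, `[[`, "", 2L)))
  tok <- trimws(vapply(fields, `[[`, "", 3L))
  # header detection: first row with an unknown token made of label-like words
  is_header <- FALSE
  if (!(tok[1L] %in% names(dialect) || tolower(tok[1L]) %in% names(dialect))) {
    hdr <- tolower(c(src[1L], tgt[1L], tok[1L]))
    if (any(hdr %in% c("source", "target", "effect", "regulator", "gene",
                       "tf", "from", "to", "sign", "type"))) {
      is_header <- TRUE
    }
  }
  if (is_header) {
    src <- src[-1L]; tgt <- tgt[-1L]; tok <- tok[-1L]; lineno <- lineno[-1L]
  }
  eff <- unname(dialect[tok])
  miss <- is.na(eff)
  if (any(miss)) {
    eff2 <- unname(dialect[tolower(tok)])
    eff[miss] <- eff2[miss]
  }
  if (anyNA(eff)) {
    i <- which(is.na(eff))[1L]
    stop("line ", lineno[i], ": unknown effect token ", dQuote(tok[i]))
  }
  key <- paste(src, tgt, eff, sep = "\r")
  dup <- duplicated(key)
  for (i in which(dup)) {
    warning("duplicate edge dropped at line ", lineno[i], ": ",
            src[i], " -> ", tgt[i], " (", eff[i], ")", call. = FALSE)
  }
  signed_digraph(data.frame(source = src[!dup], target = tgt[!dup],
                            effect = eff[!dup], stringsAsFactors = FALSE))
}

#' Read a gene-to-transcription-unit map
#'
#' Two-column TSV `gene<TAB>tu`; `#` comments and an optional header are
#' ignored. Identifiers are lowercased.
#'
#' @param path path to the TSV file
#' @return named character vector: names are genes, values transcription units
#' @export
read_tu_map <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) return(stats::setNames(character(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) stop("TU map lines need 2 columns gene<TAB>tu")
  g <- tolower(trimws(vapply(fields, `[[`, "", 1L)))
  u <- tolower(trimws(vapply(fields, `[[`, "", 2L)))
  if (g[1L] %in% c("gene", "name") || u[1L] %in% c("tu", "unit", "operon")) {
    g <- g[-1L]; u <- u[-1L]
  }
  if (anyDuplicated(g)) {
    stop("gene(s) mapped to more than one TU: ",
         paste(unique(g[duplicated(g)]), collapse = ", "))
  }
  stats::setNames(u, g)
}

#' Collapse genes into transcription-unit nodes
#'
#' Genes in the same transcription unit (operon genes under the same
#' promoters) are transcribed together and form trivially synchronized sets,
#' so they are merged into a single node before the fibration analysis. An
#' edge (TU_s, TU_t, effect) exists in the result iff some member gene pair
#' carried that typed edge; regulation within one TU becomes a self-loop.
#' Genes absent from the map are kept as their own TU.
#'
#' @param graph a [signed_digraph] over gene identifiers
#' @param tumap named character vector gene -> TU (see [read_tu_map])
#' @return list with `graph` (the TU-level [signed_digraph]) and `node_map`
#'   (named character vector gene -> TU actually used)
#' @export
collapse_transcription_units <- function(graph, tumap) {
  stopifnot_digraph(graph)
  node_map <- stats::setNames(graph$nodes, graph$nodes)
  hit <- graph$nodes %in% names(tumap)
  node_map[hit] <- unname(tumap[graph$nodes[hit]])
  e <- graph$edges
  if (nrow(e)) {
    e$source <- unname(node_map[e$source])
    e$target <- unname(node_map[e$target])
    key <- paste(e$source, e$target, e$effect, sep = "\r")
    e <- e[!duplicated(key), , drop = FALSE]
  }
  list(graph = signed_digraph(e, nodes = unique(unname(node_map))),
       node_map = node_map)
}

#' Write a network to disk
#'
#' Formats: `"edge-list"` (TSV with `+`/`-`/`+-` effect tokens; round-trips
#' through [read_grn_edge_list]), `"graphml"` (via igraph; vertex attribute
#' `label`, edge attribute `effect`) and `"dot"` (Graphviz export; activation
#' edges are plain arrows, repression uses `arrowhead=tee`, dual edges are
#' `arrowhead=diamond, style=dashed`).
#'
#' @param graph a [signed_digraph]
#' @param path output file path
#' @param format one of `"edge-list"`, `"graphml"`, `"dot"`
#' @export
write_network <- function(graph, path,
                          format = c("edge-list", "graphml", "dot")) {
  stopifnot_digraph(graph)
  format <- match.arg(format)
  if (format == "edge-list") {
    tok <- c(activation = "+", repression = "-", dual = "+-")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# source\ttarget\teffect", con)
    if (nrow(graph$edges)) {
      writeLines(paste(graph$edges$source, graph$edges$target,
                       tok[graph$edges$effect], sep = "\t"), con)
    }
    # isolated nodes are not representable in an edge list; note them
    iso <- setdiff(graph$nodes, c(graph$edges$source, graph$edges$target))
    if (length(iso)) {
      writeLines(paste0("# isolated: ", paste(iso, collapse = ",")), con)
    }
  } else if (format == "graphml") {
    ig <- as_igraph(graph)
    igraph::V(ig)$label <- igraph::V(ig)$name
    igraph::write_graph(ig, path, format = "graphml")
  } else {
    style <- c(activation = "",
               repression = " [arrowhead=tee]",
               dual = " [arrowhead=diamond, style=dashed]")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("digraph grn {", con)
    for (v in graph$nodes) writeLines(sprintf("  \"%s\";", v), con)
    if (nrow(graph$edges)) {
      writeLines(sprintf("  \"%s\" -> \"%s\"%s;", graph$edges$source,
                         graph$edges$target, style[graph$edges$effect]), con)
    }
    writeLines("}", con)
  }
  invisible(path)
}

#' Read a network written by [write_network]
#'
#' @param path file path
#' @param format `"edge-list"` or `"graphml"`
#' @return a [signed_digraph]
#' @export
read_network <- function(path, format = c("edge-list", "graphml")) {
  format <- match.arg(format)
  if (format == "edge-list") {
    read_grn_edge_list(path)
  } else {
    from_igraph(igraph::read_graph(path, format = "graphml"))
  }
}
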