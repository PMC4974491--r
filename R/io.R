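#' Read / write a probe-by-sample matrix as TSV
#'
#' Matrices are stored with probe IDs in the first column (`probe_id`) and
#' sample IDs as the remaining column names.
#'
#' @param x Numeric matrix with dimnames.
#' @param path File path.
#' @return `write_matrix_tsv()` returns `path` invisibly;
#'   `read_matrix_tsv()` returns the matrix.
#' @export
write_matrix_tsv <- function(x, path) {
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read / write gene-set collections in GMT format
#'
#' One set per line: name, description, then tab-separated member genes.
#' Duplicate members within a line are removed; duplicated set names are
#' suffixed `.1`, `.2`, ... deterministically; empty sets are skipped with a
#' warning.
#'
#' @param path File path.
#' @param db SignatureDB tibble (`set`, `gene`, optional `description`).
#' @return `read_gmt()` returns a tibble (`set`, `description`, `gene`);
#'   `write_gmt()` returns `path` invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  empty <- lengths(parts) < 3
  if (any(empty)) warning(sum(empty), " empty GMT line(s) skipped")
  parts <- parts[!empty]
  nm <- vapply(parts, `[`, "", 1)
  dup <- stats::ave(seq_along(nm), nm, FUN = seq_along)
  nm <- ifelse(dup > 1, paste0(nm, ".", dup - 1), nm)
  purrr::map2_dfr(parts, nm, function(p, name) {
    tibble::tibble(set = name, description = p[2],
                   gene = unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  })
}

#' @rdname read_gmt
#' @export
write_gmt <- function(db, path) {
  if (!"description" %in% names(db)) db$description <- "NA"
  lines <- vapply(split(db, db$set), function(d) {
    paste(c(d$set[1], d$description[1], unique(d$gene)), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write ontology structure in (minimal) OBO format
#'
#' Only the graph structure is handled: `id`, `name`, `is_a` and
#' `relationship: part_of` lines of `[Term]` stanzas.
#'
#' @param path File path.
#' @param onto Ontology list (`terms`, `edges`), see [simulate_ontology()].
#' @return `read_obo()` returns the ontology list; `write_obo()` returns
#'   `path` invisibly.
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  terms <- tibble::tibble(id = character(), name = character())
  edges <- tibble::tibble(child = character(), parent = character(),
                          relation = character())
  cur <- NULL
  in_term <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") { in_term <- TRUE; cur <- NULL; next }
    if (grepl("^\\[", ln)) { in_term <- FALSE; next }
    if (!in_term || !nzchar(ln)) next
    if (startsWith(ln, "id:")) {
      cur <- trimws(sub("^id:", "", ln))
      terms <- dplyr::bind_rows(terms, tibble::tibble(id = cur, name = NA_character_))
    } else if (startsWith(ln, "name:") && !is.null(cur)) {
      terms$name[terms$id == cur] <- trimws(sub("^name:", "", ln))
    } else if (startsWith(ln, "is_a:") && !is.null(cur)) {
      parent <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        child = cur, parent = parent, relation = "is_a"))
    } else if (startsWith(ln, "relationship:") && !is.null(cur)) {
      rel <- strsplit(trimws(sub("!.*$", "", sub("^relationship:", "", ln))),
                      "\\s+")[[1]]
      if (length(rel) >= 2 && rel[1] == "part_of") {
        edges <- dplyr::bind_rows(edges, tibble::tibble(
          child = cur, parent = rel[2], relation = "part_of"))
      }
    }
  }
  list(terms = terms, edges = edges)
}

#' @rdname read_obo
#' @export
write_obo <- function(onto, path) {
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(onto$terms))) {
    id <- onto$terms$id[i]
    stanza <- c("[Term]", paste("id:", id), paste("name:", onto$terms$name[i]))
    ed <- onto$edges[onto$edges$child == id, ]
    for (j in seq_len(nrow(ed))) {
      stanza <- c(stanza, if (ed$relation[j] == "is_a") {
        paste("is_a:", ed$parent[j])
      } else {
        paste("relationship:", ed$relation[j], ed$parent[j])
      })
    }
    out <- c(out, stanza, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read / write gene annotations in GAF 2.x column layout
#'
#' Seventeen tab-separated columns; only DB object symbol (column 3) and GO
#' ID (column 5) are interpreted, the rest are written as `NA`. Comment
#' lines start with `!`.
#'
#' @param path File path.
#' @param annot Annotation tibble (`gene`, `term`).
#' @return `read_gaf()` returns the annotation tibble; `write_gaf()` returns
#'   `path` invisibly.
#' @export
read_gaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble::tibble(gene = vapply(parts, `[`, "", 3),
                 term = vapply(parts, `[`, "", 5))
}

#' @rdname read_gaf
#' @export
write_gaf <- function(annot, path) {
  row <- function(gene, term) {
    fields <- rep("NA", 17)
    fields[1] <- "ascnet"; fields[2] <- gene; fields[3] <- gene
    fields[5] <- term; fields[4] <- ""
    paste(fields, collapse = "\t")
  }
  writeLines(c("!gaf-version: 2.2",
               mapply(row, annot$gene, annot$term, USE.NAMES = FALSE)), path)
  invisible(path)
}

#' Write a partition (with connectivity) as TSV
#'
#' @param partition Partition tibble (any columns; typically `probe`,
#'   `module`, `color`, `k_within`).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_partition_tsv <- function(partition, path) {
  utils::write.table(partition, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an edge list with node attributes as GEXF
#'
#' Nodes carry `module_color` and `betweenness` attributes; edges carry
#' their TOM weight. Suitable for import into graph-visualization tools.
#'
#' @param edges Edge tibble (`from`, `to`, `weight`).
#' @param nodes Node tibble (`probe`, `color`, `betweenness`).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_gexf <- function(edges, nodes, path) {
  doc <- xml2::xml_new_root("gexf",
                            xmlns = "http://www.gexf.net/1.2draft",
                            version = "1.2")
  graph <- xml2::xml_add_child(doc, "graph", defaultedgetype = "undirected")
  attrs <- xml2::xml_add_child(graph, "attributes", class = "node")
  xml2::xml_add_child(attrs, "attribute", id = "0", title = "module_color",
                      type = "string")
  xml2::xml_add_child(attrs, "attribute", id = "1", title = "betweenness",
                      type = "double")
  nodes_el <- xml2::xml_add_child(graph, "nodes")
  for (i in seq_len(nrow(nodes))) {
    nd <- xml2::xml_add_child(nodes_el, "node", id = nodes$probe[i],
                              label = nodes$probe[i])
    av <- xml2::xml_add_child(nd, "attvalues")
    xml2::xml_add_child(av, "attvalue", "for" = "0", value = nodes$color[i])
    xml2::xml_add_child(av, "attvalue", "for" = "1",
                        value = format(nodes$betweenness[i]))
  }
  edges_el <- xml2::xml_add_child(graph, "edges")
  for (i in seq_len(nrow(edges))) {
    xml2::xml_add_child(edges_el, "edge", id = as.character(i - 1),
                        source = edges$from[i], target = edges$to[i],
                        weight = format(edges$weight[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
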