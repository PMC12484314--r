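# Serialization: extended Newick (with #H hybrid tags) and JSON edge lists.

#' Read a network from an extended Newick string
#'
#' Plain Newick parses to a tree (r = 0). Reticulations use the shared-node
#' `#H<tag>` dialect: each hybrid tag must appear exactly twice, and its
#' child subtree is attached at exactly one of the two occurrences, e.g.
#' `"((1,(2)#H1),(#H1,3));"` is a network whose single reticulation has the
#' leaf labeled 2 as its child. The ancestral root edge is implicit in the
#' Newick text and restored on read.
#'
#' @param text a single extended Newick string, terminated by `;`.
#' @return A valid `phylo_network`.
#' @examples
#' read_enewick("((1,2),3);")
#' read_enewick("((1,(2)#H1),(#H1,3));")
#' @export
read_enewick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]", "", text)
  if (!nzchar(s) || substr(s, nchar(s), nchar(s)) != ";")
    stop("parse error: input must end with ';'")
  s <- substr(s, 1, nchar(s) - 1L)
  chars <- strsplit(s, "")[[1]]
  pos <- 1L
  n_nodes <- 0L
  edges <- character(0)   # interleaved parent/child pairs
  hybrids <- list()       # tag -> vector of node ids
  new_node <- function() {
    n_nodes <<- n_nodes + 1L
    paste0("v", n_nodes)
  }
  labels <- integer(0)
  peek <- function() if (pos <= length(chars)) chars[pos] else ""
  fail <- function(msg) stop(sprintf("parse error at position %d: %s", pos, msg))
  read_name <- function() {
    start <- pos
    while (pos <= length(chars) && !(chars[pos] %in% c("(", ")", ",", ";")))
      pos <<- pos + 1L
    paste(chars[start:(pos - 1L)], collapse = "")
  }
  parse_node <- function() {
    if (peek() == "(") {
      pos <<- pos + 1L
      kids <- list(parse_node())
      while (peek() == ",") {
        pos <<- pos + 1L
        kids[[length(kids) + 1L]] <- parse_node()
      }
      if (peek() != ")") fail("expected ')' or ','")
      pos <<- pos + 1L
      name <- if (!(peek() %in% c("(", ")", ",", "", ";"))) read_name() else ""
      id <- new_node()
      for (k in kids) edges <<- c(edges, id, k)
      if (startsWith(name, "#"))
        hybrids[[name]] <<- c(hybrids[[name]], id)
      id
    } else {
      if (peek() %in% c(")", ",", "")) fail("expected a label or '('")
      name <- read_name()
      id <- new_node()
      if (startsWith(name, "#")) {
        hybrids[[name]] <<- c(hybrids[[name]], id)
      } else {
        lab <- suppressWarnings(as.integer(name))
        if (is.na(lab)) fail(sprintf("leaf label '%s' is not an integer", name))
        labels[id] <<- lab
      }
      id
    }
  }
  top <- parse_node()
  if (pos <= length(chars)) fail("trailing characters after complete tree")
  em <- matrix(edges, ncol = 2, byrow = TRUE)
  # merge each hybrid tag's occurrences into one vertex
  for (tag in names(hybrids)) {
    occ <- hybrids[[tag]]
    if (length(occ) != 2L)
      stop(sprintf("hybrid tag '%s' used %d time(s); must appear exactly twice",
                   tag, length(occ)))
    keep <- occ[1]; drop <- occ[2]
    em[em == drop] <- keep
  }
  root <- "rho"
  em <- rbind(em, c(root, top))
  if (anyDuplicated(labels[!is.na(labels)]) > 0)
    stop("duplicate leaf labels in Newick input")
  net <- phylo_network(em, labels[!is.na(labels)], validate = FALSE)
  rep <- validate_network(net)
  if (length(rep) > 0)
    stop("Newick input is not a valid binary network: ",
         paste(rep, collapse = "; "))
  net
}

#' Write a network as a canonical extended Newick string
#'
#' Output is deterministic: equivalent networks (identical up to renaming of
#' internal vertex ids) produce identical strings. Children are emitted in
#' canonical order; each reticulation receives a `#H<k>` tag numbered in
#' traversal order, with its child subtree attached at the first occurrence.
#' The ancestral root edge is implicit and not serialized.
#'
#' @param net a valid `phylo_network`.
#' @return A single extended Newick string.
#' @examples
#' write_enewick(read_enewick("((3,1),2);"))
#' @export
write_enewick <- function(net) {
  .stop_if_invalid(net)
  ix <- .net_index(net)
  if (any(ix$kind == "retic")) {
    ord <- .canonicalize(ix)$order
    key <- integer(ix$nv)
    key[ord] <- seq_len(ix$nv)
  } else {
    # subtree-code order is canonical for trees
    code <- character(ix$nv)
    for (v in rev(ix$topo)) {
      code[v] <- if (ix$kind[v] == "leaf") as.character(ix$labels[v]) else
        paste0("(", paste(sort(code[ix$children[[v]]]), collapse = ","), ")")
    }
    key <- rank(code, ties.method = "first")
  }
  tag_of <- integer(ix$nv)
  n_tags <- 0L
  emit <- function(v) {
    if (ix$kind[v] == "leaf") return(as.character(ix$labels[v]))
    if (ix$kind[v] == "retic") {
      if (tag_of[v] == 0L) {
        n_tags <<- n_tags + 1L
        tag_of[v] <<- n_tags
        return(paste0("(", emit(ix$children[[v]][1]), ")#H", tag_of[v]))
      }
      return(paste0("#H", tag_of[v]))
    }
    ch <- ix$children[[v]]
    ch <- ch[order(key[ch])]
    paste0("(", paste(vapply(ch, emit, character(1)), collapse = ","), ")")
  }
  root_child <- ix$children[[which(ix$kind == "root")]][1]
  paste0(emit(root_child), ";")
}

#' Read / write a network as a JSON edge-list document
#'
#' The document has the schema
#' `{"vertices": [{"id": ..., "label": ...}, ...], "edges": [[parent, child], ...]}`
#' with labels present only on leaves. Round-trips losslessly (up to
#' equivalence) and validates on read.
#'
#' @param doc a JSON string, a file path to one, or an already-parsed list.
#' @return `read_edgelist`: a valid `phylo_network`.
#' @examples
#' doc <- write_edgelist(read_enewick("(1,2);"))
#' read_edgelist(doc)
#' @export
read_edgelist <- function(doc) {
  if (is.character(doc) && length(doc) == 1L) {
    doc <- jsonlite::fromJSON(doc, simplifyVector = FALSE)
  }
  if (!is.list(doc) || is.null(doc$vertices) || is.null(doc$edges))
    stop("edge-list document must have 'vertices' and 'edges' fields")
  ids <- vapply(doc$vertices, function(v) as.character(v$id), character(1))
  if (anyDuplicated(ids)) stop("edge-list document: vertex ids must be unique")
  labs <- lapply(doc$vertices, function(v) v$label)
  has_lab <- !vapply(labs, is.null, logical(1))
  labels <- stats::setNames(as.integer(unlist(labs[has_lab])), ids[has_lab])
  if (anyDuplicated(labels)) stop("edge-list document: duplicate leaf labels")
  em <- do.call(rbind, lapply(doc$edges, function(e) {
    if (length(e) != 2) stop("edge-list document: each edge must be a pair")
    c(as.character(e[[1]]), as.character(e[[2]]))
  }))
  if (!all(c(em) %in% ids))
    stop("edge-list document: edge endpoint not among vertex ids")
  net <- phylo_network(em, labels, validate = FALSE)
  rep <- validate_network(net)
  if (length(rep) > 0)
    stop("edge-list document is not a valid binary network: ",
         paste(rep, collapse = "; "))
  net
}

#' @rdname read_edgelist
#' @param net a valid `phylo_network`.
#' @return `write_edgelist`: a JSON string.
#' @export
write_edgelist <- function(net) {
  .stop_if_invalid(net)
  ix <- .net_index(net)
  verts <- lapply(seq_len(ix$nv), function(v) {
    if (ix$kind[v] == "leaf")
      list(id = ix$ids[v], label = ix$labels[v])
    else list(id = ix$ids[v])
  })
  edges <- lapply(seq_len(nrow(net$edges)), function(i)
    c(net$edges[i, 1], net$edges[i, 2]))
  jsonlite::toJSON(list(vertices = verts, edges = edges), auto_unbox = TRUE)
}
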