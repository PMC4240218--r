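#' Write a persistent perfect phylogeny as annotated Newick
#'
#' Edge gain/loss labels are encoded as node comments
#' (`[&gains=c1,losses=c2]`) and species assignments as node names, with
#' `|` separating species that share a node; the round trip through
#' [read_cppp_newick()] is lossless up to the node state vectors, which
#' are recomputed from the edge labels at verification time.
#'
#' @param tree a `"cppp_phylo"`.
#' @param path optional output file; when `NULL` the string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_cppp_newick <- function(tree, path = NULL) {
  nn <- length(tree$parent)
  children <- lapply(seq_len(nn), function(i) which(tree$parent == i))
  node_str <- function(i) {
    kids <- children[[i]]
    sub <- if (length(kids))
      paste0("(", paste(vapply(kids, node_str, character(1)),
                        collapse = ","), ")")
    else ""
    sp <- names(tree$species_node)[tree$species_node == i]
    name <- paste(sp, collapse = "|")
    ann <- character(0)
    if (length(tree$edge_gains[[i]]))
      ann <- c(ann, paste0("gains=",
                           paste(tree$edge_gains[[i]], collapse = "|")))
    if (length(tree$edge_losses[[i]]))
      ann <- c(ann, paste0("losses=",
                           paste(tree$edge_losses[[i]], collapse = "|")))
    comment <- if (length(ann))
      paste0("[&", paste(ann, collapse = ","), "]") else ""
    paste0(sub, name, comment)
  }
  s <- paste0(node_str(1L), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Read an annotated Newick tree
#'
#' Parses the format written by [write_cppp_newick()]. Node state vectors
#' are not stored in Newick; they are rebuilt from the gain/loss
#' annotations when the tree is verified against a matrix.
#'
#' @param x a Newick string or a file path.
#' @return a `"cppp_phylo"` with `labels = NULL` (filled lazily).
#' @export
read_cppp_newick <- function(x) {
  s <- if (file.exists(x)) paste(readLines(x), collapse = "") else x
  s <- gsub("[[:space:]]", "", s)
  s <- sub(";$", "", s)
  env <- new.env(parent = emptyenv())
  env$pos <- 1L
  env$parent <- integer(0)
  env$gains <- list()
  env$losses <- list()
  env$names <- character(0)
  peek <- function() substr(s, env$pos, env$pos)
  advance <- function() env$pos <- env$pos + 1L
  new_node <- function(p) {
    env$parent <- c(env$parent, p)
    id <- length(env$parent)
    env$gains[[id]] <- character(0)
    env$losses[[id]] <- character(0)
    env$names[id] <- ""
    id
  }
  parse_node <- function(p) {
    id <- new_node(p)
    if (peek() == "(") {
      advance()
      repeat {
        parse_node(id)
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        stop("malformed Newick near position ", env$pos)
      }
    }
    # name
    start <- env$pos
    while (env$pos <= nchar(s) && !peek() %in% c("(", ")", ",", "[", ";"))
      advance()
    env$names[id] <- substr(s, start, env$pos - 1L)
    if (peek() == "[") {
      close <- regexpr("]", substr(s, env$pos, nchar(s)), fixed = TRUE)
      if (close < 0L) stop("unterminated comment in Newick")
      comment <- substr(s, env$pos + 2L, env$pos + close - 2L) # strip [& ]
      env$pos <- env$pos + close
      for (part in strsplit(comment, ",", fixed = TRUE)[[1L]]) {
        kv <- strsplit(part, "=", fixed = TRUE)[[1L]]
        vals <- strsplit(kv[2L], "|", fixed = TRUE)[[1L]]
        if (kv[1L] == "gains") env$gains[[id]] <- vals
        if (kv[1L] == "losses") env$losses[[id]] <- vals
      }
    }
    id
  }
  parse_node(0L)
  species_node <- integer(0)
  for (id in seq_along(env$names)) {
    if (nzchar(env$names[id]))
      for (sp in strsplit(env$names[id], "|", fixed = TRUE)[[1L]])
        species_node[sp] <- id
  }
  structure(list(parent = env$parent, labels = NULL,
                 edge_gains = env$gains, edge_losses = env$losses,
                 species_node = species_node,
                 species = names(species_node), characters = NULL),
            class = "cppp_phylo")
}
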