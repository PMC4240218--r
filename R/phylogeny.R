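#' Build the persistent perfect phylogeny from a completed extended matrix
#'
#' Runs the classical all-zero-root directed perfect phylogeny construction
#' on the `2m` completed columns (columns sorted by decreasing 1-count;
#' ties broken gain before loss, then by character name; identical columns
#' share an edge), interprets `c+` columns as gains and `c-` columns as
#' losses, collapses node states to length-`m` 0/1 vectors (a character is
#' present when gained and not yet lost on the root path), and attaches
#' each species to the unique node matching its row. Nodes exist only at
#' mutation points; several identical rows share a node.
#'
#' @param completed a fully completed `"cppp_extmat"` passing
#'   [admits_directed_pp()].
#' @param M the original binary matrix.
#' @return an object of class `"cppp_phylo"`: list with `parent` (integer
#'   vector, 0 for the root), `labels` (node x m 0/1 matrix), `edge_gains`
#'   and `edge_losses` (per-node lists of character names on the edge above
#'   each node), `species_node` (named integer), `species`, `characters`.
#' @export
build_tree <- function(completed, M) {
  stopifnot(inherits(completed, "cppp_extmat"))
  M <- cppp_matrix(M)
  cells <- completed$cells
  if (anyNA(cells)) stop("extended matrix is not fully completed")
  if (!admits_directed_pp(completed))
    stop("completed matrix admits no directed perfect phylogeny")
  n <- nrow(cells); k <- ncol(cells)
  m <- length(completed$characters)
  colchar <- rep(completed$characters, each = 2L)
  colsign <- rep(c("+", "-"), m)
  counts <- colSums(cells)
  ord <- order(-counts, colsign, colchar) # "+" sorts before "-"
  ord <- ord[counts[ord] > 0L] # empty columns never label an edge
  # group identical columns: they label the same edge
  groups <- list()
  if (length(ord)) {
    keys <- apply(cells[, ord, drop = FALSE], 2L, paste, collapse = "")
    grp <- match(keys, unique(keys))
    groups <- lapply(seq_len(max(grp)), function(g) ord[grp == g])
  }

  parent <- 0L # node 1 = root
  labels <- matrix(0L, 1L, m, dimnames = list(NULL, completed$characters))
  edge_gains <- list(character(0))
  edge_losses <- list(character(0))
  node_group <- integer(0) # group id of the edge above each non-root node
  children <- list(integer(0)) # per node, child node per group id
  species_node <- integer(n)
  for (i in seq_len(n)) {
    gs <- which(vapply(groups, function(g) cells[i, g[1L]] == 1L,
                       logical(1)))
    cur <- 1L
    for (g in gs) { # gs is increasing = root-to-node order
      kids <- children[[cur]]
      nxt <- kids[node_group[kids - 1L] == g]
      if (!length(nxt)) {
        cols <- groups[[g]]
        lab <- labels[cur, ]
        gain_ch <- colchar[cols][colsign[cols] == "+"]
        loss_ch <- colchar[cols][colsign[cols] == "-"]
        lab[gain_ch] <- 1L
        lab[loss_ch] <- 0L
        parent <- c(parent, cur)
        labels <- rbind(labels, lab)
        edge_gains[[length(parent)]] <- gain_ch
        edge_losses[[length(parent)]] <- loss_ch
        node_group <- c(node_group, g)
        children[[length(parent)]] <- integer(0)
        children[[cur]] <- c(kids, length(parent))
        nxt <- length(parent)
      }
      cur <- nxt
    }
    species_node[i] <- cur
    if (!all(labels[cur, ] == M[i, ]))
      stop("internal error: species row does not match its node label")
  }
  names(species_node) <- rownames(M)
  rownames(labels) <- NULL
  structure(list(parent = parent, labels = labels,
                 edge_gains = edge_gains, edge_losses = edge_losses,
                 species_node = species_node,
                 species = rownames(M), characters = completed$characters),
            class = "cppp_phylo")
}

#' Verify a tree against the persistent perfect phylogeny definition
#'
#' Checks: the root is labeled all zero; every edge carries at least one
#' signed character and the child label equals the parent label changed
#' exactly by the edge's gains/losses; each character has at most one gain
#' and one loss edge, the loss strictly below the gain on the same root
#' path; each species' row equals the label of its node; and for every
#' constraint `(c, s)` no edge on the root path of `s` is labeled `c+`.
#'
#' @param tree a `"cppp_phylo"` (from [build_tree()] or
#'   [read_cppp_newick()]).
#' @param M the binary matrix the tree should explain.
#' @param constraints optional [cppp_constraints()].
#' @return list with `pass` (logical) and `violations` (character vector).
#' @export
verify_ppp <- function(tree, M, constraints = NULL) {
  M <- cppp_matrix(M)
  constraints <- check_constraints(M, constraints)
  v <- character(0)
  m <- ncol(M)
  tree <- materialize_labels(tree, colnames(M))
  nn <- length(tree$parent)
  if (!identical(colnames(tree$labels), colnames(M)))
    v <- c(v, "tree characters do not match the matrix")
  if (any(tree$labels[1L, ] != 0L))
    v <- c(v, "root label is not all zeroes")
  for (x in seq_len(nn)[-1L]) {
    g <- tree$edge_gains[[x]]; l <- tree$edge_losses[[x]]
    if (!length(g) && !length(l))
      v <- c(v, paste0("edge into node ", x, " has no character label"))
    expect <- tree$labels[tree$parent[x], ]
    bad <- c(g[expect[g] != 0L], l[expect[l] != 1L])
    expect[g] <- 1L
    expect[l] <- 0L
    if (length(bad))
      v <- c(v, paste0("edge into node ", x,
                       " labels inconsistent with parent state: ",
                       paste(bad, collapse = ",")))
    if (!all(tree$labels[x, ] == expect))
      v <- c(v, paste0("node ", x, " label does not equal parent label ",
                       "updated by its edge labels"))
  }
  anc <- function(x) { # nodes on the path root..x (inclusive)
    path <- x
    while (tree$parent[x] != 0L) {
      x <- tree$parent[x]
      path <- c(x, path)
    }
    path
  }
  for (ch in colnames(M)) {
    gains <- which(vapply(tree$edge_gains, function(g) ch %in% g, logical(1)))
    losses <- which(vapply(tree$edge_losses, function(g) ch %in% g, logical(1)))
    if (length(gains) > 1L)
      v <- c(v, paste0("character ", ch, " gained on ", length(gains), " edges"))
    if (length(losses) > 1L)
      v <- c(v, paste0("character ", ch, " lost on ", length(losses), " edges"))
    if (length(gains) == 1L && length(losses) == 1L) {
      path <- anc(losses[1L])
      if (!(gains[1L] %in% path) || gains[1L] == losses[1L])
        v <- c(v, paste0("loss of ", ch, " is not below its gain"))
    }
    if (!length(gains) && length(losses))
      v <- c(v, paste0("character ", ch, " lost but never gained"))
  }
  for (s in rownames(M)) {
    x <- tree$species_node[[s]]
    if (is.na(x) || x < 1L || x > nn) {
      v <- c(v, paste0("species ", s, " assigned to no node"))
      next
    }
    if (!all(tree$labels[x, ] == M[s, ]))
      v <- c(v, paste0("species ", s, " row differs from its node label"))
  }
  if (nrow(constraints)) for (i in seq_len(nrow(constraints))) {
    ch <- constraints$character[i]; s <- constraints$species[i]
    x <- tree$species_node[[s]]
    if (is.na(x)) next
    onpath <- any(vapply(anc(x), function(y) ch %in% tree$edge_gains[[y]],
                         logical(1)))
    if (onpath)
      v <- c(v, paste0("constraint (", ch, ", ", s, ") violated: ", ch,
                       "+ on the root path of ", s))
  }
  list(pass = length(v) == 0L, violations = v)
}

# Fill the node label matrix of a parsed tree (labels = NULL after Newick
# round trip) by walking gains/losses from the root.
materialize_labels <- function(tree, characters) {
  if (!is.null(tree$labels)) return(tree)
  nn <- length(tree$parent)
  labels <- matrix(0L, nn, length(characters),
                   dimnames = list(NULL, characters))
  ord <- order(vapply(seq_len(nn), function(x) {
    d <- 0L
    while (tree$parent[x] != 0L) {
      x <- tree$parent[x]; d <- d + 1L
    }
    d
  }, integer(1)))
  for (x in ord) {
    if (tree$parent[x] == 0L) next
    lab <- labels[tree$parent[x], ]
    g <- intersect(tree$edge_gains[[x]], characters)
    l <- intersect(tree$edge_losses[[x]], characters)
    lab[g] <- 1L
    lab[l] <- 0L
    labels[x, ] <- lab
  }
  tree$labels <- labels
  tree$characters <- characters
  tree
}

#' @export
print.cppp_phylo <- function(x, ...) {
  nn <- length(x$parent)
  cat("Persistent perfect phylogeny: ", nn, " nodes, ",
      length(x$species), " species, ", length(x$characters),
      " characters\n", sep = "")
  for (i in seq_len(nn)) {
    sp <- names(x$species_node)[x$species_node == i]
    lab <- if (!is.null(x$labels)) paste(x$labels[i, ], collapse = "") else ""
    ann <- character(0)
    if (length(x$edge_gains[[i]]))
      ann <- c(ann, paste0("+", x$edge_gains[[i]]))
    if (length(x$edge_losses[[i]]))
      ann <- c(ann, paste0("-", x$edge_losses[[i]]))
    cat(sprintf("  node %d%s parent=%d state=%s %s %s\n", i,
                if (x$parent[i] == 0L) " (root)" else "", x$parent[i], lab,
                if (length(ann)) paste0("[", paste(ann, collapse = " "), "]")
                else "",
                if (length(sp)) paste0("{", paste(sp, collapse = ","), "}")
                else ""))
  }
  invisible(x)
}

#' Convert to an ape "phylo" tree (for plotting)
#'
#' Species sharing a node are joined with `|` in the labels; gain/loss
#' annotations are appended in brackets. Trees with fewer than two nodes
#' cannot be represented.
#'
#' @param x a `"cppp_phylo"`.
#' @param ... unused.
#' @return an [ape::as.phylo] object.
#' @exportS3Method ape::as.phylo
#' @export
as.phylo.cppp_phylo <- function(x, ...) {
  nn <- length(x$parent)
  if (nn < 2L) stop("cannot convert a single-node tree to 'phylo'")
  kids <- tabulate(x$parent, nbins = nn)
  is_tip <- kids == 0L
  lab <- vapply(seq_len(nn), function(i) {
    sp <- names(x$species_node)[x$species_node == i]
    ann <- character(0)
    if (length(x$edge_gains[[i]]))
      ann <- c(ann, paste0("+", paste(x$edge_gains[[i]], collapse = "+")))
    if (length(x$edge_losses[[i]]))
      ann <- c(ann, paste0("-", paste(x$edge_losses[[i]], collapse = "-")))
    out <- paste(sp, collapse = "|")
    if (length(ann)) out <- paste0(out, "[", paste(ann, collapse = ""), "]")
    if (out == "") out <- paste0("n", i)
    out
  }, character(1))
  ntip <- sum(is_tip)
  id <- integer(nn)
  id[is_tip] <- seq_len(ntip)
  id[!is_tip] <- ntip + seq_len(nn - ntip)
  edge <- cbind(id[x$parent[-1L]], id[-1L])
  # ape wants edges, tip labels in tip id order, node labels likewise
  phy <- list(edge = edge, Nnode = nn - ntip,
              tip.label = lab[is_tip][order(id[is_tip])],
              node.label = lab[!is_tip][order(id[!is_tip])])
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  phy
}

#' @export
plot.cppp_phylo <- function(x, ...) {
  phy <- as.phylo.cppp_phylo(x)
  ape::plot.phylo(phy, show.node.label = TRUE, ...)
  invisible(x)
}
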