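#' Partial order of characters by column containment
#'
#' `c < c'` iff `M[s, c] <= M[s, c']` for every species `s` and the columns
#' differ; equal columns are tied (both maximal or both not). Maximal
#' characters play a central role in the edgeless-conflict solver: they are
#' realized before any character they dominate.
#'
#' @param M a binary matrix.
#' @return an object of class `"cppp_poset"`: list with `characters`,
#'   logical matrices `leq` (entrywise dominance, including equality) and
#'   `equal` (identical columns).
#' @export
character_poset <- function(M) {
  M <- cppp_matrix(M)
  A <- M
  storage.mode(A) <- "numeric"
  # leq[i, j]: no species has column i = 1 where column j = 0
  viol <- crossprod(A, 1 - A) > 0
  leq <- !viol
  equal <- leq & t(leq)
  dimnames(leq) <- dimnames(equal) <- list(colnames(M), colnames(M))
  structure(list(characters = colnames(M), leq = leq, equal = equal),
            class = "cppp_poset")
}

#' Maximal characters of a poset within a subset
#'
#' @param poset a `"cppp_poset"`.
#' @param subset character names to restrict to (default all).
#' @return the names in `subset` with no strictly greater character in
#'   `subset`; ties (equal columns) are all maximal together.
#' @export
maximal_characters <- function(poset, subset = poset$characters) {
  if (!length(subset)) return(character(0))
  leq <- poset$leq[subset, subset, drop = FALSE]
  equal <- poset$equal[subset, subset, drop = FALSE]
  strictly_below <- leq & !equal
  subset[!apply(strictly_below, 1L, any)]
}

#' Adjacency graph of the characters of a red-black graph
#'
#' Two characters are adjacent when some species is a neighbor of both in
#' the red-black graph (either edge color).
#'
#' @param state a `"cppp_state"` (or an extended matrix, taken fresh).
#' @return list of class `"cppp_adjgraph"` with `characters` (those present
#'   in the graph) and `edges` (2-column character matrix).
#' @export
adjacency_graph <- function(state) {
  if (inherits(state, "cppp_extmat")) state <- rb_state(state)
  e <- rb_edges(state)
  chars <- sort(unique(e$char))
  nb <- lapply(chars, function(j) e$species[e$char == j])
  edges <- matrix(character(0), 0L, 2L)
  if (length(chars) > 1L) {
    for (i in seq_along(chars)) for (k in seq_along(chars)) {
      if (i < k && length(intersect(nb[[i]], nb[[k]])))
        edges <- rbind(edges, state$ext$characters[chars[c(i, k)]])
    }
  }
  structure(list(characters = state$ext$characters[chars], edges = edges),
            class = "cppp_adjgraph")
}
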