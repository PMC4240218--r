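#' Red-black solver state
#'
#' The working state of the solvers couples the (partially completed)
#' extended matrix with a per-character status in
#' `{inactive, active, free}`. The red-black graph is fully determined by
#' this pair: a black edge `(s, c)` exists iff `c` is inactive and the pair
#' of `s` is `(1, 0)`; a red edge iff `c` is active and the pair is
#' `(1, 1)`. Isolated vertices simply have no edges and are never part of a
#' connected component.
#'
#' @param ext an extended matrix from [extend_matrix()].
#' @return an object of class `"cppp_state"`: list with `ext` and `status`
#'   (named character vector over the characters).
#' @export
rb_state <- function(ext) {
  stopifnot(inherits(ext, "cppp_extmat"))
  status <- rep("inactive", length(ext$characters))
  names(status) <- ext$characters
  structure(list(ext = ext, status = status), class = "cppp_state")
}

# Edge list of the red-black graph derived from the state.
# Returns a list(species=int, char=int, color=chr) of parallel vectors
# (integer indices into ext$species / ext$characters).
rb_edges <- function(state) {
  cells <- state$ext$cells
  n <- nrow(cells)
  m <- length(state$ext$characters)
  plus <- cells[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  minus <- cells[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  inact <- matrix(state$status == "inactive", n, m, byrow = TRUE)
  act <- matrix(state$status == "active", n, m, byrow = TRUE)
  one <- !is.na(plus) & plus == 1L
  black <- which(one & inact, arr.ind = TRUE)
  red <- which(one & act & minus == 1L, arr.ind = TRUE)
  list(species = c(black[, 1L], red[, 1L]),
       char = c(black[, 2L], red[, 2L]),
       color = rep(c("black", "red"), c(nrow(black), nrow(red))))
}

#' Red-black graph view of a state or extended matrix
#'
#' @param x a `"cppp_state"` or (fresh) `"cppp_extmat"`.
#' @return an object of class `"cppp_rbgraph"`: list with `edges`
#'   (data frame: species, character, color), `status`, and the vertex sets
#'   `species`/`characters` currently present (isolated vertices excluded).
#' @export
red_black_graph <- function(x) {
  state <- if (inherits(x, "cppp_state")) x else rb_state(x)
  e <- rb_edges(state)
  edges <- data.frame(species = state$ext$species[e$species],
                      character = state$ext$characters[e$char],
                      color = e$color, stringsAsFactors = FALSE)
  structure(list(edges = edges, status = state$status,
                 species = sort(unique(edges$species)),
                 characters = sort(unique(edges$character))),
            class = "cppp_rbgraph")
}

#' @export
print.cppp_rbgraph <- function(x, ...) {
  cat("Red-black graph:", length(x$species), "species,",
      length(x$characters), "characters,",
      sum(x$edges$color == "black"), "black /",
      sum(x$edges$color == "red"), "red edges\n")
  invisible(x)
}

# Connected components of the bipartite red-black graph (union-find).
# Returns a list of components, each list(species=int, chars=int); only
# vertices with at least one edge appear.
rb_components <- function(state, edges = rb_edges(state)) {
  if (!length(edges$species)) return(list())
  n <- length(state$ext$species)
  m <- length(state$ext$characters)
  # species vertex ids 1..n, character vertex ids n+1..n+m
  parent <- seq_len(n + m)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  a <- edges$species; b <- n + edges$char
  for (k in seq_along(a)) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[ra] <- rb
  }
  verts <- sort(unique(c(a, b)))
  roots <- vapply(verts, find, integer(1))
  lapply(unique(roots), function(r) {
    vs <- verts[roots == r]
    list(species = vs[vs <= n], chars = vs[vs > n] - n)
  })
}

# Component containing character j, or NULL when j is isolated.
component_of_char <- function(state, j, comps = NULL) {
  if (is.null(comps)) comps <- rb_components(state)
  for (cc in comps) if (j %in% cc$chars) return(cc)
  NULL
}

#' Realize a signed character in the red-black graph
#'
#' Realizing a gain `c+` of an inactive character `c` completes the pair of
#' every species outside the connected component of `c` as `(0, 0)`, the
#' pair of every component species not black-adjacent to `c` as `(1, 1)`
#' (adding a red edge), removes the black edges of `c` and makes it active.
#' Realizing a loss `c-` of an active character that is red-adjacent to all
#' species of its component deletes those red edges and makes it free.
#' Any other request is impossible; so is a gain that would force a
#' persistent completion `(1, 1)` on a constrained cell (the constrained
#' third case). The constraint check precedes any mutation, so an
#' impossible outcome leaves no partial change.
#'
#' @param state a `"cppp_state"`.
#' @param x a signed character label such as `"c1+"` or `"c1-"`.
#' @param comps optional precomputed [rb_components()] of `state` (an
#'   internal fast path for the solvers).
#' @return a list with `status` (`"ok"` or `"impossible"`), `reason`
#'   (`"none"`, `"constraint-violation"`, `"active-not-covering"`,
#'   `"free-character"` or `"wrong-state"`), and the updated `state`
#'   (unchanged when impossible).
#' @export
realize <- function(state, x, comps = NULL) {
  stopifnot(inherits(state, "cppp_state"), length(x) == 1L)
  ps <- parse_signed(x)
  j <- char_index(state$ext, ps$character)
  cells <- state$ext$cells
  n <- length(state$ext$species)
  imp <- function(reason) list(status = "impossible", reason = reason,
                               state = state)
  # defensive third case: an existing red edge on a constrained cell means
  # the state is corrupt; refuse to proceed
  if (state$status[j] == "active") {
    red_nb <- which(cells[, 2L * j - 1L] == 1L & cells[, 2L * j] == 1L)
    if (any(state$ext$mask[red_nb, j]))
      return(imp("constraint-violation"))
  }
  if (ps$sign == "+") {
    if (state$status[j] == "free") return(imp("free-character"))
    if (state$status[j] != "inactive") return(imp("wrong-state"))
    cc <- component_of_char(state, j, comps)
    comp_sp <- if (is.null(cc)) integer(0) else cc$species
    p <- cells[, 2L * j - 1L]
    black_nb <- which(!is.na(p) & p == 1L)
    to_red <- setdiff(comp_sp, black_nb)
    if (any(state$ext$mask[to_red, j])) return(imp("constraint-violation"))
    outside <- setdiff(which(is.na(p)), comp_sp)
    if (length(outside)) state$ext$cells[outside, pair_cols(j)] <- 0L
    if (length(to_red)) state$ext$cells[to_red, pair_cols(j)] <- 1L
    state$status[j] <- "active"
    list(status = "ok", reason = "none", state = state)
  } else {
    if (state$status[j] == "free") return(imp("free-character"))
    if (state$status[j] != "active") return(imp("active-not-covering"))
    cc <- component_of_char(state, j, comps)
    comp_sp <- if (is.null(cc)) integer(0) else cc$species
    red_nb <- which(cells[, 2L * j - 1L] == 1L & cells[, 2L * j] == 1L)
    if (!all(comp_sp %in% red_nb)) return(imp("active-not-covering"))
    state$status[j] <- "free"
    list(status = "ok", reason = "none", state = state)
  }
}

#' Detect a red-sigma subgraph
#'
#' A red-sigma is a path of four red edges `s1 - a - s2 - b - s3` over two
#' characters and three species whose completed columns `a+`, `b+` exhibit
#' the forbidden configurations (1,0), (1,1), (0,1) (so
#' `Me[s3, a+] = Me[s1, b+] = 0`). Its presence certifies that the current
#' partial completion admits no directed perfect phylogeny, so search
#' branches containing one can be pruned.
#'
#' @param state a `"cppp_state"`.
#' @return `NULL`, or a witness list with `species` (`s1, s2, s3`) and
#'   `characters` (`a, b`).
#' @export
detect_red_sigma <- function(state) {
  cells <- state$ext$cells
  act <- which(state$status == "active")
  if (length(act) < 2L) return(NULL)
  reds <- lapply(act, function(j)
    which(cells[, 2L * j - 1L] == 1L & cells[, 2L * j] == 1L))
  names(reds) <- as.character(act)
  for (ia in seq_along(act)) for (ib in seq_along(act)) {
    if (ia == ib) next
    a <- act[ia]; b <- act[ib]
    shared <- intersect(reds[[ia]], reds[[ib]])
    if (!length(shared)) next
    # s1: red neighbor of a with Me[s1, b+] = 0; s3: red neighbor of b
    # with Me[s3, a+] = 0
    s1s <- reds[[ia]][cells[reds[[ia]], 2L * b - 1L] == 0L]
    s3s <- reds[[ib]][cells[reds[[ib]], 2L * a - 1L] == 0L]
    if (!length(s1s) || !length(s3s)) next
    s1 <- s1s[1L]; s3 <- s3s[1L]
    s2 <- setdiff(shared, c(s1, s3))
    if (!length(s2)) next
    sp <- state$ext$species
    return(list(species = sp[c(s1, s2[1L], s3)],
                characters = state$ext$characters[c(a, b)]))
  }
  NULL
}

# Residual binary matrix of a state: rows = species with at least one edge,
# columns = inactive characters with at least one black edge, entry 1 iff a
# black edge joins them. This is the submatrix still to be explained.
residual_matrix <- function(state) {
  cells <- state$ext$cells
  m <- length(state$ext$characters)
  plus <- cells[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  B <- !is.na(plus) & plus == 1L
  storage.mode(B) <- "integer"
  dimnames(B) <- list(state$ext$species, state$ext$characters)
  B <- B[, state$status == "inactive", drop = FALSE]
  B <- B[, colSums(B) > 0L, drop = FALSE]
  B[rowSums(B) > 0L, , drop = FALSE]
}

# Conflict graph of the residual instance at a search state.
residual_conflict_graph <- function(state) {
  R <- residual_matrix(state)
  if (!nrow(R) || !ncol(R))
    return(structure(list(characters = colnames(R),
                          edges = matrix(character(0), 0L, 2L)),
                     class = "cppp_conflict"))
  conflict_graph(R)
}

# Complete every remaining (?, ?) pair as (0, 0). Once the red-black graph
# is edgeless the only incomplete pairs belong to characters that were
# never realized (all-zero columns); not-persistent is their canonical
# completion.
finalize_completion <- function(state) {
  state$ext$cells[is.na(state$ext$cells)] <- 0L
  state
}

state_is_edgeless <- function(state) {
  length(rb_edges(state)$species) == 0L
}

#' Realize a c-reduction
#'
#' Realizes an ordered sequence of signed characters left to right,
#' reporting the first impossible step if any. The reduction is
#' *successful* when every step is possible and the final red-black graph
#' is edgeless; the completed extended matrix then admits a directed
#' perfect phylogeny and hence encodes a persistent perfect phylogeny.
#'
#' @param M a binary matrix.
#' @param constraints optional [cppp_constraints()].
#' @param reduction character vector of signed labels, e.g.
#'   `c("c1+", "c2+", "c1-")`.
#' @return a list with `success` (possible and edgeless), `edgeless`,
#'   `failed_step` (index of the first impossible step or `NA`), `reason`,
#'   and the final `state` (fully completed when successful).
#' @examples
#' M <- cppp_matrix(rbind(s1 = c(1, 0), s2 = c(1, 1), s3 = c(0, 1)))
#' apply_c_reduction(M, reduction = c("c1+", "c2+", "c1-"))$success
#' @export
apply_c_reduction <- function(M, constraints = NULL, reduction) {
  M <- cppp_matrix(M)
  validate_reduction(reduction, colnames(M))
  state <- rb_state(extend_matrix(M, constraints))
  res <- apply_reduction_state(state, reduction)
  if (res$success) res$state <- finalize_completion(res$state)
  res
}

apply_reduction_state <- function(state, reduction) {
  for (k in seq_along(reduction)) {
    r <- realize(state, reduction[k])
    if (r$status != "ok")
      return(list(success = FALSE, edgeless = state_is_edgeless(state),
                  failed_step = k, reason = r$reason, state = state))
    state <- r$state
  }
  edgeless <- state_is_edgeless(state)
  list(success = edgeless, edgeless = edgeless, failed_step = NA_integer_,
       reason = if (edgeless) "none" else "graph-not-edgeless",
       state = state)
}
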