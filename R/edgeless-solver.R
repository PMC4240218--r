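#' Polynomial-time solver for edgeless conflict graphs
#'
#' When the conflict graph of the instance has no edges, a successful
#' c-reduction can be computed greedily: per connected component of the
#' red-black graph, realize the realizable maximal characters of the
#' containment poset, then free every active character that is red-adjacent
#' to all species of its component, and iterate until the graph is
#' edgeless. If at some iteration no maximal character of a component can
#' be realized, the instance (from this state) has no solution. With no
#' constraints a solution always exists.
#'
#' @param M a binary matrix whose conflict graph is edgeless.
#' @param constraints optional [cppp_constraints()].
#' @param state optional `"cppp_state"` to start from (used by the search
#'   solver when a node's residual conflict graph becomes edgeless); its
#'   residual conflict graph must be edgeless. A no-solution answer from an
#'   interior state triggers backtracking in the caller, not global
#'   unsatisfiability.
#' @param trace logical; record per-iteration details (component, maximal
#'   set, realized set, freed characters).
#' @return a list with `status` (`"solution"` or `"no-solution"`),
#'   `reduction` (signed labels, on solution), the final `state`, and
#'   `trace` (list, when requested).
#' @examples
#' M <- cppp_matrix(rbind(s1 = c(1, 0), s2 = c(1, 1), s3 = c(0, 1)))
#' solve_edgeless(M)$reduction
#' @export
solve_edgeless <- function(M = NULL, constraints = NULL, state = NULL,
                           trace = FALSE) {
  if (is.null(state)) {
    M <- cppp_matrix(M)
    if (!is_edgeless(conflict_graph(M)))
      stop("conflict graph has edges; use cppp() for the general case")
    state <- rb_state(extend_matrix(M, constraints))
  } else {
    stopifnot(inherits(state, "cppp_state"))
    if (!is_edgeless(residual_conflict_graph(state)))
      stop("residual conflict graph has edges")
  }
  # the poset is computed once, on the residual matrix of the entry state
  # (for a fresh state this is M restricted to non-isolated rows/columns)
  R <- residual_matrix(state)
  poset <- if (ncol(R)) character_poset(R) else NULL
  reduction <- character(0)
  tr <- list()
  fail <- function() list(status = "no-solution", reduction = NULL,
                          state = state, trace = tr)
  repeat {
    freed <- free_all(state)
    state <- freed$state
    reduction <- c(reduction, freed$labels)
    edges <- rb_edges(state)
    if (!length(edges$species))
      return(list(status = "solution", reduction = reduction, state = state,
                  trace = tr))
    comps <- rb_components(state, edges)
    comp <- pick_component(state, comps)
    comp_chars <- state$ext$characters[comp$chars]
    inact <- comp_chars[state$status[comp$chars] == "inactive"]
    if (!length(inact)) return(fail())
    cm <- maximal_characters(poset, intersect(poset$characters, inact))
    if (!length(cm)) return(fail())
    # keep the realizable subset, in duplicate-grouped deterministic order
    ordered <- order_duplicate_groups(state, cm)
    D <- character(0)
    for (ch in ordered) {
      if (realize(state, signed(ch, "+"))$status == "ok") D <- c(D, ch)
    }
    if (!length(D)) return(fail())
    freed_now <- character(0)
    for (ch in D) {
      r <- realize(state, signed(ch, "+"))
      if (r$status != "ok") return(fail())
      state <- r$state
      reduction <- c(reduction, signed(ch, "+"))
    }
    if (trace)
      tr[[length(tr) + 1L]] <-
        list(component_species = state$ext$species[comp$species],
             component_characters = comp_chars, maximal = cm, realized = D)
  }
}

# Deterministic realization order: decreasing count of black 1-entries,
# identical columns grouped consecutively, ties by character name.
order_duplicate_groups <- function(state, chars) {
  if (length(chars) <= 1L) return(chars)
  cells <- state$ext$cells
  js <- match(chars, state$ext$characters)
  keys <- vapply(js, function(j) {
    p <- cells[, 2L * j - 1L]
    paste(ifelse(!is.na(p) & p == 1L, 1L, 0L), collapse = "")
  }, character(1))
  counts <- vapply(js, function(j) {
    p <- cells[, 2L * j - 1L]
    sum(!is.na(p) & p == 1L)
  }, numeric(1))
  # group representative = alphabetically first member of each equal class
  rep_name <- vapply(keys, function(k) min(chars[keys == k]), character(1))
  chars[order(-counts, rep_name, chars)]
}

# Realize c- for every active character red-adjacent to all species of its
# component, repeating until a fixpoint.
free_all <- function(state) {
  labels <- character(0)
  repeat {
    e <- rb_edges(state)
    act <- sort(unique(e$char[e$color == "red"]))
    if (!length(act)) break
    progressed <- FALSE
    for (j in act) {
      ch <- state$ext$characters[j]
      r <- realize(state, signed(ch, "-"))
      if (r$status == "ok") {
        state <- r$state
        labels <- c(labels, signed(ch, "-"))
        progressed <- TRUE
        break
      }
    }
    if (!progressed) break
  }
  list(state = state, labels = labels)
}

# Component processing order: smallest species name first.
pick_component <- function(state, comps) {
  keys <- vapply(comps, function(cc)
    min(state$ext$species[cc$species]), character(1))
  comps[[which.min(rank(keys, ties.method = "first"))]]
}
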