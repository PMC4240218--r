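#' Feasible signed-character moves at a search state
#'
#' A move is feasible when its realization is not impossible: a gain `c+`
#' for any inactive character in the graph whose realization violates no
#' constraint, or a loss `c-` for any active character red-adjacent to all
#' species of its component. Moves are returned in the deterministic order
#' used by the search: losses first (freeing shrinks the graph), then gains
#' with residual-poset-maximal characters first, then by decreasing
#' residual column count, then by name.
#'
#' @param state a `"cppp_state"`.
#' @param edges,comps optional precomputed edge list and components of
#'   `state` (internal fast path).
#' @return character vector of signed labels (possibly empty).
#' @export
feasible_moves <- function(state, edges = rb_edges(state),
                           comps = rb_components(state, edges)) {
  losses <- character(0)
  gains <- character(0)
  cells <- state$ext$cells
  for (cc in comps) for (j in cc$chars) {
    ch <- state$ext$characters[j]
    st <- state$status[j]
    if (st == "active") {
      # feasible loss: red-adjacent to every species of the component
      red_nb <- which(cells[, 2L * j - 1L] == 1L & cells[, 2L * j] == 1L)
      if (all(cc$species %in% red_nb)) losses <- c(losses, signed(ch, "-"))
    } else if (st == "inactive") {
      # feasible gain: no constrained cell would be completed persistent
      p <- cells[, 2L * j - 1L]
      to_red <- setdiff(cc$species, which(!is.na(p) & p == 1L))
      if (!any(state$ext$mask[to_red, j])) gains <- c(gains, signed(ch, "+"))
    }
  }
  if (length(gains) > 1L) {
    R <- residual_matrix(state)
    poset <- character_poset(R)
    gch <- parse_signed(gains)$character
    maximal <- gch %in% maximal_characters(poset)
    counts <- colSums(R)[gch]
    gains <- gains[order(-maximal, -counts, gch)]
  }
  c(sort(losses), gains)
}

#' Solve the constrained persistent perfect phylogeny problem
#'
#' Decides whether the binary matrix `M` admits a persistent perfect
#' phylogeny (every character gained at most once and lost at most once)
#' respecting the forbidden-persistence constraints, and constructs the
#' tree when it does. The solver explores the tree of c-reduction prefixes
#' depth first, pruning branches whose red-black graph contains a red-sigma
#' subgraph and short-circuiting to the polynomial [solve_edgeless()]
#' procedure whenever the residual conflict graph becomes edgeless; the
#' first solution found is returned. The search is fixed-parameter in the
#' number of characters.
#'
#' @param M a binary matrix (see [cppp_matrix()]).
#' @param constraints optional [cppp_constraints()].
#' @param max_nodes node budget for the decision-tree exploration.
#' @param memoize logical; cache visited canonical states (active/free
#'   status plus completion fingerprint) so equivalent prefixes are
#'   explored once. Off by default: a correctness-neutral optimization
#'   that trades memory for time on unsatisfiable instances.
#' @param collect_prunes logical; keep the states at which red-sigma
#'   pruning fired (for auditing prune soundness).
#' @return an object of class `"cppp"`: list with `status` (`"solution"`,
#'   `"no-solution"` or `"budget-exceeded"`), `reduction` (successful
#'   c-reduction), `tree` (a `"cppp_phylo"`, see [build_tree()]),
#'   `completed` (the completed extended matrix), `stats` (nodes expanded,
#'   prune counts), plus the inputs.
#' @examples
#' M <- cppp_matrix(rbind(s1 = c(1, 0), s2 = c(1, 1), s3 = c(0, 1)))
#' fit <- cppp(M)
#' fit$status
#' fit$reduction
#' @export
cppp <- function(M, constraints = NULL, max_nodes = 1e6, memoize = FALSE,
                 collect_prunes = FALSE) {
  M <- cppp_matrix(M)
  constraints <- check_constraints(M, constraints)
  state0 <- rb_state(extend_matrix(M, constraints))
  env <- new.env(parent = emptyenv())
  env$nodes <- 0L
  env$prunes <- c(`red-sigma` = 0L)
  env$shortcuts <- 0L
  env$prune_states <- list()
  env$memo <- if (memoize) new.env(parent = emptyenv())
  res <- cppp_dfs(state0, character(0), env, max_nodes, collect_prunes)
  out <- list(status = res$status, reduction = NULL, tree = NULL,
              completed = NULL,
              stats = list(nodes = env$nodes, prunes = env$prunes,
                           edgeless_shortcuts = env$shortcuts),
              matrix = M, constraints = constraints,
              prune_states = if (collect_prunes) env$prune_states,
              call = match.call())
  if (res$status == "solution") {
    state <- finalize_completion(res$state)
    out$reduction <- res$prefix
    out$completed <- state$ext
    out$tree <- build_tree(state$ext, M)
  }
  class(out) <- "cppp"
  out
}

cppp_dfs <- function(state, prefix, env, max_nodes, collect_prunes) {
  env$nodes <- env$nodes + 1L
  if (env$nodes > max_nodes)
    return(list(status = "budget-exceeded"))
  key <- NULL
  if (!is.null(env$memo)) {
    key <- paste(c(state$status, state$ext$cells), collapse = "")
    if (!is.null(env$memo[[key]])) return(list(status = "no-solution"))
  }
  edges <- rb_edges(state)
  if (!length(edges$species))
    return(list(status = "solution", prefix = prefix, state = state))
  if (!is.null(detect_red_sigma(state))) {
    env$prunes["red-sigma"] <- env$prunes["red-sigma"] + 1L
    if (collect_prunes && length(env$prune_states) < 500L)
      env$prune_states[[length(env$prune_states) + 1L]] <-
        list(state = state, prefix = prefix)
    return(list(status = "no-solution"))
  }
  if (is_edgeless(residual_conflict_graph(state))) {
    env$shortcuts <- env$shortcuts + 1L
    r <- solve_edgeless(state = state)
    if (r$status == "solution")
      return(list(status = "solution",
                  prefix = c(prefix, r$reduction), state = r$state))
    # fall through: completeness of the greedy procedure from interior
    # states (red edges present) is not guaranteed, so expand normally
  }
  comps <- rb_components(state, edges)
  for (mv in feasible_moves(state, edges, comps)) {
    r <- realize(state, mv, comps)
    if (r$status != "ok") next
    sub <- cppp_dfs(r$state, c(prefix, mv), env, max_nodes, collect_prunes)
    if (sub$status %in% c("solution", "budget-exceeded")) return(sub)
  }
  if (!is.null(key)) env$memo[[key]] <- TRUE
  list(status = "no-solution")
}

#' @export
print.cppp <- function(x, ...) {
  n <- nrow(x$matrix); m <- ncol(x$matrix)
  cat("Constrained persistent perfect phylogeny\n")
  cat("  instance: ", n, " species x ", m, " characters, ",
      nrow(x$constraints), " constraint(s)\n", sep = "")
  cat("  decision:", x$status, "\n")
  if (x$status == "solution")
    cat("  c-reduction: ", paste(x$reduction, collapse = " "), "\n", sep = "")
  cat("  nodes expanded: ", x$stats$nodes, ", red-sigma prunes: ",
      x$stats$prunes[["red-sigma"]], "\n", sep = "")
  invisible(x)
}

#' @export
summary.cppp <- function(object, ...) {
  print(object)
  if (object$status == "solution") {
    cat("\n")
    print(object$tree)
    v <- verify_ppp(object$tree, object$matrix, object$constraints)
    cat("verifier:", if (v$pass) "pass" else
      paste("FAIL -", paste(v$violations, collapse = "; ")), "\n")
  }
  invisible(object)
}

#' @export
plot.cppp <- function(x, ...) {
  if (x$status != "solution" || is.null(x$tree))
    stop("no tree to plot: solver status is ", x$status)
  plot(x$tree, ...)
}
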