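#' Generate a random matrix admitting a perfect phylogeny
#'
#' Emulates coalescent-style infinite-sites data: a random rooted tree over
#' `n` leaves is grown by sequential attachment (each new node attaches to
#' a uniformly chosen existing node until `n` leaves exist), `m` mutations
#' are dropped on uniformly random edges (with replacement, so duplicated
#' columns can arise), and each leaf's presence/absence row is read off.
#' The resulting columns are subtree leaf-sets, hence pairwise compatible:
#' the conflict graph is always edgeless before any perturbation.
#' Optionally a fraction of rows is then overwritten with copies of other
#' rows to create duplicated rows (the raw material for back mutations,
#' see [inject_back_mutations()]).
#'
#' @param n number of species (>= 2).
#' @param m number of characters (>= 1).
#' @param duplicate_row_rate fraction of rows to overwrite with duplicates.
#' @param seed optional integer seed.
#' @return a binary matrix with species `s1..sn`, characters `c1..cm`.
#' @export
sim_pp_matrix <- function(n, m, duplicate_row_rate = 0, seed = NULL) {
  stopifnot(n >= 2L, m >= 1L, duplicate_row_rate >= 0,
            duplicate_row_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  parent <- c(0L) # node 1 = root
  n_children <- c(0L)
  leaves <- function() which(n_children == 0L & parent != 0L)
  while (length(leaves()) < n) {
    p <- sample.int(length(parent), 1L)
    parent <- c(parent, p)
    n_children <- c(n_children, 0L)
    n_children[p] <- n_children[p] + 1L
  }
  lv <- leaves()[seq_len(n)]
  # species below each node: walk each leaf's root path
  below <- vector("list", length(parent))
  for (i in seq_along(lv)) {
    x <- lv[i]
    while (x != 0L) {
      below[[x]] <- c(below[[x]], i)
      x <- parent[x]
    }
  }
  edges <- which(parent != 0L) # one edge above each non-root node
  hit <- sample(edges, m, replace = TRUE)
  M <- matrix(0L, n, m, dimnames = list(paste0("s", seq_len(n)),
                                        paste0("c", seq_len(m))))
  for (j in seq_len(m)) M[below[[hit[j]]], j] <- 1L
  k <- round(duplicate_row_rate * n)
  if (k > 0) {
    targets <- sample.int(n, k)
    for (i in targets) {
      src <- sample(setdiff(seq_len(n), i), 1L)
      M[i, ] <- M[src, ]
    }
  }
  M
}

#' Inject back mutations into duplicated rows
#'
#' For each row that duplicates an earlier row of the input, at most one
#' uniformly chosen entry is flipped (each duplicated row is flipped with
#' probability `prob`, 1 by default). Non-duplicate rows are untouched.
#' Flipping a single state in an otherwise infinite-sites matrix is the
#' minimal violation of the perfect phylogeny model that the persistent
#' model is designed to absorb.
#'
#' @param M a binary matrix.
#' @param seed optional integer seed.
#' @param prob per-duplicated-row probability of flipping one entry.
#' @return the perturbed matrix.
#' @export
inject_back_mutations <- function(M, seed = NULL, prob = 1) {
  M <- cppp_matrix(M)
  if (!is.null(seed)) set.seed(seed)
  out <- M
  keys <- apply(M, 1L, paste, collapse = "")
  for (i in seq_len(nrow(M))[-1L]) {
    if (keys[i] %in% keys[seq_len(i - 1L)] && stats::runif(1) <= prob) {
      j <- sample.int(ncol(M), 1L)
      out[i, j] <- 1L - out[i, j]
    }
  }
  out
}

#' Sample random forbidden-persistence constraints
#'
#' @param M a binary matrix.
#' @param k number of constraints; there must be at least `k` zero cells.
#' @param seed optional integer seed.
#' @return a [cppp_constraints()] set of `k` distinct `(character, species)`
#'   pairs with `M[s, c] = 0`.
#' @export
sim_constraints <- function(M, k, seed = NULL) {
  M <- cppp_matrix(M)
  if (!is.null(seed)) set.seed(seed)
  zeros <- which(M == 0L, arr.ind = TRUE)
  if (k > nrow(zeros))
    stop("cannot sample ", k, " constraints: only ", nrow(zeros),
         " zero cells")
  if (k == 0L) return(cppp_constraints())
  idx <- zeros[sample.int(nrow(zeros), k), , drop = FALSE]
  cppp_constraints(character = colnames(M)[idx[, 2L]],
                   species = rownames(M)[idx[, 1L]])
}

#' Generate a full synthetic instance
#'
#' Convenience wrapper reproducing the experimental protocol at desk
#' scale: an infinite-sites matrix with duplicated rows, back mutations
#' injected into the duplicates, and `constraints_k` random constraints
#' sampled from the perturbed matrix.
#'
#' @param n,m matrix dimensions.
#' @param duplicate_row_rate fraction of duplicated rows (default 0.3).
#' @param constraints_k number of random constraints (default 0).
#' @param seed integer seed (required for reproducibility).
#' @param perturb logical; inject back mutations into duplicated rows.
#' @return list with `matrix` (perturbed), `pp_matrix` (pre-perturbation),
#'   `constraints`, and `config`.
#' @export
sim_cppp_instance <- function(n, m, duplicate_row_rate = 0.3,
                              constraints_k = 0L, seed = NULL,
                              perturb = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  pp <- sim_pp_matrix(n, m, duplicate_row_rate)
  M <- if (perturb) inject_back_mutations(pp) else pp
  constraints <- sim_constraints(M, constraints_k)
  list(matrix = M, pp_matrix = pp, constraints = constraints,
       config = list(n = n, m = m, duplicate_row_rate = duplicate_row_rate,
                     constraints_k = constraints_k, seed = seed))
}
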