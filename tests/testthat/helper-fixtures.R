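# Shared fixtures and independent oracles for the test suite.

# The running 3-species example: rows (1,0), (1,1), (0,1). Its two
# characters are pairwise compatible (no (0,0) configuration) but the
# matrix admits no perfect phylogeny without persistence: c1 must be lost
# below c2's gain.
sigma_matrix <- function() {
  M <- rbind(s1 = c(1L, 0L), s2 = c(1L, 1L), s3 = c(0L, 1L))
  colnames(M) <- c("c1", "c2")
  cppp_matrix(M)
}

# Independent closed-form oracle for the directed perfect phylogeny
# criterion: columns, viewed as species sets, must form a laminar family
# (every pair nested or disjoint). Deliberately a different code path from
# admits_directed_pp (set algebra instead of configuration counting).
laminar_admits <- function(A) {
  k <- ncol(A)
  if (k < 2L) return(TRUE)
  sets <- lapply(seq_len(k), function(j) which(A[, j] == 1L))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    common <- intersect(sets[[i]], sets[[j]])
    if (length(common) &&
        !all(sets[[i]] %in% sets[[j]]) && !all(sets[[j]] %in% sets[[i]]))
      return(FALSE)
  }
  TRUE
}

# Enumerate the binary matrix encoded by `code` in row-major bit order.
binary_matrix_from_code <- function(code, n, m) {
  bits <- as.integer(intToBits(code))[seq_len(n * m)]
  cppp_matrix(matrix(bits, n, m))
}

random_binary_matrix <- function(n, m, p = 0.5) {
  cppp_matrix(matrix(stats::rbinom(n * m, 1L, p), n, m))
}

# White-box state builder: an extended matrix with selected pairs completed
# persistent and their characters active (for red-edge pattern tests).
state_with_reds <- function(M, persistent) {
  st <- rb_state(extend_matrix(M))
  for (k in seq_len(nrow(persistent))) {
    i <- match(persistent$species[k], st$ext$species)
    j <- match(persistent$character[k], st$ext$characters)
    st$ext$cells[i, c(2L * j - 1L, 2L * j)] <- 1L
    st$status[j] <- "active"
  }
  # complete the remaining pairs of touched characters so active
  # characters hold no '?' cells
  for (j in which(st$status == "active")) {
    nas <- which(is.na(st$ext$cells[, 2L * j - 1L]))
    st$ext$cells[nas, c(2L * j - 1L, 2L * j)] <- 0L
  }
  st
}

# Number of connected components of the red-edge subgraph of a state.
red_component_count <- function(state) {
  e <- ppphylo:::rb_edges(state)
  keep <- e$color == "red"
  sp <- e$species[keep]; ch <- e$char[keep]
  if (!length(sp)) return(0L)
  n <- length(state$ext$species)
  verts <- unique(c(sp, n + ch))
  parent <- stats::setNames(verts, verts)
  find <- function(x) {
    x <- as.character(x)
    while (parent[[x]] != as.numeric(x)) x <- as.character(parent[[x]])
    as.numeric(x)
  }
  for (k in seq_along(sp)) {
    a <- find(sp[k]); b <- find(n + ch[k])
    if (a != b) parent[[as.character(a)]] <- b
  }
  length(unique(vapply(verts, find, numeric(1))))
}

# Reconciliation of the derived red-black graph against its defining
# invariants; returns a character vector of violations (empty = clean).
check_state_invariants <- function(state) {
  v <- character(0)
  cells <- state$ext$cells
  for (j in seq_along(state$ext$characters)) {
    p <- cells[, 2L * j - 1L]; q <- cells[, 2L * j]
    mixed <- xor(is.na(p), is.na(q))
    if (any(mixed)) v <- c(v, paste0("mixed ?/non-? pair in character ", j))
    st <- state$status[j]
    if (st == "inactive") {
      done <- !is.na(p)
      # inactive characters may hold only (1,0) originals and (0,0)
      # constrained cells -- in particular no red (1,1) completions
      bad <- done & !((p == 1L & q == 0L) | (p == 0L & q == 0L))
      if (any(bad)) v <- c(v, paste0("inactive character ", j,
                                     " has a persistent completion"))
    } else if (anyNA(p)) {
      v <- c(v, paste0(st, " character ", j, " has ? cells"))
    }
  }
  v
}
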