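#' Brute-force ground-truth decision by completion enumeration
#'
#' Decides solvability directly from the defining equivalence: the instance
#' admits a constrained persistent perfect phylogeny iff some completion of
#' its extended matrix admits a directed perfect phylogeny. All `2^q`
#' completions of the `q` incomplete conjugate pairs are enumerated
#' (depth first, pairs ordered by species then character name, with
#' subtrees abandoned as soon as the already-completed cells exhibit a
#' forbidden column-pair configuration — such subtrees cannot contain a
#' witness, so the enumeration remains exhaustive). The oracle never
#' touches the red-black machinery and exists to validate the solvers.
#'
#' @param M a binary matrix.
#' @param constraints optional [cppp_constraints()].
#' @param limit refuse instances with more than this many incomplete pairs.
#' @param count also count all valid completions (disables early exit).
#' @return an object of class `"cppp_oracle"`: list with `decision`
#'   (logical), `witness` (a completed `"cppp_extmat"` or `NULL`),
#'   `n_pairs`, and `n_completions` when counting.
#' @export
oracle_decide <- function(M, constraints = NULL, limit = 20L, count = FALSE) {
  M <- cppp_matrix(M)
  ext <- extend_matrix(M, constraints)
  oracle_decide_ext(ext, limit = limit, count = count)
}

# Same decision from an arbitrary partially completed extended matrix
# (used to audit search prunes against ground truth).
oracle_decide_ext <- function(ext, limit = 20L, count = FALSE) {
  stopifnot(inherits(ext, "cppp_extmat"))
  pairs <- incomplete_pairs(ext)
  ord <- order(pairs$species, pairs$character)
  pairs <- pairs[ord, , drop = FALSE]
  q <- nrow(pairs)
  if (q > limit)
    stop("instance too large for the oracle: ", q,
         " incomplete pairs (limit ", limit, ")")
  si <- match(pairs$species, ext$species)
  cj <- match(pairs$character, ext$characters)
  env <- new.env(parent = emptyenv())
  env$witness <- NULL
  env$n_valid <- 0L
  recurse <- function(cells, k) {
    if (!partial_ok(cells)) return(FALSE)
    if (k > q) {
      env$n_valid <- env$n_valid + 1L
      if (is.null(env$witness)) {
        ext$cells <- cells
        env$witness <- ext
      }
      return(!count) # early exit unless counting
    }
    cols <- pair_cols(cj[k])
    for (v in c(0L, 1L)) {
      if (v == 1L && ext$mask[si[k], cj[k]]) next # constrained: (0,0) only
      cells[si[k], cols] <- v
      if (recurse(cells, k + 1L)) return(TRUE)
    }
    FALSE
  }
  recurse(ext$cells, 1L)
  structure(list(decision = env$n_valid > 0L || !is.null(env$witness),
                 witness = env$witness, n_pairs = q,
                 n_completions = if (count) env$n_valid),
            class = "cppp_oracle")
}

# Forbidden-configuration check restricted to known (non-NA) cells: for a
# column pair, configurations are counted only over species where both
# cells are decided. NA-tolerant version of admits_directed_pp().
partial_ok <- function(cells) {
  A <- cells
  storage.mode(A) <- "numeric"
  K <- !is.na(A)
  A0 <- A
  A0[!K] <- 0
  Kn <- K + 0
  has11 <- crossprod(A0) > 0
  ones_vs_known <- crossprod(A0, Kn) # pairs (1, known)
  has10 <- (ones_vs_known - crossprod(A0)) > 0 # (1, 0) with both known
  forbidden <- has11 & has10 & t(has10)
  diag(forbidden) <- FALSE
  !any(forbidden)
}

#' @export
print.cppp_oracle <- function(x, ...) {
  cat("Oracle decision:",
      if (x$decision) "solvable" else "not solvable",
      "(", x$n_pairs, "incomplete pairs)\n")
  if (!is.null(x$n_completions))
    cat("  valid completions:", x$n_completions, "\n")
  invisible(x)
}
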