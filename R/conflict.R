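#' Conflict graph of a binary matrix
#'
#' Two characters conflict when their column pair induces all four
#' configurations (0,0), (0,1), (1,0), (1,1) over the species. The conflict
#' graph has the characters as vertices and the conflicting pairs as edges;
#' instances whose conflict graph is edgeless are solvable in polynomial
#' time (see [solve_edgeless()]).
#'
#' @param M a binary matrix (see [cppp_matrix()]).
#' @return an object of class `"cppp_conflict"`: list with `characters` and
#'   `edges`, a 2-column character matrix of conflicting pairs.
#' @examples
#' M <- cppp_matrix(rbind(c(1, 0), c(1, 1), c(0, 1)))
#' conflict_graph(M) # edgeless: configuration (0,0) is missing
#' @export
conflict_graph <- function(M) {
  M <- cppp_matrix(M)
  A <- M
  storage.mode(A) <- "numeric"
  has11 <- crossprod(A) > 0
  has10 <- crossprod(A, 1 - A) > 0
  has00 <- crossprod(1 - A) > 0
  conf <- has11 & has10 & t(has10) & has00
  diag(conf) <- FALSE
  idx <- which(conf & upper.tri(conf), arr.ind = TRUE)
  edges <- cbind(colnames(M)[idx[, 1L]], colnames(M)[idx[, 2L]])
  structure(list(characters = colnames(M), edges = edges),
            class = "cppp_conflict")
}

#' @export
print.cppp_conflict <- function(x, ...) {
  cat("Conflict graph:", length(x$characters), "characters,",
      nrow(x$edges), "conflicting pairs\n")
  if (nrow(x$edges))
    cat(paste0("  ", x$edges[, 1L], " -- ", x$edges[, 2L]), sep = "\n")
  invisible(x)
}

#' Is a conflict graph edgeless?
#' @param g a `"cppp_conflict"` object.
#' @return `TRUE` when no two characters conflict.
#' @export
is_edgeless <- function(g) nrow(g$edges) == 0L
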