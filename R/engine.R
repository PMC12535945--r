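#' Boolean matrix kernels
#'
#' The engine works with plain 0/1 matrices and vectors and three kernels:
#' elementwise addition (OR), multiplication (AND-OR inner product) and
#' equality. All deductive machinery below — transitive closure of a
#' binary relation, and the iterative-extension fixpoint over a reaction
#' network — is expressed in these kernels only.
#'
#' @name bool-kernels
NULL

as_bool <- function(x) {
  x <- (x != 0)
  storage.mode(x) <- "integer"
  x
}

check_same_shape <- function(A, B) {
  da <- if (is.matrix(A)) dim(A) else length(A)
  db <- if (is.matrix(B)) dim(B) else length(B)
  if (!identical(da, db)) {
    stop("boolean kernel shape mismatch: ", paste(da, collapse = "x"),
         " vs ", paste(db, collapse = "x"), call. = FALSE)
  }
}

#' Elementwise Boolean kernels: ADD, NOT, EQ
#'
#' `ADD` is elementwise OR, `NOT` elementwise complement, `EQ` tests
#' whether all entries agree (returns a logical scalar).
#'
#' @param kind one of `"ADD"`, `"NOT"`, `"EQ"`.
#' @param A,B 0/1 matrices or vectors (`B` ignored for `NOT`).
#' @return a 0/1 object of the shape of `A`, or a logical for `EQ`.
#' @export
bool_elementwise <- function(kind = c("ADD", "NOT", "EQ"), A, B = NULL) {
  kind <- match.arg(kind)
  A <- as_bool(A)
  if (kind == "NOT") return(as_bool(1L - A))
  if (is.null(B)) stop("kernel ", kind, " needs two operands", call. = FALSE)
  B <- as_bool(B)
  check_same_shape(A, B)
  if (kind == "ADD") return(as_bool(A | B))
  all(A == B)
}

#' Boolean matrix multiplication
#'
#' `(AB)[i, k] = OR_j (A[i, j] AND B[j, k])`: the integer matrix product
#' thresholded at one.
#'
#' @param A,B 0/1 matrices (or vectors, following R's `%*%` conformance).
#' @return a 0/1 matrix.
#' @export
bool_mul <- function(A, B) {
  A <- as_bool(A)
  B <- as_bool(B)
  na <- if (is.matrix(A)) ncol(A) else length(A)
  nb <- if (is.matrix(B)) nrow(B) else length(B)
  if (na != nb) {
    stop("boolean multiplication shape mismatch: inner dimensions ",
         na, " vs ", nb, call. = FALSE)
  }
  as_bool(A %*% B)
}

#' Transitive closure of a Boolean relation matrix
#'
#' Computes R+, reachability in one or more steps, under the usual
#' recursive pathway reading of a binary relation (`pathway(X,Y)` holds
#' iff `reaction(X,Y)` or `reaction(X,Z)` and `pathway(Z,Y)`). Two
#' equivalent schedules are provided: repeated single-step sweeps
#' (`square = FALSE`) or repeated squaring (`square = TRUE`).
#'
#' @param R square 0/1 matrix.
#' @param square use the repeated-squaring schedule.
#' @return the closure matrix R+ (0/1, same shape).
#' @export
transitive_closure <- function(R, square = FALSE) {
  R <- as_bool(R)
  if (!is.matrix(R) || nrow(R) != ncol(R)) {
    stop("transitive closure requires a square matrix", call. = FALSE)
  }
  if (nrow(R) == 0L) return(R)
  acc <- R
  repeat {
    nxt <- if (square) {
      bool_elementwise("ADD", acc, bool_mul(acc, acc))
    } else {
      bool_elementwise("ADD", acc, bool_mul(acc, R))
    }
    if (bool_elementwise("EQ", nxt, acc)) return(acc)
    acc <- nxt
  }
}

#' Iterative-extension fixpoint: producible metabolites
#'
#' Starting from a source vector `v0`, repeatedly fire every active
#' reaction whose full reactant set is available and add its products,
#' until no new metabolite appears. Availability is tested with one
#' Boolean multiplication against the complement vector: reaction `j` is
#' blocked iff `(R1 NOT(v))[j] = 1`, i.e. it has at least one reactant
#' outside `v`. Active reactions with empty reactant sets fire whenever
#' their mask bit is on.
#'
#' The per-step update is
#' `v <- ADD(v, t(R2) MUL (mask AND NOT blocked))`, so one iteration
#' costs a constant number of matrix-vector kernels; the fixpoint is
#' reached in at most `n + 1` iterations for `n` metabolites (each round
#' either adds a metabolite or is the last), giving O(n^2) binary
#' operations when the reaction count is O(n).
#'
#' @param v0 0/1 source vector over metabolites.
#' @param R1,R2 reactant/product matrices from [encode_matrices()].
#' @param mask 0/1 activity vector over reactions (default: all active).
#' @return an object of class `bmlp_fixpoint`: list with `vstar` (the
#'   final 0/1 vector), `trace` (matrix whose rows are v_0 .. v_K) and
#'   `iterations` (K, the number of update steps performed).
#' @export
bmlp_ie <- function(v0, R1, R2, mask = NULL) {
  v0 <- as_bool(v0)
  R1 <- as_bool(R1)
  R2 <- as_bool(R2)
  nm <- ncol(R1)
  nr <- nrow(R1)
  if (!identical(dim(R1), dim(R2))) {
    stop("R1 and R2 dimensions differ", call. = FALSE)
  }
  if (length(v0) != nm) {
    stop("v0 length ", length(v0), " does not match ", nm, " metabolites",
         call. = FALSE)
  }
  if (is.null(mask)) mask <- rep(1L, nr)
  mask <- as_bool(mask)
  if (length(mask) != nr) {
    stop("mask length ", length(mask), " does not match ", nr, " reactions",
         call. = FALSE)
  }

  trace <- list(v0)
  v <- v0
  k <- 0L
  repeat {
    blocked <- if (nr > 0L) {
      drop(bool_mul(R1, matrix(bool_elementwise("NOT", v), ncol = 1L)))
    } else {
      integer(0L)
    }
    enabled <- as_bool(mask & !blocked)
    produced <- if (nr > 0L) {
      drop(bool_mul(t(R2), matrix(enabled, ncol = 1L)))
    } else {
      integer(nm)
    }
    vnext <- bool_elementwise("ADD", v, produced)
    k <- k + 1L
    trace[[length(trace) + 1L]] <- vnext
    if (bool_elementwise("EQ", vnext, v)) break
    if (k > nm + 1L) {
      stop("internal error: fixpoint not reached within n+1 iterations",
           call. = FALSE)
    }
    v <- vnext
  }
  tr <- do.call(rbind, trace)
  colnames(tr) <- colnames(R1)
  vstar <- trace[[length(trace)]]
  names(vstar) <- colnames(R1)
  structure(list(vstar = vstar, trace = tr, iterations = k),
            class = "bmlp_fixpoint")
}

#' @export
print.bmlp_fixpoint <- function(x, ...) {
  cat(sprintf("<bmlp_fixpoint> %d/%d metabolites producible in %d iterations\n",
              sum(x$vstar), length(x$vstar), x$iterations))
  invisible(x)
}

#' Producible metabolites for a network, medium and deletion set
#'
#' Convenience wrapper: encodes the network, builds the medium vector and
#' the reaction mask, and runs [bmlp_ie()].
#'
#' @inheritParams reaction_mask
#' @param medium character vector of source metabolite ids.
#' @return character vector of producible metabolite ids.
#' @export
producible_metabolites <- function(net, medium, hypothesis = NULL,
                                   deleted = character()) {
  enc <- encode_matrices(net)
  fp <- bmlp_ie(medium_vector(net, medium), enc$R1, enc$R2,
                reaction_mask(net, hypothesis, deleted))
  net$metabolites[fp$vstar == 1L]
}

#' Naive forward-chaining saturation (reference semantics)
#'
#' Symbolic oracle for [bmlp_ie()]: repeatedly fire any active reaction
#' whose reactant set is contained in the current metabolite set, adding
#' its products, until saturation. Quadratic and slow by design; used to
#' cross-check the matrix engine.
#'
#' @param net a [metabolic_network()].
#' @param medium character vector of source metabolite ids.
#' @param mask 0/1 vector over reactions (default all active).
#' @return sorted character vector of reachable metabolite ids.
#' @export
forward_chain_oracle <- function(net, medium, mask = NULL) {
  stopifnot(inherits(net, "metabolic_network"))
  if (is.null(mask)) mask <- rep(1L, n_reactions(net))
  have <- match(unique(as.character(medium)), net$metabolites)
  if (anyNA(have)) stop("unknown metabolite in medium", call. = FALSE)
  have <- sort(have)
  repeat {
    added <- FALSE
    for (j in seq_len(n_reactions(net))) {
      if (mask[[j]] == 0) next
      r <- net$reactions[[j]]
      if (all(r$reactants %in% have)) {
        new <- setdiff(r$products, have)
        if (length(new) > 0L) {
          have <- sort(c(have, new))
          added <- TRUE
        }
      }
    }
    if (!added) break
  }
  sort(net$metabolites[have])
}
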