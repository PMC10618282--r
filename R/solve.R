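#' Solution container for the induced surface charge
#'
#' Per-facet scaled surface charge density `c = rho/eps0` (units V/m), with
#' references to the head model and, when available, the coil and the
#' operator configuration that produced it.
#'
#' @param c numeric vector, length = facet count.
#' @param head the `head_model`.
#' @param coil optional [coil_model()].
#' @param operator optional [bem_operator()] used for the solve.
#' @return object of class `charge_solution`.
#' @export
charge_solution <- function(c, head, coil = NULL, operator = NULL) {
  c <- as.numeric(c)
  if (length(c) != head$n_facets)
    stop("solution length must equal the facet count ", head$n_facets)
  if (!all(is.finite(c))) stop("solution contains non-finite values")
  structure(list(c = c, head = head, coil = coil, operator = operator),
            class = "charge_solution")
}

#' @export
print.charge_solution <- function(x, ...) {
  cat(sprintf(
    "charge_solution: N = %d facets, max |c| = %.4g V/m, net charge fraction = %.2e\n",
    length(x$c), max(abs(x$c)),
    abs(sum(x$c * x$head$areas)) / sum(abs(x$c) * x$head$areas)))
  invisible(x)
}

#' Iterative (GMRES) solution
#'
#' Full (no-restart) GMRES on the matrix-free operator, left residual
#' relative to `||b||`; the second-kind system is well conditioned and no
#' preconditioner is used.  Reaching `max_iter` sets `converged = FALSE`
#' rather than raising an error.
#'
#' @param op a [bem_operator()].
#' @param b right-hand side from [build_rhs()].
#' @param tol relative residual tolerance in (0, 1).
#' @param max_iter maximum iterations.
#' @param coil optional coil stored in the returned solution.
#' @return list of class `bem_iterative_report` with `solution`
#'   (a [charge_solution()]), `iterations`, `residual_history`, `converged`.
#' @export
solve_iterative <- function(op, b, tol = 1e-6, max_iter = 200, coil = NULL) {
  if (anyNA(b) || !all(is.finite(b))) stop("right-hand side contains NaN/Inf")
  if (tol <= 0 || tol >= 1) stop("tol must be in (0, 1)")
  N <- length(b)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) {
    return(structure(list(solution = charge_solution(rep(0, N), op$head,
                                                     coil, op),
                          iterations = 0L,
                          residual_history = numeric(0), converged = TRUE),
                     class = "bem_iterative_report"))
  }
  V <- matrix(0, N, max_iter + 1)
  H <- matrix(0, max_iter + 1, max_iter)
  cs <- sn <- numeric(max_iter)
  g <- numeric(max_iter + 1)
  V[, 1] <- b / bnorm
  g[1] <- bnorm
  hist <- numeric(0)
  k <- 0L
  for (j in seq_len(max_iter)) {
    w <- apply_operator(op, V[, j])
    for (i in seq_len(j)) {           # modified Gram-Schmidt
      H[i, j] <- sum(w * V[, i])
      w <- w - H[i, j] * V[, i]
    }
    H[j + 1, j] <- sqrt(sum(w^2))
    breakdown <- H[j + 1, j] < 1e-14 * bnorm
    if (!breakdown) V[, j + 1] <- w / H[j + 1, j]
    for (i in seq_len(j - 1)) {       # apply stored Givens rotations
      t1 <- cs[i] * H[i, j] + sn[i] * H[i + 1, j]
      H[i + 1, j] <- -sn[i] * H[i, j] + cs[i] * H[i + 1, j]
      H[i, j] <- t1
    }
    d <- sqrt(H[j, j]^2 + H[j + 1, j]^2)
    cs[j] <- H[j, j] / d
    sn[j] <- H[j + 1, j] / d
    H[j, j] <- d
    H[j + 1, j] <- 0
    g[j + 1] <- -sn[j] * g[j]
    g[j] <- cs[j] * g[j]
    k <- j
    hist <- c(hist, abs(g[j + 1]) / bnorm)
    if (hist[j] <= tol || breakdown) break
  }
  y <- backsolve(H[seq_len(k), seq_len(k), drop = FALSE], g[seq_len(k)])
  x <- as.numeric(V[, seq_len(k), drop = FALSE] %*% y)
  structure(list(solution = charge_solution(x, op$head, coil, op),
                 iterations = k, residual_history = hist,
                 converged = hist[k] <= tol),
            class = "bem_iterative_report")
}

#' @export
print.bem_iterative_report <- function(x, ...) {
  cat(sprintf("GMRES: %d iterations, final relative residual %.3e (%s)\n",
              x$iterations,
              if (length(x$residual_history)) tail(x$residual_history, 1) else 0,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# Morton (z-curve) spatial ordering of facet centroids, 10 bits per axis
morton_order <- function(centroids) {
  q <- apply(centroids, 2, function(v) {
    r <- range(v)
    span <- max(r[2] - r[1], .Machine$double.xmin)
    pmin(as.integer(floor((v - r[1]) / span * 1024)), 1023L)
  })
  key <- numeric(nrow(q))
  for (b_ in 0:9) {
    bit <- matrix(bitwAnd(as.vector(q), as.integer(2^b_)) > 0, nrow(q))
    key <- key + bit[, 1] * 2^(3 * b_) + bit[, 2] * 2^(3 * b_ + 1) +
      bit[, 3] * 2^(3 * b_ + 2)
  }
  order(key)
}

#' Direct factorization of the boundary operator
#'
#' Assembles the dense operator and factorizes it once so that many
#' right-hand sides (coil placements) can be solved cheaply.  The
#' `"dense"` method is a plain LU with partial pivoting.  The
#' `"compressed"` method reorders facets along a Morton (octree-leaf)
#' space-filling curve, replaces every off-diagonal block by an
#' adaptive-rank truncated-SVD approximation at the requested precision
#' (hierarchically low-rank structure of the Coulomb kernel), and then
#' performs the block elimination (LU) on the compressed operator.  The
#' accuracy contract of the compressed path is agreement with the dense
#' solve at about the requested precision, not asymptotic speed.
#'
#' @param head a `head_model`.
#' @param method `"dense"` or `"compressed"`.
#' @param precision compression precision (relative Frobenius tolerance per
#'   block) for the compressed method.
#' @param quadrature_order observation-facet quadrature order.
#' @param block_size block size of the compressed partition.
#' @param cap dense-assembly facet cap.
#' @return object of class `bem_factorization` with a reusable
#'   decomposition, `N`, `build_precision`, `build_seconds`, and for the
#'   compressed method the retained block ranks.
#' @export
factorize_direct <- function(head, method = c("dense", "compressed"),
                             precision = 1e-4, quadrature_order = 1,
                             block_size = 256, cap = 20000) {
  method <- match.arg(method)
  t0 <- proc.time()[["elapsed"]]
  A <- assemble_dense(head, quadrature_order, cap)
  N <- nrow(A)
  perm <- seq_len(N)
  ranks <- NULL
  if (method == "compressed") {
    precision <- check_precision(precision)
    perm <- morton_order(head$centroids)
    A <- A[perm, perm]
    nb <- ceiling(N / block_size)
    brk <- split(seq_len(N), rep(seq_len(nb), each = block_size,
                                 length.out = N))
    ranks <- matrix(NA_integer_, nb, nb)
    for (ib in seq_len(nb)) {
      for (jb in seq_len(nb)) {
        if (ib == jb) next
        blk <- A[brk[[ib]], brk[[jb]], drop = FALSE]
        s <- svd(blk)
        fn2 <- sum(s$d^2)
        if (fn2 == 0) { ranks[ib, jb] <- 0L; next }
        # smallest rank whose discarded tail is below precision * ||blk||_F
        tail2 <- rev(cumsum(rev(s$d^2)))
        r <- which(tail2 <= precision^2 * fn2)[1] - 1L
        if (is.na(r)) r <- length(s$d)
        ranks[ib, jb] <- r
        if (r < length(s$d)) {
          A[brk[[ib]], brk[[jb]]] <- if (r == 0) 0 else
            s$u[, seq_len(r), drop = FALSE] %*%
            (s$d[seq_len(r)] * t(s$v[, seq_len(r), drop = FALSE]))
        }
      }
    }
  }
  # force the dense (dgeMatrix) LU path: Matrix() would classify special
  # cases like the half-identity (K = 0) as diagonal and route them to a
  # sparse factorization
  Ad <- methods::as(methods::as(methods::as(A, "dMatrix"),
                                "generalMatrix"), "unpackedMatrix")
  dec <- tryCatch(Matrix::lu(Ad),
                  error = function(e)
                    stop("factorization failed (singular block?): ",
                         conditionMessage(e)))
  structure(list(method = method, N = N, build_precision =
                   if (method == "compressed") precision else
                     .Machine$double.eps,
                 lu = dec, perm = perm, block_ranks = ranks,
                 head = head, quadrature_order = quadrature_order,
                 build_seconds = proc.time()[["elapsed"]] - t0),
            class = "bem_factorization")
}

#' @export
print.bem_factorization <- function(x, ...) {
  cat(sprintf("bem_factorization: N = %d, method = %s, built in %.2f s\n",
              x$N, x$method, x$build_seconds))
  if (!is.null(x$block_ranks)) {
    r <- x$block_ranks[!is.na(x$block_ranks)]
    cat(sprintf("  off-diagonal block ranks: mean %.1f, max %d (full %d)\n",
                mean(r), max(r), min(x$N, 256)))
  }
  invisible(x)
}

#' Solve with a prebuilt factorization
#'
#' One triangular solve per right-hand side; a multi-column `B` gives
#' bitwise the same result as solving column by column (columns are always
#' processed independently).
#'
#' @param fact a [bem_factorization()].
#' @param B numeric vector or N x k matrix of right-hand sides.
#' @return vector or matrix of solutions matching `B`.
#' @export
solve_factored <- function(fact, B) {
  vec <- is.null(dim(B))
  B <- as.matrix(B)
  if (nrow(B) != fact$N) stop("right-hand side length must be ", fact$N)
  X <- matrix(0, fact$N, ncol(B))
  for (k in seq_len(ncol(B))) {
    xp <- as.numeric(Matrix::solve(fact$lu, B[fact$perm, k]))
    X[fact$perm, k] <- xp
  }
  if (vec) as.numeric(X) else X
}

#' Save / load a factorization cache
#'
#' Binary container with an 8-byte magic/version header (`TMSBEMF1`)
#' followed by the serialized factorization, so that the
#' factorize-once-per-subject workflow survives process restarts.
#'
#' @param fact a [bem_factorization()].
#' @param path cache file path.
#' @export
save_factorization <- function(fact, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("TMSBEMF1"), con)
  writeBin(serialize(fact, NULL), con)
  invisible(path)
}

#' @rdname save_factorization
#' @export
load_factorization <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8))
  if (magic != "TMSBEMF1")
    stop("not a tmsbem factorization cache (bad magic '", magic, "')")
  obj <- unserialize(readBin(con, "raw", file.size(path) - 8))
  if (!inherits(obj, "bem_factorization")) stop("corrupt factorization cache")
  obj
}

#' One-call solve
#'
#' Convenience wrapper: builds the right-hand side for a coil and solves
#' either iteratively or with a (possibly supplied) direct factorization.
#'
#' @param head a `head_model`.
#' @param coil a [coil_model()].
#' @param method `"iterative"` or `"direct"`.
#' @param precision operator / factorization precision.
#' @param tol GMRES relative residual tolerance.
#' @param quadrature_order facet quadrature order.
#' @param factorization optional prebuilt [factorize_direct()] result.
#' @param operator optional prebuilt [bem_operator()].
#' @param direct_method factorization method when none is supplied.
#' @return a [charge_solution()]; for the iterative path the GMRES report
#'   is attached as attribute `"report"`.
#' @export
tms_solve <- function(head, coil, method = c("iterative", "direct"),
                      precision = 1e-4, tol = 1e-6, quadrature_order = 1,
                      factorization = NULL, operator = NULL,
                      direct_method = "dense") {
  method <- match.arg(method)
  b <- build_rhs(head, coil, quadrature_order)
  if (method == "iterative") {
    op <- if (is.null(operator))
      bem_operator(head, precision, quadrature_order = quadrature_order)
    else operator
    rep_ <- solve_iterative(op, b, tol = tol, coil = coil)
    sol <- rep_$solution
    attr(sol, "report") <- rep_
    sol
  } else {
    fact <- if (is.null(factorization))
      factorize_direct(head, direct_method, precision, quadrature_order)
    else factorization
    charge_solution(solve_factored(fact, b), head, coil)
  }
}
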