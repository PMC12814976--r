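# Minimal reverse-mode automatic differentiation over dense matrices.
#
# The equivariant denoiser and the bond refiner are small graph networks
# trained with gradient descent; this tape provides exactly the operator
# set they need (matrix product, broadcasting add/mul, SiLU, batch
# normalization, gather/segment-sum for message passing, softmax
# cross-entropy). Values are eagerly computed; backward walks the tape in
# reverse, accumulating gradients. Correctness is pinned down by
# finite-difference tests.

#' Create an autodiff tape
#'
#' @return A tape object (environment) exposing `leaf`, `param`, arithmetic
#'   ops, `backward(node)` and `grad(name)`.
#' @export
fd_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- list(); tp$back <- list(); tp$parents <- list()
  tp$param_of <- character(0)
  n_node <- 0L

  push <- function(val, parents = integer(), backfn = NULL) {
    n_node <<- n_node + 1L
    tp$vals[[n_node]] <- val
    tp$parents[[n_node]] <- parents
    tp$back[n_node] <- list(backfn)
    n_node
  }

  as_mat <- function(x) if (is.matrix(x)) x else matrix(x, nrow = 1)

  tp$leaf <- function(value) push(as_mat(value))

  tp$param <- function(name, value) {
    id <- push(as_mat(value))
    tp$param_of[[as.character(id)]] <- name
    id
  }

  tp$value <- function(id) tp$vals[[id]]

  tp$matmul <- function(a, b) {
    force(a); force(b)
    A <- tp$vals[[a]]; B <- tp$vals[[b]]
    push(A %*% B, c(a, b), function(g) {
      list(g %*% t(B), crossprod(A, g))
    })
  }

  # add/sub with row-broadcast (bias rows) support
  bcast2 <- function(a, b, f, dfa, dfb) {
    force(a); force(b)
    A <- tp$vals[[a]]; B <- tp$vals[[b]]
    brow <- nrow(B) == 1 && nrow(A) != 1
    bcol <- ncol(B) == 1 && ncol(A) != 1
    Bx <- B
    if (brow) {
      Bx <- if (nrow(A) == 0) matrix(numeric(0), 0, ncol(A)) else
        matrix(B, nrow(A), ncol(A), byrow = TRUE)
    }
    if (bcol) Bx <- matrix(B, nrow(A), ncol(A))
    push(f(A, Bx), c(a, b), function(g) {
      gB <- dfb(g, A, Bx)
      if (brow) gB <- matrix(colSums(gB), 1)
      if (bcol) gB <- matrix(rowSums(gB), ncol = 1)
      list(dfa(g, A, Bx), gB)
    })
  }

  tp$add <- function(a, b) bcast2(a, b, `+`,
                                  function(g, A, B) g,
                                  function(g, A, B) g)
  tp$sub <- function(a, b) bcast2(a, b, `-`,
                                  function(g, A, B) g,
                                  function(g, A, B) -g)
  tp$mul <- function(a, b) bcast2(a, b, `*`,
                                  function(g, A, B) g * B,
                                  function(g, A, B) g * A)

  tp$scale <- function(a, s) {
    force(a)
    A <- tp$vals[[a]]
    push(A * s, a, function(g) list(g * s))
  }
  tp$addc <- function(a, s) {
    force(a)
    A <- tp$vals[[a]]
    push(A + s, a, function(g) list(g))
  }
  tp$square <- function(a) {
    force(a)
    A <- tp$vals[[a]]
    push(A^2, a, function(g) list(2 * g * A))
  }
  tp$sqrt_ <- function(a) {
    force(a)
    A <- tp$vals[[a]]
    out <- sqrt(A)
    push(out, a, function(g) list(g * 0.5 / pmax(out, 1e-12)))
  }
  tp$exp_ <- function(a) {
    force(a)
    out <- exp(tp$vals[[a]])
    push(out, a, function(g) list(g * out))
  }
  tp$recip <- function(a) {
    force(a)
    A <- tp$vals[[a]]
    push(1 / A, a, function(g) list(-g / A^2))
  }
  tp$silu <- function(a) {
    force(a)
    A <- tp$vals[[a]]
    s <- 1 / (1 + exp(-A))
    push(A * s, a, function(g) list(g * s * (1 + A * (1 - s))))
  }

  tp$rowsums <- function(a) {
    force(a)
    A <- tp$vals[[a]]
    push(matrix(rowSums(A), ncol = 1), a, function(g) {
      list(matrix(g, nrow(A), ncol(A)))
    })
  }

  tp$sum_ <- function(a) {
    force(a)
    A <- tp$vals[[a]]
    push(matrix(sum(A), 1, 1), a, function(g) {
      list(matrix(as.numeric(g), nrow(A), ncol(A)))
    })
  }

  tp$gather <- function(a, idx) {
    force(a)
    A <- tp$vals[[a]]
    push(A[idx, , drop = FALSE], a, function(g) {
      gA <- matrix(0, nrow(A), ncol(A))
      if (length(idx)) {
        agg <- rowsum(g, group = idx)
        gA[as.integer(rownames(agg)), ] <- agg
      }
      list(gA)
    })
  }

  # sum rows of `a` by segment id (1..nseg); rows of the output align with
  # segment ids. Segments with no members yield zero rows.
  tp$segsum <- function(a, seg, nseg) {
    force(a)
    A <- tp$vals[[a]]
    out <- matrix(0, nseg, ncol(A))
    if (nrow(A)) {
      agg <- rowsum(A, group = seg)
      out[as.integer(rownames(agg)), ] <- agg
    }
    push(out, a, function(g) list(g[seg, , drop = FALSE]))
  }

  tp$concat <- function(ids) {
    force(ids)
    mats <- lapply(ids, function(i) tp$vals[[i]])
    cols <- vapply(mats, ncol, integer(1))
    ends <- cumsum(cols); starts <- c(1, utils::head(ends, -1) + 1)
    push(do.call(cbind, mats), as.integer(ids), function(g) {
      lapply(seq_along(ids), function(k) {
        g[, starts[k]:ends[k], drop = FALSE]
      })
    })
  }

  # Column-wise batch normalization (training statistics). Returns the
  # normalized output; running-stat bookkeeping lives with the caller.
  tp$batchnorm <- function(a, gamma, beta, eps = 1e-5) {
    force(a); force(gamma); force(beta)
    A <- tp$vals[[a]]; G <- tp$vals[[gamma]]; B <- tp$vals[[beta]]
    n <- nrow(A)
    mu <- colMeans(A)
    va <- colMeans(A^2) - mu^2
    sd_ <- sqrt(va + eps)
    xhat <- sweep(sweep(A, 2, mu), 2, sd_, `/`)
    out <- sweep(xhat, 2, as.numeric(G), `*`)
    out <- sweep(out, 2, as.numeric(B), `+`)
    push(out, c(a, gamma, beta), function(g) {
      gxh <- sweep(g, 2, as.numeric(G), `*`)
      xc <- sweep(A, 2, mu)
      dvar <- colSums(gxh * xc) * (-0.5) * (va + eps)^(-1.5)
      dmu <- colSums(sweep(gxh, 2, -1 / sd_, `*`)) +
        dvar * colMeans(-2 * xc)
      dx <- sweep(gxh, 2, sd_, `/`) +
        sweep(xc, 2, 2 * dvar / n, `*`) +
        matrix(dmu / n, n, ncol(A), byrow = TRUE)
      list(dx,
           matrix(colSums(g * xhat), 1),
           matrix(colSums(g), 1))
    })
  }

  # Normalization with frozen (running) statistics: a pure affine map.
  tp$batchnorm_eval <- function(a, gamma, beta, mu, va, eps = 1e-5) {
    force(a); force(gamma); force(beta)
    A <- tp$vals[[a]]; G <- tp$vals[[gamma]]; B <- tp$vals[[beta]]
    sd_ <- sqrt(va + eps)
    xhat <- sweep(sweep(A, 2, mu), 2, sd_, `/`)
    out <- sweep(sweep(xhat, 2, as.numeric(G), `*`), 2, as.numeric(B), `+`)
    push(out, c(a, gamma, beta), function(g) {
      gxh <- sweep(g, 2, as.numeric(G), `*`)
      list(sweep(gxh, 2, sd_, `/`),
           matrix(colSums(g * xhat), 1),
           matrix(colSums(g), 1))
    })
  }

  # Mean softmax cross-entropy against one-hot targets (per-row classes).
  tp$softmax_ce <- function(logits, onehot) {
    force(logits)
    L <- tp$vals[[logits]]
    m <- apply(L, 1, max)
    ex <- exp(L - m)
    p <- ex / rowSums(ex)
    n <- nrow(L)
    ce <- -sum(onehot * log(pmax(p, 1e-12))) / n
    push(matrix(ce, 1, 1), logits, function(g) {
      list(as.numeric(g) * (p - onehot) / n)
    })
  }

  tp$backward <- function(node) {
    grads <- vector("list", n_node)
    seedval <- tp$vals[[node]]
    grads[[node]] <- matrix(1, nrow(seedval), ncol(seedval))
    for (id in seq(node, 1L)) {
      g <- grads[[id]]
      if (is.null(g) || is.null(tp$back[[id]])) next
      pg <- tp$back[[id]](g)
      ps <- tp$parents[[id]]
      for (k in seq_along(ps)) {
        p <- ps[k]
        grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
      }
    }
    pg <- list()
    for (id_chr in names(tp$param_of)) {
      id <- as.integer(id_chr)
      nm <- tp$param_of[[id_chr]]
      g <- grads[[id]]
      if (is.null(g)) g <- matrix(0, nrow(tp$vals[[id]]), ncol(tp$vals[[id]]))
      pg[[nm]] <- if (is.null(pg[[nm]])) g else pg[[nm]] + g
    }
    tp$pgrads <- pg
    invisible(pg)
  }

  tp$grad <- function(name) tp$pgrads[[name]]
  tp
}
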