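# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and vectorized shortcuts) so that agreement is evidence,
# not tautology.

# textbook Pearson formula, elementwise loops
oracle_pearson <- function(x, y) {
  xb <- mean(x); yb <- mean(y)
  num <- 0; dx2 <- 0; dy2 <- 0
  for (i in seq_along(x)) {
    num <- num + (x[i] - xb) * (y[i] - yb)
    dx2 <- dx2 + (x[i] - xb)^2
    dy2 <- dy2 + (y[i] - yb)^2
  }
  num / sqrt(dx2 * dy2)
}

# BH step-up: adj_(i) = min_{j >= i} p_(j) * m / j, evaluated literally
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# partial correlation via the inverse-correlation-matrix identity
oracle_partial_inverse <- function(x, y, Z) {
  M <- cbind(x, y, as.matrix(Z))
  P <- solve(stats::cor(M))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# partial correlation via explicit residual-of-residuals two-stage OLS
oracle_partial_residuals <- function(x, y, Z) {
  Zm <- cbind(1, as.matrix(Z))
  rx <- x - Zm %*% solve(crossprod(Zm), crossprod(Zm, x))
  ry <- y - Zm %*% solve(crossprod(Zm), crossprod(Zm, y))
  oracle_pearson(as.numeric(rx), as.numeric(ry))
}

# recursive flood fill over a 3D logical array; returns a canonical
# partition (list of sorted linear-index vectors) for comparison
oracle_flood_fill <- function(binary, connectivity) {
  shape <- dim(binary)
  offs <- unname(as.matrix(expand.grid(-1:1, -1:1, -1:1)))
  nz <- rowSums(abs(offs))
  offs <- offs[switch(as.character(connectivity),
                      "6" = nz == 1, "18" = nz >= 1 & nz <= 2,
                      "26" = nz >= 1), , drop = FALSE]
  seen <- array(FALSE, shape)
  comps <- list()
  fill <- function(start) {
    stack <- list(start)
    comp <- integer(0)
    while (length(stack) > 0) {
      c0 <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- as.integer((c0[3] - 1) * shape[1] * shape[2] +
                        (c0[2] - 1) * shape[1] + c0[1])
      if (seen[i]) next
      seen[i] <<- TRUE
      comp <- c(comp, i)
      for (o in seq_len(nrow(offs))) {
        nb <- c0 + offs[o, ]
        if (all(nb >= 1) && all(nb <= shape) && binary[nb[1], nb[2], nb[3]]) {
          stack[[length(stack) + 1]] <- nb
        }
      }
    }
    sort(comp)
  }
  for (i in which(binary)) {
    if (!seen[i]) {
      comps[[length(comps) + 1]] <- fill(as.integer(arrayInd(i, shape)[1, ]))
    }
  }
  comps[order(vapply(comps, function(v) v[1], numeric(1)))]
}

# canonical partition from a label array, for comparison with the oracle
partition_from_labels <- function(labels) {
  labs <- sort(unique(labels[labels > 0]))
  comps <- lapply(labs, function(l) sort(which(labels == l)))
  comps[order(vapply(comps, function(v) v[1], numeric(1)))]
}

# small ratings fixture: 2 listeners, fully crossed, chosen values
make_tiny_ratings <- function(speaker = "s1",
                              lik = c(7, 1, 4), hos = c(1, 7, 4),
                              int = c(4, 4, 7)) {
  conds <- c("likeable", "hostile", "intelligent")
  do.call(rbind, lapply(c("l1", "l2"), function(l) {
    do.call(rbind, lapply(seq_along(conds), function(ci) {
      data.frame(listener_id = l, speaker_id = speaker, condition = conds[ci],
                 scale = conds, rating = c(lik[ci], hos[ci], int[ci]),
                 stringsAsFactors = FALSE)
    }))
  }))
}

# correlation matrix with specified off-diagonals in trait order
rsm_from_offdiag <- function(lh, li, hi) {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- lh
  m[1, 3] <- m[3, 1] <- li
  m[2, 3] <- m[3, 2] <- hi
  dimnames(m) <- list(c("likeable", "hostile", "intelligent"),
                      c("likeable", "hostile", "intelligent"))
  m
}
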