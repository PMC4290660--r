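# Independent oracles used to cross-check the package implementations.
# All are deliberately written with different algorithms than the package
# (quaternion eigendecomposition instead of SVD, plain dynamic programming,
# exhaustive search) and touch none of the package internals.

# Horn's quaternion characteristic-polynomial method for optimal
# superposition. Returns the minimum RMSD and the proper rotation that
# maps centered B onto centered A.
quat_fit <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  n <- nrow(A)
  cenA <- colMeans(A); cenB <- colMeans(B)
  Ac <- sweep(A, 2, cenA); Bc <- sweep(B, 2, cenB)
  S <- t(Bc) %*% Ac  # S[i,j] = sum b_i a_j
  K <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]
  ), 4, 4, byrow = TRUE)
  e <- eigen(K, symmetric = TRUE)
  lam <- e$values[1]
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)
  ), 3, 3, byrow = TRUE)
  msd <- (sum(Ac^2) + sum(Bc^2) - 2 * lam) / n
  list(rmsd = sqrt(max(msd, 0)), rotation = R, cenA = cenA, cenB = cenB)
}

quat_rmsd <- function(A, B) quat_fit(A, B)$rmsd

# superpose B onto A with the quaternion fit
quat_apply <- function(fit, B) {
  sweep(sweep(as.matrix(B), 2, fit$cenB) %*% t(fit$rotation), 2, fit$cenA, `+`)
}

# Brute-force minimum RMSD over proper rotations: Euler-angle grid then
# local refinement with optim. Translation is optimal at centered
# coordinates for any rotation.
grid_rmsd <- function(A, B, step_deg = 15) {
  Ac <- sweep(as.matrix(A), 2, colMeans(A))
  Bc <- sweep(as.matrix(B), 2, colMeans(B))
  rot_z <- function(t) matrix(c(cos(t),-sin(t),0, sin(t),cos(t),0, 0,0,1), 3, byrow = TRUE)
  rot_y <- function(t) matrix(c(cos(t),0,sin(t), 0,1,0, -sin(t),0,cos(t)), 3, byrow = TRUE)
  euler <- function(a, b, g) rot_z(a) %*% rot_y(b) %*% rot_z(g)
  obj <- function(p) {
    R <- euler(p[1], p[2], p[3])
    sqrt(mean(rowSums((Ac - Bc %*% t(R))^2)))
  }
  step <- step_deg * pi / 180
  grid <- expand.grid(a = seq(0, 2*pi - step, by = step),
                      b = seq(0, pi, by = step),
                      g = seq(0, 2*pi - step, by = step))
  vals <- apply(grid, 1, obj)
  starts <- grid[order(vals)[1:20], , drop = FALSE]
  best <- Inf
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(as.numeric(starts[i, ]), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
    best <- min(best, o$value)
  }
  best
}

# Gotoh affine-gap global alignment score; gap of length k costs
# open + extend * k (the Biostrings convention).
nw_score <- function(seq_a, seq_b, sub, open = 10, extend = 0.5) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -open - extend * (i - 1)
  for (j in 2:(m + 1)) Iy[1, j] <- -open - extend * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub[a[i - 1], b[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - extend,
                      Ix[i - 1, j] - extend)
      Iy[i, j] <- max(M[i, j - 1] - open - extend,
                      Iy[i, j - 1] - extend)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# Exhaustive-seed TM-score oracle: every contiguous fragment of every
# length >= 4 seeds a superposition, refined by quaternion fits on the
# pairs within the shrinking distance cutoff; the best score over all
# superpositions visited is reported.
tm_exhaustive <- function(model_ca, ref_ca, L_target) {
  d0 <- max(0.5, if (L_target > 15) 1.24 * (L_target - 15)^(1/3) - 1.8 else 0.5)
  n <- nrow(model_ca)
  d_start <- max(d0 + 1, 4.5)
  best <- 0
  score_pairs <- function(idx) {
    fit <- quat_fit(ref_ca[idx, , drop = FALSE], model_ca[idx, , drop = FALSE])
    moved <- quat_apply(fit, model_ca)
    rowSums((moved - ref_ca)^2)
  }
  for (fl in 4:n) {
    for (start in 1:(n - fl + 1)) {
      idx <- start:(start + fl - 1)
      for (iter in 1:20) {
        d2 <- score_pairs(idx)
        best <- max(best, sum(1 / (1 + d2 / d0^2)) / L_target)
        cut <- d_start
        repeat {
          inc <- which(d2 < cut^2)
          if (length(inc) >= 3 || cut <= 0.5) break
          cut <- cut - 0.5
        }
        if (length(inc) < 3) break
        if (length(inc) == length(idx) && all(inc == idx)) break
        idx <- inc
      }
    }
  }
  best
}

# Naive leader-then-Lloyd RMSD-radius clustering, all plain R loops and
# quaternion superpositions; same algorithm contract as kclust but a
# fully independent code path.
naive_kclust <- function(mats, radius, max_iter = 10) {
  n <- length(mats)
  centroids <- list(mats[[1]])
  assign <- integer(n)
  assign[1] <- 1L
  for (i in seq_len(n)[-1]) {
    placed <- FALSE
    for (k in seq_along(centroids)) {
      if (quat_rmsd(mats[[i]], centroids[[k]]) <= radius) {
        assign[i] <- k; placed <- TRUE; break
      }
    }
    if (!placed) {
      centroids[[length(centroids) + 1]] <- mats[[i]]
      assign[i] <- length(centroids)
    }
  }
  for (iter in seq_len(max_iter)) {
    for (k in seq_along(centroids)) {
      members <- which(assign == k)
      if (length(members) == 0) { centroids[k] <- list(NULL); next }
      acc <- matrix(0, nrow(mats[[1]]), 3)
      for (i in members) {
        fit <- quat_fit(centroids[[k]], mats[[i]])
        acc <- acc + quat_apply(fit, mats[[i]])
      }
      centroids[[k]] <- acc / length(members)
    }
    keep <- !vapply(centroids, is.null, logical(1))
    centroids <- centroids[keep]
    new_assign <- integer(n)
    for (i in seq_len(n)) {
      d <- vapply(centroids, function(cm) quat_rmsd(mats[[i]], cm), numeric(1))
      if (min(d) > radius) {
        centroids[[length(centroids) + 1]] <- mats[[i]]
        new_assign[i] <- length(centroids)
      } else {
        new_assign[i] <- which.min(d)
      }
    }
    stable <- identical(match(new_assign, unique(new_assign)),
                        match(assign, unique(assign)))
    assign <- new_assign
    if (stable) break
  }
  match(assign, unique(assign))
}
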