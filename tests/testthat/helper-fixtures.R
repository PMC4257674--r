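# Shared fixtures: small landmark sets, random rigid motions, and the
# dense thin-plate-spline reference solver used as the independent oracle.

make_set <- function(xyz, ids = sprintf("L%d", seq_len(nrow(xyz))),
                     feature_class = "OTHER", name = "fixture") {
  landmark_set(data.frame(id = ids, x = xyz[, 1], y = xyz[, 2],
                          z = xyz[, 3], feature_class = feature_class,
                          stringsAsFactors = FALSE),
               name = name, min_separation = 0)
}

make_pairing <- function(src_xyz, tgt_xyz,
                         ids = sprintf("L%d", seq_len(nrow(src_xyz)))) {
  pair_by_id(make_set(src_xyz, ids, name = "src"),
             make_set(tgt_xyz, ids, name = "tgt"))
}

random_points <- function(n, extent = c(400, 400, 150)) {
  cbind(runif(n, 0, extent[1]), runif(n, 0, extent[2]),
        runif(n, 0, extent[3]))
}

# uniform random proper rotation via QR of a Gaussian matrix
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# Independent dense TPS reference: solves the full (n+4) x (n+4) system
# [[K - lambda I, P], [t(P), 0]] [W; B] = [Y; 0] with base solve() (the
# smoothing term carries -lambda because the sign-positive kernel r is
# conditionally negative definite).
tps_dense_oracle <- function(src, tgt, lambda = 0) {
  n <- nrow(src)
  K <- as.matrix(dist(src))
  P <- cbind(1, src)
  M <- rbind(cbind(K - lambda * diag(n), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(tgt, matrix(0, 4, 3))
  sol <- solve(M, rhs)
  list(W = sol[1:n, , drop = FALSE],
       B = sol[(n + 1):(n + 4), , drop = FALSE])
}

# predicted positions under the dense oracle coefficients
tps_dense_predict <- function(oracle, src, pts) {
  K <- sqrt(pmax(outer(rowSums(pts^2), rowSums(src^2), `+`) -
                   2 * tcrossprod(pts, src), 0))
  cbind(1, pts) %*% oracle$B + K %*% oracle$W
}
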