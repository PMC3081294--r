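## Independent oracles used across the suite.  These deliberately share no
## code with the package internals: the Voronoi oracle enumerates cell
## vertices by brute-force triple intersection over ALL bisector planes
## (the package clips sequentially), polygon areas come from chull(), and
## the superposition oracle is a direct SVD Kabsch.

## Brute-force Voronoi cell of node i in point set P: every vertex is the
## intersection of three bisector planes that satisfies all bisector
## constraints.  Only valid for cells bounded by the other points of P
## (interior cells).  Returns volume and per-neighbor facet areas.
oracle_voronoi_cell <- function(P, i) {
  p <- P[i, ]
  Q <- P[-i, , drop = FALSE]
  map <- seq_len(nrow(P))[-i]
  rel <- sweep(Q, 2, p)
  dist <- sqrt(rowSums(rel^2))
  nrm <- rel / dist
  d <- dist / 2
  k <- nrow(Q)
  tri <- utils::combn(k, 3)
  verts <- matrix(NA_real_, 0, 3)
  for (t in seq_len(ncol(tri))) {
    A <- nrm[tri[, t], , drop = FALSE]
    if (abs(det(A)) < 1e-10) next
    v <- solve(A, d[tri[, t]])
    if (all(nrm %*% v - d <= 1e-7)) verts <- rbind(verts, v)
  }
  verts <- unique(round(verts, 7))
  if (nrow(verts) < 4) return(NULL)
  areas <- numeric(k)
  vol <- 0
  for (j in seq_len(k)) {
    on <- abs(verts %*% nrm[j, ] - d[j]) < 1e-5
    if (sum(on) < 3) next
    vv <- verts[on, , drop = FALSE]
    nj <- nrm[j, ]
    ref <- if (abs(nj[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * nj) * nj; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nj[2] * e1[3] - nj[3] * e1[2],
            nj[3] * e1[1] - nj[1] * e1[3],
            nj[1] * e1[2] - nj[2] * e1[1])
    u <- as.vector(vv %*% e1); w <- as.vector(vv %*% e2)
    h <- grDevices::chull(u, w)           # convex polygon vertex order
    u <- u[h]; w <- w[h]
    areas[j] <- 0.5 * abs(sum(u * c(w[-1], w[1]) - c(u[-1], u[1]) * w))
    vol <- vol + areas[j] * d[j] / 3
  }
  list(volume = vol,
       area = stats::setNames(areas[areas > 1e-7],
                              map[areas > 1e-7]))
}

## Direct Kabsch: rotation + translation superposing mobile[inds,] onto
## fixed[inds,], applied to the whole mobile matrix.
oracle_superpose <- function(fixed, mobile, inds) {
  A <- fixed[inds, , drop = FALSE]
  B <- mobile[inds, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(B, 2, cb)) %*% sweep(A, 2, ca)
  s <- svd(H)
  R <- s$v %*% diag(c(1, 1, sign(det(s$v %*% t(s$u))))) %*% t(s$u)
  sweep(sweep(mobile, 2, cb) %*% t(R), 2, ca, `+`)
}

## rigid rotation recovered from two conformations of the same rigid body
oracle_rigid_rotation <- function(A, B) {
  H <- t(sweep(A, 2, colMeans(A))) %*% sweep(B, 2, colMeans(B))
  s <- svd(H)
  s$v %*% diag(c(1, 1, sign(det(s$v %*% t(s$u))))) %*% t(s$u)
}

## a small hand-written PDB file with explicit atoms (text fixture)
write_mini_pdb <- function(path, residues) {
  ## residues: list of list(resid, chain, resno, atoms = list(name = xyz))
  lines <- character(0)
  k <- 0L
  for (r in residues) {
    for (an in names(r$atoms)) {
      k <- k + 1L
      xyz <- r$atoms[[an]]
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s%4s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        k, an, r$resid, r$chain, r$resno, xyz[1], xyz[2], xyz[3]))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

## ranked-set score lookup by id
score_of <- function(rs, ids) rs$score[match(ids, rs$id)]
rank_of <- function(rs, ids) rs$rank[match(ids, rs$id)]
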