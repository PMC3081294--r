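## 3D Voronoi tessellation by per-cell half-space vertex enumeration.
##
## Each Voronoi cell is the intersection of the bisector half-spaces between
## its node and every other point.  Cells are computed independently with an
## adaptive nearest-neighbor constraint set: a cell computed from the k
## nearest points is exact once every excluded point lies farther than twice
## the cell's largest vertex radius (its bisector cannot reach the cell).
## Unbounded cells are closed by a shell of dummy "solvent" points on an
## inflated sphere, oriented along the cloud's principal axes so that the
## whole construction is rigid-motion covariant.

.fibonacci_dirs <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

## Deterministic covariant frame: principal axes with sign fixed by the
## largest-magnitude component; right-handed.
.principal_frame <- function(xyz) {
  cc <- sweep(xyz, 2, colMeans(xyz))
  cv <- crossprod(cc) / max(1, nrow(xyz) - 1)
  e <- eigen(cv, symmetric = TRUE)$vectors
  for (j in 1:3) {
    k <- which.max(abs(e[, j]))
    if (e[k, j] < 0) e[, j] <- -e[, j]
  }
  if (det(e) < 0) e[, 3] <- -e[, 3]
  e
}

.bounding_shell <- function(xyz, shell_factor = 2, shell_spacing = 8) {
  ctr <- colMeans(xyz)
  rad <- sqrt(max(rowSums(sweep(xyz, 2, ctr)^2)))
  rs <- max(shell_factor * rad, rad + 12)
  n <- max(32L, ceiling(4 * pi * rs^2 / shell_spacing^2))
  dirs <- .fibonacci_dirs(n) %*% t(.principal_frame(xyz))
  sweep(dirs * rs, 2, ctr, `+`)
}

## Solvent blanket: dummy points on a body-frame grid, kept where their
## distance to the nearest node falls in [inner, outer].  The blanket hugs
## the molecular surface like a water layer, truncating surface and rim
## Voronoi facets at solvent distance, so measured interface areas do not
## depend on the distant closure shell.  Built in the cloud's principal
## frame, hence rigid-motion covariant.
.solvent_blanket <- function(xyz, r_in = 5, r_out = 10, spacing = 3.5) {
  fr <- .principal_frame(xyz)
  ctr <- colMeans(xyz)
  B <- sweep(xyz, 2, ctr) %*% fr          # body-frame coordinates
  lo <- apply(B, 2, min) - r_out - spacing
  hi <- apply(B, 2, max) + r_out + spacing
  gx <- seq(lo[1], hi[1], by = spacing)
  gy <- seq(lo[2], hi[2], by = spacing)
  gz <- seq(lo[3], hi[3], by = spacing)
  G <- as.matrix(expand.grid(gx, gy, gz))
  ## nearest-node distance, chunked
  dmin2 <- rep(Inf, nrow(G))
  b2 <- rowSums(B^2)
  step <- 50000L
  for (s in seq(1L, nrow(G), by = step)) {
    e <- min(s + step - 1L, nrow(G))
    gg <- G[s:e, , drop = FALSE]
    d2 <- outer(rowSums(gg^2), b2, `+`) - 2 * gg %*% t(B)
    dmin2[s:e] <- apply(d2, 1, min)
  }
  keep <- dmin2 >= r_in^2 & dmin2 <= r_out^2
  sweep(G[keep, , drop = FALSE] %*% t(fr), 2, ctr, `+`)
}

.cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

## One Voronoi cell by sequential half-space clipping (the Voro++ scheme).
## The cell starts as a large cube around its node and is clipped by the
## bisector plane of every other point, processed in nearness order with an
## early out: once the next point is farther than twice the current largest
## vertex radius its bisector cannot cut the cell, and neither can any
## later one.  Vertices are tracked as triples of defining plane ids so
## edges (vertex pairs sharing two planes) are combinatorial, not metric.
##
## Returns NULL on a degenerate configuration (duplicate points or a
## non-generic plane meeting), else per-clipped-point facet areas, the cell
## volume and vertex set.
.clip_cell <- function(p, P, others, d2, halfwidth) {
  ## planes: rows of N, offsets d; ids 1..6 are the cube faces
  nmax <- 6L + length(others)
  N <- matrix(0, nmax, 3)
  N[1:6, ] <- rbind(diag(3), -diag(3))
  dpl <- c(rep(halfwidth, 6), numeric(length(others)))
  h <- halfwidth
  V <- as.matrix(expand.grid(c(-h, h), c(-h, h), c(-h, h)))
  Tm <- cbind(ifelse(V[, 1] > 0, 1L, 4L),
              ifelse(V[, 2] > 0, 2L, 5L),
              ifelse(V[, 3] > 0, 3L, 6L))
  ## cube plane ids: 1..3 are +x,+y,+z, 4..6 are -x,-y,-z
  np <- 6L
  plane_pt <- integer(nmax)      # plane id -> index into `others`
  rmax2 <- max(rowSums(V^2))
  tol <- 1e-9 * max(1, h)
  for (oi in seq_along(others)) {
    if (d2[oi] > 4 * rmax2 + 1e-9) break
    q <- P[others[oi], ]
    rel <- q - p
    dist <- sqrt(sum(rel^2))
    if (dist < 1e-9) return(NULL)          # duplicate point
    np <- np + 1L
    N[np, ] <- rel / dist
    dpl[np] <- dist / 2
    plane_pt[np] <- oi
    s <- as.vector(V %*% N[np, ]) - dpl[np]
    out <- s > tol
    if (!any(out)) next                    # redundant plane, no facet
    if (all(out)) return(NULL)             # node outside own cell: degenerate
    ## edges crossing the plane: an in/out vertex pair sharing 2 plane ids
    inV <- which(!out); outV <- which(out)
    keys_of <- function(tr) c(paste(tr[c(1, 2)], collapse = "|"),
                              paste(tr[c(1, 3)], collapse = "|"),
                              paste(tr[c(2, 3)], collapse = "|"))
    ink <- lapply(inV, function(v) keys_of(sort(Tm[v, ])))
    outk <- lapply(outV, function(v) keys_of(sort(Tm[v, ])))
    inmap <- structure(rep(inV, each = 3), names = unlist(ink))
    outmap <- structure(rep(outV, each = 3), names = unlist(outk))
    shared <- intersect(names(inmap), names(outmap))
    if (length(shared) < 3) return(NULL)   # non-generic contact
    newV <- matrix(0, length(shared), 3)
    newT <- matrix(0L, length(shared), 3)
    for (e in seq_along(shared)) {
      ids <- as.integer(strsplit(shared[e], "|", fixed = TRUE)[[1]])
      A <- rbind(N[ids[1], ], N[ids[2], ], N[np, ])
      b <- c(dpl[ids[1]], dpl[ids[2]], dpl[np])
      x <- tryCatch(solve(A, b), error = function(err) NULL)
      if (is.null(x)) return(NULL)
      newV[e, ] <- x
      newT[e, ] <- c(ids, np)
    }
    V <- rbind(V[!out, , drop = FALSE], newV)
    Tm <- rbind(Tm[!out, , drop = FALSE], newT)
    if (nrow(V) < 4) return(NULL)
    rmax2 <- max(rowSums(V^2))
  }
  ## a surviving cube face means the shell failed to close the cell
  if (any(Tm %in% 1:6)) return(NULL)
  ## facet areas by defining plane
  ids <- sort(unique(as.vector(Tm)))
  nbr_idx <- integer(0); nbr_area <- numeric(0)
  vol <- 0
  for (j in ids) {
    on <- which(rowSums(Tm == j) > 0)
    if (length(on) < 3) next
    vv <- V[on, , drop = FALSE]
    nj <- N[j, ]
    ref <- if (abs(nj[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- ref - sum(ref * nj) * nj
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nj[2] * e1[3] - nj[3] * e1[2],
            nj[3] * e1[1] - nj[1] * e1[3],
            nj[1] * e1[2] - nj[2] * e1[1])
    u <- as.vector(vv %*% e1); w <- as.vector(vv %*% e2)
    o <- order(atan2(w - mean(w), u - mean(u)))
    a <- 0.5 * abs(sum(u[o] * c(w[o][-1], w[o][1]) -
                         c(u[o][-1], u[o][1]) * w[o]))
    if (a <= 0) next
    vol <- vol + a * dpl[j] / 3
    nbr_idx <- c(nbr_idx, plane_pt[j])
    nbr_area <- c(nbr_area, a)
  }
  list(volume = vol, nbr_oi = nbr_idx, area = nbr_area, verts = V)
}

## Exact Voronoi cells of nodes 1..n_real within the merged cloud
## rbind(xyz_real, shell).  Returns per-node volume and neighbor facet
## areas (global indices into the merged cloud), or a degeneracy marker.
.voronoi_cells <- function(xyz_real, shell) {
  P <- rbind(xyz_real, shell)
  n <- nrow(xyz_real)
  ctr <- colMeans(P)
  halfwidth <- 3 * sqrt(max(rowSums(sweep(P, 2, ctr)^2)))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    p <- P[i, ]
    d2 <- rowSums(sweep(P, 2, p)^2)
    others <- order(d2)[-1]
    cell <- .clip_cell(p, P, others, d2[others], halfwidth)
    if (is.null(cell)) return(structure(list(), class = "vs_degenerate"))
    keep <- cell$area > 1e-7
    out[[i]] <- list(volume = cell$volume,
                     nbr = others[cell$nbr_oi[keep]],
                     area = cell$area[keep])
  }
  out
}

#' Voronoi/Delaunay tessellation of a node cloud
#'
#' Builds the Voronoi tessellation (and its dual Delaunay adjacency) of a
#' merged two-partner node set, or of a single partner. Cells are bounded
#' by implicit solvent: a blanket of dummy points hugging the surface (kept
#' where their distance to the nearest node falls in
#' \[\code{solvent_in}, \code{solvent_out}\]) truncates surface and rim
#' facets at water distance, and a sphere shell at \code{shell_factor}
#' times the bounding radius closes anything the blanket misses. Dummy
#' points never appear in the reported adjacency; measured interface areas
#' are insensitive to the outer shell because the blanket cuts every
#' interface facet first. Returns per-node cell volumes and the
#' shared-facet area of every adjacent node pair.
#'
#' @param x a [complex_conformation()], a [partner_structure()], or a
#'   numeric n x 3 coordinate matrix
#' @param partner optional integer vector (1/2) tagging each row of a
#'   matrix input with its partner; derived automatically for conformations
#' @param shell_factor outer shell radius as a multiple of the bounding
#'   radius
#' @param shell_spacing approximate outer-shell dummy spacing, Angstrom
#' @param solvent_in,solvent_out blanket distance band from the nearest
#'   node, Angstrom; set \code{solvent_out <= solvent_in} to disable the
#'   blanket
#' @param solvent_spacing blanket grid spacing, Angstrom
#' @return object of class \code{voronoi_tessellation}: node coordinates,
#'   partner tags, per-node cell \code{volume}, \code{solvent} contact
#'   flags, and \code{pairs} (data frame \code{i}, \code{j}, \code{area},
#'   \code{cross})
#' @export
tessellate <- function(x, partner = NULL, shell_factor = 2, shell_spacing = 8,
                       solvent_in = 5, solvent_out = 10,
                       solvent_spacing = 3.5) {
  if (inherits(x, "complex_conformation")) {
    nr <- nrow(x$receptor$xyz)
    xyz <- rbind(x$receptor$xyz, x$ligand$xyz)
    partner <- rep(1:2, c(nr, nrow(x$ligand$xyz)))
  } else if (inherits(x, "partner_structure")) {
    xyz <- x$xyz
    partner <- rep(1L, nrow(xyz))
  } else {
    xyz <- as.matrix(x)
    if (is.null(partner)) partner <- rep(1L, nrow(xyz))
  }
  ## real nodes need not bound the diagram themselves: the solvent shell
  ## closes every cell, so two nodes already define a valid (single-facet)
  ## tessellation
  if (nrow(xyz) < 2) stop("degenerate geometry: fewer than 2 nodes")
  dummies <- function(xy) {
    bl <- if (solvent_out > solvent_in && solvent_spacing > 0)
      .solvent_blanket(xy, solvent_in, solvent_out, solvent_spacing)
    else matrix(0, 0, 3)
    rbind(bl, .bounding_shell(xy, shell_factor, shell_spacing))
  }
  shell <- dummies(xyz)
  cells <- .voronoi_cells(xyz, shell)
  if (inherits(cells, "vs_degenerate")) {
    ## deterministic jitter-and-retry once
    set.seed(nrow(xyz))
    message("degenerate point configuration; retrying with 1e-3 jitter")
    xyz_j <- xyz + matrix(stats::runif(length(xyz), -5e-4, 5e-4), ncol = 3)
    cells <- .voronoi_cells(xyz_j, dummies(xyz_j))
    if (inherits(cells, "vs_degenerate")) stop("degenerate geometry")
    xyz <- xyz_j
  }
  n <- nrow(xyz)
  volume <- vapply(cells, `[[`, 0, "volume")
  solvent <- vapply(cells, function(cl) any(cl$nbr > n), FALSE)
  ii <- rep(seq_len(n), vapply(cells, function(cl) length(cl$nbr), 0L))
  jj <- unlist(lapply(cells, `[[`, "nbr"), use.names = FALSE)
  aa <- unlist(lapply(cells, `[[`, "area"), use.names = FALSE)
  real <- jj <= n
  ii <- ii[real]; jj <- jj[real]; aa <- aa[real]
  lo <- pmin(ii, jj); hi <- pmax(ii, jj)
  key <- paste(lo, hi)
  agg <- tapply(aa, key, max)
  ks <- strsplit(names(agg), " ", fixed = TRUE)
  pi_ <- as.integer(vapply(ks, `[[`, "", 1L))
  pj_ <- as.integer(vapply(ks, `[[`, "", 2L))
  o <- order(pi_, pj_)
  pairs <- data.frame(i = pi_[o], j = pj_[o], area = unname(agg)[o])
  pairs$cross <- partner[pairs$i] != partner[pairs$j]
  structure(list(xyz = xyz, partner = partner, volume = volume,
                 solvent = solvent, pairs = pairs,
                 n_shell = nrow(shell)),
            class = "voronoi_tessellation")
}

#' @export
print.voronoi_tessellation <- function(x, ...) {
  cat("Voronoi tessellation:", nrow(x$xyz), "nodes,",
      nrow(x$pairs), "Delaunay-adjacent pairs,",
      sum(x$pairs$cross), "cross-partner\n")
  invisible(x)
}

#' Delaunay neighbor lists of a tessellation
#' @param tess a [tessellate()] result
#' @return list of integer vectors, neighbors of each node
#' @export
neighbors_of <- function(tess) {
  n <- nrow(tess$xyz)
  nb <- vector("list", n)
  for (r in seq_len(nrow(tess$pairs))) {
    i <- tess$pairs$i[r]; j <- tess$pairs$j[r]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

#' Interface definition of a two-partner tessellation
#'
#' A residue is at the interface iff its Voronoi cell shares a positive-area
#' facet with at least one node of the other partner. Residues that also
#' touch the bounding (solvent) shell are kept.
#'
#' @param tess a [tessellate()] result with two partner tags
#' @return list with \code{cross_pairs} (data frame \code{i}, \code{j},
#'   \code{area}; indices into the merged node set, \code{i} in partner 1),
#'   \code{partner1} and \code{partner2} (interface node indices)
#' @export
interface_of <- function(tess) {
  cp <- tess$pairs[tess$pairs$cross, , drop = FALSE]
  ## orient: i in partner 1
  swap <- tess$partner[cp$i] == 2L
  tmp <- cp$i[swap]; cp$i[swap] <- cp$j[swap]; cp$j[swap] <- tmp
  cp <- cp[order(cp$i, cp$j), c("i", "j", "area")]
  rownames(cp) <- NULL
  list(cross_pairs = cp,
       partner1 = sort(unique(cp$i)),
       partner2 = sort(unique(cp$j)))
}

#' Voronoi interface area
#'
#' Sum of the shared Voronoi facet areas over all cross-partner node pairs
#' (each unordered pair counted once). Zero iff the partners share no facet.
#'
#' @param tess a [tessellate()] result
#' @return interface area in square Angstroms
#' @export
interface_area <- function(tess) {
  sum(tess$pairs$area[tess$pairs$cross])
}
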