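#' Construct a two-partner complex conformation
#'
#' @param receptor,ligand [partner_structure()] objects; the receptor frame
#'   is the fixed reference, the ligand carries any rigid transform
#' @param transform generating transform triple (receptor vector id, ligand
#'   vector id, spin angle in degrees) or \code{NULL} for external poses
#' @param provenance one of \code{"native"}, \code{"decoy"}, \code{"external"}
#' @param rmsd_to_native ligand-node RMSD to the native pose, Angstrom
#' @return object of class \code{complex_conformation}
#' @export
complex_conformation <- function(receptor, ligand, transform = NULL,
                                 provenance = "external",
                                 rmsd_to_native = NA_real_) {
  stopifnot(inherits(receptor, "partner_structure"),
            inherits(ligand, "partner_structure"))
  structure(list(receptor = receptor, ligand = ligand,
                 transform = transform,
                 provenance = match.arg(provenance,
                                        c("native", "decoy", "external")),
                 rmsd_to_native = rmsd_to_native),
            class = "complex_conformation")
}

#' @export
print.complex_conformation <- function(x, ...) {
  cat("Complex conformation [", x$provenance, "]: ",
      nrow(x$receptor$xyz), " + ", nrow(x$ligand$xyz), " residue nodes\n",
      sep = "")
  if (!is.null(x$transform))
    cat("  transform: u=", x$transform[1], " v=", x$transform[2],
        " spin=", x$transform[3], "°\n", sep = "")
  if (!is.na(x$rmsd_to_native))
    cat("  RMSD to native:", round(x$rmsd_to_native, 2), "A\n")
  invisible(x)
}

.unit <- function(v) v / sqrt(sum(v^2))

## Rodrigues rotation matrix, axis need not be unit
.rot_axis_angle <- function(axis, theta) {
  u <- .unit(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

## deterministic unit vector perpendicular to a
.perp <- function(a) {
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(ref - sum(ref * a) * a)
}

## Rotation taking unit vector a onto unit vector b
.rot_align <- function(a, b) {
  d <- sum(a * b)
  if (d > 1 - 1e-12) return(diag(3))
  if (d < -1 + 1e-12) return(.rot_axis_angle(.perp(a), pi))
  .rot_axis_angle(c(a[2] * b[3] - a[3] * b[2],
                    a[3] * b[1] - a[1] * b[3],
                    a[1] * b[2] - a[2] * b[1]),
                  acos(max(-1, min(1, d))))
}

#' Surface pseudo-normal vectors of a partner
#'
#' For each node, the vectors to its Delaunay neighbors (within the partner)
#' are summed and negated, so the resulting vector points away from the
#' local neighbor mass. Vectors that still point inward (negative dot
#' product with the node-minus-centroid direction, a star-convexity
#' heuristic) are flipped. Near-cancelling sums are dropped with a warning.
#' Each vector's length is the radius of the sphere holding the residue's
#' mean volume.
#'
#' @param partner a [partner_structure()] with at least 4 nodes
#' @param tess optional pre-computed per-partner [tessellate()] result
#' @param drop_tol vectors with raw norm below this (Angstrom) are dropped
#' @return data frame with columns \code{node}, \code{ux,uy,uz} (unit
#'   direction) and \code{len} (Angstrom)
#' @export
pseudo_normals <- function(partner, tess = NULL, drop_tol = 1e-6) {
  if (nrow(partner$xyz) < 4) stop("degenerate structure: need >= 4 nodes")
  if (is.null(tess)) tess <- tessellate(partner)
  nb <- neighbors_of(tess)
  ctr <- colMeans(partner$xyz)
  out <- lapply(seq_len(nrow(partner$xyz)), function(i) {
    p <- partner$xyz[i, ]
    raw <- -colSums(partner$xyz[nb[[i]], , drop = FALSE] -
                      matrix(p, length(nb[[i]]), 3, byrow = TRUE))
    nr <- sqrt(sum(raw^2))
    if (nr < drop_tol) return(NULL)
    dir <- raw / nr
    if (sum(dir * (p - ctr)) < 0) dir <- -dir
    len <- (3 * partner$volume[i] / (4 * pi))^(1 / 3)
    data.frame(node = i, ux = dir[1], uy = dir[2], uz = dir[3], len = len)
  })
  dropped <- sum(vapply(out, is.null, FALSE))
  if (dropped > 0)
    warning(dropped, " node(s) with cancelling neighbor sums dropped")
  do.call(rbind, Filter(Negate(is.null), out))
}

## Rigidly place the ligand for one (receptor vector, ligand vector, spin)
## triple.  Returns the transformed ligand coordinate matrix.
.pose_ligand_xyz <- function(receptor, ligand, u_row, v_row, spin_deg) {
  p_u <- receptor$xyz[u_row$node, ]
  u <- c(u_row$ux, u_row$uy, u_row$uz)
  t_u <- p_u + u_row$len * u
  p_v <- ligand$xyz[v_row$node, ]
  v <- c(v_row$ux, v_row$uy, v_row$uz)
  t_v <- p_v + v_row$len * v
  ## step 1: tips coincide
  L <- sweep(ligand$xyz, 2, t_u - t_v, `+`)
  ## step 2: rotate about the tip so v is anti-parallel to u
  R1 <- .rot_align(v, -u)
  L <- sweep(sweep(L, 2, t_u) %*% t(R1), 2, t_u, `+`)
  ## spin-zero convention: the ligand's first principal axis, projected on
  ## the plane perpendicular to u, is aligned with a fixed reference
  ## perpendicular to u
  cc <- sweep(L, 2, colMeans(L))
  ev <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 1]
  if (sum(ev * cc[1, ]) < 0) ev <- -ev
  e1p <- ev - sum(ev * u) * u
  if (sqrt(sum(e1p^2)) < 1e-8) {
    ev <- eigen(crossprod(cc), symmetric = TRUE)$vectors[, 2]
    if (sum(ev * cc[1, ]) < 0) ev <- -ev
    e1p <- ev - sum(ev * u) * u
  }
  e1p <- .unit(e1p)
  axes <- diag(3)
  ref <- axes[, which.min(abs(axes %*% u))]
  r0 <- .unit(ref - sum(ref * u) * u)
  ## signed angle from e1p to r0 about u
  phi0 <- atan2(sum(u * c(e1p[2] * r0[3] - e1p[3] * r0[2],
                          e1p[3] * r0[1] - e1p[1] * r0[3],
                          e1p[1] * r0[2] - e1p[2] * r0[1])),
                sum(e1p * r0))
  ## step 3: spin about the common axis
  R2 <- .rot_axis_angle(u, phi0 + spin_deg * pi / 180)
  sweep(sweep(L, 2, t_u) %*% t(R2), 2, t_u, `+`)
}

#' Enumerate candidate poses by pseudo-normal pairing
#'
#' For every pair of surface vectors (one per partner) the ligand is
#' translated so the vector tips coincide, rotated so the vectors are
#' anti-parallel, and spun about the common axis in \code{step_deg}
#' increments, yielding \code{nU * nV * (360/step_deg)} candidate rigid-body
#' poses.
#'
#' @param receptor,ligand [partner_structure()] objects
#' @param step_deg spin increment in degrees; must divide 360
#' @param rec_vectors,lig_vectors optional pre-computed [pseudo_normals()]
#' @return object of class \code{pose_set}: a transform manifest (data frame
#'   \code{ru}, \code{lv}, \code{spin}) carrying the partners and vectors as
#'   attributes; poses are realized lazily with [realize_pose()]
#' @export
enumerate_poses <- function(receptor, ligand, step_deg = 5,
                            rec_vectors = NULL, lig_vectors = NULL) {
  if (360 %% step_deg != 0) stop("step_deg must divide 360")
  if (is.null(rec_vectors)) rec_vectors <- pseudo_normals(receptor)
  if (is.null(lig_vectors)) lig_vectors <- pseudo_normals(ligand)
  spins <- seq(0, 360 - step_deg, by = step_deg)
  manifest <- expand.grid(spin = spins,
                          lv = seq_len(nrow(lig_vectors)),
                          ru = seq_len(nrow(rec_vectors)))[, c("ru", "lv", "spin")]
  rownames(manifest) <- NULL
  structure(manifest, class = c("pose_set", "data.frame"),
            receptor = receptor, ligand = ligand,
            rec_vectors = rec_vectors, lig_vectors = lig_vectors)
}

#' Realize one pose from a pose manifest
#'
#' @param poses a [enumerate_poses()] manifest
#' @param k row index of the pose to build
#' @return a [complex_conformation()] with the generating transform recorded
#' @export
realize_pose <- function(poses, k) {
  stopifnot(inherits(poses, "pose_set"))
  receptor <- attr(poses, "receptor"); ligand <- attr(poses, "ligand")
  rv <- attr(poses, "rec_vectors"); lv <- attr(poses, "lig_vectors")
  row <- poses[k, ]
  lig2 <- ligand
  lig2$xyz <- .pose_ligand_xyz(receptor, ligand, rv[row$ru, ], lv[row$lv, ],
                               row$spin)
  complex_conformation(receptor, lig2,
                       transform = c(row$ru, row$lv, row$spin),
                       provenance = "decoy")
}

#' Ligand-node RMSD between two conformations
#'
#' Root-mean-square deviation over ligand node positions with the receptor
#' held fixed (no re-superposition); the standard decoy-vs-native distance
#' for rigid-body poses sharing a receptor frame.
#'
#' @param a,b [complex_conformation()] objects with identical receptors and
#'   equally sized ligands
#' @return RMSD in Angstrom
#' @export
node_rmsd <- function(a, b) {
  if (nrow(a$ligand$xyz) != nrow(b$ligand$xyz))
    stop("ligand node counts differ")
  sqrt(mean(rowSums((a$ligand$xyz - b$ligand$xyz)^2)))
}

## evaluate expr with a local RNG seed, restoring global state
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Filter and sample a labeled decoy set
#'
#' Applies the decoy-retention filters: a pose is kept when its Voronoi
#' interface area is at least \code{min_area} and its ligand-node RMSD to
#' the native conformation exceeds \code{min_rmsd}. \code{per_native}
#' survivors are then sampled uniformly with the given seed and labeled
#' \code{provenance = "decoy"}.
#'
#' @param native the native [complex_conformation()]
#' @param poses a list of [complex_conformation()] objects, or a
#'   [enumerate_poses()] manifest (realized on the fly)
#' @param min_area minimum Voronoi interface area, square Angstrom
#' @param min_rmsd minimum RMSD to native, Angstrom (strict)
#' @param per_native number of decoys to sample per native
#' @param seed RNG seed for the uniform sample
#' @return list of decoy conformations with \code{rmsd_to_native} stored
#' @export
build_decoy_set <- function(native, poses, min_area = 400, min_rmsd = 10,
                            per_native = 15, seed = 1) {
  get_pose <- if (inherits(poses, "pose_set")) {
    function(k) realize_pose(poses, k)
  } else {
    function(k) poses[[k]]
  }
  n <- if (inherits(poses, "pose_set")) nrow(poses) else length(poses)
  survivors <- list()
  for (k in seq_len(n)) {
    conf <- get_pose(k)
    r <- node_rmsd(conf, native)
    if (r <= min_rmsd) next
    a <- interface_area(tessellate(conf))
    if (a < min_area) next
    conf$provenance <- "decoy"
    conf$rmsd_to_native <- r
    survivors[[length(survivors) + 1L]] <- conf
  }
  if (length(survivors) < per_native) {
    warning("only ", length(survivors), " poses survive the filters; ",
            "returning all of them")
    return(survivors)
  }
  idx <- .with_seed(seed, sample.int(length(survivors), per_native))
  survivors[sort(idx)]
}
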