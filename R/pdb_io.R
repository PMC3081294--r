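#' Construct a coarse-grain partner structure
#'
#' One node per residue. Nodes carry the residue type, its physico-chemical
#' category, the mean residue volume, and a 3D position in Angstroms.
#'
#' @param xyz numeric matrix n x 3 of node positions (Angstrom)
#' @param restype character vector of one-letter residue codes, length n
#' @param chain chain identifier (single letter), recycled
#' @param resno residue sequence numbers (default 1..n)
#' @param label free-text role tag, conventionally "receptor" or "ligand"
#' @param volumes named volume vector as returned by [volume_table()]
#' @param source provenance string (file path or synthetic tag)
#' @return object of class \code{partner_structure}
#' @export
partner_structure <- function(xyz, restype, chain = "A", resno = NULL,
                              label = "receptor", volumes = volume_table(),
                              source = "in-memory") {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3) stop("xyz must have 3 columns")
  n <- nrow(xyz)
  if (length(restype) != n) stop("restype length must match nrow(xyz)")
  if (n < 1) stop("empty structure")
  category <- category_of(restype)
  if (is.null(resno)) resno <- seq_len(n)
  structure(list(
    label = label,
    xyz = unname(xyz),
    chain = rep_len(as.character(chain), n),
    resno = as.integer(resno),
    restype = restype,
    category = category,
    volume = unname(volumes[restype]),
    source = source
  ), class = "partner_structure")
}

#' @export
print.partner_structure <- function(x, ...) {
  cat("Coarse-grain partner structure (", x$label, ")\n", sep = "")
  cat("  ", nrow(x$xyz), " residue nodes, chains: ",
      paste(unique(x$chain), collapse = ","), "\n", sep = "")
  cat("  source: ", x$source, "\n", sep = "")
  invisible(x)
}

#' @export
length.partner_structure <- function(x) nrow(x$xyz)

.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

#' Load a partner structure from a PDB file
#'
#' Builds the coarse one-node-per-residue model: each node sits at the
#' unweighted geometric center of the residue's side-chain heavy atoms plus
#' the C-alpha; glycine uses its C-alpha alone. Hydrogens, waters and hetero
#' groups are excluded; alternate locations are resolved to the highest
#' occupancy. Residues lacking a C-alpha are skipped with a warning.
#'
#' @param pdb_path path to a PDB file
#' @param chain chain identifier(s) to load; \code{NULL} loads all chains
#' @param volumes named mean-volume vector (see [volume_table()])
#' @param label role tag stored on the result
#' @return a [partner_structure()]
#' @export
load_partner <- function(pdb_path, chain = NULL, volumes = volume_table(),
                         label = "receptor") {
  pdb <- bio3d::read.pdb(pdb_path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (!is.null(chain)) {
    if (!any(at$chain %in% chain)) stop("chain not found: ",
                                        paste(chain, collapse = ","))
    at <- at[at$chain %in% chain, , drop = FALSE]
  }
  ## drop hydrogens (by element symbol when present, else by atom name)
  if ("elesy" %in% names(at) && any(!is.na(at$elesy))) {
    at <- at[!(at$elesy %in% c("H", "D")), , drop = FALSE]
  } else {
    at <- at[!grepl("^[0-9]*[HD]", at$elety), , drop = FALSE]
  }
  at <- at[at$resid %in% names(.aa321), , drop = FALSE]
  if (nrow(at) == 0) stop("degenerate structure: no standard residues")

  ## resolve alternate locations to highest occupancy
  at$insert[is.na(at$insert)] <- ""
  rid <- paste(at$chain, at$resno, at$insert, sep = "|")
  akey <- paste(rid, at$elety, sep = "|")
  occ <- if ("o" %in% names(at)) ifelse(is.na(at$o), 1, at$o) else rep(1, nrow(at))
  keep <- unlist(lapply(split(seq_len(nrow(at)), akey), function(ix) {
    ix[which.max(occ[ix])]
  }), use.names = FALSE)
  at <- at[sort(keep), , drop = FALSE]
  rid <- paste(at$chain, at$resno, at$insert, sep = "|")

  res_order <- unique(rid)  # file order, stable
  nodes <- lapply(res_order, function(r) {
    ra <- at[rid == r, , drop = FALSE]
    if (!("CA" %in% ra$elety)) {
      warning("residue ", r, " has no CA; skipped")
      return(NULL)
    }
    use <- ra$elety == "CA" | !(ra$elety %in% .backbone_atoms)
    ra <- ra[use, , drop = FALSE]
    list(
      pos = colMeans(cbind(ra$x, ra$y, ra$z)),
      chain = ra$chain[1], resno = ra$resno[1],
      restype = unname(.aa321[ra$resid[1]])
    )
  })
  nodes <- Filter(Negate(is.null), nodes)
  if (length(nodes) < 4) stop("degenerate structure: fewer than 4 usable residues")
  partner_structure(
    xyz = do.call(rbind, lapply(nodes, `[[`, "pos")),
    restype = vapply(nodes, `[[`, "", "restype"),
    chain = vapply(nodes, `[[`, "", "chain"),
    resno = vapply(nodes, function(n) as.integer(n$resno), 1L),
    label = label, volumes = volumes, source = pdb_path
  )
}

#' Write a partner structure as a PDB file
#'
#' Serializes the coarse model: one CA pseudo-atom per residue node, placed
#' at the node position, so that a reload reproduces the node set exactly
#' (to the PDB 3-decimal coordinate precision).
#'
#' @param partner a [partner_structure()]
#' @param path output file path
#' @return \code{path}, invisibly
#' @export
write_partner <- function(partner, path) {
  n <- nrow(partner$xyz)
  bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(partner$xyz)),
    type = rep("ATOM", n),
    resno = partner$resno,
    resid = unname(.aa123[partner$restype]),
    eleno = seq_len(n),
    elety = rep("CA", n),
    chain = partner$chain,
    o = rep(1, n), b = rep(0, n)
  )
  invisible(path)
}
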