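## Quality assessment of ranked conformations: fraction of native contacts
## (fnat), interface and ligand RMSD on the coarse node model, the
## fnat-only and full CAPRI quality classes, confusion-matrix metrics,
## ranked-tail enrichment and report tables.  All RMSDs are coarse-node
## RMSDs: the package never builds all-atom models.

#' Cross-partner residue contacts of a conformation
#'
#' @param conf a [complex_conformation()]
#' @param cutoff node-node distance cutoff in Angstrom (distance mode)
#' @param mode \code{"distance"} (default, pairs within \code{cutoff}) or
#'   \code{"voronoi"} (pairs sharing a Voronoi facet)
#' @return two-column matrix of (receptor node, ligand node) index pairs
#' @export
contact_pairs <- function(conf, cutoff = 5, mode = c("distance", "voronoi")) {
  mode <- match.arg(mode)
  if (mode == "voronoi") {
    ifc <- interface_of(tessellate(conf))
    cp <- as.matrix(ifc$cross_pairs[, c("i", "j")])
    cp[, 2] <- cp[, 2] - nrow(conf$receptor$xyz)
    colnames(cp) <- c("rec", "lig")
    return(cp)
  }
  R <- conf$receptor$xyz; L <- conf$ligand$xyz
  d2 <- outer(rowSums(R^2), rowSums(L^2), `+`) - 2 * R %*% t(L)
  idx <- which(d2 <= cutoff^2, arr.ind = TRUE)
  m <- cbind(rec = idx[, 1], lig = idx[, 2])
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Fraction of native contacts
#'
#' The fraction of the native structure's cross-partner residue contacts
#' that are reproduced by the evaluated conformation.
#'
#' @param pred,native [complex_conformation()] objects over the same
#'   partners (same residue numbering)
#' @param cutoff,mode contact definition, see [contact_pairs()]
#' @return fnat in \[0, 1\]
#' @export
fnat <- function(pred, native, cutoff = 5, mode = "distance") {
  if (nrow(pred$receptor$xyz) != nrow(native$receptor$xyz) ||
      nrow(pred$ligand$xyz) != nrow(native$ligand$xyz))
    stop("partner node counts differ between prediction and native")
  nat <- contact_pairs(native, cutoff, mode)
  if (nrow(nat) == 0) stop("undefined fnat: native has no contacts")
  prd <- contact_pairs(pred, cutoff, mode)
  natk <- paste(nat[, 1], nat[, 2])
  prdk <- paste(prd[, 1], prd[, 2])
  sum(natk %in% prdk) / length(natk)
}

## least-squares superposition of mobile onto fixed using the index set,
## via bio3d; returns the transformed full mobile coordinate matrix
.superpose <- function(fixed, mobile, inds) {
  n <- nrow(mobile)
  fitted <- bio3d::fit.xyz(
    fixed = as.vector(t(fixed)), mobile = as.vector(t(mobile)),
    fixed.inds = bio3d::atom2xyz(inds), mobile.inds = bio3d::atom2xyz(inds))
  matrix(fitted, ncol = 3, byrow = TRUE)[seq_len(n), , drop = FALSE]
}

.node_matrix <- function(conf) rbind(conf$receptor$xyz, conf$ligand$xyz)

#' Interface and ligand RMSD (coarse nodes)
#'
#' i_rmsd: RMSD over the native interface residues after least-squares
#' superposition of the prediction's interface nodes onto the native's.
#' l_rmsd: RMSD over the smaller partner's nodes after superposing the
#' larger partner. Both are computed on the one-node-per-residue model.
#'
#' @param pred,native [complex_conformation()] objects over the same
#'   partners
#' @param cutoff contact cutoff defining the native interface, Angstrom
#' @return named numeric vector \code{c(i_rmsd, l_rmsd)}
#' @export
interface_and_ligand_rmsd <- function(pred, native, cutoff = 5) {
  if (nrow(pred$receptor$xyz) != nrow(native$receptor$xyz) ||
      nrow(pred$ligand$xyz) != nrow(native$ligand$xyz))
    stop("unmappable residues: partner node counts differ")
  nr <- nrow(native$receptor$xyz)
  nat_xyz <- .node_matrix(native)
  prd_xyz <- .node_matrix(pred)
  cp <- contact_pairs(native, cutoff)
  if (nrow(cp) == 0) stop("native has no contacts; interface undefined")
  iface <- sort(unique(c(cp[, "rec"], cp[, "lig"] + nr)))
  fitted <- .superpose(nat_xyz, prd_xyz, iface)
  i_rmsd <- sqrt(mean(rowSums((fitted[iface, , drop = FALSE] -
                                 nat_xyz[iface, , drop = FALSE])^2)))
  nl <- nrow(native$ligand$xyz)
  big <- if (nr >= nl) seq_len(nr) else nr + seq_len(nl)
  small <- if (nr >= nl) nr + seq_len(nl) else seq_len(nr)
  fitted <- .superpose(nat_xyz, prd_xyz, big)
  l_rmsd <- sqrt(mean(rowSums((fitted[small, , drop = FALSE] -
                                 nat_xyz[small, , drop = FALSE])^2)))
  c(i_rmsd = i_rmsd, l_rmsd = l_rmsd)
}

#' fnat-only quality class
#'
#' High (fnat >= 0.5), Medium (0.3 <= fnat < 0.5), Acceptable
#' (0.1 <= fnat < 0.3), Incorrect (fnat < 0.1).
#'
#' @param fnat numeric vector of fnat values
#' @return character vector of classes
#' @export
fnat_class <- function(fnat) {
  ifelse(fnat >= 0.5, "High",
         ifelse(fnat >= 0.3, "Medium",
                ifelse(fnat >= 0.1, "Acceptable", "Incorrect")))
}

#' Full CAPRI quality class
#'
#' Standard three-measure criteria: High requires fnat >= 0.5 with
#' I_RMSD <= 1 or L_RMSD <= 1; Medium requires fnat >= 0.3 with
#' I_RMSD <= 2 or L_RMSD <= 5 (including fnat >= 0.5 poses failing the
#' High RMSD test); Acceptable requires fnat >= 0.1 with I_RMSD <= 4 or
#' L_RMSD <= 10 (including fnat >= 0.3 poses failing the Medium RMSD
#' test); otherwise Incorrect. With missing RMSDs, falls back to
#' [fnat_class()] with a warning.
#'
#' @param fnat,i_rmsd,l_rmsd quality measures (vectors recycle)
#' @return character vector of classes
#' @export
capri_class <- function(fnat, i_rmsd = NA, l_rmsd = NA) {
  n <- max(length(fnat), length(i_rmsd), length(l_rmsd))
  fnat <- rep_len(fnat, n); i_rmsd <- rep_len(i_rmsd, n)
  l_rmsd <- rep_len(l_rmsd, n)
  out <- character(n)
  for (k in seq_len(n)) {
    if (is.na(i_rmsd[k]) || is.na(l_rmsd[k])) {
      warning("missing RMSD; falling back to the fnat-only class")
      out[k] <- fnat_class(fnat[k])
      next
    }
    out[k] <-
      if (fnat[k] >= 0.5 && (i_rmsd[k] <= 1 || l_rmsd[k] <= 1)) "High"
      else if (fnat[k] >= 0.3 && (i_rmsd[k] <= 2 || l_rmsd[k] <= 5)) "Medium"
      else if (fnat[k] >= 0.1 && (i_rmsd[k] <= 4 || l_rmsd[k] <= 10)) "Acceptable"
      else "Incorrect"
  }
  out
}

#' Confusion-matrix metrics
#'
#' @param tp,fp,fn,tn confusion counts
#' @return named vector: precision TP/(TP+FP) (0 on empty denominator),
#'   recall TP/(TP+FN), accuracy, FNR FN/(FN+TP), TNR TN/(TN+FP)
#' @export
confusion_metrics <- function(tp, fp, fn, tn) {
  total <- tp + fp + fn + tn
  if (total <= 0) stop("empty confusion matrix")
  div <- function(a, b) if (b == 0) 0 else a / b
  c(precision = div(tp, tp + fp),
    recall = div(tp, tp + fn),
    accuracy = (tp + tn) / total,
    fnr = div(fn, fn + tp),
    tnr = div(tn, tn + fp))
}

#' Ranked-tail enrichment
#'
#' Proportion of qualifying conformations in the best (and worst)
#' \code{tail} fraction of the ranking, divided by their proportion in the
#' complete set. NA (flagged) when the complete-set proportion is zero.
#'
#' @param ranking a [ranked_set()]
#' @param good logical vector indexed by item id, TRUE = qualifying at the
#'   chosen level (e.g. acceptable-or-better)
#' @param tail tail fraction (default 0.2)
#' @return named vector \code{c(top, bottom)}
#' @export
enrichment <- function(ranking, good, tail = 0.2) {
  n <- nrow(ranking)
  g <- good[ranking$id]
  base <- mean(g)
  if (base == 0) return(c(top = NA_real_, bottom = NA_real_))
  m <- ceiling(tail * n)
  ord <- order(ranking$rank)
  top <- mean(g[ord][seq_len(m)]) / base
  bottom <- mean(g[ord][seq(n - m + 1, n)]) / base
  c(top = top, bottom = bottom)
}

#' Per-ranking top-10 report row
#'
#' @param ranking a [ranked_set()]
#' @param classes character vector of quality classes indexed by item id
#' @param top consider the best \code{top} ranks (default 10)
#' @return list: \code{best} class present in the top ranks, \code{N}
#'   (acceptable-or-better count in the top), \code{R} (rank of the first
#'   acceptable-or-better solution anywhere, NA when none exists)
#' @export
rank_report <- function(ranking, classes, top = 10) {
  lev <- c("High", "Medium", "Acceptable", "Incorrect")
  cl <- factor(classes[ranking$id], levels = lev)
  ord <- order(ranking$rank)
  topcl <- cl[ord][seq_len(min(top, nrow(ranking)))]
  ok <- cl[ord] != "Incorrect"
  list(best = as.character(sort(topcl)[1]),
       N = sum(topcl != "Incorrect"),
       R = if (any(ok)) ranking$rank[ord][which(ok)[1]] else NA_real_)
}

#' Summarize a per-target report table
#'
#' Given per-target top-10 outcomes of one ranking method (columns
#' \code{target}, \code{N}, \code{R}), computes the mean rank of the first
#' acceptable-or-better solution (with stated target exclusions), the mean
#' number of acceptable-or-better solutions in the top 10, and the count
#' of targets with at least one acceptable-or-better solution in the top
#' 10.
#'
#' @param df data frame with columns \code{target}, \code{N}, \code{R}
#' @param exclude_rank_targets targets excluded from the mean-rank average
#'   (e.g. targets whose first hit is too deep to be meaningful)
#' @return list \code{mean_first_rank}, \code{mean_top10_count},
#'   \code{n_success}, \code{n_targets}
#' @export
summarize_report <- function(df, exclude_rank_targets = character(0)) {
  keep <- !(df$target %in% exclude_rank_targets) & !is.na(df$R)
  list(mean_first_rank = mean(df$R[keep]),
       mean_top10_count = mean(df$N),
       n_success = sum(df$N > 0),
       n_targets = nrow(df))
}

#' Concordance between fnat-only and full-CAPRI classifications
#'
#' From a contingency table (rows = fnat-only class, columns = full-CAPRI
#' class, both ordered High, Medium, Acceptable, Incorrect) computes, for
#' each fnat-only tier, the percentage of its conformations evaluated at or
#' above each CAPRI tier.
#'
#' @param tab 4x4 numeric matrix of counts
#' @return 4x4 matrix of percentages; entry \[r, k\] is the percentage of
#'   fnat-tier-r conformations whose CAPRI tier is k or better
#' @export
class_concordance <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(4, 4)))
  lev <- c("High", "Medium", "Acceptable", "Incorrect")
  dimnames(tab) <- list(fnat = lev, capri = lev)
  cum <- t(apply(tab, 1, cumsum))
  pct <- 100 * cum / rowSums(tab)
  colnames(pct) <- paste0(lev, "+")
  pct
}

#' Cross-tabulate two classification schemes
#'
#' @param fnat_cl,capri_cl character class vectors (High, Medium,
#'   Acceptable, Incorrect)
#' @return 4x4 contingency matrix, rows = fnat-only class
#' @export
class_contingency <- function(fnat_cl, capri_cl) {
  lev <- c("High", "Medium", "Acceptable", "Incorrect")
  table(fnat = factor(fnat_cl, levels = lev),
        capri = factor(capri_cl, levels = lev))
}

#' Full evaluation report for a set of ranking methods
#'
#' @param rankings named list of [ranked_set()] objects (one per method)
#' @param classes character vector of quality classes indexed by item id
#' @param top top-rank window (default 10)
#' @return data frame with one row per method: \code{best}, \code{N},
#'   \code{R}
#' @export
report_table <- function(rankings, classes, top = 10) {
  rows <- lapply(rankings, rank_report, classes = classes, top = top)
  data.frame(method = names(rankings),
             best = vapply(rows, `[[`, "", "best"),
             N = vapply(rows, `[[`, 0L, "N"),
             R = vapply(rows, function(r) as.numeric(r$R), 0),
             row.names = NULL)
}
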