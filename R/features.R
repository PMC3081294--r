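## The 96-attribute Voronoi interface descriptor.
##
## Fixed layout (documented, order matters for serialized models):
##   c1        Voronoi interface area (A^2)
##   c2        number of interface residues (both partners pooled)
##   c3..c22   fraction of interface residues of each type (alphabetical)
##   c23..c42  mean Voronoi cell volume of interface residues of each type
##   c43..c63  fraction of cross pairs per category pair (21 unordered
##             pairs, row-major upper triangle, canonical category order)
##   c64..c84  mean node-node distance per category pair (A)
##   c85..c90  fraction of interface residues per category
##   c91..c96  mean Voronoi cell volume per category
## A value is missing (NA, mask true) exactly when its defining set is
## empty; fractions are taken over present entities.

#' Category-pair table for the pair attribute blocks
#'
#' The 21 unordered pairs (with repetition) of the six residue categories,
#' in the fixed row-major upper-triangle order used by the descriptor.
#'
#' @return data frame with columns \code{cat1}, \code{cat2}
#' @export
category_pairs <- function() {
  cats <- residue_categories()
  idx <- which(upper.tri(matrix(0, 6, 6), diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), ]
  data.frame(cat1 = cats[idx[, "row"]], cat2 = cats[idx[, "col"]],
             stringsAsFactors = FALSE)
}

#' Descriptor layout
#'
#' @return data frame with columns \code{name} (c1..c96), \code{block} and
#'   \code{detail} describing each attribute
#' @export
feature_layout <- function() {
  types <- residue_types()
  cats <- residue_categories()
  cp <- category_pairs()
  pair_lab <- paste(cp$cat1, cp$cat2, sep = ":")
  data.frame(
    name = paste0("c", 1:96),
    block = c("area", "count",
              rep("type_fraction", 20), rep("type_mean_volume", 20),
              rep("pair_fraction", 21), rep("pair_mean_distance", 21),
              rep("category_fraction", 6), rep("category_mean_volume", 6)),
    detail = c("interface_area", "n_interface_residues",
               types, types, pair_lab, pair_lab, cats, cats),
    stringsAsFactors = FALSE
  )
}

## map two category names to the 1..21 pair slot
.pair_slot <- local({
  m <- matrix(0L, 6, 6)
  k <- 0L
  for (r in 1:6) for (cl in r:6) { k <- k + 1L; m[r, cl] <- m[cl, r] <- k }
  m
})

#' Compute the 96-attribute interface descriptor
#'
#' @param x a [complex_conformation()] (tessellated internally) or a
#'   two-partner [tessellate()] result
#' @param conf when \code{x} is a tessellation, the conformation providing
#'   residue metadata
#' @param complex_id identifier stored on the result
#' @param label optional \code{"positive"} or \code{"negative"}
#' @return object of class \code{feature_vector}: named \code{values}
#'   (length 96, NA where missing), logical \code{mask}, \code{label},
#'   \code{complex_id}
#' @export
featurize <- function(x, conf = NULL, complex_id = NA_character_,
                      label = NA_character_) {
  if (inherits(x, "complex_conformation")) {
    conf <- x
    tess <- tessellate(conf)
  } else if (inherits(x, "voronoi_tessellation")) {
    tess <- x
    if (is.null(conf)) stop("conf metadata required with a tessellation")
  } else stop("x must be a conformation or tessellation")

  restype <- c(conf$receptor$restype, conf$ligand$restype)
  category <- c(conf$receptor$category, conf$ligand$category)
  cellvol <- tess$volume
  types <- residue_types()
  cats <- residue_categories()

  values <- rep(NA_real_, 96)
  names(values) <- paste0("c", 1:96)

  iface <- interface_of(tess)
  cp <- iface$cross_pairs
  ir <- c(iface$partner1, iface$partner2)

  values[1] <- sum(cp$area)
  values[2] <- length(ir)
  if (length(ir) > 0) {
    rt <- factor(restype[ir], levels = types)
    values[3:22] <- as.vector(table(rt)) / length(ir)
    values[23:42] <- vapply(types, function(tp) {
      sel <- ir[restype[ir] == tp]
      if (length(sel) == 0) NA_real_ else mean(cellvol[sel])
    }, 0)
    ct <- factor(category[ir], levels = cats)
    values[85:90] <- as.vector(table(ct)) / length(ir)
    values[91:96] <- vapply(cats, function(cg) {
      sel <- ir[category[ir] == cg]
      if (length(sel) == 0) NA_real_ else mean(cellvol[sel])
    }, 0)
    ## pair blocks over cross pairs
    s1 <- match(category[cp$i], cats)
    s2 <- match(category[cp$j], cats)
    slot <- .pair_slot[cbind(s1, s2)]
    d <- sqrt(rowSums((tess$xyz[cp$i, , drop = FALSE] -
                         tess$xyz[cp$j, , drop = FALSE])^2))
    values[43:63] <- tabulate(slot, 21) / nrow(cp)
    values[64:84] <- vapply(1:21, function(k) {
      if (any(slot == k)) mean(d[slot == k]) else NA_real_
    }, 0)
  }
  structure(list(values = values, mask = is.na(values),
                 label = label, complex_id = complex_id),
            class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat("Interface descriptor (", sum(!x$mask), "/96 attributes present",
      if (!is.na(x$complex_id)) paste0(", complex ", x$complex_id), ")\n",
      sep = "")
  cat("  area:", round(x$values[1], 1), "A^2, interface residues:",
      x$values[2], "\n")
  invisible(x)
}

#' Number of missing attributes of a descriptor
#' @param fv a [featurize()] result
#' @return integer count of masked attributes
#' @export
missing_count <- function(fv) sum(fv$mask)

#' Assemble a labeled learning set with the missing-value filter
#'
#' Natives are positives; each native's decoys are negatives. A decoy is
#' dropped when its missing-attribute count exceeds \code{missing_factor}
#' times the missing count of its native (decoys with too many undefined
#' interface attributes carry no usable signal).
#'
#' @param natives list of [featurize()] descriptors, one per complex
#' @param decoys_per_native list (parallel to \code{natives}) of descriptor
#'   lists
#' @param missing_factor multiplier on the native's missing count
#' @param complex_ids identifiers; defaults to those on the natives or
#'   \code{cmplx1..n}
#' @return object of class \code{learning_set}: matrix \code{x} (rows =
#'   conformations, NA where masked), \code{label}
#'   (\code{"positive"}/\code{"negative"}), \code{complex_id}, and a
#'   \code{dropped} count per complex
#' @export
assemble_learning_set <- function(natives, decoys_per_native,
                                  missing_factor = 2, complex_ids = NULL) {
  stopifnot(length(natives) == length(decoys_per_native))
  if (is.null(complex_ids)) {
    complex_ids <- vapply(seq_along(natives), function(i) {
      id <- natives[[i]]$complex_id
      if (is.na(id)) paste0("cmplx", i) else id
    }, "")
  }
  rows <- list(); label <- character(); cid <- character()
  dropped <- integer(length(natives))
  for (i in seq_along(natives)) {
    nat <- natives[[i]]
    thr <- missing_factor * missing_count(nat)
    rows[[length(rows) + 1L]] <- nat$values
    label <- c(label, "positive"); cid <- c(cid, complex_ids[i])
    kept <- 0L
    for (dc in decoys_per_native[[i]]) {
      if (missing_count(dc) > thr) { dropped[i] <- dropped[i] + 1L; next }
      rows[[length(rows) + 1L]] <- dc$values
      label <- c(label, "negative"); cid <- c(cid, complex_ids[i])
      kept <- kept + 1L
    }
    if (kept == 0L)
      warning("complex ", complex_ids[i],
              ": no decoy survives the missing-value filter")
  }
  x <- do.call(rbind, rows)
  rownames(x) <- NULL
  structure(list(x = x, label = label, complex_id = cid, dropped = dropped),
            class = "learning_set")
}

#' @export
print.learning_set <- function(x, ...) {
  cat("Learning set:", nrow(x$x), "conformations (",
      sum(x$label == "positive"), "positive /",
      sum(x$label == "negative"), "negative ) over",
      length(unique(x$complex_id)), "complexes\n")
  if (sum(x$dropped) > 0)
    cat("  ", sum(x$dropped), "decoys dropped by the missing-value filter\n")
  invisible(x)
}

#' Write / read a learning set as TSV
#'
#' Columns: \code{complex_id}, \code{label}, \code{mask} (96-character 0/1
#' string, 1 = missing) and \code{c1..c96} (empty where missing).
#'
#' @param set a [assemble_learning_set()] result
#' @param path file path
#' @return \code{path} invisibly; \code{read_features} returns a
#'   \code{learning_set}
#' @export
write_features <- function(set, path) {
  df <- data.frame(complex_id = set$complex_id, label = set$label,
                   mask = apply(set$x, 1, function(r)
                     paste(as.integer(is.na(r)), collapse = "")),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(set$x))
  names(df)[-(1:3)] <- paste0("c", 1:96)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  x <- as.matrix(df[, paste0("c", 1:96)])
  rownames(x) <- NULL
  structure(list(x = x, label = df$label, complex_id = df$complex_id,
                 dropped = integer(0)),
            class = "learning_set")
}
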