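## Deterministic synthetic fixtures: toy two-partner complexes with a
## planted contact zone, planted-signal feature sets emulating the
## native/decoy learning-set structure, and simulated classifier-vote
## panels.  Everything is reproducible from (spec, seed) alone.  Toy
## "proteins" are compact residue-node clouds with realistic ~3.8 A
## nearest-neighbor spacing, not folded chains.

#' Fixture specification
#'
#' @param seed master RNG seed; fully determines every fixture
#' @param n_residues residues per partner
#' @param n_contacts planted cross-partner contact pairs in the docked
#'   native
#' @param decoys_per_native decoys generated per native complex
#' @param informative_fraction fraction of the 96 attributes carrying
#'   class signal in planted feature sets
#' @param effect_size mean shift (in SD units) of informative attributes
#' @param n_classifiers simulated classifier roster size
#' @param precisions nominal classifier precisions (recycled to
#'   \code{n_classifiers})
#' @param noise positional noise scale, Angstrom
#' @return object of class \code{fixture_spec}
#' @export
fixture_spec <- function(seed = 1, n_residues = 30, n_contacts = 20,
                         decoys_per_native = 15,
                         informative_fraction = 0.1, effect_size = 2,
                         n_classifiers = 12,
                         precisions = seq(0.55, 0.95,
                                          length.out = n_classifiers),
                         noise = 0.5) {
  stopifnot(seed == round(seed), n_residues >= 10, n_contacts >= 0,
            decoys_per_native >= 1,
            informative_fraction > 0, informative_fraction <= 1,
            n_classifiers >= 1)
  structure(list(seed = as.integer(seed), n_residues = n_residues,
                 n_contacts = n_contacts,
                 decoys_per_native = decoys_per_native,
                 informative_fraction = informative_fraction,
                 effect_size = effect_size,
                 n_classifiers = n_classifiers,
                 precisions = rep_len(precisions, n_classifiers),
                 noise = noise),
            class = "fixture_spec")
}

## compact cloud of n points with minimum spacing ~3.8 A (Poisson-disk by
## dart throwing; box inflated on failure)
.packed_cloud <- function(n, spacing = 3.8) {
  box <- spacing * max(3, ceiling((n * 1.8)^(1 / 3)))
  for (attempt in 1:6) {
    pts <- matrix(NA_real_, n, 3)
    k <- 0L
    for (trial in seq_len(4000 * n)) {
      cand <- stats::runif(3, 0, box)
      if (k == 0L ||
          min(rowSums(sweep(pts[seq_len(k), , drop = FALSE], 2, cand)^2)) >=
            spacing^2) {
        k <- k + 1L
        pts[k, ] <- cand
        if (k == n) break
      }
    }
    if (k == n) return(sweep(pts, 2, colMeans(pts)))
    box <- box * 1.3
  }
  stop("unsatisfiable packing")
}

#' Generate a docked toy complex with a planted contact zone
#'
#' Two compact residue clouds are generated and docked by translating the
#' second along the line of centers until the requested number of
#' cross-partner node pairs falls within the contact cutoff. The planted
#' contact list (distance criterion) is the ground truth; the Voronoi
#' interface of the docked native recovers at least the planted contact
#' residues.
#'
#' @param spec a [fixture_spec()]
#' @param contact_cutoff contact distance, Angstrom
#' @param volumes mean-volume table
#' @return list with the native [complex_conformation()], the planted
#'   \code{contacts} matrix (receptor node, ligand node), per-partner
#'   ground-truth interface residue sets, and the spec
#' @export
make_toy_complex <- function(spec = fixture_spec(), contact_cutoff = 5,
                             volumes = volume_table()) {
  .with_seed(spec$seed, {
    n <- spec$n_residues
    types <- residue_types()
    rec_xyz <- .packed_cloud(n)
    lig_xyz <- .packed_cloud(n)
    rec <- partner_structure(rec_xyz, sample(types, n, replace = TRUE),
                             chain = "A", label = "receptor",
                             volumes = volumes,
                             source = sprintf("synthetic(seed=%d)", spec$seed))
    lig <- partner_structure(lig_xyz, sample(types, n, replace = TRUE),
                             chain = "B", label = "ligand",
                             volumes = volumes,
                             source = sprintf("synthetic(seed=%d)", spec$seed))
    ## dock: slide the ligand along +x until the contact count reaches the
    ## plant target
    dir <- c(1, 0, 0)
    span <- max(rec$xyz[, 1]) - min(lig$xyz[, 1])
    count_at <- function(offset) {
      lig2 <- lig
      lig2$xyz <- sweep(lig$xyz, 2, dir * offset, `+`)
      nrow(contact_pairs(complex_conformation(rec, lig2), contact_cutoff))
    }
    if (spec$n_contacts == 0) {
      offset <- span + 40
    } else {
      lo <- span - 20; hi <- span + 30
      offset <- hi
      for (o in seq(hi, lo, by = -0.25)) {
        if (count_at(o) >= spec$n_contacts) { offset <- o; break }
      }
    }
    lig$xyz <- sweep(lig$xyz, 2, dir * offset, `+`)
    native <- complex_conformation(rec, lig, provenance = "native",
                                   rmsd_to_native = 0)
    contacts <- contact_pairs(native, contact_cutoff)
    list(native = native, contacts = contacts,
         interface1 = sort(unique(contacts[, "rec"])),
         interface2 = sort(unique(contacts[, "lig"])),
         spec = spec)
  })
}

#' Write a toy complex as a PDB file
#'
#' Serializes both partners into one PDB (receptor chain A, ligand chain
#' B), writing per residue a CA pseudo-atom and one pseudo side-chain atom
#' (CB) placed symmetrically about the node, so that reloading through
#' [load_partner()] exercises the real side-chain-averaging path and
#' reproduces the node positions.
#'
#' @param native a [complex_conformation()]
#' @param path output PDB path
#' @return \code{path}, invisibly
#' @export
write_toy_pdb <- function(native, path) {
  ser <- function(p, eleno0) {
    n <- nrow(p$xyz)
    off <- matrix(rep(c(0.5, 0, 0), each = n), n, 3)
    xyz2 <- rbind(p$xyz + off, p$xyz - off)  # CA and CB average to the node
    ord <- as.vector(rbind(seq_len(n), n + seq_len(n)))
    data.frame(eleno = eleno0 + seq_len(2 * n),
               elety = rep(c("CA", "CB"), n),
               resid = rep(unname(.aa123[p$restype]), each = 2),
               chain = rep(p$chain, each = 2),
               resno = rep(p$resno, each = 2),
               x = xyz2[ord, 1], y = xyz2[ord, 2], z = xyz2[ord, 3])
  }
  a <- ser(native$receptor, 0L)
  b <- ser(native$ligand, nrow(a))
  at <- rbind(a, b)
  ## glycine has no side chain: keep CA only
  gly <- at$resid == "GLY" & at$elety == "CB"
  at <- at[!gly, ]
  ## re-center glycine CA on the node
  glyca <- at$resid == "GLY" & at$elety == "CA"
  at$x[glyca] <- at$x[glyca] - 0.5
  bio3d::write.pdb(file = path, xyz = as.vector(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = rep("ATOM", nrow(at)), eleno = at$eleno,
                   elety = at$elety, resid = at$resid, chain = at$chain,
                   resno = at$resno, o = rep(1, nrow(at)),
                   b = rep(0, nrow(at)))
  invisible(path)
}

#' Generate a planted-signal learning set
#'
#' Positives and negatives are drawn from Gaussians that differ (by
#' \code{effect_size} standard deviations) in a random informative subset
#' of the 96 attributes only; the class ratio follows
#' \code{decoys_per_native}. Missingness is planted on the mean-value
#' blocks the way real interfaces produce it: every descriptor of a
#' complex misses a common random attribute subset, and decoys may miss
#' more.
#'
#' @param spec a [fixture_spec()]
#' @param n_complexes number of native complexes
#' @param native_missing attributes missing in each native
#' @param decoy_extra_missing additional attributes missing in each decoy
#'   (before the assembly filter)
#' @return list: \code{set} (a \code{learning_set}), \code{informative}
#'   (indices of signal attributes)
#' @export
make_planted_feature_set <- function(spec = fixture_spec(), n_complexes = 10,
                                     native_missing = 2,
                                     decoy_extra_missing = 0) {
  .with_seed(spec$seed + 1L, {
    d <- 96
    n_inf <- max(1, round(spec$informative_fraction * d))
    ## signal only in maskable blocks is fragile; draw anywhere
    informative <- sample(d, n_inf)
    shift <- rep(0, d); shift[informative] <- spec$effect_size
    natives <- list(); decoys <- list()
    for (i in seq_len(n_complexes)) {
      miss_nat <- sample(d, native_missing)
      nv <- stats::rnorm(d) + shift
      nv[miss_nat] <- NA
      natives[[i]] <- structure(
        list(values = stats::setNames(nv, paste0("c", 1:d)),
             mask = is.na(nv), label = "positive",
             complex_id = paste0("synth", i)),
        class = "feature_vector")
      decoys[[i]] <- lapply(seq_len(spec$decoys_per_native), function(j) {
        miss <- unique(c(miss_nat, sample(d, decoy_extra_missing)))
        dv <- stats::rnorm(d)
        dv[miss] <- NA
        structure(list(values = stats::setNames(dv, paste0("c", 1:d)),
                       mask = is.na(dv), label = "negative",
                       complex_id = paste0("synth", i)),
                  class = "feature_vector")
      })
    }
    list(set = assemble_learning_set(natives, decoys),
         informative = sort(informative))
  })
}

#' Simulate a classifier vote panel with known ground truth
#'
#' Simulates \code{n_classifiers} binary voters over a labeled set: a
#' classifier votes + on a true positive with probability equal to its
#' nominal precision-linked hit rate, and + on a true negative with a
#' complementary false-positive rate; GA-style ranks are drawn correlated
#' with the labels at a configurable level.
#'
#' @param spec a [fixture_spec()]
#' @param n_pos,n_neg class sizes
#' @param ga_strength correlation level of the simulated GA ranking with
#'   the labels (0 = random, 1 = strong)
#' @return list: \code{votes} (a [vote_records()] data frame), \code{ga}
#'   (a [ranked_set()]), \code{labels} (logical, TRUE = positive)
#' @export
make_vote_fixture <- function(spec = fixture_spec(), n_pos = 20, n_neg = 80,
                              ga_strength = 0.8) {
  stopifnot(all(spec$precisions > 0.5), all(spec$precisions <= 1))
  .with_seed(spec$seed + 2L, {
    n <- n_pos + n_neg
    labels <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
    k <- spec$n_classifiers
    votes <- matrix(-1L, n, k)
    for (j in seq_len(k)) {
      p <- spec$precisions[j]
      hit <- stats::runif(n) < ifelse(labels, p, 1 - p)
      votes[hit, j] <- 1L
    }
    ga_score <- ifelse(labels, ga_strength, 0) + stats::rnorm(n, sd = 0.5)
    list(votes = vote_records(votes, spec$precisions),
         ga = ranked_set(ga_score, decreasing = TRUE),
         labels = labels)
  })
}
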