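## helix-strand complexes with exactly controllable contact structure:
## residue i of each partner faces residue i of the other at just under
## the contact cutoff, every other cross pair is beyond it, and the node
## clouds are genuinely 3-dimensional (no degenerate superpositions)
.strand_complex <- function(n_rec = 10, n_lig = 8, gap = 4.2, spacing = 4) {
  helix <- function(n, x0, phase) {
    i <- seq_len(n)
    cbind(x0 + 0.5 * cos(0.5 * i + phase), spacing * (i - 1),
          0.5 * sin(0.5 * i + phase))
  }
  rec <- partner_structure(helix(n_rec, 0, 0), rep("A", n_rec),
                           chain = "A", label = "receptor")
  lig <- partner_structure(helix(n_lig, gap, 1), rep("L", n_lig),
                           chain = "B", label = "ligand")
  complex_conformation(rec, lig, provenance = "native")
}

test_that("fnat counts preserved native contacts", {
  native <- .strand_complex(10, 10)
  expect_equal(nrow(contact_pairs(native, 5)), 10)
  expect_equal(fnat(native, native), 1)
  ## break 6 of the 10 facing pairs: 4 native contacts survive
  pred <- native
  pred$ligand$xyz[1:6, 1] <- pred$ligand$xyz[1:6, 1] + 50
  expect_equal(fnat(pred, native), 0.4)
  expect_equal(fnat_class(0.4), "Medium")
  ## no shared contact
  pred2 <- native
  pred2$ligand$xyz <- sweep(pred2$ligand$xyz, 2, c(40, 0, 0), `+`)
  expect_equal(fnat(pred2, native), 0)
  ## undefined when the native has no contacts
  apart <- .strand_complex(10, 10, gap = 30)
  expect_error(fnat(native, apart), "undefined fnat")
})

test_that("fnat is monotone as contacts are destroyed", {
  native <- .strand_complex(10, 10)
  pred <- native
  vals <- numeric(10)
  for (k in 1:10) {
    pred$ligand$xyz[k, 1] <- pred$ligand$xyz[k, 1] + 50
    vals[k] <- fnat(pred, native)
  }
  expect_true(all(diff(vals) <= 0))
  expect_equal(vals[10], 0)
})

test_that("the Voronoi contact mode agrees with the tessellation", {
  tc <- make_toy_complex(fixture_spec(seed = 3, n_residues = 15))
  cp <- contact_pairs(tc$native, mode = "voronoi")
  ifc <- interface_of(tessellate(tc$native))
  expect_equal(nrow(cp), nrow(ifc$cross_pairs))
  expect_equal(fnat(tc$native, tc$native, mode = "voronoi"), 1)
})

test_that("interface and ligand RMSD match the Kabsch oracle", {
  native <- .strand_complex(12, 8)
  expect_equal(unname(interface_and_ligand_rmsd(native, native)),
               c(0, 0), tolerance = 1e-9)
  ## rigid ligand shift with the receptor fixed: l_rmsd equals the shift
  pred <- native
  pred$ligand$xyz <- sweep(pred$ligand$xyz, 2, c(3, 0, 0), `+`)
  r <- interface_and_ligand_rmsd(pred, native)
  expect_equal(unname(r["l_rmsd"]), 3, tolerance = 1e-6)
  ## random rigid motion of the whole prediction: both RMSDs match a
  ## direct SVD superposition oracle
  set.seed(13)
  th <- 0.9
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  pred2 <- native
  pred2$ligand$xyz <- sweep(pred2$ligand$xyz %*% t(R), 2, c(2, -1, 3), `+`)
  pred2$ligand$xyz <- pred2$ligand$xyz +
    matrix(rnorm(24, sd = 0.3), 8, 3)
  got <- interface_and_ligand_rmsd(pred2, native)
  nat_xyz <- rbind(native$receptor$xyz, native$ligand$xyz)
  prd_xyz <- rbind(pred2$receptor$xyz, pred2$ligand$xyz)
  cp <- contact_pairs(native, 5)
  iface <- sort(unique(c(cp[, "rec"], cp[, "lig"] + 12)))
  fit_i <- oracle_superpose(nat_xyz, prd_xyz, iface)
  i_oracle <- sqrt(mean(rowSums((fit_i[iface, ] - nat_xyz[iface, ])^2)))
  fit_l <- oracle_superpose(nat_xyz, prd_xyz, 1:12)  # larger partner
  l_oracle <- sqrt(mean(rowSums((fit_l[13:20, ] - nat_xyz[13:20, ])^2)))
  expect_equal(unname(got["i_rmsd"]), i_oracle, tolerance = 1e-6)
  expect_equal(unname(got["l_rmsd"]), l_oracle, tolerance = 1e-6)
})

test_that("quality classes follow the printed thresholds", {
  expect_equal(fnat_class(c(0.95, 0.4, 0.15, 0.05)),
               c("High", "Medium", "Acceptable", "Incorrect"))
  expect_equal(capri_class(0.95, 0.5, 8), "High")
  expect_equal(capri_class(0.05, 0.1, 0.1), "Incorrect")
  ## fails the Medium RMSD clause, passes the Acceptable fallback
  expect_equal(capri_class(0.4, 3, 12), "Acceptable")
  expect_equal(capri_class(0.4, 1.5, 20), "Medium")
  ## high fnat failing the High RMSD test drops to Medium
  expect_equal(capri_class(0.8, 1.5, 4), "Medium")
  expect_warning(cl <- capri_class(0.6, NA, NA), "falling back")
  expect_equal(cl, "High")
})

test_that("the CAPRI tier never exceeds the fnat tier", {
  set.seed(14)
  fn <- runif(300)
  ir <- runif(300, 0, 6)
  lr <- runif(300, 0, 15)
  tab <- class_contingency(fnat_class(fn), capri_class(fn, ir, lr))
  ## lower-left triangle (CAPRI strictly better than fnat-only) is empty
  expect_equal(tab[2, 1], 0L, ignore_attr = TRUE)
  expect_equal(sum(tab[3, 1:2]), 0)
  expect_equal(sum(tab[4, 1:3]), 0)
  expect_equal(sum(tab), 300)
})

test_that("confusion metrics reproduce the canonical cases", {
  ## all-negative predictor on a 10 percent positive set
  m <- confusion_metrics(tp = 0, fp = 0, fn = 10, tn = 90)
  expect_equal(unname(m[c("accuracy", "precision", "recall")]),
               c(0.9, 0, 0))
  mp <- confusion_metrics(tp = 10, fp = 0, fn = 0, tn = 90)
  expect_equal(unname(mp[c("precision", "recall", "accuracy", "fnr")]),
               c(1, 1, 1, 0))
  m2 <- confusion_metrics(3, 1, 1, 95)
  expect_equal(unname(m2[c("precision", "recall", "accuracy")]),
               c(0.75, 0.75, 0.98))
  expect_error(confusion_metrics(0, 0, 0, 0), "empty")
})

test_that("tail enrichment is the ratio of tail to overall proportions", {
  set.seed(15)
  n <- 1000
  good <- runif(n) < 0.3
  rs <- ranked_set(rnorm(n), decreasing = TRUE)
  e <- enrichment(rs, good)
  expect_equal(unname(e["top"]), 1, tolerance = 0.25)
  expect_equal(unname(e["bottom"]), 1, tolerance = 0.25)
  ## all 10 percent of good items packed into the top 20 percent
  good2 <- rep(FALSE, 100); good2[1:10] <- TRUE
  rs2 <- ranked_set(seq(100, 1), decreasing = TRUE)  # id order = rank order
  expect_equal(unname(enrichment(rs2, good2)["top"]), 5)
  expect_equal(unname(enrichment(rs2, good2)["bottom"]), 0)
  ## no qualifying item anywhere: flagged undefined
  expect_true(all(is.na(enrichment(rs2, rep(FALSE, 100)))))
})

test_that("report rows count top-10 hits and first-hit ranks", {
  classes <- rep("Incorrect", 30)
  classes[c(4, 12)] <- "Acceptable"
  classes[25] <- "High"
  rs <- ranked_set(seq(30, 1), decreasing = TRUE)   # id k has rank k
  rep1 <- rank_report(rs, classes)
  expect_equal(rep1$N, 1)                # only id 4 in the top 10
  expect_equal(rep1$R, 4)
  expect_equal(rep1$best, "Acceptable")
  ## no hit in the top 10: R is the first hit beyond it
  classes2 <- rep("Incorrect", 30); classes2[17] <- "Medium"
  rep2 <- rank_report(rs, classes2)
  expect_equal(rep2$N, 0)
  expect_equal(rep2$R, 17)
  ## single acceptable at rank 1
  classes3 <- rep("Incorrect", 30); classes3[1] <- "Acceptable"
  rep3 <- rank_report(rs, classes3)
  expect_equal(c(rep3$N, rep3$R), c(1, 1))
  ## report over methods, and the brute-force recount
  tab <- report_table(list(a = rs, b = rs), classes)
  expect_equal(tab$N, c(1L, 1L))
  summ <- summarize_report(data.frame(target = c("x", "y", "z"),
                                      N = c(2, 0, 1), R = c(1, 40, 3)),
                           exclude_rank_targets = "y")
  expect_equal(summ$mean_first_rank, 2)
  expect_equal(summ$mean_top10_count, 1)
  expect_equal(summ$n_success, 2)
})

test_that("concordance percentages are cumulative row fractions", {
  tab <- rbind(c(10, 5, 5, 0), c(0, 4, 4, 2), c(0, 0, 3, 7),
               c(0, 0, 0, 50))
  pct <- class_concordance(tab)
  expect_equal(pct["High", "Acceptable+"], 100)
  expect_equal(pct["High", "Medium+"], 75)
  expect_equal(pct["Medium", "Acceptable+"], 80)
  expect_equal(unname(pct[, "Incorrect+"]), rep(100, 4))
})
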