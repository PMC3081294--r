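test_that("vote records carry the precision-sum identities", {
  set.seed(6)
  k <- 7
  p <- runif(k, 0.55, 0.95)
  votes <- matrix(sample(c(-1L, 1L), 30 * k, replace = TRUE), 30, k)
  vr <- vote_records(votes, p)
  expect_equal(vr$s_plus + vr$s_minus, rep(sum(p), 30))
  expect_equal(vr$category_score, vr$s_plus - vr$s_minus)
  ## unit precisions reduce the category score to the vote margin
  vr1 <- vote_records(votes, rep(1, k))
  expect_equal(vr1$category_score, rowSums(votes))
  expect_error(vote_records(votes[, 0], numeric(0)), "empty")
  expect_error(vote_records(votes, p[-1]), "match")
  expect_error(vote_records(matrix(0L, 2, 2), c(1, 1)), "must be")
})

test_that("uniform voting ranks by positive-vote count", {
  votes <- rbind(c(1, 1, 1), c(1, 1, -1), c(-1, -1, -1))
  vr <- vote_records(votes, rep(1, 3))
  rs <- uniform_vote_rank(vr)
  expect_equal(rank_of(rs, 1:3), c(1, 2, 3))
})

test_that("weighted voting orders by the precision-weighted margin", {
  vr <- vote_records(rbind(c(1, -1), c(-1, 1)), c(0.9, 0.6))
  rs <- weighted_vote_rank(vr)
  expect_equal(score_of(rs, 1:2), c(0.3, -0.3))
  expect_equal(rank_of(rs, 1:2), c(1, 2))
  ## with all precisions 1 the ordering equals the uniform vote
  set.seed(7)
  votes <- matrix(sample(c(-1L, 1L), 40 * 5, replace = TRUE), 40, 5)
  vru <- vote_records(votes, rep(1, 5))
  expect_equal(rank_of(weighted_vote_rank(vru), 1:40),
               rank_of(uniform_vote_rank(vru), 1:40))
})

test_that("CF-GA fusion multiplies the GA rank by the consensus factor", {
  set.seed(9)
  n <- 20
  k <- 5
  p <- runif(k, 0.55, 0.95)
  votes <- matrix(sample(c(-1L, 1L), n * k, replace = TRUE), n, k)
  votes[3, ] <- -1L                      # an all-negative conformation
  votes[8, ] <- -1L
  vr <- vote_records(votes, p)
  ga <- ranked_set(rnorm(n), decreasing = TRUE)
  fused <- cf_ga_fuse(ga, vr)
  ## brute-force oracle
  ga_rank <- ga$rank[match(1:n, ga$id)]
  val <- ga_rank * exp(vr$s_minus - vr$s_plus)
  val[vr$s_plus == 0] <- Inf
  finite <- which(is.finite(val))
  expect_equal(rank_of(fused, finite), rank(val[finite]))
  ## sentinel items (no positive vote anywhere, including by chance)
  ## occupy the last ranks in stable input order
  expect_equal(fused$id[fused$rank > length(finite)],
               which(vr$s_plus == 0))
  expect_true(all(c(3, 8) %in% fused$id[fused$rank > length(finite)]))
  ## unanimous positive at GA rank 1 attains the minimum possible value
  best <- which(ga_rank == 1)
  votes2 <- votes; votes2[best, ] <- 1L
  fused2 <- cf_ga_fuse(ga, vote_records(votes2, p))
  expect_equal(score_of(fused2, best), exp(-sum(p)))
  expect_equal(rank_of(fused2, best), 1)
  ## every voted conformation must be covered by the GA ranking
  expect_error(cf_ga_fuse(ga[-1, ], vr), "missing from the GA")
})

test_that("a single uninformative classifier leaves the GA order intact", {
  set.seed(10)
  n <- 15
  votes <- matrix(sample(c(-1L, 1L), n, replace = TRUE), n, 1)
  ## vanishing precision: the consensus factor degenerates to 1 and the
  ## fused order among positively voted conformations is the GA order
  vr <- vote_records(votes, 1e-9)
  ga <- ranked_set(rnorm(n), decreasing = TRUE)
  fused <- cf_ga_fuse(ga, vr)
  pos <- which(votes[, 1] == 1L)
  expect_equal(order(rank_of(fused, pos)), order(rank_of(ga, pos)))
  ## negatively voted conformations still fall behind (sentinel rule)
  neg <- which(votes[, 1] == -1L)
  expect_gt(min(rank_of(fused, neg)), max(rank_of(fused, pos)))
})

test_that("CF-then-GA retains the best CF classes and ranks them by GA", {
  set.seed(11)
  n <- 12
  k <- 4
  votes <- matrix(sample(c(-1L, 1L), n * k, replace = TRUE), n, k)
  p <- c(0.9, 0.8, 0.7, 0.6)
  vr <- vote_records(votes, p)
  ga <- ranked_set(rnorm(n), decreasing = TRUE)
  ## T >= n reduces to the GA ranking
  full <- cf_then_ga(vr, ga, T = n)
  expect_equal(full$id, ga$id[order(ga$rank)])
  ## T = 1: the single best CF conformation leads regardless of GA
  cf <- weighted_vote_rank(vr)
  one <- cf_then_ga(vr, ga, T = 1)
  expect_equal(one$id[1], cf$id[which.min(cf$rank)])
  ## a GA-best item outside the CF top T appears after position T
  gabest <- ga$id[ga$rank == 1]
  T <- 3
  cf_top <- cf$id[cf$rank <= T]
  if (!(gabest %in% cf_top)) {
    res <- cf_then_ga(vr, ga, T = T)
    expect_gt(which(res$id == gabest), sum(cf$rank <= T))
  }
  expect_error(cf_then_ga(vr, ga, T = 0))
})

test_that("the diversity filter is the greedy RMSD scan", {
  tc <- make_toy_complex(fixture_spec(seed = 29, n_residues = 10))
  base <- tc$native
  shift_pose <- function(dx) {
    lig <- base$ligand
    lig$xyz <- sweep(lig$xyz, 2, dx, `+`)
    complex_conformation(base$receptor, lig)
  }
  ## three planted clusters of near-duplicate poses
  set.seed(12)
  centers <- list(c(0, 0, 0), c(12, 0, 0), c(0, 12, 0))
  confs <- list()
  for (ct in centers) {
    for (r in 1:10) {
      confs[[length(confs) + 1L]] <- shift_pose(ct + runif(3, -1, 1))
    }
  }
  ranking <- ranked_set(rnorm(30), decreasing = TRUE)
  filt <- rmsd_diversity_filter(ranking, confs, min_rmsd = 5)
  ## greedy oracle
  ord <- ranking$id[order(ranking$rank)]
  kept <- integer(0)
  for (i in ord) {
    if (all(vapply(kept, function(j)
      node_rmsd(confs[[i]], confs[[j]]) > 5, FALSE))) kept <- c(kept, i)
  }
  expect_equal(filt$id, kept)
  expect_equal(filt$rank, seq_along(kept))
  expect_length(kept, 3)               # one survivor per planted cluster
  ## an exact duplicate right behind rank 1 is removed
  dup_rank <- ranked_set(c(10, 9, 1), decreasing = TRUE)
  dup_confs <- list(confs[[1]], confs[[1]], confs[[15]])
  filt2 <- rmsd_diversity_filter(dup_rank, dup_confs, min_rmsd = 5)
  expect_equal(filt2$id, c(1, 3))
  ## all pairwise RMSD above the radius: identity
  far <- list(shift_pose(c(0, 0, 0)), shift_pose(c(20, 0, 0)),
              shift_pose(c(0, 20, 0)))
  filt3 <- rmsd_diversity_filter(ranked_set(c(3, 2, 1)), far, min_rmsd = 5)
  expect_equal(filt3$id, 1:3)
})

test_that("the fitted CF ensemble gates on cross-validated precision", {
  pf <- make_planted_feature_set(fixture_spec(seed = 11, effect_size = 3,
                                              informative_fraction = 0.08,
                                              decoys_per_native = 5),
                                 n_complexes = 30)
  ## add a worse-than-random classifier: it must be discarded
  roster <- default_roster()
  roster$INV <- base_classifier("INV",
    fit = function(x, y) colMeans(x[y, , drop = FALSE]),
    predict = function(model, x) {
      ## votes positive mostly on negatives (anti-learner)
      rowSums(sweep(x, 2, model)^2) > stats::median(
        rowSums(sweep(x, 2, model)^2))
    })
  ens <- suppressMessages(cf_ensemble(pf$set, roster = roster, folds = 4,
                                      seed = 2))
  expect_false("INV" %in% names(ens$precision))
  expect_true(all(ens$precision >= 0.5))
  vr <- predict(ens, pf$set)
  expect_s3_class(vr, "vote_record")
  expect_equal(nrow(vr), nrow(pf$set$x))
  ## the ensemble separates the planted classes
  rs <- weighted_vote_rank(vr)
  y <- pf$set$label == "positive"
  expect_gt(roc_auc(vr$category_score, y), 0.8)
})
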