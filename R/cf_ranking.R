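## Collaborative-filtering layer: an ensemble of pluggable binary
## classifiers votes native (+1) / non-native (-1) on each conformation;
## votes are fused either uniformly (count of + votes) or weighted by each
## classifier's cross-validated precision, and optionally combined with the
## ES ranking (CF-GA fusion, CF-then-GA).

#' Define a base classifier for the ensemble
#'
#' Any binary learner satisfying the fit/predict contract is admissible:
#' \code{fit(x, y)} receives a numeric matrix (missing attributes imputed)
#' and a logical vector (TRUE = positive) and returns a model object;
#' \code{predict(model, x)} returns a logical vector.
#'
#' @param name display name
#' @param fit,predict functions as described above
#' @return object of class \code{base_classifier}
#' @export
base_classifier <- function(name, fit, predict) {
  structure(list(name = name, fit = fit, predict = predict),
            class = "base_classifier")
}

.rpart_classifier <- function(name, minbucket, split = "gini") {
  base_classifier(
    name,
    fit = function(x, y) {
      df <- data.frame(y = factor(y, levels = c(FALSE, TRUE)), x)
      rpart::rpart(y ~ ., data = df, method = "class",
                   parms = list(split = split),
                   control = rpart::rpart.control(minbucket = minbucket,
                                                  cp = 0.001, xval = 0))
    },
    predict = function(model, x) {
      as.logical(predict(model, data.frame(x), type = "class") == "TRUE")
    })
}

.tree_classifier <- function(name, mincut) {
  base_classifier(
    name,
    fit = function(x, y) {
      df <- data.frame(y = factor(y, levels = c(FALSE, TRUE)), x)
      tree::tree(y ~ ., data = df,
                 control = tree::tree.control(nobs = nrow(df),
                                              mincut = mincut,
                                              minsize = 2 * mincut,
                                              mindev = 0.002))
    },
    predict = function(model, x) {
      as.logical(predict(model, data.frame(x), type = "class") == "TRUE")
    })
}

.svm_classifier <- function(name, kernel, degree = 3) {
  base_classifier(
    name,
    fit = function(x, y) {
      e1071::svm(x, factor(y, levels = c(FALSE, TRUE)), kernel = kernel,
                 degree = degree, scale = apply(x, 2, stats::sd) > 1e-9)
    },
    predict = function(model, x) as.logical(predict(model, x) == "TRUE"))
}

#' Default classifier roster
#'
#' Twelve binary learners spanning four method families, mirroring the
#' usual docking-ensemble composition: logistic regression, SVMs (RBF and
#' quadratic kernels), CART decision trees with minimum leaf sizes 2/5/10
#' (Gini and information splits) and binary-tree variants with minimum cut
#' sizes 2/5/10. The roster is data, not structure: replace or extend it
#' with any [base_classifier()].
#'
#' @return named list of 12 [base_classifier()] objects
#' @export
default_roster <- function() {
  lr <- base_classifier(
    "LR",
    fit = function(x, y) {
      df <- data.frame(y = y, x)
      suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    },
    predict = function(model, x) {
      suppressWarnings(predict(model, data.frame(x), type = "response")) > 0.5
    })
  roster <- list(
    lr,
    .svm_classifier("SVM-RBF", "radial"),
    .svm_classifier("SVM-Q2", "polynomial", degree = 2),
    .rpart_classifier("CART-M2", 2), .rpart_classifier("CART-M5", 5),
    .rpart_classifier("CART-M10", 10),
    .rpart_classifier("CARTi-M2", 2, "information"),
    .rpart_classifier("CARTi-M5", 5, "information"),
    .rpart_classifier("CARTi-M10", 10, "information"),
    .tree_classifier("TREE-M2", 2), .tree_classifier("TREE-M5", 5),
    .tree_classifier("TREE-M10", 10)
  )
  names(roster) <- vapply(roster, `[[`, "", "name")
  roster
}

## median imputation for learners that cannot handle NA
.impute_fit <- function(x) {
  med <- apply(x, 2, function(cc) {
    m <- stats::median(cc, na.rm = TRUE)
    if (is.finite(m)) m else 0
  })
  med
}
.impute_apply <- function(x, med) {
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
  x
}

#' Fit a precision-gated collaborative-filtering ensemble
#'
#' Each roster classifier is evaluated by cross-validated prediction on the
#' training set (folds at complex level when \code{complex_id} is given);
#' its precision TP/(TP+FP) is measured on the held-out predictions only.
#' Classifiers with precision below \code{min_precision} (worse than
#' random) are discarded. Retained classifiers are refit on the full set.
#'
#' @param x a \code{learning_set} or numeric matrix (NA = masked)
#' @param label \code{"positive"}/\code{"negative"} per row
#' @param roster list of [base_classifier()]s, default [default_roster()]
#' @param complex_id optional grouping for fold assignment
#' @param folds cross-validation folds for precision estimation
#' @param min_precision gate threshold (default 0.5)
#' @param seed RNG seed for fold assignment
#' @return object of class \code{cf_ensemble}: fitted \code{models},
#'   measured \code{precision} per retained classifier, \code{discarded}
#'   names, imputation medians; supports \code{print} and \code{predict}
#' @export
cf_ensemble <- function(x, label = NULL, roster = default_roster(),
                        complex_id = NULL, folds = 10, min_precision = 0.5,
                        seed = 1) {
  cl <- match.call()
  if (inherits(x, "learning_set")) {
    if (is.null(label)) label <- x$label
    if (is.null(complex_id)) complex_id <- x$complex_id
    x <- x$x
  }
  x <- as.matrix(x)
  y <- label == "positive"
  if (is.null(complex_id)) complex_id <- seq_len(nrow(x))
  fold_id <- .make_folds(complex_id, folds, seed)
  med <- .impute_fit(x)
  xi <- .impute_apply(x, med)

  precision <- numeric(length(roster))
  names(precision) <- vapply(roster, `[[`, "", "name")
  cvpred <- matrix(NA, nrow(x), length(roster))
  for (f in seq_len(attr(fold_id, "nfolds"))) {
    tr <- fold_id != f
    for (k in seq_along(roster)) {
      mod <- .with_seed(seed + 97L * f + k,
                        roster[[k]]$fit(xi[tr, , drop = FALSE], y[tr]))
      cvpred[!tr, k] <- roster[[k]]$predict(mod, xi[!tr, , drop = FALSE])
    }
  }
  for (k in seq_along(roster)) {
    tp <- sum(cvpred[, k] == 1 & y, na.rm = TRUE)
    fp <- sum(cvpred[, k] == 1 & !y, na.rm = TRUE)
    precision[k] <- if (tp + fp == 0) 0 else tp / (tp + fp)
  }
  retained <- precision >= min_precision
  if (any(!retained))
    message("discarding classifiers with precision < ", min_precision, ": ",
            paste(names(precision)[!retained], collapse = ", "))
  if (!any(retained)) stop("no classifier passes the precision gate")
  models <- lapply(which(retained), function(k)
    .with_seed(seed + k, roster[[k]]$fit(xi, y)))
  structure(list(roster = roster[retained], models = models,
                 precision = precision[retained],
                 discarded = names(precision)[!retained],
                 impute = med, call = cl),
            class = "cf_ensemble")
}

#' @export
print.cf_ensemble <- function(x, ...) {
  cat("Collaborative-filtering ensemble:", length(x$models),
      "retained classifiers\n")
  print(round(sort(x$precision, decreasing = TRUE), 3))
  if (length(x$discarded) > 0)
    cat("  discarded (precision gate):",
        paste(x$discarded, collapse = ", "), "\n")
  invisible(x)
}

#' Predict ensemble votes
#'
#' @param object a [cf_ensemble()]
#' @param newdata descriptors as accepted by [score()]
#' @param ... unused
#' @return a \code{vote_record} data frame (see [vote_records()])
#' @export
predict.cf_ensemble <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_vector"))
    newdata <- matrix(newdata$values, nrow = 1)
  if (inherits(newdata, "learning_set")) newdata <- newdata$x
  xi <- .impute_apply(as.matrix(newdata), object$impute)
  votes <- vapply(seq_along(object$models), function(k) {
    ifelse(object$roster[[k]]$predict(object$models[[k]], xi), 1L, -1L)
  }, integer(nrow(xi)))
  votes <- matrix(votes, nrow = nrow(xi))
  colnames(votes) <- names(object$precision)
  vote_records(votes, object$precision)
}

#' Build vote records from a vote matrix
#'
#' Per conformation: S+ (sum of precisions of classifiers voting +),
#' S- (sum over - votes), the category score S+ - S-, the positive-vote
#' count, and the vote pattern (the category key: with distinct precisions
#' every pattern is its own category).
#'
#' @param votes integer matrix in \{-1, +1\}, rows = conformations,
#'   columns = classifiers
#' @param precision per-classifier precision vector
#' @param id item identifiers
#' @return data frame of class \code{vote_record} with columns \code{id},
#'   \code{n_plus}, \code{s_plus}, \code{s_minus}, \code{category_score},
#'   \code{pattern}; the classifier votes are kept as an attribute
#' @export
vote_records <- function(votes, precision, id = NULL) {
  votes <- as.matrix(votes)
  if (ncol(votes) == 0) stop("empty classifier roster")
  if (length(precision) != ncol(votes))
    stop("precision length must match the classifier roster")
  if (!all(votes %in% c(-1L, 1L))) stop("votes must be +1/-1")
  if (is.null(id)) id <- seq_len(nrow(votes))
  plus <- votes == 1L
  s_plus <- as.vector(plus %*% precision)
  s_minus <- as.vector((!plus) %*% precision)
  df <- data.frame(
    id = id,
    n_plus = rowSums(plus),
    s_plus = s_plus,
    s_minus = s_minus,
    category_score = s_plus - s_minus,
    pattern = apply(plus, 1, function(r) paste(as.integer(r), collapse = ""))
  )
  attr(df, "votes") <- votes
  attr(df, "precision") <- precision
  class(df) <- c("vote_record", "data.frame")
  df
}

#' Uniform-vote collaborative-filtering ranking
#'
#' Conformations are ranked by the number of positive votes received; with
#' k classifiers this defines k+1 categories and within-category ties share
#' the average rank.
#'
#' @param votes a [vote_records()] data frame
#' @return a [ranked_set()] whose \code{score} is the positive-vote count
#' @export
uniform_vote_rank <- function(votes) {
  ranked_set(score = votes$n_plus, id = votes$id, decreasing = TRUE)
}

#' Precision-weighted collaborative-filtering ranking
#'
#' Conformations are ordered by decreasing category score S+ - S-. With k
#' classifiers of distinct precisions the reachable categories are the 2^k
#' vote patterns. With all precisions equal to 1 the ordering reduces to
#' the uniform vote.
#'
#' @param votes a [vote_records()] data frame
#' @return a [ranked_set()] whose \code{score} is the category score
#' @export
weighted_vote_rank <- function(votes) {
  p <- attr(votes, "precision")
  if (!is.null(p) && anyDuplicated(round(p, 12)) > 0)
    message("classifier precisions are not all distinct; ",
            "some vote patterns share a category score")
  ranked_set(score = votes$category_score, id = votes$id, decreasing = TRUE)
}

#' Hybrid CF-GA fusion
#'
#' For conformations with at least one positive vote the fused value is
#' GA_rank * exp(S- - S+), ranked ascending (lower = better): positive
#' consensus shrinks the factor below 1 and promotes the conformation,
#' negative consensus inflates it. Conformations with only negative votes
#' (S+ = 0) take a maximal sentinel and occupy the last ranks in stable
#' input order.
#'
#' @param ga a [ranked_set()] from the ES/GA ranking, covering all voted
#'   conformations
#' @param votes a [vote_records()] data frame
#' @return a [ranked_set()] with the fused value as \code{score}
#'   (\code{Inf} for the sentinel)
#' @export
cf_ga_fuse <- function(ga, votes) {
  m <- match(votes$id, ga$id)
  if (any(is.na(m))) stop("conformation(s) missing from the GA ranking: ",
                          paste(votes$id[is.na(m)][1:5], collapse = ", "))
  ga_rank <- ga$rank[m]
  fused <- ga_rank * exp(votes$s_minus - votes$s_plus)
  sentinel <- votes$s_plus == 0
  fused[sentinel] <- Inf
  n <- length(fused)
  r <- numeric(n)
  r[!sentinel] <- rank(fused[!sentinel])
  ## sentinel items occupy the last ranks in stable input order
  r[sentinel] <- sum(!sentinel) + seq_len(sum(sentinel))
  df <- data.frame(id = votes$id, score = fused, rank = r)
  df <- df[order(df$rank), ]
  rownames(df) <- NULL
  class(df) <- c("ranked_set", "data.frame")
  df
}

#' CF-then-GA ranking
#'
#' First classify with the weighted CF, retain the conformations of the
#' best classes (weighted-CF rank at most \code{T}), and rank those by the
#' GA; discarded conformations follow in CF order.
#'
#' @param votes a [vote_records()] data frame
#' @param ga a [ranked_set()] from the ES/GA ranking
#' @param T retention cutoff on the weighted-CF rank
#' @return a [ranked_set()]
#' @export
cf_then_ga <- function(votes, ga, T) {
  stopifnot(T >= 1)
  cf <- weighted_vote_rank(votes)
  keep_ids <- cf$id[cf$rank <= T]
  m <- match(ga$id, keep_ids)
  kept <- ga[!is.na(m), , drop = FALSE]          # GA order among retained
  rest <- cf[!(cf$id %in% keep_ids), , drop = FALSE]  # CF order among rest
  df <- data.frame(id = c(kept$id, rest$id),
                   score = c(kept$rank, nrow(ga) + rest$rank))
  df$rank <- seq_len(nrow(df))
  class(df) <- c("ranked_set", "data.frame")
  df
}

#' RMSD diversity filter
#'
#' Scans the ranking from best to worst and keeps a conformation only if
#' its ligand-node RMSD to every already-kept (better ranked) conformation
#' exceeds \code{min_rmsd}; survivors are re-ranked 1..m. Removes
#' near-duplicate poses so the top of the list samples distinct binding
#' modes.
#'
#' @param ranking a [ranked_set()] whose ids index \code{confs}
#' @param confs list of [complex_conformation()] objects
#' @param min_rmsd diversity radius in Angstrom
#' @return the filtered, re-ranked [ranked_set()]
#' @export
rmsd_diversity_filter <- function(ranking, confs, min_rmsd = 5) {
  ord <- ranking$id[order(ranking$rank)]
  kept <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in kept) {
      if (node_rmsd(confs[[i]], confs[[j]]) <= min_rmsd) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, i)
  }
  df <- data.frame(id = kept,
                   score = ranking$score[match(kept, ranking$id)],
                   rank = seq_along(kept))
  class(df) <- c("ranked_set", "data.frame")
  df
}
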