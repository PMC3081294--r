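## Centered linear scoring function trained by a (mu+lambda) evolution
## strategy with ROC-AUC fitness, under complex-level cross-validation.
## One individual = (weights w, centers c, per-gene step sizes sigma);
## the score of a descriptor x is S = sum_i w_i (x_i - c_i) over the
## attributes that are not masked, higher = more native-like.

#' Rank-based ROC AUC
#'
#' Mann-Whitney formulation with average-rank tie handling: the probability
#' that a random positive scores above a random negative.
#'
#' @param scores numeric scores, higher = predicted more positive
#' @param labels \code{"positive"}/\code{"negative"} (or logical, TRUE =
#'   positive)
#' @return AUC in \[0, 1\]
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "positive"
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("AUC undefined: both classes required")
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Evaluate a scoring function on descriptors
#'
#' S = sum over unmasked attributes of w_i (x_i - c_i) (or
#' w_i |x_i - c_i| for the absolute-deviation variant). Masked attributes
#' contribute zero.
#'
#' @param f list with numeric \code{w} and \code{c} of length 96 (one
#'   element of an [es_scoring()] fit, or any such pair)
#' @param x a [featurize()] result, a \code{learning_set}, or a numeric
#'   matrix with NA for masked entries
#' @param form \code{"centered"} (default) or \code{"absdev"}
#' @return numeric score vector
#' @export
score <- function(f, x, form = c("centered", "absdev")) {
  form <- match.arg(form)
  if (inherits(x, "feature_vector")) x <- matrix(x$values, nrow = 1)
  if (inherits(x, "learning_set")) x <- x$x
  x <- as.matrix(x)
  M <- !is.na(x)
  x0 <- ifelse(M, x, 0)
  if (form == "centered") {
    as.vector(x0 %*% f$w - M %*% (f$w * f$c))
  } else {
    dev <- abs(sweep(x0, 2, f$c)) * M
    as.vector(dev %*% f$w)
  }
}

#' Rank-sum aggregation of scoring functions
#'
#' Each function ranks the conformations by descending score; the aggregate
#' score of a conformation is the sum of its per-function ranks and the
#' final rank is ascending in that sum (ties share the average rank).
#'
#' @param functions list of scoring functions (elements with \code{w},
#'   \code{c}), or a pre-computed score matrix (rows = conformations,
#'   columns = functions)
#' @param x descriptors as accepted by [score()] (ignored when
#'   \code{functions} is a score matrix)
#' @param form passed to [score()]
#' @param id optional item identifiers
#' @return a \code{ranked_set}: data frame \code{id}, \code{score}
#'   (aggregate rank sum, lower = better), \code{rank}
#' @export
aggregate_rank <- function(functions, x = NULL, form = "centered", id = NULL) {
  S <- if (is.matrix(functions)) functions
       else vapply(functions, function(f) score(f, x, form),
                   numeric(if (inherits(x, "learning_set")) nrow(x$x)
                           else if (inherits(x, "feature_vector")) 1L
                           else nrow(as.matrix(x))))
  S <- as.matrix(S)
  ranks <- apply(S, 2, function(s) rank(-s))
  agg <- rowSums(as.matrix(ranks))
  ranked_set(id = id, score = agg, decreasing = FALSE)
}

#' Construct a ranked set
#'
#' @param score per-item aggregate score
#' @param id item identifiers (default 1..n)
#' @param decreasing if TRUE higher score is better, else lower is better
#' @return data frame of class \code{ranked_set} with columns \code{id},
#'   \code{score}, \code{rank} (1 = best, average-rank ties), ordered by
#'   rank
#' @export
ranked_set <- function(score, id = NULL, decreasing = TRUE) {
  n <- length(score)
  if (n == 0) stop("empty set")
  if (is.null(id)) id <- seq_len(n)
  r <- if (decreasing) rank(-score) else rank(score)
  df <- data.frame(id = id, score = score, rank = r)
  df <- df[order(df$rank), ]
  rownames(df) <- NULL
  class(df) <- c("ranked_set", "data.frame")
  df
}

#' Granularity of a ranking
#'
#' Number of distinct scores divided by the number of items; 1 means a
#' total order, 1/n means everything is tied.
#'
#' @param ranking a [ranked_set()]
#' @return scalar in (0, 1]
#' @export
granularity <- function(ranking) {
  if (nrow(ranking) == 0) stop("empty set")
  length(unique(ranking$score)) / nrow(ranking)
}

## complex-level fold assignment: all conformations of a complex share a
## fold.  With a single complex (nothing to leak between) folds fall back
## to the row level so cross-validation remains possible.
.make_folds <- function(complex_id, folds, seed) {
  ids <- unique(complex_id)
  if (length(ids) < 2) {
    message("single complex: falling back to row-level folds")
    n <- length(complex_id)
    folds <- min(folds, n)
    grp <- .with_seed(seed, sample(rep_len(seq_len(folds), n)))
    return(structure(grp, nfolds = folds))
  }
  if (length(ids) < folds) folds <- length(ids)
  grp <- .with_seed(seed, sample(rep_len(seq_len(folds), length(ids))))
  structure(grp[match(complex_id, ids)], nfolds = folds)
}

## one (mu+lambda)-ES run on standardized training data; returns the best
## individual and its fitness trajectory
.es_run <- function(X0, M, y, mu, lambda, generations, sigma_init,
                    stagnation, form) {
  d <- ncol(X0)
  ng <- 2L * d
  tau <- 1 / sqrt(2 * sqrt(ng))
  taup <- 1 / sqrt(2 * ng)
  fitness_of <- function(W, C) {
    S <- if (form == "centered") X0 %*% W - M %*% (W * C)
         else vapply(seq_len(ncol(W)), function(j)
           (abs(sweep(X0, 2, C[, j])) * M) %*% W[, j, drop = FALSE],
           numeric(nrow(X0)))
    apply(as.matrix(S), 2, function(s) {
      if (!all(is.finite(s))) return(NA_real_)
      roc_auc(s, y)
    })
  }
  W <- matrix(stats::rnorm(d * mu), d, mu)
  C <- matrix(stats::rnorm(d * mu, sd = 0.5), d, mu)
  SG <- matrix(sigma_init, d * 2, mu)
  fit <- fitness_of(W, C)
  fit[is.na(fit)] <- -Inf
  best_traj <- numeric(generations)
  best <- max(fit)
  since_improve <- 0L
  for (g in seq_len(generations)) {
    p1 <- sample.int(mu, lambda, replace = TRUE)
    p2 <- sample.int(mu, lambda, replace = TRUE)
    ## discrete recombination of genes, intermediate for step sizes
    pick <- matrix(stats::runif(d * lambda) < 0.5, d, lambda)
    Wc <- ifelse(pick, W[, p1, drop = FALSE], W[, p2, drop = FALSE])
    pick <- matrix(stats::runif(d * lambda) < 0.5, d, lambda)
    Cc <- ifelse(pick, C[, p1, drop = FALSE], C[, p2, drop = FALSE])
    SGc <- (SG[, p1, drop = FALSE] + SG[, p2, drop = FALSE]) / 2
    ## log-normal self-adaptation, then Gaussian gene mutation
    glob <- rep(stats::rnorm(lambda, sd = taup), each = 2L * d)
    SGc <- SGc * exp(glob + tau * stats::rnorm(2L * d * lambda))
    dim(SGc) <- c(2L * d, lambda)
    Wc <- Wc + SGc[1:d, , drop = FALSE] *
      matrix(stats::rnorm(d * lambda), d, lambda)
    Cc <- Cc + SGc[(d + 1L):(2L * d), , drop = FALSE] *
      matrix(stats::rnorm(d * lambda), d, lambda)
    fitc <- fitness_of(Wc, Cc)
    fitc[is.na(fitc)] <- -Inf
    allW <- cbind(W, Wc); allC <- cbind(C, Cc); allS <- cbind(SG, SGc)
    allf <- c(fit, fitc)
    sel <- order(allf, decreasing = TRUE)[seq_len(mu)]
    W <- allW[, sel, drop = FALSE]
    C <- allC[, sel, drop = FALSE]
    SG <- allS[, sel, drop = FALSE]
    fit <- allf[sel]
    best_traj[g] <- fit[1]
    if (fit[1] > best + 1e-9) {
      best <- fit[1]; since_improve <- 0L
    } else since_improve <- since_improve + 1L
    if (since_improve >= stagnation) { best_traj <- best_traj[1:g]; break }
  }
  list(w = W[, 1], c = C[, 1], fitness = fit[1], trajectory = best_traj)
}

#' Fit an evolution-strategy scoring ensemble
#'
#' Trains the centered linear scoring function S = sum w_i (x_i - c_i) by a
#' (mu+lambda) evolution strategy maximizing training-fold ROC AUC.
#' Cross-validation folds are split at complex level (all conformations of
#' a complex share a fold, preventing native/decoy leakage); each fold is
#' trained \code{runs} times from independent initializations and the full
#' ensemble of \code{folds * runs} functions is kept for rank-sum
#' aggregation at prediction time.
#'
#' Attributes are standardized internally; the returned weights and centers
#' are on the raw attribute scale.
#'
#' @param x a \code{learning_set} or numeric matrix (NA = masked attribute)
#' @param label \code{"positive"}/\code{"negative"} per row (taken from the
#'   learning set when omitted)
#' @param complex_id grouping for fold assignment (rows = complexes when
#'   omitted)
#' @param folds number of cross-validation folds
#' @param runs independent ES runs per fold
#' @param mu,lambda parent and child population sizes
#' @param generations maximum generations per run
#' @param sigma_init initial mutation step size (standardized scale)
#' @param stagnation stop a run after this many generations without
#'   improvement
#' @param form \code{"centered"} or \code{"absdev"} (see [score()])
#' @param seed RNG seed; every run derives its own sub-seed from it
#' @return object of class \code{es_scoring} with elements
#'   \code{functions} (list of \code{w}, \code{c}, \code{fold}, \code{run},
#'   \code{train_auc}), \code{cv} (per-function held-out AUC), plus the
#'   configuration; supports \code{print}, \code{summary}, \code{coef} and
#'   \code{predict}
#' @export
es_scoring <- function(x, label = NULL, complex_id = NULL, folds = 10,
                       runs = 30, mu = 10, lambda = 70, generations = 500,
                       sigma_init = 0.5, stagnation = 50,
                       form = c("centered", "absdev"), seed = 1) {
  form <- match.arg(form)
  cl <- match.call()
  if (inherits(x, "learning_set")) {
    if (is.null(label)) label <- x$label
    if (is.null(complex_id)) complex_id <- x$complex_id
    x <- x$x
  }
  x <- as.matrix(x)
  if (is.null(label)) stop("label required")
  if (is.null(complex_id)) complex_id <- seq_len(nrow(x))
  y <- label == "positive"
  if (!any(y) || all(y)) stop("both classes required")
  stopifnot(mu >= 1, lambda >= mu)

  ## standardize on observed entries; constant columns get sd 1
  mu_col <- apply(x, 2, function(cc) mean(cc, na.rm = TRUE))
  mu_col[is.na(mu_col)] <- 0
  sd_col <- apply(x, 2, function(cc) stats::sd(cc, na.rm = TRUE))
  sd_col[!is.finite(sd_col) | sd_col < 1e-12] <- 1
  Z <- sweep(sweep(x, 2, mu_col), 2, sd_col, `/`)
  M <- !is.na(Z)
  Z0 <- ifelse(M, Z, 0)
  Mi <- matrix(as.numeric(M), nrow(M), ncol(M))

  fold_id <- .make_folds(complex_id, folds, seed)
  nf <- attr(fold_id, "nfolds")
  functions <- list()
  cv <- data.frame(fold = integer(), run = integer(),
                   train_auc = numeric(), heldout_auc = numeric())
  for (f in seq_len(nf)) {
    tr <- fold_id != f
    ho <- !tr
    if (!any(y[tr]) || all(y[tr])) stop("fold ", f, " lacks a class")
    for (r in seq_len(runs)) {
      res <- .with_seed(seed + 7919L * f + r, {
        .es_run(Z0[tr, , drop = FALSE], Mi[tr, , drop = FALSE], y[tr],
                mu, lambda, generations, sigma_init, stagnation, form)
      })
      ## back-transform to raw attribute scale
      fn <- list(w = res$w / sd_col,
                 c = mu_col + res$c * sd_col,
                 fold = f, run = r, train_auc = res$fitness,
                 trajectory = res$trajectory)
      functions[[length(functions) + 1L]] <- fn
      hauc <- if (any(y[ho]) && !all(y[ho]))
        roc_auc(score(fn, x[ho, , drop = FALSE], form), y[ho])
      else NA_real_
      cv <- rbind(cv, data.frame(fold = f, run = r,
                                 train_auc = res$fitness,
                                 heldout_auc = hauc))
    }
  }
  structure(list(functions = functions, cv = cv, fold_id = as.vector(fold_id),
                 form = form, scaling = list(center = mu_col, scale = sd_col),
                 config = list(folds = nf, runs = runs, mu = mu,
                               lambda = lambda, generations = generations,
                               sigma_init = sigma_init,
                               stagnation = stagnation, seed = seed),
                 call = cl),
            class = "es_scoring")
}

#' @export
print.es_scoring <- function(x, ...) {
  cfg <- x$config
  cat("Evolution-strategy scoring ensemble\n")
  cat("  ", length(x$functions), " functions (", cfg$folds, " folds x ",
      cfg$runs, " runs), (", cfg$mu, "+", cfg$lambda, ")-ES, max ",
      cfg$generations, " generations\n", sep = "")
  ho <- x$cv$heldout_auc
  if (any(!is.na(ho)))
    cat("  held-out AUC: mean", round(mean(ho, na.rm = TRUE), 3),
        " range", paste(round(range(ho, na.rm = TRUE), 3), collapse = "-"),
        "\n")
  invisible(x)
}

#' @export
summary.es_scoring <- function(object, ...) {
  out <- list(config = object$config,
              heldout_auc = object$cv$heldout_auc,
              train_auc = object$cv$train_auc,
              mean_abs_weight = rowMeans(abs(coef(object))))
  class(out) <- "summary.es_scoring"
  out
}

#' @export
print.summary.es_scoring <- function(x, ...) {
  cat("ES scoring ensemble:", length(x$train_auc), "functions\n")
  cat("  training AUC:  ", paste(round(stats::quantile(x$train_auc), 3),
                                 collapse = " "), "\n")
  if (any(!is.na(x$heldout_auc)))
    cat("  held-out AUC:  ",
        paste(round(stats::quantile(x$heldout_auc, na.rm = TRUE), 3),
              collapse = " "), "\n")
  top <- sort(x$mean_abs_weight, decreasing = TRUE)[1:10]
  cat("  largest mean |weight| attributes:\n")
  print(round(top, 4))
  invisible(x)
}

#' @export
coef.es_scoring <- function(object, ...) {
  W <- vapply(object$functions, `[[`, numeric(96), "w")
  rownames(W) <- paste0("c", 1:96)
  colnames(W) <- vapply(object$functions,
                        function(f) paste0("f", f$fold, "r", f$run), "")
  W
}

#' Predict with an ES scoring ensemble
#'
#' @param object an [es_scoring()] fit
#' @param newdata descriptors as accepted by [score()]
#' @param type \code{"rank"} for the rank-sum aggregated [ranked_set()]
#'   (the ensemble's native output), \code{"score"} for the mean raw score
#' @param ... unused
#' @return a \code{ranked_set} or numeric vector
#' @export
predict.es_scoring <- function(object, newdata, type = c("rank", "score"),
                               ...) {
  type <- match.arg(type)
  S <- vapply(object$functions, function(f) score(f, newdata, object$form),
              numeric(if (inherits(newdata, "learning_set")) nrow(newdata$x)
                      else if (inherits(newdata, "feature_vector")) 1L
                      else nrow(as.matrix(newdata))))
  S <- as.matrix(S)
  if (type == "score") return(rowMeans(S))
  aggregate_rank(S)
}

#' @export
plot.es_scoring <- function(x, ...) {
  tr <- lapply(x$functions, `[[`, "trajectory")
  gmax <- max(lengths(tr))
  plot(NULL, xlim = c(1, gmax), ylim = c(0.5, 1),
       xlab = "generation", ylab = "best training AUC",
       main = "ES fitness trajectories", ...)
  for (t in tr) graphics::lines(seq_along(t), t,
                                col = grDevices::adjustcolor("steelblue", 0.4))
  invisible(x)
}
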