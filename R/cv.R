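# Consistent-positive-set construction and the double-loop cross-validation
# that evaluates a tissue classifier. Folds are grouped by promoter: all
# CNEs attributed to one promoter share a fold, so held-out promoters are
# never seen at training time.

#' Training configuration
#'
#' @param gamma_grid candidate multipliers for the positive-class weight
#'   `w1 = (n-/n+) * gamma` (class-balancing ratio times gamma).
#' @param C_override fixed C; `NULL` estimates C from each training fold
#'   via [estimate_cost()].
#' @param folds,repeats cross-validation geometry (default 5 x 5).
#' @param per_promoter_pick positive-scoring elements kept per promoter in
#'   the consistent set (default 2).
#' @param seed master seed; fold assignments and per-promoter picks derive
#'   deterministic substreams from it.
#' @param weight_direction `"neg_over_pos"` uses `w1 = (n-/n+) * gamma`;
#'   `"pos_over_neg"` flips the ratio.
#' @param literal_heldout_negatives if `TRUE`, reproduce the literal
#'   description of training the final fold classifier on the held-out 1/5
#'   negatives (default `FALSE`: train on the training-fold negatives and
#'   evaluate on untouched held-out data).
#' @return list of class `"train_config"`.
#' @export
train_config <- function(gamma_grid = c(1/3, 2/3, 1, 4/3, 5/3),
                         C_override = NULL, folds = 5L, repeats = 5L,
                         per_promoter_pick = 2L, seed = 1L,
                         weight_direction = c("neg_over_pos", "pos_over_neg"),
                         literal_heldout_negatives = FALSE) {
  stopifnot(folds >= 2, length(gamma_grid) >= 1)
  structure(list(gamma_grid = gamma_grid, C_override = C_override,
                 folds = as.integer(folds), repeats = as.integer(repeats),
                 per_promoter_pick = as.integer(per_promoter_pick),
                 seed = as.integer(seed),
                 weight_direction = match.arg(weight_direction),
                 literal_heldout_negatives = literal_heldout_negatives),
            class = "train_config")
}

class_weight <- function(n_pos, n_neg, gamma, direction = "neg_over_pos") {
  if (direction == "neg_over_pos") (n_neg / n_pos) * gamma
  else (n_pos / n_neg) * gamma
}

# deterministic substream seeds below 2^31
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 16807) %% 2147483647)
}

# first promoter symbol of each element (elements of a promoter share folds)
primary_promoter <- function(fm) {
  vapply(fm$promoter_of, function(p)
    if (length(p)) p[1] else NA_character_, character(1))
}

#' Build the consistent positive set of a training fold
#'
#' For each promoter P of the positive class, a model is trained on the
#' fold's training data excluding every element attributed to P; P's own
#' elements are then scored with that model, and up to `pick` randomly
#' chosen positive-scoring ones represent P (all of them if fewer, none if
#' none scores positive). The union over promoters is the consistent set.
#'
#' @param fm a labeled [feature_matrix()] with promoter attributions
#'   (the training fold).
#' @param C cost parameter.
#' @param w1 positive-class weight used for the leave-one-promoter-out
#'   models.
#' @param pick elements kept per promoter (default 2).
#' @param seed RNG seed for the random picks.
#' @return integer indices (into `fm`) of the selected positive elements.
#' @export
build_consistent_positive_set <- function(fm, C = NULL, w1 = 1, pick = 2L,
                                          seed = 1L) {
  prom <- primary_promoter(fm)
  pos <- which(fm$label == 1)
  if (all(is.na(prom[pos]))) stop("positive elements carry no promoter map")
  promoters <- unique(prom[pos])
  if (length(promoters) < 2)
    stop("need at least 2 positive promoters to build a consistent set")
  if (is.null(C)) C <- estimate_cost(fm)
  selected <- integer(0)
  rng <- sub_seed(seed, 7L)
  for (k in seq_along(promoters)) {
    p <- promoters[k]
    own <- which(prom == p & fm$label == 1)
    rest <- setdiff(seq_along(fm$label), own)
    y <- fm$label[rest]
    if (length(unique(y)) < 2) next
    model <- train_svm(fm$counts[rest, , drop = FALSE], y, C = C, w1 = w1)
    sc <- decision_score(model, fm$counts[own, , drop = FALSE])
    good <- own[sc > 0]
    if (length(good) == 0) next
    if (length(good) > pick) {
      set.seed(sub_seed(rng, k))
      good <- sample(good, pick)
    }
    selected <- c(selected, good)
  }
  sort(unique(selected))
}

# fold assignment grouped by promoter, balanced within each class
promoter_folds <- function(fm, folds, seed) {
  prom <- primary_promoter(fm)
  fold_of_prom <- character(0)
  assignment <- integer(length(fm$label))
  set.seed(seed)
  for (cls in c(1, -1)) {
    pr <- unique(prom[fm$label == cls & !is.na(prom)])
    f <- sample(rep(seq_len(folds), length.out = length(pr)))
    names(f) <- pr
    idx <- which(fm$label == cls)
    assignment[idx] <- f[prom[idx]]
  }
  assignment
}

#' Double-loop cross-validation of a promoter classifier
#'
#' Outer loop: `folds x repeats` promoter-grouped splits. In each split the
#' consistent positive set is built from the training four-fifths
#' (leave-one-promoter-out models with the balanced weight, gamma = 1);
#' the final fold classifier is then trained on the consistent positives
#' plus the training-fold negatives, once per candidate gamma, and
#' evaluated by AUC on the held-out fifth. gamma is selected once, as the
#' grid value maximizing the median AUC over all splits, ties resolved
#' toward gamma = 1.
#'
#' @param fm labeled [feature_matrix()] with promoter attributions.
#' @param cfg a [train_config()].
#' @return list of class `"cv_report"`: `fold_aucs` (repeats x folds matrix
#'   for the chosen gamma), `median_auc`, `chosen_gamma`, `gamma_medians`,
#'   `consistent_set_sizes`, `reliability`.
#' @export
double_loop_cv <- function(fm, cfg = train_config()) {
  n_pos <- sum(fm$label == 1); n_neg <- sum(fm$label == -1)
  if (n_pos < cfg$folds || n_neg < cfg$folds)
    stop("each class needs at least `folds` members")
  gammas <- cfg$gamma_grid
  aucs <- array(NA_real_, c(length(gammas), cfg$repeats, cfg$folds))
  cs_sizes <- matrix(NA_integer_, cfg$repeats, cfg$folds)
  for (r in seq_len(cfg$repeats)) {
    fold_id <- promoter_folds(fm, cfg$folds, sub_seed(cfg$seed, 100 + r))
    for (f in seq_len(cfg$folds)) {
      train_idx <- which(fold_id != f)
      test_idx <- which(fold_id == f)
      y_tr <- fm$label[train_idx]
      if (length(unique(y_tr)) < 2 ||
          length(unique(fm$label[test_idx])) < 2) {
        warning("degenerate fold skipped (one class absent)")
        next
      }
      tr <- subset_fm(fm, train_idx)
      C <- if (is.null(cfg$C_override)) estimate_cost(tr) else cfg$C_override
      w1_inner <- class_weight(sum(y_tr == 1), sum(y_tr == -1), 1,
                               cfg$weight_direction)
      cons_local <- build_consistent_positive_set(
        tr, C = C, w1 = w1_inner, pick = cfg$per_promoter_pick,
        seed = sub_seed(cfg$seed, 1000 * r + f))
      if (length(cons_local) == 0) {
        warning("empty consistent set; fold skipped")
        next
      }
      cs_sizes[r, f] <- length(cons_local)
      neg_pool <- if (cfg$literal_heldout_negatives)
        test_idx[fm$label[test_idx] == -1] else
        train_idx[fm$label[train_idx] == -1]
      Xf <- rbind(tr$counts[cons_local, , drop = FALSE],
                  fm$counts[neg_pool, , drop = FALSE])
      yf <- c(rep(1, length(cons_local)), rep(-1, length(neg_pool)))
      test_pos <- test_idx[fm$label[test_idx] == 1]
      test_neg <- test_idx[fm$label[test_idx] == -1]
      for (g in seq_along(gammas)) {
        w1 <- class_weight(sum(yf == 1), sum(yf == -1), gammas[g],
                           cfg$weight_direction)
        model <- train_svm(Xf, yf, C = C, w1 = w1)
        sp <- decision_score(model, fm$counts[test_pos, , drop = FALSE])
        sn <- decision_score(model, fm$counts[test_neg, , drop = FALSE])
        aucs[g, r, f] <- auc(sp, sn)
      }
    }
  }
  if (all(is.na(aucs))) stop("all folds degenerate")
  gamma_medians <- apply(aucs, 1, stats::median, na.rm = TRUE)
  best <- max(gamma_medians)
  tied <- which(abs(gamma_medians - best) < 1e-12)
  chosen <- tied[which.min(abs(gammas[tied] - 1))]
  fold_aucs <- aucs[chosen, , , drop = TRUE]
  fold_aucs <- matrix(fold_aucs, cfg$repeats, cfg$folds,
                      dimnames = list(paste0("repeat", seq_len(cfg$repeats)),
                                      paste0("fold", seq_len(cfg$folds))))
  report <- structure(list(
    fold_aucs = fold_aucs,
    median_auc = stats::median(fold_aucs, na.rm = TRUE),
    chosen_gamma = gammas[chosen],
    gamma_medians = stats::setNames(gamma_medians, signif(gammas, 4)),
    consistent_set_sizes = cs_sizes), class = "cv_report")
  report$reliability <- is_reliable(report)
  report
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: median AUC %.3f (%s), gamma = %.3g\n",
              x$median_auc, x$reliability, x$chosen_gamma))
  invisible(x)
}

#' Train the final tissue model
#'
#' Builds the consistent positive set on the full training data and trains
#' the final class-weighted SVM on consistent positives plus all negatives,
#' using the gamma chosen by [double_loop_cv()].
#'
#' @param fm labeled [feature_matrix()].
#' @param gamma positive-class weight multiplier.
#' @param cfg a [train_config()].
#' @return a `"linear_model"` with `consistent_size` attached.
#' @export
train_final_model <- function(fm, gamma = 1, cfg = train_config()) {
  C <- if (is.null(cfg$C_override)) estimate_cost(fm) else cfg$C_override
  n_pos <- sum(fm$label == 1); n_neg <- sum(fm$label == -1)
  cons <- build_consistent_positive_set(
    fm, C = C, w1 = class_weight(n_pos, n_neg, 1, cfg$weight_direction),
    pick = cfg$per_promoter_pick, seed = sub_seed(cfg$seed, 31L))
  if (length(cons) == 0) stop("empty consistent positive set")
  neg <- which(fm$label == -1)
  X <- rbind(fm$counts[cons, , drop = FALSE], fm$counts[neg, , drop = FALSE])
  y <- c(rep(1, length(cons)), rep(-1, length(neg)))
  w1 <- class_weight(length(cons), length(neg), gamma, cfg$weight_direction)
  model <- train_svm(X, y, C = C, w1 = w1)
  model$consistent_size <- length(cons)
  model$gamma <- gamma
  model
}
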