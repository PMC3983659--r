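# Class-weighted linear SVM and the quantities derived from it. The QP is
# solved by libsvm (via e1071) with a linear kernel and per-class penalties;
# everything around it -- the C heuristic, the class-weight grid, weight
# scaling -- is defined here.

#' Data-driven estimate of the SVM cost parameter
#'
#' `C = 1 / mean_i(||x_i||^2)`, a scale-normalizing heuristic: doubling all
#' feature vectors divides C by four, keeping the effective regularization
#' comparable across feature scales. Overridable wherever it is consumed.
#'
#' @param x numeric matrix (rows = samples) or a [feature_matrix()].
#' @return positive scalar C.
#' @export
estimate_cost <- function(x) {
  if (inherits(x, "feature_matrix")) x <- x$counts
  sq <- rowSums(x^2)
  if (all(sq == 0)) stop("cannot estimate C from an all-zero matrix")
  1 / mean(sq)
}

#' Train a class-weighted soft-margin linear SVM
#'
#' Solves the primal `min 1/2 w'w + C sum xi_i` with per-class error
#' weights: the penalty is `C * w1` for positive-class slack and `C` for
#' negative-class slack. Deterministic for fixed inputs.
#'
#' @param x numeric matrix or [feature_matrix()] (labels taken from it).
#' @param y labels in `{+1, -1}` (ignored when `x` is a feature matrix).
#' @param C cost parameter (`NULL`: [estimate_cost()]).
#' @param w1 positive-class weight multiplier (default 1).
#' @param tolerance solver termination tolerance.
#' @return list of class `"linear_model"`: `w` (named weight vector), `b`,
#'   `C`, `w1`, `motif_ids`.
#' @export
train_svm <- function(x, y = NULL, C = NULL, w1 = 1, tolerance = 1e-4) {
  if (inherits(x, "feature_matrix")) {
    y <- x$label
    x <- x$counts
  }
  x <- as.matrix(x)
  if (!all(y %in% c(-1, 1))) stop("labels must be +1/-1")
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (is.null(C)) C <- estimate_cost(x)
  yf <- factor(y, levels = c("1", "-1"))
  fit <- e1071::svm(x, yf, kernel = "linear", scale = FALSE,
                    cost = C, class.weights = c("1" = w1, "-1" = 1),
                    tolerance = tolerance)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # libsvm orients the decision function toward its internally-first label
  if (fit$levels[fit$labels[1]] == "-1") {
    w <- -w; b <- -b
  }
  names(w) <- colnames(x)
  structure(list(w = w, b = b, C = C, w1 = w1,
                 motif_ids = colnames(x)),
            class = "linear_model")
}

#' Primal objective of a (w, b) pair on a training set
#'
#' `1/2 w'w + C * sum(class_weight_i * hinge_i)`; used by tests to verify
#' optimality of [train_svm()] against random feasible probes.
#'
#' @param w,b candidate solution.
#' @param x,y training data and +1/-1 labels.
#' @param C,w1 penalty parameters as in [train_svm()].
#' @return scalar objective value.
#' @export
svm_objective <- function(w, b, x, y, C, w1 = 1) {
  f <- drop(as.matrix(x) %*% w + b)
  xi <- pmax(0, 1 - y * f)
  cw <- ifelse(y > 0, w1, 1)
  0.5 * sum(w^2) + C * sum(cw * xi)
}

#' Linear decision score
#'
#' Raw `w'x + b`; the hard class call is its sign, applied only when a
#' call is requested.
#'
#' @param model a `"linear_model"`.
#' @param x numeric vector or matrix of samples.
#' @return numeric score(s).
#' @export
decision_score <- function(model, x) {
  if (is.null(dim(x))) {
    if (length(x) != length(model$w)) stop("feature dimension mismatch")
    return(sum(model$w * x) + model$b)
  }
  x <- as.matrix(x)
  if (ncol(x) != length(model$w)) stop("feature dimension mismatch")
  unname(drop(x %*% model$w + model$b))
}

#' Scale SVM weights sign-preservingly into [-1, 1]
#'
#' Positive weights are divided by the largest positive weight; negative
#' weights are mapped by `-(1 - (w - wmin) / (-wmin))` so the most negative
#' weight reaches -1. Zeros map to zero; signs are preserved exactly.
#'
#' @param w numeric weight vector.
#' @return list with `scaled`, `wmin`, `wmax`.
#' @export
scale_weights <- function(w) {
  if (any(!is.finite(w))) stop("weights must be finite")
  wmin <- if (min(w) < 0) min(w) else 0
  wmax <- if (max(w) > 0) max(w) else 0
  scaled <- numeric(length(w))
  neg <- w < 0
  if (any(neg)) scaled[neg] <- -(1 - (w[neg] - wmin) / (-wmin))
  pos <- w >= 0
  if (wmax > 0) scaled[pos] <- w[pos] / wmax
  names(scaled) <- names(w)
  list(scaled = scaled, wmin = wmin, wmax = wmax)
}

#' Area under the ROC curve by pair counting
#'
#' The Mann-Whitney estimator: the fraction of (positive, negative) score
#' pairs ranked correctly, ties counted one half. Equals the trapezoidal
#' area under the ROC curve.
#'
#' @param scores_pos,scores_neg numeric score vectors (both non-empty).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  if (np == 0 || nn == 0) stop("both score sets must be non-empty")
  r <- rank(c(scores_pos, scores_neg))
  u <- sum(r[seq_len(np)]) - np * (np + 1) / 2
  u / (np * nn)
}

#' Classify a cross-validation report as reliable
#'
#' @param report a CV report from [double_loop_cv()] (or any list with a
#'   `median_auc` component).
#' @param cutoff reliability threshold on the median AUC (default 0.6,
#'   inclusive).
#' @return `"reliable"` or `"unreliable"`.
#' @export
is_reliable <- function(report, cutoff = 0.6) {
  if (report$median_auc >= cutoff) "reliable" else "unreliable"
}
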