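#' Normalize a propidium-displacement measurement
#'
#' Displacement assays are reported relative to the reference inhibitor
#' donepezil: its displacement is taken as 100% and each compound's raw
#' value is expressed as a percentage of it.
#'
#' @param raw_pct Raw displacement (% of propidium fluorescence change).
#' @param donepezil_raw_pct Donepezil's raw displacement; must be > 0.
#' @return Normalized displacement (percent of donepezil).
#' @examples
#' normalize_displacement(11.9, 11.9)  # 100
#' @export
normalize_displacement <- function(raw_pct, donepezil_raw_pct) {
  if (!is.finite(donepezil_raw_pct) || donepezil_raw_pct <= 0)
    stop("donepezil reference displacement must be a positive number")
  100 * raw_pct / donepezil_raw_pct
}

#' Binary displacement activity rule
#'
#' A compound is `"active"` iff its donepezil-normalized displacement is
#' strictly greater than 50%; a value of exactly 50 is inactive.
#'
#' @param norm_pct Normalized displacement (>= 0).
#' @return Character vector of `"active"` / `"inactive"`.
#' @export
label_activity <- function(norm_pct) {
  if (any(!is.finite(norm_pct)) || any(norm_pct < 0))
    stop("normalized displacement must be finite and nonnegative")
  ifelse(norm_pct > 50, "active", "inactive")
}

ACTIVITY_LEVELS <- c("inactive", "active")

as_activity <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), ACTIVITY_LEVELS)
  if (length(bad))
    stop("labels must be 'active'/'inactive'; got: ",
         paste(bad, collapse = ", "))
  factor(labels, levels = ACTIVITY_LEVELS)
}

# Core Fisher-discriminant fit on a numeric matrix; shared by the formula
# interface and the leave-one-out loop (which needs it fast and bare).
lda_core <- function(x, y, priors = "equal", jitter = 0) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as_activity(y)
  n <- nrow(x)
  if (n < 4L) stop("need at least 4 cases to fit the discriminant")
  n_by <- table(y)
  if (any(n_by < 2L))
    stop("need at least 2 cases per class (active and inactive)")
  mu_a <- colMeans(x[y == "active", , drop = FALSE])
  mu_i <- colMeans(x[y == "inactive", , drop = FALSE])
  s_a <- stats::cov(x[y == "active", , drop = FALSE])
  s_i <- stats::cov(x[y == "inactive", , drop = FALSE])
  pooled <- ((n_by[["active"]] - 1) * s_a + (n_by[["inactive"]] - 1) * s_i) /
    (n - 2)
  if (jitter > 0) pooled <- pooled + diag(jitter, ncol(x))
  if (!all(is.finite(pooled)) || rcond(pooled) < 1e-10)
    stop("pooled within-class covariance is (near-)singular; ",
         "consider the 'jitter' regularization argument")
  w <- solve(pooled, mu_a - mu_i)
  mid <- 0.5 * (sum(w * mu_a) + sum(w * mu_i))
  threshold <- switch(priors,
    equal = mid,
    proportional = mid - log(n_by[["active"]] / n_by[["inactive"]]),
    stop("priors must be 'equal' or 'proportional'"))
  list(weights = w, threshold = threshold,
       class_means = rbind(active = mu_a, inactive = mu_i),
       pooled_covariance = pooled, n_by = as.vector(n_by),
       priors = priors)
}

lda_score <- function(fit, x) {
  as.numeric(as.matrix(x) %*% fit$weights)
}

lda_label <- function(fit, x) {
  # strict inequality: a case exactly on the decision plane is called
  # inactive (conservative for an "active" call)
  ifelse(lda_score(fit, x) > fit$threshold, "active", "inactive")
}

#' Linear discriminant classifier of propidium displacement
#'
#' Fits Fisher's linear discriminant for the two-class displacement problem
#' from docking-derived predictors — canonically the percent overlap of each
#' compound's docked pose with the propidium pose and its binding energy
#' Eb = -deltaG.  The discriminant direction is
#' `w = S_pooled^-1 (mu_active - mu_inactive)` with the pooled within-class
#' covariance; under equal priors (the default) the decision threshold is
#' the midpoint of the projected class means, and under `"proportional"`
#' priors it is shifted by the log prior ratio.  A case projecting exactly
#' onto the threshold is classified inactive.  No feature standardization is
#' applied: the discriminant is affine-equivariant, so scaling a feature
#' rescales its weight without changing any prediction.
#'
#' @param formula Model formula, e.g.
#'   `label ~ propidium_overlap_pct + binding_energy`; the response must be
#'   `"active"`/`"inactive"`.
#' @param data Data frame holding the response and predictors.
#' @param priors `"equal"` (default) or `"proportional"` to class sizes.
#' @param jitter Optional nonnegative ridge added to the pooled covariance
#'   diagonal for near-singular feature sets.
#' @return An object of class `displacement_lda` with `print`, `summary`,
#'   `coef`, `predict` and `plot` methods.
#' @seealso [loo_accuracy()] for the exhaustive leave-one-out jackknife.
#' @examples
#' d <- data.frame(
#'   overlap = c(60, 55, 70, 65, 5, 0, 10, 2),
#'   energy  = c(8.6, 8.2, 9.0, 8.8, 6.3, 6.6, 6.1, 6.4),
#'   label   = rep(c("active", "inactive"), each = 4))
#' fit <- displacement_lda(label ~ overlap + energy, d)
#' predict(fit, data.frame(overlap = 50, energy = 8.5))
#' @export
displacement_lda <- function(formula, data, priors = c("equal", "proportional"),
                             jitter = 0) {
  priors <- match.arg(priors)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  terms <- attr(mf, "terms")
  x <- stats::model.matrix(terms, mf)
  x <- x[, colnames(x) != "(Intercept)", drop = FALSE]
  fit <- lda_core(x, y, priors = priors, jitter = jitter)
  fit$call <- match.call()
  fit$terms <- terms
  fit$x <- x
  fit$y <- as_activity(y)
  fit$jitter <- jitter
  class(fit) <- "displacement_lda"
  fit
}

#' @export
print.displacement_lda <- function(x, ...) {
  cat("Linear discriminant classifier of displacement activity\n")
  cat("Call: ", deparse(x$call), "\n\n")
  cat("Discriminant weights (score = w'x, active iff score > threshold):\n")
  print(round(x$weights, 6))
  cat(sprintf("Threshold: %.6g (%s priors)\n", x$threshold, x$priors))
  invisible(x)
}

#' @export
coef.displacement_lda <- function(object, ...) object$weights

#' Predict displacement activity
#'
#' @param object A fitted [displacement_lda()] model.
#' @param newdata Data frame of predictors (defaults to the training data).
#' @param type `"class"` for labels, `"score"` for the discriminant
#'   projection `w'x` (useful for plotting the classifier axis).
#' @param ... Unused.
#' @return Character labels or numeric scores.
#' @export
predict.displacement_lda <- function(object, newdata = NULL,
                                     type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$x else {
    tt <- stats::delete.response(object$terms)
    m <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
    m[, colnames(m) != "(Intercept)", drop = FALSE]
  }
  if (type == "score") lda_score(object, x) else lda_label(object, x)
}

#' @export
summary.displacement_lda <- function(object, ...) {
  pred <- lda_label(object, object$x)
  acc <- classification_accuracy(pred, as.character(object$y))
  out <- list(fit = object, resubstitution_accuracy = acc,
              confusion = table(truth = object$y,
                                predicted = factor(pred, ACTIVITY_LEVELS)))
  class(out) <- "summary.displacement_lda"
  out
}

#' @export
print.summary.displacement_lda <- function(x, ...) {
  print(x$fit)
  cat("\nClass means:\n")
  print(round(x$fit$class_means, 4))
  cat("\nPooled within-class covariance:\n")
  print(round(x$fit$pooled_covariance, 4))
  cat(sprintf("\nResubstitution accuracy: %.1f%%\n",
              x$resubstitution_accuracy))
  print(x$confusion)
  invisible(x)
}

#' Scatter plot of a two-feature discriminant model
#'
#' Training cases in the feature plane, colored by class, with the decision
#' line `w'x = threshold` overlaid.
#'
#' @param x A fitted [displacement_lda()] on exactly two features.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.displacement_lda <- function(x, ...) {
  if (ncol(x$x) != 2L)
    stop("plot method requires exactly two features")
  cols <- ifelse(x$y == "active", "#D55E00", "#0072B2")
  graphics::plot(x$x[, 1L], x$x[, 2L], col = cols, pch = 19,
                 xlab = colnames(x$x)[1L], ylab = colnames(x$x)[2L], ...)
  w <- x$weights
  if (abs(w[2L]) > abs(w[1L]) * 1e-12) {
    graphics::abline(a = x$threshold / w[2L], b = -w[1L] / w[2L], lty = 2)
  } else {
    graphics::abline(v = x$threshold / w[1L], lty = 2)
  }
  graphics::legend("topleft", legend = ACTIVITY_LEVELS[2:1], col =
                     c("#D55E00", "#0072B2"), pch = 19, bty = "n")
  invisible(x)
}

#' Classification accuracy in percent
#'
#' `100 * matches / n`, rounded to one decimal (so 18 of 19 correct reports
#' 94.7).
#'
#' @param predictions,truth Equal-length label vectors.
#' @return Accuracy percent, one decimal.
#' @export
classification_accuracy <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    stop("predictions and truth must have equal length")
  if (!length(truth)) stop("need at least one case")
  round(100 * mean(as.character(predictions) == as.character(truth)), 1)
}

#' Exhaustive leave-one-out (jackknife) accuracy
#'
#' For each case, the discriminant is refit on the remaining n - 1 cases and
#' the held-out case is predicted; accuracy is the percentage of held-out
#' cases predicted correctly, to one decimal.  Errors out if any fold would
#' lose a class entirely.
#'
#' @param x Either a fitted [displacement_lda()] (jackknifed on its training
#'   data) or a numeric feature matrix / data frame.
#' @param labels Class labels (`"active"`/`"inactive"`), required when `x`
#'   is a matrix.
#' @param priors,jitter As in [displacement_lda()].
#' @param ids Optional case identifiers for the per-case table.
#' @return A list with `accuracy` (percent, one decimal), `predictions`
#'   (per-case data.frame with `id`, `truth`, `predicted`, `correct`) and
#'   `misclassified` (ids of the errors).
#' @export
loo_accuracy <- function(x, labels = NULL, priors = "equal", jitter = 0,
                         ids = NULL) {
  if (inherits(x, "displacement_lda")) {
    labels <- as.character(x$y)
    priors <- x$priors
    jitter <- x$jitter
    x <- x$x
  }
  x <- as.matrix(x)
  if (is.null(labels)) stop("'labels' required for a feature matrix")
  labels <- as.character(labels)
  n <- nrow(x)
  if (length(labels) != n) stop("labels length must match feature rows")
  if (is.null(ids)) ids <- rownames(x) %||chr% as.character(seq_len(n))
  pred <- character(n)
  for (i in seq_len(n)) {
    yi <- labels[-i]
    if (length(unique(yi)) < 2L)
      stop("leaving out case ", ids[i], " removes a class entirely")
    fit <- lda_core(x[-i, , drop = FALSE], yi, priors = priors,
                    jitter = jitter)
    pred[i] <- lda_label(fit, x[i, , drop = FALSE])
  }
  correct <- pred == labels
  list(accuracy = round(100 * mean(correct), 1),
       predictions = data.frame(id = ids, truth = labels, predicted = pred,
                                correct = correct, row.names = NULL,
                                stringsAsFactors = FALSE),
       misclassified = ids[!correct])
}

`%||chr%` <- function(a, b) if (is.null(a)) b else a
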