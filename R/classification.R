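#' Sigmoid function
#'
#' `g(z) = 1 / (1 + exp(-z))`.
#'
#' @param z numeric vector.
#' @return values in (0, 1); `g(0) = 0.5` exactly.
#' @export
sigmoid <- function(z) 1 / (1 + exp(-z))

#' Fit a univariate logistic model on the R-parameter
#'
#' Unregularized maximum likelihood for `P(positive | R) = g(slope * R +
#' intercept)`, the positive class meaning "mature typically-developed"
#' (high-R region). The negative log-likelihood is minimized by BFGS with the
#' analytic gradient, then polished with damped Newton steps until the
#' gradient norm drops below `1e-8`. Perfectly separable data drive the
#' coefficients to infinity; this is detected (coefficient blow-up with a
#' still-improvable likelihood) and reported via a `speakr_separation`
#' warning while the (finite, large) coefficients are returned.
#'
#' @param r_values numeric vector of R values (finite).
#' @param labels logical/0-1 vector, `TRUE` = positive class.
#' @param positive_class label text for the positive class.
#' @return an object of class `speakr_logistic`: `slope` (per frame),
#'   `intercept`, `converged`, `separation`, `gradient_norm`,
#'   `log_likelihood`, `positive_class`.
#' @export
fit_logistic <- function(r_values, labels, positive_class = "mature TD") {
  y <- as.integer(as.logical(labels))
  if (any(!is.finite(r_values))) stopf("r_values must be finite")
  if (length(y) != length(r_values)) stopf("r_values and labels lengths differ")
  if (length(unique(y)) < 2L) stopf("both classes must be present to fit")
  X <- cbind(1, r_values)
  nll <- function(b) {
    z <- drop(X %*% b)
    sum(log1p(exp(-abs(z))) + pmax(z, 0) - y * z)  # stable -loglik
  }
  grad <- function(b) drop(crossprod(X, sigmoid(drop(X %*% b)) - y))
  b <- c(0, 0)
  opt <- stats::optim(b, nll, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  b <- opt$par
  # in one dimension perfect separation is decidable exactly: the classes
  # occupy disjoint half-lines, so the likelihood has no finite maximizer
  separation <- max(r_values[y == 0]) < min(r_values[y == 1]) ||
    max(r_values[y == 1]) < min(r_values[y == 0])
  for (it in 1:100) {                       # Newton polish to gradient norm 1e-8
    g <- grad(b)
    if (sqrt(sum(g^2)) < 1e-8) break
    p <- sigmoid(drop(X %*% b))
    w <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    # dampen: halve until the NLL does not increase
    f0 <- nll(b); s <- 1
    while (nll(b - s * step) > f0 && s > 1e-8) s <- s / 2
    b <- b - s * step
    if (max(abs(b)) > 1e4) { separation <- TRUE; break }
  }
  gn <- sqrt(sum(grad(b)^2))
  if (separation) {
    warning(structure(class = c("speakr_separation", "warning", "condition"),
                      list(message = "perfect separation: coefficients diverge",
                           call = sys.call(-1))))
  }
  structure(list(slope = unname(b[2]), intercept = unname(b[1]),
                 converged = gn < 1e-8, separation = separation,
                 gradient_norm = gn, log_likelihood = -nll(b),
                 positive_class = positive_class),
            class = "speakr_logistic")
}

#' @export
print.speakr_logistic <- function(x, ...) {
  cat(sprintf("<speakr_logistic> H(R) = g(%.4g R %+.4g); boundary R* = %.4g frames%s\n",
              x$slope, x$intercept,
              if (x$slope != 0) -x$intercept / x$slope else NA,
              if (x$separation) " [perfect separation]" else ""))
  invisible(x)
}

#' Predict class membership probability from R
#'
#' @param object a `speakr_logistic` model.
#' @param r_values numeric vector of R values.
#' @param type `"response"` for probabilities, `"class"` for labels
#'   (probability >= 0.5 is positive).
#' @param ... unused.
#' @return probabilities in (0, 1) or a logical label vector.
#' @export
predict.speakr_logistic <- function(object, r_values, type = c("response", "class"), ...) {
  type <- match.arg(type)
  p <- sigmoid(object$slope * r_values + object$intercept)
  if (type == "response") p else p >= 0.5
}

#' Decision boundary in R-space
#'
#' The R value where the fitted probability crosses 0.5:
#' `R* = -intercept / slope`, in frames.
#'
#' @param model a `speakr_logistic`.
#' @return R* in frames.
#' @export
decision_boundary <- function(model) {
  if (model$slope == 0) stopf("decision boundary undefined: slope is zero")
  -model$intercept / model$slope
}

#' 70/30 split evaluation protocol
#'
#' Repeatedly draws a random `train_frac` training subset (redrawn, up to 100
#' times per iteration, until both classes are present in it), fits the
#' logistic model on the training part, and records classification accuracy
#' (fraction of samples whose predicted label at threshold 0.5 is correct) on
#' both parts. Deterministic given `seed`.
#'
#' @param r_values numeric vector of R values.
#' @param labels logical/0-1 vector.
#' @param train_frac training fraction (default 0.7).
#' @param iters number of random splits (default 50).
#' @param seed integer seed.
#' @return list with `mean_train_accuracy`, `mean_test_accuracy`, and a
#'   per-iteration data frame `iterations`.
#' @export
split_evaluate <- function(r_values, labels, train_frac = 0.7, iters = 50, seed = 1) {
  y <- as.logical(labels)
  n <- length(y)
  n_train <- round(train_frac * n)
  if (n_train < 2L || n_train >= n) stopf("train_frac leaves no usable split")
  with_local_seed(seed, function() {
    res <- lapply(seq_len(iters), function(it) {
      for (try in 1:100) {
        idx <- sample.int(n, n_train)
        if (length(unique(y[idx])) == 2L) break
        if (try == 100) stopf("could not draw a training set containing both classes")
      }
      m <- suppressWarnings(fit_logistic(r_values[idx], y[idx]))
      acc <- function(ii) mean(predict(m, r_values[ii], type = "class") == y[ii])
      data.frame(iteration = it, train_accuracy = acc(idx), test_accuracy = acc(-idx))
    })
    tab <- do.call(rbind, res)
    list(mean_train_accuracy = mean(tab$train_accuracy),
         mean_test_accuracy = mean(tab$test_accuracy),
         iterations = tab)
  })
}
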