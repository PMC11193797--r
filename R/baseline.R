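#' Baseline logistic regression with separation fallback
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()] with deviance
#' tolerance 1e-8).  Collinear columns are dropped with a warning.  When the
#' fit shows signs of complete or quasi-complete separation (non-convergence
#' or exploding coefficients -- a practical certainty with 23 regional
#' observations), a lightly ridge-penalised IRLS (lambda = 1e-6) is used
#' instead and the result flagged.
#'
#' @param formula model formula with a binary response.
#' @param data data frame.
#' @param ridge penalty used by the separation fallback.
#' @return object of class `"baseline_logit"`: coefficients, covariance,
#'   fitted probabilities, the model frame, and a `separation` flag.
#' @export
baseline_logit <- function(formula, data, ridge = 1e-6) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    warning("dropping collinear column(s): ",
            paste(colnames(X)[-keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = glm.control(epsilon = 1e-8, maxit = 100)))
  sep <- !fit$converged || any(abs(fit$coefficients) > 15) ||
    any(fit$fitted.values > 1 - 1e-10 & y == 1) &&
    all(round(fit$fitted.values) == y)
  if (sep) {
    rf <- ridge_logit(X, y, lambda = ridge)
    beta <- rf$beta; V <- rf$vcov; p <- rf$fitted
  } else {
    beta <- fit$coefficients
    W <- fit$weights
    V <- solve(crossprod(X, X * W))
    p <- fit$fitted.values
  }
  structure(list(coefficients = beta, vcov = V, fitted = p,
                 X = X, y = y, data = data, formula = formula,
                 separation = sep, deviance = -2 * sum(y * log(pmax(p, 1e-12)) +
                   (1 - y) * log(pmax(1 - p, 1e-12)))),
            class = "baseline_logit")
}

# ridge-penalised IRLS, used only as a separation fallback
ridge_logit <- function(X, y, lambda = 1e-6, maxit = 200, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-12)
    H <- crossprod(X, X * w) + diag(lambda, ncol(X))
    g <- crossprod(X, y - p) - lambda * beta
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  names(beta) <- colnames(X)
  list(beta = drop(beta), vcov = solve(H), fitted = plogis(drop(X %*% beta)))
}

#' @export
coef.baseline_logit <- function(object, ...) object$coefficients

#' @export
vcov.baseline_logit <- function(object, ...) object$vcov

#' @export
print.baseline_logit <- function(x, ...) {
  cat("Baseline logistic regression",
      if (x$separation) "(ridge fallback: separation detected)" else "", "\n")
  se <- sqrt(diag(x$vcov))
  tab <- cbind(estimate = x$coefficients, se = se,
               odds_ratio = exp(x$coefficients))
  print(round(tab, 4))
  invisible(x)
}

#' @export
predict.baseline_logit <- function(object, newdata = NULL,
                                   type = c("response", "link"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$X else {
    mm <- stats::model.matrix(stats::delete.response(
      stats::terms(object$formula)), newdata)
    mm[, names(object$coefficients), drop = FALSE]
  }
  eta <- drop(X %*% object$coefficients)
  if (type == "response") plogis(eta) else eta
}

#' Average marginal effect of a covariate
#'
#' For a binary covariate: the mean over observations of the discrete change
#' in predicted probability when the covariate moves 0 to 1 (all other
#' covariates held at their observed values).  For a continuous covariate:
#' the mean numerical derivative.  Confidence interval by the delta method
#' with a numerically differentiated gradient, so polynomial terms written
#' as functions of the raw variable are handled exactly.
#'
#' AMEs are computed from one joint model (all covariates entered
#' together); per-variable bivariate fits are the obvious alternative when
#' a purely descriptive profile is wanted.
#'
#' @param fit a [baseline_logit()].
#' @param variable name of a column of the original data.
#' @param level confidence level.
#' @param h step for numerical derivatives of continuous variables.
#' @return one-row data frame: `variable`, `ame`, `se`, `lower`, `upper`.
#' @export
ame <- function(fit, variable, level = 0.95, h = 1e-4) {
  data <- fit$data
  if (!variable %in% names(data)) stop("variable not in model data: ", variable)
  v <- data[[variable]]
  binary <- all(v %in% c(0, 1, NA))
  ame_at <- function(beta) {
    pred <- function(d) {
      X <- stats::model.matrix(stats::delete.response(
        stats::terms(fit$formula)), d)
      mean(plogis(drop(X[, names(beta), drop = FALSE] %*% beta)))
    }
    if (binary) {
      d1 <- data; d1[[variable]] <- 1
      d0 <- data; d0[[variable]] <- 0
      pred(d1) - pred(d0)
    } else {
      dp <- data; dp[[variable]] <- v + h
      dm <- data; dm[[variable]] <- v - h
      (pred(dp) - pred(dm)) / (2 * h)
    }
  }
  est <- ame_at(fit$coefficients)
  # delta method: numerical gradient of the AME in beta
  eps <- 1e-6
  g <- vapply(seq_along(fit$coefficients), function(k) {
    b <- fit$coefficients; b[k] <- b[k] + eps
    (ame_at(b) - est) / eps
  }, numeric(1))
  se <- sqrt(drop(t(g) %*% fit$vcov %*% g))
  zq <- qnorm(1 - (1 - level) / 2)
  data.frame(variable = variable, ame = est, se = se,
             lower = est - zq * se, upper = est + zq * se,
             stringsAsFactors = FALSE)
}

#' Predicted-probability profile over the number of non-residents
#'
#' Averages predicted probabilities with the non-resident count set to each
#' value of `grid` for every observation.  When the model contains a
#' negative quadratic term in the variable, the interior maximiser
#' `-b1 / (2 b2)` of the latent quadratic is reported (the inverted-U
#' summary).
#'
#' @param fit a [baseline_logit()] whose formula contains `variable` (and
#'   typically `I(variable^2)`).
#' @param variable covariate name; default `"n_nonresidents"`.
#' @param grid values to profile over.
#' @return data frame `m`, `prob`, with attribute `maximiser` (NA when the
#'   profile is monotone).
#' @export
nonresident_profile <- function(fit, variable = "n_nonresidents", grid = 0:15) {
  probs <- vapply(grid, function(m) {
    d <- fit$data; d[[variable]] <- m
    mean(predict(fit, d))
  }, numeric(1))
  b <- fit$coefficients
  lin <- b[variable]
  qnames <- c(paste0("I(", variable, "^2)"), paste0(variable, "_sq"))
  quad <- b[intersect(qnames, names(b))]
  maximiser <- if (length(quad) == 1 && !is.na(quad) && quad < 0)
    unname(-lin / (2 * quad)) else NA_real_
  structure(data.frame(m = grid, prob = probs), maximiser = maximiser)
}
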