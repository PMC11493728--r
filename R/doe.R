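## Design-of-experiments factor analysis: response normalisation, model
## matrix expansion, and feature importance by repeated cross-validated
## Lasso regression.

#' Background-correct and min-max normalise selection responses
#'
#' Removes background signal using negative-control reactions — dividing
#' by their mean (gel densitometry convention) or subtracting it and
#' clamping at zero (spectrophotometric convention) — then rescales to the
#' smallest (0%) and largest (100%) yield in the run set.
#'
#' @param raw numeric vector of raw quantifications.
#' @param negatives numeric vector of negative-control quantifications
#'   (required unless `mode = "none"`).
#' @param mode `"none"`, `"divide"` or `"subtract"`.
#' @return Numeric vector on the 0-100 scale.
#' @examples
#' normalizeResponses(c(10, 20, 30))               # 0, 50, 100
#' normalizeResponses(c(3, 5, 15), negatives = 5, mode = "subtract")
#' @export
normalizeResponses <- function(raw, negatives = NULL,
                               mode = c("none", "divide", "subtract")) {
  mode <- match.arg(mode)
  x <- raw
  if (mode != "none") {
    if (is.null(negatives) || length(negatives) == 0L)
      stop("background correction requested without negative controls")
    bg <- mean(negatives)
    if (mode == "divide") {
      if (bg == 0) stop("negative-control mean is zero in divide mode")
      x <- x / bg
    } else {
      x <- pmax(x - bg, 0)
    }
  }
  rng <- range(x)
  if (diff(rng) == 0) stop("responses have zero range")
  100 * (x - rng[1]) / diff(rng)
}

#' Expand a DoE design into a model matrix
#'
#' Continuous factors are standardised to zero mean and unit variance
#' before expansion; categorical factors are one-hot encoded against a
#' declared reference level (the first level by default, e.g. dNTPs for a
#' nucleotide-chemistry factor). `order = "interactions"` adds all
#' pairwise products of the main-effect columns; `order = "quadratic"`
#' additionally adds squares of the continuous factors. Constant columns
#' are dropped with a warning.
#'
#' @param design data frame of factors (numeric columns are continuous;
#'   character/factor columns categorical).
#' @param order `"main"`, `"interactions"` or `"quadratic"`.
#' @return A numeric model matrix (no intercept column).
#' @export
expandDesign <- function(design,
                         order = c("main", "interactions", "quadratic")) {
  order <- match.arg(order)
  stopifnot(is.data.frame(design), nrow(design) > 0)
  if (anyNA(design)) stop("design contains missing cells")

  cols <- list()
  contNames <- character()
  for (nm in names(design)) {
    v <- design[[nm]]
    if (is.numeric(v)) {
      if (sd(v) == 0) {
        warning("dropping constant column: ", nm)
        next
      }
      cols[[nm]] <- (v - mean(v)) / sd(v)
      contNames <- c(contNames, nm)
    } else {
      f <- factor(v)
      if (nlevels(f) < 2L) {
        warning("dropping constant column: ", nm)
        next
      }
      for (lev in levels(f)[-1L]) # first level is the reference
        cols[[paste0(nm, ".", lev)]] <- as.numeric(f == lev)
    }
  }
  if (length(cols) == 0L) stop("no usable factor columns")
  X <- do.call(cbind, cols)

  if (order %in% c("interactions", "quadratic")) {
    main <- colnames(X)
    if (length(main) >= 2L) {
      for (i in seq_len(length(main) - 1L))
        for (j in seq.int(i + 1L, length(main))) {
          X <- cbind(X, X[, main[i]] * X[, main[j]])
          colnames(X)[ncol(X)] <- paste0(main[i], ":", main[j])
        }
    }
  }
  if (order == "quadratic") {
    for (nm in contNames) {
      X <- cbind(X, X[, nm]^2)
      colnames(X)[ncol(X)] <- paste0(nm, "^2")
    }
  }
  X
}

#' Factor importance by repeated cross-validated Lasso
#'
#' Fits a Lasso regression `repeats` times (default 100, enough for
#' stable coefficient scores); each repeat reshuffles the
#' cross-validation fold assignment, picks the regularisation parameter
#' `lambda` at minimum CV error, and records the coefficients. Mean and
#' mean-absolute coefficients over the repeats measure feature
#' importance. Performance metrics (R-squared, MSE, MAE, AIC, BIC) are
#' computed per repeat on the full fit — matching the single-dataset
#' setting of selection campaigns — with the number of nonzero
#' coefficients as the effective degrees of freedom for AIC/BIC (the
#' standard Lasso df estimate); `holdout = TRUE` switches the metrics to
#' the CV held-out predictions instead.
#'
#' A constant response yields all-zero coefficients (and undefined
#' R-squared) rather than an error.
#'
#' @param X numeric model matrix (see [expandDesign()]).
#' @param y numeric response (e.g. from [normalizeResponses()]).
#' @param repeats model iterations (default 100).
#' @param cvFolds cross-validation folds (default 5).
#' @param nlambda size of the log-spaced lambda grid (default 100).
#' @param seed integer seed; the whole procedure is reproducible.
#' @param holdout report metrics on CV held-out predictions (default
#'   FALSE: full-fit metrics).
#' @return A list of class `factorImportance`: `importance` (data frame
#'   `feature`, `meanCoef`, `meanAbsCoef`, sorted by `meanAbsCoef`),
#'   `metrics` (mean and sd of R2, MSE, MAE, AIC, BIC over repeats),
#'   `lambda` (chosen lambda per repeat), `coefficients` (repeats x
#'   features matrix), `repeats`.
#' @export
lassoImportance <- function(X, y, repeats = 100L, cvFolds = 5L,
                            nlambda = 100L, seed = 1L, holdout = FALSE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < cvFolds)
    stop("need at least as many runs as cross-validation folds")
  n <- nrow(X)
  p <- ncol(X)
  set.seed(seed)

  coefMat <- matrix(0, nrow = repeats, ncol = p,
                    dimnames = list(NULL, colnames(X)))
  lambda <- numeric(repeats)
  mets <- matrix(NA_real_, nrow = repeats, ncol = 5,
                 dimnames = list(NULL, c("R2", "MSE", "MAE", "AIC", "BIC")))

  if (var(y) == 0) {
    imp <- data.frame(feature = colnames(X), meanCoef = 0, meanAbsCoef = 0)
    return(structure(list(importance = imp,
                          metrics = data.frame(
                            metric = colnames(mets),
                            mean = c(NA, 0, 0, NA, NA),
                            sd = c(NA, 0, 0, NA, NA)),
                          lambda = rep(NA_real_, repeats),
                          coefficients = coefMat, repeats = repeats),
                     class = "factorImportance"))
  }

  for (r in seq_len(repeats)) {
    foldid <- sample(rep_len(seq_len(cvFolds), n))
    cv <- glmnet::cv.glmnet(X, y, foldid = foldid, nlambda = nlambda,
                            keep = holdout)
    lambda[r] <- cv$lambda.min
    co <- as.numeric(predict(cv$glmnet.fit, type = "coefficients",
                             s = cv$lambda.min))[-1L] # drop intercept
    coefMat[r, ] <- co
    if (holdout) {
      ix <- match(cv$lambda.min, cv$lambda)
      yhat <- cv$fit.preval[, ix]
    } else {
      yhat <- as.numeric(predict(cv$glmnet.fit, newx = X,
                                 s = cv$lambda.min))
    }
    resid <- y - yhat
    mse <- mean(resid^2)
    df <- sum(co != 0)
    mets[r, "R2"] <- 1 - mse / mean((y - mean(y))^2)
    mets[r, "MSE"] <- mse
    mets[r, "MAE"] <- mean(abs(resid))
    # Gaussian log-likelihood information criteria, up to constants
    mets[r, "AIC"] <- n * log(mse) + 2 * df
    mets[r, "BIC"] <- n * log(mse) + log(n) * df
  }

  imp <- data.frame(feature = colnames(X),
                    meanCoef = colMeans(coefMat),
                    meanAbsCoef = colMeans(abs(coefMat)))
  imp <- imp[order(-imp$meanAbsCoef), ]
  rownames(imp) <- NULL
  structure(list(importance = imp,
                 metrics = data.frame(metric = colnames(mets),
                                      mean = colMeans(mets),
                                      sd = apply(mets, 2, sd)),
                 lambda = lambda,
                 coefficients = coefMat,
                 repeats = repeats),
            class = "factorImportance")
}

#' @export
print.factorImportance <- function(x, ...) {
  cat("Repeated cross-validated Lasso importance (",
      x$repeats, " repeats)\n", sep = "")
  print(head(x$importance, 10))
  cat("\nMetrics (mean +/- sd over repeats):\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
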