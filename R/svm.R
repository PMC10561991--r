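# Soft-margin RBF-kernel support vector classification, trained with a
# simplified sequential minimal optimization (SMO) scheme. Written in
# package because no SVM library ships with the target environment; the
# problem sizes here (tens to low hundreds of specimens) are well inside
# what plain-R SMO handles. Multiclass is one-vs-one with majority vote.

rbf_kernel <- function(X1, X2, gamma) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  exp(-gamma * pmax(d2, 0))
}

# binary C-SVC; y in {-1, +1}
smo_binary <- function(K, y, cost, tol = 1e-3, max_passes = 50) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  decision <- function() as.numeric(K %*% (alpha * y)) + b
  quiet <- 0
  sweeps <- 0
  while (quiet < 3 && sweeps < max_passes * 4) {
    sweeps <- sweeps + 1
    changed <- 0
    E <- decision() - y
    for (i in seq_len(n)) {
      Ei <- E[i]
      if ((y[i] * Ei < -tol && alpha[i] < cost) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        j <- which.max(abs(Ei - E[-i]))
        j <- seq_len(n)[-i][j]
        Ej <- E[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj_old - ai_old)
          H <- min(cost, cost + aj_old - ai_old)
        } else {
          L <- max(0, ai_old + aj_old - cost)
          H <- min(cost, ai_old + aj_old)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- aj_old - y[j] * (Ei - Ej) / eta
        aj <- min(H, max(L, aj))
        if (abs(aj - aj_old) < 1e-7) next
        ai <- ai_old + y[i] * y[j] * (aj_old - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
          y[j] * (aj - aj_old) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] -
          y[j] * (aj - aj_old) * K[j, j]
        b <- if (ai > 0 && ai < cost) b1
        else if (aj > 0 && aj < cost) b2
        else (b1 + b2) / 2
        E <- decision() - y
        changed <- changed + 1
      }
    }
    quiet <- if (changed == 0) quiet + 1 else 0
  }
  list(alpha = alpha, b = b)
}

#' Fit an RBF-kernel support vector classifier
#'
#' @param X Numeric matrix, rows = cases.
#' @param y Factor of class labels.
#' @param cost Soft-margin cost C (default 1).
#' @param gamma RBF width; default 1/ncol(X).
#' @return An object of class `behav_svm`.
#' @export
svm_fit <- function(X, y, cost = 1, gamma = 1 / ncol(X)) {
  X <- as.matrix(X)
  y <- factor(y)
  lv <- levels(y)
  if (length(lv) < 2) stop("need at least 2 classes", call. = FALSE)
  K <- rbf_kernel(X, X, gamma)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  fits <- lapply(pairs, function(pr) {
    idx <- which(y %in% pr)
    yy <- ifelse(as.character(y[idx]) == pr[1], 1, -1)
    f <- smo_binary(K[idx, idx, drop = FALSE], yy, cost)
    list(pair = pr, idx = idx, y = yy, alpha = f$alpha, b = f$b)
  })
  structure(list(X = X, levels = lv, gamma = gamma, cost = cost,
                 fits = fits),
            class = "behav_svm")
}

#' @rdname svm_fit
#' @param model A fitted `behav_svm`.
#' @param newX Matrix of cases to classify.
#' @return `svm_predict` returns a factor of predicted labels.
#' @export
svm_predict <- function(model, newX) {
  newX <- as.matrix(newX)
  lv <- model$levels
  votes <- matrix(0, nrow(newX), length(lv), dimnames = list(NULL, lv))
  margin <- matrix(0, nrow(newX), length(lv), dimnames = list(NULL, lv))
  for (f in model$fits) {
    Kn <- rbf_kernel(newX, model$X[f$idx, , drop = FALSE], model$gamma)
    dec <- as.numeric(Kn %*% (f$alpha * f$y)) + f$b
    win <- ifelse(dec >= 0, f$pair[1], f$pair[2])
    for (cl in f$pair) {
      votes[, cl] <- votes[, cl] + (win == cl)
    }
    margin[, f$pair[1]] <- margin[, f$pair[1]] + dec
    margin[, f$pair[2]] <- margin[, f$pair[2]] - dec
  }
  pick <- vapply(seq_len(nrow(newX)), function(i) {
    v <- votes[i, ]
    best <- which(v == max(v))
    if (length(best) > 1) {
      m <- margin[i, best]
      best <- best[which.max(m)]
    }
    lv[best[1]]
  }, character(1))
  factor(pick, levels = lv)
}

#' @export
print.behav_svm <- function(x, ...) {
  nsv <- sum(vapply(x$fits, function(f) sum(f$alpha > 1e-8), numeric(1)))
  cat("<behav_svm>", length(x$levels), "classes,", length(x$fits),
      "pairwise machines,", nsv, "support vectors\n")
  invisible(x)
}
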