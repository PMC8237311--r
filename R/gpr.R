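# Gaussian process regression with a small registry of named kernels.
# Closed-form solve: alpha = (K + sigma2 I)^-1 y via Cholesky; predictions
# are k(X*, X) alpha. Inputs are assumed autoscaled, so unit signal
# variance and modest noise levels are sensible defaults.

#' Names of the registered GPR kernels
#'
#' Eleven kernels: five base forms (linear, squared-exponential/RBF,
#' Matérn 3/2, Matérn 5/2, rational quadratic), each also available with an
#' added white-noise component, plus a linear + RBF sum.
#'
#' @return Character vector of 11 kernel names.
#' @export
gpr_kernels <- function() c(
  "linear", "rbf", "matern32", "matern52", "rq",
  "linear_white", "rbf_white", "matern32_white", "matern52_white", "rq_white",
  "linear_rbf"
)

# Pairwise Euclidean distances between rows of A and B.
cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# Kernel matrix k(A, B). `white` contributions only enter on the training
# diagonal and are handled by the caller.
kernel_matrix <- function(name, A, B, lengthscale) {
  base <- sub("_white$", "", name)
  if (base == "linear") return(tcrossprod(A, B))
  if (base == "linear_rbf")
    return(tcrossprod(A, B) + kernel_matrix("rbf", A, B, lengthscale))
  D <- cross_dist(A, B)
  switch(base,
    rbf = exp(-D^2 / (2 * lengthscale^2)),
    matern32 = { a <- sqrt(3) * D / lengthscale; (1 + a) * exp(-a) },
    matern52 = { a <- sqrt(5) * D / lengthscale
                 (1 + a + a^2 / 3) * exp(-a) },
    rq = (1 + D^2 / (2 * lengthscale^2))^(-1), # alpha = 1
    abort_("unknown GPR kernel: ", name)
  )
}

median_lengthscale <- function(X) {
  n <- nrow(X)
  idx <- if (n > 200) round(seq(1, n, length.out = 200)) else seq_len(n)
  d <- dist(X[idx, , drop = FALSE])
  m <- median(d[d > 0])
  if (!is.finite(m) || m == 0) 1 else m
}

# Fit: returns a closure-free model object.
gpr_fit <- function(X, y, kernel, lengthscale = 1, noise = 0.1) {
  K <- kernel_matrix(kernel, X, X, lengthscale)
  if (grepl("_white$", kernel)) diag(K) <- diag(K) + 0.1
  diag(K) <- diag(K) + noise + 1e-8
  mu <- mean(y)
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y - mu))
  list(X = X, alpha = alpha, mu = mu, kernel = kernel,
       lengthscale = lengthscale)
}

gpr_predict <- function(model, Xnew) {
  Ks <- kernel_matrix(model$kernel, Xnew, model$X, model$lengthscale)
  drop(Ks %*% model$alpha) + model$mu
}
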