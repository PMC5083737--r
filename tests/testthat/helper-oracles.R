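# Fixture builders and independent oracles shared across test files.

# rasterized ellipse mask (a = row semi-axis, b = col semi-axis)
ellipse_mask <- function(a, b, margin = 3) {
  nr <- ceiling(2 * a) + 2 * margin
  nc <- ceiling(2 * b) + 2 * margin
  cr <- (nr + 1) / 2
  cc <- (nc + 1) / 2
  outer(seq_len(nr), seq_len(nc),
        function(i, j) ((i - cr) / a)^2 + ((j - cc) / b)^2 <= 1)
}

disk_mask <- function(r, margin = 3) ellipse_mask(r, r, margin)

uniform_nucleus <- function(mask, intensity = 100) {
  px <- matrix(intensity, nrow(mask), ncol(mask))
  px[!mask] <- 250
  nucleus_image(px, mask)
}

# continuous form factor of an ellipse via Ramanujan's perimeter
ramanujan_ff <- function(axis_ratio) {
  a <- axis_ratio; b <- 1
  h <- ((a - b) / (a + b))^2
  P <- pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  P^2 / (4 * pi * pi * a * b)
}

# naive cell-walking run enumerator, independent of the rle-based extractor
naive_glrlm <- function(q, mask, dir, G, jmax = max(dim(q))) {
  dv <- switch(as.character(dir),
               "0" = c(0L, 1L), "90" = c(1L, 0L),
               "45" = c(-1L, 1L), "135" = c(1L, 1L))
  nr <- nrow(q); nc <- ncol(q)
  inm <- function(i, j) i >= 1 && i <= nr && j >= 1 && j <= nc && mask[i, j]
  counts <- matrix(0, G, jmax)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    pi_ <- i - dv[1]; pj <- j - dv[2]
    if (inm(pi_, pj) && q[pi_, pj] == q[i, j]) next  # not a run start
    len <- 1L; ci <- i + dv[1]; cj <- j + dv[2]
    while (inm(ci, cj) && q[ci, cj] == q[i, j]) {
      len <- len + 1L; ci <- ci + dv[1]; cj <- cj + dv[2]
    }
    counts[q[i, j], len] <- counts[q[i, j], len] + 1
  }
  counts
}

# quantization identical to the extractor's contract (equal-width over 0..255)
quantize_bins <- function(px, mask, G) {
  q <- matrix(0L, nrow(px), ncol(px))
  q[mask] <- pmin(floor(px[mask] * G / 256), G - 1) + 1L
  q
}

# brute-force unpenalized multinomial MLE (symmetric parameterization)
brute_force_mle_deviance <- function(X, y) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  n <- nrow(X); p <- ncol(X); K <- nlevels(y)
  nll <- function(par) {
    B <- matrix(par[seq_len(p * K)], p, K)
    b0 <- par[p * K + seq_len(K)]
    S <- X %*% B + rep(b0, each = n)
    S <- S - apply(S, 1, max)
    P <- exp(S) / rowSums(exp(S))
    -mean(log(pmax(P[cbind(seq_len(n), as.integer(y))], 1e-300)))
  }
  o <- stats::optim(rep(0, p * K + K), nll, method = "BFGS",
                    control = list(maxit = 10000, reltol = 1e-14))
  2 * o$value
}

# exhaustive concordant-pair AUC
pairwise_auc <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

# random points on the 3-class probability simplex
random_simplex <- function(n) {
  m <- matrix(stats::rexp(3 * n), n, 3)
  m / rowSums(m)
}

# small non-separable labeled fixture for solver tests
overlap_fixture <- function(n = 12, p = 2, seed = 42,
                            classes = c("CP", "IPMN", "PC")) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("f%d", seq_len(p))))
    y <- factor(rep_len(classes, n))
    shift <- rnorm(length(classes), 0, 0.5)
    X[, 1] <- X[, 1] + shift[as.integer(y)]
    list(X = X, y = y)
  })
}

# widely separated three-class cohort (separable by construction)
separated_params <- function(gap = 30) {
  tab <- informative_defaults()
  tab$mean <- tab$mean + gap * tab$sd * (as.integer(factor(
    tab$class, levels = karyo_classes())) - 1)
  tab
}
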