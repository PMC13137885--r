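# shared fixtures and independent oracles for the test suite

# tiny atlas: 3 language, 3 dmn, 4 md ROIs
toy_atlas <- function() {
  validate_atlas(tibble::tibble(
    roi_id = c(paste0("lang", 1:3), paste0("dmn", 1:3), paste0("md", 1:4)),
    network = c(rep("language", 3), rep("dmn", 3), rep("md", 4)),
    hemisphere = c(rep("L", 3), c("L", "R", "L"), rep(c("L", "R"), 2)),
    x = seq(-50, 40, length.out = 10), y = 0, z = 0
  ))
}

# random rectified z-scale connectivity object over an atlas
random_connectivity <- function(atlas, seed = 1) {
  set.seed(seed)
  r <- nrow(atlas)
  m <- matrix(runif(r * r, 0, 0.8), r, r)
  m <- (m + t(m)) / 2
  diag(m) <- NA_real_
  dimnames(m) <- list(atlas$roi_id, atlas$roi_id)
  rectify_negatives(segspeech:::new_connectivity(m, scale = "z", rectified = FALSE))
}

# brute-force within-network mean over unique pairs
loop_within <- function(cm, atlas, network) {
  rois <- atlas$roi_id[atlas$network == network]
  total <- 0
  k <- 0
  for (i in seq_along(rois)) {
    for (j in seq_along(rois)) {
      if (j <= i) next
      total <- total + cm$values[rois[i], rois[j]]
      k <- k + 1
    }
  }
  total / k
}

# brute-force between-network mean over all cross edges
loop_between <- function(cm, atlas, net_a, net_b) {
  a <- atlas$roi_id[atlas$network == net_a]
  b <- atlas$roi_id[atlas$network == net_b]
  total <- 0
  for (i in a) for (j in b) total <- total + cm$values[i, j]
  total / (length(a) * length(b))
}

# step-up BH evaluated directly from the definition:
# q_(i) = min_{j >= i} m * p_(j) / j
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(pmin(1, m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Cook's distance from explicit leave-one-out refits:
# D_i = (b - b_(i))' X'X (b - b_(i)) / (p * s^2)
loo_cooks <- function(X, y) {
  n <- nrow(X)
  p <- ncol(X)
  b <- solve(crossprod(X), crossprod(X, y))
  s2 <- sum((y - X %*% b)^2) / (n - p)
  vapply(seq_len(n), function(i) {
    bi <- solve(crossprod(X[-i, , drop = FALSE]),
                crossprod(X[-i, , drop = FALSE], y[-i]))
    d <- b - bi
    as.numeric(t(d) %*% crossprod(X) %*% d) / (p * s2)
  }, numeric(1))
}

# moore-penrose OLS oracle
pinv_coefs <- function(X, y) as.numeric(MASS::ginv(X) %*% y)

# small fast cohort for model-shape tests
small_cohort <- function(n = 60, seed = 1, mode = "direct") {
  simulate_cohort(generator_params(n_participants = n), mode = mode, seed = seed)
}
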