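test_that("pearson weight reproduces the standardized cross-product formula", {
  expect_equal(pearson_weight(1:4, 1:4), 1)
  expect_equal(pearson_weight(1:4, 4:1), -1)

  ## independent closed-form evaluation for an asymmetric pair
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 100)
  expected <- sum((x - mean(x)) / sd(x) * (y - mean(y)) / sd(y)) / 3
  expect_equal(pearson_weight(x, y), expected)

  expect_true(is.na(pearson_weight(c(2, 2, 2), c(1, 2, 3))))
  expect_error(pearson_weight(1:2, 1:2), "n >= 3")
})

test_that("pearson weight recovers the generating correlation on Gaussian pairs", {
  set.seed(101)
  for (rho in c(-0.8, 0, 0.6)) {
    n <- 400
    z <- rnorm(n)
    x <- sqrt(abs(rho)) * z * sign(rho) + sqrt(1 - abs(rho)) * rnorm(n)
    y <- sqrt(abs(rho)) * z + sqrt(1 - abs(rho)) * rnorm(n)
    expect_lt(abs(pearson_weight(x, y) - rho), 3 / sqrt(n))
  }
})

test_that("mutual information is symmetric, bounded by the marginal entropies, and exact on known tables", {
  ## independent pair: joint factorizes exactly
  expect_equal(mi_weight(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)

  ## complement is a deterministic bijection: MI = H
  set.seed(5)
  for (rep in 1:20) {
    bx <- rbinom(12, 1, 0.5)
    if (length(unique(bx)) < 2) next
    expect_equal(mi_weight(bx, 1L - bx), entropy_oracle(bx), tolerance = 1e-12)
  }

  ## symmetry and entropy bound on random pairs
  for (rep in 1:200) {
    a <- rbinom(10, 1, runif(1)); b <- rbinom(10, 1, runif(1))
    expect_equal(mi_weight(a, b), mi_weight(b, a))
    expect_gte(mi_weight(a, b), 0)
    expect_lte(mi_weight(a, b),
               min(entropy_oracle(a), entropy_oracle(b)) + 1e-12)
  }

  ## alternate logarithm base rescales by a constant
  a <- c(1, 1, 0, 0, 1, 0); b <- c(1, 0, 0, 0, 1, 1)
  expect_equal(mi_weight(a, b, base = exp(1)),
               mi_weight(a, b, base = 2) * log(2))
})

test_that("permutation destroys most of the coupling information", {
  set.seed(23)
  n <- 60
  bx <- rbinom(n, 1, 0.5)
  by <- ifelse(runif(n) < 0.9, bx, 1L - bx)   # strongly coupled
  coupled <- mi_weight(bx, by)
  perm_mi <- replicate(200, mi_weight(bx, by[sample(n)]))
  expect_gt(mean(perm_mi), 0)                  # small positive plug-in bias
  expect_lt(mean(perm_mi), coupled)
})

test_that("edge weights match independent per-pair recomputation", {
  g <- pathway_graph("w3", genes = c("A", "B", "C"),
                     edges = data.frame(source = c("A", "B", "A"),
                                        target = c("B", "C", "C"),
                                        beta = c(1L, -1L, 1L)))
  set.seed(31)
  vals <- matrix(rnorm(30), 3, 10, dimnames = list(c("A", "B", "C"), NULL))
  d <- tiny_dataset(vals, 5, 5)

  wp <- edge_weights(g, d, method = "pearson")
  for (k in 1:3)
    expect_equal(wp$weights$weight[k],
                 pearson_weight(vals[wp$weights$source[k], ],
                                vals[wp$weights$target[k], ]))

  wm <- edge_weights(g, d, method = "mi")
  b <- binarize(d)
  for (k in 1:3)
    expect_equal(wm$weights$weight[k],
                 mi_weight(b[wm$weights$source[k], ],
                           b[wm$weights$target[k], ]))

  ## unit method ignores the data entirely
  wu <- edge_weights(g, data = NULL, method = "unit")
  expect_equal(wu$weights$weight, rep(1, 3))

  ## abs_weights drops the sign only
  wpa <- edge_weights(g, d, method = "pearson", abs_weights = TRUE)
  expect_equal(wpa$weights$weight, abs(wp$weights$weight))
})

test_that("edge weight fallbacks: duplicated rows, missing genes, zero variance", {
  g <- pathway_graph("fb", genes = c("A", "B", "C"),
                     edges = data.frame(source = c("A", "B"),
                                        target = c("B", "C"),
                                        beta = c(1L, 1L)))
  vals <- rbind(A = c(1, 2, 3, 4, 5, 6),
                B = c(1, 2, 3, 4, 5, 6),     # duplicate of A -> weight 1
                C = rep(4, 6))                # zero variance
  d <- tiny_dataset(vals, 3, 3)
  expect_warning(w <- edge_weights(g, d, method = "pearson"),
                 "zero-variance")
  expect_equal(w$weights$weight, c(1, 1))
  expect_equal(w$report$zero_variance_edges, 1L)

  ## gene absent from the expression data -> weight 1, reported
  g2 <- pathway_graph("mg", edges = data.frame(source = "A", target = "ZZZ",
                                               beta = 1L))
  expect_message(w2 <- edge_weights(g2, d, method = "pearson"), "absent")
  expect_equal(w2$weights$weight, 1)
  expect_equal(w2$report$missing_gene_edges, 1L)
})

test_that("weight computation can be restricted to one condition", {
  set.seed(77)
  ## correlated in control samples only
  n <- 12
  z <- rnorm(n / 2)
  vals <- rbind(A = c(z, rnorm(n / 2)),
                B = c(z + rnorm(n / 2, sd = 0.1), rnorm(n / 2)))
  g <- pathway_graph("cs", edges = data.frame(source = "A", target = "B",
                                              beta = 1L))
  d <- tiny_dataset(vals, n / 2, n / 2)
  w_ctrl <- edge_weights(g, d, method = "pearson", weight_samples = "control")
  w_test <- edge_weights(g, d, method = "pearson", weight_samples = "test")
  expect_gt(w_ctrl$weights$weight, 0.9)
  expect_lt(abs(w_test$weights$weight), 0.9)
})
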