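test_that("perturbation factors solve the propagation fixed point on hand examples", {
  ## isolated gene: no upstream term
  iso <- pathway_graph("iso", genes = "A")
  r <- perturbation_factors(iso, edge_weights(iso, method = "unit"),
                            c(A = 2))
  expect_equal(unname(r$pf), 2)
  expect_equal(r$t_a, 0)

  ## two-gene chain, unit weight: downstream gene inherits the full change
  ch <- chain_graph(2)
  d <- c(g1 = 1, g2 = 0)
  r1 <- perturbation_factors(ch, manual_weights(ch, 1), d)
  expect_equal(unname(r1$pf), c(1, 1))
  expect_equal(unname(r1$acc), c(0, 1))
  expect_equal(r1$t_a, 1)

  ## halved interaction strength halves the propagated part
  r2 <- perturbation_factors(ch, manual_weights(ch, 0.5), d)
  expect_equal(unname(r2$pf), c(1, 0.5))
  expect_equal(r2$t_a, 0.5)

  ## inhibitory edge flips the propagated sign
  ch_inh <- chain_graph(2, betas = -1L)
  r3 <- perturbation_factors(ch_inh, manual_weights(ch_inh, 1), d)
  expect_equal(unname(r3$pf), c(1, -1))
  expect_equal(r3$t_a, -1)
})

test_that("the direct linear solve satisfies the fixed-point equation", {
  set.seed(19)
  g <- random_dag(8)
  w <- manual_weights(g, runif(nrow(g$edges), -1, 1))
  delta <- setNames(rnorm(8), g$genes)
  r <- perturbation_factors(g, w, delta)
  ## pf = delta + M pf must hold to solver tolerance
  M <- wspia:::.propagation_matrix(g, w)
  expect_lt(max(abs(r$pf - (delta[g$genes] + drop(M %*% r$pf)))), 1e-8)
  expect_equal(r$t_a, sum(r$acc), tolerance = 1e-10)
})

test_that("a perfectly reinforcing feedback loop is reported singular", {
  loop <- pathway_graph("loop2", edges = data.frame(
    source = c("A", "B"), target = c("B", "A"), beta = c(1L, 1L)))
  r <- perturbation_factors(loop, manual_weights(loop, c(1, 1)),
                            c(A = 1, B = 0))
  expect_equal(r$solver_status, "singular")
  expect_true(is.na(r$t_a))

  ## damped loop (weight < 1) is solvable
  r2 <- perturbation_factors(loop, manual_weights(loop, c(0.5, 0.5)),
                             c(A = 1, B = 0))
  expect_equal(r2$solver_status, "solved")
})

test_that("hypergeometric over-representation matches closed-form cases and rejects bad bounds", {
  expect_equal(p_nde_hypergeometric(10, 5, 4, 0), 1)
  expect_equal(p_nde_hypergeometric(10, 5, 4, 4), 5 / 210)
  expect_equal(p_nde_hypergeometric(10, 5, 4, 2), hyper_enum_oracle(10, 5, 4, 2))
  expect_error(p_nde_hypergeometric(10, 11, 4, 2), "invalid")
  expect_error(p_nde_hypergeometric(10, 5, 4, 5), "invalid")
})

test_that("evidence combination follows the product-tail law", {
  expect_equal(combine_pg(1, 1), 1)
  expect_equal(combine_pg(0.1, 0.1), 0.01 * (1 + log(100)))
  expect_error(combine_pg(0, 0.5), "\\(0, 1\\]")
})

test_that("FDR adjustment reproduces hand-computed step-up values", {
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(rep(0.07, 4)), rep(0.07, 4))
  expect_equal(fdr_adjust(c(0.01, 0.04), method = "bonferroni"),
               c(0.02, 0.08))
})

test_that("bootstrap p-value is exact on degenerate nulls", {
  ## edgeless pathway: no propagation, every null t_a = 0, p = 1
  flat <- pathway_graph("flat", genes = c("A", "B", "C"))
  b <- p_pert_bootstrap(flat, edge_weights(flat, method = "unit"),
                        c(A = 1.5), n_de = 1, delta_e_pool = c(1.5),
                        iterations = 100, seed = 4)
  expect_equal(b$p_pert, 1)
  expect_equal(b$t_a_observed, 0)

  ## chain with the DE gene at an interior position: all placements are
  ## at least as extreme, so p is exactly 1 at any iteration count
  ch <- chain_graph(4)
  w <- manual_weights(ch, rep(1, 3))
  b1 <- p_pert_bootstrap(ch, w, c(g2 = 1), n_de = 1, delta_e_pool = 1,
                         iterations = 500, seed = 9)
  b2 <- p_pert_bootstrap(ch, w, c(g2 = 1), n_de = 1, delta_e_pool = 1,
                         iterations = 1000, seed = 9)
  expect_equal(b1$p_pert, 1)
  expect_lt(abs(b2$p_pert - b1$p_pert), 2 / 500)
  expect_error(p_pert_bootstrap(ch, w, c(g1 = 1), n_de = 5,
                                delta_e_pool = rep(1, 5), iterations = 10),
               "exceeds")
})

test_that("analysed pathways carry consistent probabilities and ordering", {
  spec <- fixture_spec(n_genes = 80, n_pathways = 3, genes_per_pathway = 10,
                       edge_density = 0.25, seed = 21)
  pw <- make_pathways(spec)
  fx <- make_expression(spec, pw, perturbed_pathway_index = 2)
  res <- run_analysis(fx$data, pw, method = "spia", iterations = 300,
                      seed = 3)
  expect_s3_class(res, "pathway_result")
  expect_equal(nrow(res), 3L)
  ok <- res[res$status == "ok", ]
  expect_true(all(ok$p_nde >= 0 & ok$p_nde <= 1))
  expect_true(all(ok$p_pert > 0 & ok$p_pert <= 1))
  expect_equal(ok$p_g, combine_pg(ok$p_nde, ok$p_pert), tolerance = 1e-12)
  expect_false(is.unsorted(ok$p_g))
  ## the coherently perturbed pathway wins
  expect_equal(res$pathway_id[1], "pw02")

  ## zero DEGs overall: everything skipped
  res0 <- run_analysis(fx$data, pw, method = "spia", alpha = 0,
                       iterations = 50, seed = 3)
  expect_true(all(res0$status == "skipped_no_de"))
  expect_true(all(is.na(res0$p_g)))
})

test_that("per-pathway seeding makes results independent of the pathway set", {
  spec <- fixture_spec(n_genes = 90, n_pathways = 3, genes_per_pathway = 10,
                       edge_density = 0.3, seed = 55)
  pw <- make_pathways(spec)
  fx <- make_expression(spec, pw, perturbed_pathway_index = 1)
  full <- run_analysis(fx$data, pw, method = "spia", iterations = 200, seed = 8)
  part <- run_analysis(fx$data, pw[1:2], method = "spia", iterations = 200,
                       seed = 8)
  for (id in c("pw01", "pw02"))
    expect_equal(full[full$pathway_id == id, c("t_a", "p_nde", "p_pert")],
                 part[part$pathway_id == id, c("t_a", "p_nde", "p_pert")],
                 ignore_attr = TRUE)
})

test_that("a cyclic unsolvable pathway is reported skipped, not dropped", {
  loop <- pathway_graph("loop2", edges = data.frame(
    source = c("A", "B"), target = c("B", "A"), beta = c(1L, 1L)))
  set.seed(2)
  vals <- matrix(rnorm(40), 4, 10,
                 dimnames = list(c("A", "B", "C", "D"), NULL))
  vals[1:2, 6:10] <- vals[1:2, 6:10] + 3    # make A, B DE
  d <- tiny_dataset(vals, 5, 5)
  res <- run_analysis(d, list(loop), method = "spia", iterations = 50,
                      seed = 1)
  expect_equal(res$status, "skipped_singular")
  expect_true(is.na(res$p_g))
})

test_that("results serialise to the documented TSV layout", {
  spec <- fixture_spec(n_genes = 60, n_pathways = 2, genes_per_pathway = 8,
                       edge_density = 0.3, seed = 12)
  pw <- make_pathways(spec)
  fx <- make_expression(spec, pw, perturbed_pathway_index = 1)
  res <- run_analysis(fx$data, pw, method = "pspia", iterations = 100,
                      seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_results(res, f)
  back <- read.delim(f)
  expect_equal(names(back),
               c("pathway_id", "pathway_name", "pathway_size", "n_de",
                 "t_a", "p_nde", "p_pert", "p_g", "p_g_fdr", "status"))
  expect_equal(nrow(back), 2L)
})
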