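toy_lmax_ref <- function() {
  ds <- toy_itemset()
  loss <- loss_spec("squared", ds$y)
  sppmine:::zero_reference(ds, loss, 0.5, 0.1, 3)
}

test_that("screening and pruning scores reproduce the toy worked example", {
  ref <- toy_lmax_ref()
  expect_equal(ref$gap, 0)
  # u({2}) = 0 < 0.5: screened; u({1}) = 0.5, tie keeps the feature
  expect_equal(screening_score(c(2L, 3L), ref, 4), 0)
  expect_equal(screening_score(c(1L, 2L), ref, 4), 0.5)
  # v({1}) = 0.5; v({2}) = 0.125 < 0.5 prunes the {2} subtree
  expect_equal(spp_score(c(1L, 2L), ref, 4), 0.5)
  expect_equal(spp_score(c(2L, 3L), ref, 4), 0.125)
})

test_that("zero radius and constant columns degenerate correctly", {
  ref <- toy_lmax_ref()
  # r = 0: u_j is exactly the absolute correlation
  expect_equal(screening_score(2L, ref, 4), abs(ref$alpha[2]))
  # all-ones column is annihilated by centering under 1'alpha = 0
  ref2 <- list(alpha = ref$alpha, r = 0.7)
  expect_equal(screening_score(1:4, ref2, 4), abs(sum(ref$alpha)))
  expect_lt(screening_score(1:4, ref2, 4), 1e-12)
})

test_that("the pruning score dominates the screening score everywhere", {
  sy <- small_synth("itemset", seed = 14, n = 30)
  ds <- sy$dataset
  loss <- loss_spec("squared", ds$y)
  lmax <- spp_lambda_max(ds, loss, 3)
  fit <- solve_point(ds, 0.4 * lmax, 0, loss = loss, max_length = 3,
                     cfg = spp_config(tol = 1e-2, dynamic_screening = FALSE))
  ref <- make_reference(ds, loss, 0.4 * lmax, 0, fit$beta0, fit$patterns,
                        unname(fit$coef), fit$supports, 3)
  ep <- enumerate_patterns(ds, 3)
  for (j in seq_len(nrow(ep))) {
    expect_gte(spp_score(ep$support[[j]], ref, 30) + 1e-12,
               screening_score(ep$support[[j]], ref, 30))
  }
  # subtree bound: u_k <= v_j for every descendant k of j
  for (j in seq_len(nrow(ep))) {
    pref <- paste0(ep$key[j], ",")
    desc <- which(startsWith(ep$key, pref))
    vj <- spp_score(ep$support[[j]], ref, 30)
    for (k in desc) {
      expect_lte(screening_score(ep$support[[k]], ref, 30), vj + 1e-12)
    }
  }
})

test_that("scores tighten as the reference gap shrinks", {
  sy <- small_synth("itemset", seed = 2, n = 30)
  ds <- sy$dataset
  loss <- loss_spec("squared", ds$y)
  lmax <- spp_lambda_max(ds, loss, 3)
  lam <- 0.3 * lmax
  refs <- lapply(c(1e-1, 1e-3, 1e-6), function(tl) {
    f <- solve_point(ds, lam, 0, loss = loss, max_length = 3,
                     cfg = spp_config(tol = tl, dynamic_screening = FALSE))
    make_reference(ds, loss, lam, 0, f$beta0, f$patterns, unname(f$coef),
                   f$supports, 3)
  })
  gaps <- vapply(refs, function(r) r$gap, numeric(1))
  expect_true(all(diff(gaps) < 0))
  ep <- enumerate_patterns(ds, 3)
  for (j in seq_len(nrow(ep))) {
    us <- vapply(refs, function(r) screening_score(ep$support[[j]], r, 30),
                 numeric(1))
    vs <- vapply(refs, function(r) spp_score(ep$support[[j]], r, 30),
                 numeric(1))
    expect_true(all(diff(us) <= 1e-10))
    expect_true(all(diff(vs) <= 1e-10))
  }
})

test_that("two-reference scores respect degenerate and dominance contracts", {
  sy <- small_synth("itemset", seed = 6, n = 20)
  ds <- sy$dataset
  loss <- loss_spec("squared", ds$y)
  lmax <- spp_lambda_max(ds, loss, 3)
  lam <- 0.4 * lmax
  f1 <- solve_point(ds, lam, 0, loss = loss, max_length = 3,
                    cfg = spp_config(tol = 1e-2, dynamic_screening = FALSE))
  R1 <- make_reference(ds, loss, lam, 0, f1$beta0, f1$patterns,
                       unname(f1$coef), f1$supports, 3)
  f2 <- solve_point(ds, 0.5 * lmax, 0, loss = loss, max_length = 3,
                    cfg = spp_config(tol = 1e-3, dynamic_screening = FALSE))
  R2 <- make_reference(ds, loss, lam, 0, f2$beta0, f2$patterns,
                       unname(f2$coef), f2$supports, 3)
  ep <- enumerate_patterns(ds, 3)
  # identical references: degenerate path returns the single-reference score
  geo_same <- multi_ref_geometry(R1, R1)
  expect_true(geo_same$degenerate)
  for (j in c(1L, nrow(ep))) {
    expect_equal(multi_screening_score(ep$support[[j]], R1, R1, geo_same, 20),
                 screening_score(ep$support[[j]], R1, 20))
  }
  geo <- multi_ref_geometry(R1, R2)
  for (j in seq_len(nrow(ep))) {
    s <- ep$support[[j]]
    up <- multi_screening_score(s, R1, R2, geo, 20)
    expect_lte(up, min(screening_score(s, R1, 20),
                       screening_score(s, R2, 20)) + 1e-9)
    expect_equal(multi_spp_score(s, R1, R2, 20),
                 min(spp_score(s, R1, 20), spp_score(s, R2, 20)))
  }
})

test_that("the two-sphere closed form matches numeric constrained maximization", {
  set.seed(11)
  checked <- 0L
  while (checked < 60L) {
    n <- sample(4:8, 1)
    c1 <- rnorm(n); c1 <- c1 - mean(c1)
    d <- rnorm(n, sd = runif(1, 0.1, 0.8)); d <- d - mean(d)
    c2 <- c1 + d
    r1 <- runif(1, 0.2, 1.5); r2 <- runif(1, 0.2, 1.5)
    dd <- sqrt(sum(d^2))
    if (dd > 0.95 * (r1 + r2) || dd < 1.05 * abs(r1 - r2)) next
    s <- sort(sample(n, sample(seq_len(n - 1L), 1)))
    R1 <- list(alpha = c1, r = r1); R2 <- list(alpha = c2, r = r2)
    geo <- multi_ref_geometry(R1, R2)
    u <- multi_screening_score(s, R1, R2, geo, n)
    a <- numeric(n); a[s] <- 1
    o <- max(numeric_lens_max(a, c1, r1, c2, r2),
             numeric_lens_max(-a, c1, r1, c2, r2))
    expect_equal(u, o, tolerance = 1e-6)
    checked <- checked + 1L
  }
})

test_that("disjoint reference spheres warn and fall back safely", {
  n <- 6
  c1 <- c(1, -1, 0, 0, 0, 0); c2 <- c(-3, 3, 0, 0, 0, 0)
  R1 <- list(alpha = c1, r = 0.5); R2 <- list(alpha = c2, r = 0.5)
  expect_warning(geo <- multi_ref_geometry(R1, R2), "disjoint")
  expect_true(geo$degenerate)
  s <- c(1L, 3L)
  expect_equal(multi_screening_score(s, R1, R2, geo, n),
               min(screening_score(s, R1, n), screening_score(s, R2, n)))
})
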