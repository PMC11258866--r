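small_fit_inputs <- function(seed = 1L, n = 200L, p = 20L, sparse = FALSE) {
  set.seed(seed)
  M <- matrix(rnorm(n * p), n, p)
  beta <- if (sparse) {
    b <- numeric(p); b[sample(p, 5L)] <- runif(5L, 0.5, 2); b
  } else runif(p, -1, 1)
  Y <- as.numeric(M %*% beta) + rnorm(n, sd = if (sparse) 1e-4 else 0.05)
  list(M = M, Y = Y, beta = beta, w = rep(1, n), nu = rep(1, p),
       lb = rep(-Inf, p), ub = rep(Inf, p))
}

test_that("design matrix: optimized rows vanish, single-bond column closed form", {
  orc <- oracle_spec("h2o", seed = 1L)
  dat <- generate_reference_data(orc, n_train_runs = 1L, n_valid_runs = 1L,
                                 steps_per_run = 5L)
  model <- orc$model
  design <- build_design(model, dat, icset = orc$icset)
  n <- n_atoms(orc$structure)
  # rows of the optimized geometry (the first) are zero: every term stationary
  expect_lt(max(abs(design$M[seq_len(3 * n), ])), 1e-10)
  # single harmonic bond: column equals -(d - d_eq) times the bond direction
  g <- orc$structure
  g$positions[2, ] <- g$positions[2, ] * 1.05
  dat1 <- dat
  dat1$geometries <- list(list(tag = "aimd_train", positions = g$positions,
                               forces = matrix(0, n, 3)))
  dat1$scans <- list()
  d1 <- build_design(model, dat1, icset = orc$icset)
  jb <- which(vapply(model$terms, `[[`, character(1L), "kind") == "bond_stretch")
  inst <- model$terms[[jb]]$instances
  i2 <- which(inst$b == 2L | inst$a == 2L)[1L]
  dvec <- g$positions[2, ] - g$positions[1, ]
  dlen <- sqrt(sum(dvec^2))
  expected_on_atom2 <- -(dlen - inst$d_eq[i2]) * dvec / dlen
  expect_equal(d1$M[4:6, jb], expected_on_atom2, tolerance = 1e-10)
})

test_that("design matrix: analytic gradients match central differences", {
  orc <- oracle_spec("ethane", seed = 3L)
  dat <- generate_reference_data(orc, n_train_runs = 1L, n_valid_runs = 0L,
                                 steps_per_run = 3L)
  keep <- vapply(dat$geometries, function(g)
    g$tag %in% c("optimized", "aimd_train"), logical(1L))
  dat$geometries <- dat$geometries[keep]
  da <- build_design(orc$model, dat, icset = orc$icset, gradient = "analytic")
  dn <- build_design(orc$model, dat, icset = orc$icset, gradient = "numeric")
  expect_lt(max(abs(da$M - dn$M)), 1e-6)
})

test_that("scan block: centered columns, block-diagonal coupling", {
  orc <- oracle_spec("ethane", seed = 3L)
  dat <- generate_reference_data(orc, n_train_runs = 1L, n_valid_runs = 1L,
                                 steps_per_run = 3L)
  design <- build_design(orc$model, dat, icset = orc$icset)
  scan_rows <- which(design$part == "rot_dihedrals")
  expect_length(scan_rows, 36L)
  # scan rows: nonzero entries only in rotatable-dihedral columns
  rot_cols <- which(vapply(orc$model$terms, function(tm)
    identical(tm$classification, "rotatable"), logical(1L)))
  other <- setdiff(seq_along(orc$model$terms), rot_cols)
  expect_lt(max(abs(design$M[scan_rows, other])), 1e-12)
  # each scan column sums to zero over the scan (centering), as does Y
  expect_lt(max(abs(colSums(design$M[scan_rows, rot_cols, drop = FALSE]))),
            1e-10)
  expect_lt(abs(sum(design$Y[scan_rows])), 1e-10)
})

test_that("bounds: zero lower bounds except multi-mode rotatable and cross terms", {
  s <- make_fixture("toy_rotor_framework")
  prep <- prepare_icset(s, pipeline_config(seed = 3))
  sel <- lapply(prep$scans, function(x) c(1L, 3L))
  sel1 <- lapply(prep$scans, function(x) 3L)
  m2 <- assign_term_kinds(prep$icset, sel, cross_terms = TRUE)
  b2 <- assign_bounds(m2)
  kinds <- vapply(m2$terms, `[[`, character(1L), "kind")
  cls <- vapply(m2$terms, function(tm)
    if (is.null(tm$classification)) "" else tm$classification, character(1L))
  expect_true(all(b2$lb[kinds %in% c("bond_stretch", "ub_stretch",
                                     "angle_bend",
                                     "torsion_addt_linear_mode")] == 0))
  expect_true(all(b2$lb[cls %in% c("nonrotatable", "hindered")] == 0))
  expect_true(all(b2$lb[kinds == "bond_bond_cross"] == -Inf))
  expect_true(all(b2$lb[cls == "rotatable"] == -Inf))  # two modes selected
  expect_true(all(is.infinite(b2$ub) & b2$ub > 0))
  # single-mode rotatable torsions get the zero lower bound
  m1 <- assign_term_kinds(prep$icset, sel1, cross_terms = FALSE)
  b1 <- assign_bounds(m1)
  cls1 <- vapply(m1$terms, function(tm)
    if (is.null(tm$classification)) "" else tm$classification, character(1L))
  expect_true(all(b1$lb[cls1 == "rotatable"] == 0))
})

test_that("observation weights: inverse-SST parts, rescale invariance", {
  Y <- c(rnorm(30, sd = 2), rnorm(10, sd = 1))
  part <- factor(rep(c("forces", "rot_dihedrals"), c(30, 10)))
  w <- observation_weights(Y, part)
  expect_equal(sum(w), length(Y))
  sst_f <- sum(Y[1:30]^2); sst_r <- sum(Y[31:40]^2)
  # per-observation weight ratio is the inverse SST ratio
  expect_equal(w[1] / w[31], sst_r / sst_f, tolerance = 1e-12)
  expect_length(unique(round(w[1:30], 14)), 1L)
  # a part with zero SST errors
  expect_error(observation_weights(c(Y, 0), factor(c(as.character(part), "x"))),
               "zero total")
  # rescaling all weights leaves the fit, R2 and RMSE unchanged
  inp <- small_fit_inputs(2L)
  pathA <- lasso_path(inp$M, inp$Y, inp$w, inp$nu, inp$lb, inp$ub,
                      n_lambda = 10L)
  pathB <- lasso_path(inp$M, inp$Y, 7.3 * inp$w, inp$nu, inp$lb, inp$ub,
                      n_lambda = 10L)
  expect_equal(pathB$beta, pathA$beta, tolerance = 1e-8)
})

test_that("penalty factors: unit invariance, identical and zero columns", {
  inp <- small_fit_inputs(3L)
  w <- runif(length(inp$Y), 0.5, 2)
  M <- inp$M
  M[, 2] <- M[, 1]
  nu <- penalty_factors(M, w)
  expect_equal(nu[1], nu[2], tolerance = 1e-12)
  expect_equal(sum(nu), ncol(M))
  Mz <- M
  Mz[, 3] <- 0
  expect_warning(nuz <- penalty_factors(Mz, w), "all-zero")
  expect_equal(nuz[3], 0)
  # rescaling a column's units leaves the selected model and R2 unchanged
  Ms <- inp$M
  s <- 1.8897261246
  Ms[, 5] <- Ms[, 5] * s
  nu1 <- penalty_factors(inp$M, w)
  nu2 <- penalty_factors(Ms, w)
  expect_equal(nu2[5] / nu1[5] / (nu2[1] / nu1[1]), s, tolerance = 1e-10)
  p1 <- lasso_path(inp$M, inp$Y, w, nu1, inp$lb, inp$ub, n_lambda = 20L)
  p2 <- lasso_path(Ms, inp$Y, w, nu2, inp$lb, inp$ub, n_lambda = 20L)
  b2 <- p2$beta
  b2[5, ] <- b2[5, ] * s
  expect_equal(b2, p1$beta, tolerance = 1e-6)
})

test_that("lasso path: all-zero at lambda_max, weighted least squares at lambda -> 0", {
  inp <- small_fit_inputs(4L, n = 300L, p = 20L)
  w <- runif(300L, 0.5, 2)
  nu <- penalty_factors(inp$M, w)
  path <- lasso_path(inp$M, inp$Y, w, nu, inp$lb, inp$ub,
                     n_lambda = 100L, lambda_ratio = 1e-7)
  expect_true(all(path$beta[, 1] == 0))
  # weighted normal-equations oracle
  WM <- inp$M * w
  b_wls <- solve(crossprod(WM, inp$M), crossprod(WM, inp$Y))
  expect_lt(max(abs(path$beta[, 100L] - b_wls)), 1e-6)
})

test_that("lasso agrees with glmnet under weights, penalty factors and bounds", {
  skip_if_not_installed("glmnet")
  inp <- small_fit_inputs(5L, n = 250L, p = 12L, sparse = TRUE)
  w <- runif(250L, 0.5, 2)
  w <- w * length(w) / sum(w)  # the convention both solvers rescale to
  nu <- penalty_factors(inp$M, w)
  lb <- rep(0, 12L); lb[1:4] <- -Inf
  path <- lasso_path(inp$M, inp$Y, w, nu, lb, rep(Inf, 12L), n_lambda = 5L,
                     lambda_ratio = 1e-3)
  for (li in c(2L, 4L)) {
    lam <- path$lambda[li]
    gfit <- glmnet::glmnet(inp$M, inp$Y, weights = w, lambda = lam,
                           penalty.factor = nu, lower.limits = lb,
                           upper.limits = Inf, intercept = FALSE,
                           standardize = FALSE, thresh = 1e-12)
    bg <- as.numeric(gfit$beta)
    # glmnet internally rescales weights to mean 1 and penalty factors to
    # sum p; ours are already in that convention
    expect_lt(max(abs(bg - path$beta[, li])), 1e-4)
  }
})

test_that("zero lower bound clamps negative-tending coefficients to exactly zero", {
  # two predictors; the second's unconstrained coefficient is negative
  set.seed(9)
  M <- cbind(rnorm(100), rnorm(100))
  Y <- 1.5 * M[, 1] - 0.8 * M[, 2] + rnorm(100, sd = 0.01)
  path <- lasso_path(M, Y, rep(1, 100), rep(1, 2), lb = c(0, 0),
                     ub = rep(Inf, 2), n_lambda = 30L)
  bfinal <- path$beta[, 30L]
  expect_identical(bfinal[2], 0)
  expect_gt(bfinal[1], 1.3)
})

test_that("non-convergence raises an error naming lambda", {
  inp <- small_fit_inputs(6L, n = 50L, p = 5L)
  expect_error(lasso_path(inp$M, inp$Y, inp$w, inp$nu, inp$lb, inp$ub,
                          n_lambda = 3L, max_iter = 2L),
               "did not converge at lambda")
})

test_that("lambda_best: planted sparse recovery and boundary behavior", {
  set.seed(11)
  n <- 400L; p <- 15L
  M <- matrix(rnorm(n * p), n, p)
  beta_true <- numeric(p)
  beta_true[c(2, 5, 9)] <- c(1.2, -0.7, 2.0)
  Y <- as.numeric(M %*% beta_true) + rnorm(n, sd = 1e-5)
  w <- rep(1, n)
  nu <- penalty_factors(M, w)
  path <- lasso_path(M, Y, w, nu, rep(-Inf, p), rep(Inf, p))
  part <- factor(rep("forces", n))
  sel <- select_lambda_best(path, M, Y, part, n_atoms_ = 20L)
  expect_identical(which(sel$beta != 0), which(beta_true != 0))
  expect_equal(sel$n_k_remaining, 3L)
  expect_error(select_lambda_best(structure(list(lambda = 1), class = "lasso_path"),
                                  M, Y, part, 20L), "short")
})

test_that("statistics: identities, zero-model baseline, per-atom aggregation", {
  orc <- oracle_spec("h2o", seed = 8L)
  dat <- generate_reference_data(orc, n_train_runs = 2L, n_valid_runs = 1L,
                                 steps_per_run = 10L)
  design <- build_design(orc$model, dat, icset = orc$icset)
  st <- compute_statistics(orc$model$k, design, per_atom = TRUE)
  expect_true(all(st$R2 <= 1 + 1e-12))
  expect_true(all(st$RMSE >= 0))
  # true model on noiseless data: perfect
  expect_true(all(st$R2 > 1 - 1e-12))
  expect_lt(max(st$RMSE), 1e-9)
  # beta = 0 predicts the no-intercept baseline: R2 = 0 by definition
  st0 <- compute_statistics(rep(0, length(orc$model$k)), design)
  expect_equal(st0$R2, rep(0, nrow(st0)))
  # per-atom RMSEs aggregate back to the global force RMSE
  stb <- compute_statistics(orc$model$k * runif(length(orc$model$k), 0.5, 0.9),
                            design, per_atom = TRUE)
  pa <- attr(stb, "per_atom")
  glob <- stb[stb$part == "forces", ]
  expect_equal(sqrt(sum(pa$RMSE^2 * pa$n) / sum(pa$n)), glob$RMSE,
               tolerance = 1e-12)
  expect_equal(sum(pa$n), glob$n)
})
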