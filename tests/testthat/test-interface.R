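make_df <- function(n = 80, p = 4, rho = 0.9, phi = 0.5, seed = 51) {
  set.seed(seed)
  X <- sim_design(n, p, rho)
  beta <- c(0.5, sim_coef(p, "equal"))
  y <- sim_response(cbind(1, X), beta, phi)
  data.frame(y = y, X)
}

test_that("the formula interface fits and its methods are coherent", {
  dat <- make_df()
  fit <- suppressWarnings(gklreg(y ~ ., data = dat, estimator = "gkl"))
  expect_s3_class(fit, "gklreg")
  expect_named(coef(fit), c("(Intercept)", paste0("X", 1:4)))
  expect_gt(fit$k, 0)
  expect_equal(unname(predict(fit)), unname(fitted(fit)))
  expect_equal(predict(fit, type = "link"), log(predict(fit)))
  nd <- dat[3:5, ]
  expect_equal(unname(predict(fit, newdata = nd)),
               unname(exp(drop(cbind(1, as.matrix(nd[, -1])) %*% coef(fit)))))
  r <- residuals(fit, type = "pearson")
  expect_equal(r, (dat$y - fitted(fit)) / fitted(fit))
  expect_equal(residuals(fit, "response"), dat$y - fitted(fit))
  expect_true(all(is.finite(residuals(fit, "deviance"))))
  v <- vcov(fit)
  expect_equal(v, t(v))
  expect_gte(min(eigen(v, symmetric = TRUE)$values), -1e-12)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(nrow(dat), 3L))
  expect_true(all(sims > 0))
  s <- summary(fit)
  expect_s3_class(s, "summary.gklreg")
  expect_output(print(s), "Estimated MSE")
  expect_output(print(fit), "Kibria-Lukman")
})

test_that("estimator choices and manual parameters are honored", {
  dat <- make_df()
  mle <- suppressWarnings(gklreg(y ~ ., dat, estimator = "mle"))
  expect_null(mle$k); expect_null(mle$d)
  gre <- suppressWarnings(gklreg(y ~ ., dat, estimator = "gre", k = 0))
  expect_equal(coef(gre), coef(mle), tolerance = 1e-12)
  gle <- suppressWarnings(gklreg(y ~ ., dat, estimator = "gle", d = 1))
  expect_equal(coef(gle), coef(mle), tolerance = 1e-12)
  gkl_min <- suppressWarnings(gklreg(y ~ ., dat, estimator = "gkl",
                                     k_rule = "min"))
  gkl_max <- suppressWarnings(gklreg(y ~ ., dat, estimator = "gkl",
                                     k_rule = "max"))
  expect_lte(gkl_min$k, gkl_max$k)
})

test_that("severe collinearity triggers a warning keyed to the threshold", {
  dat <- make_df(rho = 0.999)
  expect_warning(gklreg(y ~ ., dat), "multicollinearity")
  dat0 <- make_df(rho = 0)
  expect_silent(fit0 <- gklreg(y ~ ., dat0, cn_warn = 1e6))
})

test_that("without collinearity and with strong signal the estimators coincide", {
  # orthogonal design, small predictor scale but large coefficients: every
  # raw coordinate carries strong signal relative to phi, so all selected
  # biasing parameters are tiny compared to the spectrum and the four
  # estimators (and their plug-in risks) agree to within 1%. Raw selector
  # coordinates are used: the rotated ones mix coordinates through the
  # fitted weights even when the predictors themselves are orthogonal.
  set.seed(52)
  n <- 150
  Q <- qr.Q(qr(matrix(rnorm(n * 4), n, 4))) * sqrt(n) * 0.1
  beta <- rep(1.5, 4)
  y <- sim_response(Q, beta, 0.01)
  dat <- data.frame(y = y, Q)
  rep <- estimator_report(y ~ . - 1, dat, coords = "raw")
  k_sel <- rep$params[c("GRE-k", "GKL-kmin", "GKL-k2")]
  expect_lt(max(k_sel / min(rep$mle$eigenvalues)), 0.05)
  expect_gt(rep$params["GLE-d"], 0.95)
  mses <- rep$mse
  expect_lt(max(mses) / min(mses) - 1, 0.01)
  spread <- apply(rep$table, 1, function(r) diff(range(r)))
  expect_lt(max(spread), 0.05)
})

test_that("the comparison report mirrors the classical table layout", {
  set.seed(53)
  X <- sim_design(65, 15, 0.99)
  beta <- sim_coef(15, "eigvec-max", X = X)
  y <- sim_response(cbind(1, X), c(0.2, beta), 0.5)
  dat <- data.frame(y = y, X)
  suppressMessages(rep <- estimator_report(y ~ ., dat))
  expect_identical(colnames(rep$table),
                   c("MLE", "GRE-k", "GLE-d", "GKL-kmin", "GKL-k2"))
  expect_identical(nrow(rep$table), 16L)  # intercept + 15 descriptors
  expect_identical(names(rep$params), colnames(rep$table))
  expect_true(is.na(rep$params["MLE"]))
  expect_true(all(rep$mse > 0))
  # plug-in risk guarantees: the ridge k (min_j phi/alpha_j^2) satisfies
  # k alpha_j^2 <= phi for every j, and the min-rule GKL k stays below
  # every per-coordinate optimum, so both risks cannot exceed the MLE's
  expect_lte(rep$mse["GRE-k"], rep$mse["MLE"] + 1e-10)
  expect_lte(rep$mse["GKL-kmin"], rep$mse["MLE"] + 1e-10)
  expect_output(print(rep), "Condition index")
  # CSV export carries the d/k and MSE rows
  f <- tempfile(fileext = ".csv")
  suppressMessages(estimator_report(y ~ ., dat, file = f))
  out <- read.csv(f, check.names = FALSE)
  expect_identical(tail(out$term, 2L), c("d/k", "estimated MSE (plug-in)"))
  unlink(f)
})

test_that("the CSV reader enforces positivity and reports dropped rows", {
  f <- tempfile(fileext = ".csv")
  df <- data.frame(resp = c(1.2, 2.3, NA, 0.7), a = c(1, 2, 3, NA),
                   b = 1:4, label = letters[1:4])
  write.csv(df, f, row.names = FALSE)
  expect_message(got <- read_gamma_csv(f, "resp"), "2 rows")
  expect_identical(names(got)[1], "resp")
  expect_identical(nrow(got), 2L)
  df$resp <- c(1, -1, 2, 3)
  write.csv(df, f, row.names = FALSE)
  expect_error(suppressMessages(read_gamma_csv(f, "resp")), "non-positive")
  expect_error(read_gamma_csv(f, "nope"), "not found")
  unlink(f)
})

test_that("the command-line dispatcher drives fit, simulate and risk", {
  dat <- make_df(n = 60, rho = 0.9)
  f <- tempfile(fileext = ".csv"); out <- tempfile(fileext = ".csv")
  write.csv(dat, f, row.names = FALSE)
  expect_output(gklreg_cli(c("fit", "--csv", f, "--response", "y",
                             "--out", out)),
                "GKL-k2")
  tab <- read.csv(out, check.names = FALSE)
  expect_identical(ncol(tab), 6L)  # term + 5 estimator columns
  sim_out <- tempfile(fileext = ".csv")
  man <- tempfile(fileext = ".json")
  suppressMessages(gklreg_cli(c("simulate", "--out", sim_out, "--n", "25",
                                "--p", "4", "--rho", "0.9", "--phi", "0.5",
                                "--reps", "3", "--seed", "11",
                                "--manifest", man)))
  st <- read.csv(sim_out)
  expect_identical(nrow(st), 5L)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    expect_true(file.exists(man))
    expect_equal(jsonlite::read_json(man)$config$seed, 11)
  }
  expect_output(gklreg_cli(c("risk", "--phi", "1", "--gamma", "2,1",
                             "--alpha", "1,1", "--k", "1", "--d", "0.5")),
                "GKL")
  expect_output(gklreg_cli("help"), "usage")
  expect_error(gklreg_cli("bogus"), "unknown subcommand")
  unlink(c(f, out, sim_out, man))
})
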