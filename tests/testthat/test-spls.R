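toy_instance <- function(seed = 41, p = 5, n = 6, q = 3) {
  set.seed(seed)
  X <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("g%d", 1:p), sprintf("l%d", 1:n)))
  Y <- matrix(rnorm(n * q), n, q,
              dimnames = list(colnames(X), c("area_2h", "auc", "circularity")))
  list(X = X, Y = Y)
}

test_that("dense limit matches the cross-covariance SVD direction", {
  for (seed in c(41, 42, 43)) {
    inst <- toy_instance(seed)
    fit <- fit_spls(inst$X, inst$Y, spls_config(n_components = 1,
                                                keep_x = nrow(inst$X)))
    Xs <- scale(t(inst$X)); Ys <- scale(inst$Y)
    sv <- svd(crossprod(Xs, Ys))       # p x q cross-covariance
    w_ref <- sv$u[, 1]
    w <- fit$x_loadings[, 1]
    if (sum(w * w_ref) < 0) w_ref <- -w_ref
    expect_lt(max(abs(w - w_ref)), 1e-6)
  }
})

test_that("each component keeps exactly keep_x nonzero loadings", {
  inst <- toy_instance(44, p = 40, n = 10)
  for (keep in c(3, 10, 25)) {
    fit <- fit_spls(inst$X, inst$Y, spls_config(n_components = 2, keep_x = keep))
    expect_identical(colSums(fit$x_loadings != 0), c(comp1 = keep, comp2 = keep))
  }
})

test_that("standardized fits are invariant to per-gene affine rescaling", {
  inst <- toy_instance(45, p = 30, n = 12)
  fit1 <- fit_spls(inst$X, inst$Y, spls_config(2, keep_x = 10))
  set.seed(46)
  X2 <- inst$X * runif(30, 0.1, 5) + rnorm(30)
  fit2 <- fit_spls(X2, inst$Y, spls_config(2, keep_x = 10))
  expect_equal(fit1$x_loadings, fit2$x_loadings, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with diagnostics", {
  inst <- toy_instance(47)
  Y0 <- inst$Y; Y0[, ] <- 0
  expect_error(fit_spls(inst$X, Y0), "constant|degenerate")
  Xna <- inst$X; Xna[1, 1] <- NA
  expect_error(fit_spls(Xna, inst$Y), "missing")
  Xc <- inst$X; Xc[2, ] <- 7
  expect_warning(fit_spls(Xc, inst$Y, spls_config(1, keep_x = 3)), "constant")
  expect_error(fit_spls(inst$X[, 1:2], inst$Y[1:2, ]), "3 cell lines")
})

test_that("gene selection splits by sign and is sign-flip invariant", {
  w <- c(g1 = 0.5, g2 = -0.3, g3 = 0)
  fit <- structure(list(
    x_loadings = matrix(w, 3, 1, dimnames = list(names(w), "comp1")),
    y_loadings = matrix(c(0.9, 0.4, 0.1), 3, 1,
                        dimnames = list(c("auc", "area_2h", "circularity"),
                                        "comp1")),
    par_ids = c("auc", "area_2h", "circularity"),
    n_components = 1L), class = "spls_fit")
  sel <- select_genes(fit, 1, group = c("auc", "area_2h"))
  expect_identical(sel$positive, "g1")
  expect_identical(sel$negative, "g2")
  flipped <- fit
  flipped$x_loadings <- -fit$x_loadings
  flipped$y_loadings <- -fit$y_loadings
  self <- select_genes(flipped, 1, group = c("auc", "area_2h"))
  expect_identical(self$positive, sel$positive)
  expect_identical(self$negative, sel$negative)
  expect_error(select_genes(fit, 2), "not fitted")
  expect_error(select_genes(fit, 1, group = "banana"), "unknown")
})

test_that("planted genes are recovered and land on the correct sign", {
  params <- generate_line_parameters(25, window_h = 24, seed = 51)
  panel <- generate_expression_panel(params, n_genes = 500,
                                     n_planted_per_parameter = 10,
                                     effect_size = 2, noise_sd = 0.5,
                                     seed = 52)
  fit <- fit_spls(panel$matrix, as.matrix(panel$params),
                  spls_config(2, keep_x = 30))
  sel1 <- select_genes(fit, 1, group = c("auc", "area_2h"))
  sel2 <- select_genes(fit, 2, group = "circularity")
  selected <- unique(c(sel1$positive, sel1$negative,
                       sel2$positive, sel2$negative))
  planted <- panel$planted$gene
  expect_gte(mean(planted %in% selected), 0.9)
  # positive-beta genes on the AUC axis land in the positive list
  pos_auc <- with(panel$planted, gene[parameter == "auc" & beta > 0])
  hits <- intersect(pos_auc, c(sel1$positive, sel1$negative))
  expect_gte(mean(hits %in% sel1$positive), 0.9)
})

test_that("query signatures are built from signed selections", {
  sel <- structure(list(positive = c("a", "b"), negative = "c",
                        group_label = "auc+area_2h"),
                   class = "gene_selection")
  q <- build_query_signature(sel)
  expect_identical(q$up, c("a", "b"))
  expect_identical(q$down, "c")
  sel$negative <- character()
  expect_error(build_query_signature(sel), "non-empty")
  sel$negative <- "a"
  expect_error(build_query_signature(sel), "overlap")
})
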