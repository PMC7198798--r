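## Build a fold-change series set directly from a time x cytokine log2 matrix
## replicated per subject (helper for aggregation tests).
series_from_log2 <- function(mats, groups = NULL) {
  rows <- list()
  for (s in seq_along(mats)) {
    L <- mats[[s]]
    for (cy in colnames(L)) {
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = sprintf("S%02d", s),
        group = if (is.null(groups)) "HC" else groups[s],
        cytokine = cy, minutes = seq(0, by = 3, length.out = nrow(L)),
        value = 2^L[, cy], stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows), step = 3, units = "fold_change",
            class = c("uniform_series_set", "data.frame"))
}

test_that("the functional set map matches the panel design", {
  m <- functional_set_map()
  expect_identical(cytokine_set("IL-6"), "MK6")
  expect_identical(cytokine_set("IL-17"), "CK17")
  expect_identical(cytokine_set("IL-4"), "CK2")
  expect_identical(cytokine_set("IL-10"), "MK2")
  expect_identical(cytokine_set("IL-1a"), "MK1")   # shared MK1A/MK1B block
  expect_setequal(m$blocks$CK1, c("IL-2", "IFNg", "TNFa", "TNFb"))
  expect_setequal(unlist(m$blocks), PANEL_CYTOKINES)
  expect_error(cytokine_set("IL-99"), "not in the panel")
})

test_that("pooled components split blocks only below the variance threshold", {
  set.seed(42)
  n <- 120
  ## MK1 block: two latent factors -> PC1 fraction < 0.80 -> MK1A and MK1B
  f1 <- rnorm(n, sd = 2); f2 <- rnorm(n, sd = 1.6)
  L <- matrix(rnorm(n * 16, sd = 0.05), n, 16,
              dimnames = list(NULL, PANEL_CYTOKINES))
  L[, "IL-1a"] <- f1 + rnorm(n, sd = 0.05)
  L[, "IL-1b"] <- 0.8 * f1 + rnorm(n, sd = 0.05)
  L[, "IL-8"] <- f2 + rnorm(n, sd = 0.05)
  L[, "IL-12"] <- 0.7 * f2 + rnorm(n, sd = 0.05)
  ## CK1 block: one factor -> PC1 fraction near 1 -> single component
  g <- rnorm(n, sd = 2)
  for (cy in c("IL-2", "IFNg", "TNFa", "TNFb")) {
    L[, cy] <- g * runif(1, 0.7, 1) + rnorm(n, sd = 0.05)
  }
  ser <- series_from_log2(list(L))
  model <- fit_pooled_pca(ser, layout = "auto")
  expect_lt(model$sets$MK1$var_fractions[1], 0.80)
  expect_identical(colnames(model$sets$MK1$loadings), c("MK1A", "MK1B"))
  expect_gt(model$sets$CK1$var_fractions[1], 0.95)
  expect_identical(colnames(model$sets$CK1$loadings), "CK1")
  ## variance fractions are a valid non-increasing partition
  for (s in model$sets) {
    expect_true(all(diff(s$var_fractions) <= 1e-12))
    expect_lte(sum(s$var_fractions), 1 + 1e-9)
  }
  ## recovered loading direction matches the generating factor (cosine)
  w <- model$sets$MK1$loadings[, "MK1A"]
  truth <- c(1, 0.8, 0, 0) / sqrt(1 + 0.64)
  expect_gt(abs(sum(w * truth)), 0.95)

  ## perfectly collinear constituents -> PC1 fraction 1, one component
  L2 <- L
  L2[, "IL-2"] <- g; L2[, "IFNg"] <- 2 * g
  L2[, "TNFa"] <- -g; L2[, "TNFb"] <- 0.5 * g
  m2 <- fit_pooled_pca(series_from_log2(list(L2)), layout = "auto")
  expect_equal(m2$sets$CK1$var_fractions[1], 1, tolerance = 1e-9)
  ## constant block is degenerate
  L3 <- L; L3[, c("IL-4", "IL-5", "IL-13")] <- 1
  expect_error(fit_pooled_pca(series_from_log2(list(L3))), "constant")
})

test_that("fixed layout always yields the 9 canonical nodes", {
  set.seed(7)
  L <- matrix(rnorm(60 * 16, sd = 1), 60, 16,
              dimnames = list(NULL, PANEL_CYTOKINES))
  model <- fit_pooled_pca(series_from_log2(list(L)))
  expect_identical(model$node_names, AGGREGATE_NODES)
})

test_that("scoring projects onto pooled loadings with centering", {
  set.seed(11)
  L1 <- matrix(rnorm(50 * 16), 50, 16, dimnames = list(NULL, PANEL_CYTOKINES))
  L2 <- matrix(rnorm(50 * 16), 50, 16, dimnames = list(NULL, PANEL_CYTOKINES))
  ser <- series_from_log2(list(L1, L2))
  model <- fit_pooled_pca(ser)
  sc <- score_aggregates(ser, model)
  expect_length(sc, 2)
  expect_equal(rownames(sc$S01$scores), AGGREGATE_NODES)
  ## identical subjects -> identical score matrices
  sc2 <- score_aggregates(series_from_log2(list(L1, L1)), model)
  expect_equal(sc2$S01$scores, sc2$S02$scores)
  ## singleton set scores are centered log2 fold changes
  expect_equal(sc$S01$scores["MK6", ],
               L1[, "IL-6"] - mean(rbind(L1, L2)[, "IL-6"]))
  ## multi-set scores equal the centered block times the loadings
  ck1 <- model$sets$CK1
  manual <- sweep(L1[, ck1$cytokines], 2, ck1$center) %*% ck1$loadings
  expect_equal(unname(sc$S01$scores["CK1", ]), unname(manual[, 1]))
  ## column order inside a set does not matter
  perm <- PANEL_CYTOKINES[c(2, 1, 3:16)]
  sc3 <- score_aggregates(series_from_log2(list(L1[, perm], L2[, perm])), model)
  expect_equal(sc3$S01$scores, sc$S01$scores)
  ## a subject sitting at the pooled mean at every time scores 0 on every
  ## multi-cytokine set
  Lm <- matrix(rep(colMeans(rbind(L1, L2)), each = 50), 50, 16,
               dimnames = list(NULL, PANEL_CYTOKINES))
  scm <- score_aggregates(series_from_log2(list(Lm)), model)
  for (nd in c("MK1A", "MK1B", "CK1", "CK2")) {
    expect_near(scm$S01$scores[nd, ], 0, tol = 1e-9)
  }
})

test_that("synthetic single-factor sets recover generating loadings", {
  set.seed(5)
  n <- 200
  g <- rnorm(n, sd = 2)
  truth <- c(0.9, 0.6, 0.45)
  L <- matrix(rnorm(n * 16, sd = 0.08), n, 16,
              dimnames = list(NULL, PANEL_CYTOKINES))
  L[, c("IL-4", "IL-5", "IL-13")] <-
    outer(g, truth) + matrix(rnorm(n * 3, sd = 0.08), n, 3)
  model <- fit_pooled_pca(series_from_log2(list(L)))
  w <- model$sets$CK2$loadings[, 1]
  cosine <- abs(sum(w * truth) / sqrt(sum(truth^2)))
  expect_gt(cosine, 0.95)
})
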