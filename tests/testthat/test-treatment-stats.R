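test_that("cell summaries and marginal means aggregate correctly", {
  d <- data.frame(biome = rep(c("a", "b"), each = 6),
                  depth = rep(rep(c("top", "sub"), each = 3), 2),
                  y = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12))
  cells <- summarize_treatments(d, "y", by = c("biome", "depth"))
  expect_equal(nrow(cells), 4)
  expect_equal(cells$n, rep(3, 4))
  expect_equal(cells$mean[cells$biome == "a" & cells$depth == "top"], 2)
  expect_equal(cells$se[cells$biome == "a" & cells$depth == "top"],
               sd(1:3) / sqrt(3))
  # equal values give zero SE
  d0 <- data.frame(biome = "a", depth = "top", y = rep(4, 5))
  expect_equal(summarize_treatments(d0, "y", by = c("biome", "depth"))$se, 0)

  # marginal = unweighted mean of cell means
  marg <- marginal_means(cells, by = "biome")
  expect_equal(marg$mean[marg$biome == "a"], mean(c(2, 5)))
  expect_equal(marg$n_cells, c(2, 2))
  expect_error(marginal_means(cells, by = "distance"), "columns")
})

test_that("three-way ANOVA decomposes sums of squares exactly", {
  set.seed(51)
  d <- expand.grid(biome = c("a", "b"), depth = c("t", "s"),
                   distance = c(2, 30), rep = 1:3)
  d$y <- rnorm(nrow(d), 10, 2)
  av <- three_way_anova(d, "y")
  tab <- av$table
  # term SS + residual SS = total SS
  ss_tot <- sum((d$y - mean(d$y))^2)
  expect_equal(sum(tab$ss), ss_tot, tolerance = 1e-9)
  expect_equal(sum(tab$df), nrow(d) - 1)
  expect_equal(av$r_squared,
               1 - tab$ss[tab$term == "Residuals"] / ss_tot)

  # pure biome contrast: all variance in B, R^2 = 1
  d$y2 <- ifelse(d$biome == "a", 1, -1)
  av2 <- suppressWarnings(three_way_anova(d, "y2"))  # perfect fit warns
  expect_equal(av2$r_squared, 1, tolerance = 1e-12)
  expect_equal(sum(av2$table$ss[av2$table$term != "biome"]), 0,
               tolerance = 1e-20)

  # constant response: nothing to decompose
  d$y3 <- 5
  expect_equal(sum(suppressWarnings(three_way_anova(d, "y3"))$table$ss), 0,
               tolerance = 1e-20)

  # balanced design: sequential SS invariant to factor order
  av_rev <- three_way_anova(d, "y", factors = c("distance", "depth", "biome"))
  for (f in c("biome", "depth", "distance")) {
    expect_equal(av$table$ss[av$table$term == f],
                 av_rev$table$ss[av_rev$table$term == f], tolerance = 1e-9)
  }
})

test_that("balanced 2x2x2 sums of squares match mean-contrast arithmetic", {
  set.seed(52)
  d <- expand.grid(A = c("lo", "hi"), B = c("lo", "hi"), C = c("lo", "hi"),
                   rep = 1:4)
  d$y <- rnorm(nrow(d))
  r <- 4
  gm <- mean(d$y)
  m1 <- function(f) tapply(d$y, d[[f]], mean)
  m2 <- function(f, g) tapply(d$y, list(d[[f]], d[[g]]), mean)
  # brute-force projection sums of squares for the balanced layout
  ss_main <- function(f) 8 * r / 2 * sum((m1(f) - gm)^2)
  ss_int2 <- function(f, g) {
    mm <- m2(f, g)
    e <- outer(m1(f) - gm, m1(g) - gm, "+") + gm
    2 * r * sum((mm - e)^2)
  }
  av <- three_way_anova(d, "y", factors = c("A", "B", "C"))
  tab <- av$table
  expect_equal(tab$ss[tab$term == "A"], ss_main("A"), tolerance = 1e-9)
  expect_equal(tab$ss[tab$term == "B"], ss_main("B"), tolerance = 1e-9)
  expect_equal(tab$ss[tab$term == "C"], ss_main("C"), tolerance = 1e-9)
  expect_equal(tab$ss[tab$term == "A:B"], ss_int2("A", "B"),
               tolerance = 1e-9)
  expect_equal(tab$ss[tab$term == "B:C"], ss_int2("B", "C"),
               tolerance = 1e-9)
})

test_that("backwards stepwise recovers a planted single-covariate model", {
  set.seed(53)
  pts <- generate_environment(generate_design(), seed = 8)
  pts$resp <- 2 * pts$c_pct + rnorm(nrow(pts), 0, 0.5)
  sw <- backwards_stepwise(pts, "resp", covariates = c("met", "ws", "c_pct"))
  # the planted covariate always survives; its slope matches the truth
  expect_true("c_pct" %in% unlist(strsplit(sw$retained, ":")))
  simple <- stats::lm(resp ~ c_pct, data = pts)
  expect_lt(abs(coef(simple)[["c_pct"]] - 2),
            3 * summary(simple)$coefficients["c_pct", 2])
  # trace reproducible under identical input
  sw_again <- backwards_stepwise(pts, "resp",
                                 covariates = c("met", "ws", "c_pct"))
  expect_identical(sw$trace, sw_again$trace)
  # backward elimination lands on exactly {c_pct} in most replicates
  exact <- 0
  for (i in 1:10) {
    pts$resp <- 2 * pts$c_pct + rnorm(nrow(pts), 0, 0.5)
    swi <- backwards_stepwise(pts, "resp",
                              covariates = c("met", "ws", "c_pct"))
    if (identical(swi$retained, "c_pct")) exact <- exact + 1
  }
  expect_gte(exact, 6)
})

test_that("stepwise never violates marginality", {
  set.seed(54)
  for (i in 1:25) {
    pts <- generate_environment(generate_design(), seed = i)
    pts$resp <- rnorm(nrow(pts), 50, 10) +
      (i %% 3) * pts$c_pct + (i %% 2) * 0.1 * pts$met * pts$ws
    sw <- backwards_stepwise(pts, "resp",
                             covariates = c("met", "ws", "c_pct"))
    for (term in sw$retained[grepl(":", sw$retained)]) {
      parents <- strsplit(term, ":")[[1]]
      expect_true(all(parents %in% sw$retained))
    }
  }
})

test_that("average marginal slope matches coefficients and interactions", {
  set.seed(60)
  d <- data.frame(x = rnorm(60), z = rnorm(60))
  d$y <- 1 + 2 * d$x + rnorm(60, 0, 0.1)
  f1 <- lm(y ~ x + z, d)
  expect_equal(marginal_slope(f1, d, "x"), coef(f1)[["x"]])
  # with an interaction, the marginal slope averages over z
  d$y2 <- 1 + 2 * d$x + 3 * d$x * d$z
  f2 <- lm(y2 ~ x * z, d)
  expect_equal(marginal_slope(f2, d, "x"),
               coef(f2)[["x"]] + coef(f2)[["x:z"]] * mean(d$z))
  # invariant to the difference step for models linear in the covariate
  expect_equal(marginal_slope(f2, d, "x", h = 0.01),
               marginal_slope(f2, d, "x", h = 5))
})

test_that("variance explained is the squared Pearson correlation", {
  set.seed(55)
  d <- data.frame(x = rnorm(200))
  d$y <- 3 * d$x + rnorm(200)
  expect_equal(variance_explained(d, "y", "x"), cor(d$x, d$y)^2)
  d$z <- d$x
  expect_equal(suppressWarnings(variance_explained(d, "z", "x")), 1)
  d$w <- rnorm(200)
  expect_lt(variance_explained(d, "w", "x"), 0.05)
  d$k <- 1
  expect_error(variance_explained(d, "y", "k"), "zero variance")
})

test_that("ML variance components match the closed-form balanced estimators", {
  set.seed(56)
  a <- 5; n_per <- 6
  d <- data.frame(transect = rep(seq_len(a), each = n_per))
  d$y <- rnorm(a, 0, 4)[d$transect] + rnorm(a * n_per, 20, 1)
  fit <- lmm_random_intercept(d, "y", group = "transect")
  av <- anova(stats::lm(y ~ factor(transect), d))
  sse <- av$`Sum Sq`[2]
  ssa <- av$`Sum Sq`[1]
  sw_closed <- sse / (a * n_per - a)
  sb_closed <- max(0, (ssa / a - sw_closed) / n_per)
  expect_equal(fit$sigma_within^2, sw_closed, tolerance = 1e-6)
  expect_equal(fit$sigma_between^2, sb_closed, tolerance = 1e-6)
})

test_that("random-intercept AICc comparison tracks the true group variance", {
  # no between-group variance in truth: random intercept rarely helps
  set.seed(57)
  no_help <- 0
  for (i in 1:50) {
    d <- data.frame(transect = rep(1:3, each = 12),
                    x = rnorm(36))
    d$y <- 1 + 0.5 * d$x + rnorm(36)
    cmpr <- lmm_compare_random(d, "y", fixed_terms = "x")
    if (cmpr$aicc_random >= cmpr$aicc_fixed) no_help <- no_help + 1
  }
  expect_gte(no_help / 50, 0.85)

  # strong transect offsets: the random intercept should win
  set.seed(58)
  helps <- 0
  for (i in 1:50) {
    d <- data.frame(transect = rep(1:3, each = 12), x = rnorm(36))
    d$y <- 1 + 0.5 * d$x + rnorm(3, 0, 5)[d$transect] + rnorm(36)
    cmpr <- lmm_compare_random(d, "y", fixed_terms = "x")
    if (cmpr$improved) helps <- helps + 1
  }
  expect_gte(helps / 50, 0.95)

  expect_error(lmm_random_intercept(
    data.frame(transect = rep(1, 10), y = rnorm(10)), "y"), "2 groups")
})
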