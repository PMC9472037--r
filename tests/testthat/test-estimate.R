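test_that("a deterministic relation gives coefficient 1 with a tight CI", {
  x <- rnorm(100)
  tab <- data.frame(x = x, y = x)
  # lm warns about the perfect fit; the perfect fit is the point here
  e <- suppressWarnings(estimate_effect(tab, "x", "y"))
  expect_equal(e$ce, 1, tolerance = 1e-10)
  expect_lt(e$ci_high - e$ci_low, 1e-8)
})

test_that("independent variables give a near-zero estimate", {
  set.seed(41)
  tab <- data.frame(x = rnorm(100000), y = rnorm(100000))
  e <- estimate_effect(tab, "x", "y")
  expect_lt(abs(e$ce), 0.02)
  expect_gt(e$p_value, 0)
})

test_that("adjustment removes confounding in the triangle SEM", {
  spec <- confounded_triangle(0.5, 0.5, 0.3)
  tab <- simulate_trips(spec, 200000, seed = 42)
  # unadjusted estimate picks up the backdoor path: c + a b = 0.55
  un <- estimate_effect(tab, "X", "Y")
  expect_equal(un$ce, 0.55, tolerance = 0.01 / 0.55)
  # adjusting for the confounder recovers the direct/total effect 0.30
  ad <- estimate_effect(tab, "X", "Y", adjust = "Z")
  expect_equal(ad$ce, 0.30, tolerance = 0.01 / 0.30)
})

test_that("estimates are invariant to covariate order and typed errors fire", {
  spec <- sem_table1()
  tab <- simulate_trips(spec, 2000, seed = 43)
  e1 <- estimate_effect(tab, "before_valence", "after_valence",
                        adjust = c("before_arousal", "occupants"))
  e2 <- estimate_effect(tab, "before_valence", "after_valence",
                        adjust = c("occupants", "before_arousal"))
  expect_equal(e1$ce, e2$ce, tolerance = 1e-12)

  expect_error(estimate_effect(tab, "nope", "speed"), "not in table")
  expect_error(estimate_effect(tab, "speed", "flow", adjust = "speed"),
               "source or target")
  tab$dup <- tab$speed
  expect_error(estimate_effect(tab, "speed", "after_arousal",
                               adjust = "dup"), "collinear")
  tiny <- tab[1:3, ]
  expect_error(estimate_effect(tiny, "speed", "after_arousal",
                               adjust = c("sun", "length")), "complete rows")
})

test_that("degrees of freedom follow n - |Z| - 2", {
  set.seed(44)
  n <- 30
  tab <- data.frame(x = rnorm(n), y = rnorm(n), z1 = rnorm(n),
                    z2 = rnorm(n))
  e <- estimate_effect(tab, "x", "y", adjust = c("z1", "z2"))
  fit <- lm(y ~ x + z1 + z2, data = tab)
  expect_equal(e$ce, unname(coef(fit)["x"]))
  ci <- confint(fit, "x", level = 0.95)
  expect_equal(c(e$ci_low, e$ci_high), unname(ci[1, ]))
  expect_equal(e$p_value, summary(fit)$coefficients["x", 4])
})

test_that("nominal 95% intervals achieve near-nominal coverage", {
  spec <- coverage_sem()
  dag <- dag_of(spec)
  adj <- minimal_backdoor_set(dag, "X", "Y")
  truth <- sem_total_effects(spec)["X", "Y"]
  hits <- 0L
  reps <- 500L
  for (r in seq_len(reps)) {
    tab <- simulate_trips(spec, 1000, seed = 4000 + r)
    e <- estimate_effect(tab, "X", "Y", adjust = adj)
    if (e$ci_low <= truth && truth <= e$ci_high) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.92)
  expect_lte(hits / reps, 0.98)
})

test_that("effect_table is unbiased for the preset's total effects", {
  spec <- sem_table1()
  dag <- dag_of(spec)
  truth <- sem_total_effects(spec)
  edges <- dag_edges(dag)
  reps <- 200L
  acc <- matrix(0, reps, nrow(edges))
  for (r in seq_len(reps)) {
    tab <- simulate_trips(spec, 5000, seed = 6000 + r)
    et <- effect_table(tab, dag)
    key <- paste(et$source, et$target)
    acc[r, ] <- et$ce[match(paste(edges$from, edges$to), key)]
  }
  means <- colMeans(acc)
  # the adjusted regression is consistent for the SEM's total effects (on
  # the model's native scale, where the estimates are structural)
  tru <- truth[cbind(match(edges$from, spec$labels),
                     match(edges$to, spec$labels))]
  expect_equal(means, tru, tolerance = 0.012)
})

test_that("effect_table handles empty and single-edge graphs", {
  tab <- data.frame(a = rnorm(50), b = rnorm(50))
  W0 <- matrix(0, 2, 2, dimnames = rep(list(c("a", "b")), 2))
  et0 <- effect_table(tab, causal_dag(W0))
  expect_equal(nrow(et0), 0)

  W1 <- W0; W1["a", "b"] <- 0.5
  et1 <- effect_table(tab, causal_dag(W1))
  expect_equal(nrow(et1), 1)
  expect_identical(et1$adjustment_set, "")
  expect_true(et1$identifiable)
})

test_that("rows follow the published grouping order", {
  spec <- sem_table1()
  tab <- simulate_trips(spec, 1638, seed = 45)
  et <- effect_table(tab, dag_of(spec))
  expect_equal(nrow(et), 15)
  grp <- unique(et$group)
  expect_equal(grp[1], "emotions on driving behavior")
  expect_true(match("driving behavior on emotions", grp) <
              match("emotions on emotions", grp))
  # true effects of 0.74 magnitude are flagged significant at n = 1638
  expect_true(et$significant[et$source == "before_arousal" &
                             et$target == "after_arousal"])
})

test_that("effect tables round-trip to CSV", {
  spec <- confounded_triangle()
  tab <- simulate_trips(spec, 500, seed = 46)
  et <- effect_table(tab, dag_of(spec))
  path <- tempfile(fileext = ".csv")
  write_effect_table(et, path)
  back <- read.csv(path)
  expect_equal(back$ce, et$ce, tolerance = 1e-12)
  expect_true(all(c("source", "target", "ce", "ci_low", "ci_high",
                    "p_value", "adjustment_set", "robustness_delta")
                  %in% names(back)))
})
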