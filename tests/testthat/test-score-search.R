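# Combination enumeration, score arithmetic, threshold evaluation, and the
# parsimony selection rules.

test_that("enumeration counts are exactly 2^k - 1 with deterministic order", {
  expect_length(enumerate_combinations("A"), 1)
  expect_length(enumerate_combinations(c("A", "B")), 3)
  for (k in c(3, 5, 8, 11, 15))
    expect_length(enumerate_combinations(paste0("g", sprintf("%02d", 1:k))),
                  2^k - 1)
  defs <- enumerate_combinations(c("B", "A", "C"))
  sizes <- vapply(defs, function(d) length(d$genes), 0)
  expect_equal(sizes, c(1, 1, 1, 2, 2, 2, 3))
  expect_equal(defs[[1]]$genes, "A")
  expect_equal(defs[[4]]$genes, c("A", "B"))
  expect_equal(defs[[7]]$genes, c("A", "B", "C"))
  expect_error(enumerate_combinations(paste0("g", 1:21)), "max_genes")
})

test_that("weights are attached from the pooled table by name", {
  w <- c(A = 0.5, B = -0.2)
  defs <- enumerate_combinations(c("A", "B"), weights = w)
  expect_equal(defs[[3]]$weights, c(0.5, -0.2))
  expect_error(enumerate_combinations(c("A", "C"), weights = w), "C")
})

test_that("compute_score matches hand-computed weighted sums", {
  m <- matrix(c(1, 2, 3,
                4, 5, 6,
                7, 8, 9,
                10, 11, 12), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  def <- score_definition(c("g1", "g2", "g3"), c(0.5, -0.2, 1.0),
                          scale = "raw")
  expected <- c(0.5 * 1 - 0.2 * 2 + 1 * 3,
                0.5 * 4 - 0.2 * 5 + 1 * 6,
                0.5 * 7 - 0.2 * 8 + 1 * 9,
                0.5 * 10 - 0.2 * 11 + 1 * 12)
  expect_equal(unname(compute_score(m, def)), expected)

  one <- score_definition("g2", 1, scale = "raw")
  expect_equal(compute_score(m, one), m["g2", ])
  zero <- score_definition(c("g1", "g3"), c(0, 0), scale = "raw")
  expect_equal(unname(compute_score(m, zero)), rep(0, 4))
  expect_error(compute_score(m, score_definition("nope", 1)), "nope")
})

test_that("compute_score is linear in the weights", {
  set.seed(10)
  m <- matrix(rnorm(40), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  g <- paste0("g", 1:4)
  w1 <- rnorm(4); w2 <- rnorm(4)
  s1 <- compute_score(m, score_definition(g, w1, scale = "raw"))
  s2 <- compute_score(m, score_definition(g, w2, scale = "raw"))
  s12 <- compute_score(m, score_definition(g, w1 + w2, scale = "raw"))
  expect_equal(s12, s1 + s2, tolerance = 1e-12)
})

search_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_multicohort(simulation_config(
        n_cohorts = 3, cohort_sizes = rep(200, 3), n_genes = 25,
        planted_genes = data.frame(gene = c("STRONG", "MILD"),
                                   beta = c(1.0, 0.5), affects_ep2 = TRUE),
        ep2_cohorts = 1, ep2_kinds = "DFS", seed = 321))
    }
    cache
  }
})

test_that("positive rescaling of the weights leaves the evaluation invariant", {
  sim <- search_fixture()
  def1 <- score_definition(c("STRONG", "MILD"), c(0.8, 0.4))
  def2 <- score_definition(c("STRONG", "MILD"), 3.7 * c(0.8, 0.4))
  e1 <- evaluate_score(def1, sim$cohorts)
  e2 <- evaluate_score(def2, sim$cohorts)
  keep <- setdiff(names(e1$per_cohort), "cutoff")  # cutoff scales with weights
  expect_equal(e1$per_cohort[keep], e2$per_cohort[keep], tolerance = 1e-9)
  expect_equal(e1$passes, e2$passes)
})

test_that("planted scores show strong per-cohort metrics; noise scores fail", {
  sim <- search_fixture()
  ev <- evaluate_score(score_definition("STRONG", 1), sim$cohorts)
  pc <- ev$per_cohort
  expect_true(all(pc$evaluable))
  expect_true(all(pc$uni_hr > 2 & pc$uni_p < 0.01))
  expect_true(all(pc$multi_hr > 1.5 & pc$multi_p < 0.01))
  expect_true(all(pc$auc > 0.6))
  # passes is the conjunction: it can only be TRUE when every per-cohort
  # metric clears its bar (the Youden-optimal cutoff may legitimately land
  # at an asymmetric operating point with sensitivity below 0.5)
  expect_equal(ev$passes,
               all(pc$sens > 0.5 & pc$spec > 0.5 & pc$auc > 0.5 &
                   pc$uni_hr > 2 & pc$uni_p < 0.05 &
                   pc$multi_hr > 1.5 & pc$multi_p < 0.05))

  fails <- 0
  for (s in 1:40) {
    nd <- simulate_multicohort(simulation_config(
      n_cohorts = 3, cohort_sizes = rep(150, 3), n_genes = 10,
      planted_genes = data.frame(gene = character(), beta = numeric(),
                                 affects_ep2 = logical()),
      ep2_cohorts = integer(), ep2_kinds = character(), seed = 7000 + s))
    evn <- evaluate_score(
      score_definition(c("G0001", "G0002"), c(0.7, 0.7)), nd$cohorts)
    if (!evn$passes) fails <- fails + 1
  }
  expect_gte(fails, 38)
})

test_that("unreachable thresholds always fail", {
  sim <- search_fixture()
  ev <- evaluate_score(score_definition("STRONG", 1), sim$cohorts,
                       thresholds = score_thresholds(uni_hr_min = Inf))
  expect_false(ev$passes)
})

test_that("selection keeps passers and parsimony breaks ties as documented", {
  fake_eval <- function(id, genes, passes, min_hr) {
    structure(list(score_id = id, genes = genes, n_genes = length(genes),
                   per_cohort = data.frame(uni_hr = min_hr + c(0, 0.5, 1)),
                   passes = passes, reason = ""),
              class = "score_evaluation")
  }
  evs <- list(
    fake_eval("a", paste0("g", 1:7), TRUE, 2.4),
    fake_eval("b", paste0("g", 1:8), TRUE, 3.0),
    fake_eval("c", paste0("g", 1:9), TRUE, 3.0),
    fake_eval("d", paste0("g", 1:3), FALSE, 5.0))
  passing <- select_scores(evs)
  expect_length(passing, 3)
  pick <- pick_parsimonious(passing)
  expect_equal(pick$score_id, "a")           # fewest genes wins

  evs2 <- list(fake_eval("x", c("gB", "gC"), TRUE, 2.1),
               fake_eval("y", c("gA", "gD"), TRUE, 2.4))
  expect_equal(pick_parsimonious(select_scores(evs2))$score_id, "y")  # min-HR

  evs3 <- list(fake_eval("p", c("gB", "gC"), TRUE, 2.0),
               fake_eval("q", c("gA", "gD"), TRUE, 2.0))
  expect_equal(pick_parsimonious(select_scores(evs3))$score_id, "q")  # lexicographic

  none <- pick_parsimonious(select_scores(list(fake_eval("z", "g", FALSE, 9))))
  expect_false(none$found)
  expect_match(none$reason, "no score passed")
})

test_that("search_scores evaluates every combination deterministically", {
  sim <- search_fixture()
  pooled <- data.frame(gene = c("MILD", "STRONG"), beta_pooled = c(0.5, 1.0))
  evs <- search_scores(pooled, sim$cohorts, verbose = FALSE)
  expect_length(evs, 3)
  single <- evaluate_score(score_definition("STRONG", 1.0), sim$cohorts)
  batch <- evs[[which(vapply(evs, function(e)
    identical(e$genes, "STRONG"), logical(1)))]]
  expect_equal(batch$per_cohort$uni_hr, single$per_cohort$uni_hr,
               tolerance = 1e-10)
})
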