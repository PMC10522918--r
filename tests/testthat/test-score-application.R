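# Normalization/categorization, TNM integration, external-signature
# benchmarking, and drug-sensitivity correlation.

test_that("median normalization and half-open category boundaries are exact", {
  sc <- data.frame(cohort = "A", sample_id = paste0("s", 1:3),
                   score = c(2, 4, 6))
  out <- normalize_and_categorize(sc)
  expect_equal(out$normalized, c(0.5, 1.0, 1.5))
  expect_equal(as.character(out$category), c("low", "intermediate", "high"))

  sc2 <- data.frame(cohort = "A", sample_id = paste0("s", 1:5),
                    score = c(0.9, 1.1, 1, 0.89999, 1.10001))
  out2 <- normalize_and_categorize(sc2)   # median 1 -> normalized = raw
  expect_equal(as.character(out2$category),
               c("intermediate", "high", "intermediate", "low", "high"))

  all_eq <- data.frame(cohort = "B", sample_id = paste0("s", 1:4), score = 3)
  out3 <- normalize_and_categorize(all_eq)
  expect_true(all(out3$normalized == 1))
  expect_true(all(out3$category == "intermediate"))

  neg <- data.frame(cohort = "C", sample_id = paste0("s", 1:3),
                    score = c(-1, 0, 1))
  expect_error(normalize_and_categorize(neg), "non-positive median")
})

test_that("normalized medians are 1 and categories are scale-invariant", {
  set.seed(52)
  for (n in c(7, 8, 51, 100)) {
    sc <- data.frame(cohort = "A", sample_id = seq_len(n),
                     score = rlnorm(n, 1, 0.4))
    out <- normalize_and_categorize(sc)
    expect_equal(median(out$normalized), 1, tolerance = 1e-12)
    out_scaled <- normalize_and_categorize(transform(sc, score = score * 37.5))
    expect_equal(as.character(out$category), as.character(out_scaled$category))
  }
})

test_that("per-cohort medians are independent", {
  sc <- rbind(
    data.frame(cohort = "A", sample_id = paste0("a", 1:3), score = c(2, 4, 6)),
    data.frame(cohort = "B", sample_id = paste0("b", 1:3), score = c(20, 40, 60)))
  out <- normalize_and_categorize(sc)
  expect_equal(out$normalized[out$cohort == "A"],
               out$normalized[out$cohort == "B"])
})

test_that("integrate_tnm applies the map, audits groups, and flags gaps", {
  set.seed(60)
  n <- 400
  stage <- sample(c("I", "II", "IIIA", "IIIB", "IV"), n, replace = TRUE)
  category <- sample(c("low", "intermediate", "high"), n, replace = TRUE,
                     prob = c(0.4, 0.3, 0.3))
  risk <- match(stage, c("I", "II", "IIIA", "IIIB", "IV")) +
    2 * (category == "high")
  t <- rexp(n, 0.01 * exp(0.5 * risk))
  e <- rbinom(n, 1, 0.8)
  res <- integrate_tnm(stage, category, t, e)
  expect_equal(nrow(res$assignments), n)
  expect_setequal(res$group_summary$group,
                  c("favorable", "intermediate", "adverse", "very-adverse"))
  expect_equal(nrow(res$pairwise), 6)
  # strongly prognostic construction -> medians ordered across groups
  med <- res$group_summary
  ord <- match(c("favorable", "intermediate", "adverse", "very-adverse"),
               med$group)
  m <- ifelse(is.na(med$median_os[ord]), Inf, med$median_os[ord])
  expect_true(all(diff(m) <= 0))

  expect_error(integrate_tnm(c("I", "X9"), c("low", "low"), c(5, 6), c(1, 1)),
               "X9")
})

test_that("a degenerate stage-only map reproduces stage-only stratification", {
  set.seed(61)
  n <- 150
  stage <- sample(c("I", "II", "IV"), n, replace = TRUE)
  category <- sample(c("low", "intermediate", "high"), n, replace = TRUE)
  t <- rexp(n, 0.05)
  e <- rbinom(n, 1, 0.7)
  idmap <- expand.grid(stage = c("I", "II", "IV"),
                       category = c("low", "intermediate", "high"),
                       stringsAsFactors = FALSE)
  idmap$group <- idmap$stage
  res <- integrate_tnm(stage, category, t, e, map = idmap)
  expect_identical(res$assignments$group, stage)
  for (s in c("I", "II", "IV")) {
    km_direct <- km_estimate(t[stage == s], e[stage == s])
    row <- res$group_summary[res$group_summary$group == s, ]
    expect_identical(row$median_os, km_direct$median)
  }
  lr_direct <- logrank_test(stage, t, e)
  expect_equal(res$pairwise$p[1],
               logrank_test(stage[stage %in% c("I", "II")],
                            t[stage %in% c("I", "II")],
                            e[stage %in% c("I", "II")])$p)
})

sig_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_multicohort(simulation_config(
        n_cohorts = 3, cohort_sizes = rep(220, 3), n_genes = 30,
        planted_genes = data.frame(gene = c("SIGA", "SIGB", "SIGC"),
                                   beta = rep(0.8, 3), affects_ep2 = TRUE),
        ep2_cohorts = 1, ep2_kinds = "DFS", seed = 123))
    }
    cache
  }
})

test_that("a truly prognostic signature is robust under tertile evaluation", {
  sim <- sig_fixture()
  sig <- list(signature_id = "planted", genes = c("SIGA", "SIGB", "SIGC"),
              weights = rep(1, 3))
  res <- evaluate_external_signature(sig, sim$cohorts)
  expect_true(all(res$table$evaluable))
  expect_true(res$robust)
  expect_true(all(res$table$hr > 1))
})

test_that("random signatures are rarely robust; absent genes mark cohorts not-evaluable", {
  sim <- sig_fixture()
  set.seed(9)
  robust_count <- 0
  for (i in 1:20) {
    genes <- sample(grep("^G", rownames(sim$cohorts[[1]]$expression),
                         value = TRUE), 4)
    sig <- list(signature_id = paste0("rand", i), genes = genes,
                weights = rnorm(4))
    res <- evaluate_external_signature(sig, sim$cohorts)
    robust_count <- robust_count + res$robust
  }
  expect_lte(robust_count, 2)

  ghost <- list(signature_id = "ghost", genes = paste0("ZZ", 1:5),
                weights = rep(1, 5))
  res <- evaluate_external_signature(ghost, sim$cohorts)
  expect_false(any(res$table$evaluable))
  expect_false(res$robust)
  expect_match(res$table$reason[1], "coverage")

  partial <- list(signature_id = "partial",
                  genes = c("SIGA", "SIGB", "SIGC", "ZZ1", "ZZ2"),
                  weights = rep(1, 5))
  res2 <- evaluate_external_signature(partial, sim$cohorts)
  expect_true(all(res2$table$coverage == 0.6))
  expect_true(all(res2$table$evaluable))
})

test_that("drug correlation applies the conjunction rule and handles ties", {
  set.seed(30)
  score <- setNames(rnorm(16), sprintf("LINE%02d", 1:16))
  ic50 <- matrix(NA_real_, 3, 16,
                 dimnames = list(c("mono", "weak", "tied"), names(score)))
  ic50["mono", ] <- -rank(score)        # strictly decreasing in score
  ic50["weak", ] <- -0.3 * scale(score) + rnorm(16)
  ic50["tied", ] <- 5
  expect_warning(res <- drug_correlation(score, ic50), "all-tied")
  expect_equal(res$rho[res$drug == "mono"], -1)
  expect_true(res$hit[res$drug == "mono"])
  weak <- res[res$drug == "weak", ]
  if (!is.na(weak$rho) && abs(weak$rho) > 0.25 && weak$p >= 0.05)
    expect_false(weak$hit)
  expect_false(res$hit[res$drug == "tied"])
  expect_error(drug_correlation(score[1:5], ic50[, 1:5]), ">= 8")
})
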