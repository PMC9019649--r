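# frozen expected value for the 5-item, 2-rater matrix, computed with
# the Hoyt ANOVA oracle (and by hand: alpha = 8 / 8.3)
alpha_fixture <- matrix(c(1, 2, 3, 4, 5,
                          2, 2, 4, 4, 5), ncol = 2)

test_that("cronbach_alpha: perfect agreement, frozen fixture, Feldt CI", {
  dup <- cbind(c(1, 3, 5, 2, 4), c(1, 3, 5, 2, 4))
  expect_equal(cronbach_alpha(dup)$alpha, 1.0)

  ca <- cronbach_alpha(alpha_fixture)
  expect_equal(ca$alpha, 8 / 8.3, tolerance = 1e-12)
  expect_equal(ca$alpha, oracle_alpha(alpha_fixture), tolerance = 1e-12)

  # Feldt CI from first principles: (1 - alpha) scaled by F quantiles
  n <- 5; k <- 2
  expect_equal(ca$ci[1], 1 - (1 - 8 / 8.3) * qf(0.975, n - 1, (n - 1) * (k - 1)))
  expect_equal(ca$ci[2], 1 - (1 - 8 / 8.3) * qf(0.025, n - 1, (n - 1) * (k - 1)))
  expect_lt(ca$ci[1], ca$alpha)
  expect_gt(ca$ci[2], ca$alpha)
})

test_that("cronbach_alpha is ~0 for an independent shuffle of 1000 items", {
  set.seed(2024)
  r1 <- sample(1:5, 1000, replace = TRUE)
  r2 <- sample(r1) # same margin, independent order
  expect_lt(abs(cronbach_alpha(cbind(r1, r2))$alpha), 0.1)
})

test_that("cronbach_alpha invariances and degenerate input", {
  set.seed(5)
  X <- matrix(sample(1:5, 30, replace = TRUE), ncol = 3)
  a0 <- cronbach_alpha(X)$alpha
  # invariant to adding a constant to ALL columns
  expect_equal(cronbach_alpha(X + 2)$alpha, a0, tolerance = 1e-12)
  # but NOT (in general) to shifting a single rater's scale relative to
  # the item ordering: alpha depends only on variances/covariances, so a
  # single-column constant shift also leaves it unchanged -- the real
  # non-invariance is to rescaling one column
  expect_false(isTRUE(all.equal(cronbach_alpha(cbind(X[, 1] * 3, X[, -1]))$alpha,
                                a0)))
  # rater relabeling leaves alpha unchanged
  expect_equal(cronbach_alpha(X[, c(3, 1, 2)])$alpha, a0, tolerance = 1e-12)

  expect_warning(out <- cronbach_alpha(matrix(2, 4, 2)), "zero total variance")
  expect_true(is.na(out$alpha))
  expect_error(cronbach_alpha(matrix(1:4, ncol = 2)), "three items")
  expect_error(cronbach_alpha(matrix(1:4, ncol = 1)), "two raters")
})

make_records <- function(df) {
  structure(list(records = data.table::as.data.table(df),
                 needs_rating = data.table::data.table(),
                 threshold = 1.5),
            class = "collocate_records")
}

test_that("annual_sas: type and token weighting", {
  lex <- as_rating_lexicon(data.frame(
    word = c("bad", "mid", "good"), relevant = 1L,
    s_rater1 = c(1L, 3L, 5L), s_rater2 = c(1L, 3L, 5L),
    m_rater1 = c(1L, 0L, 0L), m_rater2 = c(1L, 0L, 0L)))
  rec <- make_records(data.frame(
    year = 2010L, word = c("bad", "mid", "good"), f_near = c(1L, 1L, 1L),
    mi = 2, relevant = TRUE, retained = TRUE))
  expect_equal(annual_sas(rec, lex)$sas, 3.0)
  expect_equal(annual_sas(rec, lex, weighting = "token")$sas, 3.0)

  # fixture year: mean 1.0 with F_near 2, mean 5.0 with F_near 6
  rec2 <- make_records(data.frame(
    year = 2011L, word = c("bad", "good"), f_near = c(2L, 6L),
    mi = 2, relevant = TRUE, retained = TRUE))
  expect_equal(annual_sas(rec2, lex)$sas, 3.0)
  expect_equal(annual_sas(rec2, lex, weighting = "token")$sas, 4.0)

  # adding a collocate rated at the current mean leaves type-weighted
  # SAS unchanged
  rec3 <- make_records(data.frame(
    year = 2011L, word = c("bad", "good", "mid"), f_near = c(2L, 6L, 1L),
    mi = 2, relevant = TRUE, retained = TRUE))
  expect_equal(annual_sas(rec3, lex)$sas, 3.0)
})

test_that("annual_medicalization: proportions and disagreement", {
  lex <- as_rating_lexicon(data.frame(
    word = c("w1", "w2", "w3", "w4", "w5"), relevant = 1L,
    s_rater1 = 3L, s_rater2 = 3L,
    m_rater1 = c(1L, 1L, 1L, 0L, 0L), m_rater2 = c(1L, 1L, 1L, 0L, 0L)))
  rec <- make_records(data.frame(
    year = 2010L, word = paste0("w", 1:5), f_near = 1L, mi = 2,
    relevant = TRUE, retained = TRUE))
  expect_equal(annual_medicalization(rec, lex)$med, 0.6)

  # all medical -> 1, none -> 0
  all_m <- as_rating_lexicon(data.frame(
    word = c("w1", "w2"), relevant = 1L, s_rater1 = 3L, s_rater2 = 3L,
    m_rater1 = 1L, m_rater2 = 1L))
  rec2 <- make_records(data.frame(
    year = 2010L, word = c("w1", "w2"), f_near = 1L, mi = 2,
    relevant = TRUE, retained = TRUE))
  expect_equal(annual_medicalization(rec2, all_m)$med, 1.0)

  none <- as_rating_lexicon(data.frame(
    word = c("w1", "w2"), relevant = 1L, s_rater1 = 3L, s_rater2 = 3L,
    m_rater1 = 0L, m_rater2 = 0L))
  expect_equal(annual_medicalization(rec2, none)$med, 0.0)
})

test_that("years with zero retained collocates give NA plus warning", {
  lex <- as_rating_lexicon(data.frame(
    word = "good", relevant = 1L, s_rater1 = 5L, s_rater2 = 5L,
    m_rater1 = 0L, m_rater2 = 0L))
  rec <- make_records(data.frame(
    year = c(2010L, 2011L), word = "good", f_near = 1L, mi = c(2, 1.2),
    relevant = TRUE, retained = c(TRUE, FALSE)))
  expect_warning(sas <- annual_sas(rec, lex), "2011")
  expect_equal(sas$sas, c(5, NA))
})

test_that("scores stay inside their ranges on random inputs", {
  set.seed(31)
  for (rep in 1:10) {
    nw <- sample(3:12, 1)
    lex <- as_rating_lexicon(data.frame(
      word = paste0("w", 1:nw), relevant = 1L,
      s_rater1 = sample(1:5, nw, TRUE), s_rater2 = sample(1:5, nw, TRUE),
      m_rater1 = sample(0:1, nw, TRUE), m_rater2 = sample(0:1, nw, TRUE)))
    rec <- make_records(data.frame(
      year = 2010L, word = paste0("w", 1:nw),
      f_near = sample(1:9, nw, TRUE), mi = 2, relevant = TRUE,
      retained = TRUE))
    for (wgt in c("type", "token")) {
      s <- annual_sas(rec, lex, weighting = wgt)$sas
      m <- annual_medicalization(rec, lex, weighting = wgt)$med
      expect_true(s >= 1 && s <= 5)
      expect_true(m >= 0 && m <= 1)
    }
  }
})

test_that("build_panel codes the policy step and validates coverage", {
  sas <- data.frame(year = 2010:2017, sas = 3, n_collocates = 10L)
  med <- data.frame(year = 2010:2017, med = 0.4, n_collocates = 10L)
  cov <- read.delim(ext_path("covariates_support_ratio_synthetic.tsv"))
  panel <- build_panel(sas, med, cov, policy_year = 2014)
  expect_equal(panel$policy, c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L))
  expect_equal(panel$support_ratio[c(1, 8)], c(7.4, 5.1))
  # the packaged trajectory declines by more than 30%
  decline <- (7.4 - 5.1) / 7.4 * 100
  expect_gt(decline, 30)

  expect_error(
    build_panel(data.frame(year = 2009, sas = 3, n_collocates = 1L),
                data.frame(year = 2009, med = 0, n_collocates = 1L),
                cov, policy_year = 2014),
    "covariates missing")

  one <- build_panel(data.frame(year = 2012, sas = 3, n_collocates = 1L),
                     data.frame(year = 2012, med = 0, n_collocates = 1L),
                     cov, policy_year = 2014)
  expect_equal(nrow(one), 1L)
  expect_error(polynomial_trend(one, "sas", 2), "at least")
})

test_that("panel validation enforces invariants", {
  bad <- data.frame(year = c(2010, 2010), sas = 3, med = 0.1,
                    policy = 0L, support_ratio = 7)
  expect_error(as_annual_panel(bad), "duplicate years")
  bad2 <- data.frame(year = 2010:2012, sas = c(3, 3, 6), med = 0.1,
                     policy = 0L, support_ratio = 7)
  expect_error(as_annual_panel(bad2), "sas outside")
  bad3 <- data.frame(year = 2010:2012, sas = 3, med = 0.1,
                     policy = c(1L, 0L, 0L), support_ratio = 7)
  expect_error(as_annual_panel(bad3), "non-decreasing")
})

test_that("panel round-trips through TSV", {
  res <- suppressMessages(fixture_bundle())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(res$panel, path)
  expect_equal(as.data.frame(read_panel(path)), as.data.frame(res$panel))
})
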